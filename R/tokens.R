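# Residue token registry and physicochemical scales.
#
# The alphabet is the 20 canonical one-letter codes plus registered extended
# tokens (multi-character, serialized in brackets, e.g. "[Aib]").  Every
# extended token maps to a canonical "surrogate" used wherever a scale or a
# matching policy needs a canonical residue type.

CANONICAL_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.tokens <- new.env(parent = emptyenv())
.tokens$extended <- list(Aib = "A")  # 2-aminoisobutyric acid; Ala surrogate

#' Register an extended (non-canonical) residue token
#'
#' Extended tokens are multi-character residue names such as `"Aib"`
#' (2-aminoisobutyric acid).  They are serialized in brackets in FASTA
#' (`"[Aib]"`) and carry a canonical surrogate residue used for
#' physicochemical scales and for the sequence-matching policy
#' (an extended token matches itself and its surrogate).
#'
#' @param token character scalar, the token name (e.g. `"Aib"`).
#' @param surrogate one of the 20 canonical one-letter codes.
#' @return `token`, invisibly.
#' @export
#' @examples
#' register_token("Nle", "L")
register_token <- function(token, surrogate) {
  stopifnot(is.character(token), length(token) == 1L, nchar(token) > 1L)
  if (!surrogate %in% CANONICAL_AA)
    stop("surrogate must be a canonical one-letter code, got '", surrogate, "'")
  .tokens$extended[[token]] <- surrogate
  invisible(token)
}

#' @rdname register_token
#' @export
registered_tokens <- function() {
  c(CANONICAL_AA, names(.tokens$extended))
}

is_registered_token <- function(tok) {
  tok %in% CANONICAL_AA | tok %in% names(.tokens$extended)
}

#' Canonical surrogate of residue tokens
#'
#' Canonical tokens map to themselves; registered extended tokens map to
#' their canonical surrogate (Aib -> A).
#'
#' @param tokens character vector of residue tokens.
#' @return character vector of canonical one-letter codes.
#' @export
canonical_token <- function(tokens) {
  out <- tokens
  ext <- !(tokens %in% CANONICAL_AA)
  if (any(ext)) {
    sur <- unlist(.tokens$extended[tokens[ext]], use.names = FALSE)
    if (length(sur) != sum(ext) || anyNA(sur))
      stop("unregistered residue token(s): ",
           paste(unique(tokens[ext][!is_registered_token(tokens[ext])]),
                 collapse = ", "))
    out[ext] <- sur
  }
  out
}

#' Token equivalence under the matching policy
#'
#' Two tokens match iff their canonical surrogates are equal, so `"Aib"`
#' matches both `"Aib"` and `"A"`.  This is the policy used by [recovery()]
#' and by alignment identity.
#'
#' @param a,b character vectors of residue tokens (recycled).
#' @return logical vector.
#' @export
tokens_match <- function(a, b) {
  canonical_token(a) == canonical_token(b)
}

# ---- scales ----------------------------------------------------------------

#' Default pKa table (EMBOSS values)
#'
#' N-terminus 8.6, C-terminus 3.6; side chains C 8.5, D 3.9, E 4.1, H 6.5,
#' K 10.8, R 12.5, Y 10.1.  Used by [net_charge()] and
#' [isoelectric_point()]; any list with the same shape can be substituted.
#'
#' @return list with elements `nterm`, `cterm` and named vector `sidechain`.
#' @export
pka_default <- function() {
  list(nterm = 8.6, cterm = 3.6,
       sidechain = c(C = 8.5, D = 3.9, E = 4.1, H = 6.5,
                     K = 10.8, R = 12.5, Y = 10.1))
}

#' Kyte-Doolittle hydropathy scale
#' @return named numeric vector over the 20 canonical residues.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Helix propensity scale
#'
#' Negated Pace-Scholtz helix free energies (kcal/mol) so that larger values
#' mean stronger helix formers: Ala 0, Gly -1.0, Pro -3.16.  A minimum bound
#' on the mean over a sequence is a helicity requirement.
#'
#' @return named numeric vector over the 20 canonical residues.
#' @export
helix_scale_default <- function() {
  -c(A = 0.00, L = 0.21, R = 0.21, M = 0.24, K = 0.26, Q = 0.39, E = 0.40,
     I = 0.41, W = 0.49, S = 0.50, Y = 0.53, F = 0.54, V = 0.61, H = 0.61,
     N = 0.65, T = 0.66, C = 0.68, D = 0.69, G = 1.00, P = 3.16)
}

#' Normalized hydrophobicity for SAP (Black-Mould, Gly-centered)
#'
#' Black & Mould hydrophobicities normalized to \[0,1\] and shifted so that
#' glycine sits at zero; hydrophilic residues are negative, so buried or
#' hydrophilic surface contributes nothing positive to the SAP sum.
#'
#' @return named numeric vector over the 20 canonical residues.
#' @export
sap_hydrophobicity_default <- function() {
  bm <- c(A = 0.616, C = 0.680, D = 0.028, E = 0.043, F = 1.000, G = 0.501,
          H = 0.165, I = 0.943, K = 0.283, L = 0.943, M = 0.738, N = 0.236,
          P = 0.711, Q = 0.251, R = 0.000, S = 0.359, T = 0.450, V = 0.825,
          W = 0.878, Y = 0.880)
  bm - bm[["G"]]
}

#' Reference maximum residue SASA (theoretical Gly-X-Gly)
#'
#' Tien et al. theoretical maxima in A^2, used to turn an observed
#' side-chain SASA into an exposed fraction.
#'
#' @return named numeric vector over the 20 canonical residues.
#' @export
max_sasa_default <- function() {
  c(A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225, G = 104,
    H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
    T = 172, W = 285, Y = 263, V = 174)
}

# van der Waals radii by element (A); unknown elements fall back to 1.8
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90)

vdw_radius <- function(element) {
  el <- toupper(trimws(element))
  r <- VDW_RADII[el]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(el[is.na(r)]), collapse = ", "),
            "; using 1.8 A fallback radius")
    r[is.na(r)] <- 1.8
  }
  unname(r)
}

# look a token up in a canonical-residue scale (extended tokens through the
# surrogate); error if absent
scale_value <- function(tokens, scale, what = "scale") {
  keys <- canonical_token(tokens)
  miss <- setdiff(unique(keys), names(scale))
  if (length(miss))
    stop("token(s) not covered by ", what, ": ", paste(miss, collapse = ", "))
  unname(scale[keys])
}

# 1-letter (token) <-> 3-letter residue names for PDB serialization
AA_1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

token_to_resname <- function(tokens) {
  out <- ifelse(nchar(tokens) > 1L, toupper(substr(tokens, 1L, 3L)),
                AA_1TO3[tokens])
  unname(out)
}

resname_to_token <- function(resname) {
  rn <- toupper(trimws(resname))
  inv <- stats::setNames(names(AA_1TO3), AA_1TO3)
  out <- inv[rn]
  # extended tokens serialize as their (upper-cased) first three letters
  ext <- names(.tokens$extended)
  names(ext) <- toupper(substr(ext, 1L, 3L))
  out[is.na(out)] <- ext[rn[is.na(out)]]
  unname(out)
}
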