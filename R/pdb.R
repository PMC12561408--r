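# Structure model: fixed-column PDB input (via bio3d) with per-residue
# confidence read from the B-factor column (the AF2 pLDDT convention), and a
# minimal fixed-format writer for fixtures.

#' Structure model
#'
#' Atomic coordinates grouped by chain and residue, with a per-residue
#' confidence (pLDDT) taken from the B-factor of the C-alpha atom.
#'
#' @param atoms data frame with columns `serial`, `atom`, `resname`,
#'   `chain`, `resno`, `x`, `y`, `z`, `b`, `element`.
#' @return object of class `structure_model`: `atoms` plus `plddt`, a data
#'   frame (`chain`, `resno`, `plddt`).
#' @export
structure_model <- function(atoms) {
  need <- c("serial", "atom", "resname", "chain", "resno",
            "x", "y", "z", "b", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty model")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  ca <- atoms[atoms$atom == "CA", ]
  plddt <- data.frame(chain = ca$chain, resno = ca$resno, plddt = ca$b)
  if (anyDuplicated(plddt[, c("chain", "resno")]))
    stop("residue numbers not unique within a chain")
  structure(list(atoms = atoms, plddt = plddt), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", nrow(x$atoms), " atoms, chains: ",
      paste(unique(x$atoms$chain), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a PDB file into a structure model
#'
#' Parses fixed-column ATOM/HETATM records (through `bio3d`), keeping
#' altloc blank or `'A'` only, and stores the C-alpha B-factor as the
#' residue pLDDT.  ATOM lines shorter than the coordinate columns raise an
#' error naming the line number.
#'
#' @param path PDB file path.
#' @return a [structure_model()].
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  short <- which(rec & nchar(lines) < 54L)
  if (length(short))
    stop("ATOM record shorter than coordinate columns at line ", short[1])
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (nrow(at) == 0L) stop("empty model: ", path)
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(!nzchar(trimws(el))))
    el <- substr(trimws(at$elety), 1L, 1L)
  el[is.na(el) | !nzchar(trimws(el))] <-
    substr(trimws(at$elety[is.na(el) | !nzchar(trimws(el))]), 1L, 1L)
  chain <- at$chain
  chain[is.na(chain)] <- "A"
  structure_model(data.frame(serial = at$eleno, atom = trimws(at$elety),
                             resname = trimws(at$resid), chain = chain,
                             resno = at$resno,
                             x = at$x, y = at$y, z = at$z, b = at$b,
                             element = trimws(el)))
}

#' Write a structure model as fixed-format PDB
#'
#' Minimal writer for fixtures and interchange; round-trips through
#' [read_pdb()] with coordinates at 3 decimals and B-factors at 2.
#'
#' @param model a [structure_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  name <- ifelse(nchar(a$atom) < 4L, sprintf(" %-3s", a$atom),
                 sprintf("%-4s", a$atom))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial, name, a$resname, a$chain, a$resno,
    a$x, a$y, a$z, 1.0, a$b, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# coordinate matrix of one atom type for one chain, ordered by resno
chain_coords <- function(model, chain, atom = "CA") {
  a <- model$atoms
  sel <- a[a$chain == chain & a$atom == atom, , drop = FALSE]
  sel <- sel[order(sel$resno), , drop = FALSE]
  m <- as.matrix(sel[, c("x", "y", "z")])
  rownames(m) <- sel$resno
  m
}

#' Mean pLDDT of a chain
#'
#' Arithmetic mean of the per-residue confidence (B-factor of C-alpha,
#' 0-100) over one chain.
#'
#' @param model a [structure_model()].
#' @param chain chain identifier.
#' @return numeric in \[0, 100\].
#' @export
mean_plddt <- function(model, chain = "A") {
  p <- model$plddt[model$plddt$chain == chain, "plddt"]
  if (length(p) == 0L) stop("chain '", chain, "' absent or has no C-alpha")
  mean(p)
}

#' Replace the per-residue confidence of a model
#'
#' Overwrites the pLDDT table (and the B-factors of the matching C-alpha
#' atoms) with supplied values, e.g. from [mock_confidence()].
#'
#' @param model a [structure_model()].
#' @param plddt data frame with `chain`, `resno`, `plddt`.
#' @return the updated model.
#' @export
set_plddt <- function(model, plddt) {
  key <- paste(plddt$chain, plddt$resno)
  i <- match(paste(model$plddt$chain, model$plddt$resno), key)
  if (anyNA(i)) stop("plddt table does not cover every residue")
  model$plddt$plddt <- plddt$plddt[i]
  ca <- model$atoms$atom == "CA"
  j <- match(paste(model$atoms$chain[ca], model$atoms$resno[ca]), key)
  model$atoms$b[ca] <- plddt$plddt[j]
  model
}
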