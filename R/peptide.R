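# Peptide records with template-relative numbering, the Semaglutide template,
# design masks, sequence recovery and deduplication.

#' Peptide record
#'
#' A peptide sequence as an ordered vector of residue tokens with
#' template-relative numbering.  Position of residue `i` is
#' `numbering_start + i - 1`; the GLP-1 convention numbers the mature
#' peptide 7-37, so the default start is 7.
#'
#' @param id character scalar identifier.
#' @param residues character vector of residue tokens, or a single string in
#'   the bracket dialect (`"H[Aib]EGT"`), parsed with [parse_token_string()].
#' @param numbering_start integer, template position of the first residue.
#' @param annotations named list of free-form metadata strings.
#' @return object of class `peptide_record`.
#' @export
#' @examples
#' peptide_record("sema", "H[Aib]EGTFTSDVSSYLEGQAAKEFIAWLVRGRG")
peptide_record <- function(id, residues, numbering_start = 7L,
                           annotations = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.character(residues) && length(residues) == 1L &&
      (nchar(residues) > 1L || grepl("\\[", residues)))
    residues <- parse_token_string(residues)
  if (length(residues) == 0L) stop("residues must be non-empty")
  bad <- !is_registered_token(residues)
  if (any(bad))
    stop("unregistered residue token(s): ",
         paste(unique(residues[bad]), collapse = ", "))
  structure(list(id = id, residues = as.character(residues),
                 numbering_start = as.integer(numbering_start),
                 annotations = annotations),
            class = "peptide_record")
}

#' @export
print.peptide_record <- function(x, ...) {
  cat("<peptide_record> ", x$id, "  positions ", x$numbering_start, "-",
      x$numbering_start + length(x$residues) - 1L, "\n  ",
      token_string(x$residues), "\n", sep = "")
  invisible(x)
}

#' @export
length.peptide_record <- function(x) length(x$residues)

#' Template positions covered by a record
#' @param record a [peptide_record()].
#' @return integer vector of template positions.
#' @export
record_positions <- function(record) {
  record$numbering_start + seq_along(record$residues) - 1L
}

#' Parse / serialize the bracket token dialect
#'
#' `parse_token_string("H[Aib]EGT")` yields `c("H", "Aib", "E", "G", "T")`;
#' `token_string()` is its inverse, bracketing multi-character tokens.
#'
#' @param x a single string (parse) or token vector (serialize).
#' @param allow_gaps if `TRUE`, `-` is passed through (alignment rows).
#' @return character vector of tokens, or a single string.
#' @export
parse_token_string <- function(x, allow_gaps = FALSE) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(x, "")[[1]]
  tokens <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) stop("unterminated '[' in sequence: ", x)
      tokens <- c(tokens, paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1L
    }
  }
  ok <- is_registered_token(tokens) | (allow_gaps & tokens == "-")
  if (any(!ok))
    stop("unregistered token '", tokens[!ok][1], "' in sequence: ", x)
  tokens
}

#' @rdname parse_token_string
#' @export
token_string <- function(x) {
  paste(ifelse(nchar(x) > 1L, paste0("[", x, "]"), x), collapse = "")
}

#' Template specification
#'
#' A template peptide plus the set of anchored (fixed) positions; the
#' required residue at each anchored position is the template's own token
#' there.
#'
#' @param template a [peptide_record()].
#' @param anchored_positions integer vector of template positions to fix.
#' @return object of class `template_spec`.
#' @export
template_spec <- function(template, anchored_positions = integer()) {
  stopifnot(inherits(template, "peptide_record"))
  anchored_positions <- sort(unique(as.integer(anchored_positions)))
  pos <- record_positions(template)
  out <- setdiff(anchored_positions, pos)
  if (length(out))
    stop("anchored position(s) outside template range: ",
         paste(out, collapse = ", "))
  structure(list(template = template, anchored_positions = anchored_positions),
            class = "template_spec")
}

#' Built-in GLP-1(7-37) and Semaglutide templates
#'
#' `glp1_7_37()` is canonical GLP-1(7-37) (Ala8, Lys34).
#' `semaglutide_template()` is the Semaglutide backbone: GLP-1(7-37) with
#' Aib at position 8 and Arg at 34 (the Lys26 fatty-acid conjugation is
#' metadata, not a residue change).  `semaglutide_spec()` pairs the
#' template with the 13 anchored positions
#' 7, 8, 9, 10, 11, 12, 13, 14, 15, 17, 26, 34, 37.
#'
#' @return a [peptide_record()] / [template_spec()].
#' @export
semaglutide_template <- function() {
  peptide_record("Semaglutide", "H[Aib]EGTFTSDVSSYLEGQAAKEFIAWLVRGRG",
                 numbering_start = 7L,
                 annotations = list(conjugation = "C18 fatty acid at K26"))
}

#' @rdname semaglutide_template
#' @export
glp1_7_37 <- function() {
  peptide_record("GLP-1(7-37)", "HAEGTFTSDVSSYLEGQAAKEFIAWLVKGRG",
                 numbering_start = 7L)
}

#' @rdname semaglutide_template
#' @export
glp1_anchors <- function() {
  c(7L, 8L, 9L, 10L, 11L, 12L, 13L, 14L, 15L, 17L, 26L, 34L, 37L)
}

#' @rdname semaglutide_template
#' @export
semaglutide_spec <- function() {
  template_spec(semaglutide_template(), glp1_anchors())
}

#' Build the design mask from a template specification
#'
#' Fixed positions are the anchors; designable positions are the rest of the
#' template range.  The two sets always partition the template positions.
#'
#' @param spec a [template_spec()].
#' @return object of class `design_mask` with integer sets `fixed` and
#'   `designable`.
#' @export
#' @examples
#' mask <- build_design_mask(semaglutide_spec())
#' length(mask$designable)  # 18
build_design_mask <- function(spec) {
  stopifnot(inherits(spec, "template_spec"))
  pos <- record_positions(spec$template)
  fixed <- spec$anchored_positions
  structure(list(fixed = fixed, designable = setdiff(pos, fixed)),
            class = "design_mask")
}

#' Sequence recovery against the template
#'
#' Fraction of template positions at which the candidate token matches the
#' template token under the equivalence policy of [tokens_match()] (Aib
#' matches Aib and Ala).  The denominator is the template length, and the
#' value is rounded half-up to `digits` decimals to match reporting
#' convention (25 matches of 31 gives 0.81).
#'
#' @param candidate,template [peptide_record()]s sharing the same numbering
#'   range.
#' @param digits decimals for half-up rounding; `NULL` for the raw fraction.
#' @return numeric in \[0, 1\].
#' @export
recovery <- function(candidate, template, digits = 2) {
  stopifnot(inherits(candidate, "peptide_record"),
            inherits(template, "peptide_record"))
  if (length(candidate) != length(template) ||
      candidate$numbering_start != template$numbering_start)
    stop("candidate and template numbering ranges differ")
  frac <- sum(tokens_match(candidate$residues, template$residues)) /
    length(template)
  if (is.null(digits)) frac else round_half_up(frac, digits)
}

round_half_up <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Deduplicate a candidate pool
#'
#' Keeps the first occurrence of each distinct token sequence, preserving
#' input order; identifiers are ignored for the purpose of equality.
#'
#' @param records list of [peptide_record()]s.
#' @return list with `records` (unique, first-id policy), `n_input`,
#'   `n_unique`, `n_duplicates`, and `duplicate_of` (named character vector
#'   mapping each dropped id to the id kept in its place).
#' @export
dedupe <- function(records) {
  keys <- vapply(records, function(r) token_string(r$residues), character(1))
  first <- !duplicated(keys)
  kept_ids <- vapply(records[first], `[[`, character(1), "id")
  names(kept_ids) <- keys[first]
  dup_ids <- vapply(records[!first], `[[`, character(1), "id")
  list(records = records[first],
       n_input = length(records),
       n_unique = sum(first),
       n_duplicates = sum(!first),
       duplicate_of = stats::setNames(unname(kept_ids[keys[!first]]), dup_ids))
}
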