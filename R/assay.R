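# In-vitro bookkeeping over assay tables: relative expression, the
# expression-threshold filter and label tallies.  Assay outcomes are data,
# never recomputed.

#' Relative expression from band densities
#'
#' Ratio of the fusion-peptide band density to the reference (GLP-1) band
#' density in the pulldown gel; values above 1 are permitted (expression
#' exceeding the reference).
#'
#' @param peptide_band_density,reference_band_density positive densities.
#' @return the ratio.
#' @export
relative_expression <- function(peptide_band_density,
                                reference_band_density) {
  if (any(peptide_band_density <= 0) || any(reference_band_density <= 0))
    stop("band densities must be positive")
  peptide_band_density / reference_band_density
}

#' Read an assay table
#'
#' TSV keyed by candidate id with any subset of the columns `recovery`,
#' `pulldown`, `relative_expression`, `kd`, `spr`, `ec50`, `t_half`,
#' `indication`.  Label columns take values `Success` / `Fail` or empty.
#'
#' @param path TSV path.
#' @return data frame with unique ids.
#' @export
read_assay_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!"id" %in% names(df)) stop("assay table needs an 'id' column")
  if (anyDuplicated(df$id)) stop("duplicate candidate ids in assay table")
  for (col in intersect(c("pulldown", "spr"), names(df))) {
    bad <- !is.na(df[[col]]) & !df[[col]] %in% c("Success", "Fail")
    if (any(bad)) stop("invalid label(s) in column '", col, "': ",
                       paste(unique(df[[col]][bad]), collapse = ", "))
  }
  df
}

#' Bundled pulldown/SPR/cAMP outcome table
#'
#' The packaged table of per-candidate in-vitro outcomes for the 60
#' designed agonists plus the Semaglutide control: sequence recovery,
#' pulldown label and relative expression, SPR dissociation constant and
#' label, cAMP EC50 (nM) and measured half-life (h).
#'
#' @param include_reference keep the Semaglutide control row?
#' @return data frame as from [read_assay_table()].
#' @export
glp1_assay_table <- function(include_reference = FALSE) {
  path <- system.file("extdata", "glp1ra_assay_table.tsv",
                      package = "pepfunnel", mustWork = TRUE)
  df <- read_assay_table(path)
  if (!include_reference) df <- df[df$id != "Semaglutide", , drop = FALSE]
  df
}

#' Expression-threshold filter
#'
#' Among rows with pulldown label `Success`, excludes those with relative
#' expression strictly below `threshold`; a value exactly at the threshold
#' is retained (a candidate at 0.70 proceeds under the default 0.7).  A
#' Success row with no expression value is an error.
#'
#' @param table assay data frame with `pulldown` and
#'   `relative_expression` columns.
#' @param threshold exclusion threshold (default 0.7).
#' @return list with character vectors `retained` and `excluded`.
#' @export
apply_expression_filter <- function(table, threshold = 0.7) {
  succ <- table[!is.na(table$pulldown) & table$pulldown == "Success", ,
                drop = FALSE]
  if (anyNA(succ$relative_expression))
    stop("missing relative expression on Success row(s): ",
         paste(succ$id[is.na(succ$relative_expression)], collapse = ", "))
  excl <- succ$relative_expression < threshold
  list(retained = succ$id[!excl], excluded = succ$id[excl])
}

#' Count exact labels in an assay column
#'
#' @param table assay data frame.
#' @param column column name.
#' @param label exact label to count (`NA` cells never match).
#' @return integer count.
#' @export
count_labels <- function(table, column, label) {
  if (!column %in% names(table))
    stop("unknown column '", column, "'")
  sum(!is.na(table[[column]]) & table[[column]] == label)
}
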