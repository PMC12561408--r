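# FASTA I/O in the bracket-token dialect, aligned-FASTA MSA input,
# conservation profiles and conserved-site selection.
#
# Dialect: headers are ">id key=value ...": a "start=" key carries the
# template numbering offset (default 7, the GLP-1 convention); sequence
# lines may wrap and may contain bracketed extended tokens ("H[Aib]EGT...").

#' Read / write FASTA in the bracket-token dialect
#'
#' @param path file path.
#' @param records list of [peptide_record()]s.
#' @param width line-wrap width for writing.
#' @return `read_fasta()`: list of [peptide_record()]s; `write_fasta()`:
#'   `path`, invisibly.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("FASTA must start with a '>' header: ", path)
  grp <- cumsum(hdr)
  lapply(split(lines, grp), function(block) {
    header <- sub("^>", "", block[1])
    if (length(block) < 2L)
      stop("header without sequence: >", header)
    fields <- strsplit(trimws(header), "\\s+")[[1]]
    id <- fields[1]
    kv <- fields[-1][grepl("=", fields[-1])]
    keys <- sub("=.*", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    start <- if ("start" %in% keys) as.integer(vals[keys == "start"][1]) else 7L
    ann <- as.list(vals[keys != "start"])
    names(ann) <- keys[keys != "start"]
    seq <- paste(gsub("\\s", "", block[-1]), collapse = "")
    peptide_record(id, parse_token_string(seq), numbering_start = start,
                   annotations = ann)
  }) |> unname()
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "peptide_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    ann <- if (length(r$annotations))
      paste0(" ", paste0(names(r$annotations), "=",
                         unlist(r$annotations), collapse = " ")) else ""
    writeLines(paste0(">", r$id, " start=", r$numbering_start, ann), con)
    s <- token_string(r$residues)
    # wrap without splitting a bracketed token
    while (nchar(s) > 0L) {
      take <- min(width, nchar(s))
      chunk <- substr(s, 1L, take)
      no <- nchar(gsub("\\[[^]]*$", "", chunk))  # back off mid-bracket cuts
      if (no > 0L && no < take) take <- no
      writeLines(substr(s, 1L, take), con)
      s <- substr(s, take + 1L, nchar(s))
    }
  }
  invisible(path)
}

# ---- multiple sequence alignment ------------------------------------------

#' Read an aligned FASTA into an MSA object
#'
#' Rows must be equal length after parsing; `-` marks gaps.  The alignment
#' itself is an input (built elsewhere); only pairwise alignment is
#' recomputed in this package.
#'
#' @param path aligned FASTA path.
#' @return object of class `msa`: list with `ids`, `rows` (list of gapped
#'   token vectors), `ncol`, `numbering_start` (of the first row).
#' @export
read_msa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty alignment file: ", path)
  hdr <- grepl("^>", lines)
  grp <- cumsum(hdr)
  rows <- lapply(split(lines, grp), function(block) {
    seq <- paste(gsub("\\s", "", block[-1]), collapse = "")
    parse_token_string(seq, allow_gaps = TRUE)
  })
  ids <- sub("\\s.*", "", sub("^>", "", lines[hdr]))
  starts <- vapply(lines[hdr], function(h) {
    m <- regmatches(h, regexpr("start=\\d+", h))
    if (length(m)) as.integer(sub("start=", "", m)) else 7L
  }, integer(1))
  msa(ids, unname(rows), numbering_start = unname(starts[1]))
}

#' @rdname read_msa
#' @param ids row identifiers.
#' @param rows list of gapped token vectors (equal lengths).
#' @param numbering_start template numbering of the first row's first
#'   non-gap residue.
#' @export
msa <- function(ids, rows, numbering_start = 7L) {
  stopifnot(length(ids) == length(rows), length(rows) >= 1L)
  nc <- unique(lengths(rows))
  if (length(nc) != 1L) stop("alignment rows have unequal lengths")
  m <- do.call(rbind, rows)
  if (any(colSums(m != "-") == 0L))
    stop("alignment has an all-gap column")
  structure(list(ids = as.character(ids), rows = rows, ncol = nc,
                 numbering_start = as.integer(numbering_start)),
            class = "msa")
}

#' Per-column conservation profile
#'
#' Majority-fraction mode scores each column by the frequency of its most
#' common residue among non-gap tokens (1 = unanimous).  Entropy mode
#' scores the Shannon entropy in bits (0 = unanimous).  Columns are mapped
#' to template numbering through the ungapped positions of `template_id`'s
#' row (columns where that row is gapped get `NA` positions and can never
#' be selected).
#'
#' @param msa an [msa()] object.
#' @param mode `"majority_fraction"` or `"shannon_entropy"`.
#' @param template_id row id used to map columns to template numbering;
#'   defaults to the first row.
#' @return object of class `conservation_profile` with `score`, `position`,
#'   `mode` and the template position `range`.
#' @export
conservation_profile <- function(msa,
                                 mode = c("majority_fraction",
                                          "shannon_entropy"),
                                 template_id = msa$ids[1]) {
  stopifnot(inherits(msa, "msa"))
  mode <- match.arg(mode)
  score <- vapply(seq_len(msa$ncol), function(j) {
    col <- vapply(msa$rows, `[`, character(1), j)
    col <- canonical_token(col[col != "-"])
    p <- table(col) / length(col)
    switch(mode,
           majority_fraction = max(p),
           shannon_entropy = -sum(p * log2(p)))
  }, numeric(1))
  ti <- match(template_id, msa$ids)
  if (is.na(ti)) stop("template row '", template_id, "' not in alignment")
  trow <- msa$rows[[ti]]
  position <- rep(NA_integer_, msa$ncol)
  position[trow != "-"] <- msa$numbering_start +
    seq_len(sum(trow != "-")) - 1L
  structure(list(score = score, position = position, mode = mode,
                 range = range(position, na.rm = TRUE)),
            class = "conservation_profile")
}

#' Select conserved template positions
#'
#' Columns whose conservation score is at least `threshold` are mapped to
#' template numbering and united with `anchors` (which carry positions that
#' are fixed for non-conservation reasons, e.g. Semaglutide's own
#' modification sites 8Aib, 26K, 34R).  `profile = NULL` selects anchors
#' alone.
#'
#' @param profile a [conservation_profile()], or `NULL`.
#' @param threshold minimum score, in (0, 1\] for majority-fraction mode.
#' @param anchors integer template positions always included.
#' @param template optional [peptide_record()] used to validate anchors when
#'   no profile is given.
#' @return sorted integer vector of template positions.
#' @export
#' @examples
#' select_conserved_sites(NULL, anchors = glp1_anchors(),
#'                        template = semaglutide_template())
select_conserved_sites <- function(profile = NULL, threshold = 1,
                                   anchors = integer(), template = NULL) {
  anchors <- sort(unique(as.integer(anchors)))
  rng <- if (!is.null(profile)) profile$range
         else if (!is.null(template)) range(record_positions(template))
  if (!is.null(rng) && length(anchors) &&
      (min(anchors) < rng[1] || max(anchors) > rng[2]))
    stop("anchor outside template range [", rng[1], ", ", rng[2], "]")
  sel <- integer()
  if (!is.null(profile)) {
    stopifnot(threshold > 0)
    keep <- profile$score >= threshold & !is.na(profile$position)
    sel <- profile$position[keep]
  }
  sort(unique(c(sel, anchors)))
}

#' Export a conservation profile as a data frame (TSV-ready)
#' @param profile a [conservation_profile()].
#' @return data frame with columns `column`, `position`, `score`, `mode`.
#' @export
conservation_table <- function(profile) {
  data.frame(column = seq_along(profile$score),
             position = profile$position,
             score = profile$score,
             mode = profile$mode)
}
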