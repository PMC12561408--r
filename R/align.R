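# Pairwise global alignment (Needleman-Wunsch, linear gap penalty) over the
# residue-token alphabet.  Hand-rolled because the alphabet includes
# registered extended tokens such as Aib, which standard aligners cannot
# carry; the deterministic traceback makes identity distances reproducible.

#' Global pairwise alignment
#'
#' Needleman-Wunsch dynamic programming with a linear gap penalty.  The
#' default substitution score is 1 for a token match under the
#' [tokens_match()] policy and 0 otherwise.  Traceback ties are broken
#' deterministically: diagonal, then up (gap in `b`), then left (gap in
#' `a`).
#'
#' @param a,b [peptide_record()]s or token vectors.
#' @param substitution either `NULL` (match/mismatch default), a symmetric
#'   numeric matrix with token dimnames, or a function `(tok_a, tok_b) ->
#'   score`.
#' @param gap_penalty nonnegative penalty subtracted per gap position.
#' @return object of class `alignment_result`: `a_aligned` and `b_aligned`
#'   (gapped token vectors), `score`, and `identity` (identical aligned
#'   columns / alignment length).
#' @export
#' @examples
#' global_align(c("G", "A", "T", "T"), c("G", "A", "T"))$score  # 2
global_align <- function(a, b, substitution = NULL, gap_penalty = 1) {
  ta <- if (inherits(a, "peptide_record")) a$residues else as.character(a)
  tb <- if (inherits(b, "peptide_record")) b$residues else as.character(b)
  stopifnot(gap_penalty >= 0)
  sub_fn <- make_sub_fn(substitution, c(ta, tb))
  n <- length(ta); m <- length(tb)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- -gap_penalty * (0:n)
  S[1L, ] <- -gap_penalty * (0:m)
  if (n > 0L && m > 0L) {
    sub <- outer(seq_len(n), seq_len(m),
                 function(i, j) sub_fn(ta[i], tb[j]))
    for (i in seq_len(n)) for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[i, j],
                               S[i, j + 1L] - gap_penalty,
                               S[i + 1L, j] - gap_penalty)
    }
  }
  # traceback, tie-break diagonal > up > left
  aa <- character(0); bb <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    here <- S[i + 1L, j + 1L]
    if (i > 0L && j > 0L && here == S[i, j] + sub[i, j]) {
      aa <- c(ta[i], aa); bb <- c(tb[j], bb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && here == S[i, j + 1L] - gap_penalty) {
      aa <- c(ta[i], aa); bb <- c("-", bb); i <- i - 1L
    } else {
      aa <- c("-", aa); bb <- c(tb[j], bb); j <- j - 1L
    }
  }
  len <- length(aa)
  ident <- if (len == 0L) 1 else {
    both <- aa != "-" & bb != "-"
    eq <- both
    eq[both] <- tokens_match(aa[both], bb[both])
    sum(eq) / len
  }
  structure(list(a_aligned = aa, b_aligned = bb,
                 score = S[n + 1L, m + 1L], identity = ident),
            class = "alignment_result")
}

make_sub_fn <- function(substitution, tokens) {
  if (is.null(substitution))
    return(function(x, y) as.numeric(tokens_match(x, y)))
  if (is.function(substitution)) return(substitution)
  if (is.matrix(substitution)) {
    miss <- setdiff(unique(tokens), rownames(substitution))
    if (length(miss))
      stop("token(s) absent from substitution table: ",
           paste(miss, collapse = ", "))
    return(function(x, y) substitution[x, y])
  }
  stop("substitution must be NULL, a matrix, or a function")
}

#' Alignment identity between two peptides
#'
#' Convenience wrapper: identical aligned columns divided by alignment
#' length from [global_align()].
#'
#' @inheritParams global_align
#' @return numeric in \[0, 1\].
#' @export
alignment_identity <- function(a, b, substitution = NULL, gap_penalty = 1) {
  global_align(a, b, substitution, gap_penalty)$identity
}
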