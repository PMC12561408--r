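# Predicted-aligned-error matrices: AF2 JSON dialects in, interface pAE out.

#' Predicted aligned error matrix
#'
#' Square nonnegative matrix of pairwise predicted aligned errors (A) with
#' an index map assigning each row/column to a chain and residue number.
#'
#' @param mat square numeric matrix, entries >= 0.
#' @param chain_lengths named integer vector, residues per chain in row
#'   order (e.g. `c(A = 31, B = 40)`).
#' @return object of class `pae_matrix`: `mat` and `index` (data frame
#'   `chain`, `resno`).
#' @export
pae_matrix <- function(mat, chain_lengths) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat))
    stop("PAE matrix must be square, got ", nrow(mat), "x", ncol(mat))
  if (any(mat < 0)) stop("PAE entries must be nonnegative")
  if (is.null(names(chain_lengths)) || any(!nzchar(names(chain_lengths))))
    stop("chain_lengths must be named by chain id")
  if (sum(chain_lengths) != nrow(mat))
    stop("chain lengths (", sum(chain_lengths),
         ") do not sum to matrix size (", nrow(mat), ")")
  index <- data.frame(
    chain = rep(names(chain_lengths), chain_lengths),
    resno = unlist(lapply(unname(chain_lengths), seq_len)))
  structure(list(mat = unname(mat), index = index), class = "pae_matrix")
}

#' Read / write PAE JSON
#'
#' Accepts both the bare-object dialect (`{"predicted_aligned_error":
#' [[...]]}`, also under key `"pae"`) and the list-wrapped dialect
#' (`[{...}]`) that structure predictors emit.
#'
#' @param path JSON path.
#' @param chain_lengths named integer vector, see [pae_matrix()].
#' @param pae a [pae_matrix()] (for writing).
#' @return a [pae_matrix()]; the writer returns `path` invisibly.
#' @export
read_pae_json <- function(path, chain_lengths) {
  obj <- jsonlite::fromJSON(path)
  if (is.data.frame(obj)) obj <- as.list(obj)
  if (is.list(obj) && is.null(names(obj)) && length(obj) >= 1L)
    obj <- obj[[1]]
  key <- intersect(c("predicted_aligned_error", "pae"), names(obj))
  if (length(key) == 0L)
    stop("no predicted-aligned-error key in ", path)
  mat <- obj[[key[1]]]
  if (is.list(mat) && !is.matrix(mat)) mat <- do.call(rbind, mat)
  pae_matrix(mat, chain_lengths)
}

#' @rdname read_pae_json
#' @export
write_pae_json <- function(pae, path) {
  jsonlite::write_json(list(predicted_aligned_error = pae$mat), path,
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Interface predicted aligned error
#'
#' Mean PAE over the two inter-chain blocks (a rows vs b columns and b rows
#' vs a columns), equally weighted per entry; intra-chain entries are
#' excluded.  Low values indicate a confidently predicted interface.
#'
#' @param pae a [pae_matrix()].
#' @param chain_a,chain_b distinct chain ids present in the index.
#' @return mean interface PAE in A.
#' @export
interface_pae <- function(pae, chain_a = "A", chain_b = "B") {
  stopifnot(inherits(pae, "pae_matrix"))
  ia <- which(pae$index$chain == chain_a)
  ib <- which(pae$index$chain == chain_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("chain(s) absent from PAE index")
  if (length(intersect(ia, ib)))
    stop("chain index sets overlap")
  mean(c(pae$mat[ia, ib], pae$mat[ib, ia]))
}
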