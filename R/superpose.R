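# Rigid-body superposition (Kabsch), C-alpha RMSD and TM-score.

#' Kabsch least-squares superposition
#'
#' Optimal proper rotation and translation mapping `coords_b` onto
#' `coords_a` (row-per-point, 3 columns), with the reflection corrected so
#' that the rotation determinant is +1.  Degenerate (collinear) point sets
#' are flagged via the `degenerate` field but a result is still returned.
#'
#' @param coords_a,coords_b n x 3 matrices, n >= 3.
#' @return list with `rotation` (3 x 3, applied as `x %*% rotation`),
#'   `translation` (length 3), `rmsd`, `degenerate`.  The fit of point `i`
#'   is `coords_b[i, ] %*% rotation + translation`.
#' @export
kabsch <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  stopifnot(ncol(a) == 3L, ncol(b) == 3L)
  n <- nrow(a)
  if (n != nrow(b)) stop("point lists differ in length")
  if (n < 3L) stop("need at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca); b0 <- sweep(b, 2L, cb)
  H <- crossprod(b0, a0)                 # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-300)
  fit <- b0 %*% R
  rmsd <- sqrt(sum((a0 - fit)^2) / n)
  list(rotation = R, translation = as.numeric(ca - cb %*% R),
       rmsd = rmsd, degenerate = degenerate)
}

# paired C-alpha coordinates of model and reference on a common chain
paired_ca <- function(model, reference, chain = "A",
                      pairing = c("chain", "complex")) {
  pairing <- match.arg(pairing)
  chains <- if (pairing == "chain") chain
            else intersect(unique(model$atoms$chain),
                           unique(reference$atoms$chain))
  am <- NULL; ar <- NULL
  for (ch in chains) {
    res_m <- unique(model$atoms$resno[model$atoms$chain == ch])
    res_r <- unique(reference$atoms$resno[reference$atoms$chain == ch])
    common <- sort(intersect(res_m, res_r))
    cm <- chain_coords(model, ch); cr <- chain_coords(reference, ch)
    no_ca <- union(setdiff(common, as.integer(rownames(cm))),
                   setdiff(common, as.integer(rownames(cr))))
    if (length(no_ca))
      stop("paired residue without a C-alpha in chain ", ch, ": ",
           paste(no_ca, collapse = ", "))
    key <- as.character(common)
    am <- rbind(am, cm[key, , drop = FALSE])
    ar <- rbind(ar, cr[key, , drop = FALSE])
  }
  if (is.null(am) || nrow(am) < 3L)
    stop("fewer than 3 paired residues")
  list(model = am, reference = ar)
}

#' C-alpha RMSD after Kabsch superposition
#'
#' Residues are paired by chain and residue number (template numbering
#' keeps candidate and reference in one-to-one correspondence); the RMSD
#' is computed after least-squares superposition of the paired C-alphas.
#'
#' @param model,reference [structure_model()]s.
#' @param chain chain to pair when `pairing = "chain"` (default the
#'   peptide chain `"A"`).
#' @param pairing `"chain"` (one chain) or `"complex"` (all shared chains).
#' @return RMSD in A.
#' @export
ca_rmsd <- function(model, reference, chain = "A",
                    pairing = c("chain", "complex")) {
  p <- paired_ca(model, reference, chain, match.arg(pairing))
  kabsch(p$reference, p$model)$rmsd
}

#' TM-score distance scale d0
#'
#' \eqn{d_0 = 1.24 (L-15)^{1/3} - 1.8}, clamped below at 0.5 for short
#' peptides (L = 31 gives 1.3246, so the clamp is inactive for the
#' template length used here).
#'
#' @param L reference length (residues).
#' @return d0 in A.
#' @export
tm_d0 <- function(L) {
  x <- L - 15
  max(0.5, 1.24 * sign(x) * abs(x)^(1 / 3) - 1.8)
}

# score a distance vector at scale d0
tm_terms <- function(d, d0) 1 / (1 + (d / d0)^2)

#' TM-score of a model against a reference
#'
#' Length-normalized structural similarity
#' \eqn{TM = \max \frac{1}{L}\sum_i 1/(1+(d_i/d_0)^2)} over superpositions.
#' Residues are in fixed one-to-one correspondence via template numbering,
#' so instead of a fragment search the superposition is optimized by
#' iterative Kabsch reweighting: start from the all-pair superposition,
#' then repeatedly re-superpose on the pairs with \eqn{d_i < d_0} until the
#' selected set is stable (at most `max_iter` rounds), keeping the best
#' score seen.
#'
#' @param reference,model [structure_model()]s; `reference` defines L.
#' @param chain,pairing see [ca_rmsd()].
#' @param max_iter iteration cap for the reweighting.
#' @return TM-score in (0, 1\].
#' @export
tm_score <- function(reference, model, chain = "A",
                     pairing = c("chain", "complex"), max_iter = 20L) {
  p <- paired_ca(model, reference, chain, match.arg(pairing))
  L <- nrow(p$reference)
  d0 <- tm_d0(L)
  sel <- seq_len(L)
  best <- 0
  prev <- NULL
  for (iter in seq_len(max_iter)) {
    k <- kabsch(p$reference[sel, , drop = FALSE],
                p$model[sel, , drop = FALSE])
    fit <- sweep(p$model %*% k$rotation, 2L, k$translation, `+`)
    d <- sqrt(rowSums((p$reference - fit)^2))
    best <- max(best, mean(tm_terms(d, d0)))
    nxt <- which(d < d0)
    if (length(nxt) < 3L || identical(nxt, prev) || identical(nxt, sel))
      break
    prev <- sel
    sel <- nxt
  }
  best
}
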