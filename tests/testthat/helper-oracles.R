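# Independent oracles and fixture builders used across the suite.

# Horn quaternion-method RMSD: independent of the SVD/Kabsch route.
quaternion_rmsd <- function(a, b) {
  a0 <- scale(a, scale = FALSE)
  b0 <- scale(b, scale = FALSE)
  S <- crossprod(b0, a0)
  K <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2], S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3], S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1], -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3], S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- sum(a0^2) + sum(b0^2) - 2 * lambda
  sqrt(max(0, e2) / nrow(a))
}

# Exhaustive global-alignment score by enumeration of the move tree
# (Delannoy-sized for short sequences), independent of the DP matrix.
brute_force_align_score <- function(a, b, gap = 1) {
  if (length(a) == 0L) return(-gap * length(b))
  if (length(b) == 0L) return(-gap * length(a))
  max(brute_force_align_score(a[-1], b[-1], gap) +
        as.numeric(tokens_match(a[1], b[1])),
      brute_force_align_score(a[-1], b, gap) - gap,
      brute_force_align_score(a, b[-1], gap) - gap)
}

# Dense-grid isoelectric point
grid_pi <- function(record, n_grid = 14000L) {
  grid <- seq(1e-4, 14 - 1e-4, length.out = n_grid)
  q <- vapply(grid, function(p) net_charge(record, p), numeric(1))
  grid[which.min(abs(q))]
}

random_peptide <- function(len, id = "p") {
  peptide_record(id, sample(pepfunnel:::CANONICAL_AA, len, replace = TRUE))
}

# random additive distance matrix from a random tree's path metric
random_additive_dm <- function(n) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 2))
  as.matrix(stats::cophenetic(tr))
}

# two-chain complex fixture: peptide helix (chain A) + receptor stand-in
# helix (chain B), rigidly offset
complex_fixture <- function(record = semaglutide_template(),
                            receptor_len = 20L) {
  pep <- build_ideal_helix(record, chain = "A")
  rec <- build_ideal_helix(
    peptide_record("receptor", rep("A", receptor_len), numbering_start = 1L),
    chain = "B")
  rec$atoms$x <- rec$atoms$x + 9
  rec$atoms$serial <- rec$atoms$serial + max(pep$atoms$serial)
  structure_model(rbind(pep$atoms, rec$atoms))
}

# alphabet that can form no NEP-24.11 dipeptide anywhere
motif_free_alphabet <- function() c("A", "G", "K", "N", "Q", "R", "T")

motif_free_distribution <- function() {
  ab <- motif_free_alphabet()
  stats::setNames(rep(1 / length(ab), length(ab)), ab)
}
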