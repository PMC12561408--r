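# PDB/PAE parsing, Kabsch superposition, C-alpha RMSD and TM-score.

test_that("PDB reader keeps coordinates, altlocs and pLDDT semantics", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    paste0("ATOM      1  CA AALA A   1       1.234   5.678   9.012",
           "  1.00 91.20           C"),
    paste0("ATOM      2  CA BALA A   1       9.000   0.000   0.000",
           "  1.00 50.00           C"),
    paste0("ATOM      3  CA  GLY A   2       4.000   5.000   6.000",
           "  1.00 80.00           C")), f)
  m <- read_pdb(f)
  expect_equal(nrow(m$atoms), 2L)            # altloc B dropped
  expect_equal(m$atoms$x[1], 1.234)
  expect_equal(m$atoms$z[1], 9.012)
  expect_equal(m$plddt$plddt, c(91.20, 80.00))
  expect_equal(mean_plddt(m, "A"), (91.2 + 80) / 2)

  writeLines("ATOM      1  CA  ALA A   1       1.0", f)
  expect_error(read_pdb(f), "line 1")
})

test_that("PDB writer round-trips through the reader", {
  h <- build_ideal_helix(semaglutide_template())
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(h, f)
  back <- read_pdb(f)
  expect_equal(nrow(back$atoms), nrow(h$atoms))
  expect_equal(back$atoms$x, h$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$resno, h$atoms$resno)
  expect_identical(back$atoms$atom, h$atoms$atom)
  expect_equal(back$plddt$plddt, rep(100, 31))
})

test_that("mean pLDDT averages one chain and rejects absent chains", {
  cx <- complex_fixture()
  expect_equal(mean_plddt(cx, "A"), 100)
  p <- cx$plddt
  p$plddt[p$chain == "A"] <- c(80, 100, rep(90, sum(p$chain == "A") - 2))
  cx2 <- set_plddt(cx, p)
  expect_equal(mean_plddt(cx2, "A"),
               mean(c(80, 100, rep(90, 29))))
  expect_error(mean_plddt(cx, "Z"), "absent")
})

test_that("PAE JSON dialects parse and round-trip", {
  f <- withr::local_tempfile(fileext = ".json")
  m4 <- matrix(c(0, 1, 5, 6, 1, 0, 7, 8, 5, 7, 0, 2, 6, 8, 2, 0), 4, 4)
  writeLines(jsonlite::toJSON(list(predicted_aligned_error = m4)), f)
  pae <- read_pae_json(f, c(A = 2L, B = 2L))
  expect_identical(pae$index$chain, c("A", "A", "B", "B"))
  expect_equal(pae$mat, m4)

  # list-wrapped dialect under the short key
  writeLines(jsonlite::toJSON(list(list(pae = m4))), f)
  pae2 <- read_pae_json(f, c(A = 2L, B = 2L))
  expect_equal(pae2$mat, m4)

  # write/read round-trip preserves entries exactly
  write_pae_json(pae, f)
  expect_equal(read_pae_json(f, c(A = 2L, B = 2L))$mat, m4)

  expect_error(pae_matrix(matrix(0, 3, 4), c(A = 2L, B = 2L)), "square")
  expect_error(pae_matrix(matrix(-1, 2, 2), c(A = 1L, B = 1L)),
               "nonnegative")
})

test_that("interface PAE averages the two inter-chain blocks only", {
  n <- 6L
  mat <- matrix(30, n, n)
  mat[1:3, 4:6] <- 5; mat[4:6, 1:3] <- 5
  diag(mat) <- 0
  pae <- pae_matrix(mat, c(A = 3L, B = 3L))
  expect_equal(interface_pae(pae), 5.0)

  mat[1:3, 4:6] <- 4; mat[4:6, 1:3] <- 8   # asymmetric blocks: (4+8)/2
  pae <- pae_matrix(mat, c(A = 3L, B = 3L))
  expect_equal(interface_pae(pae), 6.0)

  # affine equivariance on the inter blocks
  pae_c <- pae_matrix(mat + 3, c(A = 3L, B = 3L))
  expect_equal(interface_pae(pae_c), 9.0)

  # symmetric matrix: equals the one-block mean
  sym <- (mat + t(mat)) / 2
  pae_s <- pae_matrix(sym, c(A = 3L, B = 3L))
  expect_equal(interface_pae(pae_s), mean(sym[1:3, 4:6]))

  expect_error(interface_pae(pae, "A", "A"), "overlap")
})

test_that("Kabsch recovers rigid motions and matches the quaternion oracle", {
  set.seed(101)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch(a, a)$rmsd, 0, tolerance = 1e-12)

  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  b <- a %*% R + matrix(rep(c(3, -1, 2), each = 10), 10, 3)
  k <- kabsch(a, b)
  expect_equal(k$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)

  for (i in 1:100) {
    n <- sample(3:50, 1)
    p <- matrix(rnorm(3 * n), n, 3)
    q <- matrix(rnorm(3 * n), n, 3)
    expect_equal(kabsch(p, q)$rmsd, quaternion_rmsd(p, q),
                 tolerance = 1e-8)
    expect_equal(det(kabsch(p, q)$rotation), 1, tolerance = 1e-8)
  }
  expect_error(kabsch(a[1:2, ], a[1:2, ]), "at least 3")
})

test_that("C-alpha RMSD pairs residues by numbering and is rigid-invariant", {
  h <- build_ideal_helix(semaglutide_template())
  expect_equal(ca_rmsd(h, h), 0, tolerance = 1e-9)

  # displace one CA by 1 A along x and recompute the superposition
  h2 <- h
  i <- which(h2$atoms$atom == "CA")[5]
  h2$atoms$x[i] <- h2$atoms$x[i] + 1
  p <- list(ref = chain_coords_of(h), mod = chain_coords_of(h2))
  expect_equal(ca_rmsd(h2, h), quaternion_rmsd(p$ref, p$mod),
               tolerance = 1e-8)

  # global rotation of the model leaves the RMSD unchanged
  h3 <- rotate_model(h2, pi / 3)
  expect_equal(ca_rmsd(h3, h), ca_rmsd(h2, h), tolerance = 1e-9)

  h4 <- h
  h4$atoms <- h4$atoms[h4$atoms$atom != "CA" | h4$atoms$resno != 10, ]
  expect_error(ca_rmsd(h4, h), "C-alpha")
})

test_that("TM-score has the right scale, bounds and fixed points", {
  expect_equal(tm_d0(31), 1.3246, tolerance = 1e-4)
  expect_equal(tm_d0(10), 0.5)  # clamp active for short peptides

  h <- build_ideal_helix(semaglutide_template())
  expect_equal(tm_score(h, h), 1.0, tolerance = 1e-12)

  # all distances exactly d0 give mean term 1/2 (frozen superposition)
  d0 <- tm_d0(31)
  expect_equal(mean(pepfunnel:::tm_terms(rep(d0, 31), d0)), 0.5)
  # terms decrease when any distance increases
  d <- rep(1, 31); d2 <- d; d2[4] <- 2
  expect_lt(mean(pepfunnel:::tm_terms(d2, d0)),
            mean(pepfunnel:::tm_terms(d, d0)))

  set.seed(55)
  for (sg in c(0.1, 0.5, 1.5)) {
    hp <- perturb_structure(h, sg, seed = 17)
    tm <- tm_score(h, hp)
    expect_gt(tm, 0); expect_lte(tm, 1)
  }
  # heavier perturbation scores lower on average
  tm_small <- tm_score(h, perturb_structure(h, 0.2, seed = 3))
  tm_large <- tm_score(h, perturb_structure(h, 2.0, seed = 3))
  expect_gt(tm_small, tm_large)
})

test_that("threshold derivation and the efficacy gate agree", {
  ref <- struct_score(tm = 1.0, ca_rmsd = 0, mean_plddt = 92,
                      interface_pae = 4)
  th <- derive_thresholds(ref, slack = 0.1)
  expect_equal(th$min_tm, 0.9)
  expect_equal(th$max_ca_rmsd, 0.55)          # floor 0.5 then +10%
  expect_equal(th$min_mean_plddt, 82.8)
  expect_equal(th$max_interface_pae, 4.4)

  th0 <- derive_thresholds(ref, slack = 0)
  expect_equal(th0$min_tm, 1.0)
  expect_equal(th0$max_ca_rmsd, 0.5)
  # monotone in slack
  th2 <- derive_thresholds(ref, slack = 0.2)
  expect_lt(th2$min_tm, th$min_tm)
  expect_gt(th2$max_interface_pae, th$max_interface_pae)

  expect_true(efficacy_gate(ref, th)$passed)
  bad <- struct_score(1.0, 0, 92, interface_pae = 5)
  g <- efficacy_gate(bad, th)
  expect_false(g$passed)
  expect_identical(g$reasons$criterion, "interface_pae")

  th_aff <- derive_thresholds(ref, slack = 0.1, max_affinity = -20)
  expect_error(efficacy_gate(bad, th_aff), "missing")
})

test_that("external affinities ingest with validation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\taffinity", "D01\t-42.1", "D02\t-38.5", "D03\t-51"), f)
  aff <- ingest_affinity(f)
  expect_length(aff, 3L)
  expect_equal(aff[["D03"]], -51)

  writeLines(c("id\taffinity", "D01\t-42.1", "D01\t-38.5"), f)
  expect_error(ingest_affinity(f), "duplicate")
  writeLines(c("id\taffinity", "D01\tnot_a_number"), f)
  expect_error(ingest_affinity(f), "non-numeric")
  writeLines("id\taffinity", f)
  expect_length(ingest_affinity(f), 0L)
})
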