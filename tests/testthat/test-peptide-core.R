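# Sequence data model, FASTA dialect, conservation, design mask, recovery,
# deduplication and pairwise alignment.

test_that("FASTA round-trips with bracketed tokens and start= numbering", {
  f <- withr::local_tempfile(fileext = ".fasta")
  recs <- list(
    peptide_record("a", "H[Aib]EGT", numbering_start = 7L),
    peptide_record("b", "HAEGTFTSDVSSYLEGQAAKEFIAWLVKGRG", numbering_start = 7L))
  write_fasta(recs, f, width = 10L)
  back <- read_fasta(f)
  expect_length(back, 2L)
  expect_identical(back[[1]]$residues, c("H", "Aib", "E", "G", "T"))
  expect_identical(back[[1]]$numbering_start, 7L)
  expect_identical(back[[2]]$residues, recs[[2]]$residues)

  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x start=9", "H[Aib]EGT"), f2)
  r <- read_fasta(f2)[[1]]
  expect_identical(r$numbering_start, 9L)
  expect_identical(r$residues[2], "Aib")
})

test_that("FASTA reader rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
  writeLines(c(">x", "HB#T"), f)
  expect_error(read_fasta(f), "#")
  writeLines(c(">x", "HAT", ">orphan"), f)
  expect_error(read_fasta(f), "without sequence")
})

test_that("conservation profile scores columns, ignoring gaps", {
  rows <- list(c("E", "A", "H", "-"),
               c("E", "A", "Q", "A"),
               c("E", "G", "Q", "A"),
               c("E", "G", "Q", "A"),
               c("E", "A", "Q", "A"),
               c("E", "G", "Q", "A"))
  al <- msa(paste0("s", 1:6), rows)
  pm <- conservation_profile(al, "majority_fraction")
  expect_equal(pm$score[1], 1.0)     # unanimous
  expect_equal(pm$score[2], 0.5)     # 3 A vs 3 G
  pe <- conservation_profile(al, "shannon_entropy")
  expect_equal(pe$score[1], 0)
  expect_equal(pe$score[2], 1.0)     # uniform over two symbols = 1 bit
  # gap excluded: column 4 has 5 informative rows, all A
  expect_equal(pm$score[4], 1.0)
  # row order invariance
  pm2 <- conservation_profile(msa(paste0("s", 1:6), rev(rows)))
  expect_equal(pm2$score, pm$score)
})

test_that("conserved-site selection unions threshold picks with anchors", {
  expect_identical(
    select_conserved_sites(NULL, anchors = glp1_anchors(),
                           template = semaglutide_template()),
    glp1_anchors())
  expect_length(select_conserved_sites(NULL, anchors = glp1_anchors(),
                                       template = semaglutide_template()), 13L)
  expect_error(select_conserved_sites(NULL, anchors = 99L,
                                      template = semaglutide_template()),
               "outside template range")

  rows <- list(c("H", "A", "E"), c("H", "G", "E"), c("H", "T", "Q"))
  al <- msa(c("t", "u", "v"), rows, numbering_start = 7L)
  prof <- conservation_profile(al)
  expect_identical(select_conserved_sites(prof, 1.0), 7L)
  # anchors are always a subset of the result
  got <- select_conserved_sites(prof, 0.5, anchors = c(8L, 9L))
  expect_true(all(c(8L, 9L) %in% got))
})

test_that("design mask partitions the template positions", {
  mask <- build_design_mask(semaglutide_spec())
  expect_length(mask$fixed, 13L)
  expect_length(mask$designable, 18L)
  expect_setequal(c(mask$fixed, mask$designable),
                  record_positions(semaglutide_template()))
  expect_length(intersect(mask$fixed, mask$designable), 0L)

  tpl <- semaglutide_template()
  all_free <- build_design_mask(template_spec(tpl))
  expect_length(all_free$designable, 31L)
  all_fixed <- build_design_mask(template_spec(tpl, record_positions(tpl)))
  expect_length(all_fixed$designable, 0L)
})

test_that("recovery counts matching positions over the template length", {
  tpl <- semaglutide_template()
  expect_equal(recovery(tpl, tpl), 1.00)
  # Aib matches Ala under the policy: canonical GLP-1 differs only at 34
  expect_equal(recovery(glp1_7_37(), tpl, digits = NULL), 30 / 31)

  cand <- tpl
  idx <- c(1, 5, 10, 15, 20, 25)          # mutate 6 of 31 positions
  cand$residues[idx] <- "P"
  expect_equal(recovery(cand, tpl, digits = NULL), 25 / 31)
  expect_equal(recovery(cand, tpl), 0.81)  # half-up 2-dp as reported
  expect_equal(recovery(cand, tpl), recovery(tpl, cand))  # symmetric

  none <- peptide_record("none", rep("P", 31))
  expect_equal(recovery(none, tpl), 0.00)
  expect_error(recovery(peptide_record("short", "HAE"), tpl), "numbering")
})

test_that("recovery equals 1 iff sequences are equivalent under the policy", {
  set.seed(401)
  tpl <- semaglutide_template()
  for (i in 1:20) {
    cand <- tpl
    nmut <- sample(0:5, 1)
    if (nmut > 0) {
      at <- sample(31, nmut)
      cand$residues[at] <- sample(setdiff(pepfunnel:::CANONICAL_AA,
                                          canonical_token(cand$residues[at])),
                                  nmut, replace = TRUE)
    }
    expect_equal(recovery(cand, tpl, digits = NULL) == 1, nmut == 0)
    expect_equal(recovery(cand, tpl, digits = NULL),
                 recovery(tpl, cand, digits = NULL))
  }
})

test_that("dedupe keeps first occurrences and is idempotent", {
  set.seed(7)
  base <- lapply(1:4, function(i) random_peptide(8, paste0("u", i)))
  pool <- c(base, lapply(5:10, function(i) {
    r <- base[[((i - 1) %% 4) + 1]]
    r$id <- paste0("d", i)
    r
  }))
  dd <- dedupe(pool)
  expect_equal(dd$n_unique, 4L)
  expect_equal(dd$n_duplicates, 6L)
  expect_identical(vapply(dd$records, `[[`, character(1), "id"),
                   paste0("u", 1:4))
  expect_true(all(names(dd$duplicate_of) == paste0("d", 5:10)))
  # idempotent
  dd2 <- dedupe(dd$records)
  expect_identical(dd2$records, dd$records)
  expect_equal(dd2$n_duplicates, 0L)
  # all-distinct input is the identity
  expect_identical(dedupe(base)$records, base)
})

test_that("global alignment matches the exhaustive enumeration oracle", {
  al <- global_align(c("G", "A", "T", "T"), c("G", "A", "T"))
  expect_equal(al$score,
               brute_force_align_score(c("G", "A", "T", "T"), c("G", "A", "T")))
  expect_equal(al$score, 2)

  ident <- global_align(rep("A", 5), rep("A", 5))
  expect_equal(ident$score, 5)
  expect_equal(ident$identity, 1.0)

  empty <- global_align(c("A", "G", "T"), character(0))
  expect_equal(empty$score, -3)

  set.seed(42)
  ab <- c("A", "G", "T")
  for (i in 1:60) {
    la <- sample(0:6, 1); lb <- sample(0:6, 1)
    a <- sample(ab, la, replace = TRUE)
    b <- sample(ab, lb, replace = TRUE)
    expect_equal(global_align(a, b)$score, brute_force_align_score(a, b),
                 info = paste(paste(a, collapse = ""), "vs",
                              paste(b, collapse = "")))
  }
})

test_that("alignment removes to its inputs and flags missing table tokens", {
  set.seed(9)
  a <- random_peptide(12)$residues
  b <- random_peptide(9)$residues
  al <- global_align(a, b)
  expect_identical(al$a_aligned[al$a_aligned != "-"], a)
  expect_identical(al$b_aligned[al$b_aligned != "-"], b)
  expect_gte(al$identity, 0)
  expect_lte(al$identity, 1)

  m <- matrix(1, 2, 2, dimnames = list(c("A", "G"), c("A", "G")))
  expect_error(global_align(c("A", "T"), c("A", "G"), substitution = m),
               "absent from substitution")
})

test_that("extended tokens match their surrogate in alignment identity", {
  sema <- semaglutide_template()
  glp1 <- glp1_7_37()
  # only position 34 (K vs R) differs once Aib ~ Ala
  expect_equal(alignment_identity(sema, glp1), 30 / 31)
})
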