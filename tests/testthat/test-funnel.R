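# Funnel orchestration, count conservation and the assay-table bookkeeping.

test_that("the stability stage removes exactly the spiked candidates", {
  spec <- generator_spec(n = 100L, distribution = motif_free_distribution(),
                         duplicate_fraction = 0, cleavage_spike = 40L,
                         seed = 19L)
  cands <- generate_candidates(spec)
  rep1 <- run_funnel(cands, semaglutide_spec(),
                     config = funnel_config(stages = "stability"))
  counts <- funnel_counts(rep1)
  expect_equal(counts$n_in, 100L)
  expect_equal(counts$n_out, 60L)
  expect_true(all(grepl("cleavage",
                        rep1$stages$stability$failed)))
})

test_that("an empty stage list passes everything through", {
  cands <- generate_candidates(generator_spec(n = 10L,
                                              duplicate_fraction = 0,
                                              seed = 2L))
  rep0 <- run_funnel(cands, semaglutide_spec(),
                     config = funnel_config(stages = character(0)))
  expect_length(rep0$stages, 0L)
  expect_length(rep0$final_ids, 10L)
  expect_true(all(rep0$scorecards$final_status == "pass"))
})

test_that("dedupe stage drop equals the generator's duplicate count", {
  spec <- generator_spec(n = 50L, duplicate_fraction = 0.3, seed = 8L)
  cands <- generate_candidates(spec)
  rep1 <- run_funnel(cands, semaglutide_spec(),
                     config = funnel_config(stages = "dedupe"))
  counts <- funnel_counts(rep1)
  expect_equal(counts$n_in - counts$n_out, round(0.3 * 50))
})

test_that("counts conserve and telescope across randomized campaigns", {
  for (seed in c(4L, 9L, 23L)) {
    spec <- generator_spec(n = 60L, distribution = motif_free_distribution(),
                           duplicate_fraction = 0.2,
                           cleavage_spike = sample(0:10, 1), seed = seed)
    cands <- generate_candidates(spec)
    cfg <- funnel_config(stages = c("dedupe", "stability", "diversity"),
                         target_count = 8L)
    rep1 <- run_funnel(cands, semaglutide_spec(), config = cfg)
    counts <- funnel_counts(rep1)
    # pass + fail = in at every stage; entering(i+1) = passing(i)
    for (s in rep1$stages)
      expect_equal(s$n_out + length(s$failed), s$n_in)
    expect_equal(counts$n_in[-1], counts$n_out[-nrow(counts)])
    expect_equal(counts$n_out[nrow(counts)], length(rep1$final_ids))
    expect_equal(sum(vapply(rep1$stages, function(s) length(s$failed),
                            integer(1))),
                 length(cands) - length(rep1$final_ids))
  }
})

test_that("stage order changes membership but never count conservation", {
  spec <- generator_spec(n = 40L, distribution = motif_free_distribution(),
                         duplicate_fraction = 0.25, cleavage_spike = 5L,
                         seed = 31L)
  cands <- generate_candidates(spec)
  for (stages in list(c("dedupe", "stability"), c("stability", "dedupe"))) {
    r <- run_funnel(cands, semaglutide_spec(),
                    config = funnel_config(stages = stages))
    for (s in r$stages)
      expect_equal(s$n_out + length(s$failed), s$n_in)
  }
})

test_that("the efficacy stage gates on structure metrics", {
  cands <- generate_candidates(
    generator_spec(n = 8L, distribution = motif_free_distribution(),
                   duplicate_fraction = 0, seed = 3L))
  ids <- vapply(cands, `[[`, character(1), "id")
  ref <- build_ideal_helix(semaglutide_template())
  structs <- stats::setNames(lapply(seq_along(cands), function(i) {
    sg <- if (i <= 4) 0.15 else 6.0     # half close to reference, half far
    perturb_structure(build_ideal_helix(cands[[i]]), sg, seed = 40L + i)
  }), ids)
  th <- derive_thresholds(struct_score(1, 0, 100, 0), slack = 0.2)
  cfg <- funnel_config(stages = "efficacy",
                       efficacy = list(thresholds = th))
  r <- run_funnel(cands, semaglutide_spec(), structures = structs,
                  reference = ref, config = cfg)
  expect_setequal(r$final_ids, ids[1:4])

  # strict mode: a candidate without a structure is an error
  expect_error(
    run_funnel(cands, semaglutide_spec(), structures = structs[1:3],
               reference = ref, config = cfg),
    "strict")
  # lenient mode: tagged not-evaluated, passes through
  cfg_len <- funnel_config(stages = "efficacy",
                           efficacy = list(thresholds = th), strict = FALSE)
  r2 <- run_funnel(cands[5:8], semaglutide_spec(), structures = NULL,
                   reference = ref, config = cfg_len)
  expect_length(r2$final_ids, 4L)
  expect_true(all(grepl("not evaluated", r2$stages$efficacy$notes)))
})

test_that("the diversity stage keeps one representative per cluster", {
  spec <- generator_spec(n = 30L, distribution = motif_free_distribution(),
                         duplicate_fraction = 0, seed = 77L)
  cands <- generate_candidates(spec)
  cfg <- funnel_config(stages = "diversity", target_count = 6L)
  r <- run_funnel(cands, semaglutide_spec(), config = cfg)
  expect_length(r$final_ids, 6L)
  # every survivor passes the patent cap against the template
  for (id in r$final_ids) {
    rec <- cands[[match(id, vapply(cands, `[[`, character(1), "id"))]]
    expect_true(patent_gate(rec, semaglutide_template(), 0.9)$passed)
  }
})

test_that("funnel runs are pure functions of inputs and config", {
  spec <- generator_spec(n = 40L, distribution = motif_free_distribution(),
                         duplicate_fraction = 0.2, cleavage_spike = 6L,
                         seed = 13L)
  cfg <- funnel_config(stages = c("dedupe", "stability", "diversity"),
                       target_count = 5L)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  r1 <- run_funnel(generate_candidates(spec), semaglutide_spec(),
                   config = cfg)
  r2 <- run_funnel(generate_candidates(spec), semaglutide_spec(),
                   config = cfg)
  write_report(r1, f1); write_report(r2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical
  expect_identical(r1$final_ids, r2$final_ids)
})

test_that("reports serialize losslessly with empty cells for missing scores", {
  cands <- generate_candidates(
    generator_spec(n = 12L, distribution = motif_free_distribution(),
                   duplicate_fraction = 0, seed = 5L))
  cfg <- funnel_config(stages = c("dedupe", "stability"))
  r <- run_funnel(cands, semaglutide_spec(), config = cfg)
  fj <- withr::local_tempfile(fileext = ".json")
  write_report(r, fj, "json")
  counts <- read_report_counts(fj)
  expect_equal(counts$n_in, funnel_counts(r)$n_in)
  expect_equal(counts$n_out, funnel_counts(r)$n_out)

  ft <- withr::local_tempfile(fileext = ".tsv")
  write_report(r, ft, "tsv")
  tab <- utils::read.delim(ft)
  expect_equal(nrow(tab), 12L)
  expect_true(all(is.na(tab$tm)))   # no structures: empty, not zero
  raw <- readLines(ft)
  expect_false(any(grepl("\tNA(\t|$)", raw[-1])))
})

test_that("relative expression is the plain density ratio", {
  expect_equal(relative_expression(0.87, 1.0), 0.87)
  expect_equal(relative_expression(1.11, 1.0), 1.11)  # > 1 permitted
  expect_equal(relative_expression(3.7, 3.7), 1.0)
  expect_error(relative_expression(0, 1), "positive")
  expect_error(relative_expression(1, -2), "positive")
})

test_that("the 0.7 expression filter excludes five and keeps the boundary", {
  tab <- glp1_assay_table()
  res <- apply_expression_filter(tab, 0.7)
  expect_length(res$excluded, 5L)
  expect_setequal(res$excluded, c("D19", "D35", "D50", "D57", "D59"))
  expect_true("D49" %in% res$retained)  # exactly 0.70 is retained

  # monotone in the threshold
  res_low <- apply_expression_filter(tab, 0.6)
  expect_true(all(res_low$excluded %in% res$excluded))
  expect_length(apply_expression_filter(tab, 0)$excluded, 0L)

  broken <- tab
  broken$relative_expression[broken$id == "D02"] <- NA
  expect_error(apply_expression_filter(broken), "missing relative expression")
})

test_that("label tallies match the recorded assay outcomes", {
  tab <- glp1_assay_table()
  expect_equal(nrow(tab), 60L)
  expect_equal(count_labels(tab, "pulldown", "Success"), 31L)
  expect_equal(count_labels(tab, "pulldown", "Fail"), 29L)
  expect_equal(count_labels(tab, "spr", "Success"), 6L)
  expect_equal(count_labels(tab[0, ], "pulldown", "Success"), 0L)
  expect_error(count_labels(tab, "nonexistent", "Success"),
               "unknown column")
  # the control row is available on request
  expect_equal(nrow(glp1_assay_table(include_reference = TRUE)), 61L)
})

test_that("funnel config validates stages and loads from YAML", {
  expect_error(funnel_config(stages = c("stability", "mystery")),
               "unknown stage")
  expect_error(funnel_config(stages = c("dedupe", "dedupe")), "unique")

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("stages: [dedupe, stability]",
               "target_count: 25",
               "stability:",
               "  max_cleavage_sites: 1",
               "  pH: 7.0",
               "diversity:",
               "  patent_cap: 0.85"), f)
  cfg <- read_funnel_config(f)
  expect_identical(cfg$stages, c("dedupe", "stability"))
  expect_equal(cfg$target_count, 25L)
  expect_equal(cfg$stability$max_cleavage_sites, 1L)
  expect_equal(cfg$stability$pH, 7.0)
  expect_equal(cfg$diversity$patent_cap, 0.85)
})
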