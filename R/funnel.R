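# Funnel orchestration: configured gate order, per-candidate scorecards,
# stage accounting and report serialization.

#' Funnel configuration
#'
#' Stage order defaults to the screening narrative: dedupe, stability,
#' efficacy, diversity.  Every stage is deterministic; `seed` is carried
#' for any stochastic stage a user might configure (none by default).
#'
#' @param stages character vector of stage names, a subset (in any order)
#'   of `"dedupe"`, `"stability"`, `"efficacy"`, `"diversity"`.
#' @param target_count desired number of final candidates; also the
#'   default diversity cluster count `k`.
#' @param stability a [stability_thresholds()].
#' @param efficacy list: `thresholds` (an [derive_thresholds()] result, or
#'   `NULL` to derive from the reference at run time) and `slack`.
#' @param diversity list: `k` (`NULL` = `target_count`), `rule`,
#'   `patent_cap`, `correction`.
#' @param strict if `TRUE` (default), candidates lacking a structure when
#'   the efficacy stage runs are an error; if `FALSE` they pass through
#'   tagged "not evaluated".
#' @param seed integer seed.
#' @return object of class `funnel_config`.
#' @export
funnel_config <- function(stages = c("dedupe", "stability", "efficacy",
                                     "diversity"),
                          target_count = 60L,
                          stability = stability_thresholds(),
                          efficacy = list(thresholds = NULL, slack = 0.1),
                          diversity = list(k = NULL, rule = "max_recovery",
                                           patent_cap = 0.9,
                                           correction = "none"),
                          strict = TRUE, seed = 1L) {
  known <- c("dedupe", "stability", "efficacy", "diversity")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(stages)) stop("stage names must be unique")
  structure(list(stages = stages, target_count = as.integer(target_count),
                 stability = stability, efficacy = efficacy,
                 diversity = diversity, strict = isTRUE(strict),
                 seed = as.integer(seed)),
            class = "funnel_config")
}

#' Load a funnel configuration from YAML
#'
#' Recognized blocks: top-level `stages`, `target_count`, `strict`;
#' `stability:` (arguments of [stability_thresholds()]); `efficacy:`
#' (`slack`); `diversity:` (`k`, `rule`, `patent_cap`, `correction`).
#'
#' @param path YAML file path.
#' @return a [funnel_config()].
#' @export
read_funnel_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- funnel_config()
  stab <- if (!is.null(y$stability))
    do.call(stability_thresholds, y$stability) else defaults$stability
  eff <- utils::modifyList(defaults$efficacy, y$efficacy %||% list())
  div <- utils::modifyList(defaults$diversity, y$diversity %||% list())
  funnel_config(stages = y$stages %||% defaults$stages,
                target_count = y$target_count %||% defaults$target_count,
                stability = stab, efficacy = eff, diversity = div,
                strict = y$strict %||% defaults$strict,
                seed = y$seed %||% defaults$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the screening funnel
#'
#' Executes the configured gates in order over a candidate pool, recording
#' per-stage pass/fail with reasons.  Count conservation holds at every
#' stage: candidates entering stage i+1 are exactly those passing stage i,
#' and passing + failing = entering.  The run is a pure function of its
#' inputs and configuration.
#'
#' @param candidates list of [peptide_record()]s.
#' @param template_spec a [template_spec()]; the template drives recovery
#'   and the patent gate.
#' @param structures named list of [structure_model()]s by candidate id
#'   (required by the efficacy stage).
#' @param pae named list of [pae_matrix()]s by candidate id (optional).
#' @param affinity named numeric vector of external affinities (optional).
#' @param reference reference complex [structure_model()] (required to
#'   derive efficacy thresholds when none are configured).
#' @param reference_pae [pae_matrix()] of the reference complex (optional).
#' @param config a [funnel_config()].
#' @return object of class `funnel_report`: `stages` (list of per-stage
#'   summaries), `scorecards` (data frame), `final_ids`, `config`.
#' @export
run_funnel <- function(candidates, template_spec, structures = NULL,
                       pae = NULL, affinity = NULL, reference = NULL,
                       reference_pae = NULL, config = funnel_config()) {
  stopifnot(length(candidates) > 0L, inherits(config, "funnel_config"),
            inherits(template_spec, "template_spec"))
  template <- template_spec$template
  ids <- vapply(candidates, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("candidate ids must be unique")
  names(candidates) <- ids

  cards <- data.frame(id = ids,
                      recovery = vapply(candidates, recovery, numeric(1),
                                        template = template),
                      row.names = NULL)
  for (m in c("n_cleavage", "net_charge", "gravy", "helix_propensity",
              "tm", "ca_rmsd", "mean_plddt", "interface_pae"))
    cards[[m]] <- NA_real_

  alive <- ids
  stages <- list()
  fail_reason <- stats::setNames(rep(NA_character_, length(ids)), ids)

  for (stage in config$stages) {
    entering <- alive
    res <- switch(stage,
      dedupe = stage_dedupe(candidates[entering]),
      stability = stage_stability(candidates[entering], config, cards),
      efficacy = stage_efficacy(candidates[entering], structures, pae,
                                affinity, reference, reference_pae, config),
      diversity = stage_diversity(candidates[entering], template, config))
    if (!is.null(res$cards)) {
      i <- match(res$cards$id, cards$id)
      for (m in setdiff(names(res$cards), "id"))
        cards[[m]][i] <- res$cards[[m]]
    }
    passed <- res$passed
    failed <- setdiff(entering, passed)
    fail_reason[failed] <- res$reason[failed]
    cards[[paste0("stage_", stage)]] <-
      ifelse(cards$id %in% passed, "pass",
             ifelse(cards$id %in% failed, "fail", NA))
    stages[[stage]] <- list(stage = stage, n_in = length(entering),
                            n_out = length(passed),
                            failed = stats::setNames(res$reason[failed],
                                                     failed),
                            notes = res$notes)
    alive <- passed
  }
  cards$final_status <- ifelse(cards$id %in% alive, "pass", "fail")
  structure(list(stages = stages, scorecards = cards, final_ids = alive,
                 config = config),
            class = "funnel_report")
}

stage_dedupe <- function(cands) {
  dd <- dedupe(unname(cands))
  keep <- vapply(dd$records, `[[`, character(1), "id")
  reason <- stats::setNames(paste("duplicate of", dd$duplicate_of),
                            names(dd$duplicate_of))
  list(passed = keep, reason = reason, notes = NULL, cards = NULL)
}

stage_stability <- function(cands, config, cards) {
  passed <- character(0)
  reason <- stats::setNames(character(length(cands)), names(cands))
  sc <- data.frame(id = names(cands), n_cleavage = NA_real_,
                   net_charge = NA_real_, gravy = NA_real_,
                   helix_propensity = NA_real_)
  for (i in seq_along(cands)) {
    r <- cands[[i]]
    g <- stability_gate(r, config$stability)
    sc$n_cleavage[i] <- nrow(scan_cleavage(r, mode = config$stability$scan_mode))
    sc$net_charge[i] <- net_charge(r, config$stability$pH)
    sc$gravy[i] <- gravy(r)
    sc$helix_propensity[i] <- helix_propensity(r)
    if (g$passed) passed <- c(passed, r$id)
    else reason[r$id] <- paste(g$reasons$criterion, collapse = "; ")
  }
  list(passed = passed, reason = reason, notes = NULL, cards = sc)
}

stage_efficacy <- function(cands, structures, pae, affinity, reference,
                           reference_pae, config) {
  thresholds <- config$efficacy$thresholds
  if (is.null(thresholds)) {
    if (is.null(reference))
      stop("efficacy stage needs configured thresholds or a reference complex")
    ref_scores <- score_structure(reference, reference, reference_pae)
    thresholds <- derive_thresholds(ref_scores,
                                    slack = config$efficacy$slack %||% 0.1)
  }
  passed <- character(0)
  notes <- character(0)
  reason <- stats::setNames(character(length(cands)), names(cands))
  sc <- data.frame(id = names(cands), tm = NA_real_, ca_rmsd = NA_real_,
                   mean_plddt = NA_real_, interface_pae = NA_real_)
  for (i in seq_along(cands)) {
    id <- names(cands)[i]
    st <- structures[[id]]
    if (is.null(st)) {
      if (config$strict)
        stop("no structure for candidate '", id,
             "' (strict mode); supply one or set strict = FALSE")
      notes <- c(notes, paste0(id, ": not evaluated (no structure)"))
      passed <- c(passed, id)
      next
    }
    scores <- score_structure(st, reference, pae[[id]],
                              affinity = affinity[id] %||% NA_real_)
    sc$tm[i] <- scores$tm; sc$ca_rmsd[i] <- scores$ca_rmsd
    sc$mean_plddt[i] <- scores$mean_plddt
    sc$interface_pae[i] <- scores$interface_pae
    g <- efficacy_gate(scores, thresholds)
    if (g$passed) passed <- c(passed, id)
    else reason[id] <- paste(g$reasons$criterion, collapse = "; ")
  }
  list(passed = passed, reason = reason, notes = notes, cards = sc)
}

stage_diversity <- function(cands, template, config) {
  k <- config$diversity$k %||% config$target_count
  cap <- config$diversity$patent_cap %||% 0.9
  reason <- stats::setNames(character(length(cands)), names(cands))
  ok <- character(0)
  for (id in names(cands)) {
    g <- patent_gate(cands[[id]], template, cap)
    if (g$passed) ok <- c(ok, id)
    else reason[id] <- "patent_identity"
  }
  if (length(ok) > max(k, 2L)) {
    dm <- identity_distance_matrix(cands[ok],
                                   correction = config$diversity$correction
                                   %||% "none")
    tree <- nj_tree(dm)
    clusters <- cut_clusters(tree, min(k, length(ok)))
    rec <- vapply(cands[ok], recovery, numeric(1), template = template)
    reps <- select_representatives(clusters,
                                   rule = config$diversity$rule
                                   %||% "max_recovery",
                                   recovery = rec, dist = dm)
    dropped <- setdiff(ok, reps)
    reason[dropped] <- "not cluster representative"
    ok <- reps[order(match(reps, names(cands)))]
  }
  list(passed = ok, reason = reason, notes = NULL, cards = NULL)
}

#' Stage count table
#'
#' @param report a [run_funnel()] report.
#' @return data frame with columns `stage`, `n_in`, `n_out`; counts
#'   telescope (`n_out` of the last stage equals the final list length).
#' @export
funnel_counts <- function(report) {
  stopifnot(inherits(report, "funnel_report"))
  do.call(rbind, lapply(report$stages, function(s)
    data.frame(stage = s$stage, n_in = s$n_in, n_out = s$n_out)))
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report> ", nrow(x$scorecards), " candidates -> ",
      length(x$final_ids), " final\n", sep = "")
  if (length(x$stages)) print(funnel_counts(x))
  invisible(x)
}

#' Serialize / reload a funnel report
#'
#' JSON serializes the stage summaries and the scorecards losslessly;
#' TSV writes the scorecard table (absent structure scores stay empty
#' cells, never zeros).  Output bytes are deterministic given the inputs.
#'
#' @param report a [run_funnel()] report.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(report$scorecards, path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  } else {
    payload <- list(
      counts = funnel_counts(report),
      stages = lapply(report$stages, function(s)
        list(stage = s$stage, n_in = s$n_in, n_out = s$n_out,
             failed = as.list(s$failed),
             notes = if (length(s$notes)) s$notes)),
      final_ids = report$final_ids,
      scorecards = report$scorecards)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report_counts <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$counts
}
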