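# Efficacy gate: structure scorecards, reference-derived thresholds, and
# external (MM/GBSA-style) affinity ingestion.

#' Structure score container
#'
#' @param tm TM-score in (0, 1].
#' @param ca_rmsd C-alpha RMSD in A (>= 0).
#' @param mean_plddt mean per-residue confidence in \[0, 100\].
#' @param interface_pae mean inter-chain PAE in A (>= 0).
#' @param sap_aggregate aggregate SAP score (optional).
#' @param affinity external binding-energy score, kcal/mol (optional; more
#'   negative is stronger).
#' @return object of class `struct_score`.
#' @export
struct_score <- function(tm, ca_rmsd, mean_plddt, interface_pae,
                         sap_aggregate = NA_real_, affinity = NA_real_) {
  stopifnot(tm > 0, tm <= 1, ca_rmsd >= 0,
            mean_plddt >= 0, mean_plddt <= 100, interface_pae >= 0)
  structure(list(tm = tm, ca_rmsd = ca_rmsd, mean_plddt = mean_plddt,
                 interface_pae = interface_pae,
                 sap_aggregate = sap_aggregate, affinity = affinity),
            class = "struct_score")
}

#' Score a predicted complex against the reference
#'
#' Computes the full efficacy scorecard for one candidate model: TM-score
#' and C-alpha RMSD of the peptide chain against the reference (after
#' superposition, see [tm_score()] / [ca_rmsd()]), mean pLDDT of the
#' peptide chain, interface PAE (if a PAE matrix is supplied), and the
#' aggregate SAP (if requested).
#'
#' @param model,reference [structure_model()]s of the candidate and native
#'   complex.
#' @param pae optional [pae_matrix()] for the candidate complex.
#' @param chain peptide chain id.
#' @param chain_receptor receptor chain id (for interface PAE).
#' @param sap_params a [sap_params()], or `NULL` to skip SAP.
#' @param affinity optional external affinity value.
#' @return a [struct_score()].
#' @export
score_structure <- function(model, reference, pae = NULL, chain = "A",
                            chain_receptor = "B", sap_params = NULL,
                            affinity = NA_real_) {
  struct_score(
    tm = tm_score(reference, model, chain = chain),
    ca_rmsd = ca_rmsd(model, reference, chain = chain),
    mean_plddt = mean_plddt(model, chain),
    interface_pae = if (!is.null(pae))
      interface_pae(pae, chain, chain_receptor) else 0,
    sap_aggregate = if (!is.null(sap_params))
      sap(model, sap_params)$aggregate else NA_real_,
    affinity = affinity)
}

#' Derive efficacy thresholds from the reference complex
#'
#' The native complex's own scores define the critical bounds, loosened by
#' a symmetric slack fraction: minimum TM and pLDDT are scaled down by
#' `1 - slack`; maximum RMSD and interface PAE are scaled up by
#' `1 + slack`, with the RMSD bound floored at `rmsd_floor` so that a
#' self-scored reference (RMSD 0) still admits finite deviation.
#'
#' @param reference_scores a [struct_score()] of the reference complex.
#' @param slack nonnegative slack fraction (default 0.1).
#' @param rmsd_floor lower floor for the RMSD bound in A.
#' @param max_sap optional cap on aggregate SAP.
#' @param max_affinity optional cap on external affinity.
#' @return object of class `efficacy_thresholds`.
#' @export
derive_thresholds <- function(reference_scores, slack = 0.1,
                              rmsd_floor = 0.5, max_sap = NA_real_,
                              max_affinity = NA_real_) {
  stopifnot(inherits(reference_scores, "struct_score"), slack >= 0)
  structure(list(
    min_tm = reference_scores$tm * (1 - slack),
    max_ca_rmsd = max(reference_scores$ca_rmsd, rmsd_floor) * (1 + slack),
    min_mean_plddt = reference_scores$mean_plddt * (1 - slack),
    max_interface_pae = reference_scores$interface_pae * (1 + slack),
    max_sap = max_sap, max_affinity = max_affinity, slack = slack),
    class = "efficacy_thresholds")
}

#' Efficacy gate
#'
#' Passes iff every bounded score satisfies its bound; `reasons` lists
#' each violation with observed value and bound.  A bound on an absent
#' (NA) score is an error: the gate never silently skips a configured
#' criterion.
#'
#' @param scores a [struct_score()].
#' @param thresholds an [derive_thresholds()] result (or compatible list).
#' @return a `gate_result`.
#' @export
efficacy_gate <- function(scores, thresholds) {
  stopifnot(inherits(scores, "struct_score"))
  reasons <- NULL
  chk <- function(value, bound, name, dir) {
    if (is.na(bound) || is.null(bound)) return(invisible())
    if (is.na(value))
      stop("score '", name, "' missing but a bound is set")
    bad <- if (dir == "min") value < bound else value > bound
    if (bad)
      reasons <<- add_reason(reasons, name, signif(value, 4),
                             paste0(if (dir == "min") ">= " else "<= ",
                                    signif(bound, 4)))
  }
  chk(scores$tm, thresholds$min_tm, "tm", "min")
  chk(scores$ca_rmsd, thresholds$max_ca_rmsd, "ca_rmsd", "max")
  chk(scores$mean_plddt, thresholds$min_mean_plddt, "mean_plddt", "min")
  chk(scores$interface_pae, thresholds$max_interface_pae,
      "interface_pae", "max")
  chk(scores$sap_aggregate, thresholds$max_sap, "sap_aggregate", "max")
  chk(scores$affinity, thresholds$max_affinity, "affinity", "max")
  gate_result(reasons)
}

#' Ingest externally computed affinities
#'
#' Reads a TSV with columns `id` and `affinity` (e.g. MM/GBSA binding
#' energies computed outside this package) into a named numeric vector.
#'
#' @param path TSV path.
#' @return named numeric vector (possibly empty).
#' @export
ingest_affinity <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", "affinity"), names(df))
  if (length(miss)) stop("affinity TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (anyDuplicated(df$id))
    stop("duplicate id(s) in affinity TSV: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  val <- suppressWarnings(as.numeric(df$affinity))
  if (anyNA(val)) stop("non-numeric affinity for id(s): ",
                       paste(df$id[is.na(val)], collapse = ", "))
  stats::setNames(val, df$id)
}
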