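# Stability gate: NEP-24.11 cleavage-site scanning and physicochemical
# scoring (net charge, isoelectric point, hydrophobicity, helix propensity).

#' NEP-24.11 cleavage rules
#'
#' Neutral endopeptidase 24.11 cleaves GLP-1 at six dipeptide sites in the
#' central and C-terminal regions: Asp15-Val16, Ser18-Tyr19, Tyr19-Leu20,
#' Glu27-Phe28, Phe28-Ile29 and Trp31-Leu32 (template numbering).
#' `cleavage_rule()` builds a single rule; `default_nep_rules()` returns
#' all six.
#'
#' @param label rule name.
#' @param p1,p1p residue tokens on either side of the scissile bond.
#' @param position template position of the P1 residue (optional; required
#'   for position-anchored scanning).
#' @return a `cleavage_rule`, or a list of six for `default_nep_rules()`.
#' @export
cleavage_rule <- function(label, p1, p1p, position = NULL) {
  stopifnot(is_registered_token(p1), is_registered_token(p1p))
  structure(list(label = label, p1 = p1, p1p = p1p,
                 position = if (!is.null(position)) as.integer(position)),
            class = "cleavage_rule")
}

#' @rdname cleavage_rule
#' @export
default_nep_rules <- function() {
  list(cleavage_rule("Asp15-Val16", "D", "V", 15L),
       cleavage_rule("Ser18-Tyr19", "S", "Y", 18L),
       cleavage_rule("Tyr19-Leu20", "Y", "L", 19L),
       cleavage_rule("Glu27-Phe28", "E", "F", 27L),
       cleavage_rule("Phe28-Ile29", "F", "I", 28L),
       cleavage_rule("Trp31-Leu32", "W", "L", 31L))
}

#' Scan a peptide for cleavage sites
#'
#' `position_anchored` mode (default) reports a hit for a rule iff the
#' residues at the rule's template position and the next position equal the
#' rule's P1-P1' pair; this follows the template-numbered site definitions.
#' `motif_scan` mode reports a hit at every adjacent pair matching the
#' dipeptide anywhere in the sequence (stricter: designed sequences may
#' relocate a motif).
#'
#' @param record a [peptide_record()].
#' @param rules list of [cleavage_rule()]s.
#' @param mode `"position_anchored"` or `"motif_scan"`.
#' @return data frame with columns `label`, `position` (template position
#'   of P1), `dipeptide`; zero rows if no hits; sorted by position.
#' @export
#' @examples
#' nrow(scan_cleavage(glp1_7_37()))  # 6
scan_cleavage <- function(record, rules = default_nep_rules(),
                          mode = c("position_anchored", "motif_scan")) {
  mode <- match.arg(mode)
  pos <- record_positions(record)
  res <- record$residues
  hits <- list()
  for (rule in rules) {
    if (mode == "position_anchored") {
      if (is.null(rule$position))
        stop("rule '", rule$label, "' has no template position; ",
             "use motif_scan mode")
      i <- match(rule$position, pos)
      if (!is.na(i) && i < length(res) &&
          tokens_match(res[i], rule$p1) && tokens_match(res[i + 1L], rule$p1p))
        hits[[length(hits) + 1L]] <-
          data.frame(label = rule$label, position = pos[i],
                     dipeptide = paste0(res[i], res[i + 1L]))
    } else {
      for (i in seq_len(length(res) - 1L)) {
        if (tokens_match(res[i], rule$p1) &&
            tokens_match(res[i + 1L], rule$p1p))
          hits[[length(hits) + 1L]] <-
            data.frame(label = rule$label, position = pos[i],
                       dipeptide = paste0(res[i], res[i + 1L]))
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits)
         else data.frame(label = character(), position = integer(),
                         dipeptide = character())
  out[order(out$position, out$label), , drop = FALSE]
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch sum: each basic group (N-terminus, His, Lys, Arg)
#' contributes \eqn{1/(1+10^{pH-pKa})}, each acidic group (C-terminus, Asp,
#' Glu, Cys, Tyr) contributes \eqn{-1/(1+10^{pKa-pH})}.  Aib carries no
#' side-chain charge.  A record annotated `c_terminus = "amide"` has no
#' C-terminal carboxyl.
#'
#' @param record a [peptide_record()].
#' @param pH pH in (0, 14); default 7.4 (physiological).
#' @param pka pKa table as from [pka_default()].
#' @return net charge in elementary charges.
#' @export
net_charge <- function(record, pH = 7.4, pka = pka_default()) {
  stopifnot(pH > 0, pH < 14)
  res <- canonical_token(record$residues)
  basic <- c("H", "K", "R")
  acidic <- c("D", "E", "C", "Y")
  pos_pka <- c(pka$nterm, pka$sidechain[res[res %in% basic]])
  neg_pka <- pka$sidechain[res[res %in% acidic]]
  if (!identical(record$annotations$c_terminus, "amide"))
    neg_pka <- c(pka$cterm, neg_pka)
  sum(1 / (1 + 10^(pH - pos_pka))) - sum(1 / (1 + 10^(neg_pka - pH)))
}

#' Isoelectric point by bisection
#'
#' Root of [net_charge()] on pH (0, 14) to 1e-3 pH tolerance.  Defined only
#' when the peptide has ionizable groups of both signs (sign change over
#' the interval).
#'
#' @inheritParams net_charge
#' @param tol pH tolerance of the bisection.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(record, pka = pka_default(), tol = 1e-3) {
  f <- function(pH) net_charge(record, pH, pka)
  lo <- 1e-6; hi <- 14 - 1e-6
  if (f(lo) <= 0 || f(hi) >= 0)
    stop("pI undefined: net charge has no sign change on (0, 14)")
  stats::uniroot(f, c(lo, hi), tol = tol / 10)$root
}

#' Mean hydropathy (GRAVY) and mean helix propensity
#'
#' Arithmetic per-residue means over an injectable scale; extended tokens
#' are scored through their canonical surrogate (Aib uses Ala's value).
#'
#' @param record a [peptide_record()].
#' @param scale named numeric vector over canonical residues.
#' @return numeric scalar (scale units per residue).
#' @export
#' @examples
#' gravy(peptide_record("a", "AAA"))  # 1.8 on Kyte-Doolittle
gravy <- function(record, scale = kyte_doolittle()) {
  mean(scale_value(record$residues, scale, "hydropathy scale"))
}

#' @rdname gravy
#' @export
helix_propensity <- function(record, scale = helix_scale_default()) {
  mean(scale_value(record$residues, scale, "helix propensity scale"))
}

#' Stability thresholds
#'
#' Cleavage sites are capped at `max_cleavage_sites` (default 0: any site
#' rejects, the stated filter).  The physicochemical bounds default to
#' non-rejecting (infinite) because no numeric cutoffs are published for
#' them; set them to make the gate bite, or leave them for report-only
#' profiling.
#'
#' @param max_cleavage_sites maximum allowed cleavage hits.
#' @param charge_range length-2 numeric, allowed net-charge interval at `pH`.
#' @param gravy_max maximum mean hydropathy.
#' @param helix_min minimum mean helix propensity.
#' @param pi_exclude optional length-2 pH window the pI must avoid.
#' @param pH pH at which net charge is evaluated.
#' @param scan_mode cleavage scan mode, see [scan_cleavage()].
#' @return object of class `stability_thresholds`.
#' @export
stability_thresholds <- function(max_cleavage_sites = 0L,
                                 charge_range = c(-Inf, Inf),
                                 gravy_max = Inf,
                                 helix_min = -Inf,
                                 pi_exclude = NULL,
                                 pH = 7.4,
                                 scan_mode = "position_anchored") {
  stopifnot(length(charge_range) == 2L, charge_range[1] <= charge_range[2])
  if (!is.null(pi_exclude))
    stopifnot(length(pi_exclude) == 2L, pi_exclude[1] <= pi_exclude[2])
  structure(list(max_cleavage_sites = as.integer(max_cleavage_sites),
                 charge_range = charge_range, gravy_max = gravy_max,
                 helix_min = helix_min, pi_exclude = pi_exclude,
                 pH = pH, scan_mode = scan_mode),
            class = "stability_thresholds")
}

gate_result <- function(reasons) {
  if (is.null(reasons) || nrow(reasons) == 0L)
    reasons <- data.frame(criterion = character(), observed = character(),
                          bound = character())
  structure(list(passed = nrow(reasons) == 0L, reasons = reasons),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat("<gate_result> ", if (x$passed) "PASS" else "FAIL", "\n", sep = "")
  if (!x$passed) print(x$reasons)
  invisible(x)
}

add_reason <- function(reasons, criterion, observed, bound) {
  rbind(reasons, data.frame(criterion = criterion,
                            observed = as.character(observed),
                            bound = as.character(bound)))
}

#' Stability gate
#'
#' Evaluates the cleavage-site count and the physicochemical bounds of
#' `thresholds`; the result fails iff at least one bound is violated, and
#' `reasons` lists every violation with the observed value and the bound
#' (so each reported violation can be re-tested independently).
#'
#' @param record a [peptide_record()].
#' @param thresholds a [stability_thresholds()].
#' @param rules cleavage rules for [scan_cleavage()].
#' @return a `gate_result` (fields `passed`, `reasons`).
#' @export
stability_gate <- function(record, thresholds = stability_thresholds(),
                           rules = default_nep_rules()) {
  stopifnot(inherits(thresholds, "stability_thresholds"))
  reasons <- NULL
  hits <- scan_cleavage(record, rules, thresholds$scan_mode)
  if (nrow(hits) > thresholds$max_cleavage_sites)
    reasons <- add_reason(reasons, "cleavage_sites",
                          paste0(nrow(hits), " (",
                                 paste(hits$label, collapse = ", "), ")"),
                          paste0("<= ", thresholds$max_cleavage_sites))
  q <- net_charge(record, thresholds$pH)
  if (q < thresholds$charge_range[1] || q > thresholds$charge_range[2])
    reasons <- add_reason(reasons, "net_charge", signif(q, 4),
                          paste0("[", thresholds$charge_range[1], ", ",
                                 thresholds$charge_range[2], "]"))
  g <- gravy(record)
  if (g > thresholds$gravy_max)
    reasons <- add_reason(reasons, "gravy", signif(g, 4),
                          paste0("<= ", thresholds$gravy_max))
  h <- helix_propensity(record)
  if (h < thresholds$helix_min)
    reasons <- add_reason(reasons, "helix_propensity", signif(h, 4),
                          paste0(">= ", thresholds$helix_min))
  if (!is.null(thresholds$pi_exclude)) {
    pi <- tryCatch(isoelectric_point(record), error = function(e) NA_real_)
    if (!is.na(pi) && pi >= thresholds$pi_exclude[1] &&
        pi <= thresholds$pi_exclude[2])
      reasons <- add_reason(reasons, "isoelectric_point", signif(pi, 4),
                            paste0("outside [", thresholds$pi_exclude[1],
                                   ", ", thresholds$pi_exclude[2], "]"))
  }
  gate_result(reasons)
}

#' Physicochemical profile of a peptide
#'
#' @param record a [peptide_record()].
#' @param pH pH for net charge.
#' @return data frame row: `id`, `length`, `net_charge`, `pI` (`NA` when
#'   undefined), `gravy`, `helix_propensity`.
#' @export
physchem_profile <- function(record, pH = 7.4) {
  data.frame(id = record$id,
             length = length(record),
             net_charge = net_charge(record, pH),
             pI = tryCatch(isoelectric_point(record),
                           error = function(e) NA_real_),
             gravy = gravy(record),
             helix_propensity = helix_propensity(record))
}
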