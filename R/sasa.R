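# Shrake-Rupley solvent-accessible surface area and spatial aggregation
# propensity (SAP).

# deterministic golden-spiral point set on the unit sphere
golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley per-atom SASA
#'
#' Sphere-point sampling on each atom's solvent-expanded sphere (van der
#' Waals radius + probe) with a deterministic golden-spiral point set, so
#' results are bit-reproducible.  A point is accessible if it lies outside
#' every neighbouring atom's expanded sphere; neighbours are atoms within
#' \eqn{r_i + r_j + 2 \cdot probe}.
#'
#' @param model a [structure_model()].
#' @param probe probe radius in A (water, 1.4).
#' @param n_points sphere points per atom (>= 64); more points, tighter
#'   quadrature.
#' @return numeric vector of per-atom SASA (A^2), in atom order.
#' @export
shrake_rupley <- function(model, probe = 1.4, n_points = 256L) {
  stopifnot(n_points >= 64L)
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- vdw_radius(a$element)
  n <- nrow(xyz)
  pts <- golden_spiral(n_points)
  d2 <- as.matrix(stats::dist(xyz))^2
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    ri <- radii[i] + probe
    cutoff <- (radii[i] + radii + 2 * probe)^2
    nb <- which(d2[i, ] < cutoff & seq_len(n) != i)
    if (length(nb) == 0L) {
      sasa[i] <- 4 * pi * ri^2
      next
    }
    sp <- sweep(pts * ri, 2L, xyz[i, ], `+`)     # points on sphere i
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      rj2 <- (radii[j] + probe)^2
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 >= rj2
      if (!any(acc)) break
    }
    sasa[i] <- 4 * pi * ri^2 * sum(acc) / n_points
  }
  sasa
}

#' SAP parameters
#'
#' @param radius spatial neighbourhood radius in A.
#' @param hydrophobicity normalized residue hydrophobicity scale
#'   (Gly-centered by default, see [sap_hydrophobicity_default()]).
#' @param ref_sasa fully-exposed reference SASA per residue type (A^2).
#' @param probe probe radius for the underlying SASA.
#' @param n_points sphere points for the underlying SASA.
#' @return object of class `sap_params`.
#' @export
sap_params <- function(radius = 5.0,
                       hydrophobicity = sap_hydrophobicity_default(),
                       ref_sasa = max_sasa_default(),
                       probe = 1.4, n_points = 256L) {
  stopifnot(radius > 0, all(ref_sasa > 0))
  structure(list(radius = radius, hydrophobicity = hydrophobicity,
                 ref_sasa = ref_sasa, probe = probe,
                 n_points = as.integer(n_points)),
            class = "sap_params")
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Spatial aggregation propensity
#'
#' For each residue r, SAP(r) sums, over every side-chain atom j lying
#' within `radius` of any atom of r, the atom's exposed fraction
#' (SASA_j / reference SASA of j's residue type) times the residue-type
#' hydrophobicity.  High positive values flag exposed hydrophobic patches.
#' The aggregate score sums `max(SAP(r), 0)` over residues.
#'
#' @param model a [structure_model()].
#' @param params a [sap_params()].
#' @param sasa optional precomputed per-atom SASA (from
#'   [shrake_rupley()]); computed if `NULL`.
#' @return list with `per_residue` (data frame `chain`, `resno`, `resname`,
#'   `sap`) and `aggregate`.
#' @export
sap <- function(model, params = sap_params(), sasa = NULL) {
  stopifnot(inherits(params, "sap_params"))
  a <- model$atoms
  if (is.null(sasa))
    sasa <- shrake_rupley(model, params$probe, params$n_points)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  tok <- resname_to_token(a$resname)
  if (anyNA(tok))
    stop("unknown residue name(s): ",
         paste(unique(a$resname[is.na(tok)]), collapse = ", "))
  key <- canonical_token(tok)
  miss <- setdiff(unique(key), names(params$ref_sasa))
  if (length(miss))
    stop("residue type(s) missing from reference SASA table: ",
         paste(miss, collapse = ", "))
  side <- !(a$atom %in% BACKBONE_ATOMS)
  contrib <- ifelse(side,
                    sasa / params$ref_sasa[key] * params$hydrophobicity[key],
                    0)
  res_id <- paste(a$chain, a$resno)
  ures <- unique(res_id)
  d <- as.matrix(stats::dist(xyz))
  per <- vapply(ures, function(r) {
    mine <- res_id == r
    near <- apply(d[, mine, drop = FALSE], 1L, min) <= params$radius
    sum(contrib[side & near])
  }, numeric(1))
  first <- match(ures, res_id)
  list(per_residue = data.frame(chain = a$chain[first],
                                resno = a$resno[first],
                                resname = a$resname[first],
                                sap = unname(per)),
       aggregate = sum(pmax(per, 0)))
}
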