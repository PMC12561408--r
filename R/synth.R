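# Synthetic inputs: template-constrained candidate pools (with duplicates
# and cleavage spikes), ideal alpha-helical structures with controlled
# perturbation, and mock confidence files.  All randomness flows through an
# explicit seed; the global RNG state is saved and restored.

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Candidate-pool generator specification
#'
#' Defaults mirror the design campaign being emulated: 10,000 candidates
#' with a duplicate fraction of 0.8557 (so about 1,443 unique sequences),
#' substitutions at the 18 designable template positions drawn uniformly
#' over the canonical alphabet.  The generator is a stand-in exercising
#' the funnel, not a model of any learned sequence distribution.
#'
#' @param template_spec a [template_spec()]; defaults to
#'   [semaglutide_spec()].
#' @param n pool size.
#' @param distribution named probability vector over residue tokens for
#'   designable positions (`NULL` = uniform over the 20 canonical).
#' @param duplicate_fraction fraction of records that are copies of
#'   earlier records, in \[0, 1).
#' @param cleavage_spike number of candidates that get one cleavage-site
#'   dipeptide installed.
#' @param seed integer seed.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(template_spec = semaglutide_spec(), n = 10000L,
                           distribution = NULL, duplicate_fraction = 0.8557,
                           cleavage_spike = 0L, seed = 1L) {
  stopifnot(n > 0, duplicate_fraction >= 0, duplicate_fraction < 1,
            cleavage_spike >= 0)
  if (!is.null(distribution)) {
    bad <- !is_registered_token(names(distribution))
    if (any(bad))
      stop("distribution assigns mass to unregistered token(s): ",
           paste(names(distribution)[bad], collapse = ", "))
    distribution <- distribution / sum(distribution)
  }
  structure(list(template_spec = template_spec, n = as.integer(n),
                 distribution = distribution,
                 duplicate_fraction = duplicate_fraction,
                 cleavage_spike = as.integer(cleavage_spike),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a template-constrained candidate pool
#'
#' Every record keeps the template residues at the anchored positions;
#' designable positions are sampled from the configured distribution.  The
#' first `n - round(f n)` records are fresh draws (the first
#' `cleavage_spike` of them get one cleavage dipeptide installed); the
#' remaining `round(f n)` duplicate earlier fresh records under new ids,
#' realizing the duplicate fraction `f`.  Fully reproducible from the
#' seed.
#'
#' @param spec a [generator_spec()].
#' @return list of [peptide_record()]s with ids `D00001`, `D00002`, ...
#' @export
generate_candidates <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  tpl <- spec$template_spec$template
  mask <- build_design_mask(spec$template_spec)
  pos <- record_positions(tpl)
  des <- match(mask$designable, pos)
  tokens <- if (is.null(spec$distribution)) CANONICAL_AA
            else names(spec$distribution)
  probs <- if (is.null(spec$distribution)) NULL else spec$distribution
  n_dup <- round(spec$duplicate_fraction * spec$n)
  n_fresh <- spec$n - n_dup
  if (spec$cleavage_spike > n_fresh)
    stop("cleavage_spike exceeds the number of fresh candidates")
  with_seed(spec$seed, {
    fresh <- vector("list", n_fresh)
    for (i in seq_len(n_fresh)) {
      res <- tpl$residues
      res[des] <- sample(tokens, length(des), replace = TRUE, prob = probs)
      rec <- peptide_record(sprintf("D%05d", i), res,
                            numbering_start = tpl$numbering_start)
      if (i <= spec$cleavage_spike)
        rec <- spike_cleavage_sites(rec, count = 1L,
                                    seed = spec$seed + i,
                                    template_spec = spec$template_spec)
      fresh[[i]] <- rec
    }
    dups <- if (n_dup > 0L) {
      src <- sample.int(n_fresh, n_dup, replace = TRUE)
      lapply(seq_len(n_dup), function(j) {
        r <- fresh[[src[j]]]
        r$id <- sprintf("D%05d", n_fresh + j)
        r
      })
    } else list()
    c(fresh, dups)
  })
}

#' Install cleavage-site dipeptides into a record
#'
#' Overwrites the residues at `count` rule positions (chosen by seed) with
#' the rule's P1-P1' pair, leaving every other position untouched.  A rule
#' conflicts with the template specification when either of its two
#' positions is anchored with a different required residue; conflicting
#' rules are unavailable, and requesting more sites than available rules is
#' an error.
#'
#' @param record a [peptide_record()].
#' @param rules list of position-carrying [cleavage_rule()]s.
#' @param count number of sites to install.
#' @param seed integer seed for rule choice.
#' @param template_spec optional [template_spec()] for conflict checking.
#' @return the modified [peptide_record()].
#' @export
spike_cleavage_sites <- function(record, rules = default_nep_rules(),
                                 count = 1L, seed = 1L,
                                 template_spec = NULL) {
  if (count == 0L) return(record)
  pos <- record_positions(record)
  ok <- vapply(rules, function(rule) {
    if (is.null(rule$position)) return(FALSE)
    i <- match(rule$position, pos)
    if (is.na(i) || i >= length(pos)) return(FALSE)
    if (!is.null(template_spec)) {
      anch <- template_spec$anchored_positions
      tpl <- template_spec$template
      for (off in 0:1) {
        p <- rule$position + off
        if (p %in% anch) {
          need <- tpl$residues[match(p, record_positions(tpl))]
          want <- if (off == 0L) rule$p1 else rule$p1p
          if (!tokens_match(need, want)) return(FALSE)
        }
      }
    }
    TRUE
  }, logical(1))
  if (count > sum(ok))
    stop("requested ", count, " sites but only ", sum(ok),
         " rules are available without conflicting with fixed positions")
  chosen <- with_seed(seed, sample(which(ok), count))
  for (ci in chosen) {
    rule <- rules[[ci]]
    i <- match(rule$position, pos)
    record$residues[i] <- rule$p1
    record$residues[i + 1L] <- rule$p1p
  }
  record
}

#' Ideal-helix geometry parameters
#'
#' Canonical alpha-helix dihedrals (phi -57, psi -47, omega 180 degrees)
#' and standard backbone stereochemistry (N-CA 1.458, CA-C 1.525, C-N
#' 1.329 A; angles N-CA-C 111.0, CA-C-N 116.2, C-N-CA 121.7 degrees).
#'
#' @param phi,psi,omega backbone dihedrals in degrees.
#' @return object of class `helix_params`.
#' @export
helix_params <- function(phi = -57, psi = -47, omega = 180) {
  stopifnot(all(c(phi, psi, omega) > -180), all(c(phi, psi, omega) <= 180))
  structure(list(phi = phi, psi = psi, omega = omega,
                 b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                 a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
                 b_c_o = 1.231, a_ca_c_o = 120.8,
                 b_ca_cb = 1.521, a_n_ca_cb = 110.5),
            class = "helix_params")
}

# NeRF: place D given A-B-C with bond |CD|, angle B-C-D, dihedral A-B-C-D
nerf_place <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Build an ideal alpha-helical structure for a peptide
#'
#' Sequential internal-coordinate (NeRF) construction of the backbone
#' (N, CA, C, O) at the configured helix dihedrals; a CB is added for
#' non-glycine residues at tetrahedral geometry.  Residues are numbered by
#' the record's template numbering, the chain id is configurable and
#' per-residue confidence is initialized to 100.
#'
#' @param record a [peptide_record()].
#' @param params a [helix_params()].
#' @param chain chain identifier.
#' @return a [structure_model()].
#' @export
build_ideal_helix <- function(record, params = helix_params(),
                              chain = "A") {
  n_res <- length(record)
  res3 <- token_to_resname(record$residues)
  pos <- record_positions(record)
  atoms <- list()
  serial <- 0L
  add <- function(name, xyz, resno, resname, element) {
    serial <<- serial + 1L
    atoms[[serial]] <<- data.frame(
      serial = serial, atom = name, resname = resname, chain = chain,
      resno = resno, x = xyz[1], y = xyz[2], z = xyz[3], b = 100,
      element = element)
  }
  # first residue in a canonical local frame
  N <- c(0, 0, 0)
  CA <- c(params$b_n_ca, 0, 0)
  ang <- params$a_n_ca_c * pi / 180
  C <- CA + params$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    add("N", N, pos[i], res3[i], "N")
    add("CA", CA, pos[i], res3[i], "C")
    add("C", C, pos[i], res3[i], "C")
    # O in the peptide plane, anti to the chain direction (psi + 180)
    O <- nerf_place(N, CA, C, params$b_c_o, params$a_ca_c_o,
                    params$psi + 180)
    add("O", O, pos[i], res3[i], "O")
    if (canonical_token(record$residues[i]) != "G") {
      CB <- place_cb(N, CA, C, params$b_ca_cb, params$a_n_ca_cb)
      add("CB", CB, pos[i], res3[i], "C")
    }
    if (i < n_res) {
      N1 <- nerf_place(N, CA, C, params$b_c_n, params$a_ca_c_n, params$psi)
      CA1 <- nerf_place(CA, C, N1, params$b_n_ca, params$a_c_n_ca,
                        params$omega)
      C1 <- nerf_place(C, N1, CA1, params$b_ca_c, params$a_n_ca_c,
                       params$phi)
      N <- N1; CA <- CA1; C <- C1
    }
  }
  structure_model(do.call(rbind, atoms))
}

# tetrahedral CB: equal angles to the N and C directions, L-chirality
place_cb <- function(N, CA, C, bond, angle_deg) {
  u1 <- N - CA; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- C - CA; u2 <- u2 / sqrt(sum(u2^2))
  bis <- u1 + u2; bis <- bis / sqrt(sum(bis^2))
  perp <- pracma_cross(u2, u1); perp <- perp / sqrt(sum(perp^2))
  target <- cos(angle_deg * pi / 180)
  half <- sum(bis * u1)
  cg <- min(1, max(-1, -target / half))
  sg <- sqrt(max(0, 1 - cg^2))
  CA + bond * (-bis * cg + perp * sg) * c(1)
}

#' Perturb a structure with isotropic Gaussian noise
#'
#' Adds independent N(0, sigma^2) displacements to every atomic
#' coordinate; `sigma = 0` returns the model unchanged; the same seed
#' gives the same perturbation.
#'
#' @param model a [structure_model()].
#' @param sigma displacement standard deviation in A.
#' @param seed integer seed.
#' @return the perturbed [structure_model()].
#' @export
perturb_structure <- function(model, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(model)
  n <- nrow(model$atoms)
  noise <- with_seed(seed, matrix(stats::rnorm(3L * n, sd = sigma), n, 3L))
  model$atoms$x <- model$atoms$x + noise[, 1]
  model$atoms$y <- model$atoms$y + noise[, 2]
  model$atoms$z <- model$atoms$z + noise[, 3]
  model
}

#' Mock per-residue confidence and PAE for a two-chain complex
#'
#' Draws pLDDT around the requested per-chain means (clipped to
#' \[0, 100\]) and builds a PAE matrix with the requested intra- and
#' inter-chain levels, plus seeded Gaussian noise clamped at zero.
#'
#' @param model_lengths named integer vector of chain lengths (two
#'   chains).
#' @param plddt_levels named numeric vector of per-chain mean pLDDT.
#' @param pae_levels numeric vector `c(intra = , inter = )`, both >= 0.
#' @param seed integer seed.
#' @param noise_sd Gaussian noise standard deviation (0 = exact levels).
#' @return list with `plddt` (data frame `chain`, `resno`, `plddt`) and
#'   `pae` (a [pae_matrix()]).
#' @export
mock_confidence <- function(model_lengths, plddt_levels,
                            pae_levels = c(intra = 5, inter = 10),
                            seed = 1L, noise_sd = 0) {
  stopifnot(length(model_lengths) == 2L,
            all(names(model_lengths) %in% names(plddt_levels)))
  if (any(pae_levels < 0)) stop("requested PAE levels must be nonnegative")
  n <- sum(model_lengths)
  chains <- rep(names(model_lengths), model_lengths)
  with_seed(seed, {
    plddt <- data.frame(
      chain = chains,
      resno = unlist(lapply(unname(model_lengths), seq_len)),
      plddt = pmin(100, pmax(0, plddt_levels[chains] +
                               stats::rnorm(n, sd = noise_sd))))
    same <- outer(chains, chains, `==`)
    mat <- ifelse(same, pae_levels[["intra"]], pae_levels[["inter"]])
    mat <- mat + matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
    diag(mat) <- 0
    mat <- pmax(mat, 0)
    list(plddt = plddt, pae = pae_matrix(mat, model_lengths))
  })
}

#' Write a complete synthetic fixture set
#'
#' Generates a candidate pool, the reference complex (two ideal helices),
#' per-candidate structures and confidence files, and an affinity TSV
#' under `dir`, with a manifest recording seeds and parameters.  This is
#' the file-level entry point behind the `synth` CLI subcommand.
#'
#' @param dir output directory (created if needed).
#' @param spec a [generator_spec()].
#' @param n_structures number of candidates (taken from the head of the
#'   pool) for which structures and confidence files are written.
#' @return invisibly, the manifest list.
#' @export
write_synthetic_fixtures <- function(dir, spec = generator_spec(n = 100L),
                                     n_structures = 5L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cands <- generate_candidates(spec)
  write_fasta(cands, file.path(dir, "candidates.fasta"))
  tpl <- spec$template_spec$template
  ref <- build_ideal_helix(tpl, chain = "A")
  write_pdb(ref, file.path(dir, "reference.pdb"))
  ids <- vapply(cands[seq_len(min(n_structures, length(cands)))],
                `[[`, character(1), "id")
  for (i in seq_along(ids)) {
    m <- build_ideal_helix(cands[[i]], chain = "A")
    m <- perturb_structure(m, sigma = 0.2, seed = spec$seed + i)
    write_pdb(m, file.path(dir, paste0(ids[i], ".pdb")))
    conf <- mock_confidence(c(A = length(cands[[i]]), B = 40L),
                            c(A = 90, B = 85), seed = spec$seed + i)
    write_pae_json(conf$pae, file.path(dir, paste0(ids[i], "_pae.json")))
  }
  utils::write.table(
    data.frame(id = ids, affinity = -40 - seq_along(ids)),
    file.path(dir, "affinity.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(seed = spec$seed, n = spec$n,
                   duplicate_fraction = spec$duplicate_fraction,
                   cleavage_spike = spec$cleavage_spike,
                   structures = ids)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
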