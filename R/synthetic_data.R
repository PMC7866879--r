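# Synthetic-data generators.  These replace the MD engine and the external
# calculators (pKa solver, folding-energy and sequence predictors) with
# distributionally matched stand-ins carrying known ground truth, so every
# downstream metric can be validated by planted-effect recovery.  All
# generators are pure functions of their spec plus a mandatory seed.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# natural-extension (NeRF) placement: new atom bonded to c with bond length
# r, angle b-c-new theta, dihedral a-b-c-new chi (degrees)
.place_atom <- function(a, b, c, r, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cbind(bc, .cross3(n, bc), n)
  d <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
  as.numeric(c + m %*% d)
}

#' Generate an ideal toy backbone structure
#'
#' Builds an N-CA-C-O backbone with standard bond geometry (N-CA 1.458,
#' CA-C 1.525, C-N 1.329, C=O 1.231 angstrom; trans peptide) and preset
#' phi/psi torsions: canonical alpha-helix (-57/-47), beta-strand
#' (-139/135), or a deterministic mixed "coil". Deterministic for a given
#' spec.
#'
#' @param n_residues number of residues (>= 3)
#' @param preset "helix", "strand" or "coil"
#' @param chain chain identifier (default "A")
#' @param start_resseq first author residue number (default 1)
#' @return a `protein_structure` (residues named ALA)
#' @export
make_structure <- function(n_residues, preset = c("helix", "strand", "coil"),
                           chain = "A", start_resseq = 1) {
  preset <- match.arg(preset)
  stopifnot(n_residues >= 3)
  tor <- switch(preset,
    helix = list(phi = rep(-57, n_residues), psi = rep(-47, n_residues)),
    strand = list(phi = rep(-139, n_residues), psi = rep(135, n_residues)),
    coil = list(phi = -100 + 40 * sin(seq_len(n_residues)),
                psi = 120 + 30 * cos(2 * seq_len(n_residues))))
  xyz <- matrix(0, 4 * n_residues, 3)
  nm <- rep(c("N", "CA", "C", "O"), n_residues)
  iN <- function(i) 4 * (i - 1) + 1
  # first residue laid out in the xy-plane
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  xyz[3, ] <- xyz[2, ] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_residues)) {
    if (i > 1) {
      pN <- iN(i - 1); pCA <- pN + 1; pC <- pN + 2
      xyz[iN(i), ] <- .place_atom(xyz[pN, ], xyz[pCA, ], xyz[pC, ],
                                  1.329, 116.2, tor$psi[i - 1])
      xyz[iN(i) + 1, ] <- .place_atom(xyz[pCA, ], xyz[pC, ], xyz[iN(i), ],
                                      1.458, 121.7, 180)
      xyz[iN(i) + 2, ] <- .place_atom(xyz[pC, ], xyz[iN(i), ], xyz[iN(i) + 1, ],
                                      1.525, 111.2, tor$phi[i])
    }
    xyz[iN(i) + 3, ] <- .place_atom(xyz[iN(i), ], xyz[iN(i) + 1, ], xyz[iN(i) + 2, ],
                                    1.231, 120.8, tor$psi[i] + 180)
  }
  atoms <- data.frame(
    serial = seq_len(4 * n_residues), name = nm, alt = "",
    resname = "ALA", chain = chain,
    resseq = rep(start_resseq + seq_len(n_residues) - 1, each = 4), icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
    element = rep(c("N", "C", "C", "O"), n_residues), is_hetero = FALSE,
    stringsAsFactors = FALSE)
  .new_structure(atoms, title = paste("synthetic", preset, "backbone"))
}

#' Specification for a synthetic conformational ensemble
#'
#' Defaults mirror a standard production protocol: 1000 stored frames at
#' 10 ps intervals, 10 replicates, per-coordinate Gaussian fluctuation
#' sigma of 0.3 angstrom.
#'
#' @param n_frames frames per replicate (default 1000)
#' @param frame_interval ps between frames (default 10)
#' @param n_replicates replicates (default 10)
#' @param sigma per-coordinate fluctuation s.d., angstrom; scalar or
#'   per-residue vector (default 0.3)
#' @param modes list of planted collective modes, each
#'   `list(window = c(lo, hi) residue numbers, direction = 3-vector,
#'   amplitude = angstrom, cycles = periods over the trajectory)`
#' @param outliers `list(count =, factor =)`: number of replicates whose
#'   sigma is inflated by `factor`
#' @param seed mandatory RNG seed
#' @return list of class `ensemble_spec`
#' @export
ensemble_spec <- function(n_frames = 1000, frame_interval = 10,
                          n_replicates = 10, sigma = 0.3, modes = list(),
                          outliers = list(count = 0, factor = 2.5), seed) {
  if (missing(seed)) stop("seed is mandatory for every stochastic generator")
  stopifnot(all(sigma > 0), n_frames >= 2, n_replicates >= 1)
  structure(list(n_frames = n_frames, frame_interval = frame_interval,
                 n_replicates = n_replicates, sigma = sigma, modes = modes,
                 outliers = outliers, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Generate a replicate set of Gaussian fluctuation ensembles
#'
#' Frames are the reference coordinates plus independent per-coordinate
#' Gaussian noise (sigma profile, optionally scaled over a variant's effect
#' window), plus planted low-rank collective modes (sinusoidal amplitude
#' over frames along the mode direction, replicate-specific phase), plus a
#' constant mean-shift offset for variants that perturb the local structure.
#' Outlier replicates receive inflated sigma. Fluctuations are sampled
#' i.i.d. per frame (no autocorrelation); the metrics consuming them (RMSF,
#' median RMSD, PCA) are distributional, so this is sufficient for recovery
#' testing but is not kinetics.
#'
#' @param structure reference `protein_structure`
#' @param spec an [ensemble_spec()]
#' @param variant_effect optional `list(label =, rmsf = list(window, multiplier),
#'   mean_shift = list(window, disp))` planting a region-specific fluctuation
#'   change and/or mean displacement (disp: 3-vector, angstrom)
#' @return a `replicate_set`; attribute "truth" records the planted effects
#'   and outlier replicate ids
#' @export
make_ensemble <- function(structure, spec, variant_effect = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  a <- structure$atoms
  n <- nrow(a)
  resseq <- a$resseq
  res_ids <- unique(resseq)
  sig_res <- if (length(spec$sigma) == 1) rep(spec$sigma, length(res_ids)) else spec$sigma
  if (length(sig_res) != length(res_ids)) stop("sigma length must be 1 or n_residues")
  sig_atom <- sig_res[match(resseq, res_ids)]
  label <- "WT"
  shift <- matrix(0, n, 3)
  if (!is.null(variant_effect)) {
    label <- variant_effect$label
    if (!is.null(variant_effect$rmsf)) {
      w <- variant_effect$rmsf$window
      stopifnot(variant_effect$rmsf$multiplier > 0)
      sig_atom[resseq >= w[1] & resseq <= w[2]] <-
        sig_atom[resseq >= w[1] & resseq <= w[2]] * variant_effect$rmsf$multiplier
    }
    if (!is.null(variant_effect$mean_shift)) {
      w <- variant_effect$mean_shift$window
      in_w <- resseq >= w[1] & resseq <= w[2]
      shift[in_w, ] <- matrix(variant_effect$mean_shift$disp, sum(in_w), 3,
                              byrow = TRUE)
    }
  }
  ref <- coords(structure) + shift
  set.seed(spec$seed %% .Machine$integer.max)
  out_count <- min(spec$outliers$count, spec$n_replicates)
  outlier_reps <- if (out_count > 0) {
    sort(sample(spec$n_replicates, out_count))
  } else integer(0)
  atab <- data.frame(chain = a$chain, resseq = a$resseq, icode = a$icode,
                     resname = a$resname, name = a$name, element = a$element,
                     stringsAsFactors = FALSE)
  t_frac <- (seq_len(spec$n_frames) - 1) / spec$n_frames
  ensembles <- lapply(seq_len(spec$n_replicates), function(r) {
    set.seed((spec$seed + 7919L * r) %% .Machine$integer.max)
    s3 <- rep(sig_atom * if (r %in% outlier_reps) spec$outliers$factor else 1,
              each = 3)
    base <- rep(as.vector(t(ref)), each = spec$n_frames)
    xyz <- matrix(base, nrow = spec$n_frames) +
      matrix(rnorm(spec$n_frames * 3 * n), nrow = spec$n_frames,
             byrow = TRUE) * matrix(s3, spec$n_frames, 3 * n, byrow = TRUE)
    phase <- runif(length(spec$modes), 0, 2 * pi)
    for (k in seq_along(spec$modes)) {
      md <- spec$modes[[k]]
      in_w <- resseq >= md$window[1] & resseq <= md$window[2]
      dir <- md$direction / sqrt(sum(md$direction^2))
      cycles <- if (is.null(md$cycles)) 2 else md$cycles
      amp <- md$amplitude * sin(2 * pi * cycles * t_frac + phase[k])
      cols <- which(rep(in_w, each = 3))
      dvec <- rep(dir, sum(in_w))
      xyz[, cols] <- xyz[, cols] + outer(amp, dvec)
    }
    new_ensemble(xyz, atab, frame_interval = spec$frame_interval,
                 replicate_id = r, label = label)
  })
  rs <- new_replicate_set(ensembles)
  attr(rs, "truth") <- list(spec = spec, variant_effect = variant_effect,
                            outlier_replicates = outlier_reps,
                            sigma_per_residue = sig_res)
  rs
}

.canonical_pka <- c(ASP = 3.65, GLU = 4.25, HIS = 6.00, LYS = 10.53,
                    ARG = 12.48, CYS = 8.30, TYR = 10.07)

#' Generate wild-type and variant pKa tables with planted weak-spot shifts
#'
#' The wild-type table draws each titratable residue's pKa from its
#' canonical value plus a seeded environmental jitter. Benign variants add
#' Gaussian noise of s.d. `noise_sd`; damaging variants additionally shift
#' the designated weak-spot residues by seeded magnitudes in
#' `delta_range` (random sign).
#'
#' @param n_benign,n_damaging numbers of benign / damaging variant tables
#' @param n_sites number of titratable residues in the universe (default 40)
#' @param weak_spots indices (into the site list) of weak-spot residues
#'   (default 3 sites)
#' @param delta_range planted |shift| range in pH units (default 0.5-1.5)
#' @param noise_sd benign noise s.d. (default 0.02)
#' @param seed mandatory RNG seed
#' @param chain chain id (default "A")
#' @return list with `wt` (`pka_table`), `variants` (named list of
#'   `pka_table`), `truth` (weak-spot keys and planted shifts)
#' @export
make_pka_tables <- function(n_benign, n_damaging, n_sites = 40,
                            weak_spots = NULL, delta_range = c(0.5, 1.5),
                            noise_sd = 0.02, seed, chain = "A") {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(noise_sd >= 0)
  set.seed(seed %% .Machine$integer.max)
  resname <- sample(names(.canonical_pka), n_sites, replace = TRUE)
  resseq <- sort(sample(1000:1400, n_sites))
  wt_pka <- .canonical_pka[resname] + rnorm(n_sites, sd = 0.3)
  universe <- data.frame(chain = chain, resseq = resseq, resname = resname,
                         pka = as.numeric(wt_pka), stringsAsFactors = FALSE)
  wt <- pka_table(universe, provenance = "synthetic", ph = 7.0)
  if (is.null(weak_spots)) weak_spots <- sample(n_sites, 3)
  mk <- function(damaging, label) {
    tb <- universe
    tb$pka <- tb$pka + rnorm(n_sites, sd = noise_sd)
    planted <- NULL
    if (damaging) {
      mag <- runif(length(weak_spots), delta_range[1], delta_range[2])
      sgn <- sample(c(-1, 1), length(weak_spots), replace = TRUE)
      tb$pka[weak_spots] <- tb$pka[weak_spots] + sgn * mag
      planted <- setNames(sgn * mag, wt$residues$key[weak_spots])
    }
    list(table = pka_table(tb, provenance = "synthetic", ph = 7.0),
         planted = planted)
  }
  variants <- list(); planted <- list()
  for (i in seq_len(n_benign)) {
    v <- mk(FALSE, paste0("B", i)); variants[[paste0("B", i)]] <- v$table
  }
  for (i in seq_len(n_damaging)) {
    v <- mk(TRUE, paste0("D", i)); variants[[paste0("D", i)]] <- v$table
    planted[[paste0("D", i)]] <- v$planted
  }
  list(wt = wt, variants = variants,
       truth = list(weak_spot_keys = wt$residues$key[weak_spots],
                    planted = planted, noise_sd = noise_sd))
}

#' Generate a small two-group interaction system with tabulated parameters
#'
#' Two spatially separated groups of point atoms with seeded charges and
#' Lennard-Jones parameters, for validating the nonbonded energy path
#' against brute-force recomputation and for variant charge-scaling
#' experiments.
#'
#' @param n_a,n_b atoms per group (defaults 4 and 4)
#' @param separation center-to-center distance, angstrom (default 6)
#' @param charge_scale factor applied to group B charges (a "variant" with
#'   `charge_scale != 1` perturbs the electrostatics; default 1)
#' @param qa_range,qb_range uniform charge ranges (e) for groups A and B;
#'   opposite-signed ranges give a net-attractive pair
#' @param seed mandatory RNG seed
#' @return list with `structure`, `params` (`nb_params`), `group_a`,
#'   `group_b` (atom indices)
#' @export
make_interaction_system <- function(n_a = 4, n_b = 4, separation = 6,
                                    charge_scale = 1,
                                    qa_range = c(-0.8, 0.8),
                                    qb_range = c(-0.8, 0.8), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed %% .Machine$integer.max)
  n <- n_a + n_b
  xyz <- rbind(matrix(runif(3 * n_a, -1.5, 1.5), ncol = 3),
               cbind(separation + runif(n_b, -1.5, 1.5),
                     matrix(runif(2 * n_b, -1.5, 1.5), ncol = 2)))
  q <- round(c(runif(n_a, qa_range[1], qa_range[2]),
               runif(n_b, qb_range[1], qb_range[2])), 3)
  q[(n_a + 1):n] <- q[(n_a + 1):n] * charge_scale
  tb <- data.frame(resname = "SYN", name = paste0("X", seq_len(n)),
                   charge = q, epsilon = round(runif(n, 0.05, 0.3), 3),
                   rmin_half = round(runif(n, 1.5, 2.2), 3),
                   stringsAsFactors = FALSE)
  atoms <- data.frame(
    serial = seq_len(n), name = tb$name, alt = "", resname = "SYN",
    chain = "X", resseq = rep(c(1L, 2L), c(n_a, n_b)), icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
    element = "C", is_hetero = TRUE, stringsAsFactors = FALSE)
  list(structure = .new_structure(atoms, title = "synthetic interaction system"),
       params = nb_params(table = tb),
       group_a = seq_len(n_a), group_b = (n_a + 1):n)
}

#' Generate a score table with planted benign/damaging queries
#'
#' Benign-control and benign-query badness values are half-normal draws of
#' scale `benign_scale` per layer; each planted damaging query receives, in
#' at least one randomly chosen layer, a badness of `damaging_multiple`
#' times the realized benign-control maximum of that layer (with a small
#' multiplicative jitter), emulating the clear separation between damaging
#' variants and benign controls that the calibration logic keys on.
#'
#' @param n_benign benign controls (>= 1; default 3); together with any
#'   benign queries these are the planted-benign rows of the truth record
#' @param n_damaging planted damaging queries (default 5)
#' @param n_benign_queries additional null-distributed queries (default 0).
#'   Note that a null query can exceed twice the benign-control maximum by
#'   chance in some layer (about one table in five with three controls and
#'   five layers), which is the calibration scheme's intrinsic
#'   false-positive behavior, not a planted effect.
#' @param benign_scale half-normal scale of the null badness (default 1)
#' @param damaging_multiple multiple of the benign-control maximum planted
#'   in the affected layer(s) (default 3)
#' @param layers layer names, one metric generated per layer
#' @param seed mandatory RNG seed
#' @return a `score_table`; attribute "truth" maps each variant to
#'   "benign" or "damaging" planted status
#' @export
make_score_table <- function(n_benign = 3, n_damaging = 5, n_benign_queries = 0,
                             benign_scale = 1, damaging_multiple = 3,
                             layers = c("structure", "pka", "dynamics",
                                        "substrate_zn", "active_site"),
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_benign >= 1)
  set.seed(seed %% .Machine$integer.max)
  metrics <- paste0(layers, "_score")
  variants <- c(paste0("BC", seq_len(n_benign)),
                if (n_benign_queries > 0) paste0("BQ", seq_len(n_benign_queries)),
                if (n_damaging > 0) paste0("DQ", seq_len(n_damaging)))
  vals <- matrix(abs(rnorm(length(variants) * length(metrics),
                           sd = benign_scale)),
                 nrow = length(variants),
                 dimnames = list(variants, metrics))
  ben_max <- apply(vals[seq_len(n_benign), , drop = FALSE], 2, max)
  if (n_damaging > 0) {
    for (i in seq_len(n_damaging)) {
      hit <- sample(length(metrics), sample(1:2, 1))
      vals[paste0("DQ", i), hit] <- damaging_multiple * ben_max[hit] *
        runif(length(hit), 0.95, 1.1)
    }
  }
  reg <- data.frame(metric = metrics, layer = layers,
                    orientation = "higher_is_worse", units = "",
                    stringsAsFactors = FALSE)
  roles <- setNames(c(rep("benign_control", n_benign),
                      rep("query", n_benign_queries + n_damaging)), variants)
  st <- score_table(vals, reg, roles)
  attr(st, "truth") <- setNames(c(rep("benign", n_benign + n_benign_queries),
                                  rep("damaging", n_damaging)), variants)
  st
}
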