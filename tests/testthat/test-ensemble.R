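test_that("rmsd_series is zero for identical or rigidly moved frames", {
  s <- make_structure(6, "helix")
  x <- coords(s)
  ens <- ens_from_frames(s, list(x, x, x))
  expect_equal(rmsd_series(ens), rep(0, 3))
  # per-frame rigid motions are removed by superposition
  frames <- lapply(1:4, function(i) {
    x %*% rot_axis(c(i, 1, 2), 0.3 * i) + matrix(i, nrow(x), 3)
  })
  expect_lt(max(rmsd_series(ens_from_frames(s, frames))), 1e-8)
})

test_that("rmsd_series matches the direct formula on a planted displacement", {
  s <- make_structure(5, "strand")
  x <- coords(s)
  x2 <- x; x2[1, ] <- x2[1, ] + c(1, 0, 0)
  ens <- ens_from_frames(s, list(x, x2, x))
  ser <- rmsd_series(ens)
  expect_equal(ser[c(1, 3)], c(0, 0))
  # frame 2: Kabsch-fitted single-atom displacement; oracle via direct fit
  fit <- kabsch(x2, x)
  expect_equal(ser[2], fit$rmsd, tolerance = 1e-12)
  expect_gt(ser[2], 0)
})

test_that("median_rmsd equals the sort median over the window", {
  expect_equal(median_rmsd(rep(2.5, 10)), 2.5)
  expect_equal(median_rmsd(1:5), 3)
  set.seed(5)
  series <- rnorm(1000, 1.5, 0.2)
  win <- 501:1000
  expect_equal(median_rmsd(series, win), sort(series[win])[250:251] |> mean())
  expect_error(median_rmsd(1:5, integer(0)), "empty")
})

test_that("outlier replicates are excluded by the median/MAD rule with a cap", {
  s <- make_structure(6, "helix")
  x <- coords(s)
  mk_rep <- function(id, drift) {
    frames <- lapply(seq(0, drift, length.out = 10), function(d) {
      x + matrix(rnorm(length(x), sd = 0.02 + d), nrow(x), 3)
    })
    ens_from_frames(s, frames, replicate_id = id)
  }
  set.seed(31)
  # replicates with identical series: nothing excluded
  set.seed(99)
  frames_same <- lapply(1:10, function(i) x + matrix(rnorm(length(x), sd = 0.05),
                                                     nrow(x), 3))
  rs_same <- new_replicate_set(lapply(1:10, function(id)
    ens_from_frames(s, frames_same, replicate_id = id)))
  expect_equal(nrow(exclude_outlier_replicates(rs_same)$excluded), 0)
  set.seed(31)
  # one clear deviant among replicates of identical median: exactly it goes
  base_frames <- lapply(1:10, function(i) x + matrix(rnorm(length(x), sd = 0.05),
                                                     nrow(x), 3))
  same_rep <- function(id) ens_from_frames(s, base_frames, replicate_id = id)
  rs_one <- new_replicate_set(c(lapply(1:9, same_rep),
                                list(mk_rep(10, drift = 2.5))))
  ex1 <- exclude_outlier_replicates(rs_one)
  expect_equal(ex1$excluded$replicate_id, "10")
  expect_gt(ex1$excluded$deviation, 0)
  # three extremes: only the worst two go (cap)
  rs_three <- new_replicate_set(c(lapply(1:7, same_rep),
                                  list(mk_rep(8, 2.0), mk_rep(9, 2.6),
                                       mk_rep(10, 3.2))))
  ex3 <- exclude_outlier_replicates(rs_three)
  expect_equal(sort(ex3$excluded$replicate_id), c("10", "9"))
  expect_error(exclude_outlier_replicates(
    new_replicate_set(list(mk_rep(1, 0.1), mk_rep(2, 0.1)))), "at least 3")
})

test_that("rmsd_score computes the median difference against pooled baselines", {
  s <- make_structure(5, "helix")
  x <- coords(s)
  # frames 2..6 displace atom 1 by `level`; the per-frame fitted RMSD oracle
  # is computed directly with kabsch (validated independently above)
  disp <- function(level) { y <- x; y[1, 1] <- y[1, 1] + level; y }
  mk_set <- function(level) {
    frames <- c(list(x), replicate(5, disp(level), simplify = FALSE))
    new_replicate_set(list(ens_from_frames(s, frames)))
  }
  r_of <- function(level) kabsch(disp(level), x)$rmsd
  # same data: zero difference
  same <- rmsd_score(mk_set(1), list(mk_set(1)))
  expect_equal(same$median_diff, 0, tolerance = 1e-12)
  # two baseline sets average their statistics
  sc <- rmsd_score(mk_set(1.5), list(mk_set(1.4), mk_set(1.6)))
  expect_equal(sc$baseline_stat, (r_of(1.4) + r_of(1.6)) / 2, tolerance = 1e-9)
  expect_equal(sc$variant_stat, r_of(1.5), tolerance = 1e-9)
  sc2 <- rmsd_score(mk_set(1.66), list(mk_set(1.5)))
  expect_equal(sc2$median_diff, r_of(1.66) - r_of(1.5), tolerance = 1e-9)
  expect_equal(sc2$percent_change, 100 * sc2$median_diff / r_of(1.5),
               tolerance = 1e-6)
  expect_error(rmsd_score(mk_set(1), list()), "empty")
})

test_that("rmsf recovers planted two-point and Gaussian fluctuations", {
  s <- make_structure(4, "strand")
  x <- coords(s)
  # one CA alternating +/- d along x, no refit
  ca2 <- atom_select(s, "calpha")[2]
  xp <- x; xp[ca2, 1] <- xp[ca2, 1] + 0.8
  xm <- x; xm[ca2, 1] <- xm[ca2, 1] - 0.8
  ens <- ens_from_frames(s, list(xp, xm, xp, xm))
  prof <- rmsf(ens, superpose = FALSE)
  expect_equal(as.numeric(unclass(prof))[2], 0.8, tolerance = 1e-12)
  expect_equal(as.numeric(unclass(prof))[-2], rep(0, 3), tolerance = 1e-12)
  # identical frames give zeros
  expect_equal(max(unclass(rmsf(ens_from_frames(s, list(x, x, x)),
                                superpose = FALSE))), 0)
  # Gaussian sigma recovery at 500 frames: RMSF -> sigma * sqrt(3)
  big <- make_structure(20, "helix")
  rs <- make_ensemble(big, ensemble_spec(n_frames = 500, n_replicates = 1,
                                         sigma = 0.3, seed = 404))
  prof_g <- rmsf(rs)
  expect_equal(mean(unclass(prof_g)), 0.3 * sqrt(3), tolerance = 0.05 * 0.3 * sqrt(3))
})

test_that("rmsf is invariant to a rigid motion applied to all frames", {
  s <- make_structure(8, "helix")
  rs <- make_ensemble(s, ensemble_spec(n_frames = 60, n_replicates = 1,
                                       sigma = 0.2, seed = 77))
  ens <- rs$ensembles[[1]]
  prof0 <- rmsf(ens)
  R <- rot_axis(c(1, 0, 2), 0.9)
  moved <- ens
  for (f in seq_len(n_frames(ens))) {
    m <- matrix(ens$xyz[f, ], ncol = 3, byrow = TRUE) %*% R + 5
    moved$xyz[f, ] <- as.vector(t(m))
  }
  expect_equal(unclass(rmsf(moved)), unclass(prof0), tolerance = 1e-8)
})

test_that("rmsf_compare metrics agree with direct formulas", {
  s <- make_structure(50, "coil")
  set.seed(9)
  rs <- make_ensemble(s, ensemble_spec(n_frames = 40, n_replicates = 1,
                                       sigma = 0.3, seed = 10))
  w <- rmsf(rs)
  # identical profiles
  id <- rmsf_compare(w, w)
  expect_equal(id$avg_abs_diff, 0); expect_equal(id$abs_residual_sum, 0)
  expect_equal(id$pearson, 1); expect_equal(id$spearman, 1)
  # uniform +0.1 shift
  v <- w; v[] <- unclass(w) + 0.1
  sh <- rmsf_compare(w, v)
  expect_equal(sh$avg_abs_diff, 0.1, tolerance = 1e-12)
  expect_equal(sh$avg_diff, -0.1, tolerance = 1e-12)
  expect_equal(sh$spearman, 1)
  # random profiles vs brute-force formulas
  v2 <- w; v2[] <- unclass(w) + rnorm(length(w), sd = 0.1)
  mm <- rmsf_compare(w, v2)
  a <- unclass(w); b <- unclass(v2)
  expect_equal(mm$avg_abs_diff, mean(abs(a - b)))
  expect_equal(mm$avg_diff, mean(a - b))
  expect_equal(mm$abs_residual_sum, sum(abs(a - b)))
  expect_equal(mm$pearson, cor(a, b))
  expect_equal(mm$spearman, cor(a, b, method = "spearman"))
  expect_equal(mm$percent_elevation, 100 * (mean(b) - mean(a)) / mean(a))
})

test_that("planted fluctuation elevation separates from wild-type resampling noise", {
  s <- make_structure(60, "helix")
  spec_wt1 <- ensemble_spec(n_frames = 200, n_replicates = 2, sigma = 0.3, seed = 1001)
  spec_wt2 <- ensemble_spec(n_frames = 200, n_replicates = 2, sigma = 0.3, seed = 2002)
  spec_var <- ensemble_spec(n_frames = 200, n_replicates = 2, sigma = 0.3, seed = 3003)
  wt1 <- rmsf(make_ensemble(s, spec_wt1))
  wt2 <- rmsf(make_ensemble(s, spec_wt2))
  var <- rmsf(make_ensemble(s, spec_var, variant_effect = list(
    label = "V", rmsf = list(window = c(20, 39), multiplier = 1.5))))
  null_score <- rmsf_compare(wt1, wt2)$avg_abs_diff
  var_score <- rmsf_compare(wt1, var)$avg_abs_diff
  expect_gte(var_score, 2 * null_score)
})

test_that("bfactor conversion and correlations behave", {
  s <- make_structure(10, "helix")
  rs <- make_ensemble(s, ensemble_spec(n_frames = 50, n_replicates = 1,
                                       sigma = 0.25, seed = 55))
  prof <- rmsf(rs)
  # closed form: RMSF of 1 A -> B = 8 pi^2 / 3
  unit <- prof; unit[] <- 1
  ba <- bfactor_agreement(unit, s)
  expect_equal(unname(ba$predicted_b[1]), 8 * pi^2 / 3, tolerance = 1e-12)
  # affine crystal-B pattern gives Pearson 1
  s$atoms$b <- 5 + 2 * (8 * pi^2 / 3) * (unclass(prof)[atom_res_keys(s)])^2
  ba2 <- bfactor_agreement(prof, s)
  expect_equal(ba2$pearson, 1, tolerance = 1e-12)
  # degenerate profile errors
  zero <- prof; zero[] <- 0
  expect_error(bfactor_agreement(zero, s), "undefined")
})

test_that("mobility classes split at 0.7 and 1.0 angstrom with inclusive boundaries", {
  prof <- structure(c(0.5, 0.7, 0.85, 1.0, 1.21),
                    names = res_key("A", 1:5), class = "rmsf_profile")
  got <- classify_mobility(prof)
  expect_equal(unname(got), c("still", "intermediate", "intermediate",
                              "intermediate", "mobile"))
})
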