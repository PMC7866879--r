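test_that("pca handles the rank-1 case and conserves the trace", {
  s <- make_structure(5, "helix")
  x <- coords(s)
  set.seed(3)
  amp <- rnorm(20, sd = 1)
  frames <- lapply(amp, function(a) { y <- x; y[2, 1] <- y[2, 1] + a; y })
  ens <- ens_from_frames(s, frames)
  p <- suppressWarnings(ed_pca(ens, preset = "all", superpose = FALSE))
  expect_equal(p$eigenvalues[1], var(amp), tolerance = 1e-10)
  expect_lt(max(abs(p$eigenvalues[-1])), 1e-12)
  expect_equal(sum(p$eigenvalues), p$trace, tolerance = 1e-10 * p$trace)
})

test_that("pca eigen-decomposition matches independent oracles", {
  s <- make_structure(5, "coil")
  rs <- make_ensemble(s, ensemble_spec(n_frames = 50, n_replicates = 1,
                                       sigma = 0.3, seed = 66))
  ens <- rs$ensembles[[1]]
  p <- suppressWarnings(ed_pca(ens, preset = "all", superpose = FALSE))
  # brute-force dense covariance assembled coordinate by coordinate
  n <- nrow(ens$atom)
  X <- ens$xyz
  C <- matrix(0, 3 * n, 3 * n)
  mu <- colMeans(X)
  for (f in seq_len(nrow(X))) {
    d <- X[f, ] - mu
    C <- C + outer(d, d)
  }
  C <- C / (nrow(X) - 1)
  ev <- eigen(C, symmetric = TRUE)$values
  expect_equal(p$eigenvalues, ev, tolerance = 1e-8)
  # cross-check against bio3d on the same coordinates
  pb <- bio3d::pca.xyz(X)
  expect_equal(p$eigenvalues, pb$L, tolerance = 1e-8)
  # orthonormality and non-negativity
  expect_equal(crossprod(p$vectors), diag(3 * n), tolerance = 1e-8)
  expect_true(all(p$eigenvalues > -1e-10))
})

test_that("pca is equivariant under a global rotation of the frames", {
  s <- make_structure(6, "helix")
  rs <- make_ensemble(s, ensemble_spec(n_frames = 80, n_replicates = 1,
                                       sigma = 0.25, seed = 12))
  ens <- rs$ensembles[[1]]
  p0 <- ed_pca(ens, preset = "all", superpose = FALSE)
  R <- rot_axis(c(1, 2, 0), 0.8)
  rot <- ens
  for (f in seq_len(n_frames(ens))) {
    rot$xyz[f, ] <- as.vector(t(matrix(ens$xyz[f, ], ncol = 3, byrow = TRUE) %*% R))
  }
  p1 <- ed_pca(rot, preset = "all", superpose = FALSE)
  expect_equal(p1$eigenvalues, p0$eigenvalues, tolerance = 1e-8)
  # porcupine magnitudes are rotation invariant, directions co-rotate
  porc0 <- porcupine(p0, 1); porc1 <- porcupine(p1, 1)
  expect_equal(porc1$magnitude, porc0$magnitude, tolerance = 1e-8)
  v0 <- as.matrix(porc0[, c("vx", "vy", "vz")]) %*% R
  v1 <- as.matrix(porc1[, c("vx", "vy", "vz")])
  expect_equal(abs(rowSums(v0 * v1)), rep(1, nrow(v1)), tolerance = 1e-6)
})

test_that("projections satisfy the spectral identity and match direct dot products", {
  s <- make_structure(6, "strand")
  rs <- make_ensemble(s, ensemble_spec(n_frames = 90, n_replicates = 1,
                                       sigma = 0.3, seed = 23))
  ens <- rs$ensembles[[1]]
  p <- ed_pca(ens, preset = "all", superpose = FALSE)
  pr <- ed_project(ens, p, k = 3)
  expect_equal(var(pr[, 1]), p$eigenvalues[1], tolerance = 1e-8)
  expect_equal(var(pr[, 2]), p$eigenvalues[2], tolerance = 1e-8)
  expect_equal(colMeans(pr), rep(0, 3), tolerance = 1e-10)
  # cross-projection oracle: explicit centered dot products
  rs2 <- make_ensemble(s, ensemble_spec(n_frames = 20, n_replicates = 1,
                                        sigma = 0.3, seed = 24))
  ens2 <- rs2$ensembles[[1]]
  pr2 <- ed_project(ens2, p, k = 2)
  mu <- as.vector(t(p$mean_coords))
  want <- sweep(ens2$xyz, 2, mu) %*% p$vectors[, 1:2]
  expect_equal(pr2, want, tolerance = 1e-10)
})

test_that("porcupine averages eigenvector components per residue", {
  s <- make_structure(3, "helix")
  x <- coords(s)
  set.seed(4)
  amp <- rnorm(30)
  # move residue 2 rigidly along (1,1,0)/sqrt(2)
  dir <- c(1, 1, 0) / sqrt(2)
  idx <- which(s$atoms$resseq == 2)
  frames <- lapply(amp, function(a) {
    y <- x; y[idx, ] <- y[idx, ] + matrix(a * dir, length(idx), 3, byrow = TRUE); y
  })
  p <- suppressWarnings(ed_pca(ens_from_frames(s, frames), preset = "all",
                               superpose = FALSE))
  porc <- porcupine(p, 1)
  expect_equal(porc$magnitude[1], 0, tolerance = 1e-8)
  expect_equal(porc$magnitude[3], 0, tolerance = 1e-8)
  expect_gt(porc$magnitude[2], 0.5 * sqrt(var(amp)))
  got_dir <- abs(c(porc$vx[2], porc$vy[2], porc$vz[2]))
  expect_equal(got_dir, abs(dir), tolerance = 1e-6)
  # hand-computed residue average of the raw eigenvector
  v1 <- matrix(p$vectors[, 1], ncol = 3, byrow = TRUE)
  hand <- colMeans(v1[5:8, ]) * sqrt(p$eigenvalues[1])
  expect_equal(c(porc$vx[2], porc$vy[2], porc$vz[2]) * porc$magnitude[2],
               hand, tolerance = 1e-8)
})

test_that("fel converts counts to kT with a zero minimum and masked empties", {
  # all frames in one bin
  one <- fel(matrix(0, 10, 2), bins = 5)
  expect_equal(min(one$free_energy, na.rm = TRUE), 0)
  expect_equal(sum(!is.na(one$free_energy)), 1)
  # constructed two-bin landscape: counts 100 and 37
  pr <- rbind(matrix(c(-1, 0), 100, 2, byrow = TRUE),
              matrix(c(1, 0), 37, 2, byrow = TRUE))
  two <- fel(pr, bins = 2)
  occ <- sort(two$free_energy[!is.na(two$free_energy)])
  expect_equal(occ, c(0, -log(0.37)), tolerance = 1e-12)
  # uniform occupancy is flat at 0 kT
  u <- fel(cbind(rep(c(-1, 1), 50), rep(c(-1, 1), each = 50)), bins = 2)
  expect_equal(max(u$free_energy, na.rm = TRUE), 0)
  expect_error(fel(matrix(0, 0, 2)), "no frames")
  expect_equal(fel(pr, temperature = 300)$kcal_per_kt, 0.0019872041 * 300)
})

test_that("pc_shift recovers a planted displacement along PC1 and is antisymmetric", {
  s <- make_structure(6, "helix")
  rs <- make_ensemble(s, ensemble_spec(n_frames = 100, n_replicates = 1,
                                       sigma = 0.3, seed = 31))
  wt <- rs$ensembles[[1]]
  p <- ed_pca(wt, preset = "all", superpose = FALSE)
  # identical data: all shifts zero
  sh0 <- pc_shift(wt, wt, pca = p)
  expect_equal(sh0$shift, rep(0, 3), tolerance = 1e-12)
  expect_equal(sh0$overlap, rep(1, 3), tolerance = 1e-12)
  # displace every frame by +2 units along v1 in coordinate space
  v1 <- p$vectors[, 1]
  var_ens <- wt
  var_ens$xyz <- wt$xyz + matrix(2 * v1, n_frames(wt), length(v1), byrow = TRUE)
  sh <- pc_shift(wt, var_ens, pca = p)
  expect_equal(sh$shift[1], 2, tolerance = 1e-8)
  expect_equal(sh$shift[2:3], rep(0, 2), tolerance = 1e-8)
  # antisymmetry
  rs2 <- make_ensemble(s, ensemble_spec(n_frames = 100, n_replicates = 1,
                                        sigma = 0.3, seed = 32))
  other <- rs2$ensembles[[1]]
  a <- pc_shift(wt, other, pca = p)
  b <- pc_shift(other, wt, pca = p)
  expect_equal(a$shift, -b$shift, tolerance = 1e-10)
})

test_that("planted collective mode dominates PC1 and localizes in its window", {
  s <- make_structure(60, "helix")
  rs <- make_ensemble(s, ensemble_spec(
    n_frames = 300, n_replicates = 1, sigma = 0.1,
    modes = list(list(window = c(40, 60), direction = c(1, 0.5, 0),
                      amplitude = 1.2)),
    seed = 99))
  p <- ed_pca(rs$ensembles[[1]], production_window = 1:300)
  fr <- p$eigenvalues / sum(pmax(p$eigenvalues, 0))
  expect_gt(fr[1], 0.5)
  porc <- porcupine(p, 1)
  resseq <- parse_res_key(porc$key)$resseq
  # the mode peaks inside the planted window; superposition spreads the
  # compensating rigid counter-motion over the rest, so the outside
  # magnitudes are reduced but not zero
  expect_gte(resseq[which.max(porc$magnitude)], 40)
  expect_gt(mean(porc$magnitude[resseq >= 40]),
            mean(porc$magnitude[resseq < 40]))
  # the planted window carries a larger share of variance in PC1 than PC3
  share <- function(comp) {
    v <- matrix(p$vectors[, comp], ncol = 3, byrow = TRUE)
    w <- rowSums(v^2)
    sum(w[p$atom$resseq >= 40]) / sum(w)
  }
  expect_gt(share(1), share(3))
})
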