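# independent oracle: minimize RMSD over a hierarchically refined grid of
# Euler rotations (about centroids); translation is optimal at the centroid
# match for any rotation, so only rotations need searching.
grid_rmsd_oracle <- function(mobile, reference) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(reference, 2, colMeans(reference))
  euler <- function(a, b, g) rot_axis(c(0, 0, 1), a) %*%
    rot_axis(c(0, 1, 0), b) %*% rot_axis(c(0, 0, 1), g)
  eval_r <- function(a, b, g) sqrt(mean(rowSums((mc %*% euler(a, b, g) - rc)^2)))
  best <- c(0, 0, 0); step <- 20 * pi / 180
  grid0 <- expand.grid(a = seq(0, 2 * pi, by = step),
                       b = seq(0, pi, by = step),
                       g = seq(0, 2 * pi, by = step))
  vals <- mapply(eval_r, grid0$a, grid0$b, grid0$g)
  best <- as.numeric(grid0[which.min(vals), ])
  for (step in c(4, 0.8, 0.16, 0.032, 0.0064) * pi / 180) {
    grid <- expand.grid(a = best[1] + seq(-5, 5) * step,
                        b = best[2] + seq(-5, 5) * step,
                        g = best[3] + seq(-5, 5) * step)
    vals <- mapply(eval_r, grid$a, grid$b, grid$g)
    best <- as.numeric(grid[which.min(vals), ])
  }
  eval_r(best[1], best[2], best[3])
}

test_that("kabsch recovers rigid motions exactly and matches a grid-search oracle", {
  set.seed(11)
  ref <- matrix(rnorm(30), 10, 3)
  # identity case
  f0 <- kabsch(ref, ref)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(f0$translation, rep(0, 3), tolerance = 1e-10)
  expect_lt(f0$rmsd, 1e-10)
  # rotated + translated copy
  R <- rot_axis(c(0, 0, 1), 37 * pi / 180)
  mob <- ref %*% R + matrix(c(5, -2, 1), 10, 3, byrow = TRUE)
  fit <- kabsch(mob, ref)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  # distorted tetrahedron vs the rotation-grid oracle
  tet <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.75, 1.3, 0), c(0.75, 0.43, 1.22))
  tet2 <- tet; tet2[4, ] <- tet2[4, ] + c(0.6, -0.5, 0.62)  # ~1.0 A displacement
  tet2 <- tet2 %*% rot_axis(c(1, 2, 3), 0.7) + 2
  expect_equal(kabsch(tet2, tet)$rmsd, grid_rmsd_oracle(tet2, tet),
               tolerance = 1e-3)
  # cross-check against bio3d least-squares fitting
  fitted <- suppressWarnings(bio3d::fit.xyz(as.vector(t(tet)), as.vector(t(tet2))))
  expect_equal(kabsch(tet2, tet)$rmsd,
               sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - tet)^2))),
               tolerance = 1e-6)
})

test_that("kabsch rejects degenerate geometry", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "collinear")
})

test_that("rmsd_between handles identity, shifts and matches the direct sum", {
  s <- make_structure(6, "helix")
  expect_equal(rmsd_between(s, s), 0)
  shifted <- s
  shifted$atoms$x <- shifted$atoms$x + 1
  expect_equal(rmsd_between(s, shifted, superpose = FALSE), 1.0, tolerance = 1e-12)
  expect_lt(rmsd_between(s, shifted, superpose = TRUE), 1e-8)
  # direct-sum oracle on randomly perturbed copy
  set.seed(7)
  pert <- s
  d <- matrix(rnorm(n_atoms(s) * 3, sd = 0.3), ncol = 3)
  pert$atoms[, c("x", "y", "z")] <- pert$atoms[, c("x", "y", "z")] + d
  bb <- atom_select(s, "backbone")
  expect_equal(rmsd_between(s, pert, superpose = FALSE),
               sqrt(mean(rowSums(d[bb, ]^2))), tolerance = 1e-12)
})

test_that("rmsd_between is symmetric and obeys the triangle bound unsuperposed", {
  set.seed(21)
  a <- make_structure(8, "strand")
  jitter_struct <- function(s, sd) {
    s$atoms[, c("x", "y", "z")] <- s$atoms[, c("x", "y", "z")] +
      matrix(rnorm(n_atoms(s) * 3, sd = sd), ncol = 3)
    s
  }
  b <- jitter_struct(a, 0.4); c <- jitter_struct(a, 0.8)
  expect_equal(rmsd_between(a, b), rmsd_between(b, a))
  expect_lte(rmsd_between(a, c), rmsd_between(a, b) + rmsd_between(b, c) + 1e-12)
})

test_that("mutated residue side chains are excluded from matching", {
  s <- make_structure(5, "helix")
  cb <- s$atoms[s$atoms$name == "CA" & s$atoms$resseq == 3, ]
  cb$name <- "CB"; cb$serial <- 100L
  a <- s; a$atoms <- rbind(a$atoms, cb)
  b <- s
  b$atoms$resname[b$atoms$resseq == 3] <- "VAL"  # mutation at residue 3
  expect_equal(rmsd_between(a, b, preset = "heavy"), 0)
})

test_that("local_perturbation matches the closed form on a planted shift", {
  s <- make_structure(12, "helix")
  site <- res_key("A", 6)
  shell <- residues_within(s, site, 10, "heavy")
  v <- s
  # shift the backbone of exactly one shell residue by 0.5 A
  target <- parse_res_key(shell[1])$resseq
  sel <- v$atoms$resseq == target & trimws(v$atoms$name) %in% c("N", "CA", "C", "O")
  v$atoms$x[sel] <- v$atoms$x[sel] + 0.5
  lp <- local_perturbation(s, v, site, radius = 10)
  expect_equal(lp$n_residues, length(shell))
  expect_equal(lp$rmsd, 0.5 * sqrt(4 / (4 * length(shell))), tolerance = 1e-6)
  expect_equal(lp$mean_disp, 0.5 * 4 / (4 * length(shell)), tolerance = 1e-6)
  # identity and degenerate-radius contracts
  lp0 <- local_perturbation(s, s, site)
  expect_equal(lp0$rmsd, 0); expect_equal(lp0$mean_disp, 0)
  expect_error(local_perturbation(s, v, site, radius = 0.01), "shell|radius")
})

test_that("sasa reproduces analytic limits", {
  one <- struct_from_xyz(matrix(c(0, 0, 0), 1), element = "C")
  s1 <- sasa(one)
  expect_equal(s1$total, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.01)
  # coincident pair occludes nothing in total
  two_same <- struct_from_xyz(rbind(c(0, 0, 0), c(0, 0, 1e-9)), element = "C")
  expect_equal(sasa(two_same)$total, s1$total, tolerance = 0.01 * s1$total)
  # non-interacting pair is additive
  two_far <- struct_from_xyz(rbind(c(0, 0, 0), c(20, 0, 0)), element = "C")
  expect_equal(sasa(two_far)$total, 2 * s1$total, tolerance = 1e-9)
  # polar/nonpolar split sums to the total
  s <- make_structure(6, "helix")
  rep_ <- sasa(s)
  expect_equal(rep_$polar + rep_$nonpolar, rep_$total, tolerance = 1e-6)
  expect_true(all(rep_$per_atom >= 0))
})

test_that("sasa is invariant under rigid motion of the whole structure", {
  s <- make_structure(10, "coil")
  base <- sasa(s)$total
  R <- rot_axis(c(1, 1, 0), 1.1)
  moved <- s
  moved$atoms[, c("x", "y", "z")] <-
    as.matrix(s$atoms[, c("x", "y", "z")]) %*% R + 3
  expect_equal(sasa(moved)$total, base, tolerance = 0.005 * base)
})

test_that("sasa demands a radius or default for unknown elements", {
  odd <- struct_from_xyz(matrix(0, 1, 3), element = "XX")
  expect_error(sasa(odd, radii = c(C = 1.7)), "no radius")
  expect_silent(sasa(odd))  # bundled table has a default entry
})

test_that("buried_surface decomposes against independently recomputed SASA terms", {
  s <- make_structure(12, "helix")
  half_a <- atom_select(s, resseq = 1:6)
  half_b <- atom_select(s, resseq = 7:12)
  bs_tot <- buried_surface(s, half_a, half_b, convention = "total")
  bs_per <- buried_surface(s, half_a, half_b, convention = "per_side")
  # recompute the three SASA terms independently
  sub <- function(idx) {
    ss <- s; ss$atoms <- ss$atoms[idx, , drop = FALSE]; ss
  }
  t_ab <- sasa(s)$total
  t_a <- sasa(sub(half_a))$total
  t_b <- sasa(sub(half_b))$total
  expect_equal(bs_tot$buried, t_a + t_b - t_ab, tolerance = 1e-9)
  expect_equal(bs_tot$buried, 2 * bs_per$buried, tolerance = 1e-12)
  expect_equal(bs_tot$polar + bs_tot$nonpolar, bs_tot$buried, tolerance = 1e-6)
  expect_gt(bs_tot$buried, 0)  # the halves are covalently contiguous
  # disjointness is enforced
  expect_error(buried_surface(s, half_a, c(half_a[1], half_b)), "overlap")
})

test_that("non-contacting parts bury no surface", {
  a <- make_structure(4, "helix")
  b <- make_structure(4, "helix")
  b$atoms[, "x"] <- b$atoms[, "x"] + 50
  b$atoms$resseq <- b$atoms$resseq + 100L
  b$atoms$serial <- b$atoms$serial + 100L
  comp <- a; comp$atoms <- rbind(a$atoms, b$atoms)
  bs <- buried_surface(comp, seq_len(n_atoms(a)),
                       n_atoms(a) + seq_len(n_atoms(b)), convention = "total")
  expect_equal(bs$buried, 0, tolerance = 1e-9)
})
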