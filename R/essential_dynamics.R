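# Essential dynamics: covariance PCA of coordinate fluctuations, porcupine
# vectors, bidimensional free-energy landscapes and per-PC distribution
# shifts.  The decomposition is Lambda = T' C T with C the covariance of the
# superposed coordinate fluctuations about their mean; columns of T are the
# eigenvectors ordered by descending eigenvalue.

#' Principal component analysis of an ensemble
#'
#' Frames are superposed with the same protocol as [rmsf()] (window-mean fit
#' over `fit_preset`), the 3N x 3N covariance matrix of the selected
#' coordinates is formed, and eigendecomposed with eigenvalues sorted
#' descending. Eigenvector signs follow a deterministic convention: the
#' largest-magnitude component of each eigenvector is positive.
#'
#' @param x an `ensemble` or `replicate_set` (retained replicates are
#'   concatenated after superposition)
#' @param preset atom selection (default "calpha")
#' @param fit_preset superposition selection (default "backbone")
#' @param production_window frame indices (defaults as in [rmsf()])
#' @param superpose superpose frames before the decomposition (default TRUE)
#' @return an `ed_pca` object: `eigenvalues` (square angstrom, descending),
#'   `vectors` (3n x 3n orthonormal columns), `mean_coords` (n x 3), `trace`,
#'   `atom` (selected-atom table), `fit_reference` (superposition reference
#'   reused for cross-projection)
#' @export
ed_pca <- function(x, preset = "calpha", fit_preset = "backbone",
                   production_window = NULL, superpose = TRUE) {
  if (inherits(x, "replicate_set")) {
    ens <- retained(x)
    win <- if (is.null(production_window)) x$production_window else production_window
    fit_idx <- .ens_select(ens[[1]], fit_preset)
    ref <- if (superpose) .mean_reference(ens[[1]], fit_idx, win) else NULL
    mats <- lapply(ens, .superposed_flat, preset = preset,
                   fit_preset = fit_preset, window = win, ref = ref,
                   superpose = superpose)
    X <- do.call(rbind, mats)
    atom <- ens[[1]]$atom[.ens_select(ens[[1]], preset), , drop = FALSE]
  } else {
    stopifnot(inherits(x, "ensemble"))
    win <- if (is.null(production_window)) seq_len(n_frames(x)) else production_window
    fit_idx <- .ens_select(x, fit_preset)
    ref <- if (superpose) .mean_reference(x, fit_idx, win) else NULL
    X <- .superposed_flat(x, preset, fit_preset, win, ref = ref,
                          superpose = superpose)
    atom <- x$atom[.ens_select(x, preset), , drop = FALSE]
  }
  if (nrow(X) <= ncol(X)) {
    warning("fewer frames (", nrow(X), ") than coordinates (", ncol(X),
            "): covariance is rank-deficient")
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (max(abs(Xc)) < 1e-12) stop("degenerate ensemble: zero coordinate variance")
  C <- crossprod(Xc) / (nrow(Xc) - 1)
  eg <- eigen(C, symmetric = TRUE)
  V <- eg$vectors
  # deterministic sign: largest-magnitude component positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(eigenvalues = eg$values, vectors = V,
                 mean_coords = matrix(mu, ncol = 3, byrow = TRUE),
                 trace = sum(diag(C)), atom = atom, fit_reference = ref,
                 preset = preset, fit_preset = fit_preset,
                 superpose = superpose),
            class = "ed_pca")
}

# superposed, selected coordinates flattened to F x 3n
.superposed_flat <- function(ensemble, preset, fit_preset, window, ref = NULL,
                             superpose = TRUE) {
  fit_idx <- .ens_select(ensemble, fit_preset)
  sel_idx <- .ens_select(ensemble, preset)
  arr <- if (superpose) {
    if (is.null(ref)) ref <- .mean_reference(ensemble, fit_idx, window)
    .fit_frames(ensemble, fit_idx, ref, frames = window)[, sel_idx, , drop = FALSE]
  } else {
    a <- array(0, dim = c(length(window), length(sel_idx), 3))
    for (i in seq_along(window)) a[i, , ] <- .frame_coords(ensemble, window[i], sel_idx)
    a
  }
  F_ <- dim(arr)[1]; n <- dim(arr)[2]
  X <- matrix(0, F_, 3 * n)
  X[, seq(1, 3 * n, 3)] <- arr[, , 1]
  X[, seq(2, 3 * n, 3)] <- arr[, , 2]
  X[, seq(3, 3 * n, 3)] <- arr[, , 3]
  X
}

#' @export
print.ed_pca <- function(x, ...) {
  ev <- x$eigenvalues
  cat("ed_pca:", nrow(x$atom), "atoms;",
      "PC1-3 variance fractions:",
      paste(round(100 * ev[1:min(3, length(ev))] / sum(pmax(ev, 0)), 1),
            collapse = "/"), "%\n")
  invisible(x)
}

#' Project an ensemble onto principal components
#'
#' The ensemble is superposed with the PCA's protocol, centered on the PCA
#' mean, and dotted with the leading eigenvectors (cross-projection when the
#' ensemble is not the one the PCA was fitted on).
#'
#' @param ensemble an `ensemble` (or `replicate_set`; retained replicates are
#'   concatenated), sharing the PCA's atom space
#' @param pca an `ed_pca`
#' @param k number of components (default 3)
#' @param production_window frame indices (defaults as in [rmsf()])
#' @return F x k projection matrix
#' @export
ed_project <- function(ensemble, pca, k = 3, production_window = NULL) {
  if (inherits(ensemble, "replicate_set")) {
    win <- if (is.null(production_window)) ensemble$production_window else production_window
    mats <- lapply(retained(ensemble), ed_project, pca = pca, k = k,
                   production_window = win)
    return(do.call(rbind, mats))
  }
  win <- if (is.null(production_window)) seq_len(n_frames(ensemble)) else production_window
  X <- .superposed_flat(ensemble, pca$preset, pca$fit_preset, win,
                        ref = pca$fit_reference, superpose = pca$superpose)
  if (ncol(X) != ncol(pca$vectors)) stop("atom mismatch with the PCA atom space")
  mu <- as.vector(t(pca$mean_coords))
  sweep(X, 2, mu) %*% pca$vectors[, seq_len(k), drop = FALSE]
}

#' Per-residue porcupine vectors for one principal component
#'
#' For each residue, the eigenvector's per-atom 3-vectors are averaged and
#' scaled by the square root of the eigenvalue (an RMS displacement along the
#' mode, angstrom); the origin is the residue's mean coordinates.
#'
#' @param pca an `ed_pca`
#' @param component principal component index (1, 2 or 3)
#' @return data.frame: residue key, origin (ox, oy, oz), direction
#'   (vx, vy, vz, unit), magnitude (angstrom)
#' @export
porcupine <- function(pca, component = 1) {
  if (component > length(pca$eigenvalues)) stop("component out of range")
  v <- matrix(pca$vectors[, component], ncol = 3, byrow = TRUE)
  lam <- max(pca$eigenvalues[component], 0)
  keys <- res_key(pca$atom$chain, pca$atom$resseq,
                  if ("icode" %in% names(pca$atom)) pca$atom$icode else "")
  agg <- function(m) do.call(rbind, lapply(split(seq_along(keys), keys), function(i)
    colMeans(m[i, , drop = FALSE])))
  vec <- agg(v) * sqrt(lam)
  org <- agg(pca$mean_coords)
  mag <- sqrt(rowSums(vec^2))
  dir <- vec / ifelse(mag > 0, mag, 1)
  out <- data.frame(key = rownames(vec),
                    ox = org[, 1], oy = org[, 2], oz = org[, 3],
                    vx = dir[, 1], vy = dir[, 2], vz = dir[, 3],
                    magnitude = mag, stringsAsFactors = FALSE)
  rk <- parse_res_key(out$key)
  out <- out[order(rk$chain, rk$resseq), ]
  rownames(out) <- NULL
  out
}

#' Bidimensional free-energy landscape over two principal components
#'
#' Histograms the (PC1, PC2) projections on a `bins` x `bins` grid and
#' converts occupancy to free energy, F = -ln(count / max count), in kT
#' units; empty bins are masked (NA), never extrapolated, so the landscape
#' minimum over occupied bins is exactly 0.
#'
#' @param projections F x 2 matrix of projections
#' @param bins grid size per axis (default 50)
#' @param temperature kelvin; only used for the reported kT -> kcal/mol
#'   conversion factor (k_B = 0.0019872041 kcal/mol/K)
#' @return a `fel_grid`: `x_edges`, `y_edges`, `free_energy` (kT, NA =
#'   masked), `counts`, `masked_fraction`, `kcal_per_kt`
#' @export
fel <- function(projections, bins = 50, temperature = 300) {
  projections <- as.matrix(projections)
  if (nrow(projections) == 0) stop("no frames to histogram")
  stopifnot(ncol(projections) >= 2)
  p1 <- projections[, 1]; p2 <- projections[, 2]
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  xe <- seq(pad(range(p1))[1], pad(range(p1))[2], length.out = bins + 1)
  ye <- seq(pad(range(p2))[1], pad(range(p2))[2], length.out = bins + 1)
  ix <- pmin(pmax(findInterval(p1, xe, rightmost.closed = TRUE), 1), bins)
  iy <- pmin(pmax(findInterval(p2, ye, rightmost.closed = TRUE), 1), bins)
  counts <- matrix(0L, bins, bins)
  for (f in seq_along(ix)) counts[ix[f], iy[f]] <- counts[ix[f], iy[f]] + 1L
  fe <- -log(counts / max(counts))
  fe[counts == 0] <- NA
  structure(list(x_edges = xe, y_edges = ye, free_energy = fe, counts = counts,
                 masked_fraction = mean(counts == 0),
                 kcal_per_kt = 0.0019872041 * temperature),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  cat("fel_grid:", nrow(x$free_energy), "x", ncol(x$free_energy), "bins,",
      round(100 * x$masked_fraction, 1), "% masked; max",
      round(max(x$free_energy, na.rm = TRUE), 2), "kT\n")
  invisible(x)
}

# overlap coefficient of two 1-D samples on a common histogram
.overlap_coef <- function(a, b, bins = 40) {
  r <- range(c(a, b))
  if (diff(r) == 0) return(1)
  e <- seq(r[1], r[2], length.out = bins + 1)
  ca <- tabulate(pmin(pmax(findInterval(a, e, rightmost.closed = TRUE), 1), bins), bins)
  cb <- tabulate(pmin(pmax(findInterval(b, e, rightmost.closed = TRUE), 1), bins), bins)
  sum(pmin(ca / sum(ca), cb / sum(cb)))
}

#' Per-PC distribution shifts of a variant ensemble vs wild type
#'
#' Fits (or reuses) a PCA on the wild-type ensemble, cross-projects both
#' ensembles, and reports per component the shift of medians
#' (variant - wild type) and the overlap coefficient of the two 1-D
#' projection distributions.
#'
#' @param wt_ensemble,variant_ensemble ensembles (or replicate sets) sharing
#'   one atom space
#' @param pca optional pre-fitted `ed_pca` on the wild type
#' @param k components (default 3)
#' @return data.frame with pc, shift, overlap
#' @export
pc_shift <- function(wt_ensemble, variant_ensemble, pca = NULL, k = 3) {
  if (is.null(pca)) pca <- ed_pca(wt_ensemble)
  pw <- ed_project(wt_ensemble, pca, k = k)
  pv <- ed_project(variant_ensemble, pca, k = k)
  data.frame(
    pc = seq_len(k),
    shift = vapply(seq_len(k), function(i) median(pv[, i]) - median(pw[, i]), 0),
    overlap = vapply(seq_len(k), function(i) .overlap_coef(pw[, i], pv[, i]), 0)
  )
}

#' Write a porcupine table as delimited text
#' @param porc data.frame from [porcupine()]
#' @param path output path (TSV)
#' @export
write_porcupine <- function(porc, path) {
  write.table(porc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
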