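# Conformational-ensemble containers and per-replicate trajectory metrics.
#
# An ensemble is a frame stack over a fixed atom selection; a replicate set
# groups independently seeded ensembles of the same system, carries the
# production window (the equilibrated tail of each trajectory) and the
# outlier-exclusion record.

#' Construct a conformational ensemble
#'
#' @param xyz F x 3N coordinate matrix (frame per row, xyz interleaved per atom)
#' @param atom data.frame describing the N atoms (chain, resseq, icode,
#'   resname, name, element columns)
#' @param frame_interval time between stored frames, ps
#' @param replicate_id identifier of the replicate
#' @param label system label ("WT" or a variant name)
#' @return an object of class `ensemble`
#' @export
new_ensemble <- function(xyz, atom, frame_interval = 10, replicate_id = 1L,
                         label = "WT") {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 2) stop("an ensemble needs at least 2 frames")
  if (ncol(xyz) != 3 * nrow(atom)) stop("xyz width does not match atom table")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  structure(list(xyz = xyz, atom = atom, frame_interval = frame_interval,
                 replicate_id = replicate_id, label = label),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble:", nrow(x$xyz), "frames x", nrow(x$atom), "atoms,",
      x$frame_interval, "ps/frame, replicate", x$replicate_id,
      paste0("(", x$label, ")"), "\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble an `ensemble`
#' @return integer
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

.ens_res_keys <- function(ensemble) {
  res_key(ensemble$atom$chain, ensemble$atom$resseq, ensemble$atom$icode)
}

# atom indices within the ensemble's atom table
.ens_select <- function(ensemble, preset = c("all", "backbone", "calpha", "heavy")) {
  preset <- match.arg(preset)
  a <- ensemble$atom
  nm <- trimws(a$name)
  el <- if ("element" %in% names(a)) a$element else .infer_element(a$name, a$resname, FALSE)
  switch(preset,
         all = seq_len(nrow(a)),
         backbone = which(nm %in% c("N", "CA", "C", "O")),
         calpha = which(nm == "CA"),
         heavy = which(el != "H"))
}

.frame_coords <- function(ensemble, f, idx = NULL) {
  m <- matrix(ensemble$xyz[f, ], ncol = 3, byrow = TRUE)
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Extract one frame of an ensemble as a structure
#' @param ensemble an `ensemble`
#' @param frame frame index (default 1)
#' @return a `protein_structure`
#' @export
frame_structure <- function(ensemble, frame = 1) {
  a <- ensemble$atom
  x <- .frame_coords(ensemble, frame)
  atoms <- data.frame(
    serial = seq_len(nrow(a)), name = a$name, alt = "",
    resname = a$resname, chain = a$chain, resseq = a$resseq,
    icode = if ("icode" %in% names(a)) a$icode else "",
    x = x[, 1], y = x[, 2], z = x[, 3], occ = 1, b = 0,
    element = if ("element" %in% names(a)) a$element else
      .infer_element(a$name, a$resname, FALSE),
    is_hetero = FALSE, stringsAsFactors = FALSE)
  .new_structure(atoms, model_id = frame)
}

#' Group replicate ensembles into a replicate set
#'
#' @param ensembles list of `ensemble` objects sharing one atom table
#' @param production_window integer frame indices used for analysis; default
#'   the last 500 frames (or the last half for shorter trajectories)
#' @param max_excluded cap on outlier exclusions (default 2 per set)
#' @return an object of class `replicate_set`
#' @export
new_replicate_set <- function(ensembles, production_window = NULL,
                              max_excluded = 2) {
  stopifnot(length(ensembles) >= 1)
  f <- n_frames(ensembles[[1]])
  for (e in ensembles) {
    if (n_frames(e) != f) stop("replicates differ in frame count")
    if (nrow(e$atom) != nrow(ensembles[[1]]$atom)) stop("replicates differ in atoms")
  }
  if (is.null(production_window)) {
    w <- min(500, floor(f / 2))
    production_window <- seq(f - w + 1, f)
  }
  if (any(production_window < 1 | production_window > f)) {
    stop("production_window outside frame range")
  }
  structure(list(ensembles = ensembles, production_window = production_window,
                 excluded = data.frame(replicate_id = character(0),
                                       deviation = numeric(0),
                                       stringsAsFactors = FALSE),
                 max_excluded = max_excluded,
                 label = ensembles[[1]]$label),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat("replicate_set:", length(x$ensembles), "replicates (", x$label, "),",
      length(x$production_window), "production frames,",
      nrow(x$excluded), "excluded\n")
  invisible(x)
}

#' Retained (non-excluded) ensembles of a replicate set
#' @param rset a `replicate_set`
#' @return list of `ensemble`
#' @export
retained <- function(rset) {
  ids <- vapply(rset$ensembles, function(e) as.character(e$replicate_id), "")
  rset$ensembles[!ids %in% rset$excluded$replicate_id]
}

#' Per-frame RMSD series against a reference structure
#'
#' Each frame is Kabsch-superposed onto the reference over the selection,
#' then the RMSD over that selection is recorded ("structural drift" when the
#' reference is the initial structure, the default).
#'
#' @param ensemble an `ensemble`
#' @param reference reference coordinates: a `protein_structure`, an N x 3
#'   matrix over the ensemble's atoms, or NULL (frame 1)
#' @param preset atom selection preset (default "all")
#' @return numeric vector of length F (angstrom)
#' @export
rmsd_series <- function(ensemble, reference = NULL, preset = "all") {
  idx <- .ens_select(ensemble, preset)
  ref <- if (is.null(reference)) {
    .frame_coords(ensemble, 1, idx)
  } else if (inherits(reference, "protein_structure")) {
    m <- .match_ens_structure(ensemble, reference, idx)
    coords(reference, m)
  } else {
    as.matrix(reference)[idx, , drop = FALSE]
  }
  vapply(seq_len(n_frames(ensemble)), function(f) {
    kabsch(.frame_coords(ensemble, f, idx), ref)$rmsd
  }, 0)
}

# match ensemble atoms (at idx) to structure atoms by residue key + name
.match_ens_structure <- function(ensemble, structure, idx) {
  ke <- paste(.ens_res_keys(ensemble)[idx], trimws(ensemble$atom$name[idx]))
  ks <- paste(atom_res_keys(structure), trimws(structure$atoms$name))
  m <- match(ke, ks)
  if (anyNA(m)) {
    stop("atom pairing failed between ensemble and structure; unmatched: ",
         paste(head(ke[is.na(m)], 10), collapse = ", "))
  }
  m
}

#' Median RMSD over the production window
#' @param series numeric RMSD series
#' @param production_window integer frame indices
#' @return median (angstrom)
#' @export
median_rmsd <- function(series, production_window = seq_along(series)) {
  if (length(production_window) == 0) stop("empty production window")
  median(series[production_window])
}

#' Exclude outlier replicates by their production-window median RMSD
#'
#' A replicate is flagged iff its production-window median RMSD deviates from
#' the median of the replicate medians by more than `k` times the MAD of
#' those medians (scaled by the usual 1.4826 consistency constant, so `k`
#' reads as a robust z-score). At most `max_excluded` replicates are removed,
#' worst first. If every replicate is flagged the set is returned unchanged
#' with a warning.
#'
#' @param rset a `replicate_set` (at least 3 replicates)
#' @param k MAD multiplier (default 2.5)
#' @param max_excluded exclusion cap (default 2)
#' @param preset atom selection for the drift series (default "all")
#' @param reference optional common reference structure (default: each
#'   replicate's first frame)
#' @return the `replicate_set` with its `excluded` record filled in
#' @export
exclude_outlier_replicates <- function(rset, k = 2.5, max_excluded = 2,
                                       preset = "all", reference = NULL) {
  if (length(rset$ensembles) < 3) stop("need at least 3 replicates")
  meds <- vapply(rset$ensembles, function(e) {
    median_rmsd(rmsd_series(e, reference = reference, preset = preset),
                rset$production_window)
  }, 0)
  ids <- vapply(rset$ensembles, function(e) as.character(e$replicate_id), "")
  center <- median(meds)
  dev <- abs(meds - center)
  scale <- 1.4826 * median(dev)  # consistency-scaled MAD of the medians
  flagged <- if (scale > 0) dev > k * scale else dev > 0
  if (all(flagged)) {
    warning("all replicates flagged as outliers; none excluded")
    return(rset)
  }
  ord <- order(dev, decreasing = TRUE)
  take <- ord[flagged[ord]][seq_len(min(max_excluded, sum(flagged)))]
  rset$excluded <- data.frame(replicate_id = ids[take], deviation = dev[take],
                              stringsAsFactors = FALSE)
  rset
}

# pooled production-window RMSD median across retained replicates
.set_rmsd_statistic <- function(rset, preset = "all", reference = NULL) {
  pooled <- unlist(lapply(retained(rset), function(e) {
    rmsd_series(e, reference = reference, preset = preset)[rset$production_window]
  }))
  median(pooled)
}

#' Median-difference RMSD drift score of a variant vs baseline sets
#'
#' The variant statistic is the median of pooled production-window RMSD values
#' across retained replicates; the baseline is the mean of the same statistic
#' over the baseline sets (typically the benign controls). Reported as the
#' median difference and as percent change of the baseline.
#'
#' @param variant_set a `replicate_set` (outlier exclusion already applied)
#' @param baseline_sets list of `replicate_set` (e.g. benign controls)
#' @param preset atom selection (default "all")
#' @return list with `median_diff` (angstrom), `percent_change`,
#'   `variant_stat`, `baseline_stat`
#' @export
rmsd_score <- function(variant_set, baseline_sets, preset = "all") {
  if (length(baseline_sets) == 0) stop("empty baseline")
  if (inherits(baseline_sets, "replicate_set")) baseline_sets <- list(baseline_sets)
  v <- .set_rmsd_statistic(variant_set, preset)
  b <- mean(vapply(baseline_sets, .set_rmsd_statistic, 0, preset = preset))
  list(median_diff = v - b, percent_change = 100 * (v - b) / b,
       variant_stat = v, baseline_stat = b)
}

# Superposition protocol shared by RMSF and PCA: the reference is the
# production-window mean structure over the fit selection, iterated once
# (frames first fitted to the window's first frame, averaged, then every
# frame is fitted onto that mean).  Kabsch fitting is independent of a
# frame's initial rigid placement, so fitting directly onto the reference is
# exact and reusable for cross-projection onto a stored reference.

.fit_frames <- function(ensemble, fit_idx, ref, frames = seq_len(n_frames(ensemble))) {
  n <- nrow(ensemble$atom)
  out <- array(0, dim = c(length(frames), n, 3))
  for (i in seq_along(frames)) {
    x <- .frame_coords(ensemble, frames[i])
    fit <- kabsch(x[fit_idx, , drop = FALSE], ref)
    out[i, , ] <- .apply_fit(x, fit)
  }
  out
}

.mean_reference <- function(ensemble, fit_idx, window) {
  ref0 <- .frame_coords(ensemble, window[1], fit_idx)
  acc <- matrix(0, length(fit_idx), 3)
  for (f in window) {
    x <- .frame_coords(ensemble, f, fit_idx)
    acc <- acc + .apply_fit(x, kabsch(x, ref0))
  }
  acc / length(window)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames in the production window are superposed onto the window-mean
#' structure over `fit_preset` (one mean-refit iteration); per atom, RMSF is
#' the root mean squared distance to the atom's mean position; per residue,
#' the mean over the residue's selected atoms. For a replicate set the
#' retained replicates' profiles are averaged.
#'
#' @param x an `ensemble` or `replicate_set`
#' @param preset atoms aggregated per residue (default "calpha")
#' @param fit_preset superposition selection (default "backbone")
#' @param production_window frame indices (default: all frames of an
#'   ensemble; the set's window for a `replicate_set`)
#' @param superpose superpose frames before measuring (default TRUE; FALSE
#'   treats the frames as already co-registered)
#' @return an `rmsf_profile`: named numeric vector (residue key -> angstrom)
#'   with attributes `resseq` and `scope`
#' @export
rmsf <- function(x, preset = "calpha", fit_preset = "backbone",
                 production_window = NULL, superpose = TRUE) {
  if (inherits(x, "replicate_set")) {
    ens <- retained(x)
    win <- if (is.null(production_window)) x$production_window else production_window
    profs <- lapply(ens, rmsf, preset = preset, fit_preset = fit_preset,
                    production_window = win, superpose = superpose)
    out <- Reduce(`+`, profs) / length(profs)
    attributes(out) <- attributes(profs[[1]])
    return(out)
  }
  stopifnot(inherits(x, "ensemble"))
  if (n_frames(x) < 2) stop("need at least 2 frames")
  win <- if (is.null(production_window)) seq_len(n_frames(x)) else production_window
  fit_idx <- .ens_select(x, fit_preset)
  sel_idx <- .ens_select(x, preset)
  arr <- if (superpose) {
    .fit_frames(x, fit_idx, .mean_reference(x, fit_idx, win), frames = win)
  } else {
    a <- array(0, dim = c(length(win), nrow(x$atom), 3))
    for (i in seq_along(win)) a[i, , ] <- .frame_coords(x, win[i])
    a
  }
  mu <- apply(arr, c(2, 3), mean)
  dev2 <- (arr[, sel_idx, 1] - rep(mu[sel_idx, 1], each = length(win)))^2 +
          (arr[, sel_idx, 2] - rep(mu[sel_idx, 2], each = length(win)))^2 +
          (arr[, sel_idx, 3] - rep(mu[sel_idx, 3], each = length(win)))^2
  atom_rmsf <- sqrt(colMeans(matrix(dev2, nrow = length(win))))
  keys <- .ens_res_keys(x)[sel_idx]
  prof <- tapply(atom_rmsf, keys, mean)
  resseq <- tapply(x$atom$resseq[sel_idx], keys, function(v) v[1])
  ord <- order(resseq)
  out <- as.numeric(prof)[ord]
  names(out) <- names(prof)[ord]
  attr(out, "resseq") <- as.integer(resseq[ord])
  attr(out, "scope") <- preset
  class(out) <- "rmsf_profile"
  out
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat("rmsf_profile:", length(x), "residues, mean",
      round(mean(unclass(x)), 3), "angstrom (scope:", attr(x, "scope"), ")\n")
  invisible(x)
}

#' Candidate comparison metrics between two RMSF profiles
#'
#' Computes, over the shared residues, the five candidate metrics (Spearman
#' and Pearson correlation, average difference wt - variant, average absolute
#' difference, absolute residual sum) plus the percent elevation of the
#' variant's mean RMSF over the wild type's. The headline impact score is
#' `avg_abs_diff` (mean |WT - variant| per residue).
#'
#' @param wt,variant `rmsf_profile` objects
#' @return list of metrics; `n_shared` records the residue overlap
#' @export
rmsf_compare <- function(wt, variant) {
  shared <- intersect(names(wt), names(variant))
  w <- unclass(wt)[shared]; v <- unclass(variant)[shared]
  if (length(shared) < 3) stop("need at least 3 shared residues")
  d <- w - v
  list(avg_abs_diff = mean(abs(d)),
       avg_diff = mean(d),
       abs_residual_sum = sum(abs(d)),
       pearson = cor(w, v, method = "pearson"),
       spearman = cor(w, v, method = "spearman"),
       percent_elevation = 100 * (mean(v) - mean(w)) / mean(w),
       n_shared = length(shared))
}

#' Agreement between an RMSF profile and crystallographic B-factors
#'
#' Converts RMSF to a predicted isotropic temperature factor via
#' B = (8 pi^2 / 3) RMSF^2 and correlates it with the per-residue mean
#' crystallographic B of the structure.
#'
#' @param profile an `rmsf_profile`
#' @param structure a `protein_structure` carrying B-factors
#' @return list with `pearson`, `spearman`, `predicted_b` (square angstrom,
#'   named by residue key), `crystal_b`
#' @export
bfactor_agreement <- function(profile, structure) {
  pred <- (8 * pi^2 / 3) * unclass(profile)^2
  a <- structure$atoms[!structure$atoms$is_hetero, ]
  keys <- res_key(a$chain, a$resseq, a$icode)
  bres <- tapply(a$b, keys, mean)
  shared <- intersect(names(pred), names(bres))
  if (length(shared) < 3) stop("need at least 3 shared residues with B-factors")
  p <- pred[shared]; b <- as.numeric(bres[shared])
  if (all(p == 0)) stop("all-zero RMSF profile: correlation undefined")
  # a constant profile or constant B column yields NA correlations
  list(pearson = suppressWarnings(cor(p, b, method = "pearson")),
       spearman = suppressWarnings(cor(p, b, method = "spearman")),
       predicted_b = pred, crystal_b = setNames(b, shared))
}

#' Classify per-residue mobility
#'
#' Residues fluctuating less than `still_cut` are "still", more than
#' `mobile_cut` are "mobile", boundary values inclusive are "intermediate".
#'
#' @param profile an `rmsf_profile`
#' @param still_cut still threshold, angstrom (default 0.7)
#' @param mobile_cut mobile threshold, angstrom (default 1.0)
#' @return named character vector (residue key -> class)
#' @export
classify_mobility <- function(profile, still_cut = 0.7, mobile_cut = 1.0) {
  v <- unclass(profile)
  out <- ifelse(v < still_cut, "still",
                ifelse(v > mobile_cut, "mobile", "intermediate"))
  setNames(out, names(profile))
}
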