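# Rigid-body superposition, structural-perturbation scores and numerical
# solvent-accessible surface area.

#' Kabsch superposition
#'
#' Least-squares rigid-body fit of `mobile` onto `reference` via singular
#' value decomposition of the cross-covariance matrix, with reflection
#' corrected through the sign of the smallest singular value.
#'
#' The fitted coordinates are `mobile %*% rotation + translation` (points as
#' rows); `det(rotation)` is +1.
#'
#' @param mobile N x 3 coordinate matrix
#' @param reference N x 3 coordinate matrix
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) stop("coordinate sets differ in length")
  if (nrow(mobile) < 3) stop("degenerate geometry: need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  mc <- sweep(mobile, 2, cm); rc <- sweep(reference, 2, cr)
  A <- crossprod(mc, rc)
  sv <- svd(A)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    stop("degenerate geometry: points are (near) collinear")
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- mc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - rc)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% R), rmsd = rmsd)
}

.apply_fit <- function(xyz, fit) sweep(xyz %*% fit$rotation, 2, fit$translation, "+")

.rmsd_raw <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Match atoms of two structures by (residue key, atom name).  Side-chain
# atoms of residues whose residue name differs between the two structures
# (i.e. the mutated residue) are dropped from matching; any other unmatched
# atom is an error.
.match_atoms <- function(a, b, idx_a, idx_b) {
  ka <- paste(atom_res_keys(a)[idx_a], trimws(a$atoms$name[idx_a]))
  kb <- paste(atom_res_keys(b)[idx_b], trimws(b$atoms$name[idx_b]))
  ra <- residue_table(a); rb <- residue_table(b)
  shared_res <- merge(ra[, c("key", "resname")], rb[, c("key", "resname")], by = "key")
  mutated <- shared_res$key[shared_res$resname.x != shared_res$resname.y]
  bb <- c("N", "CA", "C", "O")
  ok_a <- !(atom_res_keys(a)[idx_a] %in% mutated & !trimws(a$atoms$name[idx_a]) %in% bb)
  ok_b <- !(atom_res_keys(b)[idx_b] %in% mutated & !trimws(b$atoms$name[idx_b]) %in% bb)
  ka <- ka[ok_a]; ia <- idx_a[ok_a]
  kb <- kb[ok_b]; ib <- idx_b[ok_b]
  mpos <- match(ka, kb)
  un_a <- ka[is.na(mpos)]
  un_b <- setdiff(kb, ka)
  if (length(un_a) > 0 || length(un_b) > 0) {
    stop("atom pairing failed; unmatched atoms: ",
         paste(head(c(un_a, un_b), 10), collapse = ", "))
  }
  list(ia = ia, ib = ib[mpos])
}

#' RMSD between two structures
#'
#' Atoms are matched by residue key and atom name; side chains of mutated
#' residues (differing residue name at a shared position) are automatically
#' excluded. By default the coordinates are compared as-is (structures derived
#' from one common starting model are already co-registered); set
#' `superpose = TRUE` to Kabsch-fit first.
#'
#' @param a,b `protein_structure` objects sharing residue numbering
#' @param preset,chain,resseq,names selection filters (see [atom_select()])
#' @param superpose logical; Kabsch-superpose before measuring
#' @return RMSD in angstrom
#' @export
rmsd_between <- function(a, b, preset = "backbone", chain = NULL, resseq = NULL,
                         names = NULL, superpose = FALSE) {
  idx_a <- atom_select(a, preset = preset, chain = chain, resseq = resseq, names = names)
  idx_b <- atom_select(b, preset = preset, chain = chain, resseq = resseq, names = names)
  m <- .match_atoms(a, b, idx_a, idx_b)
  xa <- coords(a, m$ia); xb <- coords(b, m$ib)
  if (superpose) {
    fit <- kabsch(xa, xb)
    xa <- .apply_fit(xa, fit)
  }
  .rmsd_raw(xa, xb)
}

#' Local structural perturbation around a mutation site
#'
#' Selects every residue with any heavy atom within `radius` of the mutated
#' residue's heavy atoms (site excluded) and measures the backbone RMSD over
#' that shell between wild type and variant, together with the mean per-atom
#' backbone displacement.
#'
#' @param wt,variant `protein_structure` objects sharing numbering
#' @param site mutated residue key ("chain:resseq" or "chain:resseq:icode")
#' @param radius shell radius in angstrom (default 10)
#' @param superpose Kabsch-fit the shell before measuring (default FALSE:
#'   structures minimized from a common model are co-registered)
#' @return list with `rmsd`, `mean_disp` (angstrom) and `n_residues`
#' @export
local_perturbation <- function(wt, variant, site, radius = 10, superpose = FALSE) {
  shell <- residues_within(wt, site, radius, atom_scope = "heavy")
  if (length(shell) == 0) stop("empty shell: no residue within ", radius,
                               " angstrom of ", site)
  pk <- parse_res_key(shell)
  idx_w <- atom_select(wt, preset = "backbone", resseq = unique(pk$resseq))
  idx_w <- idx_w[atom_res_keys(wt)[idx_w] %in% shell]
  idx_v <- atom_select(variant, preset = "backbone", resseq = unique(pk$resseq))
  idx_v <- idx_v[atom_res_keys(variant)[idx_v] %in% shell]
  m <- .match_atoms(wt, variant, idx_w, idx_v)
  xw <- coords(wt, m$ia); xv <- coords(variant, m$ib)
  if (superpose) xw <- .apply_fit(xw, kabsch(xw, xv))
  disp <- sqrt(rowSums((xw - xv)^2))
  list(rmsd = sqrt(mean(disp^2)), mean_disp = mean(disp), n_residues = length(shell))
}

#' Default element radii for SASA (angstrom)
#'
#' Bundled van der Waals radii; any element not listed uses the `default`
#' entry. Overridable via the `radii` argument of [sasa()].
#' @return named numeric vector
#' @export
default_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
    FE = 1.80, ZN = 1.39, NI = 1.63, MG = 1.73, default = 1.80)
}

# Deterministic near-uniform points on the unit sphere (golden spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA from probe-inflated atomic spheres sampled with a
#' deterministic golden-spiral point set and occlusion testing against
#' neighboring atoms. Computed over heavy atoms (hydrogens, if present, are
#' ignored). Polar area is the sum over N and O atoms by default; the
#' remainder (C, S, metals) is nonpolar.
#'
#' @param structure a `protein_structure`
#' @param probe probe radius in angstrom (default 1.4, water)
#' @param sphere_points number of test points per atom (default 960)
#' @param radii named element-radius vector (see [default_radii()])
#' @param polar_elements elements counted as polar (default N, O)
#' @param idx optional atom indices restricting the computation
#' @return list with `total`, `per_atom` (named by atom index), `polar`,
#'   `nonpolar`, `probe_radius` (all areas in square angstrom)
#' @export
sasa <- function(structure, probe = 1.4, sphere_points = 960,
                 radii = default_radii(), polar_elements = c("N", "O"),
                 idx = NULL) {
  if (is.null(idx)) idx <- atom_select(structure, preset = "heavy", hetero = "include")
  el <- structure$atoms$element[idx]
  r <- radii[el]
  miss <- is.na(r)
  if (any(miss)) {
    if (!"default" %in% names(radii)) {
      stop("no radius for element(s) ", paste(unique(el[miss]), collapse = ", "),
           " and no default radius provided")
    }
    r[miss] <- radii[["default"]]
  }
  r <- as.numeric(r) + probe
  x <- coords(structure, idx)
  n <- nrow(x)
  pts <- .sphere_points(sphere_points)
  per_atom <- numeric(n)
  # neighbor search via squared-distance threshold
  d2 <- as.matrix(dist(x))^2
  for (i in seq_len(n)) {
    cutoff2 <- (r[i] + r)^2
    nbr <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, x[i, ], "+")
    if (length(nbr) > 0) {
      acc <- rep(TRUE, sphere_points)
      for (j in nbr) {
        if (!any(acc)) break
        dj2 <- rowSums(sweep(p[acc, , drop = FALSE], 2, x[j, ], "-")^2)
        acc[acc] <- dj2 >= r[j]^2
      }
      frac <- mean(acc)
    } else frac <- 1
    per_atom[i] <- frac * 4 * pi * r[i]^2
  }
  names(per_atom) <- idx
  polar <- sum(per_atom[el %in% polar_elements])
  list(total = sum(per_atom), per_atom = per_atom,
       polar = polar, nonpolar = sum(per_atom) - polar, probe_radius = probe)
}

.subset_structure <- function(structure, idx) {
  .new_structure(structure$atoms[idx, , drop = FALSE],
                 model_id = structure$model_id, title = structure$title)
}

#' Buried surface area between two parts of a complex
#'
#' Delta-SASA decomposition: `SASA(A alone) + SASA(B alone) - SASA(complex)`,
#' with polar/nonpolar components classified as in [sasa()]. The `per_side`
#' convention (default) divides the delta by two (the average interface area
#' contributed by each side); `total` reports the full delta.
#'
#' @param complex a `protein_structure` containing both parts
#' @param part_a,part_b disjoint atom index vectors into `complex`
#' @param convention "per_side" (default) or "total"
#' @param ... passed to [sasa()] (probe, sphere_points, radii, ...)
#' @return list with `buried`, `polar`, `nonpolar` (square angstrom) and
#'   `convention`
#' @export
buried_surface <- function(complex, part_a, part_b,
                           convention = c("per_side", "total"), ...) {
  convention <- match.arg(convention)
  if (length(intersect(part_a, part_b)) > 0) {
    stop("part_a and part_b overlap")
  }
  s_ab <- sasa(.subset_structure(complex, sort(c(part_a, part_b))), ...)
  s_a <- sasa(.subset_structure(complex, sort(part_a)), ...)
  s_b <- sasa(.subset_structure(complex, sort(part_b)), ...)
  f <- if (convention == "per_side") 0.5 else 1
  list(buried = f * (s_a$total + s_b$total - s_ab$total),
       polar = f * (s_a$polar + s_b$polar - s_ab$polar),
       nonpolar = f * (s_a$nonpolar + s_b$nonpolar - s_ab$nonpolar),
       convention = convention)
}
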