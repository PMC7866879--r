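# Nonbonded (van der Waals + electrostatic) interaction energies between
# atom groups, with an implicit distance-dependent dielectric.
#
# Electrostatics: E = k q_i q_j / (eps(r) r), k = 332.0637 kcal A / (mol e^2),
# with eps(r) = D r (distance-dependent, the default, D = 80) or eps(r) = D
# (constant).  Lennard-Jones: E = eps_ij [ (rmin_ij / r)^12 - 2 (rmin_ij/r)^6 ]
# with eps_ij the geometric mean and rmin_ij the sum of the rmin/2 halves.
# Interactions are truncated (plainly) beyond the cutoff.  Absolute energies
# are not comparable to any specific force-field implementation; deltas and
# orderings between variants are the meaningful outputs.

#' Nonbonded parameter set
#'
#' @param table data.frame with columns resname, name, charge (e),
#'   epsilon (kcal/mol, LJ well depth), rmin_half (angstrom). A resname of
#'   "*" is a wildcard matched after exact (resname, name) lookup.
#' @param dielectric_model "distance_dependent" (eps = D r) or "constant"
#' @param D dielectric factor (default 80)
#' @param cutoff truncation distance, angstrom (default 12)
#' @return an object of class `nb_params`
#' @export
nb_params <- function(table = default_nb_table(),
                      dielectric_model = c("distance_dependent", "constant"),
                      D = 80, cutoff = 12) {
  dielectric_model <- match.arg(dielectric_model)
  stopifnot(all(c("resname", "name", "charge", "epsilon", "rmin_half") %in%
                names(table)),
            all(table$epsilon >= 0), all(table$rmin_half > 0), cutoff > 0)
  structure(list(table = table, dielectric_model = dielectric_model,
                 D = D, cutoff = cutoff, coulomb = 332.0637),
            class = "nb_params")
}

#' Bundled minimal nonbonded parameter table
#'
#' Approximate CHARMM-style charges and LJ parameters for protein backbone
#' and common side-chain atoms, divalent metal centers (Fe2+, Zn2+ as +2e
#' point charges), the 2-oxoglutarate cofactor and trimethyl-lysine. Intended
#' as a starting point; override any entry by supplying your own table.
#'
#' @return data.frame (resname, name, charge, epsilon, rmin_half)
#' @export
default_nb_table <- function() {
  path <- system.file("extdata", "nb_params.tsv", package = "dynimpact")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             comment.char = "#")
}

# resolve (resname, name) -> parameter rows; exact match, then wildcard "*"
.nb_lookup <- function(params, resname, name) {
  tb <- params$table
  key_exact <- paste(tb$resname, trimws(tb$name))
  key_wild <- ifelse(tb$resname == "*", trimws(tb$name), NA)
  q <- paste(resname, trimws(name))
  m <- match(q, key_exact)
  mw <- match(trimws(name), key_wild)
  m[is.na(m)] <- mw[is.na(m)]
  if (anyNA(m)) {
    stop("missing nonbonded parameters for atom(s): ",
         paste(unique(q[is.na(m)]), collapse = ", "))
  }
  tb[m, c("charge", "epsilon", "rmin_half")]
}

#' Nonbonded energy of one atom pair
#'
#' @param atom_i,atom_j lists with `coords` (3-vector) and either explicit
#'   `charge`, `epsilon`, `rmin_half` or a `resname`/`name` pair resolved
#'   against the parameter table
#' @param params an `nb_params`
#' @return list with `elec`, `vdw` (kcal/mol)
#' @export
pair_energy <- function(atom_i, atom_j, params) {
  res <- function(a) {
    if (!is.null(a$charge)) a
    else c(a, as.list(.nb_lookup(params, a$resname, a$name)))
  }
  ai <- res(atom_i); aj <- res(atom_j)
  r <- sqrt(sum((ai$coords - aj$coords)^2))
  if (r == 0) stop("singularity: coincident atoms (r = 0)")
  if (r > params$cutoff) return(list(elec = 0, vdw = 0))
  eps_r <- if (params$dielectric_model == "distance_dependent") params$D * r else params$D
  elec <- params$coulomb * ai$charge * aj$charge / (eps_r * r)
  eps_ij <- sqrt(ai$epsilon * aj$epsilon)
  rmin_ij <- ai$rmin_half + aj$rmin_half
  sr6 <- (rmin_ij / r)^6
  list(elec = elec, vdw = eps_ij * (sr6^2 - 2 * sr6))
}

#' Nonbonded interaction energy between two atom groups
#'
#' Sums [pair_energy()] over all cross pairs within the cutoff (vectorized);
#' symmetric in its group arguments.
#'
#' @param structure a `protein_structure`
#' @param group_a,group_b disjoint atom index vectors
#' @param params an `nb_params`
#' @return list with `elec`, `vdw`, `total` (kcal/mol)
#' @export
group_energy <- function(structure, group_a, group_b, params) {
  if (length(intersect(group_a, group_b)) > 0) stop("groups overlap")
  a <- structure$atoms
  .group_energy_xyz(coords(structure, group_a), coords(structure, group_b),
                    .nb_lookup(params, a$resname[group_a], a$name[group_a]),
                    .nb_lookup(params, a$resname[group_b], a$name[group_b]),
                    params)
}

.group_energy_xyz <- function(xa, xb, pa, pb, params) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  r <- sqrt(pmax(d2, 0))
  if (any(r < 1e-12)) stop("singularity: coincident atoms across groups")
  within <- r <= params$cutoff
  qq <- outer(pa$charge, pb$charge)
  eps_r <- if (params$dielectric_model == "distance_dependent") params$D * r else params$D
  elec <- sum((params$coulomb * qq / (eps_r * r))[within])
  eps_ij <- outer(sqrt(pa$epsilon), sqrt(pb$epsilon))
  rmin_ij <- outer(pa$rmin_half, pb$rmin_half, "+")
  sr6 <- (rmin_ij / r)^6
  vdw <- sum((eps_ij * (sr6^2 - 2 * sr6))[within])
  list(elec = elec, vdw = vdw, total = elec + vdw)
}

#' Time-dependent interaction energy series over an ensemble
#'
#' Evaluates [group_energy()] for every frame and summarizes the production
#' window (mean, standard deviation).
#'
#' @param ensemble an `ensemble`
#' @param group_a,group_b disjoint atom index vectors into the ensemble's
#'   atom table
#' @param params an `nb_params`
#' @param production_window frame indices (default all frames)
#' @param partner label of the partner group (e.g. "substrate_peptide",
#'   "K27me3_residue", "cofactor_2OG", "Fe_site", "Zn_site")
#' @return an `interaction_series`: data.frame `series` (frame, elec, vdw,
#'   total), `mean`, `sd`, `partner`
#' @export
interaction_series <- function(ensemble, group_a, group_b, params,
                               production_window = NULL, partner = "custom") {
  if (length(intersect(group_a, group_b)) > 0) stop("groups overlap")
  win <- if (is.null(production_window)) seq_len(n_frames(ensemble)) else production_window
  a <- ensemble$atom
  pa <- .nb_lookup(params, a$resname[group_a], a$name[group_a])
  pb <- .nb_lookup(params, a$resname[group_b], a$name[group_b])
  rows <- lapply(seq_len(n_frames(ensemble)), function(f) {
    e <- .group_energy_xyz(.frame_coords(ensemble, f, group_a),
                           .frame_coords(ensemble, f, group_b), pa, pb, params)
    data.frame(frame = f, elec = e$elec, vdw = e$vdw, total = e$total)
  })
  series <- do.call(rbind, rows)
  structure(list(series = series,
                 mean = mean(series$total[win]), sd = sd(series$total[win]),
                 window = win, partner = partner),
            class = "interaction_series")
}

#' @export
print.interaction_series <- function(x, ...) {
  cat("interaction_series (", x$partner, "): ", nrow(x$series), " frames, ",
      "windowed mean ", round(x$mean, 3), " +/- ", round(x$sd, 3),
      " kcal/mol\n", sep = "")
  invisible(x)
}

#' Variant-vs-wild-type interaction energy delta
#'
#' `delta_mean = mean(variant) - mean(wt)` over the production windows; the
#' call is "destabilizing" above +tau, "stabilizing" below -tau, otherwise
#' "neutral" (strict inequalities).
#'
#' @param variant_series,wt_series `interaction_series` with the same partner
#' @param tau neutrality band half-width, kcal/mol (default 0.5)
#' @return list with `delta_mean` and `direction`
#' @export
interaction_delta <- function(variant_series, wt_series, tau = 0.5) {
  if (!identical(variant_series$partner, wt_series$partner)) {
    stop("partner labels differ: ", variant_series$partner, " vs ",
         wt_series$partner)
  }
  d <- variant_series$mean - wt_series$mean
  dir <- if (d > tau) "destabilizing" else if (d < -tau) "stabilizing" else "neutral"
  list(delta_mean = d, direction = dir)
}
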