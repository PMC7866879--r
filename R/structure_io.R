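#' @importFrom stats median mad sd cor setNames aggregate complete.cases
#' @importFrom utils read.table write.table head tail
NULL

# Residue key strings ("chain:resseq:icode") identify residues everywhere in
# the package.  Author (PDB) numbering is canonical: no renumbering is ever
# performed, so results can be cross-referenced against published residue
# numbers directly.

#' Build a residue key string
#'
#' @param chain chain identifier
#' @param resseq author-assigned residue number (integer, may be discontinuous)
#' @param icode insertion code, "" when absent
#' @return character key of the form "chain:resseq:icode"
#' @export
res_key <- function(chain, resseq, icode = "") {
  icode[is.na(icode)] <- ""
  chain[is.na(chain)] <- ""
  paste(chain, as.integer(resseq), icode, sep = ":")
}

#' Parse a residue key string back into its fields
#' @param key character vector of "chain:resseq:icode" keys
#' @return data.frame with chain, resseq, icode
#' @export
parse_res_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(
    chain  = vapply(parts, function(p) p[1], ""),
    resseq = as.integer(vapply(parts, function(p) p[2], "")),
    icode  = vapply(parts, function(p) if (length(p) >= 3) p[3] else "", ""),
    stringsAsFactors = FALSE
  )
}

# Atom-name based element inference for files lacking the element column.
.infer_element <- function(name, resname, is_hetero) {
  nm <- toupper(trimws(name))
  two <- c("FE", "ZN", "NI", "MG", "MN", "CU", "NA", "CL", "CA", "BR", "SE")
  ifelse(is_hetero & nm %in% two, nm,
         substr(gsub("^[0-9]+", "", nm), 1, 1))
}

.validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records found in '", path, "'")
  bad <- which(rec & nchar(lines) < 54)
  if (length(bad) == 0) {
    coords <- substr(lines[rec], 31, 54)
    ok <- grepl("^[-+ .0-9]+$", coords)
    if (!all(ok)) bad <- which(rec)[!ok]
  }
  if (length(bad) > 0) {
    stop("malformed fixed-width PDB record at line ", bad[1], " of '", path, "'")
  }
  invisible(TRUE)
}

.new_structure <- function(atoms, model_id = 1L, title = "") {
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model_id = as.integer(model_id), title = title),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure:", nrow(x$atoms), "atoms,",
      length(unique(res_key(x$atoms$chain, x$atoms$resseq, x$atoms$icode))),
      "residues (model", x$model_id, ")\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure a protein_structure
#' @return integer atom count
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Read a PDB file
#'
#' Reads ATOM/HETATM records (fixed-width PDB) into a structure object.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (first on ties); author residue numbering is preserved; the element is
#' inferred from the atom name when the element column is absent.
#'
#' @param path path to a PDB file
#' @param model_policy "first" returns the first MODEL as a single structure;
#'   "all" returns a list with one structure per MODEL.
#' @return a `protein_structure`, or a list of them when `model_policy = "all"`
#' @export
read_pdb <- function(path, model_policy = c("first", "all")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  .validate_pdb_lines(path)
  p <- bio3d::read.pdb(path, multi = (model_policy == "all"),
                       rm.alt = FALSE, verbose = FALSE)
  at <- p$atom
  # resolve alt-locs: highest occupancy wins, first occurrence on ties
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  akey <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  keep <- rep(TRUE, nrow(at))
  dup <- akey %in% akey[duplicated(akey)]
  if (any(dup)) {
    for (k in unique(akey[dup])) {
      idx <- which(akey == k)
      best <- idx[which.max(occ[idx])]  # which.max takes first on ties
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  ikeep <- which(keep)
  at <- at[ikeep, , drop = FALSE]

  build_atoms <- function(at, xyz) {
    icode <- at$insert; icode[is.na(icode)] <- ""
    chain <- at$chain; chain[is.na(chain)] <- ""
    el <- at$elesy
    miss <- is.na(el) | trimws(el) == ""
    is_het <- at$type == "HETATM"
    if (any(miss)) el[miss] <- .infer_element(at$elety[miss], at$resid[miss], is_het[miss])
    data.frame(
      serial = at$eleno, name = at$elety, alt = ifelse(is.na(at$alt), "", at$alt),
      resname = at$resid, chain = chain, resseq = at$resno, icode = icode,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occ = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
      element = toupper(trimws(el)), is_hetero = is_het,
      stringsAsFactors = FALSE
    )
  }

  if (model_policy == "first") {
    xyz <- matrix(p$xyz[1, ], ncol = 3, byrow = TRUE)[ikeep, , drop = FALSE]
    return(.new_structure(build_atoms(at, xyz), model_id = 1L))
  }
  nmod <- nrow(p$xyz)
  lapply(seq_len(nmod), function(m) {
    xyz <- matrix(p$xyz[m, ], ncol = 3, byrow = TRUE)[ikeep, , drop = FALSE]
    .new_structure(build_atoms(at, xyz), model_id = m)
  })
}

#' Write a structure (or list of structures) to a PDB file
#'
#' Coordinates are written in the fixed-width PDB format (3 decimals). A list
#' of structures sharing one atom table is written as a multi-model file.
#'
#' @param structure a `protein_structure` or list of them (same atoms per model)
#' @param path output path
#' @export
write_pdb <- function(structure, path) {
  if (inherits(structure, "protein_structure")) structure <- list(structure)
  a <- structure[[1]]$atoms
  if (nrow(a) == 0) stop("cannot write an empty structure")
  if (any(nchar(trimws(a$name)) > 4)) {
    stop("atom name longer than 4 characters cannot be serialized: ",
         paste(unique(a$name[nchar(trimws(a$name)) > 4]), collapse = ", "))
  }
  xyz <- do.call(rbind, lapply(structure, function(s) {
    stopifnot(all(is.finite(c(s$atoms$x, s$atoms$y, s$atoms$z))))
    as.vector(t(as.matrix(s$atoms[, c("x", "y", "z")])))
  }))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = ifelse(a$is_hetero, "HETATM", "ATOM"),
    resno = a$resseq, resid = a$resname, eleno = a$serial, elety = a$name,
    chain = ifelse(a$chain == "", " ", a$chain),
    insert = ifelse(a$icode == "", "", a$icode),
    o = a$occ, b = a$b, elesy = a$element
  )
  invisible(path)
}

#' Select atoms from a structure
#'
#' Returns integer atom indices (in the structure's stable atom order).
#' Multiple filters compose by intersection.
#'
#' @param structure a `protein_structure`
#' @param preset "all", "backbone" (N, CA, C, O), "calpha", or "heavy"
#'   (non-hydrogen)
#' @param chain optional chain id(s)
#' @param resseq optional residue number(s)
#' @param names optional atom-name set
#' @param hetero "exclude" (default), "include", or "only"
#' @return integer vector of atom indices
#' @export
atom_select <- function(structure, preset = c("all", "backbone", "calpha", "heavy"),
                        chain = NULL, resseq = NULL, names = NULL,
                        hetero = c("exclude", "include", "only")) {
  preset <- match.arg(preset)
  hetero <- match.arg(hetero)
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  keep <- keep & switch(preset,
    all = TRUE,
    backbone = trimws(a$name) %in% c("N", "CA", "C", "O"),
    calpha = trimws(a$name) == "CA",
    heavy = a$element != "H")
  if (preset %in% c("backbone", "calpha")) keep <- keep & !a$is_hetero
  keep <- keep & switch(hetero,
    exclude = !a$is_hetero, include = TRUE, only = a$is_hetero)
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resseq)) keep <- keep & a$resseq %in% resseq
  if (!is.null(names)) keep <- keep & trimws(a$name) %in% names
  which(keep)
}

#' Coordinates of (a subset of) a structure
#' @param structure a `protein_structure`
#' @param idx optional atom indices (default: all atoms)
#' @return N x 3 numeric matrix (angstrom)
#' @export
coords <- function(structure, idx = NULL) {
  m <- as.matrix(structure$atoms[, c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' Residue keys of a structure's atoms
#' @param structure a `protein_structure`
#' @return character vector, one key per atom
#' @export
atom_res_keys <- function(structure) {
  res_key(structure$atoms$chain, structure$atoms$resseq, structure$atoms$icode)
}

#' Residues within a radius of a site
#'
#' A residue is a neighbor iff the minimum pairwise distance between its
#' scoped atoms and the site residue's scoped atoms is at most `radius`.
#' The site residue itself is excluded from the returned set.
#'
#' @param structure a `protein_structure`
#' @param site residue key string ("chain:resseq:icode" or "chain:resseq")
#' @param radius neighborhood radius (angstrom), > 0
#' @param atom_scope "heavy" (default) or "calpha"
#' @return character vector of neighbor residue keys
#' @export
residues_within <- function(structure, site, radius, atom_scope = c("heavy", "calpha")) {
  atom_scope <- match.arg(atom_scope)
  stopifnot(radius > 0)
  if (grepl("^[^:]+:[^:]+$", site)) site <- paste0(site, ":")
  keys <- atom_res_keys(structure)
  scope_idx <- atom_select(structure, preset = atom_scope, hetero = "include")
  site_idx <- intersect(which(keys == site), scope_idx)
  if (length(site_idx) == 0) stop("site residue not found in structure: ", site)
  other_idx <- setdiff(scope_idx, which(keys == site))
  if (length(other_idx) == 0) return(character(0))
  sx <- coords(structure, site_idx)
  ox <- coords(structure, other_idx)
  # min distance from each non-site atom to the site residue's atoms
  d2 <- outer(rowSums(ox^2), rowSums(sx^2), "+") - 2 * ox %*% t(sx)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  sort(unique(keys[other_idx][mind <= radius]))
}

#' Extract a residue-level table of a structure
#' @param structure a `protein_structure`
#' @return data.frame with key, chain, resseq, icode, resname, is_hetero
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  key <- res_key(a$chain, a$resseq, a$icode)
  first <- !duplicated(key)
  data.frame(key = key[first], chain = a$chain[first], resseq = a$resseq[first],
             icode = a$icode[first], resname = a$resname[first],
             is_hetero = a$is_hetero[first], stringsAsFactors = FALSE)
}
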