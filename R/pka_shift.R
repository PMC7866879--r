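# Aggregation of per-residue pKa tables (computed externally, e.g. by a
# Poisson-Boltzmann solver, or synthetically) into directional shift sums,
# weak-spot detection and the variants-by-residues heatmap matrix.

.titratable <- c("ASP", "GLU", "HIS", "LYS", "ARG", "CYS", "TYR")

#' Construct a pKa table
#'
#' @param residues data.frame with chain, resseq, resname, pka columns
#'   (icode optional); resnames restricted to the titratable set
#'   (ASP, GLU, HIS, LYS, ARG, CYS, TYR)
#' @param provenance free-text label of the source calculator
#' @param ph pH at which the values were computed (default 7.0)
#' @return an object of class `pka_table`
#' @export
pka_table <- function(residues, provenance = "external", ph = 7.0) {
  stopifnot(all(c("chain", "resseq", "resname", "pka") %in% names(residues)))
  if (!"icode" %in% names(residues)) residues$icode <- ""
  bad <- !residues$resname %in% .titratable
  if (any(bad)) stop("non-titratable residue type(s): ",
                     paste(unique(residues$resname[bad]), collapse = ", "))
  if (!all(is.finite(residues$pka))) stop("non-finite pKa value(s)")
  residues$key <- paste(res_key(residues$chain, residues$resseq, residues$icode),
                        residues$resname, sep = ":")
  if (anyDuplicated(residues$key)) stop("duplicated titratable residue keys")
  rownames(residues) <- NULL
  structure(list(residues = residues, provenance = provenance, ph = ph),
            class = "pka_table")
}

#' Read a pKa table from delimited text (chain, resseq, resname, pka)
#' @param path TSV path
#' @param ... passed to [pka_table()]
#' @return a `pka_table`
#' @export
read_pka_table <- function(path, ...) {
  pka_table(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE), ...)
}

#' Write a pKa table as delimited text
#' @param table a `pka_table`
#' @param path TSV path
#' @export
write_pka_table <- function(table, path) {
  write.table(table$residues[, c("chain", "resseq", "resname", "pka")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-residue pKa shift profile of a variant vs wild type
#'
#' Computes Delta = pKa(variant) - pKa(wild type) for every titratable
#' residue present in both tables (position and residue type must match, so
#' a titratable residue lost or gained by the substitution is automatically
#' excluded), always excluding the mutation site itself, and sums the
#' shifts in both directions: `positive_sum` (sum of positive Delta),
#' `negative_sum` (sum of negative Delta) and the headline score
#' `total_abs = positive_sum + |negative_sum|`.
#'
#' @param wt,variant `pka_table` objects
#' @param mutation_site residue key "chain:resseq" or "chain:resseq:icode"
#'   of the substituted residue
#' @return a `shift_profile`: `delta` (named by "chain:resseq:icode:resname"),
#'   `excluded_sites`, `positive_sum`, `negative_sum`, `total_abs`
#' @export
shift_profile <- function(wt, variant, mutation_site = NULL) {
  w <- wt$residues; v <- variant$residues
  site_of <- function(k) sub("^([^:]*:[^:]*:[^:]*):.*$", "\\1", k)
  excl <- union(setdiff(w$key, v$key), setdiff(v$key, w$key))
  shared <- intersect(w$key, v$key)
  if (!is.null(mutation_site)) {
    if (grepl("^[^:]+:[^:]+$", mutation_site)) {
      mutation_site <- paste0(mutation_site, ":")
    }
    at_site <- shared[site_of(shared) == mutation_site]
    excl <- union(excl, union(at_site,
                              unique(c(w$key, v$key))[site_of(unique(c(w$key, v$key))) == mutation_site]))
    shared <- setdiff(shared, at_site)
  }
  if (length(shared) == 0) stop("no shared titratable residues after exclusions")
  delta <- setNames(v$pka[match(shared, v$key)] - w$pka[match(shared, w$key)],
                    shared)
  pos <- sum(delta[delta > 0]); neg <- sum(delta[delta < 0])
  structure(list(delta = delta, excluded_sites = sort(unique(excl)),
                 positive_sum = pos, negative_sum = neg,
                 total_abs = pos + abs(neg)),
            class = "shift_profile")
}

#' @export
print.shift_profile <- function(x, ...) {
  cat("shift_profile:", length(x$delta), "residues; +",
      round(x$positive_sum, 3), "/", round(x$negative_sum, 3),
      "; total_abs", round(x$total_abs, 3), "pH units\n")
  invisible(x)
}

#' Detect weak-spot residues across variant shift profiles
#'
#' Residues whose |Delta| reaches `threshold` in at least `min_variants`
#' profiles, sorted by hit count then by maximum |Delta|.
#'
#' @param profiles named list of `shift_profile` (one per variant)
#' @param threshold pH-unit magnitude threshold
#' @param min_variants minimum number of profiles hitting the threshold
#' @return data.frame with key, n_hits, max_abs_delta
#' @export
weak_spots <- function(profiles, threshold, min_variants = 1) {
  stopifnot(length(profiles) >= 1)
  keys <- unique(unlist(lapply(profiles, function(p) names(p$delta))))
  hits <- sapply(keys, function(k) {
    d <- vapply(profiles, function(p) {
      if (k %in% names(p$delta)) abs(p$delta[[k]]) else NA_real_
    }, 0)
    c(n = sum(!is.na(d) & d >= threshold & d > 0),
      mx = if (all(is.na(d))) 0 else max(d, na.rm = TRUE))
  })
  out <- data.frame(key = keys, n_hits = as.integer(hits["n", ]),
                    max_abs_delta = as.numeric(hits["mx", ]),
                    stringsAsFactors = FALSE)
  out <- out[out$n_hits >= min_variants, ]
  out <- out[order(-out$n_hits, -out$max_abs_delta), ]
  rownames(out) <- NULL
  out
}

#' Variants-by-residues heatmap matrix of pKa shifts
#'
#' Rows are variants, columns the union of titratable residues across the
#' profiles ordered by residue number descending (top of the rendered
#' heatmap); entries excluded from a profile are NA (missing), distinguished
#' from a true zero shift.
#'
#' @param profiles named list of `shift_profile`
#' @return numeric matrix (variants x residues) with NA for missing entries
#' @export
heatmap_matrix <- function(profiles) {
  keys <- unique(unlist(lapply(profiles, function(p) names(p$delta))))
  resseq <- as.integer(sub("^[^:]*:([^:]*):.*$", "\\1", keys))
  keys <- keys[order(resseq, decreasing = TRUE)]
  m <- t(vapply(profiles, function(p) {
    out <- rep(NA_real_, length(keys))
    i <- match(names(p$delta), keys)
    out[i] <- p$delta
    out
  }, numeric(length(keys))))
  dimnames(m) <- list(names(profiles), keys)
  m
}
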