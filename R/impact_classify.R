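# Control-calibrated benign/VUS/damaging classification.
#
# Per metric, values are mapped to a "badness" via the metric's orientation,
# the benign controls' maximum badness (b_max) sets the thresholds, and a
# variant is benign up to b_max, VUS up to 2 b_max, damaging above.  Layers
# take the worst severity of their metrics; the overall call is damaging if
# any layer is damaging, benign only if every layer is benign, otherwise VUS.

.severity <- c(benign = 1L, VUS = 2L, damaging = 3L)
.layers_known <- c("sequence", "structure", "pka", "dynamics",
                   "substrate_zn", "active_site")

#' Construct a variant-by-metric score table
#'
#' @param values numeric matrix or data.frame, variants in rows, metrics in
#'   columns (NA = missing value); external columns (e.g. a folding
#'   delta-delta-G or sequence-predictor score) sit alongside internally
#'   computed metrics
#' @param metric_registry data.frame with metric, layer, orientation
#'   ("higher_is_worse" or "magnitude_is_worse") and optional units
#' @param control_registry named character vector mapping variant name to
#'   role: "benign_control", "damaging_control" or "query"
#' @return an object of class `score_table`
#' @export
score_table <- function(values, metric_registry, control_registry) {
  values <- as.matrix(values)
  stopifnot(!is.null(rownames(values)), !is.null(colnames(values)))
  stopifnot(all(c("metric", "layer", "orientation") %in% names(metric_registry)))
  if (!"units" %in% names(metric_registry)) {
    metric_registry$units <- rep("", nrow(metric_registry))
  }
  if (anyDuplicated(metric_registry$metric)) {
    stop("a metric is assigned to more than one registry row")
  }
  missing_reg <- setdiff(colnames(values), metric_registry$metric)
  if (length(missing_reg) > 0) {
    stop("metric(s) absent from the registry: ",
         paste(missing_reg, collapse = ", "))
  }
  bad_or <- !metric_registry$orientation %in% c("higher_is_worse", "magnitude_is_worse")
  if (any(bad_or)) stop("unknown orientation: ",
                        paste(metric_registry$orientation[bad_or], collapse = ", "))
  missing_role <- setdiff(rownames(values), names(control_registry))
  if (length(missing_role) > 0) {
    stop("variant(s) absent from the control registry: ",
         paste(missing_role, collapse = ", "))
  }
  if (!any(control_registry == "benign_control")) {
    stop("at least one benign control is required for calibration")
  }
  structure(list(values = values, metrics = metric_registry,
                 roles = control_registry[rownames(values)]),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("score_table:", nrow(x$values), "variants x", ncol(x$values), "metrics;",
      sum(x$roles == "benign_control"), "benign /",
      sum(x$roles == "damaging_control"), "damaging controls\n")
  invisible(x)
}

# orientation -> badness; stabilizing (negative) higher_is_worse values are
# not bad at all
.badness <- function(value, orientation) {
  switch(orientation,
         higher_is_worse = pmax(value, 0),
         magnitude_is_worse = abs(value))
}

#' Calibrate per-metric thresholds from the benign controls
#'
#' For each metric, b_max is the maximum badness over the benign controls;
#' the VUS bound is twice that. A degenerate calibration (b_max below
#' `eps_abs`) is replaced by the configured absolute `floor` and logged in
#' the returned table.
#'
#' @param st a `score_table`
#' @param eps_abs degeneracy threshold in the metric's units (default 1e-6)
#' @param floor replacement b_max for degenerate metrics (default `eps_abs`)
#' @return data.frame with metric, layer, b_max, vus_max, floored
#' @export
calibrate <- function(st, eps_abs = 1e-6, floor = eps_abs) {
  ben <- st$values[st$roles == "benign_control", , drop = FALSE]
  rows <- lapply(seq_len(ncol(st$values)), function(j) {
    metric <- colnames(st$values)[j]
    reg <- st$metrics[st$metrics$metric == metric, ]
    v <- ben[, j]
    v <- v[!is.na(v)]
    if (length(v) == 0) stop("no benign-control values for metric '", metric, "'")
    b <- max(.badness(v, reg$orientation))
    floored <- b < eps_abs
    if (floored) b <- floor
    data.frame(metric = metric, layer = reg$layer, b_max = b, vus_max = 2 * b,
               floored = floored, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Label a single metric value against calibrated thresholds
#'
#' Badness at or below b_max is "benign", at or below twice b_max is "VUS",
#' above that "damaging" (boundaries inclusive downward, so a benign control
#' always labels itself benign); a missing value labels "missing".
#'
#' @param value numeric value (NA allowed)
#' @param thresholds one row of the [calibrate()] table
#' @param orientation the metric's orientation
#' @return one of "benign", "VUS", "damaging", "missing"
#' @export
label_metric <- function(value, thresholds, orientation = "higher_is_worse") {
  if (is.na(value)) return("missing")
  b <- .badness(value, orientation)
  if (b <= thresholds$b_max) "benign"
  else if (b <= thresholds$vus_max) "VUS"
  else "damaging"
}

#' Collective label of a layer from its metric labels
#'
#' Default mode takes the maximum severity across the layer's non-missing
#' metric labels (benign < VUS < damaging); "majority" mode takes the modal
#' label (ties resolved toward the worse label). All-missing layers label
#' "missing" and are excluded from the overall call.
#'
#' @param labels character vector of metric labels
#' @param mode "worst" (default) or "majority"
#' @return one of "benign", "VUS", "damaging", "missing"
#' @export
label_layer <- function(labels, mode = c("worst", "majority")) {
  mode <- match.arg(mode)
  labels <- labels[labels != "missing"]
  if (length(labels) == 0) return("missing")
  sev <- .severity[labels]
  if (mode == "worst") return(names(.severity)[max(sev)])
  tab <- table(factor(labels, levels = names(.severity)))
  names(.severity)[max(which(tab == max(tab)))]
}

#' Overall impact call from per-layer labels
#'
#' Damaging if any layer is damaging; benign only if all (non-missing)
#' layers are benign; otherwise VUS.
#'
#' @param layer_labels character vector of layer labels
#' @return one of "benign", "VUS", "damaging"
#' @export
overall_call <- function(layer_labels) {
  layer_labels <- layer_labels[layer_labels != "missing"]
  if (length(layer_labels) == 0) stop("no layer labels available")
  if (any(layer_labels == "damaging")) "damaging"
  else if (all(layer_labels == "benign")) "benign"
  else "VUS"
}

#' Build the full impact ledger from a score table
#'
#' Calibrates every metric on the benign controls, labels each metric and
#' layer per variant, merges optional externally supplied per-layer labels
#' (e.g. the sequence layer from sequence-based predictors), and derives the
#' overall benign/VUS/damaging call.
#'
#' @param st a `score_table`
#' @param external_layer_labels optional data.frame (rownames = variants,
#'   columns = layers) of labels that override or extend the computed layers
#' @param mode layer aggregation mode, see [label_layer()]
#' @param eps_abs,floor calibration degeneracy handling, see [calibrate()]
#' @return an `impact_ledger`: `layers` (variant x layer label matrix),
#'   `overall` (named vector), `metric_labels`, `calibration`, `roles`
#' @export
build_ledger <- function(st, external_layer_labels = NULL, mode = "worst",
                         eps_abs = 1e-6, floor = eps_abs) {
  cal <- calibrate(st, eps_abs = eps_abs, floor = floor)
  variants <- rownames(st$values)
  metric_labels <- matrix("missing", nrow = length(variants), ncol = ncol(st$values),
                          dimnames = list(variants, colnames(st$values)))
  for (j in seq_len(ncol(st$values))) {
    reg <- st$metrics[st$metrics$metric == colnames(st$values)[j], ]
    th <- cal[cal$metric == colnames(st$values)[j], ]
    metric_labels[, j] <- vapply(st$values[, j], label_metric, "",
                                 thresholds = th, orientation = reg$orientation)
  }
  layer_of <- setNames(st$metrics$layer, st$metrics$metric)
  layers_here <- unique(layer_of[colnames(st$values)])
  layer_labels <- matrix("missing", nrow = length(variants),
                         ncol = length(layers_here),
                         dimnames = list(variants, layers_here))
  for (ly in layers_here) {
    cols <- colnames(st$values)[layer_of[colnames(st$values)] == ly]
    layer_labels[, ly] <- apply(metric_labels[, cols, drop = FALSE], 1,
                                label_layer, mode = mode)
  }
  if (!is.null(external_layer_labels)) {
    ext <- as.matrix(external_layer_labels)
    add <- setdiff(colnames(ext), colnames(layer_labels))
    if (length(add) > 0) {
      layer_labels <- cbind(layer_labels,
                            matrix("missing", nrow = length(variants), ncol = length(add),
                                   dimnames = list(variants, add)))
    }
    for (ly in colnames(ext)) {
      v <- intersect(rownames(ext), variants)
      layer_labels[v, ly] <- ext[v, ly]
    }
  }
  overall <- apply(layer_labels, 1, overall_call)
  structure(list(layers = layer_labels, overall = overall,
                 metric_labels = metric_labels, calibration = cal,
                 roles = st$roles),
            class = "impact_ledger")
}

#' @export
print.impact_ledger <- function(x, ...) {
  df <- as.data.frame(x)
  print(df, right = FALSE)
  invisible(x)
}

#' @export
as.data.frame.impact_ledger <- function(x, ...) {
  data.frame(variant = rownames(x$layers), x$layers,
             overall = x$overall, role = as.character(x$roles),
             row.names = NULL, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write an impact ledger as delimited text
#' @param ledger an `impact_ledger`
#' @param path TSV path
#' @export
write_ledger <- function(ledger, path) {
  write.table(as.data.frame(ledger), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
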