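# Trajectory ensembles, discretization into a shared emission alphabet, and
# delimited-text I/O.
#
# A trajectory ensemble is the set of single-cell response trajectories measured
# under one stimulus condition: one real-valued matrix with one row per cell and
# one column per timepoint. All per-condition models must share one emission
# alphabet, so a single discretization scheme is fitted on the data pooled
# across every condition and then applied to each ensemble.

#' Construct a trajectory ensemble
#'
#' Bundles the continuous cells-by-timepoints signal matrix measured under one
#' stimulus condition with its label and sampling interval.
#'
#' @param values Numeric matrix; rows are cells, columns are timepoints. All
#'   entries must be finite; at least 1 row and 2 columns.
#' @param condition_label Single string naming the stimulus condition.
#' @param time_step Positive number, minutes between consecutive columns.
#' @return An object of class `"trajectory_ensemble"`.
#' @export
trajectory_ensemble <- function(values, condition_label, time_step = 1) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.character(condition_label) || length(condition_label) != 1L || is.na(condition_label))
    dynmi_stop("dynmi_bad_label", "condition_label must be a single string")
  if (nrow(values) < 1L || ncol(values) < 2L)
    dynmi_stop("dynmi_bad_shape", "ensemble needs >= 1 cell and >= 2 timepoints")
  if (!all(is.finite(values)))
    dynmi_stop("dynmi_non_numeric", "all trajectory values must be finite numbers")
  if (!is.numeric(time_step) || length(time_step) != 1L || !is.finite(time_step) || time_step <= 0)
    dynmi_stop("dynmi_bad_time_step", "time_step must be a positive number")
  structure(list(condition_label = condition_label,
                 values = values,
                 time_step = as.numeric(time_step)),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble '%s': %d cells x %d timepoints (dt = %g min)\n",
              x$condition_label, nrow(x$values), ncol(x$values), x$time_step))
  invisible(x)
}

#' Construct a discrete (symbol-valued) ensemble
#'
#' @param states Integer matrix with entries in `1..K_E` (rows cells, columns
#'   timepoints).
#' @param condition_label Single string.
#' @param K_E Size of the emission alphabet.
#' @param scheme_id String identifying the discretization scheme that produced
#'   the symbols; ensembles entering one cross-condition computation must share it.
#' @return An object of class `"discrete_ensemble"`.
#' @export
discrete_ensemble <- function(states, condition_label, K_E, scheme_id) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (!is_count(K_E) || K_E < 2) dynmi_stop("dynmi_bad_alphabet", "K_E must be an integer >= 2")
  if (anyNA(states) || any(states < 1L) || any(states > K_E))
    dynmi_stop("dynmi_bad_state", sprintf("states must be integers in 1..%d", K_E))
  structure(list(condition_label = condition_label,
                 states = states,
                 K_E = as.integer(K_E),
                 scheme_id = scheme_id),
            class = "discrete_ensemble")
}

#' @export
print.discrete_ensemble <- function(x, ...) {
  cat(sprintf("Discrete ensemble '%s': %d cells x %d timepoints, alphabet 1..%d\n",
              x$condition_label, nrow(x$states), ncol(x$states), x$K_E))
  invisible(x)
}

#' Fit a discretization scheme on data pooled across conditions
#'
#' Bins the observed continuous values into `K_E` discrete emission symbols.
#' The scheme is fitted on data pooled over *all* supplied ensembles so that
#' every per-condition model shares one emission alphabet; values outside the
#' fitted range are later clamped into the first/last bin.
#'
#' @param ensembles List of [trajectory_ensemble()] objects.
#' @param K_E Number of emission symbols (>= 2).
#' @param strategy `"quantile"` (default; equal-occupancy bins, which conditions
#'   count matrices well) or `"equal_width"`.
#' @return An object of class `"discretization_scheme"` with strictly increasing
#'   `bin_edges` of length `K_E + 1`.
#' @export
fit_discretization <- function(ensembles, K_E, strategy = c("quantile", "equal_width")) {
  strategy <- match.arg(strategy)
  if (inherits(ensembles, "trajectory_ensemble")) ensembles <- list(ensembles)
  stopifnot(length(ensembles) >= 1L)
  if (!is_count(K_E) || K_E < 2) dynmi_stop("dynmi_bad_alphabet", "K_E must be an integer >= 2")
  pooled <- unlist(lapply(ensembles, function(e) as.vector(e$values)), use.names = FALSE)
  rng <- range(pooled)
  degenerate <- rng[1] == rng[2]
  if (degenerate) {
    warning("pooled data are constant; falling back to equal-width bins on [v - 0.5, v + 0.5]")
    edges <- seq(rng[1] - 0.5, rng[1] + 0.5, length.out = K_E + 1)
    strategy <- "equal_width"
  } else if (strategy == "equal_width") {
    edges <- seq(rng[1], rng[2], length.out = K_E + 1)
  } else {
    if (length(unique(pooled)) < K_E)
      dynmi_stop("dynmi_degenerate_data",
                 sprintf("quantile binning needs >= %d distinct values", K_E))
    edges <- unname(stats::quantile(pooled, probs = seq(0, 1, length.out = K_E + 1), type = 7))
    ## collapse numerically tied interior quantiles, then respread if needed
    if (any(diff(edges) <= 0)) {
      edges <- unique(edges)
      if (length(edges) < K_E + 1)
        edges <- seq(rng[1], rng[2], length.out = K_E + 1)  # heavy ties: equal width
    }
  }
  structure(list(bin_edges = edges,
                 strategy = strategy,
                 K_E = as.integer(K_E),
                 scheme_id = paste0("scheme-", strategy, "-K", K_E, "-",
                                    format(sum(edges) + K_E * 1e-9, digits = 15))),
            class = "discretization_scheme")
}

#' Discretize a trajectory ensemble under a fitted scheme
#'
#' Deterministic, monotone binning: half-open bins `[edge_k, edge_{k+1})` with
#' the final bin closed on the right; values below/above the fitted range clamp
#' to the first/last bin (a model trained on one data split must be able to
#' score the other split).
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param scheme A [fit_discretization()] result.
#' @return A [discrete_ensemble()] with the same shape as `ensemble$values`.
#' @export
discretize <- function(ensemble, scheme) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"),
            inherits(scheme, "discretization_scheme"))
  edges <- scheme$bin_edges
  ## interior edges assign ties upward; findInterval with left.open=FALSE gives
  ## [a, b) bins when we cut on interior edges only
  st <- findInterval(ensemble$values, edges[-c(1L, length(edges))]) + 1L
  st <- matrix(as.integer(st), nrow(ensemble$values), ncol(ensemble$values))
  discrete_ensemble(st, ensemble$condition_label, scheme$K_E, scheme$scheme_id)
}

#' Assemble a condition manifest
#'
#' @param labels Character vector of unique condition labels.
#' @param paths File paths (relative to the manifest location) of the trajectory
#'   matrices, one per label.
#' @param time_step Minutes per timepoint, shared by all conditions.
#' @return An object of class `"condition_manifest"`.
#' @export
condition_manifest <- function(labels, paths, time_step = 1) {
  if (anyDuplicated(labels))
    dynmi_stop("dynmi_duplicate_label",
               sprintf("duplicate condition label(s): %s",
                       paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  stopifnot(length(labels) == length(paths), length(labels) >= 1L)
  structure(list(entries = data.frame(label = as.character(labels),
                                      path = as.character(paths),
                                      stringsAsFactors = FALSE),
                 time_step = as.numeric(time_step),
                 M = length(labels)),
            class = "condition_manifest")
}

#' Write trajectory ensembles and a manifest to a directory
#'
#' Each ensemble is stored as a comma-delimited matrix (header row of timepoint
#' labels, one row per cell); the manifest is a small YAML file mapping
#' condition labels to the matrix files.
#'
#' @param ensembles Non-empty list of [trajectory_ensemble()] objects.
#' @param directory Output directory (created if needed).
#' @param manifest_file Manifest file name inside `directory`.
#' @return The [condition_manifest()], invisibly with attribute `"path"` set to
#'   the manifest file path.
#' @export
write_ensembles <- function(ensembles, directory, manifest_file = "manifest.yaml") {
  if (inherits(ensembles, "trajectory_ensemble")) ensembles <- list(ensembles)
  if (length(ensembles) == 0L)
    dynmi_stop("dynmi_empty_input", "no ensembles to write")
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!ok) dynmi_stop("dynmi_unwritable", sprintf("cannot create directory '%s'", directory))
  labels <- vapply(ensembles, `[[`, character(1), "condition_label")
  paths <- paste0(gsub("[^A-Za-z0-9._-]", "_", labels), ".csv")
  man <- condition_manifest(labels, paths, ensembles[[1L]]$time_step)
  for (i in seq_along(ensembles)) {
    v <- ensembles[[i]]$values
    df <- as.data.frame(v)
    names(df) <- paste0("t", seq_len(ncol(v)))
    utils::write.csv(df, file.path(directory, paths[i]), row.names = FALSE)
  }
  yaml::write_yaml(list(time_step = man$time_step,
                        conditions = Map(function(l, p) list(label = l, path = p),
                                         labels, paths)),
                   file.path(directory, manifest_file))
  attr(man, "path") <- file.path(directory, manifest_file)
  invisible(man)
}

#' Read a condition manifest file
#'
#' @param path Path to a YAML manifest written by [write_ensembles()] (or by
#'   hand: `time_step` plus a `conditions` list of `label`/`path` pairs).
#' @return A [condition_manifest()] with attribute `"dir"` set to the manifest's
#'   directory.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    dynmi_stop("dynmi_missing_file", sprintf("manifest '%s' does not exist", path))
  y <- yaml::read_yaml(path)
  labels <- vapply(y$conditions, `[[`, character(1), "label")
  paths <- vapply(y$conditions, `[[`, character(1), "path")
  man <- condition_manifest(labels, paths, if (is.null(y$time_step)) 1 else y$time_step)
  attr(man, "dir") <- dirname(path)
  man
}

#' Read trajectory ensembles listed in a manifest
#'
#' @param manifest A [condition_manifest()] (with `"dir"` attribute) or the path
#'   to a manifest file.
#' @return List of [trajectory_ensemble()] objects in manifest order.
#' @export
read_ensembles <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "condition_manifest"))
  base <- attr(manifest, "dir")
  if (is.null(base)) base <- "."
  lapply(seq_len(manifest$M), function(i) {
    label <- manifest$entries$label[i]
    f <- file.path(base, manifest$entries$path[i])
    if (!file.exists(f))
      dynmi_stop("dynmi_missing_file",
                 sprintf("condition '%s': file '%s' does not exist", label, f))
    lines <- readLines(f)
    if (length(lines) < 2L)
      dynmi_stop("dynmi_ragged_input", sprintf("condition '%s': no data rows", label))
    sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
    rows <- strsplit(lines[-1L], sep, fixed = TRUE)
    ncols <- length(strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]])
    lens <- lengths(rows)
    if (any(lens != ncols))
      dynmi_stop("dynmi_ragged_input",
                 sprintf("condition '%s': row %d has %d values, expected %d",
                         label, which(lens != ncols)[1L], lens[lens != ncols][1L], ncols))
    vals <- suppressWarnings(vapply(rows, as.numeric, numeric(ncols)))
    if (anyNA(vals))
      dynmi_stop("dynmi_non_numeric",
                 sprintf("condition '%s': non-numeric cell encountered", label))
    trajectory_ensemble(if (ncols == 1L) matrix(vals, ncol = 1L) else t(vals),
                        label, manifest$time_step)
  })
}
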