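EPOCH_META_COLS <- c("trigger", "channel", "participant", "task",
                     "location", "orientation", "intensity")

#' Write / read an epoch set as a CSV table with a JSON sidecar
#'
#' The on-disk form is a wide delimited table (`<prefix>_epochs.csv`): one
#' row per trial x channel, the metadata columns first, then one column per
#' sample (`s1 ... sN`). A JSON sidecar (`<prefix>_epochs.json`) carries the
#' time axis (ms), the metadata column names and a format version. The
#' write-then-read round trip reproduces values exactly (full double
#' precision is written).
#'
#' @param epoch_set An `epoch_set` (see [segment_epochs()]).
#' @param prefix Path prefix for the file pair.
#' @return `write_epochs` returns the prefix invisibly; `read_epochs`
#'   returns the `epoch_set`.
#' @export
write_epochs <- function(epoch_set, prefix) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  meta <- epoch_set$meta
  for (cl in setdiff(EPOCH_META_COLS, names(meta))) meta[[cl]] <- NA
  meta <- meta[EPOCH_META_COLS]
  dat <- data.table::as.data.table(epoch_set$data)
  data.table::setnames(dat, paste0("s", seq_len(ncol(dat))))
  data.table::fwrite(cbind(data.table::as.data.table(meta), dat),
                     paste0(prefix, "_epochs.csv"))
  jsonlite::write_json(
    list(format = "mepmap-epochs-1", time_ms = epoch_set$time_ms,
         meta_columns = EPOCH_META_COLS,
         n_epochs = nrow(epoch_set$data)),
    paste0(prefix, "_epochs.json"), digits = NA, auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(prefix) {
  csv <- paste0(prefix, "_epochs.csv")
  js <- paste0(prefix, "_epochs.json")
  if (!file.exists(csv) || !file.exists(js))
    stopf("missing epoch file pair at prefix '%s'", prefix)
  side <- jsonlite::read_json(js, simplifyVector = TRUE)
  for (key in c("format", "time_ms", "meta_columns"))
    if (is.null(side[[key]])) stopf("sidecar lacks key '%s'", key)
  tab <- data.table::fread(csv, data.table = FALSE)
  miss <- setdiff(side$meta_columns, names(tab))
  if (length(miss))
    stopf("epoch table lacks column '%s'", miss[1])
  scol <- paste0("s", seq_along(side$time_ms))
  miss_s <- setdiff(scol, names(tab))
  if (length(miss_s))
    stopf("epoch table lacks column '%s'", miss_s[1])
  structure(list(data = as.matrix(tab[scol]),
                 time_ms = as.numeric(side$time_ms),
                 meta = tab[intersect(side$meta_columns, names(tab))]),
            class = "epoch_set")
}

#' Write a MEP table to CSV
#'
#' One row per condition cell, full double precision.
#'
#' @param tab A [mep_table()].
#' @param path Output path.
#' @export
write_mep_table <- function(tab, path) {
  data.table::fwrite(as.data.frame(tab), path)
  invisible(path)
}

#' Read a modeled electric-field table
#'
#' Flat table with one row per (location, orientation): columns `location`,
#' `orientation`, `field_vpm` (modeled field magnitude in the M1 region of
#' interest, V/m) and `mep` (paired mean MEP amplitude). Field values are
#' consumed as input; their computation is out of scope.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_field_table <- function(path) {
  tab <- data.table::fread(path, data.table = FALSE)
  req <- c("location", "orientation", "field_vpm", "mep")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stopf("field table lacks column '%s'", miss[1])
  if (any(tab$field_vpm < 0)) stopf("field magnitudes must be >= 0")
  tab
}

#' Write a MEP volume as NIfTI
#'
#' @param volume A [idw_volume()] result on a regular grid.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "mep_volume"))
  sp <- vapply(volume$grid, function(a) {
    if (length(a) > 1) a[2] - a[1] else 1
  }, 1)
  img <- RNifti::asNifti(volume$values, pixdim = sp)
  RNifti::writeNifti(img, path)
  invisible(path)
}

RUN_CONFIG_KEYS <- c("seed", "filter_low_hz", "filter_high_hz",
                     "filter_order", "pre_ms", "post_ms", "post_window_ms",
                     "pre_window_ms", "normalization_scope", "t_crit",
                     "layout_kind", "criterion_uv", "sweep_min_vpm",
                     "sweep_max_vpm", "brain_cutoff_mm", "scalp_cutoff_mm",
                     "generator", "input_dir", "output_dir", "verbose")

#' Pipeline run configuration
#'
#' A validated parameter bundle covering every analysis stage, serialized
#' to YAML. Unknown keys are rejected so that typos cannot silently change
#' an analysis; the on-disk form round-trips losslessly.
#'
#' @param ... Named parameters among the documented keys (filter band,
#'   epoch windows, normalization scope, map threshold, layout kind,
#'   threshold criterion, sweep range, proximity cutoffs, generator
#'   settings, seed, paths, verbosity).
#' @return List of class `run_config` with defaults filled in.
#' @export
run_config <- function(...) {
  user <- list(...)
  bad <- setdiff(names(user), RUN_CONFIG_KEYS)
  if (length(bad)) stopf("unknown run_config key '%s'", bad[1])
  cfg <- list(seed = 1L, filter_low_hz = 25, filter_high_hz = 250,
              filter_order = 2, pre_ms = 200, post_ms = 200,
              post_window_ms = c(10, 50), pre_window_ms = c(-50, -10),
              normalization_scope = "participant_muscle", t_crit = 2.20,
              layout_kind = "grid27", criterion_uv = 50,
              sweep_min_vpm = 0, sweep_max_vpm = 79,
              brain_cutoff_mm = 42, scalp_cutoff_mm = 55,
              generator = list(), input_dir = ".", output_dir = ".",
              verbose = TRUE)
  cfg[names(user)] <- user
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}
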