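# On-disk formats (raw binary + JSON sidecar recordings, TSV events,
# CSV gaze, JSON AOIs, YAML config) and the end-to-end pipeline driver.

FORMAT_VERSION <- "cogload-raw-1"

# channels dropped on load: mastoid and cerebellar electrodes of the
# 64-channel cap are not analysis channels
DROP_CHANNELS <- c("M1", "M2", "CB1", "CB2")

#' Write a recording as raw binary plus JSON sidecar
#'
#' The sample matrix is stored as little-endian float64, channel-major
#' (channel 1 all samples, channel 2 ...), next to a `.json` sidecar with
#' the sampling rate, channel labels, history and format version.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path for the binary (`.bin`); the sidecar gets the
#'   same path with `.json` appended.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$data)), con, size = 8, endian = "little")
  meta <- list(version = FORMAT_VERSION, fs = rec$fs, labels = rec$labels,
               n_channels = nrow(rec$data), n_samples = ncol(rec$data),
               unit = "uV", history = rec$history)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' Restores the recording and attaches montage positions from the packaged
#' 10-10 table. Mastoid (M1, M2) and cerebellar (CB1, CB2) channels are
#' dropped; channels with labels outside the 10-10 table are kept but
#' flagged position-less (excluded from interpolation and asymmetry) with
#' a warning.
#'
#' @param path Path of the `.bin` file.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side))
    stop_cogload("recording %s (or its .json sidecar) not found", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$version, FORMAT_VERSION))
    stop_cogload("unsupported format version '%s'", meta$version %||% "?")
  n <- meta$n_channels * meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  if (length(x) != n)
    stop_cogload("truncated recording: expected %d samples, read %d", n, length(x))
  X <- matrix(x, nrow = meta$n_channels, byrow = TRUE)
  labels <- toupper(meta$labels)
  keep <- !(labels %in% DROP_CHANNELS)
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  unknown <- setdiff(labels, montage_1010()$label)
  if (length(unknown))
    warn_cogload("position-less channel(s) excluded from spatial operations: %s",
                 paste(unknown, collapse = ", "))
  new_recording(X, meta$fs, labels, history = unlist(meta$history))
}

#' Write / read an event schedule as TSV
#'
#' Columns: onset_s, duration_s, kind, label, trial, load.
#' @param schedule An `event_schedule`.
#' @param path File path.
#' @return `path` / an `event_schedule`.
#' @export
write_events_tsv <- function(schedule, path) {
  df <- data.frame(onset_s = schedule$onset, duration_s = schedule$duration,
                   kind = schedule$kind, label = schedule$label,
                   trial = schedule$trial, load = schedule$load)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$label[is.na(df$label)] <- ""
  sched <- data.frame(onset = df$onset_s, duration = df$duration_s,
                      kind = df$kind, label = df$label, trial = df$trial,
                      load = df$load, stringsAsFactors = FALSE)
  class(sched) <- c("event_schedule", "data.frame")
  sched
}

#' Write / read a gaze stream as CSV
#'
#' Columns: t_s, x_px, y_px, valid.
#' @param gaze A `gaze_stream`.
#' @param path File path.
#' @return `path` / a `gaze_stream`.
#' @export
write_gaze_csv <- function(gaze, path) {
  utils::write.csv(data.frame(t_s = gaze$t, x_px = gaze$x, y_px = gaze$y,
                              valid = gaze$valid),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_csv
#' @export
read_gaze_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  gz <- data.frame(t = df$t_s, x = df$x_px, y = df$y_px,
                   valid = as.logical(df$valid))
  class(gz) <- c("gaze_stream", "data.frame")
  gz
}

#' Write / read an AOI set as JSON
#'
#' @param aois An `aoi_set`.
#' @param path File path.
#' @return `path` / an `aoi_set`.
#' @export
write_aois_json <- function(aois, path) {
  jsonlite::write_json(as.data.frame(aois), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_aois_json
#' @export
read_aois_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  df$critical <- as.logical(df$critical)
  class(df) <- c("aoi_set", "data.frame")
  df
}

#' Write / read a sample table as TSV
#'
#' Meta columns subject, trial, task, segment, label, scheme first, then
#' one column per feature.
#' @param table A `sample_table`.
#' @param path File path.
#' @return `path` / a `sample_table`.
#' @export
write_sample_table <- function(table, path) {
  df <- cbind(table$meta[, c("subject", "trial", "task", "segment", "label")],
              scheme = table$scheme, as.data.frame(table$x))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("subject", "trial", "task", "segment", "label", "scheme")
  x <- as.matrix(df[, setdiff(colnames(df), meta_cols), drop = FALSE])
  new_sample_table(x, df[, c("subject", "trial", "task", "segment", "label")],
                   df$scheme[1])
}

# --- pipeline configuration -------------------------------------------------

pipeline_defaults <- function() {
  list(cohort = list(), window = list(length = 1, overlap = 0.8),
       preprocess = list(enabled = FALSE, reject_amp = 200,
                         keep_all_components = FALSE),
       selector = list(method = "pca", cev = 0.95, n_feat = 100,
                       prune_r = 0.95),
       classifier = list(method = "svm_linear", C = 1, k = 5),
       grid = NULL, scheme = "nasa", seed = 1L, log_level = "info")
}

#' Assemble and validate a pipeline configuration
#'
#' Unknown keys (top-level or within a section) are rejected; all defaults
#' are documented in [pipeline_defaults]. Round-trips losslessly through
#' YAML via [read_pipeline_config()] / [write_pipeline_config()].
#'
#' @param ... Named overrides of the default sections (`cohort`, `window`,
#'   `preprocess`, `selector`, `classifier`, `grid`, `scheme`, `seed`,
#'   `log_level`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defs <- pipeline_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(defs))
  if (length(bad))
    stop_cogload("unknown config key(s): %s", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(defs[[nm]]) && is.list(over[[nm]]) && nm != "grid" &&
        nm != "cohort") {
      extra <- setdiff(names(over[[nm]]), names(defs[[nm]]))
      if (length(extra))
        stop_cogload("unknown key(s) in '%s': %s", nm,
                     paste(extra, collapse = ", "))
      defs[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      defs[nm] <- list(over[[nm]])   # keeps explicit NULLs (e.g. grid)
    }
  }
  if (nm_ok <- length(defs$cohort)) {
    ok <- names(defs$cohort) %in% names(formals(cohort_config))
    if (!all(ok))
      stop_cogload("unknown cohort key(s): %s",
                   paste(names(defs$cohort)[!ok], collapse = ", "))
  }
  structure(defs, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config, seed) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(config = unclass(config), seed = seed), f)
  unname(tools::md5sum(f))
}

# --- pipeline driver --------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Executes simulate, (optional) preprocess, extract + baseline-normalize,
#' assemble, train (LOSO) and fuse, writing per-stage artifacts and a
#' summary report into `out`. Stages whose cached artifact carries the
#' current configuration hash are skipped on re-runs, making unchanged
#' re-runs idempotent. All randomness derives from the single seed.
#'
#' @param config A [pipeline_config()].
#' @param out Output directory (created if missing).
#' @return The report list (also written to `out/report.json`), with
#'   elements `feature_counts`, `rows`, `model` (accuracy etc.), `fusion`
#'   and `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), out) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config, config$seed)
  stage <- function(name, fn) {
    f <- file.path(out, paste0(name, ".rds"))
    if (file.exists(f)) {
      obj <- readRDS(f)
      if (identical(attr(obj, "config_hash"), hash)) {
        message(sprintf("[%s] cached, skipping", name))
        return(obj)
      }
    }
    message(sprintf("[%s] running", name))
    t0 <- proc.time()[3]
    obj <- fn()
    attr(obj, "config_hash") <- hash
    saveRDS(obj, f)
    message(sprintf("[%s] done in %.1f s", name, proc.time()[3] - t0))
    obj
  }
  cfg_cohort <- do.call(cohort_config,
                        c(config$cohort, list(seed = config$seed)))
  wspec <- window_spec(config$window$length, config$window$overlap)
  cohort <- stage("simulate", function() simulate_cohort(cfg_cohort))
  feats <- stage("features", function() {
    lapply(cohort, function(sub) {
      rec <- sub$recording
      if (isTRUE(config$preprocess$enabled)) {
        rec <- apply_filters(rec)
        bad <- detect_bad_channels(rec)
        if (length(bad)) rec <- interpolate_channels(rec, bad)
        rec <- rereference_average(rec)
        rec <- reject_gross_segments(rec, config$preprocess$reject_amp)
        ica <- fit_ica(rec, seed = derive_seed(config$seed, sub$subject, 9))
        if (!isTRUE(config$preprocess$keep_all_components)) {
          idx <- flag_artifact_components(ica, rec)
          if (length(idx) && length(idx) < ica$n_components)
            rec <- remove_components(rec, ica, idx)
        }
      }
      fm <- extract_all(rec, wspec, sub$schedule)
      list(subject = sub$subject,
           fm = baseline_normalize(fm, sub$schedule),
           tlx = sub$tlx)
    })
  })
  tables <- stage("assemble", function() {
    binary <- assemble_binary(feats)
    multi <- assemble_multiclass(feats)
    labeled <- if (identical(config$scheme, "nasa")) {
      tlx <- do.call(rbind, lapply(feats, `[[`, "tlx"))
      relabel_nasa(multi, tlx)
    } else multi
    list(binary = binary, multiclass = multi, labeled = labeled)
  })
  model <- stage("train", function() {
    sel <- do.call(selector_spec, config$selector[
      intersect(names(config$selector), names(formals(selector_spec)))])
    cls <- do.call(classifier_spec, config$classifier[
      intersect(names(config$classifier), names(formals(classifier_spec)))])
    loso_cv(tables$labeled, sel, cls, grid = config$grid)
  })
  fusion <- stage("fuse", function() {
    lapply(cohort[seq_len(min(3, length(cohort)))], function(sub) {
      tc <- feature_timecourse(sub$recording, wspec, sub$schedule)
      tryCatch(critical_region_test(tc, sub$gaze, sub$aois),
               error = function(e) data.frame(error = conditionMessage(e)))
    })
  })
  report <- list(
    version = FORMAT_VERSION, config_hash = hash, seed = config$seed,
    feature_counts = list(
      per_window = ncol(feats[[1]]$fm$values),
      second_order = ncol(tables$binary$x)),
    rows = list(binary = nrow(tables$binary$x),
                multiclass = nrow(tables$multiclass$x)),
    model = list(accuracy = model$accuracy, accuracy_sd = model$accuracy_sd,
                 selector = config$selector$method,
                 classifier = config$classifier$method),
    fusion = lapply(fusion, function(f)
      if (!is.null(f$p_value)) as.list(stats::setNames(f$p_value, f$target))
      else f))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
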