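#' @importFrom utils read.csv write.csv
#' @importFrom jsonlite write_json read_json
NULL

#' Write an LFP recording to disk
#'
#' Two formats: delimited text (`.csv` with `time_s,voltage_uv`
#' columns) and raw little-endian float32 binary (`.bin`) with a JSON
#' sidecar (`<path>.json`) holding `sampling_rate_hz`, `units`,
#' `start_time_s` and `n_samples`. Binary is preferred for long traces.
#'
#' @param rec An [lfp_recording()].
#' @param path Output path; format inferred from the extension unless
#'   given.
#' @param format `"csv"` or `"bin"` (default: from extension).
#' @return `path`, invisibly.
#' @export
write_lfp <- function(rec, path, format = c("auto", "csv", "bin")) {
  stopifnot(inherits(rec, "lfp_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "bin"
  }
  if (format == "csv") {
    utils::write.csv(
      data.frame(time_s = lfp_times(rec), voltage_uv = rec$samples),
      path, row.names = FALSE
    )
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(rec$samples, con, size = 4, endian = "little")
    jsonlite::write_json(
      list(sampling_rate_hz = rec$sampling_rate_hz, units = "uV",
           start_time_s = rec$start_time_s, n_samples = length(rec$samples)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read an LFP recording from disk
#'
#' Counterpart of [write_lfp()]. Text input must be uniformly sampled:
#' timestamp jitter beyond 1 ppm of the median sampling interval is
#' rejected with the offending line reported. Binary input requires the
#' JSON sidecar written by [write_lfp()].
#'
#' @param path Input path.
#' @param format `"csv"` or `"bin"` (default: from extension).
#' @return An [lfp_recording()].
#' @export
read_lfp <- function(path, format = c("auto", "csv", "bin")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "bin"
  }
  if (format == "csv") {
    df <- utils::read.csv(path)
    if (!all(c("time_s", "voltage_uv") %in% names(df))) {
      stop(sprintf("%s: expected columns time_s,voltage_uv", path),
           call. = FALSE)
    }
    if (any(!is.finite(df$voltage_uv))) {
      stop(sprintf("%s: non-finite samples at line(s) %s", path,
                   paste(utils::head(which(!is.finite(df$voltage_uv)) + 1L, 5),
                         collapse = ", ")), call. = FALSE)
    }
    if (nrow(df) >= 3) {
      dt <- diff(df$time_s)
      dt0 <- stats::median(dt)
      bad <- which(abs(dt - dt0) > 1e-6 * dt0 + 1e-12)
      if (length(bad)) {
        stop(sprintf(
          "%s: irregular sampling (jitter > 1 ppm) first at line %d", path,
          bad[1] + 2L
        ), call. = FALSE)
      }
      fs <- 1 / dt0
    } else if (nrow(df) == 2) {
      fs <- 1 / diff(df$time_s)
    } else {
      stop(sprintf("%s: need at least 2 rows to infer sampling rate", path),
           call. = FALSE)
    }
    lfp_recording(df$voltage_uv, fs, start_time_s = df$time_s[1])
  } else {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop(sprintf("%s: missing JSON sidecar %s", path, sidecar),
           call. = FALSE)
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (f in c("sampling_rate_hz", "n_samples")) {
      if (is.null(meta[[f]])) {
        stop(sprintf("%s: sidecar missing field %s", sidecar, f),
             call. = FALSE)
      }
    }
    con <- file(path, "rb")
    on.exit(close(con))
    x <- readBin(con, numeric(), n = meta$n_samples, size = 4,
                 endian = "little")
    if (length(x) != meta$n_samples) {
      stop(sprintf("%s: expected %d samples, read %d (truncated at byte %d)",
                   path, meta$n_samples, length(x), length(x) * 4L),
           call. = FALSE)
    }
    if (any(!is.finite(x))) {
      stop(sprintf("%s: non-finite samples present", path), call. = FALSE)
    }
    lfp_recording(x, meta$sampling_rate_hz,
                  start_time_s = meta$start_time_s %||% 0)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a ripple event table as CSV
#'
#' Columns: `id,center_s,onset_s,offset_s,duration_ms,peak_freq_hz,`
#' `amplitude_uv,mean_rms_sd,accepted,reject_reason`.
#'
#' @param events Event data frame from [detect_swrs()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_swr_events <- function(events, path) {
  cols <- c("id", "center_s", "onset_s", "offset_s", "duration_ms",
            "peak_freq_hz", "amplitude_uv", "mean_rms_sd", "accepted",
            "reject_reason")
  utils::write.csv(events[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a ripple event table CSV
#' @param path CSV written by [write_swr_events()].
#' @return Event data frame.
#' @export
read_swr_events <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a biomarker cohort CSV
#'
#' Cohort tables have `subject_id`, `group`, one column per analyte and
#' score, `hippocampal_volume` and `temporal_horn_volume`; missing
#' cells are blank.
#'
#' @param cohort Cohort data frame.
#' @param path CSV path.
#' @return `path` (writer) or the cohort data frame (reader).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!all(c("subject_id", "group") %in% names(df))) {
    stop(sprintf("%s: expected subject_id and group columns", path),
         call. = FALSE)
  }
  if (any(is.na(df$group))) {
    stop(sprintf("%s: missing group labels", path), call. = FALSE)
  }
  df
}

#' Write a run manifest
#'
#' Records package version, seed, a hash of the configuration, input
#' file checksums, timestamps and per-stage event counts, so a seeded
#' run can be reproduced and audited.
#'
#' @param path Output JSON path.
#' @param config A configuration object (list) to hash and embed.
#' @param seed The seed used.
#' @param inputs Character vector of input file paths (checksummed if
#'   they exist).
#' @param counts Named list of per-stage event counts.
#' @param started POSIXct start time (default now).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config = list(), seed = NA,
                               inputs = character(0), counts = list(),
                               started = Sys.time()) {
  tmp <- tempfile()
  saveRDS(unclass(config), tmp, version = 2)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  checksums <- if (length(inputs)) {
    ex <- file.exists(inputs)
    stats::setNames(as.list(ifelse(ex, tools::md5sum(inputs), NA)), inputs)
  } else NULL
  jsonlite::write_json(
    list(
      tool = "lfpmark",
      version = as.character(utils::packageVersion("lfpmark")),
      config_hash = cfg_hash,
      seed = seed,
      input_checksums = checksums,
      started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      counts = counts
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
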