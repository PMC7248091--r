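# Stack and table I/O plus the end-to-end pipeline entry point.
#
# Stack dialects:
#   tiff    - multi-page 16-bit TIFF (counts rounded and clipped to
#             [0, 65535]);
#   png_seq - numbered 8-bit PNG sequence (preview dialect; lossy for
#             counts above 255);
#   raw     - float64 little-endian binary, bit-identical round trip.
# Every dialect writes a YAML sidecar `<path>.yaml` carrying frame_rate,
# duration, mod_freq and geometry; read_stack() refuses a stack whose
# sidecar is missing unless the metadata are supplied explicitly.

sidecar_path <- function(path) paste0(path, ".yaml")

write_sidecar <- function(path, stack, dialect, scale) {
  d <- dim(stack$frames[[1]])
  yaml::write_yaml(list(format = "ptashb-stack", format_version = 1L,
                        dialect = dialect, image_height = d[1],
                        image_width = d[2], n_frames = length(stack$frames),
                        frame_rate = stack$frame_rate, duration = stack$duration,
                        mod_freq = stack$mod_freq, scale = scale),
                   sidecar_path(path))
}

#' Write a frame stack to disk
#'
#' @param stack A [frame_stack()].
#' @param path Output path. For `png_seq` this is a prefix: frames are
#'   written as `<path>_0001.png`, ... The YAML metadata sidecar is
#'   written next to it as `<path>.yaml`.
#' @param dialect `"tiff"` (multi-page, 16-bit), `"png_seq"` (8-bit) or
#'   `"raw"` (float64; exact round trip).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, dialect = c("tiff", "png_seq", "raw")) {
  stopifnot(inherits(stack, "frame_stack"))
  dialect <- match.arg(dialect)
  if (dialect == "tiff") {
    mx <- max(vapply(stack$frames, max, numeric(1)))
    if (mx > 65535) warn("counts above 65535 are clipped in the 16-bit TIFF dialect")
    pages <- lapply(stack$frames, function(f) {
      pmin(pmax(round(f), 0), 65535) / 65535
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
    write_sidecar(path, stack, dialect, scale = 65535)
  } else if (dialect == "png_seq") {
    mx <- max(vapply(stack$frames, max, numeric(1)))
    if (mx > 255) warn("counts above 255 are clipped in the 8-bit PNG dialect")
    for (i in seq_along(stack$frames)) {
      png::writePNG(pmin(pmax(round(stack$frames[[i]]), 0), 255) / 255,
                    sprintf("%s_%04d.png", path, i))
    }
    write_sidecar(path, stack, dialect, scale = 255)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    for (f in stack$frames) {
      writeBin(as.numeric(t(f)), con, size = 8, endian = "little")
    }
    write_sidecar(path, stack, dialect, scale = 1)
  }
  invisible(path)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  meta <- yaml::read_yaml(sp)
  if (is.null(meta$format) || meta$format != "ptashb-stack") {
    stop_input(sprintf("%s is not a ptashb stack sidecar", sp))
  }
  meta
}

#' Read a frame stack from disk
#'
#' @param path Stack path (or PNG-sequence prefix) as given to
#'   [write_stack()].
#' @param dialect One of `"tiff"`, `"png_seq"`, `"raw"`; inferred from
#'   the file extension (`.tif`/`.tiff`, `.bin`/`.raw`) when `NULL`.
#' @param frame_rate,duration,mod_freq Acquisition metadata overrides;
#'   required if the YAML sidecar is missing.
#' @return A [frame_stack()] in detector counts.
#' @export
read_stack <- function(path, dialect = NULL, frame_rate = NULL,
                       duration = NULL, mod_freq = NULL) {
  meta <- read_sidecar(path)
  if (is.null(dialect)) {
    dialect <- if (!is.null(meta)) {
      meta$dialect
    } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
      "tiff"
    } else if (grepl("\\.(bin|raw)$", path, ignore.case = TRUE)) {
      "raw"
    } else {
      stop_input("cannot infer stack dialect; pass `dialect` explicitly")
    }
  }
  frame_rate <- frame_rate %||% meta$frame_rate
  duration <- duration %||% meta$duration
  mod_freq <- mod_freq %||% meta$mod_freq
  missing <- c("frame_rate", "duration", "mod_freq")[c(is.null(frame_rate),
                                                       is.null(duration),
                                                       is.null(mod_freq))]
  if (length(missing) > 0) {
    stop_input(sprintf("missing acquisition metadata (no sidecar): %s",
                       paste(missing, collapse = ", ")))
  }
  scale <- meta$scale %||% 1
  frames <- if (dialect == "tiff") {
    if (!file.exists(path)) stop_input(sprintf("stack file not found: %s", path))
    pages <- tiff::readTIFF(path, all = TRUE)
    lapply(pages, function(p) round(p * scale))
  } else if (dialect == "png_seq") {
    files <- sort(Sys.glob(sprintf("%s_*.png", path)))
    if (length(files) == 0L) stop_input(sprintf("no PNG frames match %s_*.png", path))
    lapply(files, function(f) round(png::readPNG(f) * scale))
  } else if (dialect == "raw") {
    if (is.null(meta)) stop_input("raw dialect requires the YAML sidecar for geometry")
    if (!file.exists(path)) stop_input(sprintf("stack file not found: %s", path))
    h <- meta$image_height
    w <- meta$image_width
    n <- meta$n_frames
    vals <- readBin(path, what = "numeric", n = h * w * n + 1L, size = 8,
                    endian = "little")
    if (length(vals) != h * w * n) {
      stop_input(sprintf(
        "raw stack truncated or oversized: expected %d values, found %d (page %d)",
        h * w * n, length(vals), length(vals) %/% (h * w) + 1L))
    }
    lapply(seq_len(n), function(i) {
      matrix(vals[((i - 1) * h * w + 1):(i * h * w)], nrow = h, byrow = TRUE)
    })
  } else {
    stop_input(sprintf("unknown stack dialect: %s", dialect))
  }
  n_expected <- round(frame_rate * duration)
  if (length(frames) != n_expected) {
    stop_input(sprintf("frame count %d does not match frame_rate * duration = %d",
                       length(frames), n_expected))
  }
  frame_stack(frames, frame_rate = frame_rate, duration = duration,
              mod_freq = mod_freq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_csv_columns <- function(d, path, required) {
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    stop_input(sprintf("%s is missing required column(s): %s",
                       path, paste(missing, collapse = ", ")))
  }
}

#' Read a paired-measurement CSV
#'
#' Schema (UTF-8, header row, `.` decimal separator): columns `id`,
#' `sex` (`male`/`female`/`unknown`), `reference_hb`, `device_hb`
#' (g/dL). This is the per-specimen layout needed to reproduce
#' method-comparison and anemia-screening statistics from a real
#' evaluation; see `inst/extdata/paired_synthetic.csv` for a synthetic
#' example of the schema.
#'
#' @param path CSV path.
#' @return Tibble with validated columns.
#' @export
read_paired_csv <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  d <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  check_csv_columns(d, path, c("id", "sex", "reference_hb", "device_hb"))
  for (col in c("reference_hb", "device_hb")) {
    if (!is.numeric(d[[col]]) || any(!is.finite(d[[col]])) || any(d[[col]] <= 0)) {
      stop_input(sprintf("%s: `%s` must be finite positive numeric (check locale/decimal separator)",
                         path, col))
    }
  }
  d$sex <- tolower(d$sex)
  d
}

#' Read a replicate-measurement CSV
#'
#' Schema: columns `label`, `nominal_hb` (g/dL), `day` (integer run
#' index), `value` (measured g/dL). Used for detection-limit and
#' precision computations.
#'
#' @param path CSV path.
#' @return Tibble with validated columns.
#' @export
read_replicates_csv <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  d <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  check_csv_columns(d, path, c("label", "nominal_hb", "day", "value"))
  for (col in c("nominal_hb", "value")) {
    if (!is.numeric(d[[col]]) || any(!is.finite(d[[col]]))) {
      stop_input(sprintf("%s: `%s` must be finite numeric (check locale/decimal separator)",
                         path, col))
    }
  }
  d
}

#' Run the measurement pipeline on a stored stack
#'
#' Reads a stack, demodulates it to the sensor signal, and (when a
#' calibration is supplied) converts the signal to [Hb]. The report is
#' deterministic: identical inputs give a byte-identical JSON report.
#'
#' @param stack_path Path to a stack written by [write_stack()].
#' @param calibration A [hill_curve()], [fit_hill()] result, or path to a
#'   calibration JSON ([write_calibration()]); `NULL` reports the signal
#'   only.
#' @param mod_freq,band Demodulation settings (defaults: the stack's
#'   recorded modulation frequency; the standard fringe search band).
#' @param seed Seed recorded in the report (provenance only; the pipeline
#'   itself is deterministic).
#' @param out Optional path for the JSON report.
#' @return The report as a named list (invisibly written to `out` when
#'   given): tool/version, config hash, seed, `signal` (rad),
#'   `fringe_bin`, `quality`, and `hb` (g/dL) + `censored` when
#'   calibrated.
#' @export
run_pipeline <- function(stack_path, calibration = NULL, mod_freq = NULL,
                         band = NULL, seed = NULL, out = NULL) {
  stack <- read_stack(stack_path)
  if (is.character(calibration)) calibration <- read_calibration(calibration)
  reading <- measure_stack(stack, mod_freq = mod_freq %||% stack$mod_freq,
                           band = band)
  config <- list(mod_freq = mod_freq %||% stack$mod_freq, band = band,
                 calibration = if (is.null(calibration)) NULL else
                   unclass(as_hill_curve(calibration)))
  report <- list(tool = "ptashb",
                 version = as.character(utils::packageVersion("ptashb")),
                 config_hash = rlang::hash(config),
                 seed = seed,
                 signal = reading$signal,
                 mod_freq = reading$mod_freq,
                 fringe_bin = reading$fringe_bin,
                 quality = reading$quality)
  if (!is.null(calibration)) {
    inv <- invert_hill(calibration, reading$signal)
    report$hb <- inv$hb
    report$censored <- inv$censored
  }
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(report)
}
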