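# Analytical-performance summaries: CLSI-style detection limits
# (LoB/LoD/LoQ) and intra-/inter-assay precision.

#' Limit of blank
#'
#' By default the plain arithmetic mean of the blank replicates, the rule
#' used in the instrument evaluation this package models. The
#' conventional CLSI nonparametric-normal rule
#' `mean + 1.645 * SD` is available via `method = "mean_plus_1.645sd"`.
#'
#' @param values Blank replicate measurements (g/dL, post-calibration).
#' @param method `"mean"` (default) or `"mean_plus_1.645sd"`.
#' @return Limit of blank (g/dL).
#' @export
#' @examples
#' limit_of_blank(c(0.001, 0.005, 0.006)) # 0.004
limit_of_blank <- function(values, method = c("mean", "mean_plus_1.645sd")) {
  method <- match.arg(method)
  if (!is.numeric(values) || length(values) == 0L || any(!is.finite(values))) {
    stop_input("`values` must be a non-empty finite numeric vector")
  }
  switch(method,
         mean = mean(values),
         `mean_plus_1.645sd` = {
           if (length(values) < 2L) stop_input("need >= 2 blanks for the SD-based rule")
           mean(values) + 1.645 * sd(values)
         })
}

#' Limit of detection
#'
#' `LoD = LoB + 1.645 * SD` of a low-concentration sample's replicate
#' measurements (sample SD, n - 1 denominator).
#'
#' @param lob Limit of blank (g/dL).
#' @param values Replicate measurements of the low sample (g/dL); supply
#'   either this or `sd`.
#' @param sd_low The low sample's SD directly (g/dL), e.g. when working
#'   from a published summary table.
#' @return Limit of detection (g/dL).
#' @export
#' @examples
#' limit_of_detection(0.0039, sd_low = 0.0263)
limit_of_detection <- function(lob, values = NULL, sd_low = NULL) {
  check_scalar_number(lob, "lob")
  if (is.null(values) == is.null(sd_low)) {
    stop_input("supply exactly one of `values` or `sd_low`")
  }
  if (!is.null(values)) {
    if (!is.numeric(values) || length(values) < 2L || any(!is.finite(values))) {
      stop_input("`values` must be finite numeric with n >= 2")
    }
    sd_low <- sd(values)
  } else {
    check_scalar_number(sd_low, "sd_low", lower = 0)
  }
  lob + 1.645 * sd_low
}

#' Per-level replicate summary (mean, SD, CV)
#'
#' @param data Data frame with one row per replicate measurement.
#' @param nominal Column with the level's nominal (reference-analyzer)
#'   concentration; default `nominal_hb`.
#' @param value Column with the measured value; default `value`.
#' @return Tibble with `nominal_hb`, `n`, `mean`, `sd` and `cv`
#'   (`100 * sd / mean`, `NA` for non-positive means), sorted by level.
#' @export
summarize_replicates <- function(data, nominal = nominal_hb, value = value) {
  d <- dplyr::transmute(as_tibble(data), nominal_hb = {{ nominal }},
                        value = {{ value }})
  if (!is.numeric(d$nominal_hb) || !is.numeric(d$value) ||
      any(!is.finite(d$nominal_hb)) || any(!is.finite(d$value))) {
    stop_input("replicate table must be finite numeric")
  }
  d |>
    dplyr::group_by(.data$nominal_hb) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop") |>
    dplyr::mutate(cv = dplyr::if_else(.data$mean > 0, 100 * .data$sd / .data$mean,
                                      NA_real_)) |>
    dplyr::arrange(.data$nominal_hb)
}

#' Limit of quantitation from a ladder of low-concentration levels
#'
#' Scans adjacent pairs of levels (sorted by nominal concentration) and
#' selects the pair whose mean CV is closest to the target (ties resolve
#' to the lower-concentration pair). The LoQ is the arithmetic mean of
#' the selected pair's *nominal* concentrations.
#'
#' @param levels Data frame with one row per level.
#' @param nominal Column with nominal concentrations (g/dL); default
#'   `nominal_hb`.
#' @param cv Column with the level CVs (%); default `cv`. Compute CVs
#'   from raw replicates with [summarize_replicates()].
#' @param target_cv Target CV in percent (default 20).
#' @return One-row tibble: `loq` (g/dL), the selected pair's
#'   `nominal_lo`, `nominal_hi`, `cv_lo`, `cv_hi` and `pair_mean_cv`.
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   nominal_hb = c(0.0475, 0.0950, 0.1188, 0.1900, 0.2375),
#'   cv = c(41.74, 27.04, 16.36, 11.98, 10.49))
#' limit_of_quantitation(tab)$loq # 0.1069
limit_of_quantitation <- function(levels, nominal = nominal_hb, cv = cv,
                                  target_cv = 20) {
  check_scalar_number(target_cv, "target_cv", lower = 0, strict_lower = TRUE)
  d <- dplyr::transmute(as_tibble(levels), nominal_hb = {{ nominal }},
                        cv = {{ cv }})
  if (!is.numeric(d$nominal_hb) || any(!is.finite(d$nominal_hb))) {
    stop_input("`nominal` must be finite numeric")
  }
  bad <- !is.finite(d$cv)
  if (any(bad)) {
    warn(sprintf("excluding %d level(s) without a computable CV", sum(bad)))
    d <- d[!bad, ]
  }
  if (nrow(d) < 2L) stop_input("need >= 2 usable levels to select an LoQ pair")
  d <- dplyr::arrange(d, .data$nominal_hb)
  k <- nrow(d) - 1L
  pair_cv <- (d$cv[-nrow(d)] + d$cv[-1]) / 2
  pick <- which.min(abs(pair_cv - target_cv)) # ties -> first = lowest pair
  tibble(loq = (d$nominal_hb[pick] + d$nominal_hb[pick + 1L]) / 2,
         nominal_lo = d$nominal_hb[pick], nominal_hi = d$nominal_hb[pick + 1L],
         cv_lo = d$cv[pick], cv_hi = d$cv[pick + 1L],
         pair_mean_cv = pair_cv[pick])
}

#' Detection-limit triple (LoB, LoD, LoQ)
#'
#' Convenience wrapper combining [limit_of_blank()],
#' [limit_of_detection()] and [limit_of_quantitation()]. The expected
#' ordering `LoB <= LoD <= LoQ` is asserted; a violation is reported with
#' a warning and flagged, not silently repaired.
#'
#' @param blank Blank replicate measurements (g/dL).
#' @param low Low-sample replicate measurements (g/dL).
#' @param levels Level table for the LoQ scan (see
#'   [limit_of_quantitation()]); either raw replicates (columns
#'   `nominal_hb`, `value`) or a summary with a `cv` column.
#' @param target_cv Target CV (%) for the LoQ pair.
#' @param lob_method Passed to [limit_of_blank()].
#' @return One-row tibble: `lob`, `lod`, `loq`, `ordered` flag, plus the
#'   LoQ pair columns.
#' @export
detection_limits <- function(blank, low, levels, target_cv = 20,
                             lob_method = "mean") {
  lob <- limit_of_blank(blank, method = lob_method)
  lod <- limit_of_detection(lob, values = low)
  if (!("cv" %in% names(levels)) && "value" %in% names(levels)) {
    levels <- summarize_replicates(levels)
  }
  loq <- limit_of_quantitation(levels, target_cv = target_cv)
  ordered <- lob <= lod && lod <= loq$loq
  if (!ordered) warn("detection limits are not ordered LoB <= LoD <= LoQ")
  dplyr::bind_cols(tibble(lob = lob, lod = lod), loq, tibble(ordered = ordered))
}

#' Intra-/inter-assay precision summary
#'
#' Intra-assay: mean, SD and CV of a single day's replicates.
#' Inter-assay: replicates from several days with equal per-day counts;
#' the mean is taken over all values and the SD is the total (n - 1)
#' sample SD over all values, capturing both within-day and between-day
#' variability. CV = `100 * SD / mean`.
#'
#' @param data Data frame with one row per replicate measurement.
#' @param value Column with measured values (g/dL); default `value`.
#' @param day Column identifying the day/run (required for
#'   `mode = "inter"`); default `day`.
#' @param mode `"intra"` or `"inter"`.
#' @return One-row tibble: `mode`, `mean`, `sd`, `cv` (%), `n` (per-day
#'   replicate count) and `n_days`.
#' @export
#' @examples
#' precision_summary(tibble::tibble(value = c(11.1, 11.2, 11.3, 11.2, 11.4)),
#'                   mode = "intra")
precision_summary <- function(data, value = value, day = day,
                              mode = c("intra", "inter")) {
  mode <- match.arg(mode)
  d <- as_tibble(data)
  v <- dplyr::pull(d, {{ value }})
  if (!is.numeric(v) || any(!is.finite(v))) stop_input("values must be finite numeric")
  if (length(v) < 2L) stop_input("need >= 2 replicate values")
  if (mode == "intra") {
    m <- mean(v)
    s <- sd(v)
    return(tibble(mode = "intra", mean = m, sd = s,
                  cv = if (m > 0) 100 * s / m else NA_real_,
                  n = length(v), n_days = 1L))
  }
  days <- dplyr::pull(d, {{ day }})
  if (length(days) != length(v)) stop_input("`day` must align with values")
  counts <- table(days)
  if (length(counts) < 2L) stop_input("inter-assay mode needs >= 2 days")
  if (length(unique(as.integer(counts))) != 1L) {
    stop_input("inter-assay mode requires equal replicate counts per day")
  }
  m <- mean(v)
  s <- sd(v)
  tibble(mode = "inter", mean = m, sd = s,
         cv = if (m > 0) 100 * s / m else NA_real_,
         n = as.integer(counts[1]), n_days = length(counts))
}
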