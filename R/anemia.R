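# WHO-cutoff anemia classification and diagnostic performance metrics.

#' Classify anemia by WHO hemoglobin cutoffs
#'
#' A subject is anemic when [Hb] is strictly below the sex-specific
#' cutoff: 13.0 g/dL for males, 12.0 g/dL for females (WHO adult
#' cutoffs). Values exactly at the cutoff are non-anemic. Cutoffs are
#' overridable for non-default populations.
#'
#' @param hb Hemoglobin concentration(s) in g/dL, >= 0.
#' @param sex Character/factor vector, `"male"` or `"female"` (recycled
#'   if scalar). Unknown or missing sex is an error: such subjects cannot
#'   be classified.
#' @param cutoffs Named numeric vector of cutoffs (g/dL).
#' @return Logical vector: `TRUE` = anemic.
#' @export
#' @examples
#' classify_anemia(c(12.9, 13.0), "male") # TRUE FALSE
classify_anemia <- function(hb, sex, cutoffs = c(male = 13.0, female = 12.0)) {
  if (!is.numeric(hb) || any(!is.finite(hb)) || any(hb < 0)) {
    stop_input("`hb` must be finite numeric >= 0")
  }
  sex <- tolower(as.character(sex))
  if (length(sex) == 1L) sex <- rep(sex, length(hb))
  if (length(sex) != length(hb)) stop_input("`sex` must match `hb` in length")
  unknown <- !(sex %in% names(cutoffs))
  if (any(unknown)) {
    stop_input(sprintf("cannot classify subjects with unknown sex: %s",
                       paste(unique(sex[unknown]), collapse = ", ")))
  }
  hb < unname(cutoffs[sex])
}

pct2 <- function(num, den) if (den > 0) round(100 * num / den, 2) else NA_real_

confusion_row <- function(stratum, truth, call) {
  tp <- sum(call & truth)
  fp <- sum(call & !truth)
  tn <- sum(!call & !truth)
  fn <- sum(!call & truth)
  tibble(stratum = stratum, n = length(truth),
         tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = pct2(tp, tp + fn),
         specificity = pct2(tn, tn + fp),
         accuracy = pct2(tp + tn, length(truth)))
}

#' Diagnostic performance of device-based anemia classification
#'
#' Classifies both the device and the reference measurements with
#' [classify_anemia()] (the reference classification is ground truth)
#' and tabulates confusion counts and sensitivity / specificity /
#' accuracy (percent, 2 d.p.) per sex stratum and pooled. Strata with no
#' positives (or no negatives) report an `NA` sensitivity (or
#' specificity) rather than a misleading 0 or 100.
#'
#' @param data Data frame with one row per subject.
#' @param reference Column with the reference [Hb] (g/dL); default
#'   `reference_hb`.
#' @param device Column with the device [Hb]; default `device_hb`.
#' @param sex Column with subject sex (`"male"`/`"female"`); default
#'   `sex`.
#' @param by_sex If `TRUE` (default) report per-sex strata in addition to
#'   the pooled row.
#' @param cutoffs Passed to [classify_anemia()].
#' @return Tibble with columns `stratum`, `n`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
#' @examples
#' d <- tibble::tibble(sex = c("male", "male", "female"),
#'                     reference_hb = c(12.1, 14.0, 11.0),
#'                     device_hb = c(12.4, 13.9, 11.2))
#' evaluate_anemia(d)
evaluate_anemia <- function(data, reference = reference_hb, device = device_hb,
                            sex = sex, by_sex = TRUE,
                            cutoffs = c(male = 13.0, female = 12.0)) {
  d <- dplyr::transmute(as_tibble(data), sex = tolower(as.character({{ sex }})),
                        ref = {{ reference }}, dev = {{ device }})
  if (nrow(d) == 0L) stop_input("no subjects to evaluate")
  truth <- classify_anemia(d$ref, d$sex, cutoffs)
  call <- classify_anemia(d$dev, d$sex, cutoffs)
  out <- list()
  if (by_sex) {
    for (s in intersect(names(cutoffs), unique(d$sex))) {
      i <- d$sex == s
      out[[s]] <- confusion_row(s, truth[i], call[i])
    }
  }
  out$pooled <- confusion_row("pooled", truth, call)
  dplyr::bind_rows(out)
}
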