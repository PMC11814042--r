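#' Soil-property-adjusted target / intervention value
#'
#' Dutch soil-quality target and intervention values are defined for a
#' standard soil (25% clay, 10% organic matter) and corrected to the
#' sampled soil through element-specific constants A, B, C. Two dialects
#' are provided. `"standard"` is the conventional multiplicative
#' correction,
#' \deqn{(SW,IW)_b = base \cdot \frac{A + B\,clay + C\,om}{A + 25B + 10C},}
#' which returns the base value unchanged at the standard soil. `"literal"`
#' evaluates the alternative form in which the base value multiplies only
#' the A term of the numerator,
#' \deqn{(SW,IW)_b = \frac{base \cdot A + B\,clay + C\,om}{A + 25B + 10C}.}
#'
#' @param base Base target or intervention value at standard soil (mg/kg).
#' @param A,B,C Element-specific adjustment constants.
#' @param clay Clay content, % of particles < 2 um, in \[0, 100\].
#' @param om Organic matter, %, in \[0, 100\].
#' @param dialect `"standard"` (default) or `"literal"`.
#' @return Adjusted threshold in mg/kg (vectorised over `clay`/`om`).
#' @examples
#' adjusted_threshold(85, A = 15, B = 0.4, C = 0.4, clay = 50, om = 20)
#' @export
adjusted_threshold <- function(base, A, B, C, clay, om,
                               dialect = c("standard", "literal")) {
  dialect <- match.arg(dialect)
  if (any(base < 0)) abort("base threshold must be non-negative")
  if (any(clay < 0 | clay > 100) || any(om < 0 | om > 100)) {
    abort("clay and om must lie in [0, 100] percent")
  }
  denom <- A + 25 * B + 10 * C
  if (any(denom == 0)) abort("zero denominator: A + 25B + 10C must be non-zero")
  switch(dialect,
         standard = base * (A + B * clay + C * om) / denom,
         literal  = (base * A + B * clay + C * om) / denom)
}

#' Band sample concentrations against target and intervention values
#'
#' Classifies each concentration into one of three mutually exclusive
#' pollution bands: below the target value, between target and intervention,
#' or above the intervention (remediation) value. Values exactly equal to a
#' threshold fall in the higher band (conservative assignment).
#'
#' @param conc Numeric vector of concentrations (mg/kg).
#' @param target,intervention Thresholds (mg/kg), `target < intervention`.
#' @return An ordered factor with levels `"below_target"`,
#'   `"target_to_intervention"`, `"above_intervention"`.
#' @seealso [band_percentages()]
#' @export
band_samples <- function(conc, target, intervention) {
  if (target >= intervention) abort("target must be below intervention")
  if (any(conc < 0)) abort("concentrations must be non-negative")
  lv <- c("below_target", "target_to_intervention", "above_intervention")
  band <- ifelse(conc >= intervention, lv[3],
                 ifelse(conc >= target, lv[2], lv[1]))
  factor(band, levels = lv, ordered = TRUE)
}

#' Per-element pollution-band percentages
#'
#' Applies [band_samples()] to every requested element of a sample table,
#' using per-element (optionally per-sample soil-property-adjusted)
#' thresholds, and reports the percentage of samples per band. Percentages
#' are computed from exact counts, so they sum to 100 up to rounding of
#' the ratio itself.
#'
#' @param data Sample tibble (one column per element).
#' @param thresholds Tibble/data frame with columns `element`, `target`,
#'   `intervention` (mg/kg).
#' @return Tibble with columns `element`, `band`, `n`, `pct`.
#' @export
band_percentages <- function(data, thresholds) {
  stopifnot(all(c("element", "target", "intervention") %in% names(thresholds)))
  purrr::pmap(thresholds[c("element", "target", "intervention")],
              function(element, target, intervention) {
                b <- band_samples(data[[element]], target, intervention)
                tibble(element = element, band = levels(b),
                       n = as.integer(table(b)),
                       pct = 100 * as.integer(table(b)) / length(b))
              }) |>
    list_rbind()
}

#' Hakanson toxicity coefficients
#'
#' Default dimensionless toxicity coefficients `Tr` for the individual
#' ecological risk index; As 10, Pb 5, Sb 7, with the standard Hakanson
#' values for the remaining elements.
#'
#' @format Named numeric vector.
#' @export
default_tr <- c(As = 10, Cd = 30, Co = 5, Cr = 2, Cu = 5, Fe = 1,
                Mn = 1, Ni = 5, Pb = 5, Sb = 7, Zn = 1, Hg = 40)

#' Individual ecological risk index
#'
#' Hakanson's single-element ecological risk, `Er = Tr * Cn / GB`, where
#' `Tr` is the element's toxicity coefficient, `Cn` the measured
#' concentration and `GB` the regional background value. Categories:
#' low (< 40), medium (40-80), significant (80-160), high (160-320),
#' very high (>= 320); bins are left-closed.
#'
#' @param Cn Concentration (mg/kg), vectorised.
#' @param tr Toxicity coefficient (> 0).
#' @param gb Background value (mg/kg, > 0).
#' @return Tibble with columns `er` and `category` (ordered factor).
#' @examples
#' ecological_risk(c(10, 100), tr = 10, gb = 10)
#' @export
ecological_risk <- function(Cn, tr, gb) {
  if (gb <= 0) abort("background value gb must be positive")
  if (tr <= 0) abort("toxicity coefficient tr must be positive")
  if (any(Cn < 0)) abort("concentration must be non-negative")
  er <- tr * Cn / gb
  tibble(er = er, category = er_category(er))
}

#' @rdname ecological_risk
#' @param er Ecological risk values to categorise.
#' @export
er_category <- function(er) {
  lv <- c("low", "medium", "significant", "high", "very high")
  cut(er, breaks = c(-Inf, 40, 80, 160, 320, Inf), labels = lv,
      right = FALSE, ordered_result = TRUE)
}

#' Descriptive statistics per element
#'
#' Mean, median, extrema, sample (n - 1) standard deviation, and the
#' coefficient of variation `cv = 100 * sd / mean` for each element column.
#' Censored cells are expected to already hold their substitute value
#' (consistent with how the receptor models treat them).
#'
#' @param data Sample tibble.
#' @param elements Element columns to summarise; default: all non-metadata
#'   numeric columns.
#' @return Tibble with one row per element: `element`, `mean`, `median`,
#'   `max`, `min`, `sd`, `cv`.
#' @export
summarize_elements <- function(data, elements = NULL) {
  m <- sample_matrix(data, elements)
  if (nrow(m) < 2) abort("need at least 2 samples per element")
  tibble(element = colnames(m),
         mean = unname(colMeans(m)),
         median = unname(apply(m, 2, median)),
         max = unname(apply(m, 2, max)),
         min = unname(apply(m, 2, min)),
         sd = unname(apply(m, 2, sd))) |>
    mutate(cv = cv_percent(.data$mean, .data$sd))
}
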