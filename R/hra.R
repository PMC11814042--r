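#' USEPA-style exposure parameter sets
#'
#' Returns the complete per-population exposure parameter list used by the
#' hazard-quotient and cancer-risk equations. Defaults follow the USEPA
#' Regional Screening Level (RSL) resident-soil scenario; every value can
#' be overridden. The site-specific exposure tables of any particular
#' survey should be supplied through the overrides.
#'
#' @param population `"child"`, `"adult"`, or `"age_adjusted"` (the
#'   resident carcinogenic scenario combining a 6-year childhood with a
#'   20-year adulthood).
#' @param ... Named overrides of any field below.
#' @return Object of class `exposure_params`: a list with `IRS` soil
#'   ingestion rate (mg/day), `EF` exposure frequency (days/yr), `ED`
#'   exposure duration (yr), `BW` body weight (kg), `SA` skin surface area
#'   (cm2/day), `AF` adherence factor (mg/cm2), `PEF` particulate emission
#'   factor (m3/kg), `AT_nc`/`AT_ca` averaging times (days,
#'   non-carcinogenic = ED x 365, carcinogenic = 70 x 365), and for the
#'   age-adjusted population the child/adult sub-fields (`IRSc`, `IRSa`,
#'   `EDc`, `EDa`, `BWc`, `BWa`, `SAc`, `SAa`, `AFc`, `AFa`).
#' @examples
#' exposure_params("child")
#' exposure_params("adult", BW = 70)
#' @export
exposure_params <- function(population = c("child", "adult", "age_adjusted"),
                            ...) {
  population <- match.arg(population)
  child <- list(IRS = 200, EF = 350, ED = 6, BW = 15, SA = 2373, AF = 0.2,
                PEF = 1.36e9, AT_nc = 6 * 365, AT_ca = 70 * 365)
  adult <- list(IRS = 100, EF = 350, ED = 20, BW = 80, SA = 6032, AF = 0.07,
                PEF = 1.36e9, AT_nc = 20 * 365, AT_ca = 70 * 365)
  base <- switch(population,
    child = child,
    adult = adult,
    age_adjusted = list(
      EF = 350, ED = child$ED + adult$ED, PEF = 1.36e9,
      AT_nc = (child$ED + adult$ED) * 365, AT_ca = 70 * 365,
      IRSc = child$IRS, IRSa = adult$IRS, EDc = child$ED, EDa = adult$ED,
      BWc = child$BW, BWa = adult$BW, SAc = child$SA, SAa = adult$SA,
      AFc = child$AF, AFa = adult$AF))
  over <- list(...)
  bad <- setdiff(names(over), c(names(base), "IRS", "BW", "SA", "AF"))
  if (length(bad) > 0) abort(paste0("unknown exposure parameter(s): ",
                                    paste(bad, collapse = ", ")))
  base[names(over)] <- over
  if (any(unlist(base) <= 0)) abort("all exposure parameters must be positive")
  structure(c(base, list(population = population)), class = "exposure_params")
}

#' Default toxicity values per element
#'
#' Reference doses, slope factors and absorption fractions in the layout
#' the risk equations expect. These defaults are generic screening-level
#' placeholders in the style of the USEPA RSL tables, shipped so the
#' pipeline runs end to end; any site assessment should override them with
#' the values of its own regulatory tables. `NA` marks a route that does
#' not exist for the element (e.g. no inhalation reference concentration,
#' or no carcinogenic endpoint).
#'
#' @format Tibble with columns `element`, `RfDo` oral reference dose
#'   (mg/kg-day), `RfC` inhalation reference concentration (mg/m3),
#'   `GIABS` gastrointestinal absorption fraction, `ABSd` dermal
#'   absorption fraction, `RBA` relative bioavailability, `CSFo` oral
#'   cancer slope factor ((mg/kg-day)^-1), `IUR` inhalation unit risk
#'   ((ug/m3)^-1).
#' @export
default_toxicity <- tibble::tribble(
  ~element, ~RfDo,   ~RfC,    ~GIABS, ~ABSd,  ~RBA, ~CSFo,   ~IUR,
  "As",     3.0e-4,  1.5e-5,  1,      0.03,   0.6,  1.5,     4.3e-3,
  "Cd",     1.0e-3,  1.0e-5,  0.025,  0.001,  1,    NA,      1.8e-3,
  "Co",     3.0e-4,  6.0e-6,  1,      0.001,  1,    NA,      9.0e-3,
  "Cr",     1.5,     1.0e-4,  0.013,  0.001,  1,    NA,      NA,
  "Cu",     4.0e-2,  NA,      1,      0.001,  1,    NA,      NA,
  "Fe",     7.0e-1,  NA,      1,      0.001,  1,    NA,      NA,
  "Mn",     2.4e-2,  5.0e-5,  0.04,   0.001,  1,    NA,      NA,
  "Ni",     2.0e-2,  9.0e-5,  1,      0.001,  1,    NA,      2.4e-4,
  "Pb",     3.5e-3,  NA,      1,      0.001,  1,    8.5e-3,  1.2e-5,
  "Sb",     4.0e-4,  NA,      0.15,   0.001,  1,    NA,      NA,
  "Zn",     3.0e-1,  NA,      1,      0.001,  1,    NA,      NA,
  "Hg",     3.0e-4,  3.0e-4,  1,      0.001,  1,    NA,      NA)

tox_entry <- function(tox, element) {
  row <- tox[tox$element == element, , drop = FALSE]
  if (nrow(row) != 1) abort(paste0("no toxicity entry for element ", element))
  as.list(row)
}

#' Hazard quotients and hazard index for one element
#'
#' Non-carcinogenic risk by the three soil exposure routes:
#' \deqn{HQ_{ing} = \frac{C \cdot IRS \cdot RBA \cdot EF \cdot ED}
#'   {BW \cdot AT \cdot RfDo} \times 10^{-6}}
#' \deqn{HQ_{der} = \frac{C \cdot SA \cdot AF \cdot ABSd \cdot EF \cdot ED}
#'   {BW \cdot AT \cdot RfDo \cdot GIABS} \times 10^{-6}}
#' \deqn{HQ_{inh} = \frac{C \cdot EF \cdot ED}{AT \cdot RfC \cdot PEF}}
#' with `HI` their sum. `AT` is the non-carcinogenic averaging time. The
#' 1e-6 factor converts mg soil to kg; the particulate emission factor PEF
#' carries the soil-to-air conversion for inhalation. A route whose
#' reference value is missing is reported as `NA` (absent, not zero) and
#' excluded from HI, with the route named in `missing_routes`.
#'
#' @param C Concentration in soil (mg/kg), vectorised.
#' @param params An [exposure_params()] for a single population.
#' @param tox One element's toxicity values: a one-row slice of (or entry
#'   from) [default_toxicity].
#' @return Tibble with `HQing`, `HQder`, `HQinh`, `HI`, `missing_routes`.
#' @examples
#' hazard_quotients(100, exposure_params("child"),
#'                  dplyr::filter(default_toxicity, element == "As"))
#' @export
hazard_quotients <- function(C, params, tox) {
  stopifnot(inherits(params, "exposure_params"))
  if (any(C < 0)) abort("concentration must be non-negative")
  tox <- as.list(tox)
  p <- params
  missing_routes <- character(0)

  if (!is.na(tox$RfDo)) {
    hq_ing <- (C * p$IRS * tox$RBA * p$EF * p$ED) /
      (p$BW * p$AT_nc * tox$RfDo) * 1e-6
    hq_der <- (C * p$SA * p$AF * tox$ABSd * p$EF * p$ED) /
      (p$BW * p$AT_nc * tox$RfDo * tox$GIABS) * 1e-6
  } else {
    hq_ing <- hq_der <- rep(NA_real_, length(C))
    missing_routes <- c(missing_routes, "ingestion", "dermal")
  }
  if (!is.na(tox$RfC)) {
    hq_inh <- (C * p$EF * p$ED) / (p$AT_nc * tox$RfC * p$PEF)
  } else {
    hq_inh <- rep(NA_real_, length(C))
    missing_routes <- c(missing_routes, "inhalation")
  }
  if (length(missing_routes) > 0) {
    warn(paste0("element ", tox$element %||% "?", ": route(s) without reference value excluded from HI: ",
                paste(missing_routes, collapse = ", ")),
         class = "sourcerisk_missing_route")
  }
  # ordered elementwise sum so HI == HQing + HQder + HQinh bit-for-bit
  zero_na <- function(v) ifelse(is.na(v), 0, v)
  hi <- zero_na(hq_ing) + zero_na(hq_der) + zero_na(hq_inh)
  hi[is.na(hq_ing) & is.na(hq_der) & is.na(hq_inh)] <- NA_real_
  tibble(HQing = hq_ing, HQder = hq_der, HQinh = hq_inh, HI = hi,
         missing_routes = paste(missing_routes, collapse = ","))
}

#' Age-adjusted soil intake factors
#'
#' The carcinogenic scenario integrates exposure over childhood and
#' adulthood through the age-adjusted ingestion factor
#' \deqn{IFS = \frac{EF \cdot ED_a \cdot IRS_a}{BW_a} +
#'   \frac{EF \cdot ED_c \cdot IRS_c}{BW_c}}
#' and the dermal factor
#' \deqn{DFS = \frac{EF \cdot ED_a \cdot SA_a}{BW_a} +
#'   \frac{EF \cdot ED_c \cdot SA_c \cdot AF_c}{BW_c}.}
#' The adult dermal term carries no adherence factor in this formulation;
#' set `include_adult_af = TRUE` for the screening-table convention that
#' includes `AF_a`.
#'
#' @param params An age-adjusted [exposure_params()].
#' @param include_adult_af Multiply the adult dermal term by `AFa`?
#' @return List with `IFS` (mg yr / (kg day)) and `DFS`.
#' @examples
#' intake_factors(exposure_params("age_adjusted"))
#' @export
intake_factors <- function(params, include_adult_af = FALSE) {
  stopifnot(inherits(params, "exposure_params"))
  need <- c("IRSc", "IRSa", "EDc", "EDa", "BWc", "BWa", "SAc", "SAa", "AFc")
  if (!all(need %in% names(params))) {
    abort("intake_factors() needs an age-adjusted parameter set (child and adult sub-fields)")
  }
  p <- params
  ifs <- (p$EF * p$EDa * p$IRSa) / p$BWa + (p$EF * p$EDc * p$IRSc) / p$BWc
  adult_der <- (p$EF * p$EDa * p$SAa) / p$BWa
  if (include_adult_af) adult_der <- adult_der * p$AFa
  dfs <- adult_der + (p$EF * p$EDc * p$SAc * p$AFc) / p$BWc
  list(IFS = ifs, DFS = dfs)
}

#' Carcinogenic risks per route and total
#'
#' Incremental lifetime cancer risks for the resident scenario:
#' \deqn{CR_{ing} = \frac{C \cdot IFS \cdot RBA \cdot CSFo}{AT} \times 10^{-6}}
#' \deqn{CR_{der} = \frac{C \cdot DFS \cdot ABSd \cdot CSFo}{AT \cdot GIABS}
#'   \times 10^{-6}}
#' \deqn{CR_{inh} = \frac{C \cdot EF \cdot ED \cdot IUR \cdot 1000}{AT \cdot PEF}}
#' with `AT` the carcinogenic averaging time, IFS/DFS from
#' [intake_factors()], the 1000 factor converting mg to ug for the
#' inhalation unit risk, and `TCR` the exact sum of the three routes.
#' Routes without a slope factor / unit risk contribute 0 and are flagged.
#'
#' @param C Concentration (mg/kg), vectorised.
#' @param params Age-adjusted [exposure_params()].
#' @param tox One element's toxicity values; must have `CSFo` and/or `IUR`.
#' @param include_adult_af Passed to [intake_factors()].
#' @return Tibble `CRing`, `CRder`, `CRinh`, `TCR`, `zero_routes`.
#' @export
cancer_risks <- function(C, params, tox, include_adult_af = FALSE) {
  stopifnot(inherits(params, "exposure_params"))
  if (any(C < 0)) abort("concentration must be non-negative")
  tox <- as.list(tox)
  if (is.na(tox$CSFo) && is.na(tox$IUR)) {
    abort(paste0("element ", tox$element %||% "?", " is not a carcinogen in config"))
  }
  fac <- intake_factors(params, include_adult_af)
  p <- params
  zero_routes <- character(0)
  if (!is.na(tox$CSFo)) {
    cr_ing <- (C * fac$IFS * tox$RBA * tox$CSFo) / p$AT_ca * 1e-6
    cr_der <- (C * fac$DFS * tox$ABSd * tox$CSFo) / (p$AT_ca * tox$GIABS) * 1e-6
  } else {
    cr_ing <- cr_der <- rep(0, length(C))
    zero_routes <- c(zero_routes, "ingestion", "dermal")
  }
  if (!is.na(tox$IUR)) {
    cr_inh <- (C * p$EF * p$ED * tox$IUR * 1000) / (p$AT_ca * p$PEF)
  } else {
    cr_inh <- rep(0, length(C))
    zero_routes <- c(zero_routes, "inhalation")
  }
  tibble(CRing = cr_ing, CRder = cr_der, CRinh = cr_inh,
         TCR = cr_ing + cr_der + cr_inh,
         zero_routes = paste(zero_routes, collapse = ","))
}

#' Classify a risk value
#'
#' Non-carcinogenic hazard (`kind = "HI"`): acceptable below 1,
#' unacceptable at or above 1. Carcinogenic risk (`kind = "CR"`):
#' ignorable below 1e-6, notable in \[1e-6, 1e-4\] (boundaries inclusive),
#' unacceptable above 1e-4.
#'
#' @param value Non-negative risk value(s).
#' @param kind `"HI"` or `"CR"`.
#' @return Character vector of band labels.
#' @examples
#' classify_risk(c(0.99, 5.23), "HI")
#' classify_risk(1.23e-4, "CR")
#' @export
classify_risk <- function(value, kind = c("HI", "CR")) {
  kind <- match.arg(kind)
  if (any(value < 0, na.rm = TRUE)) abort("risk values must be non-negative")
  if (kind == "HI") {
    ifelse(value >= 1, "unacceptable", "acceptable")
  } else {
    ifelse(value > 1e-4, "unacceptable",
           ifelse(value >= 1e-6, "notable", "ignorable"))
  }
}

#' Deterministic risk table across elements and populations
#'
#' Convenience wrapper evaluating [hazard_quotients()] for each element and
#' population at given concentrations (e.g. per-sample or site means), and
#' [cancer_risks()] for the carcinogenic elements under the age-adjusted
#' scenario. Missing-route warnings are collected into the output flags
#' rather than repeated per element.
#'
#' @param conc Named concentration vector (mg/kg, one entry per element) or
#'   a sample tibble whose element means are used.
#' @param tox Toxicity table (default [default_toxicity]).
#' @param populations Populations for the hazard quotients.
#' @return Long tibble: `element`, `population`, `HQing`, `HQder`,
#'   `HQinh`, `HI`, `HI_band`, `CRing`, `CRder`, `CRinh`, `TCR`,
#'   `TCR_band` (CR columns NA for non-carcinogens and non-age-adjusted
#'   rows are repeated per population).
#' @export
deterministic_risk <- function(conc, tox = default_toxicity,
                               populations = c("child", "adult")) {
  if (is.data.frame(conc)) {
    m <- sample_matrix(conc, intersect(tox$element, names(conc)))
    conc <- colMeans(m)
  }
  elements <- intersect(names(conc), tox$element)
  aa <- exposure_params("age_adjusted")
  rows <- list()
  for (pop in populations) {
    prm <- exposure_params(pop)
    for (el in elements) {
      te <- tox_entry(tox, el)
      hq <- withCallingHandlers(
        hazard_quotients(conc[[el]], prm, te),
        sourcerisk_missing_route = function(w) invokeRestart("muffleWarning"))
      cr <- if (!is.na(te$CSFo) || !is.na(te$IUR)) {
        cancer_risks(conc[[el]], aa, te)
      } else {
        tibble(CRing = NA_real_, CRder = NA_real_, CRinh = NA_real_,
               TCR = NA_real_, zero_routes = "")
      }
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(element = el, population = pop),
        hq[, c("HQing", "HQder", "HQinh", "HI")],
        tibble(HI_band = classify_risk(hq$HI, "HI")),
        cr[, c("CRing", "CRder", "CRinh", "TCR")],
        tibble(TCR_band = ifelse(is.na(cr$TCR), NA_character_,
                                 classify_risk(cr$TCR, "CR"))))
    }
  }
  list_rbind(rows)
}
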