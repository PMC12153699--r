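# Table-1-style demographic/clinical summaries and time-to-onset
# statistics per therapy group.

age_unit_factors <- c(
  DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
  DY = 1 / 365.25, HR = 1 / 8766
)

#' Convert FAERS ages to years
#'
#' FAERS ages arrive in decades, years, months, weeks, days or hours.
#' Fixed factors: DEC x10, YR x1, MON /12, WK /52.1775, DY /365.25,
#' HR /8766.  A missing unit with a value at most 120 is taken as years
#' (larger values are uninterpretable and become missing); negative values
#' become missing.
#'
#' @param raw Numeric (or character) age values.
#' @param unit Unit codes (`DEC`, `YR`, `MON`, `WK`, `DY`, `HR`) or missing.
#' @return Numeric vector of ages in years.
#' @examples
#' age_to_years(c(6.5, 730.5, 18), c("DEC", "DY", "MON"))
#' @export
age_to_years <- function(raw, unit = NULL) {
  v <- suppressWarnings(as.numeric(blank_to_na(raw)))
  n <- length(v)
  u <- toupper(blank_to_na(unit %||% rep(NA_character_, n)))
  if (length(u) == 1L && n > 1L) u <- rep(u, n)
  fac <- unname(age_unit_factors[u])
  out <- v * fac
  no_unit <- is.na(u) & !is.na(v)
  out[no_unit & v <= 120] <- v[no_unit & v <= 120]
  out[!is.na(v) & v < 0] <- NA_real_
  out
}

age_group_levels <- c("Neonate", "Child", "Adolescent", "Adult", "Elderly",
                      "Not available")

#' Assign age bands
#'
#' ICH-style bands: Neonate < 28 days, Child < 12 years, Adolescent 12-17,
#' Adult 18-64, Elderly >= 65; missing ages map to `"Not available"`.
#'
#' @param years Numeric ages in years (see [age_to_years()]).
#' @return Factor with the six band levels.
#' @export
assign_age_group <- function(years) {
  out <- dplyr::case_when(
    is.na(years) ~ "Not available",
    years < 28 / 365.25 ~ "Neonate",
    years < 12 ~ "Child",
    years < 18 ~ "Adolescent",
    years < 65 ~ "Adult",
    TRUE ~ "Elderly"
  )
  factor(out, levels = age_group_levels)
}

weight_unit_factors <- c(KG = 1, KGS = 1, LBS = 0.453592, GMS = 0.001)

weight_to_kg <- function(raw, unit) {
  v <- suppressWarnings(as.numeric(blank_to_na(raw)))
  u <- toupper(blank_to_na(unit))
  fac <- unname(weight_unit_factors[u])
  out <- v * fac
  out[is.na(u) & !is.na(v)] <- v[is.na(u) & !is.na(v)]  # assume kg
  out
}

occp_labels <- c(
  MD = "Physician", PH = "Pharmacist", CN = "Consumer",
  HP = "Health-professional", OT = "Other health-professional"
)

# Seriousness ranking used to assign one outcome per report.
outcome_rank <- c(DE = 1, LT = 2, DS = 3, HO = 4, RI = 5, OT = 6)
outcome_labels <- c(
  DE = "Death", LT = "Life-threatening", DS = "Disability",
  HO = "Hospitalization - initial or prolonged",
  RI = "Required intervention to prevent permanent impairment/damage",
  OT = "Other serious (IME)"
)

country_regions <- c(
  US = "North America", CA = "North America", MX = "North America",
  IT = "Europe", DE = "Europe", FR = "Europe", GB = "Europe", ES = "Europe",
  NL = "Europe", PL = "Europe", CH = "Europe", AT = "Europe", SE = "Europe",
  JP = "Asia", CN = "Asia", KR = "Asia", IN = "Asia", TW = "Asia",
  BR = "South America", AR = "South America", CL = "South America",
  AU = "Oceania", NZ = "Oceania",
  ZA = "Africa", EG = "Africa", NG = "Africa",
  GT = "Central America", CR = "Central America", PA = "Central America"
)
region_levels <- c("Africa", "Asia", "Europe", "North America",
                   "Central America", "South America", "Oceania",
                   "Not available")

worst_outcome <- function(outc_codes) {
  outc_codes <- as.character(outc_codes)
  outc_codes[is.na(outc_codes)] <- ""
  vapply(strsplit(outc_codes, ";", fixed = TRUE),
         function(codes) {
           codes <- codes[codes %in% names(outcome_rank)]
           if (length(codes) == 0L) return("Not available")
           unname(outcome_labels[codes[which.min(outcome_rank[codes])]])
         }, character(1))
}

# Quartiles: Tukey median-of-halves hinges by default (stats::fivenum),
# or the usual linear interpolation (quantile type 7).
quartile_stats <- function(x, quartile = c("tukey", "linear")) {
  quartile <- match.arg(quartile)
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    return(c(n = 0, min = NA, q1 = NA, median = NA, q3 = NA, max = NA))
  }
  if (quartile == "tukey") {
    fn <- stats::fivenum(x)
    c(n = length(x), min = fn[1], q1 = fn[2], median = fn[3], q3 = fn[4],
      max = fn[5])
  } else {
    q <- stats::quantile(x, c(0, .25, .5, .75, 1), names = FALSE, type = 7)
    c(n = length(x), min = q[1], q1 = q[2], median = q[3], q3 = q[4],
      max = q[5])
  }
}

count_block <- function(block, values, levels, N) {
  tab <- table(factor(values, levels = levels))
  tibble::tibble(
    block = block, level = levels, n = as.integer(tab),
    pct = if (N > 0) round(100 * as.integer(tab) / N, 1) else rep(0, length(levels)),
    median = NA_real_, q1 = NA_real_, q3 = NA_real_
  )
}

#' Summarize the demographic and clinical profile of a report set
#'
#' Produces the block structure of a characteristics table: age median
#' (Q1-Q3) and age groups, sex, weight, type of reporter, outcome (one per
#' report, ranked by seriousness), reporter region and year of reporting.
#' Continuous blocks report median and quartiles; categorical blocks report
#' counts and percentages of the block total N.
#'
#' @param demo DEMO-style tibble (rows = the reports to summarize) with
#'   columns `age`, `age_cod`, `sex`, `wt`, `wt_cod`, `occp_cod`,
#'   `outc_codes`, `reporter_country`, `fda_dt`.
#' @param quartile Quartile convention: `"tukey"` median-of-halves hinges
#'   (default) or `"linear"` interpolation (type 7).
#' @return Tibble with columns `block`, `level`, `n`, `pct`, `median`,
#'   `q1`, `q3`; total N as attribute `"N"`.  An empty input yields
#'   all-zero blocks with N = 0.
#' @export
summarize_cohort <- function(demo, quartile = c("tukey", "linear")) {
  quartile <- match.arg(quartile)
  N <- nrow(demo)
  age_years <- age_to_years(demo$age, demo$age_cod)
  a <- quartile_stats(age_years, quartile)
  w <- quartile_stats(weight_to_kg(demo$wt, demo$wt_cod), quartile)
  num_row <- function(block, s) {
    tibble::tibble(block = block, level = "median (Q1-Q3)",
                   n = as.integer(s["n"]), pct = NA_real_,
                   median = unname(s["median"]), q1 = unname(s["q1"]),
                   q3 = unname(s["q3"]))
  }
  sex <- dplyr::case_when(
    blank_to_na(demo$sex) == "F" ~ "Female",
    blank_to_na(demo$sex) == "M" ~ "Male",
    TRUE ~ "Not available")
  rep_type <- unname(occp_labels[blank_to_na(demo$occp_cod)])
  rep_type[is.na(rep_type)] <- "Not available"
  region <- unname(country_regions[blank_to_na(demo$reporter_country)])
  region[is.na(region)] <- "Not available"
  year <- substr(blank_to_na(demo$fda_dt), 1, 4)
  year[is.na(year)] <- "Not available"
  year_levels <- sort(unique(year))
  outc <- if ("outc_codes" %in% names(demo)) demo$outc_codes else rep(NA, N)

  out <- dplyr::bind_rows(
    num_row("Age (years)", a),
    count_block("Age group", as.character(assign_age_group(age_years)),
                age_group_levels, N),
    count_block("Sex", sex, c("Female", "Male", "Not available"), N),
    num_row("Weight (kg)", w),
    count_block("Type of reporter", rep_type,
                c(unname(occp_labels), "Not available"), N),
    count_block("Outcome", worst_outcome(outc),
                c(unname(outcome_labels[names(outcome_rank)[order(outcome_rank)]]),
                  "Not available"), N),
    count_block("Reporter region", region, region_levels, N),
    count_block("Year of reporting", year, year_levels, N)
  )
  attr(out, "N") <- N
  out
}

#' Characteristics table across analysis strata
#'
#' Applies [summarize_cohort()] to the four headline strata (all reports /
#' cardiovascular cases, by combination / monotherapy) and, optionally, to
#' every therapy group separately.
#'
#' @param cases Output of [build_cases()].
#' @param combined The cleaned `faers_combined` universe the cases came
#'   from.
#' @param by_drug Also emit one stratum per therapy group code.
#' @inheritParams summarize_cohort
#' @return Long tibble with a leading `stratum` column and an `N` count
#'   per stratum.
#' @export
table1 <- function(cases, combined, by_drug = FALSE,
                   quartile = c("tukey", "linear")) {
  quartile <- match.arg(quartile)
  demo <- combined$demo
  strata <- list(
    "All AEs, combination" = cases$primaryid[cases$kind == "combination"],
    "cAEs, combination" = cases$primaryid[cases$kind == "combination" & cases$is_cae],
    "All AEs, monotherapy" = cases$primaryid[cases$kind == "monotherapy"],
    "cAEs, monotherapy" = cases$primaryid[cases$kind == "monotherapy" & cases$is_cae]
  )
  if (by_drug) {
    for (g in unique(cases$group)) {
      strata[[paste0("All AEs, ", g)]] <- cases$primaryid[cases$group == g]
      strata[[paste0("cAEs, ", g)]] <-
        cases$primaryid[cases$group == g & cases$is_cae]
    }
  }
  purrr::imap_dfr(strata, function(ids, nm) {
    blk <- summarize_cohort(demo[demo$primaryid %in% ids, , drop = FALSE],
                            quartile)
    dplyr::mutate(blk, stratum = nm, N = attr(blk, "N"),
                  .before = "block")
  })
}

#' Time to onset of cardiovascular adverse events
#'
#' Days between the earliest therapy start date of the primary suspect
#' drug of interest and the report's event date.  Both dates must be
#' complete to day precision; records with partial or missing dates at
#' either end, and negative differences, are dropped and counted in the
#' log (never imputed).
#'
#' @param cases Output of [build_cases()].
#' @param combined Cleaned `faers_combined` universe.
#' @param dictionary Drug-name normalization map.
#' @param quartile Quartile convention for the per-group summary.
#' @return List with `records` (tibble `primaryid`, `group`, `days`),
#'   `summary` (per-group n/min/Q1/median/Q3/max for box plots) and `log`
#'   (drop counts).
#' @export
compute_tto <- function(cases, combined,
                        dictionary = default_drug_dictionary(),
                        quartile = c("tukey", "linear")) {
  quartile <- match.arg(quartile)
  cae <- cases[cases$is_cae, , drop = FALSE]
  d <- combined$drug
  d$ing <- drug_ingredients(d, dictionary)
  ps <- d[d$role_cod == "PS" & !is.na(d$ing) &
            d$primaryid %in% cae$primaryid, , drop = FALSE]
  ps$start <- faers_date(ps[["start_dt"]] %||% rep(NA_character_, nrow(ps)))
  starts <- ps %>%
    dplyr::filter(!is.na(.data$start)) %>%
    dplyr::group_by(.data$primaryid) %>%
    dplyr::summarise(start = min(.data$start), .groups = "drop")

  demo <- combined$demo
  ev <- tibble::tibble(primaryid = demo$primaryid,
                       event = faers_date(demo$event_dt))

  rec <- cae %>%
    dplyr::select(dplyr::all_of(c("primaryid", "group"))) %>%
    dplyr::left_join(starts, by = "primaryid") %>%
    dplyr::left_join(ev, by = "primaryid") %>%
    dplyr::mutate(days = as.integer(.data$event - .data$start))

  n_missing <- sum(is.na(rec$days))
  n_negative <- sum(!is.na(rec$days) & rec$days < 0)
  rec <- rec[!is.na(rec$days) & rec$days >= 0, , drop = FALSE]

  summary <- rec %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(
      stats = list(quartile_stats(.data$days, quartile)), .groups = "drop") %>%
    tidyr::unnest_wider("stats")

  list(
    records = rec[c("primaryid", "group", "days")],
    summary = summary,
    log = dplyr::bind_rows(
      log_entry("tto", "cases dropped: incomplete start or event date", n_missing),
      log_entry("tto", "cases dropped: negative onset interval", n_negative))
  )
}
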