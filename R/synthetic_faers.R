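# Synthetic FAERS quarterly extracts with a ground-truth ledger.
#
# The generator writes the same dollar-delimited quarterly layout the
# reader ingests, with known report-level truth: therapy-group exposure,
# reaction sets, planted drug-event associations of configurable strength,
# injected id- and similarity-duplicates, partial dates, mixed age units
# and per-field missingness.  Every quantity the pipeline recovers is
# recorded in the ledger, so recovery can be asserted exactly (counts) or
# within sampling bands (planted odds ratios).

ingredient_brand <- c(
  dabrafenib = "TAFINLAR", trametinib = "MEKINIST",
  vemurafenib = "ZELBORAF", cobimetinib = "COTELLIC",
  encorafenib = "BRAFTOVI", binimetinib = "MEKTOVI"
)

# PS/SS ingredients per therapy group.
group_drugs <- list(
  "D" = list(ps = "dabrafenib", ss = NULL),
  "T" = list(ps = "trametinib", ss = NULL),
  "V" = list(ps = "vemurafenib", ss = NULL),
  "C" = list(ps = "cobimetinib", ss = NULL),
  "E" = list(ps = "encorafenib", ss = NULL),
  "B" = list(ps = "binimetinib", ss = NULL),
  "D+T" = list(ps = "dabrafenib", ss = "trametinib"),
  "V+C" = list(ps = "vemurafenib", ss = "cobimetinib"),
  "E+B" = list(ps = "encorafenib", ss = "binimetinib")
)

#' Default background drug catalog for the generator
#'
#' Common co-medications (plus melanoma immunotherapies) used as primary
#' suspects of background reports and as concomitants everywhere.
#'
#' @return Tibble with `ingredient` and `brand`.
#' @export
default_drug_catalog <- function() {
  tibble::tibble(
    ingredient = c("atorvastatin", "metformin", "lisinopril", "omeprazole",
                   "levothyroxine", "amlodipine", "ibuprofen", "paracetamol",
                   "sertraline", "pembrolizumab", "nivolumab", "ipilimumab"),
    brand = c("LIPITOR", "GLUCOPHAGE", "ZESTRIL", "PRILOSEC", "SYNTHROID",
              "NORVASC", "ADVIL", "TYLENOL", "ZOLOFT", "KEYTRUDA", "OPDIVO",
              "YERVOY")
  )
}

#' Default PT catalog for the generator
#'
#' Background (non-cardiovascular) PTs with typical spontaneous-report
#' frequencies, plus one row per narrow-SMQ cardiovascular PT at a low
#' background rate.  Rates are per-report sampling probabilities under
#' drug-event independence; planted signals multiply the odds for chosen
#' (group, PT) pairs.
#'
#' @param smqs SMQ definitions supplying the cardiovascular PTs.
#' @param cv_rate Background per-report probability of each CV PT.
#' @return Tibble with `pt`, `rate`, `smq` (`NA` for background PTs).
#' @export
default_pt_catalog <- function(smqs = default_smqs(), cv_rate = 0.002) {
  bg <- tibble::tibble(
    pt = c("Nausea", "Fatigue", "Pyrexia", "Rash", "Headache", "Diarrhoea",
           "Arthralgia", "Vomiting", "Dizziness", "Pruritus"),
    rate = c(0.12, 0.12, 0.08, 0.08, 0.08, 0.08, 0.06, 0.06, 0.05, 0.05),
    smq = NA_character_
  )
  cv <- smq_lookup(smqs) %>%
    dplyr::rename(pt = "pt_norm") %>%
    dplyr::mutate(rate = cv_rate) %>%
    dplyr::select(dplyr::all_of(c("pt", "rate", "smq")))
  dplyr::bind_rows(bg, cv)
}

#' Configuration for the synthetic FAERS generator
#'
#' Validates and assembles the generator settings.  `group_shares` gives
#' the expected fraction of reports assigned to each therapy group (the
#' remainder are background reports of unrelated drugs); `planted_signals`
#' multiplies the reporting odds of chosen (group, PT) pairs so the
#' expected reporting odds ratio equals the multiplier.
#'
#' @param n_reports Number of distinct reports (before duplicate
#'   injection).
#' @param quarters Character vector of quarter labels (`"YYYYqN"`).
#' @param group_shares Named numeric vector over therapy group codes,
#'   summing to at most 1.
#' @param drug_catalog Background drug catalog; see
#'   [default_drug_catalog()].
#' @param pt_catalog PT catalog; see [default_pt_catalog()].
#' @param smqs SMQ definitions used for ground-truth cardiovascular
#'   tagging.
#' @param planted_signals Tibble `group`, `pt`, `or_mult` (target odds
#'   multiplier vs the background rate), or `NULL`.
#' @param duplicate_id_fraction Fraction of reports receiving an extra
#'   version (same caseid, new primaryid, higher caseversion).
#' @param duplicate_similarity_fraction Fraction of reports cloned under a
#'   new caseid with an identical similarity key.
#' @param literature_rate Fraction of reports flagged as premarketing
#'   literature reports (excluded by the cleaning filters).
#' @param investigational_rate Fraction of reports given an extra
#'   investigational-product drug row (excluded by the cleaning filters).
#' @param nonmelanoma_rate Fraction of of-interest reports given a stated
#'   non-melanoma indication (excluded by the indication filter).
#' @param missing_rates Named list of per-field missingness /
#'   partial-date rates; unspecified entries keep their defaults.
#' @param tto_median Named numeric vector of median time-to-onset days per
#'   therapy group (lognormal; single unnamed value recycles to all
#'   groups).
#' @param tto_sdlog Lognormal sd of the time-to-onset distribution.
#' @param seed Mandatory integer seed; generation is deterministic given
#'   the seed.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_reports,
                       quarters = "2019q1",
                       group_shares = c("D+T" = 0.02, "V" = 0.01),
                       drug_catalog = default_drug_catalog(),
                       pt_catalog = default_pt_catalog(),
                       smqs = default_smqs(),
                       planted_signals = NULL,
                       duplicate_id_fraction = 0,
                       duplicate_similarity_fraction = 0,
                       literature_rate = 0,
                       investigational_rate = 0,
                       nonmelanoma_rate = 0,
                       missing_rates = list(),
                       tto_median = 30,
                       tto_sdlog = 1,
                       seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_reports >= 1)
  lapply(quarters, parse_quarter_label)
  bad <- setdiff(names(group_shares), therapy_groups()$code)
  if (length(bad)) stop("unknown therapy group(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(group_shares < 0) || sum(group_shares) > 1) {
    stop("group_shares must be non-negative and sum to at most 1",
         call. = FALSE)
  }
  if (any(pt_catalog$rate < 0 | pt_catalog$rate >= 1)) {
    stop("pt_catalog rates must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(planted_signals)) {
    planted_signals <- tibble::as_tibble(planted_signals)
    stopifnot(all(c("group", "pt", "or_mult") %in% names(planted_signals)))
    if (any(!is.finite(planted_signals$or_mult) |
            planted_signals$or_mult <= 0)) {
      stop("planted or_mult must be finite and positive", call. = FALSE)
    }
    miss <- setdiff(norm_pt(planted_signals$pt), norm_pt(pt_catalog$pt))
    if (length(miss)) stop("planted PT(s) not in pt_catalog: ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  frac_ok <- function(x) length(x) == 1 && x >= 0 && x < 1
  stopifnot(frac_ok(duplicate_id_fraction),
            frac_ok(duplicate_similarity_fraction),
            frac_ok(literature_rate), frac_ok(investigational_rate),
            frac_ok(nonmelanoma_rate))
  mr <- list(age = 0.12, sex = 0.04, wt = 0.35, country = 0.02,
             event_partial = 0.15, event_missing = 0.03,
             start_missing = 0.15, prod_ai = 0.3)
  mr[names(missing_rates)] <- missing_rates
  if (any(unlist(mr) < 0 | unlist(mr) > 1)) {
    stop("missing_rates must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(names(tto_median))) {
    tto_median <- stats::setNames(rep(tto_median[1], 9), therapy_groups()$code)
  }
  structure(list(
    n_reports = as.integer(n_reports), quarters = quarters,
    group_shares = group_shares, drug_catalog = drug_catalog,
    pt_catalog = pt_catalog, smqs = smqs,
    planted_signals = planted_signals,
    duplicate_id_fraction = duplicate_id_fraction,
    duplicate_similarity_fraction = duplicate_similarity_fraction,
    literature_rate = literature_rate,
    investigational_rate = investigational_rate,
    nonmelanoma_rate = nonmelanoma_rate,
    missing_rates = mr, tto_median = tto_median, tto_sdlog = tto_sdlog,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Per-report CV/background PT probability matrix: planted (group, pt)
# pairs have their odds multiplied by or_mult.
planted_prob <- function(rate, or_mult) {
  o <- or_mult * rate / (1 - rate)
  o / (1 + o)
}

#' Generate synthetic FAERS quarterly extracts
#'
#' Writes one sub-directory per quarter under `dir`, each containing the
#' six dollar-delimited tables (`DEMO19Q1.txt`, ...), plus `ledger.json`
#' with the ground truth.  Generation is fully deterministic given the
#' config seed; running twice produces byte-identical files.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory (created if needed).
#' @return The ledger, invisibly a list: per-report truth (`reports`),
#'   intended group counts, cardiovascular case/event counts, per-(group,
#'   PT) contingency cells over the clean universe, duplicate bookkeeping
#'   and the expected post-cleaning report count.
#' @export
generate_faers <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_reports
  mr <- config$missing_rates

  groups <- c(names(config$group_shares), NA)
  probs <- c(config$group_shares, 1 - sum(config$group_shares))
  grp <- sample(groups, n, replace = TRUE, prob = probs)

  casenum <- sprintf("%08d", 10000000L + seq_len(n))
  primaryid <- paste0(casenum, "1")

  quarter <- sample(config$quarters, n, replace = TRUE)
  qb <- lapply(config$quarters, quarter_bounds)
  names(qb) <- config$quarters
  fda <- as.Date(vapply(quarter, function(q) {
    b <- qb[[q]]
    as.numeric(b[1]) + floor(runif(1) * (as.numeric(b[2]) - as.numeric(b[1]) + 1))
  }, numeric(1), USE.NAMES = FALSE), origin = "1970-01-01")
  event <- fda - sample(0:60, n, replace = TRUE)

  age_years <- pmin(pmax(round(rnorm(n, 62, 12)), 18), 95)
  age_cod <- sample(c("YR", "DEC", "MON"), n, replace = TRUE,
                    prob = c(0.9, 0.05, 0.05))
  age <- dplyr::case_when(
    age_cod == "YR" ~ as.numeric(age_years),
    age_cod == "DEC" ~ age_years / 10,
    age_cod == "MON" ~ age_years * 12
  )
  drop_age <- runif(n) < mr$age
  age[drop_age] <- NA
  age_cod[drop_age] <- NA

  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.45, 0.55))
  sex[runif(n) < mr$sex] <- NA
  country <- sample(c("US", "IT", "DE", "FR", "GB", "JP", "AU", "BR", "CA", "ES"),
                    n, replace = TRUE,
                    prob = c(0.35, 0.08, 0.1, 0.08, 0.08, 0.1, 0.05, 0.06, 0.05, 0.05))
  country[runif(n) < mr$country] <- NA
  wt <- round(rnorm(n, 78, 15), 1)
  wt[runif(n) < mr$wt] <- NA
  wt_cod <- ifelse(is.na(wt), NA, "KG")
  occp <- sample(c("MD", "CN", "PH", "HP", "OT"), n, replace = TRUE,
                 prob = c(0.4, 0.25, 0.08, 0.12, 0.15))

  is_lit <- runif(n) < config$literature_rate
  rept_cod <- sample(c("EXP", "PER", "DIR"), n, replace = TRUE,
                     prob = c(0.7, 0.2, 0.1))
  rept_cod[is_lit] <- "EXP"
  lit_ref <- ifelse(is_lit, "Literature report reference", NA)

  # --- reactions: independent Bernoulli per catalog PT, odds multiplied
  # for planted (group, pt) pairs; every report ends with >= 1 reaction.
  cat_pt <- config$pt_catalog
  cat_pt$pt_norm <- norm_pt(cat_pt$pt)
  prob_mat <- matrix(rep(cat_pt$rate, each = n), nrow = n)
  if (!is.null(config$planted_signals)) {
    ps_tab <- config$planted_signals
    ps_tab$pt_norm <- norm_pt(ps_tab$pt)
    for (k in seq_len(nrow(ps_tab))) {
      j <- which(cat_pt$pt_norm == ps_tab$pt_norm[k])
      rows <- which(!is.na(grp) & grp == ps_tab$group[k])
      prob_mat[rows, j] <- planted_prob(cat_pt$rate[j], ps_tab$or_mult[k])
    }
  }
  draw <- matrix(runif(n * nrow(cat_pt)), nrow = n) < prob_mat
  # fallback for empty reaction sets: one background PT
  none <- which(rowSums(draw) == 0)
  bg_idx <- which(is.na(cat_pt$smq))
  if (length(none)) {
    fb <- sample(bg_idx, length(none), replace = TRUE,
                 prob = cat_pt$rate[bg_idx])
    draw[cbind(none, fb)] <- TRUE
  }
  hits <- which(draw, arr.ind = TRUE)
  reac_truth <- tibble::tibble(
    report = hits[, 1],
    pt = cat_pt$pt[hits[, 2]],
    smq = cat_pt$smq[hits[, 2]]
  ) %>% dplyr::arrange(.data$report, .data$pt)

  # --- drugs: PS (+SS for combos) for of-interest groups, background PS
  # otherwise, plus concomitants; brand or generic spelling at random.
  bg_cat <- config$drug_catalog
  spell <- function(ing, is_brand) {
    brand <- ifelse(ing %in% names(ingredient_brand),
                    ingredient_brand[ing],
                    bg_cat$brand[match(ing, bg_cat$ingredient)])
    ifelse(is_brand & !is.na(brand), brand, toupper(ing))
  }
  ps_ing <- ifelse(is.na(grp),
                   sample(bg_cat$ingredient, n, replace = TRUE),
                   vapply(grp, function(g)
                     if (is.na(g)) NA_character_ else group_drugs[[g]]$ps,
                     character(1)))
  ss_ing <- vapply(grp, function(g) {
    if (is.na(g) || is.null(group_drugs[[g]]$ss)) NA_character_
    else group_drugs[[g]]$ss
  }, character(1))

  tto_days <- round(rlnorm(n, meanlog = log(unname(
    ifelse(is.na(grp), 30, config$tto_median[grp]))), sdlog = config$tto_sdlog))
  start <- event - tto_days

  n_conc <- rbinom(n, 2, 0.3)
  conc_rows <- rep(seq_len(n), n_conc)

  mk_drug <- function(report, ing, role, seq_no) {
    tibble::tibble(
      report = report, drug_seq = seq_no, role_cod = role, ingredient = ing,
      drugname = spell(ing, runif(length(report)) < 0.5),
      prod_ai = ifelse(runif(length(report)) < mr$prod_ai, NA, toupper(ing))
    )
  }
  drug_truth <- dplyr::bind_rows(
    mk_drug(seq_len(n), ps_ing, "PS", 1L),
    mk_drug(which(!is.na(ss_ing)), ss_ing[!is.na(ss_ing)], "SS", 2L),
    mk_drug(conc_rows, sample(bg_cat$ingredient, length(conc_rows),
                              replace = TRUE), "C",
            3L + unlist(lapply(n_conc[n_conc > 0], seq_len)) - 1L)
  )
  is_invest <- runif(n) < config$investigational_rate
  if (any(is_invest)) {
    inv <- tibble::tibble(
      report = which(is_invest), drug_seq = 9L, role_cod = "C",
      ingredient = NA_character_, drugname = "INVESTIGATIONAL PRODUCT",
      prod_ai = NA_character_)
    drug_truth <- dplyr::bind_rows(drug_truth, inv)
  }
  drug_truth <- dplyr::arrange(drug_truth, .data$report, .data$drug_seq)

  # indications on the PS row
  oi <- !is.na(grp)
  indi_pt <- rep(NA_character_, n)
  u <- runif(n)
  mel_terms <- c("Malignant melanoma", "Melanoma", "Metastatic melanoma")
  indi_pt[oi & u < 0.85] <- sample(mel_terms, sum(oi & u < 0.85), replace = TRUE)
  is_nonmel <- oi & u >= 0.85 & u < 0.85 + config$nonmelanoma_rate
  indi_pt[is_nonmel] <- "Colorectal cancer"
  bg_ind <- c("Hypertension", "Diabetes mellitus", "Depression", "Pain",
              "Gastrooesophageal reflux disease")
  indi_pt[!oi & u < 0.6] <- sample(bg_ind, sum(!oi & u < 0.6), replace = TRUE)

  # therapy start dates (PS drug), partial/missing injection
  start_str <- format(start, "%Y%m%d")
  start_str[runif(n) < mr$start_missing] <- NA

  event_str <- format(event, "%Y%m%d")
  u_ev <- runif(n)
  ev_partial <- u_ev < mr$event_partial
  event_str[ev_partial] <- substr(event_str[ev_partial], 1, 6)
  ev_missing <- u_ev >= mr$event_partial &
    u_ev < mr$event_partial + mr$event_missing
  event_str[ev_missing] <- NA

  # outcomes: 0-2 codes per report
  outc_codes <- lapply(seq_len(n), function(i) {
    k <- sample(0:2, 1, prob = c(0.35, 0.45, 0.2))
    if (k == 0) character(0)
    else sample(c("DE", "LT", "HO", "DS", "OT"), k,
                prob = c(0.08, 0.07, 0.35, 0.05, 0.45))
  })

  demo_truth <- tibble::tibble(
    report = seq_len(n), primaryid = primaryid, caseid = casenum,
    caseversion = "1", fda_dt = format(fda, "%Y%m%d"), event_dt = event_str,
    rept_cod = rept_cod, age = as.character(age), age_cod = age_cod,
    sex = sex, wt = as.character(wt), wt_cod = wt_cod, occp_cod = occp,
    reporter_country = country, occr_country = country, lit_ref = lit_ref,
    quarter = quarter
  )

  # --- ground-truth ledger --------------------------------------------
  smq_tbl <- reac_truth[!is.na(reac_truth$smq), , drop = FALSE]
  excluded_reason <- dplyr::case_when(
    is_lit ~ "literature",
    is_invest ~ "investigational",
    is_nonmel ~ "nonmelanoma_indication",
    TRUE ~ NA_character_
  )
  # indication exclusion only removes reports from the cohort, not the
  # universe; literature/investigational leave the universe entirely.
  out_of_universe <- is_lit | is_invest
  clean <- which(!out_of_universe)

  # --- duplicate injection --------------------------------------------
  n_id_dup <- floor(config$duplicate_id_fraction * n)
  id_dup_of <- if (n_id_dup > 0) sort(sample.int(n, n_id_dup)) else integer(0)

  key_fields_complete <- !is.na(demo_truth$event_dt) & !is.na(sex) &
    !is.na(age) & !is.na(country)
  cand <- which(key_fields_complete)
  n_sim_dup <- min(floor(config$duplicate_similarity_fraction * n),
                   length(cand))
  sim_dup_of <- if (n_sim_dup > 0) sort(sample(cand, n_sim_dup)) else integer(0)

  clone_demo <- function(idx, new_caseid, new_version, new_pid, fda_shift) {
    cl <- demo_truth[idx, , drop = FALSE]
    cl$caseid <- new_caseid
    cl$caseversion <- new_version
    cl$primaryid <- new_pid
    cl$fda_dt <- format(as.Date(cl$fda_dt, "%Y%m%d") + fda_shift, "%Y%m%d")
    cl$orig_report <- idx
    cl
  }
  demo_truth$orig_report <- demo_truth$report
  demo_all <- demo_truth
  if (n_id_dup > 0) {
    demo_all <- dplyr::bind_rows(
      demo_all,
      clone_demo(id_dup_of, casenum[id_dup_of], "2",
                 paste0(casenum[id_dup_of], "2"), 7))
  }
  if (n_sim_dup > 0) {
    new_case <- sprintf("%08d", 20000000L + seq_len(n_sim_dup))
    demo_all <- dplyr::bind_rows(
      demo_all,
      clone_demo(sim_dup_of, new_case, "1", paste0(new_case, "1"), 14))
  }

  # child tables follow the demo rows via orig_report
  expand_child <- function(truth) {
    out <- dplyr::inner_join(demo_all[c("primaryid", "orig_report")],
                             truth, by = c(orig_report = "report"),
                             relationship = "many-to-many")
    out$orig_report <- NULL
    out
  }
  drug_out <- expand_child(drug_truth) %>%
    dplyr::mutate(drug_seq = as.character(.data$drug_seq)) %>%
    dplyr::select(dplyr::all_of(c("primaryid", "drug_seq", "role_cod",
                                  "drugname", "prod_ai")))
  reac_out <- expand_child(reac_truth[c("report", "pt")]) %>%
    dplyr::select(dplyr::all_of(c("primaryid", "pt")))
  indi_out <- expand_child(
    tibble::tibble(report = which(!is.na(indi_pt)),
                   indi_drug_seq = "1", indi_pt = indi_pt[!is.na(indi_pt)]))
  outc_out <- expand_child(
    tibble::tibble(report = rep(seq_len(n), lengths(outc_codes)),
                   outc_cod = unlist(outc_codes)))
  ther_out <- expand_child(
    tibble::tibble(report = which(!is.na(start_str)),
                   dsg_drug_seq = "1",
                   start_dt = start_str[!is.na(start_str)],
                   end_dt = NA_character_))

  demo_out <- demo_all %>%
    dplyr::select(dplyr::all_of(c(
      "primaryid", "caseid", "caseversion", "fda_dt", "event_dt", "rept_cod",
      "age", "age_cod", "sex", "wt", "wt_cod", "occp_cod",
      "reporter_country", "occr_country", "lit_ref", "quarter")))

  # Independently generated reports can coincidentally share a similarity
  # key; under the exact-match rule they merge.  Ledger quantities are
  # computed on the survivor set of that rule, so pipeline recovery is
  # exact whatever the collision pattern.
  mem <- structure(list(
    demo = demo_truth[clean, , drop = FALSE],
    drug = dplyr::inner_join(
      tibble::tibble(primaryid = primaryid[clean], report = clean),
      drug_truth, by = "report") %>%
      dplyr::select(!dplyr::all_of("report")),
    reac = dplyr::inner_join(
      tibble::tibble(primaryid = primaryid[clean], report = clean),
      reac_truth, by = "report") %>%
      dplyr::select(!dplyr::all_of("report")),
    log = log_entry("truth", "in-memory", length(clean))
  ), class = "faers_combined")
  keys <- similarity_keys(mem)
  n_collisions <- sum(!is.na(keys$key)) -
    dplyr::n_distinct(keys$key[!is.na(keys$key)])
  keyed <- dplyr::left_join(mem$demo, keys[c("primaryid", "key")],
                            by = "primaryid")
  surv_pids <- c(keep_most_recent(keyed[!is.na(keyed$key), , drop = FALSE],
                                  "key")$primaryid,
                 keyed$primaryid[is.na(keyed$key)])
  clean_surv <- clean[primaryid[clean] %in% surv_pids]

  is_cae <- seq_len(n) %in% smq_tbl$report
  reports_ledger <- tibble::tibble(
    caseid = casenum, group = grp,
    in_universe = !out_of_universe,
    survives_dedup = seq_len(n) %in% clean_surv,
    in_cohort = oi & !is_nonmel & seq_len(n) %in% clean_surv,
    is_cae = is_cae,
    n_cae_events = as.integer(tabulate(smq_tbl$report, nbins = n)),
    tto_days = ifelse(is.na(event_str) | nchar(event_str %||% "") != 8 |
                        is.na(start_str), NA_integer_, as.integer(tto_days)),
    excluded_reason = excluded_reason, quarter = quarter
  )

  cohort <- reports_ledger$in_cohort
  group_counts <- reports_ledger %>%
    dplyr::filter(.data$in_cohort) %>%
    dplyr::count(.data$group, name = "n_reports")
  cae_cases <- sum(cohort & is_cae)
  cae_events <- sum(reports_ledger$n_cae_events[cohort])
  smq_counts <- smq_tbl %>%
    dplyr::filter(.data$report %in% which(cohort)) %>%
    dplyr::group_by(.data$smq) %>%
    dplyr::summarise(events = dplyr::n(),
                     cases = dplyr::n_distinct(.data$report),
                     .groups = "drop")

  # contingency cells over the clean post-dedup universe, per (group, CV PT)
  cv_pts <- unique(cat_pt$pt[!is.na(cat_pt$smq)])
  cells <- tidyr::expand_grid(group = names(config$group_shares), pt = cv_pts)
  N_clean <- length(clean_surv)
  grp_clean <- ifelse(cohort[clean_surv], grp[clean_surv], NA)
  cells <- cells %>%
    dplyr::mutate(purrr::map2_dfr(.data$group, .data$pt, function(g, p) {
      has_pt <- clean_surv %in% reac_truth$report[reac_truth$pt == p]
      in_g <- !is.na(grp_clean) & grp_clean == g
      a <- sum(in_g & has_pt)
      tibble::tibble(a = a, b = sum(in_g) - a, c = sum(has_pt) - a,
                     d = N_clean - sum(in_g) - sum(has_pt) + a)
    }))

  # --- write quarterly files ------------------------------------------
  for (q in config$quarters) {
    qdir <- file.path(dir, q)
    dir.create(qdir, showWarnings = FALSE, recursive = TRUE)
    tag <- quarter_file_tag(q)
    ids_q <- demo_out$primaryid[demo_out$quarter == q]
    wr <- function(tb, name) {
      readr::write_delim(tb, file.path(qdir, paste0(name, tag, ".txt")),
                         delim = "$", na = "", progress = FALSE)
    }
    wr(demo_out[demo_out$quarter == q,
                setdiff(names(demo_out), "quarter")], "DEMO")
    wr(drug_out[drug_out$primaryid %in% ids_q, ], "DRUG")
    wr(indi_out[indi_out$primaryid %in% ids_q, ], "INDI")
    wr(outc_out[outc_out$primaryid %in% ids_q, ], "OUTC")
    wr(reac_out[reac_out$primaryid %in% ids_q, ], "REAC")
    wr(ther_out[ther_out$primaryid %in% ids_q, ], "THER")
  }

  ledger <- list(
    n_distinct = n,
    n_demo_rows_written = nrow(demo_out),
    n_id_duplicates = n_id_dup,
    n_similarity_duplicates = n_sim_dup,
    n_similarity_collisions = n_collisions,
    n_excluded_literature = sum(is_lit),
    n_excluded_investigational = sum(is_invest & !is_lit),
    n_excluded_nonmelanoma = sum(is_nonmel & !out_of_universe),
    expected_clean_n = length(clean_surv),
    group_counts = group_counts,
    cae_cases = cae_cases,
    cae_events = cae_events,
    smq_counts = smq_counts,
    cells = cells,
    reports = reports_ledger,
    seed = config$seed
  )
  jsonlite::write_json(
    ledger[setdiff(names(ledger), "reports")],
    file.path(dir, "ledger.json"), auto_unbox = TRUE, digits = NA)
  invisible(ledger)
}

#' Generator configuration mirroring the published cohort shape
#'
#' Returns a [sim_config()] whose expected therapy-group shares follow the
#' published report distribution of the BRAF/MEK inhibitor melanoma cohort
#' (D+T 48.4%, E+B 16.9%, V 11.8%, V+C 11.5%, D 4.6%, T 3.8%, C 1.4%,
#' B 0.8%, E 0.7% of 18,370 of-interest reports) and whose expected
#' cardiovascular-case fraction among of-interest reports is 8.7%,
#' obtained by a common odds multiplier on every narrow-SMQ PT.  `scale`
#' scales the of-interest cohort (scale = 1 means 18,370 expected
#' of-interest reports); `background_ratio` controls how many background
#' reports surround them (the published 14-million-report universe is not
#' a desk-scale object, so the comparator size is an explicit choice).
#'
#' @param scale Cohort scale in (0, 1].
#' @param background_ratio Background reports per of-interest report.
#' @param seed Seed passed to [sim_config()].
#' @param ... Further arguments passed to [sim_config()].
#' @return A `sim_config` object.
#' @export
emulate_paper_shape <- function(scale, background_ratio = 4, seed = 1, ...) {
  stopifnot(scale > 0, scale <= 1)
  counts <- c("D+T" = 8895, "E+B" = 3097, "V" = 2174, "V+C" = 2111,
              "D" = 852, "T" = 695, "C" = 263, "B" = 161, "E" = 122)
  n_oi <- round(scale * sum(counts))
  n_bg <- round(background_ratio * n_oi)
  n <- n_oi + n_bg
  shares <- counts / sum(counts) * (n_oi / n)

  pt_catalog <- default_pt_catalog()
  cv <- pt_catalog[!is.na(pt_catalog$smq), , drop = FALSE]
  target <- 0.087
  p_any <- function(m) 1 - prod(1 - planted_prob(cv$rate, m))
  m <- stats::uniroot(function(m) p_any(m) - target, c(1e-6, 1e6),
                      tol = 1e-10)$root
  planted <- tidyr::expand_grid(group = names(counts),
                                pt = unique(cv$pt)) %>%
    dplyr::mutate(or_mult = m)

  sim_config(n_reports = n, group_shares = shares, pt_catalog = pt_catalog,
             planted_signals = planted,
             tto_median = c("D+T" = 30, "V+C" = 30, "E+B" = 12, "V" = 33,
                            "T" = 45, "E" = 1212, "D" = 60, "C" = 30,
                            "B" = 30),
             seed = seed, ...)
}
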