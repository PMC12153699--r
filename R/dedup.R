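# Two-step deduplication of the report universe plus the three exclusion
# filters that define the cleaned denominator of the disproportionality
# analysis.
#
# "Most recent" is resolved by a fixed ladder: highest caseversion, then
# latest fda_dt, then lexicographically largest primaryid, so the result is
# deterministic whatever the input order.

#' Remove duplicate report versions by case identifier
#'
#' FAERS carries every submitted version of a case; each `caseid` group is
#' collapsed to its most recent version (highest `caseversion`, ties broken
#' by latest `fda_dt`, then by lexicographically largest `primaryid`).
#' Groups whose recency fields are all missing fall through the same ladder
#' and retain the largest `primaryid`; their count is logged.
#'
#' @param combined A `faers_combined` object.
#' @return The `faers_combined` object restricted to retained reports, with
#'   a log entry for the number of removed versions.
#' @seealso [dedup_by_similarity()], which must run after this step.
#' @export
dedup_by_ids <- function(combined) {
  stopifnot(inherits(combined, "faers_combined"))
  demo <- combined$demo
  demo$caseid <- blank_to_na(demo$caseid)
  # Reports without a caseid cannot be versioned; they stand alone.
  no_case <- demo[is.na(demo$caseid), , drop = FALSE]
  with_case <- demo[!is.na(demo$caseid), , drop = FALSE]

  all_missing <- with_case %>%
    dplyr::group_by(.data$caseid) %>%
    dplyr::summarise(
      degenerate = all(is.na(blank_to_na(.data$caseversion))) &&
        all(is.na(blank_to_na(.data$fda_dt))),
      .groups = "drop")
  n_degenerate <- sum(all_missing$degenerate)

  kept <- keep_most_recent(with_case, "caseid")
  keep_ids <- c(kept$primaryid, no_case$primaryid)
  n_removed <- nrow(demo) - length(keep_ids)

  combined <- restrict_combined(combined, keep_ids)
  combined <- append_log(combined, "dedup_ids",
                         "duplicate case versions removed", n_removed)
  if (n_degenerate > 0) {
    combined <- append_log(combined, "dedup_ids",
                           "caseid groups with all recency fields missing",
                           n_degenerate)
  }
  combined
}

# Similarity key of a report: event PT multiset, onset date, sex, age,
# reporting country, and the set of suspect (PS/SS) ingredients.  Exact
# equality on all six; a report missing any component can never merge.
similarity_keys <- function(combined, dictionary = default_drug_dictionary()) {
  demo <- combined$demo

  pts <- combined$reac %>%
    dplyr::mutate(pt = norm_pt(.data$pt)) %>%
    dplyr::filter(!is.na(.data$pt)) %>%
    dplyr::group_by(.data$primaryid) %>%
    dplyr::summarise(pt_multiset = paste(sort(.data$pt), collapse = "|"),
                     .groups = "drop")

  suspects <- combined$drug %>%
    dplyr::filter(.data$role_cod %in% c("PS", "SS")) %>%
    dplyr::mutate(
      ing = dplyr::coalesce(
        normalize_drug(.data$drugname, dictionary),
        normalize_drug(if ("prod_ai" %in% names(combined$drug))
          .data$prod_ai else NA_character_, dictionary),
        norm_pt(.data$drugname))
    ) %>%
    dplyr::filter(!is.na(.data$ing)) %>%
    dplyr::group_by(.data$primaryid) %>%
    dplyr::summarise(suspect_set = paste(sort(unique(.data$ing)), collapse = "|"),
                     .groups = "drop")

  age_yrs <- age_to_years(demo$age, demo$age_cod)
  keys <- tibble::tibble(
    primaryid = demo$primaryid,
    onset = blank_to_na(demo$event_dt),
    sex = blank_to_na(demo$sex),
    age = round(age_yrs, 3),
    country = blank_to_na(demo$reporter_country)
  ) %>%
    dplyr::left_join(pts, by = "primaryid") %>%
    dplyr::left_join(suspects, by = "primaryid")

  keys$complete <- !is.na(keys$onset) & !is.na(keys$sex) & !is.na(keys$age) &
    !is.na(keys$country) & !is.na(keys$pt_multiset) & !is.na(keys$suspect_set)
  keys$key <- ifelse(
    keys$complete,
    paste(keys$pt_multiset, keys$onset, keys$sex, keys$age, keys$country,
          keys$suspect_set, sep = "\r"),
    NA_character_)
  keys[c("primaryid", "key", "complete")]
}

#' Remove cross-case clones by report similarity
#'
#' Reports that agree exactly on all six similarity fields -- adverse event
#' PT multiset, onset date, sex, age, reporting country, and suspect
#' (primary/secondary) drug set -- are treated as duplicate submissions of
#' one case and collapsed to the most recent (same recency ladder as
#' [dedup_by_ids()]).  A report with any of the six fields missing never
#' merges.  Run after [dedup_by_ids()].
#'
#' @param combined A `faers_combined` object, already id-deduplicated.
#' @param dictionary Drug-name normalization map used to form the suspect
#'   drug set; see [default_drug_dictionary()].
#' @return The restricted `faers_combined` object with a log entry.
#' @export
dedup_by_similarity <- function(combined,
                                dictionary = default_drug_dictionary()) {
  stopifnot(inherits(combined, "faers_combined"))
  keys <- similarity_keys(combined, dictionary)
  demo <- dplyr::left_join(combined$demo,
                           keys[c("primaryid", "key")], by = "primaryid")
  mergeable <- demo[!is.na(demo$key), , drop = FALSE]
  keep <- keep_most_recent(mergeable, "key")
  keep_ids <- c(keep$primaryid, demo$primaryid[is.na(demo$key)])
  n_removed <- nrow(demo) - length(keep_ids)
  combined <- restrict_combined(combined, keep_ids)
  append_log(combined, "dedup_similarity",
             "similarity duplicates removed", n_removed)
}

# Default token list flagging investigational / blinded / unspecified
# products; case-insensitive fixed substrings.
default_investigational_patterns <- function() {
  c("investigational", "blinded", "unspecified ingredient")
}

#' Apply the three report-level exclusion filters
#'
#' Removes, in order and with separate log counts:
#' \enumerate{
#'   \item premarketing literature reports: non-empty literature-reference
#'     field (`lit_ref`) and, when a report-type column (`rept_cod`) is
#'     present, a type in `premarket_types`;
#'   \item reports naming at least one investigational / blinded /
#'     unspecified product among their drugs (case-insensitive substring
#'     match against `invest_patterns`);
#'   \item the PT \dQuote{no adverse event} is dropped from every report,
#'     and reports left with no reaction are excluded.
#' }
#'
#' @param combined A `faers_combined` object (normally after both dedup
#'   steps).
#' @param premarket_types Report-type codes treated as premarketing
#'   sources when `rept_cod` is available.
#' @param invest_patterns Character patterns identifying non-marketed
#'   products.
#' @param no_ae_pts PTs that state the absence of an adverse event.
#' @return The restricted `faers_combined` object with per-filter log
#'   entries.
#' @export
apply_exclusions <- function(combined,
                             premarket_types = "EXP",
                             invest_patterns = default_investigational_patterns(),
                             no_ae_pts = "no adverse event") {
  stopifnot(inherits(combined, "faers_combined"))
  demo <- combined$demo

  lit <- blank_to_na(demo[["lit_ref"]] %||% rep(NA_character_, nrow(demo)))
  drop_lit <- !is.na(lit)
  if ("rept_cod" %in% names(demo)) {
    drop_lit <- drop_lit & demo$rept_cod %in% premarket_types
  }
  ids_lit <- demo$primaryid[drop_lit]

  dn <- tolower(dplyr::coalesce(blank_to_na(combined$drug$drugname), ""))
  hit <- rep(FALSE, length(dn))
  for (p in invest_patterns) hit <- hit | grepl(p, dn, fixed = TRUE)
  ids_invest <- unique(combined$drug$primaryid[hit])

  reac <- combined$reac
  is_no_ae <- norm_pt(reac$pt) %in% norm_pt(no_ae_pts)
  n_pt_dropped <- sum(is_no_ae)
  had_no_ae <- unique(reac$primaryid[is_no_ae])
  reac <- reac[!is_no_ae, , drop = FALSE]
  combined$reac <- reac
  ids_no_ae <- setdiff(had_no_ae, unique(reac$primaryid))

  keep_ids <- setdiff(demo$primaryid, c(ids_lit, ids_invest, ids_no_ae))
  combined <- restrict_combined(combined, keep_ids)
  combined <- append_log(combined, "exclusion",
                         "premarketing literature reports removed",
                         length(ids_lit))
  combined <- append_log(combined, "exclusion",
                         "reports with investigational/blinded/unspecified products removed",
                         length(intersect(ids_invest, demo$primaryid)))
  combined <- append_log(combined, "exclusion",
                         "'no adverse event' PT rows dropped", n_pt_dropped)
  append_log(combined, "exclusion",
             "reports with no remaining adverse event removed",
             length(ids_no_ae))
}

#' Run the full cleaning sequence on combined tables
#'
#' Convenience wrapper fixing the order of the cleaning pipeline:
#' [dedup_by_ids()], then [dedup_by_similarity()], then
#' [apply_exclusions()].
#'
#' @inheritParams dedup_by_similarity
#' @inheritParams apply_exclusions
#' @return The cleaned `faers_combined` universe; its `log` mirrors the
#'   selection flowchart.
#' @export
clean_universe <- function(combined,
                           dictionary = default_drug_dictionary(),
                           premarket_types = "EXP",
                           invest_patterns = default_investigational_patterns(),
                           no_ae_pts = "no adverse event") {
  combined %>%
    dedup_by_ids() %>%
    dedup_by_similarity(dictionary) %>%
    apply_exclusions(premarket_types, invest_patterns, no_ae_pts)
}
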