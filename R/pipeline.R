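# End-to-end orchestration: quarterly files -> cleaned universe ->
# exposure cohort -> descriptives, time-to-onset and disproportionality.

#' Run the full signal-detection pipeline
#'
#' Reads the quarterly extracts, merges them, cleans the universe (id
#' dedup, similarity dedup, exclusion filters -- in that fixed order),
#' builds the melanoma-restricted exposure cohort, tags cardiovascular
#' cases, and produces the characteristics table, time-to-onset summary
#' and case/non-case disproportionality results.
#'
#' @param root Directory containing one sub-directory per quarter (as
#'   written by [generate_faers()]), or the quarter directory itself when
#'   a single label is given.
#' @param quarters Character vector of quarter labels to read.
#' @param dictionary Drug-name normalization map.
#' @param smqs SMQ definitions.
#' @param melanoma_pts Optional melanoma indication PT list.
#' @param ime_pts,dme_pts,label_map Annotation term lists; see
#'   [annotate_signals()].
#' @param min_n SDR report-count threshold.
#' @param out_dir Optional directory; when given, combined tables, the
#'   characteristics table, TTO summary, signal and log TSVs are written
#'   there.
#' @return List: `universe` (cleaned `faers_combined`), `cases`,
#'   `assignments`, `table1`, `tto`, `signals`, `log`.
#' @export
run_faers_pipeline <- function(root, quarters,
                               dictionary = default_drug_dictionary(),
                               smqs = default_smqs(),
                               melanoma_pts = NULL,
                               ime_pts = character(0),
                               dme_pts = character(0),
                               label_map = list(),
                               min_n = 3,
                               out_dir = NULL) {
  qs <- lapply(quarters, function(q) {
    p <- file.path(root, q)
    if (!dir.exists(p)) p <- root
    read_quarter(p, q)
  })
  universe <- build_combined(qs) %>%
    clean_universe(dictionary)
  cases <- build_cases(universe, dictionary, melanoma_pts, smqs)
  universe <- append_log(universe, "cohort", "reports of interest (melanoma)",
                         nrow(cases))
  universe <- append_log(universe, "cohort", "cardiovascular AE cases",
                         sum(cases$is_cae))
  assignments <- universe_assignments(cases, universe)
  tab1 <- table1(cases, universe)
  tto <- compute_tto(cases, universe, dictionary)
  signals <- run_disproportionality(assignments, universe$reac, smqs,
                                    min_n = min_n, ime_pts = ime_pts,
                                    dme_pts = dme_pts, label_map = label_map)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_combined(universe, out_dir)
    readr::write_tsv(tab1, file.path(out_dir, "table1_all.tsv"),
                     progress = FALSE)
    readr::write_tsv(tto$summary, file.path(out_dir, "tto_summary.tsv"),
                     progress = FALSE)
    write_signals(signals, out_dir)
  }
  list(universe = universe, cases = cases, assignments = assignments,
       table1 = tab1, tto = tto, signals = signals, log = universe$log)
}
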