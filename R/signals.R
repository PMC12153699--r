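# Case/non-case disproportionality: 2x2 contingency tables per
# (therapy group, PT), reporting odds ratios with 95% CIs, the SDR rule,
# IME/DME and label-expectedness annotation, and the CI-inversion audit
# used to verify printed results.

#' Build the 2x2 contingency table for one drug-group/PT pair
#'
#' Cells at report level (a report mentioning the PT twice counts once):
#' `a` reports of the group with the PT, `b` without it, `c` reports
#' outside the group with the PT, `d` all remaining reports.  The
#' comparator is every report of the cleaned universe not assigned to the
#' group.
#'
#' @param group Therapy group code (e.g. `"D+T"`).
#' @param pt Preferred Term (matched case-insensitively).
#' @param assignments Tibble `primaryid`, `group` covering the whole
#'   cleaned universe (`group` is `NA` for unexposed reports).
#' @param reac Reaction table (`primaryid`, `pt`) of the same universe.
#' @return One-row tibble with `a`, `b`, `c`, `d`.
#' @export
build_table <- function(group, pt, assignments, reac) {
  pt_ids <- unique(reac$primaryid[norm_pt(reac$pt) %in% norm_pt(pt)])
  in_group <- !is.na(assignments$group) & assignments$group == group
  grp_ids <- assignments$primaryid[in_group]
  N <- nrow(assignments)
  a <- sum(grp_ids %in% pt_ids)
  b <- length(grp_ids) - a
  c_ <- length(intersect(pt_ids, assignments$primaryid)) - a
  d <- N - a - b - c_
  tibble::tibble(a = a, b = b, c = c_, d = d)
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = (a d)/(b c)`; the CI comes from the log-normal approximation
#' `exp(log ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`.  Tables containing a
#' zero cell get the Haldane-Anscombe correction (+0.5 on every cell) and
#' are flagged `corrected`.
#'
#' @param a,b,c,d Cell counts (vectorized).
#' @param z Normal quantile for the interval (default `1.959964`, the
#'   two-sided 95% level).
#' @return Tibble with `ror`, `ci_low`, `ci_high`, `corrected`.
#' @examples
#' ror_ci(1, 1, 1, 1)            # ROR 1, CI exp(-/+ 2 z)
#' ror_ci(4, 8891, 252, 14067920)  # approx 25.12 (9.35-67.45)
#' @export
ror_ci <- function(a, b, c, d, z = 1.959964) {
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  a2 <- a + 0.5 * corrected
  b2 <- b + 0.5 * corrected
  c2 <- c + 0.5 * corrected
  d2 <- d + 0.5 * corrected
  ror <- (a2 * d2) / (b2 * c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  tibble::tibble(
    ror = ror,
    ci_low = exp(log(ror) - z * se),
    ci_high = exp(log(ror) + z * se),
    corrected = corrected
  )
}

#' Reconstruct a 2x2 table from a printed (n, ROR) pair
#'
#' Audit oracle for published disproportionality tables that print only the
#' case count and the ROR.  Given `a`, the group total and the universe
#' size, the comparator cell follows in closed form from
#' `ROR = (a d)/(b c)` with `c + d` fixed:
#' `c = a (N - G) / (ROR b + a)`, rounded to the nearest integer.  The
#' recomputed ROR must match the printed one within `tol` (relative) or
#' the audit fails.
#'
#' @param a Reports of the group with the PT (>= 1).
#' @param group_total Total reports of the group (> a).
#' @param universe_n Universe size (> group_total).
#' @param ror_printed Published ROR (> 0).
#' @param tol Relative tolerance for the recomputed ROR (default 1%).
#' @return One-row tibble `a`, `b`, `c`, `d`, `ror_recomputed`, `ok`.
#' @examples
#' invert_ror(4, 8895, 14077067, 25.12)  # solves c = 252
#' @export
invert_ror <- function(a, group_total, universe_n, ror_printed, tol = 0.01) {
  stopifnot(a >= 1, group_total > a, universe_n > group_total,
            ror_printed > 0)
  b <- group_total - a
  M <- universe_n - group_total  # c + d
  c_ <- round(a * M / (ror_printed * b + a))
  if (c_ < 1 || c_ >= M) {
    return(tibble::tibble(a = a, b = b, c = c_, d = M - c_,
                          ror_recomputed = NA_real_, ok = FALSE))
  }
  d <- M - c_
  ror_hat <- (a * d) / (b * c_)
  tibble::tibble(a = a, b = b, c = c_, d = d, ror_recomputed = ror_hat,
                 ok = abs(ror_hat / ror_printed - 1) <= tol)
}

#' Flag signals of disproportionate reporting
#'
#' A drug-event pair is an SDR when the lower 95% CI bound of its ROR
#' exceeds 1 and the pair has at least `min_n` reports.  Zero-cell
#' (corrected) results are eligible under the same rule; with `a = 0` the
#' report count is below any sensible threshold, so they never qualify.
#'
#' @param results Tibble with columns `n` (= cell a) and `ci_low`.
#' @param min_n Minimum report count (default 3).
#' @return `results` with a logical `is_sdr` column.
#' @export
detect_sdrs <- function(results, min_n = 3) {
  dplyr::mutate(results,
                is_sdr = .data$ci_low > 1 & .data$n >= min_n)
}

#' Annotate signals with IME/DME membership and label expectedness
#'
#' PT membership is case-insensitive after whitespace normalization.
#' \dQuote{Clinically relevant} in the outputs means IME membership.  An
#' event is expected when it appears in the label (expected-reaction) list
#' of its therapy group; with no list for a group, all its events are
#' unexpected.
#'
#' @param results Signal tibble with columns `pt` and `group`.
#' @param ime_pts Character vector of Important Medical Event PTs.
#' @param dme_pts Character vector of Designated Medical Event PTs.
#' @param label_map Named list: therapy group code -> character vector of
#'   labeled (expected) PTs.
#' @return `results` with logical `is_ime`, `is_dme`, `expected` columns.
#' @export
annotate_signals <- function(results, ime_pts = character(0),
                             dme_pts = character(0), label_map = list()) {
  ptn <- norm_pt(results$pt)
  expected <- purrr::map2_lgl(results$group, ptn, function(g, p) {
    lbl <- label_map[[g]]
    !is.null(lbl) && p %in% norm_pt(lbl)
  })
  dplyr::mutate(results,
                is_ime = ptn %in% norm_pt(ime_pts),
                is_dme = ptn %in% norm_pt(dme_pts),
                expected = expected)
}

#' Case/non-case disproportionality over the SMQ scope
#'
#' For every therapy group present and every narrow-SMQ PT observed in the
#' universe, builds the report-level 2x2 table against all other reports,
#' computes the ROR with 95% CI, applies the SDR rule and annotates
#' IME/DME membership and expectedness.  The number of tested pairs is
#' attached as attribute `"n_tests"` (no multiplicity adjustment is
#' applied; adjust post hoc if desired).
#'
#' @param assignments Universe-wide group assignments: tibble `primaryid`,
#'   `group` (`NA` for reports outside every group).  Use
#'   [universe_assignments()] to build it from cases + universe.
#' @param reac Reaction table of the same universe.
#' @param smqs SMQ definitions bounding the tested PTs.
#' @param min_n SDR report-count threshold.
#' @inheritParams annotate_signals
#' @param z Normal quantile for the CI.
#' @return Tibble: `group`, `smq`, `pt`, `a`, `b`, `c`, `d`, `n`, `ror`,
#'   `ci_low`, `ci_high`, `corrected`, `is_sdr`, `is_ime`, `is_dme`,
#'   `expected` -- the machine twin of a published SDR table.
#' @export
run_disproportionality <- function(assignments, reac, smqs = default_smqs(),
                                   min_n = 3, ime_pts = character(0),
                                   dme_pts = character(0), label_map = list(),
                                   z = 1.959964) {
  lu <- smq_lookup(smqs)
  N <- nrow(assignments)
  groups <- sort(unique(assignments$group[!is.na(assignments$group)]))

  hits <- reac %>%
    dplyr::mutate(pt_norm = norm_pt(.data$pt)) %>%
    dplyr::filter(.data$pt_norm %in% lu$pt_norm) %>%
    dplyr::distinct(.data$primaryid, .data$pt_norm) %>%
    dplyr::left_join(assignments, by = "primaryid")

  pt_totals <- hits %>% dplyr::count(.data$pt_norm, name = "pt_total")
  group_totals <- assignments %>%
    dplyr::filter(!is.na(.data$group)) %>%
    dplyr::count(.data$group, name = "group_total")

  cells <- hits %>%
    dplyr::filter(!is.na(.data$group)) %>%
    dplyr::count(.data$group, .data$pt_norm, name = "a") %>%
    # every (group, observed PT) pair, including a = 0 ones
    tidyr::complete(group = groups, pt_norm = unique(lu$pt_norm),
                    fill = list(a = 0L)) %>%
    dplyr::filter(.data$pt_norm %in% hits$pt_norm) %>%
    dplyr::left_join(pt_totals, by = "pt_norm") %>%
    dplyr::left_join(group_totals, by = "group") %>%
    dplyr::mutate(
      b = .data$group_total - .data$a,
      c = .data$pt_total - .data$a,
      d = N - .data$a - .data$b - .data$c
    )

  res <- dplyr::bind_cols(
    cells,
    ror_ci(cells$a, cells$b, cells$c, cells$d, z = z)
  ) %>%
    dplyr::left_join(lu, by = "pt_norm", relationship = "many-to-many") %>%
    dplyr::mutate(n = .data$a, pt = .data$pt_norm) %>%
    dplyr::select(dplyr::all_of(c(
      "group", "smq", "pt", "a", "b", "c", "d", "n", "ror",
      "ci_low", "ci_high", "corrected"))) %>%
    detect_sdrs(min_n = min_n) %>%
    annotate_signals(ime_pts, dme_pts, label_map) %>%
    dplyr::arrange(.data$group, .data$smq, .data$pt)
  attr(res, "n_tests") <- nrow(dplyr::distinct(res, .data$group, .data$pt))
  res
}

#' Universe-wide group assignments
#'
#' Expands a case table to the full cleaned universe, with `NA` group for
#' every report not in the exposure cohort -- the comparator of the
#' case/non-case analysis.
#'
#' @param cases Output of [build_cases()].
#' @param combined Cleaned `faers_combined` universe.
#' @return Tibble `primaryid`, `group` with one row per universe report.
#' @export
universe_assignments <- function(cases, combined) {
  tibble::tibble(primaryid = combined$demo$primaryid) %>%
    dplyr::left_join(cases[c("primaryid", "group")], by = "primaryid")
}

#' Audit printed disproportionality rows against recomputed CIs
#'
#' For published rows with a full (n, ROR, CI) triplet, reconstructs the
#' 2x2 table with [invert_ror()] and recomputes the 95% CI; a row passes
#' when the recomputed ROR is within 1% of the printed one and both CI
#' bounds agree with the printed values within 0.02 on the log scale.
#' `low_exact`/`high_exact` additionally report agreement at the printed
#' precision, which the printed ROR's own rounding cannot always support.
#'
#' @param rows Tibble with columns `n`, `ror`, `ci_low`, `ci_high`,
#'   `group_total`.
#' @param universe_n Universe size used for reconstruction.
#' @param z Normal quantile for the CI.
#' @return `rows` plus solved `c`, recomputed `ror_hat`, `ci_low_hat`,
#'   `ci_high_hat` and a logical `pass` -- the audit table.
#' @export
audit_printed_signals <- function(rows, universe_n, z = 1.959964) {
  printed_decimals <- function(x) {
    s <- sub("0+$", "", sub("^[^.]*\\.?", "", format(x, scientific = FALSE)))
    nchar(s)
  }
  out <- purrr::pmap_dfr(rows, function(n, ror, ci_low, ci_high,
                                        group_total, ...) {
    inv <- invert_ror(n, group_total, universe_n, ror)
    ci <- ror_ci(inv$a, inv$b, inv$c, inv$d, z = z)
    exact <- function(hat, printed) {
      round(hat, printed_decimals(printed)) == printed
    }
    tibble::tibble(
      n = n, ror = ror, ci_low = ci_low, ci_high = ci_high,
      group_total = group_total, c = inv$c,
      ror_hat = ci$ror, ci_low_hat = ci$ci_low, ci_high_hat = ci$ci_high,
      low_exact = exact(ci$ci_low, ci_low),
      high_exact = exact(ci$ci_high, ci_high),
      pass = inv$ok && abs(log(ci$ci_low) - log(ci_low)) <= 0.02 &&
        abs(log(ci$ci_high) - log(ci_high)) <= 0.02
    )
  })
  out
}

#' Write the signal and audit tables as TSV
#'
#' `signals.tsv` carries the full disproportionality output (ROR/CI
#' rounded to 2 decimals); `audit.tsv`, when an audit table is supplied,
#' the printed-triplet reconstruction results.
#'
#' @param signals Output of [run_disproportionality()].
#' @param dir Output directory.
#' @param audit Optional output of [audit_printed_signals()].
#' @return Invisibly, the files written.
#' @export
write_signals <- function(signals, dir, audit = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- signals %>%
    dplyr::mutate(dplyr::across(dplyr::all_of(c("ror", "ci_low", "ci_high")),
                                ~ round(.x, 2)))
  f <- file.path(dir, "signals.tsv")
  readr::write_tsv(out, f, progress = FALSE)
  files <- f
  if (!is.null(audit)) {
    f2 <- file.path(dir, "audit.tsv")
    readr::write_tsv(audit, f2, progress = FALSE)
    files <- c(files, f2)
  }
  invisible(files)
}
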