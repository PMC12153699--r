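test_that("contingency cells enumerate a four-report universe", {
  assignments <- tibble::tibble(primaryid = as.character(1:4),
                                group = c("D", "D", NA, NA))
  reac <- mk_reac(c("1", "3"), "Atrial fibrillation")
  tab <- build_table("D", "Atrial fibrillation", assignments, reac)
  expect_equal(unlist(tab), c(a = 1, b = 1, c = 1, d = 1))
  # report-level counting: a duplicated PT on one report counts once
  reac2 <- mk_reac(c("1", "1", "3"), "Atrial fibrillation")
  expect_equal(build_table("D", "Atrial fibrillation", assignments, reac2)$a, 1)
  # a PT confined to the group leaves c = 0
  tab0 <- build_table("D", "Atrial fibrillation", assignments,
                      mk_reac("1", "Atrial fibrillation"))
  expect_equal(tab0$c, 0)
  # absent group: all group cells zero
  tabx <- build_table("E+B", "Atrial fibrillation", assignments, reac)
  expect_equal(tabx$a + tabx$b, 0)
})

test_that("ROR and CI match the closed form", {
  r <- ror_ci(1, 1, 1, 1)
  expect_equal(r$ror, 1)
  expect_equal(r$ci_low, exp(-2 * 1.959964))
  expect_equal(r$ci_high, exp(2 * 1.959964))
  expect_false(r$corrected)

  # published bradyarrhythmia row reconstructed from its printed inputs
  r2 <- ror_ci(4, 8891, 252, 14067920)
  expect_equal(round(r2$ror, 2), 25.12)
  expect_equal(round(r2$ci_low, 2), 9.35)
  expect_equal(round(r2$ci_high, 2), 67.45)
  r3 <- ror_ci(59, 8836, 18431, 14049741)
  expect_equal(round(r3$ror, 2), 5.09)
  expect_equal(round(r3$ci_low, 2), 3.94)
  expect_equal(round(r3$ci_high, 2), 6.58)
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  r <- ror_ci(3, 10, 0, 20)
  expect_true(r$corrected)
  expect_equal(r$ror, (3.5 * 20.5) / (10.5 * 0.5))
  expect_true(is.finite(r$ci_low) && is.finite(r$ci_high))
  expect_false(ror_ci(3, 10, 1, 20)$corrected)
})

test_that("ROR obeys the symmetry and scaling invariances", {
  set.seed(4)
  for (i in 1:20) {
    cells <- sample(1:500, 4)
    r <- ror_ci(cells[1], cells[2], cells[3], cells[4])
    rswap <- ror_ci(cells[3], cells[4], cells[1], cells[2])
    expect_equal(r$ror, 1 / rswap$ror)
    k <- sample(2:5, 1)
    expect_equal(ror_ci(k * cells[1], k * cells[2], k * cells[3],
                        k * cells[4])$ror, r$ror)
    expect_true(r$ci_low <= r$ror && r$ror <= r$ci_high)
  }
})

test_that("ROR equals the brute-force odds ratio on small universes", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(20:100, 1)
    ids <- as.character(seq_len(n))
    assignments <- tibble::tibble(
      primaryid = ids,
      group = sample(c("D+T", NA), n, TRUE, prob = c(0.3, 0.7)))
    reac <- mk_reac(sample(ids, n, TRUE),
                    sample(c("Atrial fibrillation", "Nausea"), n, TRUE))
    tab <- build_table("D+T", "Atrial fibrillation", assignments, reac)
    # independent oracle: exhaustive per-report classification
    has_pt <- vapply(ids, function(id)
      any(reac$pt[reac$primaryid == id] == "Atrial fibrillation"), logical(1))
    in_g <- !is.na(assignments$group)
    a <- sum(in_g & has_pt); b <- sum(in_g & !has_pt)
    cc <- sum(!in_g & has_pt); d <- sum(!in_g & !has_pt)
    expect_equal(unlist(tab), c(a = a, b = b, c = cc, d = d))
    if (all(c(a, b, cc, d) > 0)) {
      expect_equal(ror_ci(tab$a, tab$b, tab$c, tab$d)$ror,
                   (a / b) / (cc / d))
    }
  }
})

test_that("printed-table inversion solves the comparator cell in closed form", {
  inv <- invert_ror(4, 8895, 14077067, 25.12)
  expect_equal(inv$c, 252)
  expect_true(inv$ok)
  # symmetric miniature table
  inv2 <- invert_ror(1, 2, 4, 1.0)
  expect_equal(unlist(inv2[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 1))
  # published myocarditis row: recomputed CI brackets the printed interval
  inv3 <- invert_ror(10, 2111, 14077067, 10.26)
  ci3 <- ror_ci(inv3$a, inv3$b, inv3$c, inv3$d)
  expect_equal(round(ci3$ci_low, 2), 5.51)
  expect_equal(round(ci3$ci_high, 1), 19.1)
  # infeasible request reports failure instead of inventing a table
  expect_false(invert_ror(5, 10, 20, 1e6)$ok)
})

test_that("the SDR rule requires ci_low > 1 and at least three reports", {
  res <- tibble::tibble(
    n = c(4, 2, 10, 3),
    ci_low = c(9.35, 5.0, 0.8, 1.0001))
  out <- detect_sdrs(res)
  expect_equal(out$is_sdr, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("SDR detection is monotone in ci_low and n", {
  grid <- tidyr::expand_grid(n = 0:6, ci_low = c(0.5, 0.99, 1.001, 2, 10))
  out <- detect_sdrs(grid)
  for (nn in unique(grid$n)) {
    flags <- out$is_sdr[out$n == nn][order(unique(grid$ci_low))]
    expect_true(all(diff(as.integer(flags)) >= 0))
  }
  for (cl in unique(grid$ci_low)) {
    flags <- out$is_sdr[out$ci_low == cl][order(unique(grid$n))]
    expect_true(all(diff(as.integer(flags)) >= 0))
  }
})

test_that("annotation flags IME/DME membership and label expectedness", {
  res <- tibble::tibble(
    group = c("D+T", "D+T", "V"),
    pt = c("electrocardiogram qt prolonged",
           "atrioventricular block complete", "pericarditis"))
  out <- annotate_signals(
    res,
    ime_pts = c("Electrocardiogram QT prolonged", "Pericarditis"),
    dme_pts = "Pericarditis",
    label_map = list("D+T" = "Atrioventricular block complete"))
  expect_equal(out$is_ime, c(TRUE, FALSE, TRUE))
  expect_equal(out$is_dme, c(FALSE, FALSE, TRUE))
  # QT prolongation absent from the D+T label list -> unexpected
  expect_equal(out$expected, c(FALSE, TRUE, FALSE))
})

test_that("disproportionality cells on synthetic data equal the ledger", {
  cfg <- sim_config(n_reports = 4000, quarters = "2020q1", seed = 19,
                    group_shares = c("D+T" = 0.15, "V+C" = 0.05),
                    pt_catalog = default_pt_catalog(cv_rate = 0.01),
                    planted_signals = tibble::tibble(
                      group = "D+T", pt = "Atrial fibrillation",
                      or_mult = 4))
  dir <- tempfile()
  led <- generate_faers(cfg, dir)
  res <- run_faers_pipeline(dir, cfg$quarters)
  sig <- res$signals
  led_cells <- led$cells
  led_cells$pt <- faersignal:::norm_pt(led_cells$pt)
  cmp <- dplyr::inner_join(
    dplyr::distinct(sig, group, pt, a, b, c, d),
    led_cells, by = c("group", "pt"), suffix = c("", ".led"))
  expect_gt(nrow(cmp), 10)
  expect_equal(cmp$a, cmp$a.led)
  expect_equal(cmp$b, cmp$b.led)
  expect_equal(cmp$c, cmp$c.led)
  expect_equal(cmp$d, cmp$d.led)
  expect_equal(attr(sig, "n_tests"),
               nrow(dplyr::distinct(sig, group, pt)))
})
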