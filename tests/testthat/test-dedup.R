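test_that("id dedup keeps the most recent case version", {
  demo <- dplyr::bind_rows(
    mk_demo("1001", caseid = "C1", caseversion = "1"),
    mk_demo("10012", caseid = "C1", caseversion = "2"))
  out <- dedup_by_ids(mk_combined(demo))
  expect_equal(out$demo$primaryid, "10012")
  expect_equal(out$log$n[out$log$step == "dedup_ids"][1], 1L)
})

test_that("id dedup tie-breaks by fda_dt then largest primaryid", {
  demo <- dplyr::bind_rows(
    mk_demo("5", caseid = "C1", caseversion = "2", fda_dt = "20190301"),
    mk_demo("3", caseid = "C1", caseversion = "2", fda_dt = "20190101"))
  expect_equal(dedup_by_ids(mk_combined(demo))$demo$primaryid, "5")
  demo2 <- dplyr::bind_rows(
    mk_demo("3", caseid = "C1", caseversion = "2", fda_dt = "20190301"),
    mk_demo("5", caseid = "C1", caseversion = "2", fda_dt = "20190301"))
  expect_equal(dedup_by_ids(mk_combined(demo2))$demo$primaryid, "5")
  # all recency fields missing: largest primaryid survives, logged
  demo3 <- dplyr::bind_rows(
    mk_demo("3", caseid = "C1", caseversion = NA, fda_dt = NA),
    mk_demo("5", caseid = "C1", caseversion = NA, fda_dt = NA))
  out3 <- dedup_by_ids(mk_combined(demo3))
  expect_equal(out3$demo$primaryid, "5")
  expect_true(any(grepl("missing", out3$log$detail)))
})

test_that("a single report passes through id dedup unchanged", {
  cmb <- mk_combined(mk_demo("1"))
  expect_equal(dedup_by_ids(cmb)$demo$primaryid, "1")
})

test_that("similarity dedup merges exact six-field matches only", {
  base <- function(pid, caseid, age = "60") {
    mk_demo(pid, caseid = caseid, age = age)
  }
  demo <- dplyr::bind_rows(base("1", "C1"), base("2", "C2"))
  cmb <- mk_combined(demo,
                     drug = mk_drug(c("1", "2"), c("TAFINLAR", "TAFINLAR")),
                     reac = mk_reac(c("1", "2"), c("Nausea", "Nausea")))
  out <- dedup_by_similarity(cmb)
  expect_equal(nrow(out$demo), 1)

  # any missing key field blocks merging, even if everything else matches
  demo_na <- dplyr::bind_rows(base("1", "C1"), base("2", "C2", age = NA))
  cmb_na <- mk_combined(demo_na,
                        drug = mk_drug(c("1", "2"), c("TAFINLAR", "TAFINLAR")),
                        reac = mk_reac(c("1", "2"), c("Nausea", "Nausea")))
  expect_equal(nrow(dedup_by_similarity(cmb_na)$demo), 2)

  # differing PT multisets block merging
  cmb_pt <- mk_combined(demo,
                        drug = mk_drug(c("1", "2"), c("TAFINLAR", "TAFINLAR")),
                        reac = mk_reac(c("1", "2"), c("Nausea", "Rash")))
  expect_equal(nrow(dedup_by_similarity(cmb_pt)$demo), 2)
})

test_that("both dedup steps are idempotent and monotone", {
  cfg <- sim_config(n_reports = 300, quarters = "2019q1", seed = 5,
                    duplicate_id_fraction = 0.15,
                    duplicate_similarity_fraction = 0.1)
  dir <- tempfile()
  generate_faers(cfg, dir)
  cmb <- build_combined(list(read_quarter(file.path(dir, "2019q1"), "2019q1")))
  once_id <- dedup_by_ids(cmb)
  twice_id <- dedup_by_ids(once_id)
  expect_setequal(once_id$demo$primaryid, twice_id$demo$primaryid)
  once_sim <- dedup_by_similarity(once_id)
  twice_sim <- dedup_by_similarity(once_sim)
  expect_setequal(once_sim$demo$primaryid, twice_sim$demo$primaryid)
  # monotone: each step's survivors are a subset of its input
  expect_true(all(once_id$demo$primaryid %in% cmb$demo$primaryid))
  expect_true(all(once_sim$demo$primaryid %in% once_id$demo$primaryid))
})

test_that("cleaning pipeline runs id dedup before similarity dedup", {
  cmb <- mk_combined(mk_demo("1"))
  out <- clean_universe(cmb)
  steps <- out$log$step[out$log$step %in% c("dedup_ids", "dedup_similarity")]
  expect_equal(steps[1], "dedup_ids")
  expect_equal(steps[2], "dedup_similarity")
})

test_that("exclusion filters remove the stated report classes", {
  # (ii) investigational product
  demo <- dplyr::bind_rows(mk_demo("1"), mk_demo("2"))
  cmb <- mk_combined(demo,
                     drug = mk_drug(c("1", "2"),
                                    c("INVESTIGATIONAL PRODUCT", "TAFINLAR")),
                     reac = mk_reac(c("1", "2"), c("Nausea", "Rash")))
  out <- apply_exclusions(cmb)
  expect_equal(out$demo$primaryid, "2")

  # (iii) 'no adverse event' dropped as PT; pure no-AE reports excluded
  demo2 <- dplyr::bind_rows(mk_demo("1"), mk_demo("2"))
  cmb2 <- mk_combined(demo2,
                      drug = mk_drug(c("1", "2"), c("TAFINLAR", "TAFINLAR")),
                      reac = mk_reac(c("1", "2", "2"),
                                     c("No adverse event", "No adverse event",
                                       "Atrial fibrillation")))
  out2 <- apply_exclusions(cmb2)
  expect_equal(out2$demo$primaryid, "2")
  expect_equal(out2$reac$pt, "Atrial fibrillation")

  # (i) literature premarketing reports, gated on report type when present
  demo3 <- dplyr::bind_rows(
    mk_demo("1", lit_ref = "Smith et al.", rept_cod = "EXP"),
    mk_demo("2", lit_ref = "Jones et al.", rept_cod = "DIR"),
    mk_demo("3", rept_cod = "EXP"))
  cmb3 <- mk_combined(demo3, drug = mk_drug(c("1", "2", "3"), "TAFINLAR"),
                      reac = mk_reac(c("1", "2", "3"), "Nausea"))
  out3 <- apply_exclusions(cmb3)
  expect_setequal(out3$demo$primaryid, c("2", "3"))
})

test_that("a labelled ten-report fixture keeps exactly the seven clean ones", {
  demo <- dplyr::bind_rows(lapply(as.character(1:10), mk_demo))
  demo$lit_ref[1] <- "Literature ref"
  demo$rept_cod <- c("EXP", rep("DIR", 9))
  drugnames <- rep("TAFINLAR", 10)
  drugnames[2] <- "BLINDED THERAPY"
  pts <- rep("Nausea", 10)
  pts[3] <- "No adverse event"
  cmb <- mk_combined(demo, drug = mk_drug(as.character(1:10), drugnames),
                     reac = mk_reac(as.character(1:10), pts))
  out <- apply_exclusions(cmb)
  expect_equal(nrow(out$demo), 7)
  expect_setequal(out$demo$primaryid, as.character(4:10))
})

test_that("post-dedup counts equal the generator ledger under injected duplicates", {
  cfg <- sim_config(n_reports = 1000, quarters = c("2019q1", "2019q2"),
                    seed = 21, duplicate_id_fraction = 0.1,
                    duplicate_similarity_fraction = 0.05)
  dir <- tempfile()
  led <- generate_faers(cfg, dir)
  expect_equal(led$n_demo_rows_written, 1000 + 100 + 50)
  qs <- lapply(cfg$quarters, function(q)
    read_quarter(file.path(dir, q), q))
  out <- clean_universe(build_combined(qs))
  expect_equal(nrow(out$demo), led$expected_clean_n)
})
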