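test_that("drug-name normalization handles brands, salts and unknowns", {
  expect_equal(normalize_drug("TAFINLAR"), "dabrafenib")
  expect_equal(normalize_drug("Dabrafenib Mesylate"), "dabrafenib")
  expect_equal(normalize_drug("Trametinib Dimethyl Sulfoxide"), "trametinib")
  expect_equal(normalize_drug("MEKINIST (trametinib)"), "trametinib")
  expect_true(is.na(normalize_drug("ASPIRIN")))
  expect_equal(normalize_drug(c("ZELBORAF", "cotellic", "BRAFTOVI", "Mektovi")),
               c("vemurafenib", "cobimetinib", "encorafenib", "binimetinib"))
})

test_that("suspect-role rules assign combination, monotherapy or no group", {
  drug <- dplyr::bind_rows(
    mk_drug("1", "TAFINLAR", "PS", "1"),
    mk_drug("1", "MEKINIST", "SS", "2"),          # approved pair -> D+T
    mk_drug("2", "ZELBORAF", "PS", "1"),
    mk_drug("2", "ATORVASTATIN", "C", "2"),       # lone PS -> V
    mk_drug("3", "TAFINLAR", "PS", "1"),
    mk_drug("3", "MEKTOVI", "SS", "2"),           # non-approved pair -> none
    mk_drug("4", "TAFINLAR", "PS", "1"),
    mk_drug("4", "ZELBORAF", "PS", "2"),          # conflicting PS -> none
    mk_drug("5", "MEKINIST", "C", "1"),           # only concomitant -> no row
    mk_drug("6", "COTELLIC", "PS", "1"),
    mk_drug("6", "ZELBORAF", "SS", "2"))          # MEKi PS, partner SS -> V+C
  got <- classify_exposure(drug)
  lookup <- stats::setNames(got$group, got$primaryid)
  expect_equal(unname(lookup["1"]), "D+T")
  expect_equal(unname(lookup["2"]), "V")
  expect_true(is.na(lookup["3"]))
  expect_true(is.na(lookup["4"]))
  expect_false("5" %in% got$primaryid)
  expect_equal(unname(lookup["6"]), "V+C")
})

test_that("exposure classification partitions every report into at most one group", {
  cfg <- sim_config(n_reports = 2000, quarters = "2019q1", seed = 3,
                    group_shares = c("D+T" = 0.1, "V+C" = 0.05, "V" = 0.05,
                                     "E+B" = 0.05, "B" = 0.02))
  dir <- tempfile()
  generate_faers(cfg, dir)
  cmb <- build_combined(list(read_quarter(file.path(dir, "2019q1"), "2019q1")))
  got <- classify_exposure(cmb$drug)
  expect_equal(anyDuplicated(got$primaryid), 0)
  expect_true(all(is.na(got$group) |
                    got$group %in% therapy_groups()$code))
})

test_that("indication filter excludes stated non-melanoma suspects only", {
  assignments <- tibble::tibble(primaryid = c("1", "2", "3"),
                                group = c("D", "D", "D"))
  drug <- dplyr::bind_rows(
    mk_drug("1", "TAFINLAR", "PS", indi_pt = "Malignant melanoma"),
    mk_drug("2", "TAFINLAR", "PS", indi_pt = "Colorectal cancer"),
    mk_drug("3", "TAFINLAR", "PS", indi_pt = NA))
  out <- filter_indication(assignments, drug)
  expect_setequal(out$primaryid, c("1", "3"))
  expect_equal(attr(out, "excluded"), "2")
  # a non-melanoma indication on a concomitant drug does not exclude
  drug2 <- dplyr::bind_rows(
    mk_drug("1", "TAFINLAR", "PS", indi_pt = "Malignant melanoma"),
    mk_drug("1", "ATORVASTATIN", "C", "2", indi_pt = "Hypertension"))
  expect_equal(filter_indication(assignments[1, ], drug2)$primaryid, "1")
})

test_that("narrow-SMQ tagging hits per (SMQ, PT) and respects case", {
  smqs <- fixture_smqs()
  hits <- tag_cae(mk_reac("1", "ATRIAL  Fibrillation"), smqs)
  # shared PT belongs to both fixture SMQs -> two hits, one case
  expect_equal(nrow(hits), 2)
  expect_equal(dplyr::n_distinct(hits$primaryid), 1)
  expect_equal(nrow(tag_cae(mk_reac("1", "Nausea"), smqs)), 0)
})

test_that("removing a PT from every SMQ never increases case counts", {
  set.seed(9)
  pts <- c("Atrial fibrillation", "Sinus tachycardia", "Pulmonary embolism",
           "Nausea", "Rash")
  reac <- mk_reac(as.character(sample(1:200, 400, TRUE)),
                  sample(pts, 400, TRUE))
  full <- fixture_smqs()
  reduced <- list(
    Tachy = smq_definition("Tachyarrhythmias (fixture)",
                           "Sinus tachycardia", "fixture"),
    Emb = smq_definition("Embolic and thrombotic events (fixture)",
                         "Pulmonary embolism", "fixture"))
  n_cases <- function(smqs) dplyr::n_distinct(tag_cae(reac, smqs)$primaryid)
  expect_lte(n_cases(reduced), n_cases(full))
  per_smq_full <- dplyr::count(tag_cae(reac, full), smq)
  per_smq_red <- dplyr::count(tag_cae(reac, reduced), smq)
  both <- dplyr::inner_join(per_smq_full, per_smq_red, by = "smq")
  expect_true(all(both$n.y <= both$n.x))
})

test_that("case and event counts on synthetic data match the generator ledger", {
  cfg <- sim_config(n_reports = 3000, quarters = "2019q1", seed = 17,
                    group_shares = c("D+T" = 0.2, "V" = 0.1),
                    pt_catalog = default_pt_catalog(cv_rate = 0.01))
  dir <- tempfile()
  led <- generate_faers(cfg, dir)
  cmb <- clean_universe(
    build_combined(list(read_quarter(file.path(dir, "2019q1"), "2019q1"))))
  cases <- build_cases(cmb)
  expect_equal(nrow(cases), sum(led$group_counts$n_reports))
  expect_equal(sum(cases$is_cae), led$cae_cases)
  hits <- attr(cases, "cae_hits")
  expect_equal(nrow(hits), led$cae_events)
  got_smq <- dplyr::count(hits, smq, name = "events")
  expect_equal(dplyr::arrange(got_smq, smq),
               dplyr::arrange(led$smq_counts[c("smq", "events")], smq))
  # cAE cases never exceed the group total
  per_group <- dplyr::count(cases, group, wt = is_cae, name = "cae")
  tot <- dplyr::count(cases, group)
  expect_true(all(per_group$cae <= tot$n))
})

test_that("SMQ config round-trips through YAML with versions", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(version = "26.1-fixture",
                        smqs = list("Cardiac failure" = list(
                          "Cardiac failure", "Pulmonary oedema"))), f)
  smqs <- read_smq_config(f)
  expect_equal(smqs[["Cardiac failure"]]$version_label, "26.1-fixture")
  expect_setequal(smqs[["Cardiac failure"]]$narrow_pts,
                  c("cardiac failure", "pulmonary oedema"))
})

test_that("shipped synthetic vocabularies load through the config readers", {
  ime <- read_term_list(system.file("extdata", "ime_synthetic.txt",
                                    package = "faersignal"))
  expect_gt(length(ime), 10)
  expect_equal(attr(ime, "version_label"), "synthetic-27.1")
  smqs <- read_smq_config(system.file("extdata", "smq_synthetic.yaml",
                                      package = "faersignal"))
  expect_length(smqs, 7)
  expect_setequal(names(smqs), names(default_smqs()))
  mel <- read_term_list(system.file("extdata", "melanoma_pts.txt",
                                    package = "faersignal"))
  expect_true("Malignant melanoma" %in% mel)
})
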