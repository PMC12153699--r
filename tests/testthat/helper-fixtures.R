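# Hand-built miniature FAERS fixtures, written or assembled in code.

demo_cols <- c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
               "age", "age_cod", "sex", "wt", "wt_cod", "occp_cod",
               "reporter_country", "occr_country", "lit_ref")

# One DEMO row with overridable fields.
mk_demo <- function(primaryid, caseid = primaryid, caseversion = "1",
                    fda_dt = "20190215", event_dt = "20190201", age = "60",
                    age_cod = "YR", sex = "M", wt = "80", wt_cod = "KG",
                    occp_cod = "MD", reporter_country = "US",
                    occr_country = reporter_country, lit_ref = NA_character_,
                    ...) {
  tibble::tibble(primaryid = primaryid, caseid = caseid,
                 caseversion = caseversion, fda_dt = fda_dt,
                 event_dt = event_dt, age = age, age_cod = age_cod,
                 sex = sex, wt = wt, wt_cod = wt_cod, occp_cod = occp_cod,
                 reporter_country = reporter_country,
                 occr_country = occr_country, lit_ref = lit_ref, ...)
}

mk_drug <- function(primaryid, drugname, role_cod = "PS", drug_seq = "1",
                    prod_ai = NA_character_, indi_pt = NA_character_,
                    start_dt = NA_character_) {
  tibble::tibble(primaryid = primaryid, drug_seq = drug_seq,
                 role_cod = role_cod, drugname = drugname, prod_ai = prod_ai,
                 indi_pt = indi_pt, start_dt = start_dt)
}

mk_reac <- function(primaryid, pt) {
  tibble::tibble(primaryid = primaryid, pt = pt)
}

# In-memory combined object for unit tests that do not need file IO.
mk_combined <- function(demo, drug = NULL, reac = NULL) {
  drug <- drug %||% mk_drug(demo$primaryid, "TAFINLAR")
  reac <- reac %||% mk_reac(demo$primaryid, "Nausea")
  structure(list(demo = demo, drug = drug, reac = reac,
                 log = faersignal:::log_entry("fixture", "in-memory",
                                              nrow(demo))),
            class = "faers_combined")
}

# Write a quarter directory of dollar-delimited files from raw tables.
write_fixture_quarter <- function(dir, label = "2019q1",
                                  demo, drug = NULL, indi = NULL,
                                  outc = NULL, reac = NULL, ther = NULL) {
  tag <- faersignal:::quarter_file_tag(label)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  empty <- function(cols) {
    stats::setNames(as.data.frame(matrix(character(0), 0, length(cols))),
                    cols)
  }
  tabs <- list(
    DEMO = demo,
    DRUG = drug %||% empty(c("primaryid", "drug_seq", "role_cod",
                             "drugname", "prod_ai")),
    INDI = indi %||% empty(c("primaryid", "indi_drug_seq", "indi_pt")),
    OUTC = outc %||% empty(c("primaryid", "outc_cod")),
    REAC = reac %||% empty(c("primaryid", "pt")),
    THER = ther %||% empty(c("primaryid", "dsg_drug_seq", "start_dt",
                             "end_dt"))
  )
  for (nm in names(tabs)) {
    readr::write_delim(tabs[[nm]], file.path(dir, paste0(nm, tag, ".txt")),
                       delim = "$", na = "", progress = FALSE)
  }
  invisible(dir)
}

# Two tiny SMQ fixtures with one deliberately shared PT.
fixture_smqs <- function() {
  list(
    Tachy = smq_definition("Tachyarrhythmias (fixture)",
                           c("Atrial fibrillation", "Sinus tachycardia"),
                           "fixture"),
    Emb = smq_definition("Embolic and thrombotic events (fixture)",
                         c("Pulmonary embolism", "Atrial fibrillation"),
                         "fixture")
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
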