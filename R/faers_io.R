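# Ingestion of FAERS quarterly ASCII extracts.
#
# Each quarter ships six dollar-delimited tables (DEMO, DRUG, INDI, OUTC,
# REAC, THER) keyed by `primaryid`.  The reader normalizes header drift via
# a small alias table and carries unrecognized columns through untouched.

faers_table_names <- c("demo", "drug", "indi", "outc", "reac", "ther")

# Known header synonyms across extract eras -> canonical lower-case names.
faers_column_aliases <- c(
  gndr_cod = "sex",          # DEMO pre-2014Q3 gender column
  case_id = "caseid",
  case_version = "caseversion",
  drugname_verbatim = "drugname"
)

canonical_columns <- function(nms) {
  nms <- tolower(trimws(nms))
  hit <- nms %in% names(faers_column_aliases)
  nms[hit] <- unname(faers_column_aliases[nms[hit]])
  nms
}

#' Read one FAERS quarterly extract
#'
#' Parses the six dollar-delimited ASCII tables of one quarter
#' (`DEMO19Q1.txt`, `DRUG19Q1.txt`, ... for quarter `"2019q1"`).  All
#' columns are read as character (FAERS fields are free text with partial
#' dates and mixed units); header names are lower-cased and mapped through
#' a built-in alias table so that era-specific spellings converge on one
#' schema.  Rows with too few fields are completed with missing trailing
#' fields and reported via a warning, never dropped silently.  Input is
#' decoded as Latin-1, which is lossless for the non-UTF-8 bytes present in
#' some FAERS archives.
#'
#' @param path Directory containing the six table files of the quarter.
#' @param quarter_label Quarter as `"YYYYqN"`, e.g. `"2019q1"`.
#' @return A `faers_quarter` object: list with `quarter_label` and the six
#'   tibbles `demo`, `drug`, `indi`, `outc`, `reac`, `ther`.
#' @seealso [build_combined()] to merge quarters into analysis tables.
#' @examples
#' cfg <- sim_config(n_reports = 50, quarters = "2019q1", seed = 1)
#' dir <- tempfile(); generate_faers(cfg, dir)
#' q <- read_quarter(file.path(dir, "2019q1"), "2019q1")
#' nrow(q$demo)
#' @export
read_quarter <- function(path, quarter_label) {
  parse_quarter_label(quarter_label)
  tag <- quarter_file_tag(quarter_label)
  tables <- lapply(faers_table_names, function(tbl) {
    pat <- paste0("^", toupper(tbl), tag, "\\.txt$")
    f <- list.files(path, pattern = pat, ignore.case = TRUE,
                    full.names = TRUE)
    if (length(f) == 0L) {
      stop("missing FAERS table file ", toupper(tbl), tag, ".txt in ", path,
           call. = FALSE)
    }
    read_faers_table(f[[1]])
  })
  names(tables) <- faers_table_names
  structure(c(list(quarter_label = quarter_label), tables),
            class = "faers_quarter")
}

read_faers_table <- function(file) {
  # readr's generic parse-issue warning is replaced below by a structured
  # one carrying the file name and first offending line
  x <- withCallingHandlers(
    readr::read_delim(
      file,
      delim = "$", quote = "",
      col_types = readr::cols(.default = readr::col_character()),
      locale = readr::locale(encoding = "latin1"),
      na = c("", "NA"),
      progress = FALSE, show_col_types = FALSE
    ),
    warning = function(w) {
      if (inherits(w, "vroom_parse_issue")) invokeRestart("muffleWarning")
    }
  )
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    warning(sprintf(
      "%s: %d malformed row(s) (first at line %d: %s); missing fields left empty",
      basename(file), nrow(probs), probs$row[1] + 1L, probs$expected[1]
    ), call. = FALSE)
  }
  names(x) <- canonical_columns(names(x))
  x
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat("<faers_quarter> ", x$quarter_label, "\n", sep = "")
  for (tbl in faers_table_names) {
    cat(sprintf("  %s: %d rows\n", toupper(tbl), nrow(x[[tbl]])))
  }
  invisible(x)
}

log_entry <- function(step, detail, n) {
  tibble::tibble(step = step, detail = detail, n = as.integer(n))
}

#' Merge quarterly extracts into the three combined analysis tables
#'
#' Concatenates the per-quarter tables, then builds the analysis layout:
#' `demo` (one row per report, outcome codes aggregated to a
#' semicolon-separated sorted set in `outc_codes`), `drug` (DRUG rows
#' joined with their same-sequence INDI and THER rows), and `reac` (the
#' reaction rows).  Rows in non-DEMO tables whose `primaryid` has no DEMO
#' parent are orphans: they are excluded from the combined tables and
#' counted in the run log.
#'
#' @param quarters List of `faers_quarter` objects (at least one).
#' @return A `faers_combined` object: list with tibbles `demo`, `drug`,
#'   `reac` and a `log` tibble of processing counts.
#' @examples
#' cfg <- sim_config(n_reports = 50, quarters = "2019q1", seed = 1)
#' dir <- tempfile(); generate_faers(cfg, dir)
#' q <- read_quarter(file.path(dir, "2019q1"), "2019q1")
#' cmb <- build_combined(list(q))
#' names(cmb)
#' @export
build_combined <- function(quarters) {
  if (inherits(quarters, "faers_quarter")) quarters <- list(quarters)
  stopifnot(length(quarters) >= 1L)
  ok <- vapply(quarters, inherits, logical(1), "faers_quarter")
  if (!all(ok)) stop("all inputs must be faers_quarter objects", call. = FALSE)

  stack <- function(tbl) {
    dplyr::bind_rows(lapply(quarters, function(q) q[[tbl]]))
  }
  demo <- stack("demo")
  drug <- stack("drug")
  indi <- stack("indi")
  outc <- stack("outc")
  reac <- stack("reac")
  ther <- stack("ther")

  log <- log_entry("input", "DEMO rows across quarters", nrow(demo))

  known <- unique(demo$primaryid)
  orphan_count <- function(tb) sum(!tb$primaryid %in% known)
  for (nm in c("drug", "indi", "outc", "reac", "ther")) {
    n_orphan <- orphan_count(get(nm))
    if (n_orphan > 0) {
      log <- dplyr::bind_rows(
        log, log_entry("orphans", paste0("orphan ", toupper(nm), " rows excluded"),
                       n_orphan))
    }
  }
  drug <- dplyr::filter(drug, .data$primaryid %in% known)
  indi <- dplyr::filter(indi, .data$primaryid %in% known)
  outc <- dplyr::filter(outc, .data$primaryid %in% known)
  reac <- dplyr::filter(reac, .data$primaryid %in% known)
  ther <- dplyr::filter(ther, .data$primaryid %in% known)

  n_dupseq <- sum(duplicated(drug[c("primaryid", "drug_seq")]))
  if (n_dupseq > 0) {
    log <- dplyr::bind_rows(
      log, log_entry("input", "duplicate (primaryid, drug_seq) DRUG rows kept",
                     n_dupseq))
  }

  # OUTC codes collapse to one sorted set per report.
  outc_set <- outc %>%
    dplyr::mutate(outc_cod = blank_to_na(.data$outc_cod)) %>%
    dplyr::filter(!is.na(.data$outc_cod)) %>%
    dplyr::distinct(.data$primaryid, .data$outc_cod) %>%
    dplyr::group_by(.data$primaryid) %>%
    dplyr::summarise(outc_codes = paste(sort(.data$outc_cod), collapse = ";"),
                     .groups = "drop")
  combined_demo <- dplyr::left_join(demo, outc_set, by = "primaryid")

  # INDI/THER attach to the DRUG row with the same drug sequence number.
  indi_j <- indi %>%
    dplyr::rename(drug_seq = "indi_drug_seq") %>%
    dplyr::select(dplyr::all_of(c("primaryid", "drug_seq", "indi_pt")))
  ther_j <- ther %>%
    dplyr::rename(drug_seq = "dsg_drug_seq") %>%
    dplyr::select(dplyr::any_of(c("primaryid", "drug_seq", "start_dt", "end_dt")))
  combined_drug <- drug %>%
    dplyr::left_join(indi_j, by = c("primaryid", "drug_seq")) %>%
    dplyr::left_join(ther_j, by = c("primaryid", "drug_seq"))

  structure(
    list(demo = combined_demo, drug = combined_drug, reac = reac, log = log),
    class = "faers_combined"
  )
}

#' @export
print.faers_combined <- function(x, ...) {
  cat("<faers_combined>\n")
  cat(sprintf("  demo: %d reports\n", nrow(x$demo)))
  cat(sprintf("  drug: %d rows\n", nrow(x$drug)))
  cat(sprintf("  reac: %d rows\n", nrow(x$reac)))
  cat(sprintf("  log entries: %d\n", nrow(x$log)))
  invisible(x)
}

append_log <- function(combined, step, detail, n) {
  combined$log <- dplyr::bind_rows(combined$log, log_entry(step, detail, n))
  combined
}

# Restrict all member tables to a surviving set of reports.
restrict_combined <- function(combined, keep_ids) {
  combined$demo <- dplyr::filter(combined$demo, .data$primaryid %in% keep_ids)
  combined$drug <- dplyr::filter(combined$drug, .data$primaryid %in% keep_ids)
  combined$reac <- dplyr::filter(combined$reac, .data$primaryid %in% keep_ids)
  combined
}

#' Persist combined tables as tab-separated files
#'
#' Writes `combined_demo.tsv`, `combined_drug.tsv` and `combined_reac.tsv`
#' plus `run_log.tsv` with a stable column order (canonical columns first,
#' any carried-through extras after, in first-seen order).
#'
#' @param combined A `faers_combined` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_combined <- function(combined, dir) {
  stopifnot(inherits(combined, "faers_combined"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lead <- list(
    demo = c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
             "age", "age_cod", "sex", "wt", "wt_cod", "occp_cod",
             "reporter_country", "occr_country", "lit_ref", "outc_codes"),
    drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai",
             "indi_pt", "start_dt", "end_dt"),
    reac = c("primaryid", "pt")
  )
  files <- character(0)
  for (nm in names(lead)) {
    tb <- combined[[nm]]
    ord <- c(intersect(lead[[nm]], names(tb)), setdiff(names(tb), lead[[nm]]))
    f <- file.path(dir, paste0("combined_", nm, ".tsv"))
    readr::write_tsv(tb[ord], f, progress = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "run_log.tsv")
  readr::write_tsv(combined$log, f, progress = FALSE)
  invisible(c(files, f))
}
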