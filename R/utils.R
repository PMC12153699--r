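# Internal helpers shared across the pipeline.

# Empty strings and whitespace-only values are missing in FAERS extracts.
blank_to_na <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA_character_
  x
}

# Canonical form for MedDRA Preferred Term comparison: case-insensitive,
# internal whitespace collapsed.
norm_pt <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("\\s+", " ", x)
  x[!nzchar(x)] <- NA_character_
  x
}

#  FAERS dates arrive as YYYY, YYYYMM or YYYYMMDD digit strings.
date_precision <- function(x) {
  x <- blank_to_na(x)
  out <- rep(NA_character_, length(x))
  out[grepl("^\\d{4}$", x)] <- "year"
  out[grepl("^\\d{6}$", x)] <- "month"
  out[grepl("^\\d{8}$", x)] <- "day"
  out
}

# Convert to Date only where the string is complete to day precision;
# partial dates are never imputed.
faers_date <- function(x) {
  x <- blank_to_na(x)
  full <- !is.na(x) & grepl("^\\d{8}$", x)
  out <- rep(as.Date(NA), length(x))
  out[full] <- as.Date(x[full], format = "%Y%m%d")
  out
}

parse_quarter_label <- function(label) {
  stopifnot(length(label) == 1L)
  if (!grepl("^20\\d{2}q[1-4]$", label)) {
    stop("quarter label must match '20YYqN' (e.g. '2019q1'), got: ", label,
         call. = FALSE)
  }
  list(year = as.integer(substr(label, 1, 4)),
       q = as.integer(substr(label, 6, 6)))
}

# "2019q1" -> "19Q1", the tag used in FAERS file names (DEMO19Q1.txt).
quarter_file_tag <- function(label) {
  p <- parse_quarter_label(label)
  sprintf("%02dQ%d", p$year %% 100, p$q)
}

quarter_bounds <- function(label) {
  p <- parse_quarter_label(label)
  start <- as.Date(sprintf("%d-%02d-01", p$year, (p$q - 1L) * 3L + 1L))
  end <- if (p$q == 4L) {
    as.Date(sprintf("%d-12-31", p$year))
  } else {
    as.Date(sprintf("%d-%02d-01", p$year, p$q * 3L + 1L)) - 1L
  }
  c(start, end)
}

# Deterministic "most recent" selection: highest caseversion, then latest
# fda_dt, then lexicographically largest primaryid.  One row kept per key.
keep_most_recent <- function(df, key) {
  cv <- suppressWarnings(as.numeric(df$caseversion))
  cv[is.na(cv)] <- -Inf
  fda <- blank_to_na(df$fda_dt)
  fda[is.na(fda)] <- ""
  pid <- as.character(df$primaryid)
  ord <- order(df[[key]], -cv, -xtfrm(fda), -xtfrm(pid))
  out <- df[ord, , drop = FALSE]
  out <- out[!duplicated(out[[key]]), , drop = FALSE]
  out[order(xtfrm(out$primaryid)), , drop = FALSE]
}

#' Read a one-term-per-line vocabulary file
#'
#' Reads flat term lists (IME/DME lists, melanoma indication terms, expected
#' adverse reaction lists).  Blank lines and `#` comments are skipped; a
#' comment of the form `# version: <label>` is attached as the
#' `version_label` attribute.
#'
#' @param path Path to a plain-text file with one term per line.
#' @return Character vector of terms with a `version_label` attribute
#'   (`NA` if the file does not declare one).
#' @export
read_term_list <- function(path) {
  if (!file.exists(path)) {
    stop("term list file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "latin1")
  ver <- NA_character_
  m <- grepl("^#\\s*version\\s*:", lines, ignore.case = TRUE)
  if (any(m)) {
    ver <- trimws(sub("^#\\s*version\\s*:", "", lines[which(m)[1]],
                      ignore.case = TRUE))
  }
  terms <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  terms <- terms[nzchar(terms)]
  structure(terms, version_label = ver)
}
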