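# Exposure cohort construction for the BRAF/MEK inhibitor analysis:
# free-text drug-name normalization, suspect-role therapy-group
# classification, melanoma indication filtering, and narrow-SMQ tagging of
# cardiovascular adverse event cases.

braf_mek_codes <- c(
  dabrafenib = "D", trametinib = "T", vemurafenib = "V",
  cobimetinib = "C", encorafenib = "E", binimetinib = "B"
)

# Approved BRAFi + MEKi combinations for melanoma.
approved_pairs <- list(
  dabrafenib = "trametinib",
  trametinib = "dabrafenib",
  vemurafenib = "cobimetinib",
  cobimetinib = "vemurafenib",
  encorafenib = "binimetinib",
  binimetinib = "encorafenib"
)

combo_label <- c(
  dabrafenib = "D+T", trametinib = "D+T",
  vemurafenib = "V+C", cobimetinib = "V+C",
  encorafenib = "E+B", binimetinib = "E+B"
)

#' Therapy groups of the analysis
#'
#' The nine exposure groups: six monotherapies (one per BRAF or MEK
#' inhibitor) and the three approved BRAFi+MEKi combinations.
#'
#' @return Tibble with columns `code` and `kind`.
#' @export
therapy_groups <- function() {
  tibble::tibble(
    code = c("D", "T", "V", "C", "E", "B", "D+T", "V+C", "E+B"),
    kind = c(rep("monotherapy", 6), rep("combination", 3))
  )
}

#' Default drug-name normalization dictionary
#'
#' Maps brand and generic spellings of the six BRAF/MEK inhibitors to their
#' normalized ingredient names (dabrafenib, trametinib, vemurafenib,
#' cobimetinib, encorafenib, binimetinib).  Extend or replace it to cover
#' additional verbatim variants found in real extracts.
#'
#' @return Named character vector: cleaned verbatim name -> ingredient.
#' @export
default_drug_dictionary <- function() {
  c(
    dabrafenib = "dabrafenib", tafinlar = "dabrafenib",
    trametinib = "trametinib", mekinist = "trametinib",
    vemurafenib = "vemurafenib", zelboraf = "vemurafenib",
    cobimetinib = "cobimetinib", cotellic = "cobimetinib",
    encorafenib = "encorafenib", braftovi = "encorafenib",
    binimetinib = "binimetinib", mektovi = "binimetinib"
  )
}

# Salt/ester suffixes stripped before dictionary lookup.
drug_salt_tokens <- c(
  "mesylate", "mesilate", "fumarate", "hemifumarate", "hydrochloride",
  "sulfate", "sulphate", "sodium", "dimethyl", "sulfoxide"
)

#' Normalize a verbatim drug name to an ingredient
#'
#' Case- and punctuation-insensitive dictionary lookup with salt-suffix
#' stripping (`"Dabrafenib Mesylate"` -> `"dabrafenib"`).  If the cleaned
#' string misses, each remaining token is tried, so dose or formulation
#' decorations do not defeat the match.  Unmatched names return `NA`
#' (unknown), never an error.
#'
#' @param x Character vector of verbatim drug names.
#' @param dictionary Named character vector mapping cleaned names to
#'   ingredients; see [default_drug_dictionary()].
#' @return Character vector of ingredients, `NA` where unknown.
#' @examples
#' normalize_drug(c("TAFINLAR", "Dabrafenib Mesylate", "ASPIRIN"))
#' @export
normalize_drug <- function(x, dictionary = default_drug_dictionary()) {
  x <- tolower(as.character(x))
  x <- gsub("[[:punct:]]", " ", x)
  x <- gsub("\\s+", " ", trimws(x))
  x[!nzchar(x) | is.na(x)] <- NA_character_

  strip_salt <- function(s) {
    toks <- strsplit(s, " ", fixed = TRUE)[[1]]
    paste(toks[!toks %in% drug_salt_tokens], collapse = " ")
  }
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    if (!is.na(dictionary[s])) return(unname(dictionary[s]))
    s2 <- strip_salt(s)
    if (!is.na(dictionary[s2])) return(unname(dictionary[s2]))
    for (tok in strsplit(s2, " ", fixed = TRUE)[[1]]) {
      if (!is.na(dictionary[tok])) return(unname(dictionary[tok]))
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# Normalized ingredient per drug row, preferring the verbatim name and
# falling back to the active-ingredient column.
drug_ingredients <- function(drug, dictionary) {
  ing <- normalize_drug(drug$drugname, dictionary)
  if ("prod_ai" %in% names(drug)) {
    ing <- dplyr::coalesce(ing, normalize_drug(drug$prod_ai, dictionary))
  }
  ing
}

#' Classify reports into therapy groups by suspect roles
#'
#' A report belongs to a combination group when its primary suspect (PS) is
#' one of the six drugs of interest and the partner of an approved
#' combination (D+T, V+C, E+B) is the secondary suspect (SS); to a
#' monotherapy group when the PS is a drug of interest and no other drug of
#' interest appears as PS or SS.  Everything else -- non-approved pairings,
#' drugs of interest appearing only as concomitant, conflicting multiple PS
#' drugs of interest -- is assigned to no group (`NA`).
#'
#' @param drug Combined DRUG table (`combined$drug`), with `role_cod`.
#' @param dictionary Drug-name normalization map.
#' @return Tibble with one row per report that has at least one suspect
#'   drug of interest: `primaryid`, `group` (`NA` when unclassifiable).
#' @export
classify_exposure <- function(drug, dictionary = default_drug_dictionary()) {
  d <- drug
  d$ing <- drug_ingredients(d, dictionary)
  oi <- d[!is.na(d$ing) & d$role_cod %in% c("PS", "SS"), , drop = FALSE]
  if (nrow(oi) == 0L) {
    return(tibble::tibble(primaryid = character(0), group = character(0)))
  }
  per <- oi %>%
    dplyr::distinct(.data$primaryid, .data$role_cod, .data$ing) %>%
    dplyr::group_by(.data$primaryid) %>%
    dplyr::summarise(
      ps = list(sort(unique(.data$ing[.data$role_cod == "PS"]))),
      ss = list(sort(unique(.data$ing[.data$role_cod == "SS"]))),
      .groups = "drop")
  per$group <- purrr::map2_chr(per$ps, per$ss, function(ps, ss) {
    if (length(ps) != 1L) return(NA_character_)  # none or conflicting PS
    others <- setdiff(union(ps, ss), ps)
    if (length(others) == 0L) return(unname(braf_mek_codes[ps]))
    if (length(others) == 1L && identical(others, approved_pairs[[ps]])) {
      return(unname(combo_label[ps]))
    }
    NA_character_
  })
  per[c("primaryid", "group")]
}

#' Restrict an exposure cohort to melanoma indications
#'
#' Excludes reports where any suspect (PS/SS) drug of interest carries a
#' stated indication outside the melanoma term set.  Reports whose
#' indication is missing are retained: exclusion requires a stated
#' non-melanoma condition.
#'
#' @param assignments Output of [classify_exposure()] (rows with `NA`
#'   group are passed through untouched).
#' @param drug Combined DRUG table carrying `indi_pt`.
#' @param dictionary Drug-name normalization map.
#' @param melanoma_pts Optional character vector of indication PTs counted
#'   as melanoma; default accepts any PT containing \dQuote{melanoma}.
#' @return `assignments` without the excluded reports; the excluded
#'   `primaryid`s are attached as attribute `"excluded"`.
#' @export
filter_indication <- function(assignments, drug,
                              dictionary = default_drug_dictionary(),
                              melanoma_pts = NULL) {
  d <- drug
  d$ing <- drug_ingredients(d, dictionary)
  sus <- d[!is.na(d$ing) & d$role_cod %in% c("PS", "SS"), , drop = FALSE]
  sus$indi <- norm_pt(sus[["indi_pt"]] %||% rep(NA_character_, nrow(sus)))
  stated <- sus[!is.na(sus$indi), , drop = FALSE]
  is_mel <- if (is.null(melanoma_pts)) {
    grepl("melanoma", stated$indi, fixed = TRUE)
  } else {
    stated$indi %in% norm_pt(melanoma_pts)
  }
  excluded <- unique(stated$primaryid[!is_mel])
  out <- assignments[!assignments$primaryid %in% excluded, , drop = FALSE]
  attr(out, "excluded") <- intersect(excluded, assignments$primaryid)
  out
}

#' Define a Standardized MedDRA Query (narrow scope)
#'
#' @param name SMQ name.
#' @param narrow_pts Non-empty character vector of narrow-scope PTs.
#' @param version_label Dictionary version the PT list was taken from.
#' @return An `smq_definition` object.
#' @export
smq_definition <- function(name, narrow_pts, version_label = "unversioned") {
  narrow_pts <- unique(norm_pt(narrow_pts))
  narrow_pts <- narrow_pts[!is.na(narrow_pts)]
  if (length(narrow_pts) == 0L) {
    stop("SMQ '", name, "' has no narrow PTs", call. = FALSE)
  }
  structure(list(name = name, narrow_pts = narrow_pts,
                 version_label = version_label),
            class = "smq_definition")
}

#' Read SMQ definitions from a YAML file
#'
#' Expected layout: a top-level optional `version` field and an `smqs`
#' mapping of SMQ name to a list of narrow PTs.
#'
#' @param path YAML file path.
#' @return Named list of [smq_definition()] objects.
#' @export
read_smq_config <- function(path) {
  if (!file.exists(path)) stop("SMQ config not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  ver <- y$version %||% "unversioned"
  smqs <- lapply(names(y$smqs), function(nm) {
    smq_definition(nm, unlist(y$smqs[[nm]]), ver)
  })
  stats::setNames(smqs, names(y$smqs))
}

#' Default cardiovascular SMQ set (synthetic fixture vocabulary)
#'
#' The seven narrow-scope SMQ classes of the cardiovascular analysis, each
#' populated with a small synthetic subset of publicly reported PTs.  The
#' licensed MedDRA SMQ contents are not redistributable; for a production
#' analysis supply the licensed narrow PT lists via [read_smq_config()] or
#' [smq_definition()].
#'
#' @return Named list of `smq_definition` objects.
#' @export
default_smqs <- function() {
  v <- "synthetic-fixture"
  defs <- list(
    smq_definition(
      "Bradyarrhythmias (incl conduction defects and disorders of sinus node function)",
      c("Brugada syndrome", "Electrocardiogram QT prolonged",
        "Atrioventricular block complete", "Bundle branch block right",
        "Sinus bradycardia"), v),
    smq_definition(
      "Cardiac failure",
      c("Cardiac failure", "Left ventricular failure", "Cardiogenic shock",
        "Pulmonary oedema"), v),
    smq_definition(
      "Cardiomyopathy",
      c("Cardiomyopathy", "Cardiotoxicity", "Ejection fraction decreased",
        "Stress cardiomyopathy"), v),
    smq_definition(
      "Embolic and thrombotic events",
      c("Disseminated intravascular coagulation", "Pulmonary embolism",
        "Deep vein thrombosis", "Cerebral ischaemia", "Hemiparesis",
        "Splenic infarction", "Thrombosis"), v),
    smq_definition(
      "Ischaemic heart disease",
      c("Myocardial infarction", "Coronary artery stenosis",
        "Acute coronary syndrome", "Angina pectoris"), v),
    smq_definition(
      "Noninfectious myocarditis/pericarditis",
      c("Myocarditis", "Pericarditis"), v),
    smq_definition(
      "Tachyarrhythmias (incl supraventricular and ventricular tachyarrhythmias)",
      c("Atrial fibrillation", "Ventricular arrhythmia", "Sinus tachycardia",
        "Atrial flutter"), v)
  )
  stats::setNames(defs, vapply(defs, function(s) s$name, character(1)))
}

smq_lookup <- function(smqs) {
  dplyr::bind_rows(lapply(smqs, function(s) {
    tibble::tibble(smq = s$name, pt_norm = s$narrow_pts)
  }))
}

#' Tag cardiovascular adverse event cases via narrow SMQ membership
#'
#' Matches every reaction PT (case-insensitively, whitespace-normalized)
#' against the narrow PT sets of the supplied SMQs.  A PT belonging to two
#' SMQs yields two hits.  Event counting sums (report, SMQ, PT) hits; case
#' counting takes distinct reports.
#'
#' @param reac Combined REAC table (`primaryid`, `pt`).
#' @param smqs Named list of [smq_definition()] objects.
#' @return Tibble of hits: `primaryid`, `smq`, `pt` (verbatim PT spelling
#'   as reported).
#' @export
tag_cae <- function(reac, smqs = default_smqs()) {
  lu <- smq_lookup(smqs)
  reac %>%
    dplyr::mutate(pt_norm = norm_pt(.data$pt)) %>%
    dplyr::filter(!is.na(.data$pt_norm)) %>%
    dplyr::inner_join(lu, by = "pt_norm", relationship = "many-to-many") %>%
    dplyr::distinct(.data$primaryid, .data$smq, .data$pt)
}

#' Build the classified case table for a cleaned universe
#'
#' Chains [classify_exposure()], [filter_indication()] and [tag_cae()] on a
#' cleaned `faers_combined` universe.
#'
#' @inheritParams filter_indication
#' @param combined Cleaned `faers_combined` universe.
#' @param smqs SMQ definitions for cardiovascular tagging.
#' @return Tibble with one row per classified case: `primaryid`, `group`,
#'   `kind` (monotherapy/combination) and `is_cae`; the SMQ hit table is
#'   attached as attribute `"cae_hits"`.
#' @export
build_cases <- function(combined, dictionary = default_drug_dictionary(),
                        melanoma_pts = NULL, smqs = default_smqs()) {
  stopifnot(inherits(combined, "faers_combined"))
  assignments <- classify_exposure(combined$drug, dictionary)
  assignments <- assignments[!is.na(assignments$group), , drop = FALSE]
  assignments <- filter_indication(assignments, combined$drug, dictionary,
                                   melanoma_pts)
  hits <- tag_cae(combined$reac, smqs)
  hits <- hits[hits$primaryid %in% assignments$primaryid, , drop = FALSE]
  cases <- assignments %>%
    dplyr::left_join(therapy_groups(), by = c(group = "code")) %>%
    dplyr::mutate(is_cae = .data$primaryid %in% hits$primaryid)
  attr(cases, "cae_hits") <- hits
  attr(cases, "excluded_indication") <- attr(assignments, "excluded")
  cases
}
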