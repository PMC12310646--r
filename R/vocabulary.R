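#' Drug dictionary: ingredient / synonym lookup table
#'
#' Spontaneous reports record drug names inconsistently: brand names,
#' generic names, trailing dosage strings. A drug dictionary maps every
#' synonym (case-insensitively) to a single normalized ingredient. The
#' shipped default covers the immune checkpoint inhibitors studied most
#' often in neurological adverse-event pharmacovigilance (ipilimumab,
#' pembrolizumab, nivolumab, cemiplimab, atezolizumab, durvalumab,
#' avelumab, plus tremelimumab) with their common brand names.
#'
#' @param path Optional path to a TSV with columns `ingredient` and
#'   `synonym`; replaces the shipped default.
#' @param extra Optional data frame with the same two columns, appended to
#'   the dictionary (user extensions).
#' @return A tibble with columns `ingredient` and `synonym`, one row per
#'   synonym, with synonyms cleaned the same way [normalize_drug_name()]
#'   cleans incoming names.
#' @export
#' @examples
#' dict <- drug_dictionary()
#' normalize_drug_name("KEYTRUDA", dict)
drug_dictionary <- function(path = NULL, extra = NULL) {
  path <- path %||% system.file("extdata", "drug_synonyms.tsv",
                                package = "pvsignals", mustWork = TRUE)
  dict <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  if (!all(c("ingredient", "synonym") %in% names(dict))) {
    abort("drug dictionary must have columns 'ingredient' and 'synonym'")
  }
  if (!is.null(extra)) {
    dict <- bind_rows(dict, as_tibble(extra)[c("ingredient", "synonym")])
  }
  dict <- dict |>
    mutate(ingredient = tolower(trimws(.data$ingredient)),
           synonym = clean_drug_name(.data$synonym)) |>
    distinct(.data$synonym, .keep_all = TRUE)
  # a synonym claimed by two ingredients would make normalization ambiguous
  dup <- dict |> count(.data$synonym) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("synonyms mapped to more than one ingredient: ",
                 paste(dup$synonym, collapse = ", ")))
  }
  dict
}

#' @rdname drug_dictionary
#' @return `target_ingredients()` returns the ordered character vector of
#'   immune checkpoint inhibitor ingredients the shipped dictionary targets.
#' @export
target_ingredients <- function() {
  c("ipilimumab", "pembrolizumab", "nivolumab", "cemiplimab",
    "atezolizumab", "durvalumab", "avelumab")
}

# tokens that carry dose/form information, not drug identity
.dosage_token_re <- paste0(
  "^(\\d+([.]\\d+)?(mg|mcg|ug|g|ml|mg/ml|iu)?|mg|mcg|ug|ml|iu|",
  "tablet|tablets|tab|capsule|capsules|cap|injection|inj|solution|",
  "infusion|concentrate|vial|oral|iv|unknown)$")

#' Clean a raw drug-name string
#'
#' Trims, case-folds, replaces punctuation with spaces, collapses
#' whitespace and drops pure dosage/formulation tokens (e.g. "200MG",
#' "TABLET"). Deterministic and vectorized.
#'
#' @param x Character vector of raw drug names.
#' @return Character vector of cleaned names ("" when nothing survives).
#' @export
clean_drug_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[^a-z0-9./-]+", " ", x)
  x <- gsub("(\\d)\\s*(mg|mcg|ug|g|ml|iu)\\b", "\\1\\2", x)
  vapply(strsplit(x, "\\s+"), function(tok) {
    tok <- tok[nzchar(tok) & !grepl(.dosage_token_re, tok)]
    paste(tok, collapse = " ")
  }, character(1))
}

#' Normalize raw drug names to ingredients
#'
#' @param raw_name Character vector of names as reported.
#' @param dict Dictionary from [drug_dictionary()].
#' @return Character vector of ingredient names; `NA` where the cleaned
#'   name matches no synonym.
#' @export
normalize_drug_name <- function(raw_name, dict) {
  cleaned <- clean_drug_name(raw_name)
  dict$ingredient[match(cleaned, dict$synonym)]
}

#' Event-group map: MedDRA preferred terms to composite categories
#'
#' Composite neurological immune-mediated adverse-event (NAE) categories
#' are defined as curated lists of MedDRA preferred terms (PTs): e.g.
#' autoimmune encephalitis (AIE) pools "autoimmune encephalopathy",
#' "encephalitis autoimmune", "immune-mediated encephalitis" and
#' "noninfective encephalitis". The shipped default covers thirteen
#' categories spanning central and peripheral immune-mediated disease;
#' every category carries an NAE umbrella flag. Each PT belongs to exactly
#' one category; matching is case- and whitespace-insensitive.
#'
#' @param path Optional path to a TSV with columns `pt`, `group`, `nae`;
#'   replaces the shipped default (e.g. a high-level-term clustering).
#' @return A tibble with columns `pt` (normalized), `group`, `nae`
#'   (logical umbrella flag).
#' @export
event_group_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "event_groups.tsv",
                                package = "pvsignals", mustWork = TRUE)
  map <- readr::read_tsv(path, col_types = readr::cols(
    pt = "c", group = "c", nae = "l"), progress = FALSE)
  map <- map |> mutate(pt = normalize_pt(.data$pt))
  dup <- map |> count(.data$pt) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("preferred terms mapped to more than one group: ",
                 paste(dup$pt, collapse = ", ")))
  }
  map
}

#' Normalize a MedDRA preferred-term string
#'
#' Case-folds, collapses internal whitespace and strips trailing periods.
#' No fuzzy matching: PTs are a controlled vocabulary.
#'
#' @param x Character vector of PT strings.
#' @return Normalized character vector.
#' @export
normalize_pt <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("\\s+", " ", x)
  sub("\\.+$", "", x)
}

#' Map preferred terms to composite event groups
#'
#' @param pt Character vector of PT strings.
#' @param map Event-group map from [event_group_map()].
#' @return Character vector of group labels; `NA` for PTs outside the map.
#' @export
#' @examples
#' map_pt_to_group("Encephalitis autoimmune", event_group_map())
map_pt_to_group <- function(pt, map = event_group_map()) {
  map$group[match(normalize_pt(pt), map$pt)]
}

#' Outcome severity from regulatory outcome codes
#'
#' Reports carry outcome codes DE (death), LT (life-threatening), HO
#' (hospitalization), DS (disability), CA (congenital anomaly), RI
#' (required intervention), OT (other). A report is classified SERIOUS
#' if and only if its outcome set contains DE; NON_SERIOUS if it has
#' outcomes but no DE; UNKNOWN if it has none.
#'
#' @param outcomes Character vector of outcome codes for one case (may be
#'   empty).
#' @return One of "SERIOUS", "NON_SERIOUS", "UNKNOWN".
#' @export
classify_outcome_severity <- function(outcomes) {
  outcomes <- outcomes[!is.na(outcomes) & nzchar(outcomes)]
  if (length(outcomes) == 0) return("UNKNOWN")
  bad <- setdiff(outcomes, outcome_codes())
  if (length(bad) > 0) {
    abort(paste0("unknown outcome codes: ", paste(bad, collapse = ", ")))
  }
  if ("DE" %in% outcomes) "SERIOUS" else "NON_SERIOUS"
}

#' @rdname classify_outcome_severity
#' @return `outcome_codes()` returns the seven valid outcome codes.
#' @export
outcome_codes <- function() c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Per-case severity labels for a case store
#'
#' @param store A `report_store`.
#' @return Tibble with `case_id` and `severity` for every case in the
#'   store (UNKNOWN when a case has no outcome rows).
#' @export
case_severity <- function(store) {
  stopifnot(inherits(store, "report_store"))
  sev <- store$outcomes |>
    filter(.data$code %in% outcome_codes()) |>
    group_by(.data$case_id) |>
    summarise(severity = ifelse(any(.data$code == "DE"),
                                "SERIOUS", "NON_SERIOUS"),
              .groups = "drop")
  store$cases |>
    select("case_id") |>
    left_join(sev, by = "case_id") |>
    mutate(severity = ifelse(is.na(.data$severity), "UNKNOWN",
                             .data$severity))
}

#' Suspect drug exposures for the study population
#'
#' Selects, per case, the dictionary-matched ingredients among drug rows
#' whose role code is in `roles` (default primary suspect only, the usual
#' study-population rule). Several rows naming the same ingredient (brand
#' vs generic) collapse to one exposure keeping the earliest known start
#' date.
#'
#' @param store A `report_store`.
#' @param dict Drug dictionary from [drug_dictionary()].
#' @param roles Role codes to keep; subset of PS, SS, C, I.
#' @return Tibble with columns `case_id`, `ingredient`, `start_date`.
#' @export
select_suspect_exposures <- function(store, dict = drug_dictionary(),
                                     roles = "PS") {
  stopifnot(inherits(store, "report_store"))
  bad <- setdiff(roles, c("PS", "SS", "C", "I"))
  if (length(bad) > 0) {
    abort(paste0("invalid role codes: ", paste(bad, collapse = ", ")))
  }
  store$drugs |>
    filter(.data$role %in% roles) |>
    mutate(ingredient = normalize_drug_name(.data$raw_name, dict)) |>
    filter(!is.na(.data$ingredient)) |>
    group_by(.data$case_id, .data$ingredient) |>
    summarise(start_date = if (all(is.na(.data$start_date))) {
      as.Date(NA)
    } else {
      min(.data$start_date, na.rm = TRUE)
    }, .groups = "drop") |>
    arrange(.data$case_id, .data$ingredient)
}
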