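# in-code fixtures: small case stores built directly from tibbles

blank_cases <- function(ids) {
  tibble::tibble(
    case_id = ids, sex = "UNK", age_years = NA_real_, age_group = "UNK",
    weight_kg = NA_real_, reporter = "UNK", country = "UNK",
    event_date = as.Date(NA), receipt_int = 20230101, year = 2023)
}

make_store <- function(ids, drugs = NULL, reactions = NULL,
                       outcomes = NULL, cases = NULL,
                       indications = NULL, source = "FAERS") {
  empty_drugs <- tibble::tibble(case_id = character(),
                                raw_name = character(),
                                role = character(),
                                start_date = as.Date(character()))
  empty_reac <- tibble::tibble(case_id = character(), pt = character(),
                               onset_date = as.Date(character()))
  empty_outc <- tibble::tibble(case_id = character(), code = character())
  pvsignals:::new_report_store(
    cases = cases %||% blank_cases(ids),
    drugs = drugs %||% empty_drugs,
    reactions = reactions %||% empty_reac,
    outcomes = outcomes %||% empty_outc,
    indications = indications,
    source = source)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# one representative preferred term per composite group
group_pt <- function(groups = event_group_map()) {
  groups |>
    dplyr::group_by(group) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup() |>
    (\(d) stats::setNames(d$pt, d$group))()
}

# store realizing given (group, deaths, reports) tallies: one case per
# report, each case carrying its group's representative PT, deaths get DE
outcome_tally_store <- function(tallies) {
  pts <- group_pt()
  rows <- tallies |>
    dplyr::mutate(pt = pts[group])
  ids <- sprintf("T%07d", seq_len(sum(rows$reports)))
  reac <- tibble::tibble(
    case_id = ids,
    pt = rep(rows$pt, rows$reports),
    onset_date = as.Date(NA))
  is_death <- unlist(purrr::map2(rows$deaths, rows$reports,
                                 ~ c(rep(TRUE, .x), rep(FALSE, .y - .x))))
  outc <- dplyr::bind_rows(
    tibble::tibble(case_id = ids[is_death], code = "DE"),
    tibble::tibble(case_id = ids[!is_death], code = "HO"))
  make_store(ids, reactions = reac, outcomes = outc)
}

# store with n_total cases exposed to `drug` (role PS) of which n_event
# carry an NAE preferred term
share_store <- function(drug, n_event, n_total,
                        pt = "myasthenia gravis") {
  ids <- sprintf("S%07d", seq_len(n_total))
  drugs <- tibble::tibble(case_id = ids, raw_name = drug, role = "PS",
                          start_date = as.Date(NA))
  reac <- tibble::tibble(case_id = ids[seq_len(n_event)], pt = pt,
                         onset_date = as.Date(NA))
  make_store(ids, drugs = drugs, reactions = reac)
}
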