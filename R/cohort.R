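#' Spearman correlation for an annual reporting trend
#'
#' Mid-rank Spearman correlation between calendar year and annual report
#' count. The p-value uses the exact null distribution when n <= 10 and
#' there are no ties, and the t approximation otherwise.
#'
#' @param data Data frame with the year and count columns.
#' @param year,count Column names (tidy-eval).
#' @return One-row tibble: `n_years`, `r`, `p_value`.
#' @export
trend_correlation <- function(data, year = "year", count = "count") {
  x <- data[[year]]
  y <- data[[count]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 years of data")
  r <- cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  p <- suppressWarnings(
    cor.test(x, y, method = "spearman",
             exact = (n <= 10 && !ties))$p.value)
  tibble(n_years = n, r = r, p_value = p)
}

#' Annual trend of reports matching an event filter
#'
#' Counts cases per reporting year (the year of the surviving version's
#' receipt date) and correlates counts with year.
#'
#' @param store A `report_store`.
#' @param groups Event-group map.
#' @param events Optional character vector of group labels; default all
#'   NAE-flagged groups. `NULL` with `nae_only = FALSE` counts all cases.
#' @param nae_only Restrict to cases with at least one reaction in an
#'   NAE-flagged group.
#' @return A `trend_result`: tibble of `year`, `count` with the
#'   correlation row in attribute `"correlation"`.
#' @export
annual_trend <- function(store, groups = event_group_map(),
                         events = NULL, nae_only = TRUE) {
  stopifnot(inherits(store, "report_store"))
  ids <- event_case_ids(store, groups, events, nae_only)
  counts <- store$cases |>
    filter(.data$case_id %in% ids, !is.na(.data$year)) |>
    count(.data$year, name = "count")
  if (nrow(counts) < 3) abort("need at least 3 years of data")
  out <- counts
  attr(out, "correlation") <- trend_correlation(counts, "year", "count")
  class(out) <- c("trend_result", class(out))
  out
}

# case ids with >= 1 reaction in the selected groups
event_case_ids <- function(store, groups, events = NULL,
                           nae_only = TRUE) {
  g <- groups
  if (!is.null(events)) {
    g <- g |> filter(.data$group %in% events)
  } else if (nae_only) {
    g <- g |> filter(.data$nae)
  } else {
    return(store$cases$case_id)
  }
  store$reactions |>
    mutate(group = map_pt_to_group(.data$pt, g)) |>
    filter(!is.na(.data$group)) |>
    distinct(.data$case_id) |>
    pull(.data$case_id)
}

#' Time to onset of an event after suspect-drug start
#'
#' For each case the interval is onset date of the earliest matching
#' reaction minus the earliest start date of a suspect target drug, in
#' days. Only fully dated, non-negative intervals are usable; negative
#' and undated intervals are excluded with reported counts. Quartiles use
#' linear interpolation between order statistics (the convention where
#' the median of 10, 20, 30, 40, 50 is 30 with quartiles 20 and 40).
#'
#' @param store A `report_store`.
#' @param dict Drug dictionary.
#' @param groups Event-group map.
#' @param events Optional group labels (default: all NAE groups).
#' @param roles Role codes defining exposure.
#' @param bin_width Histogram bin width in days.
#' @return A `tto_summary`: tibble with one row per drug plus a pooled
#'   `"all"` row (`n_usable`, `median_days`, `q1_days`, `q3_days`);
#'   attributes `"histogram"` (pooled binned counts) and `"exclusions"`.
#' @export
time_to_onset <- function(store, dict = drug_dictionary(),
                          groups = event_group_map(), events = NULL,
                          roles = "PS", bin_width = 30) {
  stopifnot(inherits(store, "report_store"))
  exp_tab <- select_suspect_exposures(store, dict, roles)
  onsets <- store$reactions |>
    mutate(group = map_pt_to_group(.data$pt, groups)) |>
    filter(!is.na(.data$group)) |>
    (\(df) if (is.null(events)) {
      df |> semi_join(groups |> filter(.data$nae), by = "group")
    } else {
      df |> filter(.data$group %in% events)
    })() |>
    group_by(.data$case_id) |>
    summarise(onset_date = if (all(is.na(.data$onset_date))) {
      as.Date(NA)
    } else {
      min(.data$onset_date, na.rm = TRUE)
    }, .groups = "drop")
  pairs <- exp_tab |> inner_join(onsets, by = "case_id") |>
    mutate(days = as.numeric(.data$onset_date - .data$start_date))
  n_undated <- sum(is.na(pairs$days))
  n_negative <- sum(!is.na(pairs$days) & pairs$days < 0)
  usable <- pairs |> filter(!is.na(.data$days), .data$days >= 0)
  summarise_days <- function(d) {
    if (length(d) == 0) {
      return(tibble(n_usable = 0L, median_days = NA_real_,
                    q1_days = NA_real_, q3_days = NA_real_))
    }
    q <- unname(quantile(d, c(0.25, 0.5, 0.75), type = 7))
    tibble(n_usable = length(d), median_days = q[2], q1_days = q[1],
           q3_days = q[3])
  }
  per_drug <- usable |>
    group_by(drug = .data$ingredient) |>
    reframe(summarise_days(.data$days))
  pooled <- summarise_days(usable$days) |> mutate(drug = "all")
  out <- bind_rows(per_drug, pooled) |> relocate("drug")
  hist <- if (nrow(usable) > 0) {
    usable |>
      mutate(bin = floor(.data$days / bin_width) * bin_width) |>
      count(.data$bin, name = "count") |>
      mutate(bin_label = paste0("[", .data$bin, ",",
                                .data$bin + bin_width, ")"))
  } else {
    tibble(bin = numeric(), count = integer(), bin_label = character())
  }
  attr(out, "histogram") <- hist
  attr(out, "exclusions") <- c(candidates = nrow(pairs),
                               usable = nrow(usable),
                               excluded_undated = n_undated,
                               excluded_negative = n_negative)
  class(out) <- c("tto_summary", class(out))
  if (nrow(usable) == 0) warn("no usable time-to-onset intervals")
  out
}

#' Mortality rate per event group
#'
#' Deaths are cases whose outcome set contains DE; the denominator is all
#' cases reporting the group. The rate is a percentage rounded to 2
#' decimal places. Groups with zero reports are omitted.
#'
#' @param store A `report_store`.
#' @param groups Event-group map.
#' @return Tibble with `group`, `deaths`, `reports`, `rate_pct`.
#' @export
mortality_rates <- function(store, groups = event_group_map()) {
  stopifnot(inherits(store, "report_store"))
  sev <- case_severity(store)
  store$reactions |>
    mutate(group = map_pt_to_group(.data$pt, groups)) |>
    filter(!is.na(.data$group)) |>
    distinct(.data$case_id, .data$group) |>
    left_join(sev, by = "case_id") |>
    group_by(.data$group) |>
    summarise(deaths = sum(.data$severity == "SERIOUS"),
              reports = n(), .groups = "drop") |>
    mutate(rate_pct = round(100 * .data$deaths / .data$reports, 2)) |>
    arrange(desc(.data$reports))
}

#' Serious vs non-serious association per event group
#'
#' For each group, tests whether seriousness (death vs non-death outcome)
#' is associated with membership in the group, on the 2x2 table of
#' (in-group vs other selected cases) x (serious vs non-serious). Cases
#' with unknown outcome are excluded. Pearson chi-squared without
#' continuity correction by default; when any expected cell is below 5
#' (and `method = "auto"`), Fisher's exact test supplies the p-value.
#'
#' @param store A `report_store`.
#' @param groups Event-group map.
#' @param method `"auto"`, `"none"` (always Pearson), `"yates"`, or
#'   `"fisher"`.
#' @return Tibble per group: `serious`, `non_serious`, `chi2`, `p_value`,
#'   `correction` (the rule actually applied).
#' @export
severity_association <- function(store, groups = event_group_map(),
                                 method = c("auto", "none", "yates",
                                            "fisher")) {
  method <- match.arg(method)
  stopifnot(inherits(store, "report_store"))
  sev <- case_severity(store)
  mem <- store$reactions |>
    mutate(group = map_pt_to_group(.data$pt, groups)) |>
    filter(!is.na(.data$group)) |>
    distinct(.data$case_id, .data$group) |>
    left_join(sev, by = "case_id") |>
    filter(.data$severity != "UNKNOWN")
  tot_serious <- mem |> distinct(.data$case_id, .data$severity) |>
    count(.data$severity) |> tidyr::pivot_wider(names_from = "severity",
                                                values_from = "n")
  ts <- if ("SERIOUS" %in% names(tot_serious)) tot_serious$SERIOUS else 0L
  tn <- if ("NON_SERIOUS" %in% names(tot_serious)) {
    tot_serious$NON_SERIOUS
  } else {
    0L
  }
  per_group <- mem |>
    group_by(.data$group) |>
    summarise(serious = sum(.data$severity == "SERIOUS"),
              non_serious = sum(.data$severity == "NON_SERIOUS"),
              .groups = "drop")
  purrr::pmap_dfr(per_group, function(group, serious, non_serious) {
    m <- matrix(c(serious, non_serious,
                  ts - serious, tn - non_serious), nrow = 2,
                byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      return(tibble(group = group, serious = serious,
                    non_serious = non_serious, chi2 = NA_real_,
                    p_value = NA_real_, correction = "skipped"))
    }
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    use_fisher <- method == "fisher" ||
      (method == "auto" && any(expected < 5))
    chi <- suppressWarnings(
      chisq.test(m, correct = (method == "yates")))
    p <- if (use_fisher) fisher.test(m)$p.value else chi$p.value
    tibble(group = group, serious = serious, non_serious = non_serious,
           chi2 = unname(chi$statistic), p_value = p,
           correction = if (use_fisher) "fisher"
           else if (method == "yates") "yates" else "none")
  }) |> arrange(desc(.data$serious + .data$non_serious))
}

#' Demographic characteristics table per drug
#'
#' Per-drug counts and column percentages over the requested strata, for
#' cases exposed to each target ingredient (suspect role by default).
#' Unknowns are shown explicitly; percentages within a (drug, stratum)
#' block sum to 100 up to rounding.
#'
#' @param store A `report_store`.
#' @param dict Drug dictionary.
#' @param strata Subset of `sex`, `age_group`, `weight_band`,
#'   `reporter`, `outcome`, `country`, `year`, `indication`.
#' @param roles Role codes defining exposure.
#' @param events Optional group labels restricting to cases with those
#'   events; `NULL` uses all exposed cases.
#' @param groups Event-group map (used when `events` given).
#' @return Long tibble: `drug`, `stratum`, `level`, `n`, `pct`.
#' @export
demographic_table <- function(store, dict = drug_dictionary(),
                              strata = c("sex", "age_group", "reporter",
                                         "outcome"),
                              roles = "PS", events = NULL,
                              groups = event_group_map()) {
  stopifnot(inherits(store, "report_store"))
  ok <- c("sex", "age_group", "weight_band", "reporter", "outcome",
          "country", "year", "indication")
  bad <- setdiff(strata, ok)
  if (length(bad) > 0) {
    abort(paste0("unknown strata: ", paste(bad, collapse = ", ")))
  }
  exposed <- select_suspect_exposures(store, dict, roles)
  if (!is.null(events)) {
    ids <- event_case_ids(store, groups, events)
    exposed <- exposed |> filter(.data$case_id %in% ids)
  }
  sev <- case_severity(store)
  indi <- store$indications |>
    filter(nzchar(.data$indication_pt)) |>
    group_by(.data$case_id) |>
    summarise(indication = dplyr::first(.data$indication_pt),
              .groups = "drop")
  base <- exposed |>
    left_join(store$cases, by = "case_id") |>
    left_join(sev, by = "case_id") |>
    left_join(indi, by = "case_id") |>
    mutate(
      weight_band = case_when(
        is.na(.data$weight_kg) ~ "UNK",
        .data$weight_kg < 50 ~ "<50",
        .data$weight_kg <= 100 ~ "50-100",
        TRUE ~ ">100"),
      outcome = case_when(
        .data$severity == "SERIOUS" ~ "Death",
        .data$severity == "NON_SERIOUS" ~ "Non-death",
        TRUE ~ "UNK"),
      year = ifelse(is.na(.data$year), "UNK", as.character(.data$year)))
  purrr::map_dfr(strata, function(s) {
    base |>
      mutate(level = as.character(.data[[s]]),
             level = ifelse(is.na(.data$level), "UNK", .data$level)) |>
      count(drug = .data$ingredient, .data$level, name = "n") |>
      group_by(.data$drug) |>
      mutate(pct = round(100 * .data$n / sum(.data$n), 1),
             stratum = s) |>
      ungroup()
  }) |> relocate("drug", "stratum", "level", "n", "pct")
}

#' Share of cases reporting a selected event class
#'
#' The proportion (as a percentage) of cases reporting at least one
#' reaction in the selected groups, per exposed drug and overall --
#' e.g. the share of neurological immune-mediated events among all
#' adverse-event reports for a drug.
#'
#' @param store A `report_store`.
#' @param dict Drug dictionary; `NULL` computes the overall share only.
#' @param groups Event-group map.
#' @param events Optional group labels (default: NAE-flagged groups).
#' @param roles Role codes defining exposure.
#' @return Tibble: `drug` (`"all"` row included), `n_reports`,
#'   `n_event`, `share_pct`.
#' @export
event_share <- function(store, dict = drug_dictionary(),
                        groups = event_group_map(), events = NULL,
                        roles = "PS") {
  stopifnot(inherits(store, "report_store"))
  ids <- event_case_ids(store, groups, events)
  overall <- tibble(drug = "all", n_reports = nrow(store$cases),
                    n_event = length(ids))
  per_drug <- if (is.null(dict)) {
    tibble(drug = character(), n_reports = integer(),
           n_event = integer())
  } else {
    select_suspect_exposures(store, dict, roles) |>
      group_by(drug = .data$ingredient) |>
      summarise(n_reports = n(),
                n_event = sum(.data$case_id %in% ids),
                .groups = "drop")
  }
  bind_rows(per_drug, overall) |>
    mutate(share_pct = round(100 * .data$n_event / .data$n_reports, 2))
}
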