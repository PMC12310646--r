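#' Build a 2x2 contingency cell for one drug-event pair
#'
#' Disproportionality statistics are computed from the four-cell table of
#' a drug-event pair over the whole deduplicated database: `a` = cases
#' reporting both the drug (under the chosen role rule) and at least one
#' reaction in the event group, `b` = drug without event, `c` = event
#' without drug, `d` = neither, `n = a+b+c+d` = database size. The
#' counting unit is the deduplicated case: a case with two preferred
#' terms in the same group contributes once.
#'
#' @param store A `report_store` (deduplicated).
#' @param exposure One ingredient or a character vector (counted as
#'   exposed if any matches).
#' @param event Event-group label present in `groups`.
#' @param dict Drug dictionary for exposure matching.
#' @param groups Event-group map.
#' @param roles Drug role codes defining exposure (default primary
#'   suspect).
#' @return One-row tibble: `drug`, `event`, `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(store, exposure, event,
                              dict = drug_dictionary(),
                              groups = event_group_map(), roles = "PS") {
  stopifnot(inherits(store, "report_store"))
  if (nrow(store$cases) == 0) abort("empty case store")
  if (!event %in% groups$group) {
    abort(paste0("unknown event group: ", event))
  }
  exposed <- select_suspect_exposures(store, dict, roles) |>
    filter(.data$ingredient %in% exposure) |>
    distinct(.data$case_id)
  with_event <- store$reactions |>
    mutate(group = map_pt_to_group(.data$pt, groups)) |>
    filter(.data$group == event) |>
    distinct(.data$case_id)
  n <- nrow(store$cases)
  a <- sum(exposed$case_id %in% with_event$case_id)
  b <- nrow(exposed) - a
  c_ <- nrow(with_event) - a
  tibble(drug = paste(exposure, collapse = "+"), event = event,
         a = a, b = b, c = c_, d = n - a - b - c_, n = n)
}

#' All drug-by-event contingency cells over a store
#'
#' Builds the full grid of 2x2 cells in one pass: exposures are the
#' distinct (case, drug) pairs under the role rule -- dictionary-matched
#' ingredients where possible, cleaned raw names otherwise -- and events
#' the distinct (case, group) pairs. With `complete = TRUE` zero-count
#' pairs of observed drugs x observed events are included (needed when
#' fitting the empirical-Bayes prior over the whole grid).
#'
#' @inheritParams build_contingency
#' @param drugs `"all"` to rank every drug in the store, or a character
#'   vector of ingredients to restrict to.
#' @param events Optional character vector of group labels (default all
#'   groups observed).
#' @param complete Include pairs with `a = 0`.
#' @return Tibble of cells, one row per drug-event pair.
#' @export
contingency_grid <- function(store, dict = drug_dictionary(),
                             groups = event_group_map(), drugs = "all",
                             events = NULL, roles = "PS",
                             complete = FALSE) {
  stopifnot(inherits(store, "report_store"))
  if (nrow(store$cases) == 0) abort("empty case store")
  n <- nrow(store$cases)
  exposures <- store$drugs |>
    filter(.data$role %in% roles) |>
    mutate(ingredient = normalize_drug_name(.data$raw_name, dict),
           drug = ifelse(is.na(.data$ingredient),
                         clean_drug_name(.data$raw_name),
                         .data$ingredient)) |>
    filter(nzchar(.data$drug)) |>
    distinct(.data$case_id, .data$drug)
  if (!identical(drugs, "all")) {
    exposures <- exposures |> filter(.data$drug %in% drugs)
  }
  ev <- store$reactions |>
    mutate(group = map_pt_to_group(.data$pt, groups)) |>
    filter(!is.na(.data$group)) |>
    distinct(.data$case_id, .data$group)
  if (!is.null(events)) ev <- ev |> filter(.data$group %in% events)
  drug_tot <- exposures |> count(.data$drug, name = "n_drug")
  ev_tot <- ev |> count(.data$group, name = "n_event")
  a_tab <- exposures |>
    inner_join(ev, by = "case_id", relationship = "many-to-many") |>
    count(.data$drug, .data$group, name = "a")
  grid <- if (complete) {
    tidyr::crossing(drug = drug_tot$drug, group = ev_tot$group)
  } else {
    a_tab |> select("drug", "group")
  }
  grid |>
    left_join(a_tab, by = c("drug", "group")) |>
    mutate(a = tidyr::replace_na(.data$a, 0L)) |>
    left_join(drug_tot, by = "drug") |>
    left_join(ev_tot, by = "group") |>
    transmute(drug = .data$drug, event = .data$group, a = .data$a,
              b = .data$n_drug - .data$a, c = .data$n_event - .data$a,
              d = n - .data$n_drug - .data$n_event + .data$a, n = n)
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ror = (a d)/(b c)`; the interval is
#' `exp(log ror +/- z sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell makes
#' the statistic undefined (`NA`) unless the Haldane-Anscombe 0.5
#' correction is requested.
#'
#' @param cells Tibble with columns `a`, `b`, `c`, `d` (one row per pair).
#' @param z Normal quantile for the interval (default 1.96, two-sided
#'   95%).
#' @param haldane Add 0.5 to every cell before computing.
#' @return `cells` with columns `ror`, `ror_lo`, `ror_hi` added.
#' @export
compute_ror <- function(cells, z = 1.96, haldane = FALSE) {
  k <- if (haldane) 0.5 else 0
  a <- as.numeric(cells$a) + k; b <- as.numeric(cells$b) + k
  c_ <- as.numeric(cells$c) + k; d <- as.numeric(cells$d) + k
  ok <- a > 0 & b > 0 & c_ > 0 & d > 0
  ror <- ifelse(ok, (a * d) / (b * c_), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c_ + 1 / d), NA_real_)
  cells |>
    mutate(ror = ror,
           ror_lo = exp(log(ror) - z * se),
           ror_hi = exp(log(ror) + z * se))
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' `prr = [a/(a+b)] / [c/(c+d)]`; the chi-squared statistic is the
#' Pearson one on the 2x2 table, `n (ad - bc)^2 /
#' ((a+b)(c+d)(a+c)(b+d))`, without continuity correction by default.
#' A zero margin (or zero `a`/`c` row rate) makes `prr` undefined.
#'
#' @inheritParams compute_ror
#' @param correct Apply the Yates continuity correction to chi-squared.
#' @return `cells` with columns `prr`, `chi2` added.
#' @export
compute_prr_chi2 <- function(cells, correct = FALSE) {
  a <- as.numeric(cells$a); b <- as.numeric(cells$b)
  c_ <- as.numeric(cells$c); d <- as.numeric(cells$d)
  n <- a + b + c_ + d
  m_ok <- (a + b) > 0 & (c_ + d) > 0 & (a + c_) > 0 & (b + d) > 0
  prr <- ifelse(m_ok & c_ > 0 & a > 0,
                (a / (a + b)) / (c_ / (c_ + d)), NA_real_)
  num <- abs(a * d - b * c_)
  if (correct) num <- pmax(num - n / 2, 0)
  chi2 <- ifelse(m_ok,
                 n * num^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d)),
                 NA_real_)
  cells |> mutate(prr = prr, chi2 = chi2)
}

#' Signal-detection thresholds for the four algorithms
#'
#' Literature-standard defaults: ROR flags when `a >= 3` and the lower
#' 95% bound exceeds 1; PRR when `a >= 3`, `prr >= 2` and
#' `chi2 >= 4`; BCPNN when `ic025 > 0` (strict); MGPS when
#' `ebgm05 > 2`. All thresholds are configuration, not code.
#'
#' @param ror_min_a,ror_lo ROR minimum count and lower-bound threshold.
#' @param prr_min_a,prr_min,chi2_min PRR thresholds.
#' @param ic025_min BCPNN lower-bound threshold (strict inequality).
#' @param ebgm05_min MGPS 5th-percentile threshold (strict inequality).
#' @return Named list of thresholds.
#' @export
signal_criteria <- function(ror_min_a = 3, ror_lo = 1, prr_min_a = 3,
                            prr_min = 2, chi2_min = 4, ic025_min = 0,
                            ebgm05_min = 2) {
  list(ror_min_a = ror_min_a, ror_lo = ror_lo, prr_min_a = prr_min_a,
       prr_min = prr_min, chi2_min = chi2_min, ic025_min = ic025_min,
       ebgm05_min = ebgm05_min)
}

#' Apply signal criteria to computed statistics
#'
#' An undefined (NA) statistic fails its flag. The overall signal is the
#' disjunction: a pair is flagged when at least one algorithm meets its
#' criteria.
#'
#' @param results Tibble with columns `a`, `ror_lo`, `prr`, `chi2`,
#'   `ic025`, `ebgm05` (as produced by [signal_stats()]).
#' @param criteria Thresholds from [signal_criteria()].
#' @return `results` with logical columns `flag_ror`, `flag_prr`,
#'   `flag_bcpnn`, `flag_mgps`, `signal` added.
#' @export
evaluate_signal_criteria <- function(results,
                                     criteria = signal_criteria()) {
  flag <- function(x) !is.na(x) & x
  results |>
    mutate(
      flag_ror = flag(.data$a >= criteria$ror_min_a &
                        .data$ror_lo > criteria$ror_lo),
      flag_prr = flag(.data$a >= criteria$prr_min_a &
                        .data$prr >= criteria$prr_min &
                        .data$chi2 >= criteria$chi2_min),
      flag_bcpnn = flag(.data$ic025 > criteria$ic025_min),
      flag_mgps = flag(.data$ebgm05 > criteria$ebgm05_min),
      signal = .data$flag_ror | .data$flag_prr | .data$flag_bcpnn |
        .data$flag_mgps)
}

#' All four disproportionality statistics for a set of cells
#'
#' Computes ROR (Woolf interval), PRR + Pearson chi-squared, the MGPS
#' shrinkage estimates (EBGM, EBGM05) under a gamma-mixture prior fitted
#' to the supplied cells (or a caller-supplied prior), and the BCPNN
#' information component in the selected convention, then applies the
#' signal criteria.
#'
#' @param cells Tibble of 2x2 cells (from [contingency_grid()] or
#'   [build_contingency()]).
#' @param prior Optional `gps_prior`; fitted on `cells` when `NULL`.
#' @param ic_convention `"mgps"` (IC = log2 EBGM with a normal-
#'   approximation lower bound) or `"noren"` (the self-contained
#'   credibility-interval approximation).
#' @param eb05_method `"quantile"` (exact mixture quantile by bisection)
#'   or `"normal_approx"` (`ebgm * exp(-1.645/sqrt(a))`).
#' @param criteria Thresholds from [signal_criteria()].
#' @param haldane Zero-cell correction for ROR (see [compute_ror()]).
#' @return Tibble with all statistics, flags and the fitted prior in
#'   attribute `"prior"`.
#' @export
signal_stats <- function(cells, prior = NULL,
                         ic_convention = c("mgps", "noren"),
                         eb05_method = c("quantile", "normal_approx"),
                         criteria = signal_criteria(), haldane = FALSE) {
  ic_convention <- match.arg(ic_convention)
  eb05_method <- match.arg(eb05_method)
  res <- cells |>
    compute_ror(haldane = haldane) |>
    compute_prr_chi2() |>
    mutate(e = expected_count(.data$a, .data$b, .data$c, .data$d))
  if (is.null(prior)) prior <- fit_gamma_mixture_prior(res$a, res$e)
  post <- gps_posterior(res$a, res$e, prior)
  res$ebgm <- ebgm_from_posterior(post)
  res$ebgm05 <- if (eb05_method == "quantile") {
    eb05_from_posterior(post)
  } else {
    res$ebgm * exp(qnorm(0.05) / sqrt(res$a))
  }
  ic <- compute_ic(res$a, res$e, ebgm = res$ebgm,
                   convention = ic_convention)
  res$ic <- ic$ic
  res$ic025 <- ic$ic025
  res <- evaluate_signal_criteria(res, criteria)
  attr(res, "prior") <- prior
  res
}

#' Rank drugs by reported case count for one event
#'
#' Reproduces the "top k drugs for an event" table: every drug in the
#' store (all ingredients, not only the dictionary targets) ranked by
#' `a`, descending, ties broken alphabetically, each row carrying all
#' four algorithms' statistics and flags.
#'
#' @inheritParams contingency_grid
#' @param event One event-group label.
#' @param k Number of rows to keep (fewer if fewer drugs have `a > 0`).
#' @param ... Passed to [signal_stats()].
#' @return Tibble of at most `k` ranked rows.
#' @export
rank_drugs_for_event <- function(store, event, dict = drug_dictionary(),
                                 groups = event_group_map(), k = 30,
                                 roles = "PS", ...) {
  stopifnot(k >= 1)
  cells <- contingency_grid(store, dict, groups, drugs = "all",
                            events = event, roles = roles)
  cells |>
    signal_stats(...) |>
    filter(.data$a > 0) |>
    arrange(desc(.data$a), .data$drug) |>
    head(k)
}
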