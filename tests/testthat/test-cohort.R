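test_that("trend correlation uses mid-ranks and matches a rank-Pearson oracle", {
  d <- tibble::tibble(year = 1:4, count = c(10, 10, 20, 30))
  r <- trend_correlation(d, "year", "count")
  expect_equal(r$r, 0.948683, tolerance = 1e-5)
  expect_equal(r$r, cor(rank(d$year), rank(d$count)))
  # strictly increasing counts: perfect monotonicity
  inc <- tibble::tibble(year = 2000:2009, count = (1:10)^2)
  expect_equal(trend_correlation(inc, "year", "count")$r, 1)
  expect_error(trend_correlation(tibble::tibble(year = 1:2,
                                                count = 1:2),
                                 "year", "count"),
               "at least 3 years")
  # oracle on random series: mid-rank Spearman == rank-then-Pearson
  set.seed(5)
  for (i in 1:50) {
    y <- sample(2000:2015)
    n <- sample(5:16, 1)
    cnt <- rpois(n, 20)
    dd <- tibble::tibble(year = y[seq_len(n)], count = cnt)
    expect_equal(trend_correlation(dd, "year", "count")$r,
                 cor(rank(dd$year), rank(dd$count)), tolerance = 1e-12)
  }
})

test_that("annual trend counts cases by reporting year", {
  sim <- simulate_reports(simulation_config(n_cases = 3000, seed = 21))
  tr <- annual_trend(sim$store, nae_only = FALSE)
  expect_s3_class(tr, "trend_result")
  expect_equal(sum(tr$count), 3000)
  cc <- attr(tr, "correlation")
  # year weights grow linearly in the generator, so the trend is positive
  expect_gt(cc$r, 0.5)
  p <- ggplot2::autoplot(tr)
  expect_s3_class(p, "ggplot")
})

test_that("time-to-onset quartiles follow the interpolation convention", {
  ids <- as.character(1:5)
  start <- as.Date("2023-01-01")
  drugs <- tibble::tibble(case_id = ids, raw_name = "nivolumab",
                          role = "PS", start_date = start)
  reac <- tibble::tibble(case_id = ids, pt = "myasthenia gravis",
                         onset_date = start + c(10, 20, 30, 40, 50))
  store <- make_store(ids, drugs = drugs, reactions = reac)
  tto <- time_to_onset(store)
  pooled <- tto[tto$drug == "all", ]
  expect_equal(pooled$median_days, 30)
  expect_equal(pooled$q1_days, 20)
  expect_equal(pooled$q3_days, 40)
  # same-day onset is usable with interval zero
  one <- make_store("1",
    drugs = tibble::tibble(case_id = "1", raw_name = "nivolumab",
                           role = "PS", start_date = start),
    reactions = tibble::tibble(case_id = "1", pt = "myositis",
                               onset_date = start))
  expect_equal(time_to_onset(one)$median_days[1], 0)
})

test_that("time-to-onset exclusion accounting is conserved", {
  ids <- as.character(1:6)
  start <- as.Date("2023-06-01")
  drugs <- tibble::tibble(
    case_id = ids, raw_name = "pembrolizumab", role = "PS",
    start_date = c(start, start, start, as.Date(NA), start, start))
  reac <- tibble::tibble(
    case_id = ids, pt = "myositis",
    onset_date = c(start + 5, start - 3, start + 10, start + 2,
                   as.Date(NA), start + 40))
  store <- make_store(ids, drugs = drugs, reactions = reac)
  tto <- time_to_onset(store)
  ex <- attr(tto, "exclusions")
  expect_equal(ex[["usable"]] + ex[["excluded_negative"]] +
                 ex[["excluded_undated"]], ex[["candidates"]])
  expect_equal(ex[["usable"]], 3)
  expect_equal(ex[["excluded_negative"]], 1)
  expect_equal(ex[["excluded_undated"]], 2)
})

test_that("mortality rates divide deaths by group reports", {
  tal <- tibble::tibble(group = c("MG_SPECTRUM", "CIDP", "NMOSD"),
                        deaths = c(30, 0, 2),
                        reports = c(100, 40, 25))
  store <- outcome_tally_store(tal)
  mr <- mortality_rates(store)
  expect_equal(mr$rate_pct[mr$group == "MG_SPECTRUM"], 30)
  expect_equal(mr$rate_pct[mr$group == "CIDP"], 0)
  expect_equal(mr$rate_pct[mr$group == "NMOSD"], 8)
  expect_true(all(mr$deaths <= mr$reports))
  p <- plot_mortality(mr)
  expect_s3_class(p, "ggplot")
})

test_that("severity association reproduces the Pearson closed form", {
  # group A: 10 serious / 90 non-serious; group B supplies the 30/70 rest
  tal <- tibble::tibble(group = c("AIE", "GBS_SPECTRUM"),
                        deaths = c(10, 30), reports = c(100, 100))
  store <- outcome_tally_store(tal)
  sa <- severity_association(store, method = "none")
  row <- sa[sa$group == "AIE", ]
  expect_equal(row$chi2, 12.5)
  expect_equal(row$serious, 10)
  expect_equal(row$non_serious, 90)
  # identical proportions: no association
  tal2 <- tibble::tibble(group = c("AIE", "GBS_SPECTRUM"),
                         deaths = c(20, 20), reports = c(100, 100))
  sa2 <- severity_association(outcome_tally_store(tal2),
                              method = "none")
  expect_equal(sa2$chi2, c(0, 0), tolerance = 1e-12)
  expect_equal(sa2$p_value, c(1, 1), tolerance = 1e-12)
})

test_that("2x2 chi-squared equals the squared two-proportion z statistic", {
  set.seed(99)
  for (i in 1:500) {
    m <- matrix(rpois(4, 40) + 1, 2)
    n1 <- sum(m[1, ]); n2 <- sum(m[2, ])
    p1 <- m[1, 1] / n1; p2 <- m[2, 1] / n2
    pp <- (m[1, 1] + m[2, 1]) / (n1 + n2)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    got <- compute_prr_chi2(tibble::tibble(a = m[1, 1], b = m[1, 2],
                                           c = m[2, 1], d = m[2, 2]))
    expect_equal(got$chi2, z^2, tolerance = 1e-10)
  }
})

test_that("severity counts partition each group's cases", {
  sim <- simulate_reports(simulation_config(n_cases = 2000, seed = 31))
  store <- sim$store
  sa <- severity_association(store)
  mr <- mortality_rates(store)
  sev <- case_severity(store)
  mem <- store$reactions |>
    dplyr::mutate(group = map_pt_to_group(pt)) |>
    dplyr::filter(!is.na(group)) |>
    dplyr::distinct(case_id, group) |>
    dplyr::left_join(sev, by = "case_id") |>
    dplyr::count(group, severity) |>
    tidyr::pivot_wider(names_from = severity, values_from = n,
                       values_fill = 0)
  for (g in sa$group) {
    row <- sa[sa$group == g, ]
    tot <- mr$reports[mr$group == g]
    unk <- if ("UNKNOWN" %in% names(mem)) {
      mem$UNKNOWN[mem$group == g]
    } else {
      0
    }
    expect_equal(row$serious + row$non_serious + unk, tot)
  }
})

test_that("demographic tables give per-drug percentages that total 100", {
  ids <- as.character(1:4)
  cases <- blank_cases(ids)
  cases$sex <- c("M", "M", "F", "UNK")
  drugs <- tibble::tibble(case_id = ids, raw_name = "atezolizumab",
                          role = "PS", start_date = as.Date(NA))
  store <- make_store(ids, drugs = drugs, cases = cases)
  dt <- demographic_table(store, strata = "sex")
  expect_equal(dt$pct[dt$level == "M"], 50)
  expect_equal(dt$pct[dt$level == "F"], 25)
  expect_equal(dt$pct[dt$level == "UNK"], 25)
  # percentages within every (drug, stratum) block sum to 100 +/- 0.2
  sim <- simulate_reports(simulation_config(n_cases = 1500, seed = 13))
  full <- demographic_table(sim$store,
                            strata = c("sex", "age_group", "reporter",
                                       "outcome", "weight_band"))
  sums <- full |>
    dplyr::group_by(drug, stratum) |>
    dplyr::summarise(s = sum(pct), .groups = "drop")
  expect_true(all(abs(sums$s - 100) <= 0.2))
})

test_that("indication stratum tabulates the recorded treatment reasons", {
  ids <- as.character(1:4)
  drugs <- tibble::tibble(case_id = ids, raw_name = "nivolumab",
                          role = "PS", start_date = as.Date(NA))
  indi <- tibble::tibble(case_id = c("1", "2", "3"),
                         indication_pt = c("lung cancer",
                                           "lung cancer",
                                           "malignant melanoma"))
  store <- make_store(ids, drugs = drugs, indications = indi)
  dt <- demographic_table(store, strata = "indication")
  expect_equal(dt$n[dt$level == "lung cancer"], 2)
  expect_equal(dt$pct[dt$level == "UNK"], 25)
  expect_error(demographic_table(store, strata = "shoe_size"),
               "unknown strata")
})

test_that("event shares report percentages of exposed cases", {
  store <- share_store("cemiplimab", n_event = 3, n_total = 50)
  es <- event_share(store)
  expect_equal(es$share_pct[es$drug == "cemiplimab"], 6)
  expect_equal(es$share_pct[es$drug == "all"], 6)
})
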