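#' Configuration for a synthetic spontaneous-report database
#'
#' Defines every knob of the generator: database size, drug popularity
#' (power-law by default, as report volume is in real reporting systems),
#' per-event background reporting probabilities, planted drug-event
#' signals as relative-risk multipliers over the background, the
#' duplicate-version rate, event-specific death probabilities, a
#' log-normal time-to-onset model, demographic category distributions
#' and date ranges. Defaults emulate a mid-sized extract dominated by
#' immune checkpoint inhibitors with neurological immune-mediated events
#' over a null background of common non-specific reactions.
#'
#' @param n_cases Number of distinct cases.
#' @param drugs Tibble `drug`, `weight` (normalized internally).
#' @param events Tibble `pt`, `p_background`, `death_prob`.
#' @param signal_pairs Tibble `drug`, `pt`, `rr` of planted signals.
#' @param duplicate_rate Fraction of cases that also emit an earlier
#'   report version.
#' @param onset_meanlog,onset_sdlog Log-normal onset-delay parameters in
#'   days (defaults give a median of 30 days).
#' @param start_missing_rate,onset_missing_rate Fractions of start/onset
#'   dates blanked to emulate incomplete reports.
#' @param concomitant_rate Fraction of cases that carry an extra drug row
#'   with role C (exercises role filtering).
#' @param extra_same_group_pt_rate Fraction of event rows that emit a
#'   second preferred term from the same composite group (exercises the
#'   count-once rule).
#' @param brand_fraction Fraction of drug rows written under a brand
#'   synonym instead of the ingredient name.
#' @param sex_probs,reporter_probs,country_probs Named probability
#'   vectors.
#' @param year_range Two integers; reporting years are drawn with
#'   linearly increasing weight over this span (reporting growth).
#' @param no_outcome_rate Fraction of non-death cases with no outcome
#'   rows at all.
#' @param seed Integer seed; the whole simulation is deterministic given
#'   the config.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    n_cases = 20000,
    drugs = NULL,
    events = NULL,
    signal_pairs = tibble(drug = "pembrolizumab",
                          pt = "encephalitis autoimmune", rr = 10),
    duplicate_rate = 0.1,
    onset_meanlog = log(30), onset_sdlog = 0.8,
    start_missing_rate = 0.1, onset_missing_rate = 0.1,
    concomitant_rate = 0.3,
    extra_same_group_pt_rate = 0,
    brand_fraction = 0,
    sex_probs = c(F = 0.32, M = 0.59, UNK = 0.09),
    reporter_probs = c(MD = 0.53, HP = 0.19, CN = 0.10, PH = 0.07,
                       OT = 0.08, UNK = 0.03),
    country_probs = c(US = 0.30, JP = 0.28, FR = 0.09, DE = 0.05,
                      GB = 0.04, OTH = 0.24),
    year_range = c(2016, 2024),
    no_outcome_rate = 0.1,
    seed = 1L) {
  if (n_cases <= 0) abort("n_cases must be positive")
  if (is.null(drugs)) {
    nm <- c(target_ingredients(), paste0("agent ", letters[1:13]))
    w <- seq_along(nm)^(-0.8)
    drugs <- tibble(drug = nm, weight = w / sum(w))
  }
  drugs <- as_tibble(drugs) |>
    mutate(weight = .data$weight / sum(.data$weight))
  if (is.null(events)) {
    events <- tibble(
      pt = c("encephalitis autoimmune", "guillain-barre syndrome",
             "myasthenia gravis", "myositis", "myelitis transverse",
             "meningitis aseptic",
             "chronic inflammatory demyelinating polyradiculoneuropathy",
             "neuromyelitis optica spectrum disorder",
             "central nervous system vasculitis",
             "headache", "nausea", "fatigue", "pyrexia"),
      p_background = c(0.010, 0.008, 0.012, 0.012, 0.006, 0.006,
                       0.004, 0.003, 0.003, 0.08, 0.08, 0.06, 0.05),
      death_prob = c(0.20, 0.19, 0.30, 0.28, 0.15, 0.04,
                     0.02, 0.10, 0.10, 0.02, 0.02, 0.02, 0.02))
  }
  events <- as_tibble(events)
  stopifnot(all(events$p_background >= 0 & events$p_background <= 1),
            all(events$death_prob >= 0 & events$death_prob <= 1),
            all(signal_pairs$rr > 0))
  structure(list(
    n_cases = as.integer(n_cases), drugs = drugs, events = events,
    signal_pairs = as_tibble(signal_pairs),
    duplicate_rate = duplicate_rate,
    onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
    start_missing_rate = start_missing_rate,
    onset_missing_rate = onset_missing_rate,
    concomitant_rate = concomitant_rate,
    extra_same_group_pt_rate = extra_same_group_pt_rate,
    brand_fraction = brand_fraction,
    sex_probs = sex_probs, reporter_probs = reporter_probs,
    country_probs = country_probs, year_range = year_range,
    no_outcome_rate = no_outcome_rate, seed = as.integer(seed)),
    class = "simulation_config")
}

sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Simulate a ground-truthed spontaneous-report database
#'
#' Generates cases per the configuration: one suspect drug per case drawn
#' from the popularity weights, events included independently with
#' probability `p_background * rr(drug, event)` (capped at 1, with a
#' warning), at least one event per case guaranteed by redrawing empty
#' cases, demographics and dates drawn from the configured distributions,
#' an onset delay per case from the log-normal model, outcome codes with
#' event-specific death probabilities, and -- for a configured fraction
#' of cases -- an earlier duplicate report version. Fully deterministic
#' given the config (including its seed).
#'
#' @param config A [simulation_config()].
#' @return A `sim_reports` object: list with `store` (the ground-truth
#'   deduplicated `report_store`), `tables` (raw per-version tables,
#'   duplicates included, as written to disk) and `truth` (planted
#'   quantities: per-pair counts, planted rr, latest version per case,
#'   planted onset delays).
#' @export
simulate_reports <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, .simulate_reports_impl(config))
}

.simulate_reports_impl <- function(cfg) {
  n <- cfg$n_cases
  ev <- cfg$events
  case_id <- sprintf("C%07d", seq_len(n))
  drug <- sample(cfg$drugs$drug, n, replace = TRUE,
                 prob = cfg$drugs$weight)

  # per-case x event inclusion probabilities with planted multipliers
  pmat <- matrix(rep(ev$p_background, each = n), nrow = n)
  for (i in seq_len(nrow(cfg$signal_pairs))) {
    sp <- cfg$signal_pairs[i, ]
    j <- match(sp$pt, ev$pt)
    if (is.na(j)) abort(paste0("planted pt not in event list: ", sp$pt))
    rows <- drug == sp$drug
    pmat[rows, j] <- pmat[rows, j] * sp$rr
  }
  if (any(pmat > 1)) {
    warn("some rr-multiplied event probabilities exceeded 1; capped")
    pmat <- pmin(pmat, 1)
  }
  emat <- matrix(rbinom(length(pmat), 1, pmat), nrow = n)
  # every case must report at least one event: redraw empty rows
  repeat {
    none <- rowSums(emat) == 0
    if (!any(none)) break
    k <- sum(none)
    emat[none, ] <- matrix(rbinom(k * ncol(pmat), 1, pmat[none, ]),
                           nrow = k)
  }

  # demographics
  sex <- sample_cat(n, cfg$sex_probs)
  age_group_draw <- sample_cat(n, c(`<18` = 0.02, `18-64` = 0.30,
                                    `65-84` = 0.48, `>85` = 0.02,
                                    UNK = 0.18))
  age <- dplyr::case_when(
    age_group_draw == "<18" ~ round(runif(n, 5, 17)),
    age_group_draw == "18-64" ~ round(runif(n, 18, 64)),
    age_group_draw == "65-84" ~ round(runif(n, 65, 84)),
    age_group_draw == ">85" ~ round(runif(n, 85, 95)),
    TRUE ~ NA_real_)
  weight <- ifelse(runif(n) < 0.4, round(runif(n, 45, 110), 1),
                   NA_real_)
  reporter <- sample_cat(n, cfg$reporter_probs)
  country <- sample_cat(n, cfg$country_probs)

  # dates: reporting grows linearly over the configured span
  years <- seq(cfg$year_range[1], cfg$year_range[2])
  yr <- sample(years, n, replace = TRUE,
               prob = seq_along(years) / sum(seq_along(years)))
  start <- as.Date(paste0(yr, "-01-01")) +
    floor(runif(n, 0, 334))
  onset_days <- pmax(round(rlnorm(n, cfg$onset_meanlog,
                                  cfg$onset_sdlog)), 0)
  onset <- start + onset_days
  receipt <- onset + floor(runif(n, 10, 120))
  start_obs <- replace(start, runif(n) < cfg$start_missing_rate,
                       as.Date(NA))
  onset_obs <- replace(onset, runif(n) < cfg$onset_missing_rate,
                       as.Date(NA))

  # reactions (one onset per case, shared by its reactions)
  hit <- which(emat == 1, arr.ind = TRUE)
  reactions <- tibble(case_id = case_id[hit[, 1]],
                      pt = ev$pt[hit[, 2]],
                      onset_date = onset_obs[hit[, 1]]) |>
    arrange(.data$case_id, .data$pt)
  if (cfg$extra_same_group_pt_rate > 0) {
    gm <- event_group_map()
    extra <- reactions |>
      mutate(group = map_pt_to_group(.data$pt, gm)) |>
      filter(!is.na(.data$group),
             runif(n()) < cfg$extra_same_group_pt_rate) |>
      inner_join(gm |> select("pt", "group") |>
                   rename(pt2 = "pt"), by = "group",
                 relationship = "many-to-many") |>
      filter(.data$pt2 != .data$pt) |>
      group_by(.data$case_id, .data$pt) |>
      slice_head(n = 1) |>
      ungroup() |>
      transmute(case_id = .data$case_id, pt = .data$pt2,
                onset_date = .data$onset_date)
    reactions <- bind_rows(reactions, extra) |>
      distinct() |> arrange(.data$case_id, .data$pt)
  }

  # outcomes: death probability is the max over the case's events
  dmax <- apply(emat * rep(ev$death_prob, each = n), 1, max)
  died <- runif(n) < dmax
  no_outc <- !died & runif(n) < cfg$no_outcome_rate
  nondeath_code <- sample(c("HO", "LT", "OT", "DS"), n, replace = TRUE,
                          prob = c(0.55, 0.2, 0.2, 0.05))
  fatal_ids <- case_id[died]
  outcomes <- bind_rows(
    tibble(case_id = fatal_ids, code = "DE"),
    # many fatal reports also carry a hospitalization row
    tibble(case_id = fatal_ids[runif(length(fatal_ids)) < 0.5],
           code = "HO"),
    tibble(case_id = case_id[!died & !no_outc],
           code = nondeath_code[!died & !no_outc])
  ) |> distinct() |> arrange(.data$case_id)

  # drug rows: suspect (possibly brand-named) + optional concomitant
  brand_lookup <- drug_dictionary() |>
    filter(.data$synonym != .data$ingredient) |>
    group_by(.data$ingredient) |>
    slice_head(n = 1) |>
    ungroup()
  write_name <- drug
  if (cfg$brand_fraction > 0) {
    swap <- runif(n) < cfg$brand_fraction
    br <- brand_lookup$synonym[match(drug, brand_lookup$ingredient)]
    write_name <- ifelse(swap & !is.na(br), br, drug)
  }
  conc <- runif(n) < cfg$concomitant_rate
  conc_drug <- sample(cfg$drugs$drug, n, replace = TRUE,
                      prob = cfg$drugs$weight)
  drugs_tab <- bind_rows(
    tibble(case_id = case_id, raw_name = write_name, role = "PS",
           start_date = start_obs),
    tibble(case_id = case_id[conc], raw_name = conc_drug[conc],
           role = "C", start_date = as.Date(NA))
  ) |> arrange(.data$case_id, desc(.data$role == "PS"))

  cases <- tibble(
    case_id = case_id, sex = sex,
    age_years = age, age_group = age_group_of(age),
    weight_kg = weight, reporter = reporter, country = country,
    event_date = onset_obs,
    receipt_int = as.numeric(format(receipt, "%Y%m%d")),
    year = as.numeric(format(receipt, "%Y")))
  store <- new_report_store(
    cases = cases, drugs = drugs_tab, reactions = reactions,
    outcomes = outcomes, source = "FAERS",
    quarters = "synthetic",
    stats = c(raw_versions = n, surviving = n, duplicate_versions = 0,
              orphan_rows = 0))

  # raw per-version tables: latest version 2 (or 1), plus an earlier
  # version for a duplicate_rate fraction
  pkey <- sprintf("%d02", seq_len(n) + 10000000)
  dup_idx <- which(runif(n) < cfg$duplicate_rate)
  dup_pkey <- sprintf("%d01", dup_idx + 10000000)
  dup_receipt <- receipt[dup_idx] - floor(runif(length(dup_idx), 30, 200))
  demo_raw <- bind_rows(
    tibble(primaryid = pkey, caseid = case_id, caseversion = "2",
           fda_dt = format(receipt, "%Y%m%d"),
           event_dt = ifelse(is.na(onset_obs), "",
                             format(onset_obs, "%Y%m%d")),
           age = ifelse(is.na(age), "", as.character(age)),
           age_cod = ifelse(is.na(age), "", "YR"),
           sex = ifelse(sex == "UNK", "", sex),
           wt = ifelse(is.na(weight), "", as.character(weight)),
           wt_cod = ifelse(is.na(weight), "", "KG"),
           occp_cod = ifelse(reporter == "UNK", "", reporter),
           reporter_country = country, occr_country = country),
    tibble(primaryid = dup_pkey, caseid = case_id[dup_idx],
           caseversion = "1",
           fda_dt = format(dup_receipt, "%Y%m%d"),
           event_dt = "", age = "", age_cod = "", sex = "",
           wt = "", wt_cod = "", occp_cod = "",
           reporter_country = country[dup_idx],
           occr_country = country[dup_idx]))
  pkey_of <- setNames(pkey, case_id)
  drug_raw <- drugs_tab |>
    mutate(primaryid = pkey_of[.data$case_id]) |>
    group_by(.data$case_id) |>
    mutate(drug_seq = as.character(row_number())) |>
    ungroup() |>
    transmute(primaryid = .data$primaryid, caseid = .data$case_id,
              drug_seq = .data$drug_seq, role_cod = .data$role,
              drugname = toupper(.data$raw_name),
              start_dt = ifelse(is.na(.data$start_date), "",
                                format(.data$start_date, "%Y%m%d")))
  reac_raw <- reactions |>
    mutate(primaryid = pkey_of[.data$case_id]) |>
    transmute(primaryid = .data$primaryid, caseid = .data$case_id,
              pt = .data$pt,
              onset_dt = ifelse(is.na(.data$onset_date), "",
                                format(.data$onset_date, "%Y%m%d")))
  outc_raw <- outcomes |>
    mutate(primaryid = pkey_of[.data$case_id]) |>
    transmute(primaryid = .data$primaryid, caseid = .data$case_id,
              outc_cod = .data$code)
  # duplicate versions carry the same child rows under their own key
  dup_children <- function(tab) {
    sub <- tab |> filter(.data$caseid %in% case_id[dup_idx])
    sub$primaryid <- setNames(dup_pkey, case_id[dup_idx])[sub$caseid]
    sub
  }
  drug_raw <- bind_rows(drug_raw, dup_children(drug_raw))
  reac_raw <- bind_rows(reac_raw, dup_children(reac_raw))
  outc_raw <- bind_rows(outc_raw, dup_children(outc_raw))
  indi_raw <- tibble(primaryid = character(), caseid = character(),
                     indi_drug_seq = character(),
                     indi_pt = character())

  gm <- event_group_map()
  truth_pairs <- tibble(case_id = case_id, drug = drug) |>
    inner_join(reactions |> select("case_id", "pt"), by = "case_id") |>
    count(.data$drug, .data$pt, name = "a")
  truth <- list(
    pair_counts = truth_pairs,
    planted = cfg$signal_pairs,
    n_cases = n,
    latest_pkey = tibble(case_id = case_id, primaryid = pkey),
    onset_days = tibble(case_id = case_id, days = onset_days),
    n_duplicates = length(dup_idx))
  structure(list(store = store,
                 tables = list(demo = demo_raw, drug = drug_raw,
                               reac = reac_raw, outc = outc_raw,
                               indi = indi_raw),
                 truth = truth, config = cfg),
            class = "sim_reports")
}

#' @export
print.sim_reports <- function(x, ...) {
  cat("<sim_reports> ", x$truth$n_cases, " cases (+",
      x$truth$n_duplicates, " duplicate versions), ",
      nrow(x$store$reactions), " reaction rows, ",
      nrow(x$truth$planted), " planted signal pair(s)\n", sep = "")
  invisible(x)
}

#' Write a simulated database in the FAERS file dialect
#'
#' Emits DEMO/DRUG/REAC/OUTC/INDI as "$"-delimited files with FAERS-style
#' headers (duplicate case versions included), guaranteed to round-trip
#' through [parse_faers_quarter()] and [deduplicate_cases()].
#'
#' @param sim A `sim_reports` object.
#' @param dir Output directory (created if absent).
#' @param quarter_label Used in file names, e.g. `DEMO24Q1.txt`.
#' @return Named character vector of the five file paths, invisibly
#'   usable as the `paths` argument of [parse_faers_quarter()].
#' @export
write_faers_dialect <- function(sim, dir, quarter_label = "2024Q1") {
  stopifnot(inherits(sim, "sim_reports"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  suffix <- sub("^\\d{2}", "", sub("Q", "Q", quarter_label))
  files <- c(demo = "DEMO", drug = "DRUG", reac = "REAC",
             outc = "OUTC", indi = "INDI")
  out <- character()
  for (nm in names(files)) {
    path <- file.path(dir, paste0(files[[nm]], suffix, ".txt"))
    tab <- sim$tables[[nm]]
    lines <- c(paste(names(tab), collapse = "$"),
               do.call(paste, c(as.list(tab), sep = "$")))
    writeLines(lines, path)
    out[nm] <- path
  }
  invisible(out)
}

#' Write a simulated database in the JADER file dialect
#'
#' Emits comma-separated demo/drug/reac tables (one row per case; the
#' JADER dialect carries no version or outcome tables). Round-trips
#' through [parse_jader_tables()].
#'
#' @param sim A `sim_reports` object.
#' @param dir Output directory.
#' @param encoding Output encoding (default UTF-8).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_jader_dialect <- function(sim, dir, encoding = "UTF-8") {
  stopifnot(inherits(sim, "sim_reports"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- sim$store
  fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y%m%d"))
  demo <- st$cases |>
    transmute(case_id = .data$case_id,
              sex = ifelse(.data$sex == "UNK", "", .data$sex),
              age = ifelse(is.na(.data$age_years), "",
                           as.character(.data$age_years)),
              weight = ifelse(is.na(.data$weight_kg), "",
                              as.character(.data$weight_kg)),
              reporter = ifelse(.data$reporter == "UNK", "",
                                .data$reporter),
              receipt_date = ifelse(.data$receipt_int > 0,
                                    as.character(.data$receipt_int), ""))
  drug <- st$drugs |>
    transmute(case_id = .data$case_id, role = .data$role,
              drug_name = .data$raw_name,
              start_date = fmt_date(.data$start_date))
  reac <- st$reactions |>
    transmute(case_id = .data$case_id, pt = .data$pt,
              onset_date = fmt_date(.data$onset_date))
  out <- character()
  for (nm in c("demo", "drug", "reac")) {
    path <- file.path(dir, paste0(nm, ".csv"))
    tab <- get(nm)
    txt <- readr::format_csv(tab)
    con <- file(path, open = "wb")
    writeBin(iconv(txt, from = "UTF-8", to = encoding, toRaw = TRUE)[[1]],
             con)
    close(con)
    out[nm] <- path
  }
  invisible(out)
}
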