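#' @section Case store:
#' A `report_store` is the unified, deduplicated representation of a
#' spontaneous-reporting database: four tibbles linked by `case_id`
#' (`cases`, `drugs`, `reactions`, `outcomes`) plus provenance attributes.
#' One case = one demographic row, one or more drug rows with role codes,
#' one or more MedDRA-coded reaction rows, zero or more outcome rows.
#' @name report_store
NULL

# ---- date helpers -----------------------------------------------------

# Regulatory dates arrive as YYYYMMDD, YYYYMM or YYYY strings. For version
# ordering partial dates are zero-padded (YYYYMM00, YYYY0000); for interval
# arithmetic only full dates are trusted (partial -> NA).
date_int_pad <- function(x) {
  x <- trimws(as.character(x))
  n <- nchar(x)
  v <- suppressWarnings(as.numeric(x))
  out <- rep(0, length(x))
  out[!is.na(v) & n == 8] <- v[!is.na(v) & n == 8]
  out[!is.na(v) & n == 6] <- v[!is.na(v) & n == 6] * 100
  out[!is.na(v) & n == 4] <- v[!is.na(v) & n == 4] * 10000
  out
}

date_from_int <- function(x) {
  x <- trimws(as.character(x))
  ok <- grepl("^\\d{8}$", x)
  d <- rep(as.Date(NA), length(x))
  d[ok] <- as.Date(x[ok], format = "%Y%m%d")
  d
}

# ---- FAERS parsing ----------------------------------------------------

#' Column aliases across FAERS header eras
#'
#' FAERS quarterly files changed headers over the years (e.g. `isr` vs
#' `primaryid`). This map resolves each canonical field to its known
#' aliases; extend it for local dialects.
#'
#' @return Named list: canonical name -> character vector of accepted
#'   lowercase column names, in priority order.
#' @export
faers_column_aliases <- function() {
  list(
    primaryid = c("primaryid", "isr"),
    caseid = c("caseid", "case"),
    receipt_date = c("fda_dt", "init_fda_dt", "rept_dt"),
    event_date = c("event_dt"),
    age = c("age"), age_cod = c("age_cod"),
    sex = c("sex", "gndr_cod"),
    weight = c("wt"), weight_cod = c("wt_cod"),
    reporter = c("occp_cod"),
    reporter_country = c("reporter_country"),
    occr_country = c("occr_country"),
    role = c("role_cod"),
    drugname = c("drugname"),
    start_date = c("start_dt"),
    pt = c("pt"),
    onset_date = c("onset_dt"),
    outcome = c("outc_cod", "outc_code"),
    indication = c("indi_pt")
  )
}

pick_col <- function(df, aliases, canonical, default = NA_character_) {
  for (nm in aliases[[canonical]]) {
    if (nm %in% names(df)) return(as.character(df[[nm]]))
  }
  rep(default, nrow(df))
}

# Parse one "$"-delimited FAERS-style table. Rows whose field count does
# not match the header are skipped and counted.
read_faers_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    warn(paste0("empty table file: ", path))
    out <- tibble()
    attr(out, "skipped") <- 0L
    return(out)
  }
  header <- tolower(strsplit(lines[1], "$", fixed = TRUE)[[1]])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(body, "$", fixed = TRUE)
  # a trailing empty field is dropped by strsplit; pad back
  fields <- lapply(fields, function(f) {
    if (length(f) == length(header) - 1) c(f, "") else f
  })
  ok <- lengths(fields) == length(header)
  skipped <- sum(!ok)
  if (skipped > 0) {
    warn(paste0(path, ": skipped ", skipped,
                " malformed row(s) (wrong field count)"))
  }
  if (any(ok)) {
    m <- matrix(unlist(fields[ok]), ncol = length(header), byrow = TRUE)
    out <- as_tibble(as.data.frame(m, stringsAsFactors = FALSE),
                     .name_repair = "minimal")
    names(out) <- header
  } else {
    out <- as_tibble(setNames(rep(list(character()), length(header)),
                              header))
  }
  attr(out, "skipped") <- as.integer(skipped)
  out
}

#' Parse one quarter of FAERS-dialect tables
#'
#' Reads the "$"-delimited DEMO/DRUG/REAC/OUTC/INDI files of one quarterly
#' extract. DEMO, DRUG and REAC are required; OUTC and INDI optional.
#' Unknown columns are tolerated; rows with the wrong field count are
#' skipped with a reported count.
#'
#' @param paths Named list/vector of file paths; names among `demo`,
#'   `drug`, `reac`, `outc`, `indi` (case-insensitive).
#' @param quarter_label Label such as `"2019Q3"` carried as provenance.
#' @return A `raw_table_set`: list with `source = "FAERS"`, the five row
#'   tibbles (columns keyed by lowercase header names), `quarter_label`
#'   and a named `skipped` count vector.
#' @export
parse_faers_quarter <- function(paths, quarter_label = "unknown") {
  names(paths) <- tolower(names(paths))
  for (req in c("demo", "drug", "reac")) {
    if (!req %in% names(paths) || !file.exists(paths[[req]])) {
      abort(paste0("missing required FAERS table: ", toupper(req)))
    }
  }
  tabs <- list()
  skipped <- integer()
  for (nm in c("demo", "drug", "reac", "outc", "indi")) {
    if (nm %in% names(paths) && file.exists(paths[[nm]])) {
      tabs[[nm]] <- read_faers_table(paths[[nm]])
      skipped[nm] <- attr(tabs[[nm]], "skipped")
    } else {
      tabs[[nm]] <- tibble()
      skipped[nm] <- 0L
    }
  }
  structure(list(source = "FAERS", quarter_label = quarter_label,
                 demo_rows = tabs$demo, drug_rows = tabs$drug,
                 reac_rows = tabs$reac, outc_rows = tabs$outc,
                 indi_rows = tabs$indi, skipped = skipped),
            class = "raw_table_set")
}

#' Parse JADER-dialect CSV tables
#'
#' Reads the comma-separated demo/drug/reac tables of a JADER-style
#' extract. The encoding is configurable (default UTF-8; a single-byte
#' fallback such as `"CP932"`/`"SHIFT-JIS"` may be selected). Outcome and
#' indication tables do not exist in this dialect.
#'
#' @param paths Named list/vector with elements `demo`, `drug`, `reac`.
#' @param encoding Character encoding of the files.
#' @return A `raw_table_set` with `source = "JADER"` and empty
#'   `outc_rows`/`indi_rows`.
#' @export
parse_jader_tables <- function(paths, encoding = "UTF-8") {
  names(paths) <- tolower(names(paths))
  for (req in c("demo", "drug", "reac")) {
    if (!req %in% names(paths) || !file.exists(paths[[req]])) {
      abort(paste0("missing required JADER table: ", req))
    }
  }
  read_one <- function(path) {
    raw <- readBin(path, "raw", n = file.size(path))
    txt <- iconv(rawToChar(raw), from = encoding, to = "UTF-8")
    if (is.na(txt)) {
      # locate the first undecodable byte for the error message
      off <- 1
      step <- 4096
      while (off <= length(raw)) {
        chunk <- rawToChar(raw[seq(1, min(off + step, length(raw)))])
        if (is.na(iconv(chunk, from = encoding, to = "UTF-8"))) break
        off <- off + step
      }
      abort(paste0(path, ": bytes undecodable as ", encoding,
                   " near offset ", off))
    }
    df <- readr::read_csv(I(txt), col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE)
    names(df) <- tolower(names(df))
    df
  }
  structure(list(source = "JADER", quarter_label = "all",
                 demo_rows = read_one(paths[["demo"]]),
                 drug_rows = read_one(paths[["drug"]]),
                 reac_rows = read_one(paths[["reac"]]),
                 outc_rows = tibble(), indi_rows = tibble(),
                 skipped = c(demo = 0L, drug = 0L, reac = 0L)),
            class = "raw_table_set")
}

# ---- harmonization ----------------------------------------------------

.age_unit_years <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
                     DY = 1 / 365.25, HR = 1 / 8766)

age_to_years <- function(age, unit) {
  v <- suppressWarnings(as.numeric(age))
  unit <- toupper(trimws(ifelse(is.na(unit) | unit == "", "YR", unit)))
  f <- unname(.age_unit_years[unit])
  out <- v * f
  out[is.na(f) | is.na(v) | out < 0] <- NA_real_
  out
}

age_group_of <- function(age_years) {
  cut(age_years, breaks = c(-Inf, 18, 65, 85, Inf), right = FALSE,
      labels = c("<18", "18-64", "65-84", ">85")) |>
    as.character() |>
    (\(x) ifelse(is.na(x), "UNK", x))()
}

weight_to_kg <- function(wt, unit) {
  v <- suppressWarnings(as.numeric(wt))
  unit <- toupper(trimws(ifelse(is.na(unit) | unit == "", "KG", unit)))
  f <- c(KG = 1, LBS = 0.453592, GMS = 0.001)[unit]
  out <- v * f
  out[is.na(f) | is.na(v) | out < 0] <- NA_real_
  out
}

norm_enum <- function(x, valid) {
  x <- toupper(trimws(as.character(x)))
  ifelse(x %in% valid, x, "UNK")
}

# JADER csv aliases (ascii export dialect; extendable)
jader_column_aliases <- function() {
  list(
    caseid = c("case_id", "identifier"),
    seq = c("seq", "report_seq"),
    receipt_date = c("receipt_date", "report_date"),
    sex = c("sex", "gender"),
    age = c("age"),
    weight = c("weight"),
    reporter = c("reporter", "qualification"),
    drugname = c("drug_name", "drugname"),
    role = c("role", "involvement"),
    start_date = c("start_date"),
    pt = c("pt", "reaction"),
    onset_date = c("onset_date"),
    indication = c("indication")
  )
}

# normalize one raw set to internal long tables with a version key per
# demo row; keys: case_id + primary key (FAERS primaryid / JADER seq)
normalize_raw_set <- function(raw) {
  if (raw$source == "FAERS") {
    al <- faers_column_aliases()
    demo <- raw$demo_rows
    d <- tibble(
      case_id = trimws(pick_col(demo, al, "caseid")),
      pkey = trimws(pick_col(demo, al, "primaryid")),
      receipt_int = date_int_pad(pick_col(demo, al, "receipt_date")),
      sex = norm_enum(pick_col(demo, al, "sex"), c("F", "M")),
      age_years = age_to_years(pick_col(demo, al, "age"),
                               pick_col(demo, al, "age_cod")),
      weight_kg = weight_to_kg(pick_col(demo, al, "weight"),
                               pick_col(demo, al, "weight_cod")),
      reporter = norm_enum(pick_col(demo, al, "reporter"),
                           c("HP", "MD", "PH", "OT", "CN")),
      country = {
        rc <- toupper(trimws(pick_col(demo, al, "reporter_country")))
        oc <- toupper(trimws(pick_col(demo, al, "occr_country")))
        ifelse(nzchar(rc) & !is.na(rc), rc,
               ifelse(nzchar(oc) & !is.na(oc), oc, "UNK"))
      },
      event_date = date_from_int(pick_col(demo, al, "event_date"))
    )
    key_of <- function(df) trimws(pick_col(df, al, "primaryid"))
    drugs <- tibble(
      pkey = key_of(raw$drug_rows),
      raw_name = trimws(pick_col(raw$drug_rows, al, "drugname")),
      role = norm_enum(pick_col(raw$drug_rows, al, "role"),
                       c("PS", "SS", "C", "I")),
      start_date = date_from_int(pick_col(raw$drug_rows, al, "start_date"))
    )
    reac <- tibble(
      pkey = key_of(raw$reac_rows),
      pt = trimws(pick_col(raw$reac_rows, al, "pt")),
      onset_date = date_from_int(pick_col(raw$reac_rows, al, "onset_date"))
    )
    outc <- if (nrow(raw$outc_rows) > 0) {
      tibble(pkey = key_of(raw$outc_rows),
             code = toupper(trimws(pick_col(raw$outc_rows, al, "outcome"))))
    } else {
      tibble(pkey = character(), code = character())
    }
    indi <- if (nrow(raw$indi_rows) > 0) {
      tibble(pkey = key_of(raw$indi_rows),
             indication_pt = trimws(pick_col(raw$indi_rows, al,
                                             "indication")))
    } else {
      tibble(pkey = character(), indication_pt = character())
    }
    list(demo = d, drugs = drugs, reac = reac, outc = outc, indi = indi)
  } else {
    al <- jader_column_aliases()
    demo <- raw$demo_rows
    d <- tibble(
      case_id = trimws(pick_col(demo, al, "caseid")),
      pkey = {
        s <- trimws(pick_col(demo, al, "seq"))
        ifelse(nzchar(s) & !is.na(s), s,
               trimws(pick_col(demo, al, "caseid")))
      },
      receipt_int = date_int_pad(pick_col(demo, al, "receipt_date")),
      sex = norm_enum(pick_col(demo, al, "sex"), c("F", "M")),
      age_years = age_to_years(pick_col(demo, al, "age"), "YR"),
      weight_kg = weight_to_kg(pick_col(demo, al, "weight"), "KG"),
      reporter = norm_enum(pick_col(demo, al, "reporter"),
                           c("HP", "MD", "PH", "OT", "CN")),
      country = "JP",
      event_date = as.Date(rep(NA, nrow(demo)))
    )
    by_case <- function(df) trimws(pick_col(df, al, "caseid"))
    drugs <- tibble(
      pkey = by_case(raw$drug_rows),
      raw_name = trimws(pick_col(raw$drug_rows, al, "drugname")),
      role = norm_enum(pick_col(raw$drug_rows, al, "role"),
                       c("PS", "SS", "C", "I")),
      start_date = date_from_int(pick_col(raw$drug_rows, al, "start_date"))
    )
    reac <- tibble(
      pkey = by_case(raw$reac_rows),
      pt = trimws(pick_col(raw$reac_rows, al, "pt")),
      onset_date = date_from_int(pick_col(raw$reac_rows, al, "onset_date"))
    )
    # JADER child tables key on the case identifier, not a version key
    list(demo = d, drugs = drugs, reac = reac,
         outc = tibble(pkey = character(), code = character()),
         indi = tibble(pkey = character(), indication_pt = character()),
         child_key = "case")
  }
}

# ---- deduplication ----------------------------------------------------

#' Deduplicate case versions and assemble a unified case store
#'
#' Spontaneous-report databases carry multiple versions of the same case
#' (follow-up reports). For each case identifier exactly one version
#' survives: the one with the latest receipt date, ties broken by the
#' larger report-sequence number, remaining ties by last-read order.
#' Child rows (drugs, reactions, outcomes, indications) belonging to the
#' surviving version are joined; child rows whose case has no demographic
#' row are orphans, dropped with a count. Idempotent.
#'
#' @param ... One or more `raw_table_set` objects from the same source.
#' @return A `report_store`: list of tibbles `cases`, `drugs`,
#'   `reactions`, `outcomes` with attributes `source`, `quarters` and
#'   `stats` (raw/surviving/orphan counts).
#' @export
deduplicate_cases <- function(...) {
  raws <- list(...)
  if (length(raws) == 1 && !inherits(raws[[1]], "raw_table_set") &&
      is.list(raws[[1]])) {
    raws <- raws[[1]]
  }
  stopifnot(length(raws) >= 1,
            all(vapply(raws, inherits, logical(1), "raw_table_set")))
  src <- unique(vapply(raws, `[[`, character(1), "source"))
  if (length(src) != 1) abort("all table sets must share one source")
  norm <- lapply(raws, normalize_raw_set)
  demo <- bind_rows(lapply(norm, `[[`, "demo")) |>
    mutate(read_order = row_number()) |>
    filter(nzchar(.data$case_id) & !is.na(.data$case_id))
  drugs <- bind_rows(lapply(norm, `[[`, "drugs"))
  reac <- bind_rows(lapply(norm, `[[`, "reac"))
  outc <- bind_rows(lapply(norm, `[[`, "outc"))
  indi <- bind_rows(lapply(norm, `[[`, "indi"))
  child_by_case <- src == "JADER"

  n_versions <- nrow(demo)
  keep <- demo |>
    mutate(seq_num = suppressWarnings(as.numeric(.data$pkey)),
           seq_num = ifelse(is.na(.data$seq_num), 0, .data$seq_num)) |>
    arrange(.data$case_id, .data$receipt_int, .data$seq_num,
            .data$read_order) |>
    group_by(.data$case_id) |>
    slice_tail(n = 1) |>
    ungroup()
  ties <- n_versions - n_distinct(demo$case_id)

  join_key <- if (child_by_case) {
    keep |> select("case_id") |> mutate(pkey = .data$case_id)
  } else {
    keep |> select("case_id", "pkey")
  }
  attach_children <- function(child) {
    n_orphan <- sum(!child$pkey %in% demo$pkey &
                      !(child_by_case & child$pkey %in% demo$case_id))
    kept <- child |> inner_join(join_key, by = "pkey") |>
      select(-"pkey") |> relocate("case_id")
    list(rows = kept, orphans = n_orphan)
  }
  dj <- attach_children(drugs)
  rj <- attach_children(reac)
  oj <- attach_children(outc)
  ij <- attach_children(indi)

  drugs_out <- dj$rows |> filter(nzchar(.data$raw_name))
  # attach indications to drug rows is lossy without a seq link; keep the
  # case-level indication table separate inside the drugs attr instead
  cases <- keep |>
    transmute(case_id = .data$case_id,
              sex = .data$sex,
              age_years = .data$age_years,
              age_group = age_group_of(.data$age_years),
              weight_kg = .data$weight_kg,
              reporter = .data$reporter,
              country = .data$country,
              event_date = .data$event_date,
              receipt_int = .data$receipt_int,
              year = ifelse(.data$receipt_int > 0,
                            .data$receipt_int %/% 10000, NA_real_)) |>
    arrange(.data$case_id)
  new_report_store(
    cases = cases,
    drugs = drugs_out |> arrange(.data$case_id),
    reactions = rj$rows |> filter(nzchar(.data$pt)) |>
      arrange(.data$case_id),
    outcomes = oj$rows |> filter(nzchar(.data$code)) |>
      distinct() |> arrange(.data$case_id),
    indications = ij$rows |> arrange(.data$case_id),
    source = src,
    quarters = vapply(raws, `[[`, character(1), "quarter_label"),
    stats = c(raw_versions = n_versions, surviving = nrow(cases),
              duplicate_versions = n_versions - nrow(cases),
              orphan_rows = dj$orphans + rj$orphans + oj$orphans +
                ij$orphans)
  )
}

#' Assemble a case store from its component tables
#'
#' Builds a `report_store` directly from tidy tables, for workflows that
#' reconstruct a store from published tallies or external sources rather
#' than raw regulatory files. Only `cases` is required; missing columns
#' are filled with unknowns and missing tables left empty.
#'
#' @param cases Data frame with at least `case_id`; optional `sex`,
#'   `age_years`, `weight_kg`, `reporter`, `country`, `event_date`,
#'   `receipt_int`.
#' @param drugs Optional data frame `case_id`, `raw_name`, `role`,
#'   `start_date`.
#' @param reactions Optional data frame `case_id`, `pt`, `onset_date`.
#' @param outcomes Optional data frame `case_id`, `code`.
#' @param source Database label carried as provenance.
#' @return A `report_store`.
#' @export
as_report_store <- function(cases, drugs = NULL, reactions = NULL,
                            outcomes = NULL, source = "FAERS") {
  cases <- as_tibble(cases)
  if (!"case_id" %in% names(cases)) abort("cases must have case_id")
  if (anyDuplicated(cases$case_id)) {
    abort("cases must be deduplicated: one row per case_id")
  }
  defaults <- list(sex = "UNK", age_years = NA_real_,
                   weight_kg = NA_real_, reporter = "UNK",
                   country = "UNK", event_date = as.Date(NA),
                   receipt_int = 0)
  for (nm in names(defaults)) {
    if (!nm %in% names(cases)) cases[[nm]] <- defaults[[nm]]
  }
  cases$age_group <- age_group_of(cases$age_years)
  cases$year <- ifelse(cases$receipt_int > 0,
                       cases$receipt_int %/% 10000, NA_real_)
  empty <- function(...) as_tibble(list(...))
  drugs <- as_tibble(drugs %||%
    empty(case_id = character(), raw_name = character(),
          role = character(), start_date = as.Date(character())))
  if (!"start_date" %in% names(drugs)) drugs$start_date <- as.Date(NA)
  reactions <- as_tibble(reactions %||%
    empty(case_id = character(), pt = character(),
          onset_date = as.Date(character())))
  if (!"onset_date" %in% names(reactions)) {
    reactions$onset_date <- as.Date(NA)
  }
  outcomes <- as_tibble(outcomes %||%
    empty(case_id = character(), code = character()))
  new_report_store(cases, drugs, reactions, outcomes, source = source,
                   stats = c(raw_versions = nrow(cases),
                             surviving = nrow(cases),
                             duplicate_versions = 0, orphan_rows = 0))
}

new_report_store <- function(cases, drugs, reactions, outcomes,
                             indications = NULL, source = "FAERS",
                             quarters = character(), stats = c()) {
  structure(list(cases = as_tibble(cases), drugs = as_tibble(drugs),
                 reactions = as_tibble(reactions),
                 outcomes = as_tibble(outcomes),
                 indications = if (is.null(indications)) {
                   tibble(case_id = character(),
                          indication_pt = character())
                 } else {
                   as_tibble(indications)
                 }),
            source = source, quarters = quarters, stats = stats,
            class = "report_store")
}

#' @export
print.report_store <- function(x, ...) {
  st <- attr(x, "stats")
  cat("<report_store> ", attr(x, "source"), ": ",
      format(nrow(x$cases), big.mark = ","), " cases, ",
      nrow(x$drugs), " drug rows, ", nrow(x$reactions),
      " reaction rows, ", nrow(x$outcomes), " outcome rows\n", sep = "")
  if (length(st) > 0) {
    cat("  dedup: ", st[["raw_versions"]], " raw versions -> ",
        st[["surviving"]], " cases (", st[["orphan_rows"]],
        " orphan child rows dropped)\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::glance
glance.report_store <- function(x, ...) {
  st <- attr(x, "stats")
  tibble(source = attr(x, "source"),
         n_cases = nrow(x$cases),
         n_drug_rows = nrow(x$drugs),
         n_reaction_rows = nrow(x$reactions),
         n_outcome_rows = nrow(x$outcomes),
         raw_versions = if (length(st)) st[["raw_versions"]] else NA,
         orphan_rows = if (length(st)) st[["orphan_rows"]] else NA)
}

# ---- store serialization ---------------------------------------------

#' Write / read a normalized case store
#'
#' Serializes a `report_store` as a directory of TSV files (`cases.tsv`,
#' `drugs.tsv`, `reactions.tsv`, `outcomes.tsv`, `indications.tsv`) plus
#' a JSON manifest carrying source, quarters and dedup statistics.
#'
#' @param store A `report_store`.
#' @param dir Directory to write into (created if absent).
#' @return `write_store()` returns `dir` invisibly; `read_store()`
#'   returns the reconstructed `report_store`.
#' @export
write_store <- function(store, dir) {
  stopifnot(inherits(store, "report_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("cases", "drugs", "reactions", "outcomes", "indications")) {
    readr::write_tsv(store[[nm]], file.path(dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  manifest <- list(source = attr(store, "source"),
                   quarters = attr(store, "quarters"),
                   stats = as.list(attr(store, "stats")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_store
#' @export
read_store <- function(dir) {
  rd <- function(nm, types) {
    readr::read_tsv(file.path(dir, paste0(nm, ".tsv")), col_types = types,
                    progress = FALSE)
  }
  cases <- rd("cases", readr::cols(case_id = "c", sex = "c",
                                   age_years = "d", age_group = "c",
                                   weight_kg = "d", reporter = "c",
                                   country = "c", event_date = "D",
                                   receipt_int = "d", year = "d"))
  drugs <- rd("drugs", readr::cols(case_id = "c", raw_name = "c",
                                   role = "c", start_date = "D"))
  reactions <- rd("reactions", readr::cols(case_id = "c", pt = "c",
                                           onset_date = "D"))
  outcomes <- rd("outcomes", readr::cols(case_id = "c", code = "c"))
  indications <- rd("indications", readr::cols(case_id = "c",
                                               indication_pt = "c"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  new_report_store(cases, drugs, reactions, outcomes, indications,
                   source = manifest$source,
                   quarters = unlist(manifest$quarters),
                   stats = unlist(manifest$stats))
}
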