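#' Read one FAERS-style quarterly extract
#'
#' Parses the "$"-delimited ASCII tables of a FAERS quarter from a directory.
#' Files are located case-insensitively by name prefix (DEMO, DRUG, REAC,
#' OUTC, THER); DEMO, DRUG and REAC are mandatory, OUTC and THER optional.
#' Each file must carry a header line; field names are lower-cased. Rows
#' whose field count differs from the header are skipped and counted in the
#' ingest log.
#'
#' @param dir Directory containing the quarterly files.
#' @param sep Field delimiter (FAERS uses `"$"`).
#' @return A `faers_raw` object: data.frames `demo`, `drug`, `reac`, `outc`,
#'   `ther` (character columns) plus a `log` list with per-table row and
#'   skip counts.
#' @export
faers_read_quarter <- function(dir, sep = "$") {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  files <- list.files(dir, full.names = TRUE)
  find <- function(prefix) {
    hit <- files[grepl(paste0("^", prefix), basename(files), ignore.case = TRUE)]
    if (length(hit)) hit[[1]] else NA_character_
  }
  tabs <- c("demo", "drug", "reac", "outc", "ther")
  mandatory <- c("demo", "drug", "reac")
  out <- list()
  log <- list(rows = integer(0), skipped = integer(0))
  for (tb in tabs) {
    path <- find(tb)
    if (is.na(path)) {
      if (tb %in% mandatory) stop("missing mandatory FAERS file: ", toupper(tb))
      out[[tb]] <- data.frame()
      next
    }
    parsed <- read_dollar_file(path, sep)
    out[[tb]] <- parsed$table
    log$rows[tb] <- nrow(parsed$table)
    log$skipped[tb] <- parsed$skipped
    if (parsed$skipped > 0) {
      warning(sprintf("%s: skipped %d malformed row(s)", basename(path), parsed$skipped))
    }
    if (nrow(parsed$table) == 0) warning(basename(path), ": empty table")
  }
  out$log <- log
  structure(out, class = "faers_raw")
}

# Parse one "$"-delimited file with a header; malformed rows (field count
# different from the header) are dropped and counted.
read_dollar_file <- function(path, sep = "$") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(list(table = data.frame(), skipped = 0L))
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  # strsplit drops a trailing empty field; pad to the delimiter count + 1
  ndelim <- lengths(gregexpr(sep, lines, fixed = TRUE))
  ndelim[!grepl(sep, lines, fixed = TRUE)] <- 0L
  want <- ndelim + 1L
  fields <- Map(function(f, n) c(f, rep("", n - length(f))), fields, want)
  header <- tolower(trimws(fields[[1]]))
  body <- fields[-1]
  ok <- lengths(body) == length(header)
  skipped <- sum(!ok)
  body <- body[ok]
  if (length(body) == 0) {
    tab <- as.data.frame(matrix(character(0), 0, length(header),
                                dimnames = list(NULL, header)),
                         stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, body)
    colnames(m) <- header
    tab <- as.data.frame(m, stringsAsFactors = FALSE)
  }
  list(table = tab, skipped = skipped)
}

#' Deduplicate FAERS case versions
#'
#' FAERS cases are re-submitted as new versions under the same `caseid` with
#' distinct `primaryid`s; keeping every version double-counts reports. The
#' default strategy retains, per `caseid`, the version with the latest FDA
#' receipt date (`fda_dt`), breaking ties by the largest `primaryid` — the
#' standard practice for FAERS analyses. `"primaryid-distinct"` merely drops
#' exact `primaryid` duplicates. Child tables are filtered to the retained
#' `primaryid`s. The operation is idempotent.
#'
#' @param raw A `faers_raw` object.
#' @param strategy `"caseid-latest"` (default) or `"primaryid-distinct"`.
#' @return A deduplicated `faers_raw`; `log$dedup_removed` records the count.
#' @export
faers_dedup <- function(raw, strategy = c("caseid-latest", "primaryid-distinct")) {
  strategy <- match.arg(strategy)
  demo <- raw$demo
  if (is.null(demo) || nrow(demo) == 0) return(raw)
  if (strategy == "primaryid-distinct") {
    keep <- !duplicated(demo$primaryid)
  } else {
    fda <- pad_date8(demo$fda_dt)
    fda[is.na(fda)] <- 0
    pid <- suppressWarnings(as.numeric(demo$primaryid))
    pid[is.na(pid)] <- -Inf
    ord <- order(demo$caseid, -fda, -pid)
    demo_sorted <- demo[ord, , drop = FALSE]
    keep_sorted <- !duplicated(demo_sorted$caseid)
    keep <- logical(nrow(demo))
    keep[ord] <- keep_sorted
  }
  retained <- demo$primaryid[keep]
  out <- raw
  out$demo <- demo[keep, , drop = FALSE]
  rownames(out$demo) <- NULL
  for (tb in c("drug", "reac", "outc", "ther")) {
    if (!is.null(out[[tb]]) && nrow(out[[tb]]) > 0) {
      out[[tb]] <- out[[tb]][out[[tb]]$primaryid %in% retained, , drop = FALSE]
      rownames(out[[tb]]) <- NULL
    }
  }
  out$log$dedup_removed <- nrow(demo) - sum(keep)
  out$log$dedup_strategy <- strategy
  out
}

# FAERS dates come as YYYYMMDD with partial forms YYYYMM / YYYY; pad to a
# numeric YYYYMMDD (first day / first month) for ordering.
pad_date8 <- function(x) {
  x <- trimws(as.character(x))
  n <- nchar(x)
  x[n == 6L & grepl("^[0-9]{6}$", x)] <- paste0(x[n == 6L & grepl("^[0-9]{6}$", x)], "01")
  x[n == 4L & grepl("^[0-9]{4}$", x)] <- paste0(x[n == 4L & grepl("^[0-9]{4}$", x)], "0101")
  out <- suppressWarnings(as.numeric(x))
  out[!grepl("^[0-9]{8}$", x)] <- NA
  out
}

# Parse a FAERS date string to Date; partial dates resolve to the first
# day/month and are flagged.
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  partial <- grepl("^[0-9]{4}$", x) | grepl("^[0-9]{6}$", x)
  num <- pad_date8(x)
  d <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(num)
  d[ok] <- as.Date(sprintf("%08.0f", num[ok]), format = "%Y%m%d")
  partial[is.na(d)] <- FALSE
  list(date = d, partial = partial)
}

AGE_FACTORS <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775, DY = 1 / 365.25,
                 HR = 1 / (365.25 * 24))

#' Convert a FAERS age to years
#'
#' Unit codes: `DEC` decades, `YR` years, `MON` months, `WK` weeks, `DY`
#' days, `HR` hours. Unparseable values, unknown codes and negative ages
#' degrade to `NA`.
#'
#' @param value Age value (character or numeric).
#' @param code Age unit code.
#' @return Age in years, or `NA`.
#' @export
age_to_years <- function(value, code) {
  v <- suppressWarnings(as.numeric(value))
  f <- AGE_FACTORS[toupper(trimws(code))]
  out <- unname(v * f)
  out[!is.finite(out) | out < 0] <- NA
  out
}

#' Convert a FAERS weight to kilograms
#'
#' Unit codes: `KG` (or `KGS`) kilograms, `LBS` pounds, `GMS` grams.
#'
#' @param value Weight value.
#' @param code Weight unit code.
#' @return Weight in kg, or `NA`.
#' @export
weight_to_kg <- function(value, code) {
  v <- suppressWarnings(as.numeric(value))
  f <- c(KG = 1, KGS = 1, LBS = 0.45359237, GMS = 0.001)[toupper(trimws(code))]
  out <- unname(v * f)
  out[!is.finite(out) | out < 0] <- NA
  out
}

OUTCOME_MAP <- c(DE = "death", LT = "life_threatening", HO = "hospitalization",
                 DS = "disability", CA = "other_serious", RI = "other_serious",
                 OT = "other_serious")
OUTCOME_LEVELS <- c("death", "life_threatening", "hospitalization",
                    "disability", "other_serious")

SEX_MAP <- c(F = "female", M = "male")
REPORTER_MAP <- c(CN = "consumer", MD = "physician", PH = "pharmacist",
                  OT = "other_health_professional", HP = "other_health_professional")

#' Normalize raw FAERS tables into analysis-ready cases
#'
#' Converts ages to years and weights to kg, maps outcome/sex/reporter codes,
#' parses dates (partial dates resolve to the first day/month and are
#' flagged), and collapses reaction rows to the set of distinct PTs per
#' report. Every unparseable field degrades to missing and increments a
#' warning counter; the function never fails on malformed text. A report is
#' serious exactly when it carries at least one serious outcome code.
#'
#' @param raw A (preferably deduplicated) `faers_raw` object.
#' @return A `faers_cases` object: `demo` (one row per report: `primaryid`,
#'   `caseid`, `fda_date`, `sex`, `age_years`, `weight_kg`, `country`,
#'   `reporter`, outcome indicator columns, `serious`, `event_date`,
#'   `therapy_start`, partial-date flags), `drugs` (`primaryid`, `name`,
#'   `role`), `events` (`primaryid`, `pt`), and a `log` of warning counters.
#' @export
normalize_cases <- function(raw) {
  demo <- raw$demo
  if (is.null(demo) || nrow(demo) == 0) {
    return(structure(list(
      demo = data.frame(), drugs = data.frame(), events = data.frame(),
      log = list()), class = "faers_cases"))
  }
  getcol <- function(df, name) {
    if (!is.null(df) && name %in% names(df)) df[[name]] else rep(NA_character_, nrow(df))
  }
  n <- nrow(demo)
  pid <- trimws(demo$primaryid)
  warn <- c(age = 0L, weight = 0L, sex = 0L, reporter = 0L, outcome = 0L, date = 0L)

  age_raw <- getcol(demo, "age")
  age <- age_to_years(age_raw, getcol(demo, "age_cod"))
  warn["age"] <- sum(is.na(age) & nzchar(trimws(ifelse(is.na(age_raw), "", age_raw))))
  wt_raw <- getcol(demo, "wt")
  wt <- weight_to_kg(wt_raw, getcol(demo, "wt_cod"))
  warn["weight"] <- sum(is.na(wt) & nzchar(trimws(ifelse(is.na(wt_raw), "", wt_raw))))

  sex_raw <- toupper(trimws(getcol(demo, "sex")))
  sex <- unname(SEX_MAP[sex_raw])
  sex[is.na(sex)] <- "unknown"
  warn["sex"] <- sum(sex == "unknown" & nzchar(sex_raw) & !is.na(sex_raw))

  rep_raw <- toupper(trimws(getcol(demo, "occp_cod")))
  reporter <- unname(REPORTER_MAP[rep_raw])
  reporter[is.na(reporter)] <- "unknown"

  country <- trimws(getcol(demo, "reporter_country"))
  country[!nzchar(country) | is.na(country)] <- NA_character_

  fda <- parse_faers_date(getcol(demo, "fda_dt"))
  evd <- parse_faers_date(getcol(demo, "event_dt"))

  # therapy start: earliest THER start per report
  ther <- raw$ther
  ts_date <- as.Date(rep(NA_character_, n))
  ts_partial <- logical(n)
  if (!is.null(ther) && nrow(ther) > 0 && "start_dt" %in% names(ther)) {
    pt <- parse_faers_date(ther$start_dt)
    ok <- !is.na(pt$date)
    if (any(ok)) {
      idx <- split(seq_len(nrow(ther))[ok], trimws(ther$primaryid)[ok])
      first <- vapply(idx, function(i) i[which.min(pt$date[i])], integer(1))
      m <- match(names(first), pid)
      hit <- !is.na(m)
      ts_date[m[hit]] <- pt$date[first[hit]]
      ts_partial[m[hit]] <- pt$partial[first[hit]]
    }
  }

  # outcomes
  outc <- raw$outc
  omat <- matrix(FALSE, n, length(OUTCOME_LEVELS),
                 dimnames = list(NULL, OUTCOME_LEVELS))
  if (!is.null(outc) && nrow(outc) > 0 && "outc_cod" %in% names(outc)) {
    code <- toupper(trimws(outc$outc_cod))
    mapped <- OUTCOME_MAP[code]
    warn["outcome"] <- sum(is.na(mapped) & nzchar(code))
    keep <- !is.na(mapped)
    i <- match(trimws(outc$primaryid)[keep], pid)
    j <- match(mapped[keep], OUTCOME_LEVELS)
    ok <- !is.na(i)
    omat[cbind(i[ok], j[ok])] <- TRUE
  }

  demo_out <- data.frame(
    primaryid = pid, caseid = trimws(demo$caseid), fda_date = fda$date,
    sex = sex, age_years = age, weight_kg = wt, country = country,
    reporter = reporter, stringsAsFactors = FALSE)
  for (lv in OUTCOME_LEVELS) demo_out[[lv]] <- omat[, lv]
  demo_out$serious <- rowSums(omat) > 0
  demo_out$event_date <- evd$date
  demo_out$event_date_partial <- evd$partial
  demo_out$therapy_start <- ts_date
  demo_out$therapy_start_partial <- ts_partial

  drug <- raw$drug
  drugs <- if (!is.null(drug) && nrow(drug) > 0) {
    data.frame(primaryid = trimws(drug$primaryid),
               name = trimws(getcol(drug, "drugname")),
               role = toupper(trimws(getcol(drug, "role_cod"))),
               stringsAsFactors = FALSE)
  } else data.frame(primaryid = character(0), name = character(0),
                    role = character(0), stringsAsFactors = FALSE)

  reac <- raw$reac
  events <- if (!is.null(reac) && nrow(reac) > 0) {
    ev <- data.frame(primaryid = trimws(reac$primaryid),
                     pt = trimws(getcol(reac, "pt")), stringsAsFactors = FALSE)
    ev <- ev[nzchar(ev$pt) & !is.na(ev$pt), , drop = FALSE]
    ev[!duplicated(ev[c("primaryid", "pt")]), , drop = FALSE]
  } else data.frame(primaryid = character(0), pt = character(0),
                    stringsAsFactors = FALSE)
  rownames(events) <- NULL

  structure(list(demo = demo_out, drugs = drugs, events = events,
                 log = as.list(warn)),
            class = "faers_cases")
}

#' Normalize a single report
#'
#' Convenience view of one report as a list (demographics, outcome set, drug
#' list with role codes, PT set, dates), as produced by [normalize_cases()].
#'
#' @param raw A `faers_raw` object.
#' @param primaryid The report version id.
#' @return A list describing the report.
#' @export
normalize_case <- function(raw, primaryid) {
  sub <- raw
  sub$demo <- raw$demo[trimws(raw$demo$primaryid) == primaryid, , drop = FALSE]
  if (nrow(sub$demo) == 0) stop("primaryid not found: ", primaryid)
  for (tb in c("drug", "reac", "outc", "ther")) {
    if (!is.null(sub[[tb]]) && nrow(sub[[tb]]) > 0) {
      sub[[tb]] <- sub[[tb]][trimws(sub[[tb]]$primaryid) == primaryid, , drop = FALSE]
    }
  }
  cs <- normalize_cases(sub)
  d <- cs$demo[1, ]
  list(primaryid = d$primaryid, caseid = d$caseid, fda_date = d$fda_date,
       sex = d$sex, age_years = d$age_years, weight_kg = d$weight_kg,
       country = d$country, reporter = d$reporter,
       outcomes = OUTCOME_LEVELS[unlist(d[OUTCOME_LEVELS])],
       serious = d$serious,
       drugs = cs$drugs[c("name", "role")],
       events = cs$events$pt,
       event_date = d$event_date, therapy_start = d$therapy_start)
}

#' Partition reports by target-drug exposure
#'
#' A report is exposed when at least one of its drug entries matches a target
#' name (case-insensitive substring match after trimming) with a role code in
#' `roles` (default `"PS"`, primary suspect). The partition is exhaustive and
#' disjoint.
#'
#' @param cases A `faers_cases` object.
#' @param names Non-empty character vector of drug names (generic and trade).
#' @param roles Role codes counting as exposure (subset of PS, SS, C, I).
#' @return A list with character vectors `exposed` and `unexposed`.
#' @export
select_target_reports <- function(cases, names, roles = "PS") {
  if (length(names) == 0 || all(!nzchar(names))) stop("names must be non-empty")
  drugs <- cases$drugs
  hit <- rep(FALSE, nrow(drugs))
  dn <- tolower(drugs$name)
  for (nm in tolower(trimws(names))) {
    hit <- hit | grepl(nm, dn, fixed = TRUE)
  }
  hit <- hit & drugs$role %in% roles
  exposed <- unique(drugs$primaryid[hit])
  all_ids <- cases$demo$primaryid
  list(exposed = all_ids[all_ids %in% exposed],
       unexposed = all_ids[!all_ids %in% exposed])
}

#' Load PT annotations (SOC mapping, DME/IME lists, evidence grades)
#'
#' MedDRA itself is licensed, so the PT-to-SOC mapping is user-supplied as a
#' TSV with columns `pt` and `soc`. The EMA designated medical event (DME)
#' and important medical event (IME) lists are TSVs with a `pt` column, and
#' literature-evidence grades a TSV with columns `pt` and `grade` (one of
#' `++`, `+`, `-`). A PT may sit on both the DME and IME lists; downstream
#' scoring gives DME precedence.
#'
#' @param pt_soc_file Path to the PT/SOC TSV (required).
#' @param dme_file,ime_file,evidence_file Optional TSV paths.
#' @return A `faers_annotation` object.
#' @export
read_annotation <- function(pt_soc_file, dme_file = NULL, ime_file = NULL,
                            evidence_file = NULL) {
  read_tsv <- function(p) utils::read.delim(p, stringsAsFactors = FALSE,
                                            colClasses = "character")
  ps <- read_tsv(pt_soc_file)
  stopifnot(all(c("pt", "soc") %in% names(ps)))
  pt_to_soc <- stats::setNames(ps$soc, ps$pt)
  dme <- if (!is.null(dme_file)) read_tsv(dme_file)$pt else character(0)
  ime <- if (!is.null(ime_file)) read_tsv(ime_file)$pt else character(0)
  evidence <- if (!is.null(evidence_file)) {
    ev <- read_tsv(evidence_file)
    stopifnot(all(c("pt", "grade") %in% names(ev)))
    stats::setNames(ev$grade, ev$pt)
  } else stats::setNames(character(0), character(0))
  structure(list(pt_to_soc = pt_to_soc, dme = unique(dme), ime = unique(ime),
                 evidence = evidence),
            class = "faers_annotation")
}

#' Annotate PTs with SOC, DME/IME membership and evidence grade
#'
#' PTs absent from the SOC mapping receive `soc = "UNMAPPED"`. DME and IME
#' membership are reported independently; PTs without an evidence grade get
#' `NA`.
#'
#' @param pts Character vector of preferred terms.
#' @param annotation A `faers_annotation`.
#' @return data.frame with columns `pt`, `soc`, `dme`, `ime`, `evidence`.
#' @export
annotate_events <- function(pts, annotation) {
  soc <- unname(annotation$pt_to_soc[pts])
  soc[is.na(soc)] <- "UNMAPPED"
  ev <- unname(annotation$evidence[pts])
  data.frame(pt = pts, soc = soc,
             dme = pts %in% annotation$dme,
             ime = pts %in% annotation$ime,
             evidence = ev, stringsAsFactors = FALSE)
}
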