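# Pipeline orchestration: descriptive summary of a cohort and an
# end-to-end driver (ingest -> dedup -> describe -> screening -> priority
# -> stratified serious-event analysis -> severity comparison -> TTO) with
# a validated configuration and CSV artifacts.

#' Descriptive summary of an exposed cohort
#'
#' Counts and percentages by sex, reporter occupation, country (top 5) and
#' reporting year, age and weight medians with quartiles, and the serious
#' outcome categories in the conventional order (Hospitalization, Other
#' Serious, Death, Disability, Threat to Life). Percentages are relative to
#' the exposed-report total.
#'
#' @param cases A `faers_cases` object.
#' @param exposed_ids Report ids of the cohort to describe.
#' @return A list of data.frames (`sex`, `reporter`, `country`, `year`,
#'   `outcomes`, `continuous`) plus `n`.
#' @export
describe_cohort <- function(cases, exposed_ids) {
  demo <- cases$demo[cases$demo$primaryid %in% exposed_ids, , drop = FALSE]
  n <- nrow(demo)
  pct <- function(k) if (n > 0) round(100 * k / n, 2) else k * 0
  count_tab <- function(x, levels = NULL, top = NULL) {
    tb <- sort(table(x), decreasing = TRUE)
    if (!is.null(levels)) tb <- table(factor(x, levels = levels))
    if (!is.null(top)) tb <- utils::head(tb, top)
    data.frame(category = names(tb), n = as.integer(tb),
               pct = pct(as.integer(tb)), stringsAsFactors = FALSE)
  }
  outc_levels <- c("hospitalization", "other_serious", "death", "disability",
                   "life_threatening")
  outc_labels <- c("Hospitalization", "Other Serious Events", "Death",
                   "Disability", "Threat to Life")
  outc_n <- vapply(outc_levels, function(l) sum(demo[[l]]), integer(1))
  q <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(c(NA_real_, NA_real_, NA_real_, 0))
    c(stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE), length(x))
  }
  qa <- q(demo$age_years); qw <- q(demo$weight_kg)
  list(
    n = n,
    sex = count_tab(demo$sex, levels = c("female", "male", "unknown")),
    reporter = count_tab(demo$reporter,
                         levels = c("consumer", "physician", "pharmacist",
                                    "other_health_professional", "unknown")),
    country = count_tab(demo$country[!is.na(demo$country)], top = 5),
    year = count_tab(format(demo$fda_date, "%Y")),
    outcomes = data.frame(category = outc_labels, n = unname(outc_n),
                          pct = pct(unname(outc_n)), stringsAsFactors = FALSE),
    continuous = data.frame(
      variable = c("age_years", "weight_kg"),
      median = c(qa[1], qw[1]), q1 = c(qa[2], qw[2]), q3 = c(qa[3], qw[3]),
      n_known = c(qa[4], qw[4]), stringsAsFactors = FALSE))
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected
#' so that typos fail before any computation.
#'
#' @param quarter_dirs Character vector of quarterly extract directories.
#' @param drug_names Target drug names (generic and trade).
#' @param roles Exposure role codes (default PS).
#' @param dedup_strategy Passed to [faers_dedup()].
#' @param pt_soc_file,dme_file,ime_file,evidence_file Annotation TSV paths.
#' @param signal Pt-level [signal_config()].
#' @param signal_soc SOC-level [signal_config()].
#' @param rubric A [priority_rubric()].
#' @param strat_soc SOC whose serious reports are stratified (set `NULL` to
#'   skip).
#' @param severity_min_count Minimum PT count for the severity comparison.
#' @param tto_window TTO cap in days.
#' @param out_dir Output directory for CSV artifacts.
#' @param seed Integer seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(quarter_dirs, drug_names, roles = "PS",
                            dedup_strategy = "caseid-latest",
                            pt_soc_file = NULL, dme_file = NULL,
                            ime_file = NULL, evidence_file = NULL,
                            signal = signal_config("all4"),
                            signal_soc = signal_config("any1"),
                            rubric = priority_rubric(),
                            strat_soc = "Infections and infestations",
                            severity_min_count = 30,
                            tto_window = 365, out_dir = tempfile("faers_run_"),
                            seed = 1L) {
  cfg <- mget(names(formals()))
  stopifnot(length(cfg$quarter_dirs) >= 1, length(cfg$drug_names) >= 1)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    if (!is.list(config)) stop("config must be a pipeline_config or list")
    known <- names(formals(pipeline_config))
    bad <- setdiff(names(config), known)
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    config <- do.call(pipeline_config, config)
  }
  config
}

#' Run the full pipeline
#'
#' Executes ingest, deduplication, normalization, exposure selection,
#' descriptive summary, PT- and SOC-level screening, clinical-priority
#' scoring, stratified serious-SOC analysis, serious-vs-non-serious
#' comparison and time-to-onset analysis, writing each stage's CSV plus a
#' run log and a manifest (with the config and seed) under `out_dir`. Any
#' stage error aborts with the stage name.
#'
#' @param config A [pipeline_config()] (or a plain list of its keys, which
#'   is validated with unknown keys rejected).
#' @return Invisibly, a list with the stage results and `out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  set.seed(config$seed)
  log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(df, name) {
    utils::write.csv(df, file.path(config$out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }

  raws <- stage("ingest", lapply(config$quarter_dirs, faers_read_quarter))
  raw <- stage("ingest", {
    if (length(raws) == 1) raws[[1]] else {
      merged <- raws[[1]]
      for (r in raws[-1]) {
        for (tb in c("demo", "drug", "reac", "outc", "ther")) {
          merged[[tb]] <- rbind(merged[[tb]], r[[tb]])
        }
      }
      merged
    }
  })
  log$ingested_reports <- nrow(raw$demo)
  raw <- stage("dedup", faers_dedup(raw, config$dedup_strategy))
  log$dedup_removed <- raw$log$dedup_removed
  cases <- stage("normalize", normalize_cases(raw))
  log$cases <- nrow(cases$demo)

  ann <- if (!is.null(config$pt_soc_file)) {
    stage("annotation", read_annotation(config$pt_soc_file, config$dme_file,
                                        config$ime_file, config$evidence_file))
  } else NULL

  part <- stage("select", select_target_reports(cases, config$drug_names,
                                                config$roles))
  log$exposed <- length(part$exposed)

  desc <- stage("describe", describe_cohort(cases, part$exposed))
  emit(desc$sex, "describe_sex"); emit(desc$outcomes, "describe_outcomes")
  emit(desc$reporter, "describe_reporter"); emit(desc$continuous, "describe_continuous")

  pt_sig <- stage("screen_pt", screen_signals(cases, part$exposed, ann,
                                              level = "pt", config = config$signal))
  emit(pt_sig, "signals_pt")
  log$pt_terms_screened <- nrow(pt_sig)
  log$pt_signals <- sum(pt_sig$signal)

  soc_sig <- if (!is.null(ann)) {
    s <- stage("screen_soc", screen_signals(cases, part$exposed, ann,
                                            level = "soc", config = config$signal_soc))
    emit(s, "signals_soc"); s
  } else NULL

  prio <- NULL
  sig_rows <- pt_sig[pt_sig$signal, , drop = FALSE]
  if (nrow(sig_rows) > 0) {
    annot <- if (!is.null(ann)) annotate_events(sig_rows$term, ann) else
      data.frame(pt = sig_rows$term, dme = FALSE, ime = FALSE,
                 evidence = NA_character_, stringsAsFactors = FALSE)
    prio <- stage("priority", cbind(
      pt = sig_rows$term,
      score_priority(sig_rows$a, sig_rows$ror, sig_rows$deaths,
                     annot$dme, annot$ime, annot$evidence, config$rubric)))
    emit(prio, "priority")
    log$priority_bands <- as.list(band_counts(prio))
  }

  strat <- NULL
  if (!is.null(config$strat_soc) && !is.null(ann)) {
    evt <- event_reports(cases, config$strat_soc, level = "soc",
                         annotation = ann, serious_only = TRUE)
    strat <- stage("stratify", do.call(rbind, lapply(
      c("sex", "age", "weight", "reporter"), function(dm) {
        tb <- stratified_tables(cases, part$exposed, evt, dimension = dm)
        tb$dimension <- dm
        tb
      })))
    strat$ror <- NA_real_; strat$ror_lo <- NA_real_; strat$ror_hi <- NA_real_
    ok <- strat$a > 0 & strat$b > 0 & strat$c > 0 & strat$d > 0
    for (i in which(ok)) {
      r <- ror_estimate(contab(strat$a[i], strat$b[i], strat$c[i], strat$d[i]))
      strat$ror[i] <- r$ror; strat$ror_lo[i] <- r$lo; strat$ror_hi[i] <- r$hi
    }
    emit(strat, "stratified_serious_soc")
  }

  sev <- stage("severity", tryCatch(
    compare_severity(cases, part$exposed, config$severity_min_count),
    error = function(e) NULL))
  if (!is.null(sev)) emit(sev, "severity")

  tto <- stage("tto", compute_tto(cases, part$exposed, window = config$tto_window))
  log$tto_retained <- length(tto$days)
  log$tto_excluded_missing <- tto$n_excluded_missing
  log$tto_excluded_negative <- tto$n_excluded_negative
  tto_fit <- if (length(unique(tto$days)) >= 10) {
    stage("tto", weibull_mle(tto))
  } else NULL
  if (!is.null(tto_fit)) {
    s <- tto_summary(tto)
    emit(data.frame(group = "all", n = s$n, median = s$median, q1 = s$q1,
                    q3 = s$q3, alpha = tto_fit$alpha,
                    alpha_lo = tto_fit$alpha_ci[1], alpha_hi = tto_fit$alpha_ci[2],
                    beta = tto_fit$beta, beta_lo = tto_fit$beta_ci[1],
                    beta_hi = tto_fit$beta_ci[2],
                    failure_type = tto_fit$failure_type), "tto")
  }

  manifest <- list(seed = config$seed, drug_names = config$drug_names,
                   quarter_dirs = config$quarter_dirs, log = log)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(paste(names(unlist(log)), unlist(log), sep = ": "),
             file.path(config$out_dir, "run_log.txt"))
  invisible(list(out_dir = config$out_dir, cases = cases, exposed = part$exposed,
                 describe = desc, signals_pt = pt_sig, signals_soc = soc_sig,
                 priority = prio, stratified = strat, severity = sev,
                 tto = tto, tto_fit = tto_fit, log = log))
}

#' Path to a bundled extdata file
#'
#' @param file File name under the package's `extdata/`.
#' @return Absolute path.
#' @export
faersignal_extdata <- function(file) {
  p <- system.file("extdata", file, package = "faersignal")
  if (!nzchar(p)) stop("no such extdata file: ", file)
  p
}
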