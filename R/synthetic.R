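# Synthetic FAERS-format report generator with known ground truth.
#
# Emulates the structure of a spontaneous-report quarter: one DEMO row per
# report version (with duplicate case versions), DRUG rows with role codes,
# REAC rows with one or more PTs, OUTC serious-outcome codes and THER
# therapy-start dates, all in the "$"-delimited ASCII dialect. Drug-event
# associations are planted as relative risks, optionally modified within
# demographic strata, so that every pipeline stage can be checked against
# the generating truth.

#' Default synthetic PT catalog
#'
#' Eighteen preferred terms with background reporting probabilities,
#' per-event serious probabilities and death probabilities, loosely shaped
#' like the adverse-event mix of a biologic immunomodulator cohort
#' (infection-heavy, mostly non-fatal).
#'
#' @return data.frame with columns `pt`, `soc`, `background_prob`,
#'   `serious_prob`, `death_prob`.
#' @export
synth_pt_catalog <- function() {
  data.frame(
    pt = c("Headache", "Nausea", "Rash", "Pneumonia", "Infection", "Sepsis",
           "Arthralgia", "Pyrexia", "Fatigue", "Deafness", "Diarrhoea",
           "Cough", "Dyspnoea", "Dizziness", "Vomiting",
           "Urinary tract infection", "Malaise", "Hepatotoxicity"),
    soc = c("Nervous system disorders", "Gastrointestinal disorders",
            "Skin and subcutaneous tissue disorders",
            "Infections and infestations", "Infections and infestations",
            "Infections and infestations",
            "Musculoskeletal and connective tissue disorders",
            "General disorders and administration site conditions",
            "General disorders and administration site conditions",
            "Ear and labyrinth disorders", "Gastrointestinal disorders",
            "Respiratory, thoracic and mediastinal disorders",
            "Respiratory, thoracic and mediastinal disorders",
            "Nervous system disorders", "Gastrointestinal disorders",
            "Infections and infestations",
            "General disorders and administration site conditions",
            "Hepatobiliary disorders"),
    background_prob = c(0.08, 0.07, 0.05, 0.02, 0.03, 0.005, 0.04, 0.06,
                        0.06, 0.003, 0.05, 0.04, 0.03, 0.04, 0.04, 0.02,
                        0.04, 0.008),
    serious_prob = c(0.2, 0.15, 0.2, 0.8, 0.6, 0.95, 0.2, 0.3, 0.2, 0.5,
                     0.2, 0.15, 0.5, 0.2, 0.25, 0.4, 0.3, 0.7),
    death_prob = c(0.005, 0.002, 0.002, 0.12, 0.05, 0.3, 0.001, 0.01,
                   0.002, 0, 0.002, 0.002, 0.03, 0.002, 0.002, 0.01,
                   0.005, 0.05),
    stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' Defaults emulate a canakinumab-like pharmacovigilance cohort: a 10%
#' exposed fraction, an infection-dominated planted signal set (relative
#' risks 2.25-3, with serious infection risk amplified in males, in
#' subjects aged 60 and over, and above 100 kg body weight), a young-skewed
#' bimodal age distribution (paediatric autoinflammatory plus adult
#' indications), early-failure Weibull onset times (scale 100 days, shape
#' 0.9), a 5% duplicate case-version rate, and FAERS-like missingness.
#'
#' @param n_reports Number of unique cases.
#' @param exposure_prob Probability a report lists the target drug as PS.
#' @param pt_catalog data.frame as [synth_pt_catalog()].
#' @param planted_effects data.frame with columns `pt`, `rr` and optional
#'   stratum multipliers `male_mult`, `age60_mult`, `wt100_mult` (applied
#'   multiplicatively to the relative risk within the stratum, exposed
#'   reports only).
#' @param target_names Drug name spellings used for exposed reports.
#' @param target_as_conc_prob Probability an unexposed report carries the
#'   target as a concomitant (role C) drug.
#' @param sex_probs,reporter_probs,country_probs Named sampling weights.
#' @param age_mix Lognormal mixture for age: `w`, `meanlog`, `sdlog`.
#' @param tto_alpha,tto_beta Weibull onset-time parameters (days).
#' @param duplicate_rate Fraction of cases emitted twice as a later version.
#' @param missing_rates Per-field missingness probabilities.
#' @param seed Integer seed; the same config is byte-reproducible.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_reports = 5000, exposure_prob = 0.1,
                         pt_catalog = synth_pt_catalog(),
                         planted_effects = data.frame(
                           pt = c("Pneumonia", "Infection", "Deafness"),
                           rr = c(2.25, 2.5, 3),
                           male_mult = c(1, 1.5, 1),
                           age60_mult = c(1, 2, 1),
                           wt100_mult = c(1, 2, 1),
                           stringsAsFactors = FALSE),
                         target_names = c("CANAKINUMAB", "ILARIS"),
                         target_as_conc_prob = 0.02,
                         sex_probs = c(F = 0.55, M = 0.40, U = 0.05),
                         reporter_probs = c(CN = 0.41, MD = 0.32, PH = 0.17,
                                            OT = 0.08, U = 0.02),
                         country_probs = c(US = 0.56, CA = 0.11, JP = 0.10,
                                           DE = 0.05, GB = 0.02, OTHER = 0.16),
                         age_mix = list(w = c(0.55, 0.45),
                                        meanlog = log(c(11, 48)),
                                        sdlog = c(0.6, 0.45)),
                         tto_alpha = 100, tto_beta = 0.9,
                         duplicate_rate = 0.05,
                         missing_rates = c(age = 0.10, weight = 0.30,
                                           sex = 0.05, country = 0.05,
                                           event_dt = 0.35, start_dt = 0.35),
                         seed = 1L) {
  cfg <- list(n_reports = n_reports, exposure_prob = exposure_prob,
              pt_catalog = pt_catalog, planted_effects = planted_effects,
              target_names = target_names,
              target_as_conc_prob = target_as_conc_prob,
              sex_probs = sex_probs, reporter_probs = reporter_probs,
              country_probs = country_probs, age_mix = age_mix,
              tto_alpha = tto_alpha, tto_beta = tto_beta,
              duplicate_rate = duplicate_rate, missing_rates = missing_rates,
              seed = as.integer(seed))
  stopifnot(n_reports >= 1, exposure_prob >= 0, exposure_prob <= 1,
            all(pt_catalog$background_prob >= 0 & pt_catalog$background_prob <= 1),
            all(planted_effects$rr > 0),
            duplicate_rate >= 0, duplicate_rate < 1,
            all(missing_rates >= 0 & missing_rates <= 1),
            tto_alpha > 0, tto_beta > 0)
  if (!all(planted_effects$pt %in% pt_catalog$pt)) {
    stop("planted_effects refer to PTs absent from the catalog")
  }
  structure(cfg, class = "synth_config")
}

# Per-report effective event probability matrix (n x npt), exposed reports
# scaled by rr and stratum multipliers, clipped to [0, 1].
synth_event_probs <- function(config, exposed, male, age60, wt100) {
  cat <- config$pt_catalog
  n <- length(exposed)
  p <- matrix(rep(cat$background_prob, each = n), n, nrow(cat))
  pe <- config$planted_effects
  if (nrow(pe) > 0) {
    getm <- function(col) if (col %in% names(pe)) pe[[col]] else rep(1, nrow(pe))
    mm <- getm("male_mult"); am <- getm("age60_mult"); wm <- getm("wt100_mult")
    for (k in seq_len(nrow(pe))) {
      j <- match(pe$pt[k], cat$pt)
      rr_eff <- pe$rr[k] * ifelse(male, mm[k], 1) *
        ifelse(age60, am[k], 1) * ifelse(wt100, wm[k], 1)
      p[exposed, j] <- cat$background_prob[j] * rr_eff[exposed]
    }
  }
  clipped <- p > 1
  p[clipped] <- 1
  list(p = p, clipped_frac = colSums(clipped) / n)
}

#' Draw a synthetic cohort in memory
#'
#' Performs all sampling for a synthetic quarter and returns the raw FAERS
#' tables (as a `faers_raw` object, exactly as [faers_read_quarter()] would
#' parse them) together with the ground truth: per-report assignments,
#' duplicate lineage, the unique-case count and the analytic expected
#' contingency cells. [synth_generate()] writes the same draw to disk.
#'
#' @param config A [synth_config()].
#' @return A list with `tables` (a `faers_raw`) and `truth`.
#' @export
synth_draw <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_reports
  caseid <- sprintf("%08d", 10000000 + seq_len(n))
  primaryid <- paste0(caseid, "1")

  sex <- sample(names(config$sex_probs), n, TRUE, config$sex_probs)
  comp <- sample(seq_along(config$age_mix$w), n, TRUE, config$age_mix$w)
  age <- round(stats::rlnorm(n, config$age_mix$meanlog[comp],
                             config$age_mix$sdlog[comp]), 1)
  wt <- ifelse(age < 18,
               (8 + 3.2 * age) * exp(stats::rnorm(n, 0, 0.18)),
               stats::rlnorm(n, log(72), 0.25))
  wt <- round(wt, 1)
  reporter <- sample(names(config$reporter_probs), n, TRUE, config$reporter_probs)
  country <- sample(names(config$country_probs), n, TRUE, config$country_probs)
  exposed <- stats::runif(n) < config$exposure_prob

  probs <- synth_event_probs(config, exposed, male = sex == "M",
                             age60 = age >= 60, wt100 = wt > 100)
  if (any(probs$clipped_frac > 0.05)) {
    warning("event probability clipped for >5% of reports for PT(s): ",
            paste(config$pt_catalog$pt[probs$clipped_frac > 0.05], collapse = ", "))
  }
  cat_ <- config$pt_catalog
  npt <- nrow(cat_)
  has_evt <- matrix(stats::runif(n * npt), n, npt) < probs$p
  serious_evt <- has_evt & matrix(stats::runif(n * npt), n, npt) <
    matrix(rep(cat_$serious_prob, each = n), n, npt)
  death_evt <- serious_evt & matrix(stats::runif(n * npt), n, npt) <
    matrix(rep(cat_$death_prob, each = n), n, npt)
  serious <- rowSums(serious_evt) > 0
  death <- rowSums(death_evt) > 0
  n_events <- rowSums(has_evt)

  # dates: therapy start uniform over 2010-2023, onset Weibull days later
  start <- as.Date("2010-01-01") + floor(stats::runif(n, 0, 5113))
  tto_days <- pmax(1, ceiling(stats::rweibull(n, shape = config$tto_beta,
                                              scale = config$tto_alpha)))
  event <- start + tto_days
  fda <- event + floor(stats::runif(n, 3, 120))

  # non-death serious outcome codes
  other_code <- sample(c("HO", "OT", "DS", "LT"), n, TRUE,
                       c(0.6, 0.3, 0.06, 0.04))

  # missingness masks (drawn for every report in fixed order)
  mr <- config$missing_rates
  miss <- function(field) stats::runif(n) < mr[[field]]
  m_age <- miss("age"); m_wt <- miss("weight"); m_sex <- miss("sex")
  m_ctry <- miss("country"); m_evt <- miss("event_dt"); m_start <- miss("start_dt")

  # drugs: exposed get the target as PS (+0-2 concomitants); unexposed get
  # 1-3 background drugs, occasionally the target as concomitant
  others <- c("METHOTREXATE", "PREDNISONE", "ADALIMUMAB", "IBUPROFEN",
              "TOCILIZUMAB", "ASPIRIN")
  tgt_name <- sample(config$target_names, n, TRUE)
  n_conc <- sample(0:2, n, TRUE, c(0.5, 0.3, 0.2))
  ps_other <- sample(others, n, TRUE)
  tgt_conc <- !exposed & stats::runif(n) < config$target_as_conc_prob

  ps_idx <- match(ps_other, others)
  di <- list(data.frame(i = seq_len(n),
                        nm = ifelse(exposed, tgt_name, ps_other),
                        rl = "PS", stringsAsFactors = FALSE))
  if (any(tgt_conc)) {
    di[[length(di) + 1L]] <- data.frame(i = which(tgt_conc),
                                        nm = tgt_name[tgt_conc], rl = "C",
                                        stringsAsFactors = FALSE)
  }
  for (j in 1:2) {
    sel <- which(n_conc >= j)
    if (length(sel)) {
      di[[length(di) + 1L]] <- data.frame(
        i = sel, nm = others[(ps_idx[sel] + j) %% 6L + 1L], rl = "C",
        stringsAsFactors = FALSE)
    }
  }
  dd <- do.call(rbind, di)
  dd <- dd[order(dd$i, dd$rl != "PS"), , drop = FALSE]

  fmt_d <- function(d, m) ifelse(m, "", format(d, "%Y%m%d"))
  demo_df <- data.frame(
    primaryid = primaryid, caseid = caseid, fda_dt = format(fda, "%Y%m%d"),
    event_dt = fmt_d(event, m_evt),
    sex = ifelse(m_sex | sex == "U", "", sex),
    age = ifelse(m_age, "", format(age, trim = TRUE)),
    age_cod = ifelse(m_age, "", "YR"),
    wt = ifelse(m_wt, "", format(wt, trim = TRUE)),
    wt_cod = ifelse(m_wt, "", "KG"),
    reporter_country = ifelse(m_ctry, "", country),
    occp_cod = ifelse(reporter == "U", "", reporter),
    stringsAsFactors = FALSE)

  evt_idx <- which(has_evt, arr.ind = TRUE)
  reac_df <- data.frame(primaryid = primaryid[evt_idx[, 1]],
                        caseid = caseid[evt_idx[, 1]],
                        pt = cat_$pt[evt_idx[, 2]], stringsAsFactors = FALSE)
  reac_df <- reac_df[order(evt_idx[, 1], evt_idx[, 2]), , drop = FALSE]

  drug_df <- data.frame(
    primaryid = primaryid[dd$i], caseid = caseid[dd$i],
    drug_seq = as.integer(stats::ave(dd$i, dd$i, FUN = seq_along)),
    drugname = dd$nm, role_cod = dd$rl, stringsAsFactors = FALSE)

  outc_list <- list()
  ser_idx <- which(serious)
  if (length(ser_idx)) {
    code1 <- ifelse(death[ser_idx], "DE", other_code[ser_idx])
    outc_list[[1]] <- data.frame(primaryid = primaryid[ser_idx],
                                 caseid = caseid[ser_idx], outc_cod = code1,
                                 stringsAsFactors = FALSE)
    # fatal hospitalized cases also carry HO
    both <- ser_idx[death[ser_idx] & other_code[ser_idx] == "HO"]
    if (length(both)) {
      outc_list[[2]] <- data.frame(primaryid = primaryid[both],
                                   caseid = caseid[both], outc_cod = "HO",
                                   stringsAsFactors = FALSE)
    }
  }
  outc_df <- if (length(outc_list)) do.call(rbind, outc_list) else
    data.frame(primaryid = character(0), caseid = character(0),
               outc_cod = character(0), stringsAsFactors = FALSE)

  ther_df <- data.frame(primaryid = primaryid, caseid = caseid,
                        dsg_drug_seq = "1",
                        start_dt = fmt_d(start, m_start), stringsAsFactors = FALSE)

  # duplicate case versions: later fda_dt, new primaryid, same content
  n_dup <- round(config$duplicate_rate * n)
  dup_lineage <- data.frame(caseid = character(0), primaryid_orig = character(0),
                            primaryid_dup = character(0), stringsAsFactors = FALSE)
  if (n_dup > 0) {
    dup_i <- sort(sample.int(n, n_dup))
    dup_pid <- paste0(caseid[dup_i], "2")
    dup_demo <- demo_df[dup_i, , drop = FALSE]
    dup_demo$primaryid <- dup_pid
    dup_demo$fda_dt <- format(fda[dup_i] + floor(stats::runif(n_dup, 10, 200)),
                              "%Y%m%d")
    demo_df <- rbind(demo_df, dup_demo)
    copy_child <- function(df) {
      cp <- df[df$primaryid %in% primaryid[dup_i], , drop = FALSE]
      cp$primaryid <- paste0(cp$caseid, "2")
      rbind(df, cp)
    }
    drug_df <- copy_child(drug_df)
    reac_df <- copy_child(reac_df)
    outc_df <- copy_child(outc_df)
    ther_df <- copy_child(ther_df)
    dup_lineage <- data.frame(caseid = caseid[dup_i],
                              primaryid_orig = primaryid[dup_i],
                              primaryid_dup = dup_pid, stringsAsFactors = FALSE)
  }

  reports <- data.frame(
    caseid = caseid, primaryid = primaryid, exposed = exposed, sex = sex,
    age = age, weight = wt, reporter = reporter, country = country,
    serious = serious, death = death, n_events = n_events,
    tto_days = tto_days, start_dt = format(start, "%Y%m%d"),
    event_dt = format(event, "%Y%m%d"),
    event_dt_missing = m_evt, start_dt_missing = m_start,
    stringsAsFactors = FALSE)
  truth <- list(reports = reports,
                events = reac_df[reac_df$primaryid %in% primaryid, c("primaryid", "pt")],
                n_unique_cases = n, duplicates = dup_lineage,
                expected = synth_expected_tables(config))
  tables <- structure(list(demo = demo_df, drug = drug_df, reac = reac_df,
                           outc = outc_df, ther = ther_df, log = list()),
                      class = "faers_raw")
  list(tables = tables, truth = truth)
}

#' Generate a synthetic FAERS quarter on disk
#'
#' Writes the draw of [synth_draw()] as DEMO/DRUG/REAC/OUTC/THER files in
#' the "$"-delimited dialect, plus a ground-truth CSV sidecar and the
#' configuration as JSON, for provenance. The same seed produces
#' byte-identical files.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `files` and `truth`.
#' @export
synth_generate <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- synth_draw(config)
  write_dollar <- function(df, name) {
    path <- file.path(dir, paste0(name, ".txt"))
    lines <- c(paste(names(df), collapse = "$"),
               do.call(paste, c(unname(as.list(df)), sep = "$")))
    writeLines(lines, path)
    path
  }
  files <- c(demo = write_dollar(d$tables$demo, "DEMO"),
             drug = write_dollar(d$tables$drug, "DRUG"),
             reac = write_dollar(d$tables$reac, "REAC"),
             outc = write_dollar(d$tables$outc, "OUTC"),
             ther = write_dollar(d$tables$ther, "THER"))
  utils::write.csv(d$truth$reports, file.path(dir, "ground_truth_reports.csv"),
                   row.names = FALSE)
  cfg_out <- unclass(config)
  cfg_out$pt_catalog <- NULL
  jsonlite::write_json(cfg_out, file.path(dir, "synth_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(dir = dir, files = files, truth = d$truth))
}

# Joint stratum probabilities (sex x age60 x wt100) under the demographic
# model, by numeric integration over the age density.
synth_stratum_probs <- function(config) {
  grid <- seq(0.025, 150, by = 0.05)
  dens <- rowSums(vapply(seq_along(config$age_mix$w), function(k) {
    config$age_mix$w[k] * stats::dlnorm(grid, config$age_mix$meanlog[k],
                                        config$age_mix$sdlog[k])
  }, numeric(length(grid)))) * 0.05
  p_wt_gt100 <- ifelse(grid < 18,
                       stats::pnorm(log(100 / (8 + 3.2 * grid)) / 0.18,
                                    lower.tail = FALSE),
                       stats::plnorm(100, log(72), 0.25, lower.tail = FALSE))
  p_a1w1 <- sum(dens * (grid >= 60) * p_wt_gt100)
  p_a1w0 <- sum(dens * (grid >= 60) * (1 - p_wt_gt100))
  p_a0w1 <- sum(dens * (grid < 60) * p_wt_gt100)
  p_a0w0 <- sum(dens * (grid < 60) * (1 - p_wt_gt100))
  aw <- c(a0w0 = p_a0w0, a0w1 = p_a0w1, a1w0 = p_a1w0, a1w1 = p_a1w1)
  aw <- aw / sum(aw)
  sp <- config$sex_probs / sum(config$sex_probs)
  out <- expand.grid(sex = names(sp), aw = names(aw),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$prob <- sp[out$sex] * aw[out$aw]
  out$male <- out$sex == "M"
  out$age60 <- out$aw %in% c("a1w0", "a1w1")
  out$wt100 <- out$aw %in% c("a0w1", "a1w1")
  out
}

#' Analytic expected contingency tables under a synthetic configuration
#'
#' Computes, before any sampling, the expected 2x2 cells for every catalog
#' PT: the exposed event probability averages the clipped
#' `background x RR x stratum-multiplier` over the demographic stratum
#' distribution (numeric integration over the age/weight model). Useful for
#' tolerance-based convergence tests against empirical counts.
#'
#' @param config A [synth_config()].
#' @return data.frame with columns `pt`, `a`, `b`, `c`, `d` (expected
#'   counts; rows sum to `n_reports`).
#' @export
synth_expected_tables <- function(config) {
  n <- config$n_reports
  pexp <- config$exposure_prob
  strata <- synth_stratum_probs(config)
  cat_ <- config$pt_catalog
  pe <- config$planted_effects
  getm <- function(col) if (col %in% names(pe)) pe[[col]] else rep(1, nrow(pe))
  mm <- getm("male_mult"); am <- getm("age60_mult"); wm <- getm("wt100_mult")
  rows <- lapply(seq_len(nrow(cat_)), function(j) {
    bg <- min(cat_$background_prob[j], 1)
    k <- match(cat_$pt[j], pe$pt)
    p_exp_evt <- if (is.na(k)) bg else {
      rr_eff <- pe$rr[k] * ifelse(strata$male, mm[k], 1) *
        ifelse(strata$age60, am[k], 1) * ifelse(strata$wt100, wm[k], 1)
      sum(strata$prob * pmin(bg * rr_eff, 1))
    }
    a <- n * pexp * p_exp_evt
    c_ <- n * (1 - pexp) * bg
    data.frame(pt = cat_$pt[j], a = a, b = n * pexp - a, c = c_,
               d = n * (1 - pexp) - c_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
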