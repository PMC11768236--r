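# Build a faers_cases object directly (no file round trip), for tests that
# need many replicate cohorts cheaply.
make_cases <- function(exposed, events, serious = NULL, death = NULL,
                       sex = NULL, age = NULL, weight = NULL,
                       reporter = NULL, event_date = NULL,
                       therapy_start = NULL) {
  n <- length(exposed)
  pid <- as.character(seq_len(n))
  if (is.null(serious)) serious <- rep(FALSE, n)
  if (is.null(death)) death <- rep(FALSE, n)
  demo <- data.frame(
    primaryid = pid, caseid = pid, fda_date = as.Date("2020-01-01") + seq_len(n) %% 365,
    sex = if (is.null(sex)) rep("unknown", n) else sex,
    age_years = if (is.null(age)) rep(NA_real_, n) else age,
    weight_kg = if (is.null(weight)) rep(NA_real_, n) else weight,
    country = rep("US", n),
    reporter = if (is.null(reporter)) rep("unknown", n) else reporter,
    death = death, life_threatening = rep(FALSE, n),
    hospitalization = serious & !death, disability = rep(FALSE, n),
    other_serious = rep(FALSE, n), serious = serious | death,
    stringsAsFactors = FALSE)
  demo$event_date <- if (is.null(event_date)) as.Date(rep(NA, n)) else event_date
  demo$event_date_partial <- rep(FALSE, n)
  demo$therapy_start <- if (is.null(therapy_start)) as.Date(rep(NA, n)) else therapy_start
  demo$therapy_start_partial <- rep(FALSE, n)
  drugs <- data.frame(primaryid = pid,
                      name = ifelse(exposed, "TARGETDRUG", "OTHERDRUG"),
                      role = "PS", stringsAsFactors = FALSE)
  nev <- lengths(events)
  ev <- data.frame(primaryid = rep(pid, nev), pt = unlist(events),
                   stringsAsFactors = FALSE)
  structure(list(demo = demo, drugs = drugs,
                 events = ev[!duplicated(ev), , drop = FALSE],
                 log = list()),
            class = "faers_cases")
}

# Random cohort with independent per-PT event probabilities; exposed reports
# get background * rr for planted PTs. Returns cases plus the assignment
# matrices for truth checks.
sim_cohort <- function(n, p_exp = 0.2, pt_probs = c(EV1 = 0.1, EV2 = 0.05),
                       rr = setNames(rep(1, length(pt_probs)), names(pt_probs)),
                       p_serious = 0.3) {
  exposed <- runif(n) < p_exp
  pts <- names(pt_probs)
  evm <- sapply(pts, function(pt) {
    p <- pmin(pt_probs[[pt]] * ifelse(exposed, rr[[pt]], 1), 1)
    runif(n) < p
  })
  idx <- which(evm, arr.ind = TRUE)
  events <- split(pts[idx[, 2]], factor(idx[, 1], levels = seq_len(n)))
  serious <- runif(n) < p_serious
  list(cases = make_cases(exposed, events, serious = serious),
       exposed = as.character(which(exposed)), evm = evm,
       exposed_flag = exposed, serious = serious)
}
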