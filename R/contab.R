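#' 2x2 contingency table for disproportionality analysis
#'
#' The unit of counting is the deduplicated report. For a target drug and a
#' target event definition, `a` counts reports with both, `b` reports with the
#' drug but not the event, `c` reports with the event but not the drug, and
#' `d` reports with neither, so that `a + b` is the exposed-report count and
#' `a + c` the event-report count.
#'
#' @param a,b,c,d Non-negative counts.
#' @return An object of class `contab` with fields `a`, `b`, `c`, `d`, `n`.
#' @examples
#' contab(25, 75, 100, 900)
#' @export
contab <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (length(cells) != 4L || any(!is.finite(cells)) || any(cells < 0)) {
    stop("contab: all four cells must be finite, non-negative counts")
  }
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d),
            class = "contab")
}

#' @export
print.contab <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "no drug"), c("event", "no event")))
  cat("2x2 report contingency table (N =", x$n, ")\n")
  print(m)
  invisible(x)
}

# Accept a contab or a length-4 numeric c(a, b, c, d).
as_contab <- function(x) {
  if (inherits(x, "contab")) return(x)
  if (is.numeric(x) && length(x) == 4L) return(contab(x[[1]], x[[2]], x[[3]], x[[4]]))
  stop("expected a contab or a numeric vector c(a, b, c, d)")
}

#' Report ids matching an event definition
#'
#' Resolves an event specification to the set of report ids (`primaryid`)
#' carrying the event. At PT level a report matches when it lists the
#' preferred term; at SOC level when at least one of its PTs maps to the
#' system organ class (the report is counted once). With `serious_only` the
#' match is additionally restricted to reports with at least one serious
#' outcome code.
#'
#' @param cases A `faers_cases` object from [normalize_cases()].
#' @param term PT or SOC name (exact, case-sensitive, as coded).
#' @param level `"pt"` or `"soc"`.
#' @param annotation A `faers_annotation` (required for SOC level).
#' @param serious_only Restrict to reports with serious outcomes.
#' @return Character vector of report ids.
#' @export
event_reports <- function(cases, term, level = c("pt", "soc"),
                          annotation = NULL, serious_only = FALSE) {
  level <- match.arg(level)
  ev <- cases$events
  if (level == "pt") {
    ids <- unique(ev$primaryid[ev$pt == term])
  } else {
    if (is.null(annotation)) stop("SOC-level events need an annotation")
    socs <- annotation$pt_to_soc[ev$pt]
    socs[is.na(socs)] <- "UNMAPPED"
    ids <- unique(ev$primaryid[socs == term])
  }
  if (serious_only) {
    ids <- intersect(ids, cases$demo$primaryid[cases$demo$serious])
  }
  ids
}

#' Build the 2x2 table for a drug/event pair
#'
#' @param cases A `faers_cases` object.
#' @param exposed_ids Report ids exposed to the target drug (see
#'   [select_target_reports()]).
#' @param event_ids Report ids with the target event, either a character
#'   vector (e.g. from [event_reports()]) or a predicate function mapping the
#'   `faers_cases` object to such a vector.
#' @param subset_ids Optional restriction of the report universe (e.g. one
#'   demographic stratum); cells then sum to `length(subset_ids)`.
#' @return A [contab()].
#' @export
contingency_table <- function(cases, exposed_ids, event_ids, subset_ids = NULL) {
  if (is.function(event_ids)) event_ids <- event_ids(cases)
  universe <- cases$demo$primaryid
  if (!is.null(subset_ids)) universe <- intersect(universe, subset_ids)
  exp_in <- universe %in% exposed_ids
  evt_in <- universe %in% event_ids
  contab(sum(exp_in & evt_in), sum(exp_in & !evt_in),
         sum(!exp_in & evt_in), sum(!exp_in & !evt_in))
}

#' Stratified 2x2 tables
#'
#' Splits the report universe along one demographic dimension and builds one
#' table per stratum. Numeric dimensions (`age`, `weight`) use half-open
#' intervals `[lo, hi)`; categorical dimensions (`sex`, `reporter`) use
#' named groups of category labels, which must be disjoint. Reports with a
#' missing value on the dimension are excluded from every stratum.
#'
#' @param cases A `faers_cases` object.
#' @param exposed_ids,event_ids As for [contingency_table()].
#' @param dimension One of `"age"`, `"weight"`, `"sex"`, `"reporter"`.
#' @param breaks Numeric cut points for age/weight (e.g. `c(0, 18, 60, Inf)`).
#' @param groups Named list of category vectors for sex/reporter.
#' @param labels Optional stratum labels for numeric breaks.
#' @return A data.frame with columns `stratum`, `a`, `b`, `c`, `d`.
#' @export
stratified_tables <- function(cases, exposed_ids, event_ids,
                              dimension = c("age", "weight", "sex", "reporter"),
                              breaks = NULL, groups = NULL, labels = NULL) {
  dimension <- match.arg(dimension)
  if (is.function(event_ids)) event_ids <- event_ids(cases)
  demo <- cases$demo
  field <- switch(dimension,
                  age = demo$age_years, weight = demo$weight_kg,
                  sex = demo$sex, reporter = demo$reporter)
  if (dimension %in% c("age", "weight")) {
    if (is.null(breaks)) {
      breaks <- if (dimension == "age") c(0, 18, 60, Inf) else c(0, 50, 100, Inf)
    }
    if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must be strictly increasing")
    grp <- cut(field, breaks = breaks, right = FALSE, labels = labels)
    strata <- levels(grp)
  } else {
    if (is.null(groups)) {
      groups <- if (dimension == "sex") {
        list(female = "female", male = "male")
      } else {
        list(health_professional = c("physician", "pharmacist",
                                     "other_health_professional"),
             consumer = "consumer")
      }
    }
    all_cats <- unlist(groups)
    if (anyDuplicated(all_cats)) stop("overlapping strata: groups must be disjoint")
    grp <- rep(NA_character_, length(field))
    for (g in names(groups)) grp[field %in% groups[[g]]] <- g
    strata <- names(groups)
  }
  out <- lapply(strata, function(s) {
    ids <- demo$primaryid[!is.na(grp) & grp == s]
    t <- contingency_table(cases, exposed_ids, event_ids, subset_ids = ids)
    data.frame(stratum = s, a = t$a, b = t$b, c = t$c, d = t$d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
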