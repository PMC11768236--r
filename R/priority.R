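# Semiquantitative clinical-priority scoring of signal PTs: five items
# (case count, ROR, mortality proportion, DME/IME status, literature
# evidence), each 0-2, totalled 0-10 and banded weak / moderate / strong.

#' Default clinical-priority rubric
#'
#' Cut points for the five 0/1/2 items:
#' cases `<10 / 10-50 / >50`; ROR `<2 / 2-<5 / >=5`; death proportion
#' `<25% / 25-50% / >50%`; event-list status `none / IME / DME` (DME takes
#' precedence when a PT sits on both lists); evidence grade `- / + / ++`.
#' Boundary placements inside ranges not pinned down by published scores
#' (death proportions of exactly 25% or 50%, ROR exactly 5) are conventions
#' and configurable here.
#'
#' @param cases_breaks Two thresholds `(t1, t2)`: score 1 from `cases >= t1`,
#'   2 from `cases > t2`.
#' @param ror_breaks Score 1 from `ror >= t1`, 2 from `ror >= t2`.
#' @param death_breaks Proportions: score 1 from `p >= t1`, 2 from `p > t2`.
#' @param dme_score,ime_score Points for DME / IME membership.
#' @param evidence_scores Named points for the `++`, `+`, `-` grades.
#' @return A `priority_rubric` list.
#' @export
priority_rubric <- function(cases_breaks = c(10, 50), ror_breaks = c(2, 5),
                            death_breaks = c(0.25, 0.5),
                            dme_score = 2, ime_score = 1,
                            evidence_scores = c("++" = 2, "+" = 1, "-" = 0)) {
  structure(list(cases_breaks = cases_breaks, ror_breaks = ror_breaks,
                 death_breaks = death_breaks, dme_score = dme_score,
                 ime_score = ime_score, evidence_scores = evidence_scores),
            class = "priority_rubric")
}

#' Band a total priority score
#'
#' Totals 0-4 are weak, 5-7 moderate, 8-10 strong.
#'
#' @param total Integer total score(s).
#' @return Character vector of bands.
#' @export
priority_band <- function(total) {
  ifelse(total >= 8, "strong", ifelse(total >= 5, "moderate", "weak"))
}

#' Score PTs on the five-item clinical-priority scale
#'
#' Vectorized over PTs. `evidence` values missing from the rubric's grade
#' map (including `NA`) score 0.
#'
#' @param cases Report count `a` per PT (must be >= 1).
#' @param ror ROR point estimate.
#' @param deaths Death-outcome report count among the `a` cases.
#' @param dme,ime Logical list membership; DME precedence.
#' @param evidence Evidence grade (`"++"`, `"+"`, `"-"` or `NA`).
#' @param rubric A [priority_rubric()].
#' @return data.frame with the five item scores (`s_cases`, `s_ror`,
#'   `s_death`, `s_listed`, `s_evidence`), `total` and `band`.
#' @export
score_priority <- function(cases, ror, deaths, dme, ime, evidence,
                           rubric = priority_rubric()) {
  if (any(cases < 1)) stop("cases must be >= 1 for every PT")
  if (any(deaths > cases)) stop("deaths cannot exceed cases")
  s_cases <- (cases >= rubric$cases_breaks[1]) + (cases > rubric$cases_breaks[2])
  s_ror <- (ror >= rubric$ror_breaks[1]) + (ror >= rubric$ror_breaks[2])
  p <- deaths / cases
  s_death <- (p >= rubric$death_breaks[1]) + (p > rubric$death_breaks[2])
  s_listed <- ifelse(dme, rubric$dme_score, ifelse(ime, rubric$ime_score, 0))
  ev <- rubric$evidence_scores[as.character(evidence)]
  s_evidence <- ifelse(is.na(ev), 0, ev)
  total <- s_cases + s_ror + s_death + s_listed + s_evidence
  data.frame(s_cases = as.integer(s_cases), s_ror = as.integer(s_ror),
             s_death = as.integer(s_death), s_listed = as.integer(s_listed),
             s_evidence = as.integer(unname(s_evidence)),
             total = as.integer(total), band = priority_band(total),
             stringsAsFactors = FALSE)
}

#' Score a single PT
#'
#' @inheritParams score_priority
#' @return A list with `items` (length-5 integer vector), `total`, `band`.
#' @export
score_pt <- function(cases, ror, deaths, dme, ime, evidence,
                     rubric = priority_rubric()) {
  s <- score_priority(cases, ror, deaths, dme, ime, evidence, rubric)
  list(items = c(cases = s$s_cases, ror = s$s_ror, death = s$s_death,
                 listed = s$s_listed, evidence = s$s_evidence),
       total = s$total, band = s$band)
}

#' Count weak / moderate / strong bands
#'
#' @param bands Character vector of bands (or a data.frame with a `band`
#'   column as returned by [score_priority()]).
#' @return Named integer vector `(weak, moderate, strong)`.
#' @export
band_counts <- function(bands) {
  if (is.data.frame(bands)) bands <- bands$band
  c(weak = sum(bands == "weak"), moderate = sum(bands == "moderate"),
    strong = sum(bands == "strong"))
}
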