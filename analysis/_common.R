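# Shared helpers for the analysis scripts: paths and cohort loading.
library(faersignal)

QUARTER_DIR <- "scratch/synthetic_quarter"
RESULTS_DIR <- "results"
DRUG_NAMES <- c("canakinumab", "ilaris")

catalog_annotation <- function() {
  cat <- synth_pt_catalog()
  structure(list(pt_to_soc = setNames(cat$soc, cat$pt),
                 dme = "Sepsis",
                 ime = c("Pneumonia", "Sepsis", "Deafness", "Hepatotoxicity"),
                 evidence = c(Pneumonia = "++", Infection = "++",
                              `Urinary tract infection` = "+",
                              Sepsis = "+", Deafness = "-")),
            class = "faers_annotation")
}

load_cases <- function() {
  if (!dir.exists(QUARTER_DIR)) {
    stop("run analysis/01_simulate_cohort.R first: ", QUARTER_DIR, " is missing")
  }
  raw <- faers_read_quarter(QUARTER_DIR)
  cases <- normalize_cases(faers_dedup(raw))
  part <- select_target_reports(cases, DRUG_NAMES)
  list(cases = cases, exposed = part$exposed, raw_rows = nrow(raw$demo))
}
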