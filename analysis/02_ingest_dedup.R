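#!/usr/bin/env Rscript
# Parse the quarter, deduplicate case versions, normalize units and codes,
# and identify target-drug exposure.
source("analysis/_common.R")

raw <- faers_read_quarter(QUARTER_DIR)
cat("Parsed rows:", paste(names(raw$log$rows), raw$log$rows, collapse = ", "), "\n")
dd <- faers_dedup(raw)
cat("Removed", dd$log$dedup_removed, "duplicate case versions (caseid-latest rule)\n")
cases <- normalize_cases(dd)
cat("Normalization warning counters:",
    paste(names(cases$log), unlist(cases$log), collapse = ", "), "\n")
part <- select_target_reports(cases, DRUG_NAMES)
cat("Exposed reports (PS role):", length(part$exposed),
    "of", nrow(cases$demo), "\n")
write.csv(cases$demo, file.path("scratch", "normalized_cases.csv"),
          row.names = FALSE)
cat("Normalized case table -> scratch/normalized_cases.csv\n")
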