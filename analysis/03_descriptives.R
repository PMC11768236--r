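#!/usr/bin/env Rscript
# Descriptive features of the exposed cohort: sex, reporters, countries,
# serious outcome categories, age/weight medians.
source("analysis/_common.R")

lc <- load_cases()
desc <- describe_cohort(lc$cases, lc$exposed)
cat("Exposed cohort size:", desc$n, "\n")
cat("Sex split:\n"); print(desc$sex)
cat("Serious outcome categories:\n"); print(desc$outcomes)
cat("Age / weight:\n"); print(desc$continuous)
for (nm in c("sex", "reporter", "country", "year", "outcomes", "continuous")) {
  write.csv(desc[[nm]], file.path(RESULTS_DIR, paste0("describe_", nm, ".csv")),
            row.names = FALSE)
}
cat("Descriptive tables -> results/describe_*.csv\n")
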