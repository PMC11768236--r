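#!/usr/bin/env Rscript
# Four-algorithm disproportionality screen at PT level (all-four policy)
# and SOC level (any-one policy).
source("analysis/_common.R")

lc <- load_cases()
ann <- catalog_annotation()
pt <- screen_signals(lc$cases, lc$exposed, ann, level = "pt")
soc <- screen_signals(lc$cases, lc$exposed, ann, level = "soc")
cat("PT-level: screened", nrow(pt), "terms;", sum(pt$signal),
    "meet all four algorithms:\n")
print(pt[pt$signal, c("term", "a", "ror", "prr", "ic025", "ebgm05")], digits = 3)
cat("SOC-level: ", sum(soc$signal), "of", nrow(soc),
    "organ classes meet at least one algorithm\n")
write.csv(pt, file.path(RESULTS_DIR, "signals_pt.csv"), row.names = FALSE)
write.csv(soc, file.path(RESULTS_DIR, "signals_soc.csv"), row.names = FALSE)
cat("Signal tables -> results/signals_pt.csv, results/signals_soc.csv\n")
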