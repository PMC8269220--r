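#!/usr/bin/env Rscript
# Salinity arithmetic for the two media-design schemes: NaCl-only addition
# to the base medium and proportional dilution of all major ions.
# Writes results/salinity_series.tsv.

suppressPackageStartupMessages(library(ecophys))
dir.create("results", showWarnings = FALSE)

base <- 8.66          # permil, unamended base medium
full <- 34.8          # permil, full-strength major-ion composition

nacl_pct <- c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5)
nacl <- data.frame(scheme = "nacl_addition", level = nacl_pct,
                   salinity = nacl_series(base, nacl_pct))

dil <- c(0.36 / full, 0.05, 0.1, 0.25, 0.5, 0.75, 1)
prop <- data.frame(scheme = "proportional_dilution", level = dil,
                   salinity = proportional_series(full, dil))

series <- rbind(nacl, prop)
write.table(series, "results/salinity_series.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("NaCl-addition series spans",
    sprintf("%.2f to %.1f permil (0 to 5%% w/v);", min(nacl$salinity),
            max(nacl$salinity)),
    "slope", sprintf("%.2f permil per %% w/v.\n",
                     1.80655 * 10 * 35.453 / 58.443))
cat("Proportional series spans",
    sprintf("%.2f to %.1f permil.\n", min(prop$salinity), max(prop$salinity)))
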