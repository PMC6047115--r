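#!/usr/bin/env Rscript
# Stage 2: data cleaning.
#
# Two rules, applied before any fitting: (i) imaging days on which not every
# line was phenotyped are discarded wholesale; (ii) per (line, replicate,
# trait) series, observations with Cook's distance above 4x the series mean
# (against a cubic-in-DAS OLS reference) are removed, capped at 5% of a
# series.

suppressPackageStartupMessages(library(growthqtl))

geno <- read_genotypes("results/data/genotypes.tsv")
series <- read_phenotypes("results/data/phenotypes.csv")

report <- validate_inputs(geno, series)
stopifnot(!any(report$severity == "fatal"))
cat(sprintf("Validation: %d warning(s), no fatal problems.\n",
            sum(report$severity == "warning")))

roster <- intersect(rownames(geno$genotypes), unique(series$line))
flt <- filter_incomplete_timepoints(series, roster)
cat(sprintf("Timepoint filter: dropped %d of %d DAS.\n",
            length(flt$report$dropped_timepoints),
            length(unique(series$DAS))))

cleaned <- flt$series
n_out <- 0
for (tr in unique(cleaned$trait)) {
  ck <- suppressWarnings(remove_cooks_outliers(cleaned, tr))
  cleaned <- ck$series
  n_out <- n_out + nrow(ck$report)
}
cat(sprintf("Cook's-distance rule removed %d of %d observations (%.2f%%).\n",
            n_out, nrow(flt$series), 100 * n_out / nrow(flt$series)))

write_phenotypes(cleaned, "results/data/phenotypes_clean.csv")
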