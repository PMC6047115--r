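#!/usr/bin/env Rscript
# Stage 5: variance components of the fitted parameters.
#
# With two replicates per line, the between/within-line mean squares separate
# genetic from environmental variance for every curve parameter: heritability
# H2 = s2_g / (s2_g + s2_e), and genetic/environmental covariances and
# correlations between parameters come from the sum-trait identity.

suppressPackageStartupMessages(library(growthqtl))

dir.create("results/quantgen", showWarnings = FALSE, recursive = TRUE)
herit_all <- list()
for (tr in c("Area", "Height", "TYP_Area", "water_amount")) {
  tab <- read.csv(sprintf("results/fits/params_%s.csv", tr))
  tab <- tab[tab$converged %in% TRUE, ]
  h <- heritability_table(tab)
  h$trait <- tr
  herit_all[[tr]] <- h
  cm <- correlation_matrices(tab)
  write.csv(round(cm$r_g, 4), sprintf("results/quantgen/corr_genetic_%s.csv", tr))
  write.csv(round(cm$r_e, 4), sprintf("results/quantgen/corr_environment_%s.csv", tr))
}
herit <- do.call(rbind, herit_all)
rownames(herit) <- NULL
write.csv(herit, "results/quantgen/heritability.csv", row.names = FALSE)

cat("Heritability of fitted parameters:\n")
print(herit[order(herit$trait, -herit$H2), c("trait", "parameter", "H2")],
      row.names = FALSE, digits = 3)
top <- herit[which.max(herit$H2), ]
cat(sprintf("\nMost heritable parameter: %s / %s (H2 = %.2f).\n",
            top$trait, top$parameter, top$H2))
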