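#!/usr/bin/env Rscript
# Clinical associations (screening, group-median imputation, Spearman
# correlations with BH) and spin-tested receptor-map associations of the
# regional t-maps.
source("analysis/00_config.R")

cfg <- analysis_config()
res <- run_pipeline(cfg)

cl <- res$clinical
cat(sprintf("clinical correlation screen: %d metric x score pairs\n", nrow(cl)))
top <- cl[order(cl$q), ][1:5, ]
cat("strongest associations:\n")
print(top, digits = 3, row.names = FALSE)

rec <- res$receptor
cat(sprintf("\nreceptor associations: %d t-map x receptor pairs, %d spins\n",
            nrow(rec), cfg$n_perm))
cat(sprintf("significant at q < .05: %d\n", sum(rec$q < .05)))
write.table(rec, file.path(RESULTS, "receptor_associations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
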