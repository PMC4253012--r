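#!/usr/bin/env Rscript

# Stage 5: interspecies heterozygosity comparison and outlier contrast.
#
# Compares per-marker heterozygosity between species across the whole
# retained panel, flags markers whose chimpanzee heterozygosity falls more
# than 2 SD below the identity line, and contrasts the variability
# measures of outlier and non-outlier markers (relative difference in
# means with rank-sum tests).

library(orthosat)

res <- readRDS("results/pipeline_result.rds")
profiles <- read.delim("results/variability_profiles.tsv")

he <- res$he
wide <- merge(he[he$species == "chimpanzee", c("marker", "he")],
              he[he$species == "human", c("marker", "he")],
              by = "marker", suffixes = c("_chimp", "_human"))
wide <- wide[stats::complete.cases(wide), ]
names(wide) <- c("marker", "he_chimp", "he_human")
flags <- classify_outliers(wide)
write.table(flags, "results/he_outliers.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("%d of %d markers flagged as low-chimpanzee-heterozygosity outliers (band SD %.3f)",
                sum(flags$outlier), nrow(flags), attr(flags, "sd")))
message(sprintf("%d markers lie within 1 SD of the identity line",
                sum(flags$within_1sd)))

if (sum(flags$outlier) >= 2) {
  grouping <- do.call(rbind, lapply(res$conversion_markers, function(m) {
    data.frame(marker = m,
               n_regions = length(res$structures[[m]]$chimp$regions),
               unit_size = res$models[[m]]$chimpanzee$unit_size)
  }))
  contrast <- stats::setNames(flags$outlier, flags$marker)
  cmp <- group_compare(profiles, grouping, contrast = contrast, min_group = 5L)
  if (!is.null(cmp$rdm)) {
    write.table(cmp$rdm, "results/outlier_rdm.tsv",
                sep = "\t", quote = FALSE, row.names = FALSE)
    message("outlier/non-outlier RDM contrasts written to results/outlier_rdm.tsv")
  }
} else {
  message("too few outliers under these study conditions for a group contrast")
}
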