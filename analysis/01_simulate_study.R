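#!/usr/bin/env Rscript

# Stage 1: generate the study bundle.
#
# Builds the default synthetic study — 138 concordant single-unit-size core
# loci (tri- and tetranucleotide, one or two STR regions), a species
# repeat-count offset of 2 (chimpanzee lower), species-specific flank
# insertions of 1-32 bp at about half the loci, plus one engineered marker
# per branch of the retention and ortholog-assessment decision trees — and
# writes it as plain-text files under results/study/.

library(orthosat)

seed <- 20260924L
dir.create("results", showWarnings = FALSE)

study <- make_study(study_config(), seed = seed)
write_study(study, "results/study")

n_markers <- length(study$refs_chimp)
n_indel <- sum(vapply(study$manifests, function(m) length(m$indels) > 0, logical(1)))
message(sprintf("generated %d markers (%d with a species-specific flank indel)",
                n_markers, n_indel))
message(sprintf("genotypes: %d individuals x %d loci in %d populations",
                nrow(study$samples), length(study$genotypes$loci),
                length(unique(study$samples$population))))
message("bundle written to results/study/")
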