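#!/usr/bin/env Rscript

# Stage 1: simulate a pooled Bar-seq competition to FASTQ.
#
# Emulates the chemogenomic screen at desk scale: a 60-strain barcoded pool
# grown under two azole-like compounds plus solvent controls (quadruplicate
# cultures, ~15 generations), with a handful of planted transporter
# effects. Deleting an importer confers resistance (the strain enriches);
# deleting an exporter confers sensitivity (the strain depletes). The two
# compounds share most of their planted effects, as the agrochemical and
# clinical azoles do, so stage 3 can examine profile correlation.
#
# Writes FASTQ, reference, sample sheets and truth tables under
# scratch/screen_sim/ (bulk simulation data; downstream stages put their
# small result tables under results/).

suppressMessages(library(cgprofiler))

out <- "scratch/screen_sim"  # FASTQ bulk; small tables go to results/
dir.create(out, showWarnings = FALSE, recursive = TRUE)

n <- 60
reference <- generate_reference(n, seed = 101)

# planted effects: strains 5/9 enrich (importer deletions), 12 depletes
# (exporter deletion); compound B shares them at slightly different sizes
delta_a <- rep(0, n); delta_a[c(5, 9, 12)] <- c(3, 1.5, -3)
delta_b <- rep(0, n); delta_b[c(5, 9, 12)] <- c(2.5, 1.8, -2.6)

design <- sim_design(n_barcodes = n, read_depth = 50000, error_rate = 0.005,
                     n_replicates = 4, seed = 102)
sim_a <- simulate_screen(design, delta_a, file.path(out, "azoleA"),
                         reference = reference, compound = "azoleA")
design_b <- sim_design(n_barcodes = n, read_depth = 50000, error_rate = 0.005,
                       n_replicates = 4, seed = 103)
sim_b <- simulate_screen(design_b, delta_b, file.path(out, "azoleB"),
                         reference = reference, compound = "azoleB")

cat(sprintf("simulated %d-strain pool: 2 compounds x 4+4 samples at depth %d\n",
            n, design$read_depth))
cat(sprintf("planted effects (azoleA): %s\n",
            paste(sprintf("%s=%+.1f", reference$records$strain_id[c(5, 9, 12)],
                          delta_a[c(5, 9, 12)]), collapse = ", ")))
cat("FASTQ and truth tables under", out, "\n")
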