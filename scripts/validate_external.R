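#!/usr/bin/env Rscript
# Optional validation against an external combinatorial-screen dataset.
#
# Reported best-run enrichment values for published SpCas9/KKH-SaCas9 screens
# depend on their supplementary per-variant E-score tables, which are not
# shipped here. Given such a table (variant_name,escore), the matching design
# CSV, and the reported enrichment, this script re-runs the pipeline at 20%
# training input over 3 seeded replicates and checks agreement within +/-15%.
#
# Usage:
#   Rscript scripts/validate_external.R --fitness <escore.csv> \
#     --design <design.csv> --reference <enrichment> \
#     [--floor -2] [--fraction 0.2] [--replicates 3] [--seed 1]

suppressPackageStartupMessages(library(combiscreen))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(
  floor = -2, fraction = 0.2, replicates = 3L, seed = 1L,
  fitness = NULL, design = NULL, reference = NULL
)
i <- 1
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  if (!key %in% names(opt)) stop("unknown argument: ", args[i])
  opt[[key]] <- args[i + 1]
  i <- i + 2
}
if (is.null(opt$fitness) || is.null(opt$design) || is.null(opt$reference)) {
  stop("--fitness, --design and --reference are required")
}

fitness <- read_fitness(opt$fitness, escore_floor = as.numeric(opt$floor))
design <- read_design(opt$design)
v <- validate_external(
  fitness, design,
  reference_enrichment = as.numeric(opt$reference),
  fraction = as.numeric(opt$fraction),
  replicates = as.integer(opt$replicates),
  seed = as.integer(opt$seed)
)
cat(sprintf(
  "best-run enrichment %.3f vs reported %.3f (relative error %.1f%%): %s\n",
  v$best_enrichment, v$reference_enrichment, 100 * v$relative_error,
  if (v$within_tolerance) "WITHIN tolerance" else "OUTSIDE tolerance"
))
if (!v$within_tolerance) quit(status = 1)
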