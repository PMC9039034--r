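#' Check reproduction of a reported best-run enrichment on an external dataset
#'
#' Dataset-specific performance numbers from published combinatorial screens
#' (e.g. the prior SpCas9 CombiSEAL datasets) require the corresponding
#' supplementary fitness tables, which are not distributed with this package.
#' Given such a table and its library design, this helper re-runs the MLDE
#' pipeline at a stated training fraction over seeded replicates and checks
#' whether the best-run test-set enrichment falls within a relative tolerance
#' of the reported value.
#'
#' @param fitness A `fitness_dataset` (e.g. from [read_fitness()]).
#' @param design The matching [library_design()] (e.g. from [read_design()]).
#' @param reference_enrichment The reported best-run enrichment to reproduce.
#' @param fraction Training fraction (default 0.2).
#' @param replicates Seeded replicates (default 3).
#' @param spec Base [ensemble_spec()].
#' @param seed Global seed.
#' @param tolerance Relative tolerance (default 0.15, i.e. +/-15%).
#' @param ... Further arguments passed to [run_grid()].
#' @return List with `best_enrichment`, `reference_enrichment`,
#'   `relative_error`, `within_tolerance`, and the full `reports` table.
#' @export
validate_external <- function(fitness, design, reference_enrichment,
                              fraction = 0.2, replicates = 3,
                              spec = ensemble_spec(), seed = 1L,
                              tolerance = 0.15, ...) {
  stopifnot(is.finite(reference_enrichment), reference_enrichment > 0)
  reports <- run_grid(fitness, design,
    fractions = fraction,
    replicates = replicates, spec = spec, seed = seed, ...
  )
  best <- max(reports$enrichment)
  rel <- abs(best - reference_enrichment) / reference_enrichment
  list(
    best_enrichment = best,
    reference_enrichment = reference_enrichment,
    relative_error = rel,
    within_tolerance = rel <= tolerance,
    reports = reports
  )
}
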