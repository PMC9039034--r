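#' Run a replicate grid of MLDE experiments
#'
#' Orchestrates the full workflow -- withhold test set, draw a training
#' subset, encode, train the ensemble, predict the whole library, evaluate
#' on the withheld test set -- over a grid of training fractions, replicates,
#' sampling schemes, and encoders, reproducing the replicate-grid experiments
#' used to benchmark MLDE on combinatorial Cas9 screens (e.g. training
#' fractions 5/10/20/50/70% with 3 replicates each).
#'
#' Seeding is hierarchical: each grid cell receives `seed + cell_counter`
#' (cells enumerated in grid order), so any cell can be reproduced
#' independently; re-running the same configuration reproduces every report.
#'
#' @param fitness A `fitness_dataset` covering the library (missing
#'   measurements allowed).
#' @param design The [library_design()].
#' @param fractions Training sizes as fractions of the measured data (or
#'   explicit integers > 1).
#' @param replicates Replicates per size (default 3).
#' @param schemes Sampling schemes, subset of `c("random", "diverse")`.
#' @param encoders Encoder ids (see [list_encoders()]).
#' @param spec Base [ensemble_spec()]; its seed is replaced per cell.
#' @param test_fraction Fraction of the library withheld a priori as the
#'   test set (default 0.2); the same withheld set is used for every cell.
#' @param p,q Diversity constraints for the `"diverse"` scheme.
#' @param wt_threshold_frac,top_frac Evaluation options (see
#'   [evaluate_predictions()]).
#' @param eval_universe `"test"` (default) scores the withheld test set;
#'   `"full"` scores every measured variant in the library.
#' @param seed Global integer seed.
#' @param out_dir Optional directory; when given, per-cell prediction tables
#'   and a YAML run manifest are written there.
#' @return Tibble of metrics reports, one row per grid cell, with cell
#'   metadata columns (`fraction`, `train_size`, `replicate`, `scheme`,
#'   `encoder`, `parameter_set`, `cell_seed`).
#' @export
run_grid <- function(fitness, design, fractions = c(0.05, 0.1, 0.2, 0.5, 0.7),
                     replicates = 3L, schemes = "random", encoders = "georgiev",
                     spec = ensemble_spec(), test_fraction = 0.2,
                     p = 0L, q = 2L, wt_threshold_frac = 0.7, top_frac = 0.05,
                     eval_universe = c("test", "full"), seed = 1L,
                     out_dir = NULL) {
  eval_universe <- match.arg(eval_universe)
  stopifnot(length(fractions) >= 1, replicates >= 1)
  if (!all(schemes %in% c("random", "diverse"))) stop("unknown sampling scheme")
  split <- withhold_test_set(fitness, test_fraction = test_fraction, seed = seed)
  lib <- enumerate_library(design)
  enc_cache <- lapply(
    setNames(encoders, encoders),
    function(id) get_encoder(id)(lib, design)
  )
  grid <- tidyr::expand_grid(
    encoder = encoders, scheme = schemes,
    fraction = fractions, replicate = seq_len(replicates)
  )
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # fractions are of the empirical (measured) data of the whole dataset, as
  # screen benchmarks quote them; explicit integer sizes pass through
  n_meas <- sum(!is.na(fitness$fitness_scaled))
  reports <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell_seed <- seed + i
    size_i <- if (grid$fraction[i] < 1) round(grid$fraction[i] * n_meas) else grid$fraction[i]
    train <- if (grid$scheme[i] == "random") {
      sample_random(split$train_pool, size_i, seed = cell_seed)
    } else {
      sample_diverse(split$train_pool, size_i, design,
        p = p, q = q, seed = cell_seed
      )
    }
    X_all <- enc_cache[[grid$encoder[i]]]
    rows <- match(train$variant_name, rownames(X_all))
    cell_spec <- spec
    cell_spec$seed <- cell_seed
    ens <- train_ensemble(
      X_all[rows, , drop = FALSE],
      train$fitness_scaled, cell_spec
    )
    pred <- predict_library(ens, X_all, training_names = train$variant_name)
    truth <- if (eval_universe == "test") split$test_set else fitness
    rep_i <- evaluate_predictions(pred, truth,
      wt_threshold_frac = wt_threshold_frac,
      top_frac = top_frac, wt = wt_fitness(fitness),
      screened = nrow(train)
    )
    meta <- tibble::tibble(
      encoder = grid$encoder[i], scheme = grid$scheme[i],
      fraction = grid$fraction[i], train_size = nrow(train),
      replicate = grid$replicate[i],
      parameter_set = spec$parameter_set, cell_seed = cell_seed
    )
    reports[[i]] <- dplyr::bind_cols(meta, rep_i)
    if (!is.null(out_dir)) {
      tag <- sprintf(
        "%s_%s_f%s_r%d", grid$encoder[i], grid$scheme[i],
        gsub("\\.", "p", format(grid$fraction[i])), grid$replicate[i]
      )
      utils::write.csv(pred, file.path(out_dir, paste0("pred_", tag, ".csv")),
        row.names = FALSE, quote = FALSE
      )
    }
  }
  out <- dplyr::bind_rows(reports)
  if (!is.null(out_dir)) {
    manifest <- list(
      package_version = as.character(utils::packageVersion("combiscreen")),
      seed = seed, test_fraction = test_fraction,
      fractions = fractions, replicates = replicates, schemes = schemes,
      encoders = encoders, eval_universe = eval_universe,
      wt_threshold_frac = wt_threshold_frac, top_frac = top_frac,
      parameter_set = spec$parameter_set,
      hyperopt_rounds = spec$hyperopt_rounds, cv_folds = spec$cv_folds,
      top_k_average = spec$top_k_average,
      n_library = nrow(lib), design_name = design$name
    )
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    utils::write.csv(out, file.path(out_dir, "metrics.csv"),
      row.names = FALSE, quote = FALSE
    )
  }
  out
}

#' Aggregate a grid of metric reports
#'
#' Per-cell (encoder x scheme x fraction) mean and SD of each metric across
#' replicates, with the best run flagged by NDCG then enrichment.
#'
#' @param reports Tibble from [run_grid()] (one row per run).
#' @return List with `summary` (per-cell means/SDs) and `best_run` (the
#'   single best row of `reports`).
#' @export
report_summary <- function(reports) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1)
  metric_cols <- intersect(
    c(
      "precision", "specificity", "sensitivity", "enrichment", "ndcg",
      "capture_rate_percent", "resource_efficiency"
    ),
    names(reports)
  )
  group_cols <- intersect(c("encoder", "scheme", "fraction", "parameter_set"), names(reports))
  summary <- reports |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      dplyr::across(
        dplyr::all_of(metric_cols),
        list(mean = ~ mean(.x, na.rm = TRUE), sd = ~ sd(.x, na.rm = TRUE))
      ),
      .groups = "drop"
    )
  best <- reports[order(-reports$ndcg, -reports$enrichment), ][1, , drop = FALSE]
  list(summary = summary, best_run = best)
}
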