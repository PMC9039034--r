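#' Specify a fitness-regression ensemble
#'
#' Two rosters are provided, mirroring common MLDE practice. Parameter set
#' `"p2"` (the default, and the better performer on combinatorial Cas9
#' screens) uses four less complex model families -- ridge-penalized Tweedie
#' regression, random forest, linear-kernel support-vector regression, and
#' elastic net -- each with 50 rounds of randomized hyperparameter
#' optimization. Parameter set `"p1"` is an optional roster of small
#' feed-forward neural networks (no-hidden-layer and one-hidden-layer),
#' each with 20 rounds. Candidates are scored by k-fold cross-validated mean
#' squared error and the ensemble prediction is the unweighted mean of the
#' `top_k_average` best candidates refit on the full training data.
#'
#' @param parameter_set `"p2"` (default) or `"p1"`.
#' @param model_families Override the roster (character vector of family ids
#'   among `"tweedie"`, `"rf"`, `"svr"`, `"enet"`, `"nn_nohidden"`,
#'   `"nn_onehidden"`).
#' @param hyperopt_rounds Random hyperparameter draws per family (default 50
#'   for p2, 20 for p1).
#' @param cv_folds Cross-validation folds (default 5).
#' @param top_k_average Number of best candidates averaged (default 3).
#' @param seed Integer seed controlling hyperparameter draws, CV folds, and
#'   stochastic fits; identical specs give identical ensembles.
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(parameter_set = c("p2", "p1"), model_families = NULL,
                          hyperopt_rounds = NULL, cv_folds = 5L,
                          top_k_average = 3L, seed = 1L) {
  parameter_set <- match.arg(parameter_set)
  if (is.null(model_families)) {
    model_families <- switch(parameter_set,
      p2 = c("tweedie", "rf", "svr", "enet"),
      p1 = c("nn_nohidden", "nn_onehidden")
    )
  }
  if (is.null(hyperopt_rounds)) {
    hyperopt_rounds <- switch(parameter_set, p2 = 50L, p1 = 20L)
  }
  stopifnot(
    hyperopt_rounds >= 1, cv_folds >= 2,
    top_k_average >= 1,
    top_k_average <= hyperopt_rounds * length(model_families)
  )
  structure(
    list(
      parameter_set = parameter_set, model_families = model_families,
      hyperopt_rounds = as.integer(hyperopt_rounds),
      cv_folds = as.integer(cv_folds),
      top_k_average = as.integer(top_k_average), seed = as.integer(seed)
    ),
    class = "ensemble_spec"
  )
}

log_unif <- function(lo, hi) exp(runif(1, log(lo), log(hi)))

draw_hyper <- function(family) {
  switch(family,
    tweedie = list(
      power = sample(c(0, 1, 1.5, 2), 1),
      alpha = log_unif(1e-4, 10)
    ),
    rf = list(
      num_trees = sample(50:500, 1),
      max_depth = sample(0:20, 1), # 0 = unlimited; depth 1 not admitted
      min_node = sample(1:10, 1)
    ),
    svr = list(
      cost = log_unif(1e-3, 1),
      epsilon = log_unif(1e-4, 1)
    ),
    enet = list(
      lambda = log_unif(1e-5, 1),
      l1_ratio = runif(1)
    ),
    nn_nohidden = list(decay = log_unif(1e-5, 1)),
    nn_onehidden = list(
      size = sample(2:16, 1),
      decay = log_unif(1e-4, 1),
      maxit = sample(100:400, 1)
    ),
    stop("unknown model family: ", family)
  )
}

fit_family <- function(family, hyper, X, y, fit_seed) {
  force(family)
  if (family %in% c("tweedie", "enet")) {
    fam <- if (family == "enet" || hyper$power == 0) {
      "gaussian"
    } else {
      statmod::tweedie(var.power = hyper$power, link.power = 0)
    }
    lam <- if (family == "enet") hyper$lambda else hyper$alpha
    alp <- if (family == "enet") hyper$l1_ratio else 0
    # glmnet needs >= 2 columns; pad degenerate single-feature matrices
    pad <- ncol(X) < 2
    if (pad) X <- cbind(X, `..pad..` = 0)
    fit <- suppressWarnings(glmnet::glmnet(X, y,
      family = fam, alpha = alp,
      lambda = lam, standardize = FALSE
    ))
    return(function(Xn) {
      if (pad) Xn <- cbind(Xn, `..pad..` = 0)
      as.numeric(predict(fit, Xn, s = lam, type = "response"))
    })
  }
  if (family == "rf") {
    fit <- ranger::ranger(
      y = y, x = X, num.trees = hyper$num_trees,
      max.depth = if (hyper$max_depth == 0) NULL else max(hyper$max_depth, 2L),
      min.node.size = hyper$min_node, seed = fit_seed, num.threads = 1
    )
    return(function(Xn) predict(fit, data = Xn, num.threads = 1)$predictions)
  }
  if (family == "svr") {
    fit <- e1071::svm(X, y,
      type = "eps-regression", kernel = "linear",
      cost = hyper$cost, epsilon = hyper$epsilon, scale = FALSE,
      tolerance = 0.01, fitted = FALSE
    )
    return(function(Xn) as.numeric(predict(fit, Xn)))
  }
  if (family %in% c("nn_nohidden", "nn_onehidden")) {
    if (!requireNamespace("nnet", quietly = TRUE)) {
      stop("parameter set p1 requires the nnet package")
    }
    set.seed(fit_seed)
    fit <- if (family == "nn_nohidden") {
      nnet::nnet(X, y,
        size = 0, skip = TRUE, linout = TRUE, decay = hyper$decay,
        maxit = 500, trace = FALSE
      )
    } else {
      nnet::nnet(X, y,
        size = hyper$size, linout = TRUE, decay = hyper$decay,
        maxit = hyper$maxit, trace = FALSE, MaxNWts = 10000
      )
    }
    return(function(Xn) as.numeric(predict(fit, Xn)))
  }
  stop("unknown model family: ", family)
}

#' Train a fitness-regression ensemble
#'
#' For each family in the spec, `hyperopt_rounds` random hyperparameter draws
#' are scored by `cv_folds`-fold cross-validated mean squared error on the
#' training data. The `top_k_average` candidates with the lowest CV error are
#' refit on all training data; the ensemble prediction is their unweighted
#' mean. Fully seed-deterministic: draws, fold assignment, and stochastic
#' fits all derive from `spec$seed`. Candidates whose fit fails (e.g. a
#' Tweedie power incompatible with zero targets) receive infinite CV error
#' and are never selected.
#'
#' @param X Numeric feature matrix for the training variants (rows named by
#'   variant).
#' @param y Scaled fitness targets in \[0, 1\], no missing values.
#' @param spec An [ensemble_spec()].
#' @return A `combiscreen_ensemble`: list with `candidates` (tibble of all
#'   scored draws), `members` (refit top candidates), `spec`,
#'   `feature_names`, and for degenerate targets a `constant` fallback.
#' @export
train_ensemble <- function(X, y, spec = ensemble_spec()) {
  stopifnot(inherits(spec, "ensemble_spec"), is.matrix(X), nrow(X) == length(y))
  if (anyNA(y)) stop("training targets contain missing values")
  if (length(y) < spec$cv_folds) stop("fewer training samples than CV folds")
  if (var(y) == 0) {
    warning("degenerate targets (zero variance); returning constant predictor")
    return(structure(
      list(
        constant = y[1], spec = spec, feature_names = colnames(X),
        candidates = tibble::tibble(), members = list()
      ),
      class = "combiscreen_ensemble"
    ))
  }
  n <- length(y)
  out <- withr::with_seed(spec$seed, {
    folds <- sample(rep_len(seq_len(spec$cv_folds), n))
    cand <- tidyr::expand_grid(
      family = spec$model_families,
      round = seq_len(spec$hyperopt_rounds)
    )
    cand$hyper <- lapply(seq_len(nrow(cand)), function(i) draw_hyper(cand$family[i]))
    cand$fit_seed <- sample.int(.Machine$integer.max, nrow(cand))
    cand$cv_mse <- vapply(seq_len(nrow(cand)), function(i) {
      pred <- rep(NA_real_, n)
      for (k in seq_len(spec$cv_folds)) {
        hold <- folds == k
        p <- tryCatch(
          {
            f <- fit_family(
              cand$family[i], cand$hyper[[i]],
              X[!hold, , drop = FALSE], y[!hold], cand$fit_seed[i]
            )
            f(X[hold, , drop = FALSE])
          },
          error = function(e) NULL
        )
        if (is.null(p) || anyNA(p)) {
          return(Inf)
        }
        pred[hold] <- p
      }
      mean((pred - y)^2)
    }, numeric(1))
    ord <- order(cand$cv_mse, seq_len(nrow(cand)))
    top <- ord[seq_len(spec$top_k_average)]
    if (any(!is.finite(cand$cv_mse[top]))) {
      stop("fewer than top_k_average candidates fit successfully")
    }
    members <- lapply(top, function(i) {
      fit_family(cand$family[i], cand$hyper[[i]], X, y, cand$fit_seed[i])
    })
    list(candidates = cand, top = top, members = members)
  })
  structure(
    list(
      candidates = out$candidates, top = out$top, members = out$members,
      spec = spec, feature_names = colnames(X), constant = NULL
    ),
    class = "combiscreen_ensemble"
  )
}

#' @export
print.combiscreen_ensemble <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat("<combiscreen_ensemble> constant predictor (degenerate targets)\n")
    return(invisible(x))
  }
  best <- x$candidates[x$top, ]
  cat(
    "<combiscreen_ensemble> ", x$spec$parameter_set, ": ",
    nrow(x$candidates), " candidates, averaging top ", length(x$members),
    " (", paste(best$family, collapse = ", "), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Ensemble predictions for a feature matrix
#'
#' @param ensemble A trained [train_ensemble()] object.
#' @param X Feature matrix with the training feature layout.
#' @return Numeric vector: the unweighted mean of the member predictions.
#' @export
predict_ensemble <- function(ensemble, X) {
  stopifnot(inherits(ensemble, "combiscreen_ensemble"), is.matrix(X))
  if (!identical(colnames(X), ensemble$feature_names)) {
    stop("feature layout does not match the training matrix")
  }
  if (!is.null(ensemble$constant)) {
    return(rep(ensemble$constant, nrow(X)))
  }
  preds <- vapply(ensemble$members, function(f) f(X), numeric(nrow(X)))
  if (nrow(X) == 1) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

#' Predict scaled fitness for the whole library
#'
#' Applies a trained ensemble to the full in-silico library and ranks every
#' variant. Ranks are assigned by descending predicted fitness; ties are
#' broken by ascending canonical variant index (the row order of `X_all`),
#' so ranks are always a permutation of `1..n`.
#'
#' @param ensemble A trained [train_ensemble()] object.
#' @param X_all Feature matrix for the full library, rows named by variant
#'   and in canonical library order.
#' @param training_names Variant names used in training (flagged in the
#'   output).
#' @return A prediction tibble: `variant_name`, `pred_fitness`, `pred_rank`
#'   (1 = highest), `in_training`.
#' @export
predict_library <- function(ensemble, X_all, training_names = character(0)) {
  pred <- predict_ensemble(ensemble, X_all)
  n <- length(pred)
  ord <- order(-pred, seq_len(n))
  rk <- integer(n)
  rk[ord] <- seq_len(n)
  tibble::tibble(
    variant_name = rownames(X_all),
    pred_fitness = pred,
    pred_rank = rk,
    in_training = rownames(X_all) %in% training_names
  )
}
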