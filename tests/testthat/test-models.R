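# shared small training problem: additive landscape on a 72-variant design
additive_problem <- function(noise_sd = 0, seed = 2) {
  d <- library_design(data.frame(
    position = c(10L, 20L, 30L, 40L, 50L),
    wildtype = c("N", "A", "K", "R", "E"),
    alternatives = c("R;Q", "Q;S", "H", "K", "D")
  ))
  addl <- dplyr::bind_rows(lapply(seq_len(5), function(j) {
    alts <- d$positions$alternatives[[j]]
    tibble::tibble(
      position = d$positions$position[j], residue = alts,
      effect = withr::with_seed(seed * 10 + j, runif(length(alts), -1, 0.3))
    )
  }))
  truth <- generate_landscape(d, baseline = 0.5, additive = addl,
    noise_sd = noise_sd, seed = seed)
  lib <- enumerate_library(d)
  y <- truth$true_fitness
  y <- (y - min(y)) / (max(y) - min(y))
  list(design = d, lib = lib, y = y)
}

test_that("a noiseless additive landscape is learned almost exactly", {
  pr <- additive_problem(noise_sd = 0)
  X <- encode_onehot(pr$lib, pr$design)
  idx <- withr::with_seed(4, sample(nrow(X), round(0.5 * nrow(X))))
  # oracle: additive landscapes are exactly linear in one-hot features
  fit_ls <- stats::lm.fit(cbind(1, X[idx, ]), pr$y[idx])
  beta <- ifelse(is.na(fit_ls$coefficients), 0, fit_ls$coefficients)
  oracle_pred <- as.numeric(cbind(1, X[-idx, ]) %*% beta)
  expect_lt(max(abs(oracle_pred - pr$y[-idx])), 1e-8)
  spec <- ensemble_spec("p2",
    model_families = c("enet", "svr"), hyperopt_rounds = 15,
    cv_folds = 5, top_k_average = 1, seed = 6
  )
  ens <- train_ensemble(X[idx, ], pr$y[idx], spec)
  pred <- predict_ensemble(ens, X[-idx, ])
  r2 <- 1 - sum((pred - pr$y[-idx])^2) / sum((pr$y[-idx] - mean(pr$y[-idx]))^2)
  expect_gte(r2, 0.99)
})

test_that("training and prediction are seed-deterministic", {
  pr <- additive_problem(noise_sd = 0.1)
  X <- encode_georgiev(pr$lib, pr$design)
  idx <- 1:36
  spec <- ensemble_spec("p2", hyperopt_rounds = 4, seed = 3)
  e1 <- train_ensemble(X[idx, ], pr$y[idx], spec)
  e2 <- train_ensemble(X[idx, ], pr$y[idx], spec)
  expect_identical(e1$candidates$cv_mse, e2$candidates$cv_mse)
  expect_identical(e1$top, e2$top)
  p1 <- predict_library(e1, X, rownames(X)[idx])
  p2 <- predict_library(e2, X, rownames(X)[idx])
  expect_identical(p1, p2)
})

test_that("the p2 roster scores families x rounds candidates", {
  pr <- additive_problem(noise_sd = 0.05)
  X <- encode_georgiev(pr$lib, pr$design)
  spec <- ensemble_spec("p2", hyperopt_rounds = 2, seed = 1)
  expect_equal(spec$model_families, c("tweedie", "rf", "svr", "enet"))
  # at the full defaults the roster yields 4 x 50 = 200 candidates
  expect_equal(
    ensemble_spec("p2")$hyperopt_rounds * length(ensemble_spec("p2")$model_families),
    200L
  )
  ens <- train_ensemble(X[1:40, ], pr$y[1:40], spec)
  expect_equal(nrow(ens$candidates), 2L * 4L)
  expect_true(all(ens$candidates$family %in% spec$model_families))
  expect_length(ens$members, spec$top_k_average)
})

test_that("ensemble predictions average the top-k member predictions exactly", {
  pr <- additive_problem(noise_sd = 0.05)
  X <- encode_georgiev(pr$lib, pr$design)
  spec <- ensemble_spec("p2", hyperopt_rounds = 3, top_k_average = 3, seed = 9)
  ens <- train_ensemble(X[1:40, ], pr$y[1:40], spec)
  member_preds <- vapply(ens$members, function(f) f(X), numeric(nrow(X)))
  expect_equal(predict_ensemble(ens, X), rowMeans(member_preds))
})

test_that("degenerate targets give a constant predictor with a warning", {
  pr <- additive_problem()
  X <- encode_georgiev(pr$lib, pr$design)
  expect_warning(
    ens <- train_ensemble(X[1:10, ], rep(0.4, 10), ensemble_spec("p2", hyperopt_rounds = 2)),
    "degenerate"
  )
  pred <- predict_library(ens, X)
  expect_true(all(pred$pred_fitness == 0.4))
  # all tied: ranks fall back to the canonical tie-break, a permutation of 1..n
  expect_equal(sort(pred$pred_rank), seq_len(nrow(X)))
  expect_equal(pred$pred_rank, seq_len(nrow(X)))
})

test_that("library predictions rank every variant with a deterministic tie-break", {
  pr <- additive_problem(noise_sd = 0.02)
  X <- encode_georgiev(pr$lib, pr$design)
  spec <- ensemble_spec("p2", model_families = "enet", hyperopt_rounds = 3, seed = 2)
  ens <- train_ensemble(X[1:36, ], pr$y[1:36], spec)
  pred <- predict_library(ens, X, rownames(X)[1:36])
  expect_equal(nrow(pred), nrow(X))
  expect_setequal(pred$pred_rank, seq_len(nrow(X)))
  expect_equal(sum(pred$in_training), 36)
  # rank order consistent with descending predicted fitness
  expect_true(all(diff(pred$pred_fitness[order(pred$pred_rank)]) <= 0))
  expect_error(predict_ensemble(ens, X[, 1:10]), "feature layout")
})

test_that("a perfect-oracle ensemble reproduces the true fitness order", {
  pr <- additive_problem(noise_sd = 0)
  X <- encode_onehot(pr$lib, pr$design)
  ens <- structure(
    list(
      constant = NULL, spec = ensemble_spec("p2"), feature_names = colnames(X),
      members = list(local({
        y <- pr$y
        lib <- pr$lib
        function(Xn) y[match(rownames(Xn), lib$variant_name)]
      }))
    ),
    class = "combiscreen_ensemble"
  )
  pred <- predict_library(ens, X)
  expect_equal(pred$pred_fitness, pr$y)
  # predicted rank order equals the true fitness order (ties broken canonically)
  expect_equal(order(pred$pred_rank), order(-pr$y, seq_along(pr$y)))
})

test_that("pure-noise targets give null-level test enrichment on average", {
  b <- small_bundle(seed = 31)
  lib <- enumerate_library(b$design)
  X <- encode_georgiev(lib, b$design)
  enr <- numeric(20)
  for (s in 1:20) {
    perm <- withr::with_seed(500 + s, sample(b$fitness$fitness_scaled))
    f_perm <- b$fitness
    f_perm$fitness_scaled <- perm
    split <- withhold_test_set(f_perm, test_fraction = 0.3, seed = 600 + s)
    train <- sample_random(split$train_pool, 25, seed = 700 + s)
    spec <- ensemble_spec("p2", model_families = "enet", hyperopt_rounds = 3, seed = 800 + s)
    ens <- train_ensemble(
      X[match(train$variant_name, rownames(X)), ],
      train$fitness_scaled, spec
    )
    pred <- predict_library(ens, X, train$variant_name)
    enr[s] <- enrichment_score(pred, split$test_set)$enrichment
  }
  # mean enrichment of an uninformative model is 1; allow 3 standard errors
  se <- sd(enr) / sqrt(length(enr))
  expect_lt(abs(mean(enr) - 1), 3 * se + 1e-9)
})
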