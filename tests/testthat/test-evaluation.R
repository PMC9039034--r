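test_that("confusion counts and derived rates match direct substitution", {
  # TP=3, FP=1, TN=5, FN=1 by construction around a threshold of 0.7
  truth <- c(0.9, 0.8, 0.75, 0.72, 0.3, 0.2, 0.1, 0.15, 0.25, 0.05)
  pred <- c(0.95, 0.85, 0.71, 0.50, 0.90, 0.10, 0.20, 0.30, 0.40, 0.05)
  m <- classification_metrics(as_pred(pred), as_truth(truth), wt = 1)
  expect_equal(c(m$TP, m$FP, m$TN, m$FN), c(3L, 1L, 5L, 1L))
  expect_equal(m$precision, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$sensitivity, 0.75)
  # predictions identical to truth: all three metrics are 1
  m2 <- classification_metrics(as_pred(truth), as_truth(truth), wt = 1)
  expect_equal(c(m2$precision, m2$specificity, m2$sensitivity), c(1, 1, 1))
  expect_equal(m2$FP + m2$FN, 0L)
  # all predicted negative with true positives present: sensitivity 0,
  # precision undefined (never reported as 0)
  m3 <- classification_metrics(as_pred(rep(0, 10)), as_truth(truth), wt = 1)
  expect_equal(m3$sensitivity, 0)
  expect_true(is.na(m3$precision))
  expect_equal(m3$TP + m3$TN + m3$FP + m3$FN, 10L)
})

test_that("classification counts always partition the evaluation set", {
  withr::with_seed(11, for (r in 1:20) {
    n <- sample(5:40, 1)
    truth <- runif(n)
    pred <- runif(n)
    m <- classification_metrics(as_pred(pred), as_truth(truth), wt = runif(1, 0.5, 1))
    expect_equal(m$TP + m$TN + m$FP + m$FN, n)
    o <- oracle_confusion(truth, pred, m$threshold)
    expect_equal(c(m$TP, m$TN, m$FP, m$FN), unname(o))
  })
})

test_that("enrichment matches its brute-force oracle and attains its bounds", {
  # perfect ranking on N=260: k=13, enrichment = 400*13/260 = 20
  withr::with_seed(2, truth <- runif(260))
  e <- enrichment_score(as_pred(truth), as_truth(truth))
  expect_equal(e$top_set_size, 13L)
  expect_equal(e$enrichment, 20)
  expect_equal(e$enrichment, 400 * e$overlap / e$n_eval)
  # zero overlap: reverse ranking of distinct values
  e0 <- enrichment_score(as_pred(-truth), as_truth(truth))
  expect_equal(e0$enrichment, 0)
  # random instances agree with the naive set-intersection oracle
  withr::with_seed(3, for (r in 1:20) {
    n <- sample(40:200, 1)
    tr <- runif(n)
    pr <- runif(n)
    e <- enrichment_score(as_pred(pr), as_truth(tr))$enrichment
    expect_equal(e, oracle_enrichment(tr, pr))
    expect_gte(e, 0)
    k <- ceiling(0.05 * n)
    expect_lte(e, 400 * k / n + 1e-9)
  })
})

test_that("NDCG matches hand computation and brute force over all permutations", {
  # truths (1.0, 0.5, 0.0), prediction swaps the top two
  truth <- c(1.0, 0.5, 0.0)
  pred_swap <- c(0.5, 1.0, 0.0)
  nd <- ndcg_score(as_pred(pred_swap), as_truth(truth))
  expect_equal(nd, (0.5 / 1 + 1.0 / log2(3)) / (1.0 / 1 + 0.5 / log2(3)))
  expect_equal(round(nd, 4), 0.8597)
  # identity ranking gives exactly 1
  expect_equal(ndcg_score(as_pred(truth), as_truth(truth)), 1)
  # exhaustive: all 720 orderings of 6 distinct truths; reversal minimizes
  truth6 <- c(0.9, 0.7, 0.5, 0.3, 0.2, 0.05)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), , drop = FALSE]
  vals <- apply(perms, 1, function(p) {
    pred <- numeric(6)
    pred[p] <- 6:1 # variant p[k] gets predicted rank k
    nd_pkg <- ndcg_score(as_pred(pred), as_truth(truth6))
    expect_equal(nd_pkg, oracle_ndcg(truth6, pred))
    nd_pkg
  })
  expect_equal(max(vals), 1)
  rev_pred <- numeric(6)
  rev_pred[6:1] <- 6:1
  expect_equal(min(vals), oracle_ndcg(truth6, rev(6:1)))
  expect_equal(which.min(vals), which(apply(perms, 1, function(p) all(p == 6:1))))
})

test_that("NDCG strictly increases when an adjacent misordered pair is corrected", {
  withr::with_seed(13, for (r in 1:20) {
    n <- sample(4:20, 1)
    truth <- runif(n)
    ord <- sample(n) # predicted order, position k = variant at rank k
    # find an adjacent pair that is misordered w.r.t. truth
    bad <- which(truth[ord[-n]] < truth[ord[-1]])
    if (!length(bad)) next
    j <- bad[1]
    pred <- numeric(n)
    pred[ord] <- n:1
    nd_before <- ndcg_score(as_pred(pred), as_truth(truth))
    ord2 <- ord
    ord2[c(j, j + 1)] <- ord2[c(j + 1, j)]
    pred2 <- numeric(n)
    pred2[ord2] <- n:1
    nd_after <- ndcg_score(as_pred(pred2), as_truth(truth))
    expect_gt(nd_after, nd_before)
  })
})

test_that("resource efficiency and capture rate reproduce screening arithmetic", {
  expect_equal(round(resource_efficiency(17, 130), 3), 0.131)
  expect_equal(round(resource_efficiency(33, 952), 3), 0.035)
  expect_equal(resource_efficiency(0, 57), 0)
  expect_error(resource_efficiency(5, 0))
  expect_equal(round(capture_rate(paste0("v", 1:65)[1:32], paste0("t", 1:65)), 1), 0)
  expect_equal(round(capture_rate(paste0("v", 1:32), paste0("v", 1:65)), 1), 49.2)
  expect_equal(round(capture_rate(paste0("v", 1:17), paste0("v", 1:33)), 1), 51.5)
  expect_equal(capture_rate(c("a", "b"), c("a", "b")), 100)
  expect_error(capture_rate("a", character(0)), "empty")
})

test_that("T7E1 efficiency follows the square-root band formula", {
  expect_equal(t7e1_efficiency(1, 0, 0), 0)
  expect_equal(t7e1_efficiency(0, 2, 3), 100)
  expect_equal(t7e1_efficiency(1, 1, 1), 100 * (1 - sqrt(1 / 3)))
  expect_equal(round(t7e1_efficiency(1, 1, 1), 1), 42.3)
  # scale invariance and range
  withr::with_seed(4, for (r in 1:10) {
    abc <- runif(3)
    expect_equal(t7e1_efficiency(abc[1], abc[2], abc[3]),
      t7e1_efficiency(10 * abc[1], 10 * abc[2], 10 * abc[3]))
    v <- t7e1_efficiency(abc[1], abc[2], abc[3])
    expect_gte(v, 0)
    expect_lte(v, 100)
  })
  expect_error(t7e1_efficiency(0, 0, 0), "zero")
})

test_that("the combined metrics report is internally consistent", {
  withr::with_seed(21, {
    n <- 120
    truth <- tibble::tibble(
      variant_name = c("WT", paste0("v", 1:(n - 1))),
      fitness_scaled = c(0.8, runif(n - 1)),
      escore = rnorm(n)
    )
    pred <- tibble::tibble(
      variant_name = truth$variant_name,
      pred_fitness = truth$fitness_scaled + rnorm(n, 0, 0.2),
      in_training = FALSE
    )
  })
  rep <- evaluate_predictions(pred, truth, screened = 30)
  expect_equal(rep$TP + rep$TN + rep$FP + rep$FN, n)
  expect_equal(rep$top_set_size, ceiling(0.05 * n))
  expect_gte(rep$ndcg, 0)
  expect_lte(rep$ndcg, 1)
  expect_equal(
    rep$capture_rate_percent / 100 * rep$top_set_size / 30,
    rep$resource_efficiency
  )
})
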