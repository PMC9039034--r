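#' Classification metrics against a wild-type activity threshold
#'
#' Variants with true scaled fitness of at least `wt_threshold_frac` times
#' the wild-type scaled fitness are labeled positive; predictions are
#' labeled the same way on the predicted fitness. From the confusion counts,
#' \deqn{\mathrm{specificity} = TN/(TN+FP),\quad
#'       \mathrm{sensitivity} = TP/(TP+FN),\quad
#'       \mathrm{precision} = TP/(TP+FP).}
#' Ratios with zero denominators are reported as `NA`, never as 0.
#'
#' @param predictions Prediction tibble (from [predict_library()]), or any
#'   data frame with `variant_name` and `pred_fitness`.
#' @param truth A `fitness_dataset` (or data frame with `variant_name`,
#'   `fitness_scaled`); only variants present in both and with non-missing
#'   truth are evaluated.
#' @param wt_threshold_frac Fraction of wild-type activity defining a
#'   positive (default 0.7).
#' @param wt Wild-type scaled fitness; defaults to [wt_fitness()] of `truth`.
#' @return List with `TP`, `TN`, `FP`, `FN`, `precision`, `specificity`,
#'   `sensitivity`, `threshold`, `n_eval`.
#' @export
classification_metrics <- function(predictions, truth, wt_threshold_frac = 0.7,
                                   wt = NULL) {
  ev <- eval_frame(predictions, truth)
  wt <- wt %||% wt_fitness(truth)
  if (is.null(wt) || is.na(wt)) stop("no wild-type fitness available in `truth`")
  thr <- wt_threshold_frac * wt
  tp <- sum(ev$truth >= thr & ev$pred >= thr)
  tn <- sum(ev$truth < thr & ev$pred < thr)
  fp <- sum(ev$truth < thr & ev$pred >= thr)
  fn <- sum(ev$truth >= thr & ev$pred < thr)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(
    TP = tp, TN = tn, FP = fp, FN = fn,
    precision = ratio(tp, tp + fp),
    specificity = ratio(tn, tn + fp),
    sensitivity = ratio(tp, tp + fn),
    threshold = thr, n_eval = nrow(ev)
  )
}

# align predictions and truth on variant_name, dropping missing truths
eval_frame <- function(predictions, truth) {
  stopifnot(is.data.frame(predictions), is.data.frame(truth))
  tr <- truth[!is.na(truth$fitness_scaled), c("variant_name", "fitness_scaled")]
  if ("escore" %in% names(truth)) tr$escore <- truth$escore[!is.na(truth$fitness_scaled)]
  m <- dplyr::inner_join(
    tibble::tibble(
      variant_name = predictions$variant_name,
      pred = predictions$pred_fitness,
      canon = seq_len(nrow(predictions))
    ),
    tr,
    by = "variant_name"
  )
  if (!nrow(m)) stop("no overlapping evaluated variants")
  dplyr::rename(m, truth = "fitness_scaled")
}

# index of the true top-k, ties at the boundary broken by descending raw
# E-score then ascending canonical index
true_top_idx <- function(ev, k) {
  es <- if ("escore" %in% names(ev)) ev$escore else rep(0, nrow(ev))
  es[is.na(es)] <- -Inf
  order(-ev$truth, -es, ev$canon)[seq_len(k)]
}

#' Top-k enrichment of a predicted ranking
#'
#' Fold-improvement over random selection in recovering the true top
#' `top_frac` variants within the predicted top set. With top-set size
#' \eqn{k = \lceil \mathrm{top\_frac} \cdot N \rceil} and overlap \eqn{I}
#' between predicted-top-k and true-top-k, enrichment is
#' \eqn{(I/k)/(k/N)}; at the default `top_frac = 0.05` this is the
#' \eqn{400 \cdot I_5 / N} form used for sort-seq MLDE benchmarks
#' (maximum \eqn{400\,k/N}, e.g. 20 on an evaluation set of 260).
#' Random rankings give enrichment 1 in expectation.
#'
#' @inheritParams classification_metrics
#' @param top_frac Top fraction defining "hits" (default 0.05).
#' @return List with `enrichment`, `overlap`, `top_set_size`, `n_eval`.
#' @export
enrichment_score <- function(predictions, truth, top_frac = 0.05) {
  ev <- eval_frame(predictions, truth)
  n <- nrow(ev)
  k <- ceiling(top_frac * n)
  if (k < 1) stop("empty top set: increase top_frac or the evaluation set")
  pred_top <- order(-ev$pred, ev$canon)[seq_len(k)]
  overlap <- length(intersect(pred_top, true_top_idx(ev, k)))
  # canonical 400*I5/N form at the standard top-5%; the ratio-of-proportions
  # generalization (identical when k = N/20 exactly) for other fractions
  enr <- if (identical(top_frac, 0.05)) {
    400 * overlap / n
  } else {
    (overlap / k) / (k / n)
  }
  list(enrichment = enr, overlap = overlap, top_set_size = k, n_eval = n)
}

#' Normalized discounted cumulative gain of a predicted ranking
#'
#' \deqn{\mathrm{NDCG} = \frac{\sum_k f_{(k)} / \log_2(k+1)}
#'                            {\sum_k f_{[k]} / \log_2(k+1)}}
#' where \eqn{f_{(k)}} is the true fitness of the variant at predicted rank
#' \eqn{k} and \eqn{f_{[k]}} the k-th largest true fitness (the ideal
#' ordering). Equals 1 exactly when the predicted ordering sorts variants by
#' non-increasing true fitness; misplacing low-fitness variants at top ranks
#' lowers it. Requires non-negative truths (scaled fitness).
#'
#' @inheritParams classification_metrics
#' @return NDCG in (0, 1].
#' @export
ndcg_score <- function(predictions, truth) {
  ev <- eval_frame(predictions, truth)
  if (any(ev$truth < 0)) stop("NDCG requires non-negative true fitness")
  disc <- 1 / log2(seq_len(nrow(ev)) + 1)
  dcg <- sum(ev$truth[order(-ev$pred, ev$canon)] * disc)
  idcg <- sum(sort(ev$truth, decreasing = TRUE) * disc)
  if (idcg == 0) stop("all true fitness values are zero; NDCG undefined")
  dcg / idcg
}

#' Resource efficiency of a screening campaign
#'
#' The number of true top-performing variants identified divided by the
#' number of variants experimentally screened, e.g. 17 hits from screening
#' 130 variants gives 0.131, versus 33/952 = 0.035 for exhaustively
#' screening a full library.
#'
#' @param hits Number of true top-performing variants identified.
#' @param screened Number of variants experimentally screened.
#' @return `hits / screened`.
#' @export
resource_efficiency <- function(hits, screened) {
  stopifnot(screened > 0, hits >= 0, hits <= screened)
  hits / screened
}

#' Capture rate of the true top set
#'
#' Percentage of the true top variants present in the predicted top set.
#'
#' @param predicted_top Character vector (or set) of predicted top variants.
#' @param true_top Non-empty character vector of true top variants.
#' @return Percentage in \[0, 100\].
#' @export
capture_rate <- function(predicted_top, true_top) {
  if (!length(true_top)) stop("true top set is empty")
  100 * length(intersect(predicted_top, true_top)) / length(true_top)
}

#' T7 endonuclease-I editing efficiency from band intensities
#'
#' Estimates percent indel-mediated editing from gel band intensities of a
#' T7E1 cleavage assay:
#' \deqn{100 \times \left(1 - \sqrt{1 - (b+c)/(a+b+c)}\right)}
#' where `a` is the integrated intensity of the uncleaved PCR product and
#' `b`, `c` the cleavage products.
#'
#' @param a Uncleaved-band intensity (>= 0).
#' @param b,c Cleavage-product intensities (>= 0).
#' @return Editing efficiency in percent, in \[0, 100\].
#' @examples
#' t7e1_efficiency(1, 1, 1) # ~42.3
#' @export
t7e1_efficiency <- function(a, b, c) {
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0))
  tot <- a + b + c
  if (any(tot <= 0)) stop("band intensities sum to zero")
  100 * (1 - sqrt(1 - (b + c) / tot))
}

#' Full metrics report for one evaluation
#'
#' Combines the classification metrics, enrichment, NDCG, and resource
#' accounting for one prediction run into a single report. The evaluation
#' universe defaults to the withheld test set (pass the test subset as
#' `truth`); passing the full dataset scores the entire library.
#'
#' @inheritParams classification_metrics
#' @inheritParams enrichment_score
#' @param screened Number of variants screened to train the model (for
#'   resource efficiency; default the number flagged `in_training`).
#' @return A one-row tibble (class `metrics_report`) with confusion counts,
#'   `precision`, `specificity`, `sensitivity`, `enrichment`, `ndcg`,
#'   `capture_rate_percent`, `resource_efficiency`, `n_eval`,
#'   `top_set_size`, `wt_threshold_frac`, `top_frac`.
#' @export
evaluate_predictions <- function(predictions, truth, wt_threshold_frac = 0.7,
                                 top_frac = 0.05, wt = NULL, screened = NULL) {
  cls <- classification_metrics(predictions, truth, wt_threshold_frac, wt)
  enr <- enrichment_score(predictions, truth, top_frac)
  nd <- ndcg_score(predictions, truth)
  ev <- eval_frame(predictions, truth)
  k <- enr$top_set_size
  pred_top <- ev$variant_name[order(-ev$pred, ev$canon)[seq_len(k)]]
  true_top <- ev$variant_name[true_top_idx(ev, k)]
  screened <- screened %||% sum(predictions$in_training %||% FALSE)
  tibble::tibble(
    TP = cls$TP, TN = cls$TN, FP = cls$FP, FN = cls$FN,
    precision = cls$precision, specificity = cls$specificity,
    sensitivity = cls$sensitivity,
    enrichment = enr$enrichment, ndcg = nd,
    capture_rate_percent = capture_rate(pred_top, true_top),
    resource_efficiency = if (screened > 0) {
      resource_efficiency(length(intersect(pred_top, true_top)), screened)
    } else {
      NA_real_
    },
    n_eval = cls$n_eval, top_set_size = k,
    wt_threshold_frac = wt_threshold_frac, top_frac = top_frac
  )
}
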