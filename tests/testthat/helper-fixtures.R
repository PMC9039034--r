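# Shared fixtures and independent brute-force reference implementations.
# The oracles deliberately use naive loops/set arithmetic so they share no
# code path with the package implementations they check.

tiny_design <- function() {
  library_design(
    data.frame(
      position = c(2L, 5L, 7L),
      wildtype = c("A", "C", "D"),
      alternatives = c("G", "H;K", ""),
      domain = c("WED", "PI", "PI")
    ),
    name = "tiny"
  )
}

# random small design: n_positions sites with 1-3 residue options each
random_design <- function(n_positions, seed, max_alts = 2) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_positions), function(i) {
      k <- sample(0:max_alts, 1)
      menu <- sample(c("A","C","D","E","F","G","H","I","K","L",
                      "M","N","P","Q","R","S","T","V","W","Y"), k + 1)
      data.frame(
        position = i * 3L, wildtype = menu[1],
        alternatives = paste(menu[-1], collapse = ";")
      )
    })
  })
  library_design(do.call(rbind, rows), name = paste0("rand", seed))
}

small_bundle <- function(seed = 7) {
  d <- library_design(
    data.frame(
      position = c(10L, 20L, 30L, 40L, 50L),
      wildtype = c("N", "A", "K", "R", "E"),
      alternatives = c("R;Q", "Q;S", "H", "K", "D"),
      domain = c("WED", "WED", "PI", "PI", "PI")
    ),
    name = "small72"
  )
  make_benchmark_bundle(design = d, total_reads_per_bin = 2e5, seed = seed)
}

# --- brute-force metric oracles -------------------------------------------

# confusion counts by explicit looping over variants
oracle_confusion <- function(truth, pred, thr) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(truth)) {
    tpos <- truth[i] >= thr
    ppos <- pred[i] >= thr
    if (tpos && ppos) tp <- tp + 1L
    if (!tpos && !ppos) tn <- tn + 1L
    if (!tpos && ppos) fp <- fp + 1L
    if (tpos && !ppos) fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# enrichment via explicit top-set construction
oracle_enrichment <- function(truth, pred, top_frac = 0.05) {
  n <- length(truth)
  k <- ceiling(top_frac * n)
  pred_top <- sort.int(pred, decreasing = TRUE, index.return = TRUE)$ix[1:k]
  true_top <- sort.int(truth, decreasing = TRUE, index.return = TRUE)$ix[1:k]
  i5 <- sum(pred_top %in% true_top)
  if (top_frac == 0.05) 400 * i5 / n else (i5 / k) / (k / n)
}

# NDCG by direct summation over predicted ranks
oracle_ndcg <- function(truth, pred) {
  ord <- order(pred, decreasing = TRUE)
  dcg <- 0
  for (k in seq_along(ord)) dcg <- dcg + truth[ord[k]] / log2(k + 1)
  ideal <- sort(truth, decreasing = TRUE)
  idcg <- 0
  for (k in seq_along(ideal)) idcg <- idcg + ideal[k] / log2(k + 1)
  dcg / idcg
}

# wrap plain vectors as prediction/truth frames for the package evaluators
as_pred <- function(pred, names = paste0("v", seq_along(pred))) {
  tibble::tibble(variant_name = names, pred_fitness = pred)
}

as_truth <- function(truth, names = paste0("v", seq_along(truth))) {
  tibble::tibble(variant_name = names, fitness_scaled = truth)
}
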