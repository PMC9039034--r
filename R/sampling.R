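#' Withhold an a-priori test set
#'
#' Uniformly at random withholds a test set from the full variant library of
#' a fitness dataset (measured or not), leaving the remainder as the training
#' pool. Mirrors the screening workflow in which 20% of the library is set
#' aside before any training subset is drawn.
#'
#' @param fitness A `fitness_dataset` (or data frame with `variant_name`).
#' @param test_size Explicit number of variants to withhold; overrides
#'   `test_fraction`.
#' @param test_fraction Fraction of the dataset to withhold, resolved as
#'   `round(fraction * n)`.
#' @param seed Integer seed; the split is seed-reproducible.
#' @return List with elements `train_pool` and `test_set` (disjoint subsets
#'   of the input rows) and `seed`.
#' @export
withhold_test_set <- function(fitness, test_size = NULL, test_fraction = NULL,
                              seed = 1L) {
  stopifnot(is.data.frame(fitness))
  n <- nrow(fitness)
  if (is.null(test_size)) {
    if (is.null(test_fraction)) stop("give `test_size` or `test_fraction`")
    stopifnot(test_fraction >= 0, test_fraction < 1)
    test_size <- round(test_fraction * n)
  }
  test_size <- as.integer(test_size)
  if (test_size > n) stop("requested test size exceeds dataset")
  idx <- withr::with_seed(seed, sample.int(n, test_size))
  list(
    train_pool = fitness[setdiff(seq_len(n), idx), , drop = FALSE],
    test_set = fitness[sort(idx), , drop = FALSE],
    seed = seed
  )
}

measured_pool <- function(pool) {
  if ("fitness_scaled" %in% names(pool)) {
    pool[!is.na(pool$fitness_scaled), , drop = FALSE]
  } else {
    pool
  }
}

#' Randomly sample a training subset
#'
#' Uniform sampling without replacement from the measured variants of a
#' training pool (variants with missing fitness are never selected).
#'
#' @param pool Training pool (data frame with `variant_name`, and
#'   `fitness_scaled` if missingness is to be respected).
#' @param size Number of variants to draw, or a fraction in (0, 1) of the
#'   measured pool, resolved as `round(fraction * n_measured)`.
#' @param seed Integer seed.
#' @return Subset of `pool` rows, in drawn order.
#' @export
sample_random <- function(pool, size, seed = 1L) {
  m <- measured_pool(pool)
  size <- resolve_size(size, nrow(m))
  idx <- withr::with_seed(seed, sample.int(nrow(m), size))
  m[idx, , drop = FALSE]
}

resolve_size <- function(size, n_avail) {
  if (size > 0 && size < 1) size <- round(size * n_avail)
  size <- as.integer(size)
  if (size > n_avail) {
    stop("requested ", size, " variants but only ", n_avail, " measured available")
  }
  size
}

#' Sample a diversity-constrained training subset
#'
#' Draws a training subset in which every member has at most `p` 1-mismatch
#' neighbors and at most `q` 2-mismatch neighbors within the subset,
#' increasing sequence diversity relative to uniform sampling. Each attempt
#' scans the measured pool in a fresh random order, greedily admitting
#' variants that keep the (p, q) constraint satisfied; an attempt succeeds
#' when the subset reaches the requested size. If no attempt succeeds within
#' `max_attempts`, the best subset found is returned with `satisfied = FALSE`
#' and the achieved neighbor maxima.
#'
#' @param pool Training pool (see [sample_random()]).
#' @param size Subset size (integer, or fraction of the measured pool).
#' @param design The [library_design()] the variants belong to (used for
#'   mismatch distances).
#' @param p Maximum allowed 1-mismatch neighbors per selected variant
#'   (`Inf` disables the constraint).
#' @param q Maximum allowed 2-mismatch neighbors (`Inf` disables).
#' @param seed Integer seed.
#' @param max_attempts Maximum random restarts (default 100000; each attempt
#'   is one randomized greedy pass, so typical draws need only a few).
#' @return Subset of `pool` rows with attributes `satisfied` (logical),
#'   `max_neighbors_1`, `max_neighbors_2`, `attempts`.
#' @export
sample_diverse <- function(pool, size, design, p = Inf, q = Inf, seed = 1L,
                           max_attempts = 100000L) {
  stopifnot(inherits(design, "library_design"), p >= 0, q >= 0, max_attempts >= 1)
  m <- measured_pool(pool)
  size <- resolve_size(size, nrow(m))
  if (is.infinite(p) && is.infinite(q)) {
    out <- sample_random(pool, size, seed)
    return(structure(out,
      satisfied = TRUE, attempts = 1L,
      max_neighbors_1 = NA_integer_, max_neighbors_2 = NA_integer_
    ))
  }
  dist <- pairwise_mismatch(m$variant_name, design)
  best <- NULL
  best_score <- Inf
  attempts_used <- max_attempts
  withr::with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      ord <- sample.int(nrow(m))
      sel <- integer(0)
      # neighbor counts of current members are maintained incrementally; a
      # candidate is admitted only if it and all members stay within (p, q).
      n1 <- integer(0)
      n2 <- integer(0)
      for (i in ord) {
        d_i <- dist[i, sel]
        add1 <- d_i == 1L
        add2 <- d_i == 2L
        if (sum(add1) > p || sum(add2) > q) next
        if (any(n1 + add1 > p) || any(n2 + add2 > q)) next
        n1 <- c(n1 + add1, sum(add1))
        n2 <- c(n2 + add2, sum(add2))
        sel <- c(sel, i)
        if (length(sel) == size) break
      }
      viol <- sum(pmax(n1 - p, 0)) + sum(pmax(n2 - q, 0)) + (size - length(sel))
      if (length(sel) == size && viol == 0) {
        best <- sel
        best_score <- 0
        attempts_used <- attempt
        break
      }
      # fall back to the fullest subset found, topped up at random
      if (viol < best_score) {
        avail <- setdiff(seq_len(nrow(m)), sel)
        extra <- avail[sample.int(length(avail), size - length(sel))]
        best <- c(sel, extra)
        best_score <- viol
        attempts_used <- attempt
      }
    }
  })
  out <- m[best, , drop = FALSE]
  sub_d <- dist[best, best, drop = FALSE]
  nb1 <- rowSums(sub_d == 1L)
  nb2 <- rowSums(sub_d == 2L)
  structure(out,
    satisfied = best_score == 0,
    attempts = attempts_used,
    max_neighbors_1 = max(nb1),
    max_neighbors_2 = max(nb2)
  )
}

#' Pairwise mismatch histogram of a variant subset
#'
#' Summarizes the sequence diversity of a subset as the number of unordered
#' variant pairs at each mismatch distance 0..n_positions.
#'
#' @param subset Data frame with `variant_name`, or a character vector of
#'   variant names.
#' @param design A [library_design()].
#' @return Named integer vector of pair counts for distances
#'   `0..n_positions`; the counts total `choose(n, 2)`.
#' @export
mismatch_profile <- function(subset, design) {
  nm <- if (is.data.frame(subset)) subset$variant_name else subset
  if (!length(nm)) stop("subset is empty")
  n_pos <- nrow(design$positions)
  counts <- setNames(integer(n_pos + 1L), 0:n_pos)
  if (length(nm) >= 2) {
    d <- pairwise_mismatch(nm, design)
    up <- d[upper.tri(d)]
    tab <- table(factor(up, levels = 0:n_pos))
    counts[] <- as.integer(tab)
  }
  counts
}
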