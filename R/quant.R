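#' Enrichment scores from two-bin sort-seq counts
#'
#' Converts per-variant barcode counts from a two-bin sorting screen (bin A:
#' the edited, GFP-disrupted population; bin B: the unedited, GFP-positive
#' population) into log2 enrichment scores (E-scores). With bin totals
#' \eqn{A} and \eqn{B} and pseudocount \eqn{c},
#' \deqn{E_i = \log_2\frac{(a_i + c)/A}{(b_i + c)/B}.}
#' An E-score of 1 corresponds to the "2-fold enrichment" reference used when
#' displaying such screens; the pseudocount keeps scores finite for variants
#' absent from one bin and makes the score antisymmetric under swapping bins.
#'
#' @param counts Data frame with columns `variant_name`, `count_binA`,
#'   `count_binB` (non-negative integers; every library variant should have a
#'   row, zero counts allowed).
#' @param pseudocount Positive real added to each raw count (default 0.5).
#' @return Tibble `variant_name`, `escore`.
#' @examples
#' counts <- data.frame(
#'   variant_name = c("WT", "N888R"),
#'   count_binA = c(100, 400), count_binB = c(100, 100)
#' )
#' escore_from_bins(counts)
#' @export
escore_from_bins <- function(counts, pseudocount = 0.5) {
  stopifnot(is.data.frame(counts), nrow(counts) > 0)
  req <- c("variant_name", "count_binA", "count_binB")
  if (!all(req %in% names(counts))) {
    stop("`counts` must have columns: ", paste(req, collapse = ", "))
  }
  if (pseudocount <= 0) stop("pseudocount must be positive")
  a <- as.numeric(counts$count_binA)
  b <- as.numeric(counts$count_binB)
  if (anyNA(a) || anyNA(b) || any(a < 0) || any(b < 0)) {
    stop("counts must be non-negative and non-missing")
  }
  A <- sum(a)
  B <- sum(b)
  if (A <= 0 || B <= 0) stop("both bins must contain reads")
  tibble::tibble(
    variant_name = counts$variant_name,
    escore = log2(((a + pseudocount) / A) / ((b + pseudocount) / B))
  )
}

#' Floor extreme E-scores and min-max scale to fitness
#'
#' Extreme-low outliers are removed by flooring E-scores at `escore_floor`
#' (e.g. -2 for on-target screens, -2.5 for off-target screens), then the
#' floored scores are min-max normalized to a scaled fitness in \[0, 1\] over
#' all non-missing entries of the dataset. Scaling is done once on the full
#' dataset, before any train/test splitting. Missing E-scores (variants
#' without an empirical measurement) are carried through as missing.
#'
#' @param escores Data frame with columns `variant_name`, `escore` (`NA`
#'   allowed), e.g. from [escore_from_bins()] or a read-in fitness table.
#' @param escore_floor Lower bound applied to E-scores (default -2).
#' @param label Free-text dataset label (e.g. the sgRNA id).
#' @return A `fitness_dataset`: a tibble `variant_name`, `escore`,
#'   `escore_floored`, `fitness_scaled`, with attributes `wt_fitness` (the
#'   scaled fitness of the `"WT"` row, if present), `escore_floor`, `label`.
#' @examples
#' d <- data.frame(variant_name = c("a", "b", "c", "d"), escore = c(-3, -2, 0, 2))
#' floor_and_minmax(d)$fitness_scaled # 0 0 0.5 1
#' @export
floor_and_minmax <- function(escores, escore_floor = -2, label = NA_character_) {
  stopifnot(is.data.frame(escores))
  req <- c("variant_name", "escore")
  if (!all(req %in% names(escores))) {
    stop("`escores` must have columns: ", paste(req, collapse = ", "))
  }
  e <- as.numeric(escores$escore)
  floored <- pmax(e, escore_floor)
  ok <- !is.na(floored)
  if (sum(ok) < 2) stop("need at least two measured variants to scale")
  lo <- min(floored[ok])
  hi <- max(floored[ok])
  if (hi - lo <= 0) stop("degenerate range: all E-scores identical after flooring")
  out <- tibble::tibble(
    variant_name = escores$variant_name,
    escore = e,
    escore_floored = floored,
    fitness_scaled = (floored - lo) / (hi - lo)
  )
  wt <- out$fitness_scaled[match("WT", out$variant_name)]
  structure(
    out,
    wt_fitness = if (length(wt)) wt else NA_real_,
    escore_floor = escore_floor,
    label = label,
    class = c("fitness_dataset", class(out))
  )
}

#' Wild-type scaled fitness of a fitness dataset
#'
#' @param fitness A `fitness_dataset` from [floor_and_minmax()], or any data
#'   frame with `variant_name` and `fitness_scaled` columns containing a
#'   `"WT"` row.
#' @return The wild-type scaled fitness (numeric scalar, `NA` if absent).
#' @export
wt_fitness <- function(fitness) {
  w <- attr(fitness, "wt_fitness")
  if (!is.null(w) && !is.na(w)) {
    return(w)
  }
  fitness$fitness_scaled[match("WT", fitness$variant_name)]
}

#' Read and write screen tables
#'
#' `read_counts()` reads `variant_name,count_binA,count_binB`;
#' `read_fitness()` reads `variant_name,escore[,escore_floored,fitness_scaled]`
#' and (re)applies flooring and scaling so the invariants hold;
#' `write_fitness()` writes the four-column fitness table.
#'
#' @param path File path.
#' @param escore_floor,label Passed to [floor_and_minmax()] (read only).
#' @return See each function.
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' @rdname read_counts
#' @export
read_fitness <- function(path, escore_floor = -2, label = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  floor_and_minmax(df[, c("variant_name", "escore")], escore_floor, label)
}

#' @rdname read_counts
#' @param fitness A `fitness_dataset`.
#' @export
write_fitness <- function(fitness, path) {
  utils::write.csv(as.data.frame(fitness), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
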