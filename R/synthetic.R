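#' Generate a ground-truth combinatorial fitness landscape
#'
#' Latent fitness of each library variant is a wild-type baseline plus the
#' sum of per-residue additive effects, plus pairwise epistatic effects for
#' designated residue pairs, plus Gaussian noise:
#' \deqn{f(v) = \mu + \sum_j \beta_{j,r_j(v)} +
#'   \sum_{j<k} \gamma_{(j,r_j),(k,r_k)} + \varepsilon,\quad
#'   \varepsilon \sim N(0, \sigma^2).}
#' Wild-type residues carry additive effect 0 by definition.
#'
#' @param design A [library_design()].
#' @param baseline Wild-type latent fitness.
#' @param additive Data frame `position`, `residue`, `effect` for alternative
#'   residues (rows for wild-type residues must have effect 0).
#' @param epistatic Optional data frame `position1`, `residue1`, `position2`,
#'   `residue2`, `effect`.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return Tibble `variant_name`, `true_fitness` over the full enumerated
#'   library, in canonical order.
#' @export
generate_landscape <- function(design, baseline = 0, additive = NULL,
                               epistatic = NULL, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(design, "library_design"), noise_sd >= 0)
  lib <- enumerate_library(design)
  m <- residue_matrix(lib, design)
  pos <- design$positions
  fit <- rep(baseline, nrow(m))
  if (!is.null(additive) && nrow(additive)) {
    for (i in seq_len(nrow(additive))) {
      j <- match(additive$position[i], pos$position)
      if (is.na(j)) stop("additive effect at non-design position ", additive$position[i])
      r <- additive$residue[i]
      if (r == pos$wildtype[j]) {
        if (additive$effect[i] != 0) {
          stop("wild-type residue must have additive effect 0 (position ", pos$position[j], ")")
        }
        next
      }
      if (!r %in% pos$alternatives[[j]]) {
        stop("additive effect references residue ", r, " not allowed at ", pos$position[j])
      }
      fit <- fit + additive$effect[i] * (m[, j] == r)
    }
  }
  if (!is.null(epistatic) && nrow(epistatic)) {
    for (i in seq_len(nrow(epistatic))) {
      j1 <- match(epistatic$position1[i], pos$position)
      j2 <- match(epistatic$position2[i], pos$position)
      if (is.na(j1) || is.na(j2)) stop("epistatic effect references a non-design position")
      ok1 <- epistatic$residue1[i] %in% c(pos$wildtype[j1], pos$alternatives[[j1]])
      ok2 <- epistatic$residue2[i] %in% c(pos$wildtype[j2], pos$alternatives[[j2]])
      if (!ok1 || !ok2) stop("epistatic effect references a residue outside the design")
      hit <- (m[, j1] == epistatic$residue1[i]) & (m[, j2] == epistatic$residue2[i])
      fit <- fit + epistatic$effect[i] * hit
    }
  }
  if (noise_sd > 0) {
    fit <- fit + withr::with_seed(seed, rnorm(length(fit), 0, noise_sd))
  }
  tibble::tibble(variant_name = lib$variant_name, true_fitness = fit)
}

#' Simulate a two-bin sorting screen
#'
#' Emulates sorting a pooled variant library into an edited (bin A) and an
#' unedited (bin B) population followed by barcode sequencing. Each
#' variant's latent fitness is standardized and mapped through a logistic
#' function to its probability of sorting into bin A,
#' \eqn{p_A = \mathrm{logit}^{-1}(s \cdot z)} with steepness \eqn{s}; reads
#' are then drawn multinomially within each bin (equal variant abundance
#' before sorting). The log-odds are linear in standardized fitness, so the
#' log-ratio E-score recovers the landscape up to scale as read depth grows.
#'
#' @param fitness Tibble `variant_name`, `true_fitness` (or a named numeric
#'   vector).
#' @param total_reads_per_bin Total reads sequenced per bin (>= number of
#'   variants).
#' @param sort_steepness Logistic steepness (> 0) of the fitness-to-bin
#'   mapping.
#' @param seed Integer seed.
#' @return A counts tibble `variant_name`, `count_binA`, `count_binB`; each
#'   bin's counts sum to `total_reads_per_bin`.
#' @export
simulate_screen <- function(fitness, total_reads_per_bin = 2e6,
                            sort_steepness = 1, seed = 1L) {
  if (is.data.frame(fitness)) {
    f <- setNames(fitness$true_fitness, fitness$variant_name)
  } else {
    f <- fitness
  }
  stopifnot(all(is.finite(f)), sort_steepness > 0)
  n <- length(f)
  if (total_reads_per_bin < n) stop("read budget smaller than the library")
  z <- if (sd(f) > 0) (f - mean(f)) / sd(f) else rep(0, n)
  pA <- stats::plogis(sort_steepness * z)
  withr::with_seed(seed, {
    cA <- stats::rmultinom(1, total_reads_per_bin, pA / sum(pA))[, 1]
    cB <- stats::rmultinom(1, total_reads_per_bin, (1 - pA) / sum(1 - pA))[, 1]
  })
  tibble::tibble(
    variant_name = names(f),
    count_binA = as.integer(cA), count_binB = as.integer(cB)
  )
}

#' KKH-SaCas9-like eight-position benchmark design
#'
#' A synthetic stand-in for an eight-position WED/PI combinatorial design:
#' three WED positions admitting 12 residue combinations and five PI
#' positions admitting 108, for `12 x 108 = 1296` variants in total (at most
#' two alternatives per site). Residue menus are drawn at random from the
#' canonical alphabet.
#'
#' @param seed Integer seed for the residue menus.
#' @return A [library_design()] with 1296 variant combinations.
#' @export
benchmark_design <- function(seed = 1L) {
  option_counts <- c(2L, 2L, 3L, 2L, 2L, 3L, 3L, 3L) # 12 WED x 108 PI
  domains <- c(rep("WED", 3), rep("PI", 5))
  positions <- c(887L, 888L, 889L, 985L, 986L, 988L, 989L, 991L)
  withr::with_seed(seed, {
    rows <- lapply(seq_along(positions), function(i) {
      menu <- sample(AA_ALPHABET, option_counts[i])
      list(
        position = positions[i], wildtype = menu[1],
        alternatives = list(menu[-1]), domain = domains[i]
      )
    })
  })
  library_design(
    dplyr::bind_rows(rows),
    name = sprintf("synthetic-8pos-1296 (seed %d)", seed)
  )
}

#' Generate a complete synthetic benchmark bundle
#'
#' One call yields a reproducible synthetic dataset shaped like a
#' 1296-variant, eight-position combinatorial sort-seq screen: a design, a
#' ground-truth landscape, simulated two-bin counts, and the derived
#' fitness dataset (E-scores floored and min-max scaled). The default
#' landscape is additive-dominant: alternative residues draw mostly
#' deleterious additive effects, a fraction of position pairs carry weaker
#' epistatic couplings, and Gaussian noise is added at a stated fraction of
#' the noiseless fitness range, leaving only a few percent of variants at or
#' above wild-type-like activity -- the regime of a typical activity screen.
#'
#' @param design A [library_design()]; default [benchmark_design()].
#' @param additive_mean,additive_sd Normal parameters of additive effects for
#'   alternative residues (defaults -1.0, 0.35: substitutions mostly hurt).
#' @param epistatic_fraction Fraction of position-pair residue-pairs given an
#'   epistatic effect (default 0.1).
#' @param epistatic_sd Epistatic effect scale (default 0.15, weak relative to
#'   the additive effects).
#' @param noise_frac Noise SD as a fraction of the noiseless fitness range
#'   (default 0.1).
#' @param total_reads_per_bin Reads per sorted bin (default 2e6).
#' @param sort_steepness Logistic sorting steepness (default 2.5).
#' @param escore_floor E-score floor applied during quantification.
#' @param seed Integer seed controlling effects, noise, and the screen.
#' @return List with `design`, `truth` (variant, `true_fitness`), `counts`,
#'   and `fitness` (a `fitness_dataset`).
#' @export
make_benchmark_bundle <- function(design = benchmark_design(seed),
                                  additive_mean = -1.0, additive_sd = 0.35,
                                  epistatic_fraction = 0.1, epistatic_sd = 0.15,
                                  noise_frac = 0.1, total_reads_per_bin = 2e6,
                                  sort_steepness = 2.5, escore_floor = -2,
                                  seed = 1L) {
  pos <- design$positions
  eff <- withr::with_seed(seed + 1L, {
    additive <- dplyr::bind_rows(lapply(seq_len(nrow(pos)), function(j) {
      alts <- pos$alternatives[[j]]
      if (!length(alts)) {
        return(NULL)
      }
      tibble::tibble(
        position = pos$position[j], residue = alts,
        effect = rnorm(length(alts), additive_mean, additive_sd)
      )
    }))
    pairs <- utils::combn(seq_len(nrow(pos)), 2)
    epi <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(k) {
      j1 <- pairs[1, k]
      j2 <- pairs[2, k]
      grid <- expand.grid(
        r1 = c(pos$wildtype[j1], pos$alternatives[[j1]]),
        r2 = c(pos$wildtype[j2], pos$alternatives[[j2]]),
        stringsAsFactors = FALSE
      )
      take <- runif(nrow(grid)) < epistatic_fraction
      if (!any(take)) {
        return(NULL)
      }
      tibble::tibble(
        position1 = pos$position[j1], residue1 = grid$r1[take],
        position2 = pos$position[j2], residue2 = grid$r2[take],
        effect = rnorm(sum(take), 0, epistatic_sd)
      )
    }))
    list(additive = additive, epistatic = epi)
  })
  noiseless <- generate_landscape(design,
    baseline = 0, additive = eff$additive,
    epistatic = eff$epistatic, noise_sd = 0
  )
  noise_sd <- noise_frac * diff(range(noiseless$true_fitness))
  truth <- generate_landscape(design,
    baseline = 0, additive = eff$additive,
    epistatic = eff$epistatic, noise_sd = noise_sd, seed = seed + 2L
  )
  counts <- simulate_screen(truth, total_reads_per_bin, sort_steepness, seed + 3L)
  fitness <- floor_and_minmax(escore_from_bins(counts), escore_floor,
    label = design$name
  )
  list(
    design = design, truth = truth, counts = counts, fitness = fitness,
    additive = eff$additive, epistatic = eff$epistatic, noise_sd = noise_sd
  )
}
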