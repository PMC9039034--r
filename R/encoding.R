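# Encoder registry: maps encoder ids to functions (variants, design) -> matrix.
.encoders <- new.env(parent = emptyenv())

#' Physicochemical amino-acid descriptors
#'
#' Returns a 20 x 19 matrix of numerical physicochemical descriptors, one row
#' per canonical amino acid. The descriptors are the complete set of 19
#' principal components of the standardized AAindex collection of published
#' amino-acid property scales (as shipped with \pkg{seqinr}): indices with
#' missing values are dropped, each remaining index is z-scored across the 20
#' residues, and the principal-component scores of the residues are taken.
#' Twenty points admit at most 19 non-degenerate components, so the 19-column
#' descriptor set captures the full amino-acid property space. This follows
#' the construction of the widely used 19-parameter descriptor sets derived
#' by principal-component analysis of amino-acid indices (Georgiev-style
#' descriptors); component signs are fixed deterministically so that each
#' component's largest-magnitude residue score is positive.
#'
#' @return Numeric matrix, rownames the one-letter residue codes, colnames
#'   `G1..G19`.
#' @export
georgiev_descriptors <- function() {
  cached <- .encoders$.georgiev_table
  if (!is.null(cached)) {
    return(cached)
  }
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  idx <- env$aaindex
  vals <- vapply(idx, function(x) {
    v <- x$I
    # seqinr names entries by three-letter code ("Ala", ...); map to one-letter
    v[match(AA_THREE, names(v))]
  }, numeric(20))
  rownames(vals) <- AA_ALPHABET
  keep <- colSums(is.na(vals)) == 0 & apply(vals, 2, sd) > 0
  vals <- vals[, keep, drop = FALSE]
  z <- scale(vals)
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  sc <- pc$x[, 1:19, drop = FALSE]
  # deterministic sign convention
  for (j in seq_len(ncol(sc))) {
    if (sc[which.max(abs(sc[, j])), j] < 0) sc[, j] <- -sc[, j]
  }
  colnames(sc) <- paste0("G", 1:19)
  .encoders$.georgiev_table <- sc
  sc
}

# three-letter codes aligned with AA_ALPHABET
AA_THREE <- c(
  "Ala", "Cys", "Asp", "Glu", "Phe", "Gly", "His", "Ile", "Lys", "Leu",
  "Met", "Asn", "Pro", "Gln", "Arg", "Ser", "Thr", "Val", "Trp", "Tyr"
)

#' Encode variants with physicochemical descriptors
#'
#' For each mutable position, the 19 descriptor values
#' ([georgiev_descriptors()]) of the residue carried there, concatenated in
#' position order (n_positions x 19 features). By default each feature column
#' is standardized to zero mean and unit variance over the encoded set;
#' constant columns are set to zero. In the prediction pipeline the full
#' enumerated library is encoded once, so standardization statistics come
#' from the complete combinatorial space.
#'
#' @param variants Library tibble, character vector of variant names, or
#'   residue matrix (see [residue_matrix()]).
#' @param design A [library_design()].
#' @param standardize Standardize feature columns (default `TRUE`).
#' @return Numeric matrix with one row per variant (rownames variant names),
#'   columns `p<position>.G<k>`, and attribute `encoder_id = "georgiev"`.
#' @export
encode_georgiev <- function(variants, design, standardize = TRUE) {
  m <- residue_matrix(variants, design)
  tab <- georgiev_descriptors()
  bad <- setdiff(unique(as.vector(m)), rownames(tab))
  if (length(bad)) stop("residue without descriptor entry: ", paste(bad, collapse = ","))
  blocks <- lapply(seq_len(ncol(m)), function(j) {
    b <- tab[m[, j], , drop = FALSE]
    colnames(b) <- paste0(colnames(m)[j], ".", colnames(tab))
    b
  })
  X <- do.call(cbind, blocks)
  rownames(X) <- rownames(m)
  if (standardize) X <- standardize_columns(X)
  structure(X, encoder_id = "georgiev")
}

standardize_columns <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  X <- sweep(X, 2, mu, "-")
  pos <- s > 0
  X[, pos] <- sweep(X[, pos, drop = FALSE], 2, s[pos], "/")
  X[, !pos] <- 0
  X
}

#' One-hot encode variants
#'
#' Per mutable position a 20-long indicator block over the canonical
#' amino-acid alphabet, with exactly one 1 per block. With this geometry the
#' mismatch distance between two variants equals half the squared Euclidean
#' distance between their rows.
#'
#' @inheritParams encode_georgiev
#' @return Numeric matrix (n_variants x 20 n_positions), columns
#'   `p<position>.<residue>`, attribute `encoder_id = "onehot"`.
#' @export
encode_onehot <- function(variants, design) {
  m <- residue_matrix(variants, design)
  bad <- setdiff(unique(as.vector(m)), AA_ALPHABET)
  if (length(bad)) stop("non-canonical residue: ", paste(bad, collapse = ","))
  blocks <- lapply(seq_len(ncol(m)), function(j) {
    b <- matrix(0, nrow(m), 20L,
      dimnames = list(NULL, paste0(colnames(m)[j], ".", AA_ALPHABET))
    )
    b[cbind(seq_len(nrow(m)), match(m[, j], AA_ALPHABET))] <- 1
    b
  })
  X <- do.call(cbind, blocks)
  rownames(X) <- rownames(m)
  structure(X, encoder_id = "onehot")
}

#' Encoder registry
#'
#' `register_encoder()` registers a feature encoder under an id so pipelines
#' can request it by name; `get_encoder()` retrieves one; `list_encoders()`
#' lists the registered ids. An encoder is a function
#' `function(variants, design)` returning a numeric matrix with one row per
#' variant. The built-in `"georgiev"` and `"onehot"` encoders are registered
#' when the package loads; learned sequence embeddings (e.g. a pretrained
#' protein language model) can be plugged in through this hook.
#'
#' @param encoder_id Unique encoder id.
#' @param fun Encoder function.
#' @param overwrite Allow replacing an existing id (default `FALSE`;
#'   registering a duplicate id errors).
#' @return `register_encoder()` invisibly returns `encoder_id`.
#' @export
register_encoder <- function(encoder_id, fun, overwrite = FALSE) {
  stopifnot(is.character(encoder_id), length(encoder_id) == 1, is.function(fun))
  if (!overwrite && !is.null(.encoders[[encoder_id]])) {
    stop("encoder id already registered: ", encoder_id)
  }
  .encoders[[encoder_id]] <- fun
  invisible(encoder_id)
}

#' @rdname register_encoder
#' @export
get_encoder <- function(encoder_id) {
  fun <- .encoders[[encoder_id]]
  if (is.null(fun)) stop("no encoder registered under id: ", encoder_id)
  fun
}

#' @rdname register_encoder
#' @export
list_encoders <- function() {
  setdiff(sort(names(.encoders)), ".georgiev_table")
}

register_builtin_encoders <- function() {
  if (is.null(.encoders[["georgiev"]])) {
    register_encoder("georgiev", function(variants, design) {
      encode_georgiev(variants, design)
    })
  }
  if (is.null(.encoders[["onehot"]])) {
    register_encoder("onehot", function(variants, design) {
      encode_onehot(variants, design)
    })
  }
}

.onLoad <- function(libname, pkgname) {
  register_builtin_encoders()
}
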