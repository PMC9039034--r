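#' Define a focused combinatorial mutagenesis library
#'
#' A library design lists the mutable residue positions of a protein, the
#' wild-type residue at each, and the alternative residues admitted there.
#' The combinatorial library is the cross-product of the per-position residue
#' menus (wild type included), e.g. eight positions in the WED and PI domains
#' of KKH-SaCas9 with up to two alternatives per site give
#' `12 x 108 = 1296` variant combinations.
#'
#' @param positions A data frame with columns `position` (1-based residue
#'   number, strictly increasing), `wildtype` (single residue code),
#'   `alternatives` (either a list-column of character vectors or a character
#'   column of semicolon-joined residues; may be empty), and optionally
#'   `domain` (free-text label such as `"WED"` or `"PI"`).
#' @param reference Optional full-length reference amino-acid sequence
#'   (single string). When supplied, each position's wild-type residue must
#'   match the reference at that index.
#' @param name Free-text name for the design.
#'
#' @return An object of class `library_design`: a list with elements
#'   `positions` (a tibble with list-column `alternatives`), `reference`,
#'   and `name`.
#'
#' @examples
#' d <- library_design(data.frame(
#'   position = c(887, 888), wildtype = c("D", "N"),
#'   alternatives = c("E", "R;Q"), domain = "WED"
#' ))
#' n_library_variants(d) # 2 * 3
#' @export
library_design <- function(positions, reference = NULL, name = "library") {
  stopifnot(is.data.frame(positions), nrow(positions) >= 1)
  req <- c("position", "wildtype", "alternatives")
  if (!all(req %in% names(positions))) {
    stop("`positions` must have columns: ", paste(req, collapse = ", "))
  }
  pos <- tibble::as_tibble(positions)
  pos$position <- as.integer(pos$position)
  if (!("domain" %in% names(pos))) pos$domain <- NA_character_
  if (!is.list(pos$alternatives)) {
    pos$alternatives <- lapply(
      as.character(pos$alternatives),
      function(s) {
        if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
      }
    )
  }
  if (anyDuplicated(pos$position)) stop("duplicate mutable positions in design")
  if (is.unsorted(pos$position, strictly = TRUE)) {
    stop("position indices must be strictly increasing")
  }
  if (any(pos$position < 1L)) stop("positions are 1-based residue numbers")
  for (i in seq_len(nrow(pos))) {
    wt <- pos$wildtype[i]
    alts <- pos$alternatives[[i]]
    if (!wt %in% AA_ALPHABET) stop("wild-type residue not a canonical amino acid: ", wt)
    if (!all(alts %in% AA_ALPHABET)) {
      stop("non-canonical residue in alternatives at position ", pos$position[i])
    }
    if (anyDuplicated(alts)) stop("duplicate alternatives at position ", pos$position[i])
    if (wt %in% alts) stop("wild-type residue listed as alternative at position ", pos$position[i])
  }
  if (!is.null(reference)) {
    reference <- toupper(as.character(reference))
    if (nchar(reference) < max(pos$position)) {
      stop("reference sequence shorter than the largest mutable position")
    }
    ref_res <- substring(reference, pos$position, pos$position)
    bad <- which(ref_res != pos$wildtype)
    if (length(bad)) {
      stop(
        "wild-type residue disagrees with reference at position ",
        paste(pos$position[bad], collapse = ", ")
      )
    }
  }
  structure(
    list(positions = pos, reference = reference, name = name),
    class = "library_design"
  )
}

#' @export
print.library_design <- function(x, ...) {
  cat(
    "<library_design> ", x$name, ": ", nrow(x$positions), " positions, ",
    n_library_variants(x), " variant combinations\n",
    sep = ""
  )
  invisible(x)
}

#' Number of variants in the full combinatorial library
#'
#' Product over positions of (1 + number of alternatives).
#'
#' @param design A [library_design()].
#' @return Integer count of variant combinations, wild type included.
#' @export
n_library_variants <- function(design) {
  stopifnot(inherits(design, "library_design"))
  prod(vapply(design$positions$alternatives, length, 1L) + 1L)
}

# Per-position residue menus, wild type first then alternatives in design order.
position_menus <- function(design) {
  mapply(
    function(wt, alts) c(wt, alts),
    design$positions$wildtype, design$positions$alternatives,
    SIMPLIFY = FALSE, USE.NAMES = FALSE
  )
}

residue_columns <- function(design) paste0("p", design$positions$position)

#' Enumerate the full combinatorial library
#'
#' Produces every combination of the per-position residue menus in a
#' deterministic canonical order: option indices (wild type = 0, then
#' alternatives in design order) are enumerated lexicographically with the
#' first (lowest-numbered) position most significant. Row 1 is always the
#' all-wild-type variant `"WT"`.
#'
#' @param design A [library_design()].
#' @return A tibble with column `variant_name` followed by one residue column
#'   per mutable position (named `p<position>`), one row per variant.
#' @examples
#' d <- library_design(data.frame(
#'   position = 1:2, wildtype = c("A", "C"), alternatives = c("G", "H;K")
#' ))
#' enumerate_library(d)
#' @export
enumerate_library <- function(design) {
  stopifnot(inherits(design, "library_design"))
  menus <- position_menus(design)
  # expand.grid varies the first factor fastest; feed reversed menus so the
  # first design position is most significant in the canonical order.
  grid <- expand.grid(rev(menus), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(menus)), drop = FALSE]
  names(grid) <- residue_columns(design)
  res <- tibble::as_tibble(grid)
  nm <- make_variant_names(as.matrix(res), design)
  dplyr::bind_cols(tibble::tibble(variant_name = nm), res)
}

#' Render canonical variant names
#'
#' Variants are named `"WT"` when all positions carry the wild-type residue,
#' otherwise by slash-joined substitution tokens in ascending position order,
#' e.g. `"N888R/A889Q"`.
#'
#' @param residues A character matrix (rows = variants, one column per mutable
#'   position in design order) or a single character vector of residues.
#' @param design A [library_design()].
#' @return Character vector of canonical names.
#' @export
make_variant_names <- function(residues, design) {
  stopifnot(inherits(design, "library_design"))
  if (is.null(dim(residues))) residues <- matrix(residues, nrow = 1)
  stopifnot(ncol(residues) == nrow(design$positions))
  wt <- design$positions$wildtype
  idx <- design$positions$position
  apply(residues, 1, function(r) {
    diff <- which(r != wt)
    if (!length(diff)) {
      "WT"
    } else {
      paste0(wt[diff], idx[diff], r[diff], collapse = "/")
    }
  })
}

#' Parse a canonical variant name
#'
#' Inverse of [make_variant_names()]: `"WT"` or slash-joined tokens of the
#' form `<wildtype><position><alternative>` are resolved against a design.
#'
#' @param name A single variant name.
#' @param design A [library_design()].
#' @return Named character vector of residues, one per mutable position
#'   (names are the residue numbers).
#' @examples
#' d <- library_design(data.frame(
#'   position = c(888, 889), wildtype = c("N", "A"), alternatives = c("R", "Q")
#' ))
#' parse_variant_name("N888R/A889Q", d)
#' @export
parse_variant_name <- function(name, design) {
  stopifnot(inherits(design, "library_design"), is.character(name), length(name) == 1)
  pos <- design$positions
  res <- setNames(pos$wildtype, pos$position)
  if (identical(name, "WT")) {
    return(res)
  }
  tokens <- strsplit(name, "/", fixed = TRUE)[[1]]
  m <- regmatches(tokens, regexec("^([A-Z])([0-9]+)([A-Z])$", tokens))
  for (k in seq_along(tokens)) {
    if (length(m[[k]]) != 4) stop("malformed variant token: ", tokens[k])
    wt <- m[[k]][2]
    at <- as.integer(m[[k]][3])
    alt <- m[[k]][4]
    i <- match(at, pos$position)
    if (is.na(i)) stop("position ", at, " is not mutable in this design")
    if (pos$wildtype[i] != wt) {
      stop("token ", tokens[k], ": design wild type at ", at, " is ", pos$wildtype[i])
    }
    if (!alt %in% pos$alternatives[[i]]) {
      stop("residue ", alt, " not an allowed substitution at position ", at)
    }
    res[i] <- alt
  }
  res
}

#' Residue matrix for a set of variants
#'
#' @param variants A library tibble (from [enumerate_library()]), a character
#'   vector of variant names, or a character matrix of residues.
#' @param design A [library_design()].
#' @return Character matrix, rows named by variant name, one column per
#'   mutable position.
#' @export
residue_matrix <- function(variants, design) {
  stopifnot(inherits(design, "library_design"))
  cols <- residue_columns(design)
  if (is.matrix(variants)) {
    stopifnot(ncol(variants) == length(cols))
    return(variants)
  }
  if (is.data.frame(variants)) {
    stopifnot(all(cols %in% names(variants)))
    m <- as.matrix(variants[, cols, drop = FALSE])
    rownames(m) <- variants$variant_name
    return(m)
  }
  m <- t(vapply(
    variants, parse_variant_name,
    character(nrow(design$positions)),
    design = design
  ))
  rownames(m) <- variants
  colnames(m) <- cols
  m
}

#' Mismatch distance between two variants
#'
#' The number of mutable positions at which two variants of the same design
#' carry different residues (the Hamming distance over the mutable sites).
#'
#' @param v1,v2 Variant names (or residue vectors of length n_positions).
#' @param design A [library_design()]; required when names are given.
#' @return Non-negative integer.
#' @export
mismatch_distance <- function(v1, v2, design = NULL) {
  to_res <- function(v) {
    if (length(v) == 1 && (grepl("[0-9]", v) || identical(v, "WT"))) {
      if (is.null(design)) stop("`design` needed to parse variant names")
      parse_variant_name(v, design)
    } else {
      v
    }
  }
  r1 <- to_res(v1)
  r2 <- to_res(v2)
  if (length(r1) != length(r2)) stop("variants come from different designs")
  sum(r1 != r2)
}

#' Pairwise mismatch distances within a variant set
#'
#' @param variants As in [residue_matrix()].
#' @param design A [library_design()].
#' @return Symmetric integer matrix of Hamming distances over mutable sites.
#' @export
pairwise_mismatch <- function(variants, design) {
  m <- residue_matrix(variants, design)
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(ncol(m))) {
    d <- d + outer(m[, j], m[, j], "!=")
  }
  storage.mode(d) <- "integer"
  d
}

#' Apply a variant's substitutions to a reference protein sequence
#'
#' @param reference Full-length amino-acid sequence (single string).
#' @param variant Variant name or residue vector.
#' @param design A [library_design()].
#' @return The substituted sequence; same length as `reference`.
#' @export
build_protein_sequence <- function(reference, variant, design) {
  stopifnot(inherits(design, "library_design"))
  reference <- toupper(as.character(reference))
  if (nchar(reference) < max(design$positions$position)) {
    stop("reference sequence shorter than the largest mutable position")
  }
  res <- if (length(variant) == 1 && (grepl("[0-9]", variant) || identical(variant, "WT"))) {
    parse_variant_name(variant, design)
  } else {
    variant
  }
  chars <- strsplit(reference, "")[[1]]
  chars[design$positions$position] <- res
  paste0(chars, collapse = "")
}

#' Read and write library designs and libraries
#'
#' `read_design()` reads a delimited design table with header
#' `position,wildtype,alternatives,domain` (alternatives semicolon-joined);
#' `write_design()` writes one. `write_library()` exports an enumerated
#' library as `variant_name,<p...>` rows. `read_fasta_reference()` reads the
#' first record of a FASTA file as the reference protein sequence.
#'
#' @param path File path.
#' @param design A [library_design()].
#' @param name Design name (read only).
#' @return `read_design()` returns a [library_design()];
#'   `read_fasta_reference()` a single string.
#' @export
read_design <- function(path, name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  df$position <- as.integer(df$position)
  library_design(df, name = name)
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "library_design"))
  df <- data.frame(
    position = design$positions$position,
    wildtype = design$positions$wildtype,
    alternatives = vapply(design$positions$alternatives, paste, "", collapse = ";"),
    domain = design$positions$domain
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_design
#' @param library A library tibble from [enumerate_library()].
#' @export
write_library <- function(library, path) {
  utils::write.csv(library, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_design
#' @export
read_fasta_reference <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE, seqonly = TRUE)
  if (!length(seqs)) stop("no sequences in ", path)
  toupper(as.character(seqs[[1]]))
}
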