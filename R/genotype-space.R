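#' Define a genotype space
#'
#' A genotype space is the combinatorial set of all `K^L` sequences of length
#' `L` over an ordered alphabet of `K` symbols, together with the
#' point-mutation (Hamming distance 1) neighbourhood structure. All map
#' builders and property calculations in this package operate on such spaces.
#'
#' Genotypes are enumerated in lexicographic order over the alphabet
#' *indices*, with position 1 the most significant: the genotype with 0-based
#' symbol indices `s_1 ... s_L` receives the 0-based index
#' `sum_i s_i * K^(L - i)`. This ordering is part of the package contract and
#' is relied upon by the serialisation format.
#'
#' @param L Sequence length (positive integer).
#' @param K Alphabet size (integer, at least 2). Defaults to the length of
#'   `alphabet`.
#' @param alphabet Ordered character vector of `K` distinct single- or
#'   multi-character symbols. Defaults: `c("+1", "-1")` for `K = 2` (the
#'   synthetic-model convention: symbol index 0 is the spin +1, index 1 the
#'   spin -1), `c("0", "1", ..., "K-1")` otherwise.
#' @param max_genotypes Capacity guard: an error is raised if `K^L` exceeds
#'   this value (default `1e7`), preventing accidental blow-ups.
#'
#' @return An object of class `"genotype_space"`: a list with elements `L`,
#'   `K`, `alphabet` and `n_genotypes`.
#' @examples
#' sp <- genotype_space(L = 2, K = 3)
#' sp$n_genotypes  # 9
#' @seealso [enumerate_genotypes()], [mutational_neighbours()]
#' @export
genotype_space <- function(L, K = length(alphabet), alphabet = NULL,
                           max_genotypes = 1e7) {
  if (!is.numeric(L) || length(L) != 1L || L < 1 || L != round(L))
    stop("`L` must be a positive integer")
  if (is.null(alphabet)) {
    alphabet <- if (K == 2) c("+1", "-1") else as.character(seq_len(K) - 1L)
  }
  alphabet <- as.character(alphabet)
  if (length(alphabet) != K)
    stop("`alphabet` must have exactly K = ", K, " symbols")
  if (anyDuplicated(alphabet))
    stop("alphabet symbols must be unique")
  if (!is.numeric(K) || K < 2 || K != round(K))
    stop("`K` must be an integer >= 2")
  n <- K^L
  if (n > max_genotypes)
    stop("genotype space has K^L = ", format(n, scientific = TRUE),
         " genotypes, exceeding the capacity guard of ",
         format(max_genotypes, scientific = TRUE),
         "; raise `max_genotypes` to override")
  structure(
    list(L = as.integer(L), K = as.integer(K), alphabet = alphabet,
         n_genotypes = n),
    class = "genotype_space"
  )
}

#' @exportS3Method base::print
print.genotype_space <- function(x, ...) {
  cat("genotype space: K =", x$K, ", L =", x$L, "->", x$n_genotypes,
      "genotypes\n  alphabet:", paste(x$alphabet, collapse = " "), "\n")
  invisible(x)
}

#' Matrix of 0-based symbol indices for every genotype
#'
#' Rows follow the canonical lexicographic enumeration order.
#'
#' @param space A [genotype_space()].
#' @return Integer matrix of dimension `K^L x L` with entries in `0:(K-1)`.
#' @export
genotype_index_matrix <- function(space) {
  stopifnot(inherits(space, "genotype_space"))
  n <- space$n_genotypes
  L <- space$L
  K <- space$K
  m <- matrix(0L, nrow = n, ncol = L)
  idx <- 0:(n - 1)
  for (i in seq_len(L)) {
    # position i is most significant first
    m[, i] <- as.integer((idx %/% K^(L - i)) %% K)
  }
  m
}

#' Enumerate all genotypes of a space
#'
#' @param space A [genotype_space()].
#' @param collapse Separator between the per-position symbols in the returned
#'   strings. The default `""` is appropriate for single-character alphabets;
#'   spaces with multi-character symbols (e.g. the synthetic `"+1"/"-1"`
#'   alphabet) use `","`.
#' @return Character vector of length `K^L`, in the canonical lexicographic
#'   order described in [genotype_space()].
#' @examples
#' enumerate_genotypes(genotype_space(2, alphabet = c("H", "P")))
#' @export
enumerate_genotypes <- function(space, collapse = NULL) {
  stopifnot(inherits(space, "genotype_space"))
  if (is.null(collapse))
    collapse <- if (any(nchar(space$alphabet) > 1L)) "," else ""
  m <- genotype_index_matrix(space)
  sym <- space$alphabet[m + 1L]
  dim(sym) <- dim(m)
  apply(sym, 1L, paste, collapse = collapse)
}

#' Split genotype strings into 0-based symbol-index rows
#'
#' Inverse of [enumerate_genotypes()] at the level of symbol indices.
#' @param genotypes Character vector of genotype strings.
#' @param space A [genotype_space()].
#' @param collapse Separator used in the strings (same default rule as
#'   [enumerate_genotypes()]).
#' @return Integer matrix, one row per genotype, entries in `0:(K-1)`.
#' @export
genotype_to_indices <- function(genotypes, space, collapse = NULL) {
  stopifnot(inherits(space, "genotype_space"))
  if (is.null(collapse))
    collapse <- if (any(nchar(space$alphabet) > 1L)) "," else ""
  if (collapse == "") {
    chars <- strsplit(genotypes, "", fixed = TRUE)
  } else {
    chars <- strsplit(genotypes, collapse, fixed = TRUE)
  }
  bad_len <- vapply(chars, length, integer(1)) != space$L
  if (any(bad_len))
    stop("genotype(s) of wrong length at position(s): ",
         paste(utils::head(which(bad_len), 5), collapse = ", "))
  m <- matrix(match(unlist(chars), space$alphabet) - 1L,
              ncol = space$L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))
    stop("unknown alphabet symbol in genotype(s): ",
         paste(utils::head(genotypes[bad], 5), collapse = ", "))
  }
  m
}

#' 0-based canonical index of genotype strings
#' @inheritParams genotype_to_indices
#' @return Integer vector of 0-based indices into the canonical enumeration.
#' @export
genotype_index <- function(genotypes, space, collapse = NULL) {
  m <- genotype_to_indices(genotypes, space, collapse)
  L <- space$L
  K <- space$K
  idx <- numeric(nrow(m))
  for (i in seq_len(L)) idx <- idx + m[, i] * K^(L - i)
  as.integer(idx)
}

#' Point-mutation neighbours of a genotype
#'
#' Every genotype has exactly `(K - 1) * L` neighbours, each differing at
#' exactly one position. The relation is symmetric.
#'
#' @param g A single genotype string.
#' @param space A [genotype_space()].
#' @param collapse Symbol separator (see [enumerate_genotypes()]).
#' @return Character vector of the `(K - 1) * L` neighbouring genotypes.
#' @examples
#' mutational_neighbours("HP", genotype_space(2, alphabet = c("H", "P")))
#' @export
mutational_neighbours <- function(g, space, collapse = NULL) {
  stopifnot(inherits(space, "genotype_space"), length(g) == 1L)
  if (is.null(collapse))
    collapse <- if (any(nchar(space$alphabet) > 1L)) "," else ""
  idx <- genotype_to_indices(g, space, collapse)[1L, ]
  out <- character((space$K - 1L) * space$L)
  k <- 0L
  for (i in seq_len(space$L)) {
    for (s in 0:(space$K - 1L)) {
      if (s == idx[i]) next
      v <- idx
      v[i] <- s
      k <- k + 1L
      out[k] <- paste(space$alphabet[v + 1L], collapse = collapse)
    }
  }
  out
}

#' Neighbour index matrix for a whole genotype space
#'
#' For the canonical enumeration order, returns an integer matrix whose row
#' `g` lists the 0-based indices of the `(K - 1) * L` point-mutation
#' neighbours of genotype `g - 1`. This is the form consumed by the compiled
#' property kernels.
#'
#' @param space A [genotype_space()].
#' @return Integer matrix of dimension `K^L x (K - 1) L` (0-based entries).
#' @export
neighbour_index_matrix <- function(space) {
  stopifnot(inherits(space, "genotype_space"))
  n <- space$n_genotypes
  L <- space$L
  K <- space$K
  d <- (K - 1L) * L
  nb <- matrix(0L, nrow = n, ncol = d)
  idx <- 0:(n - 1)
  col <- 0L
  for (i in seq_len(L)) {
    place <- K^(L - i)
    digit <- (idx %/% place) %% K
    for (delta in seq_len(K - 1L)) {
      col <- col + 1L
      newdigit <- (digit + delta) %% K
      nb[, col] <- as.integer(idx + (newdigit - digit) * place)
    }
  }
  nb
}

#' The +1/-1 spin encoding of a binary genotype space
#'
#' Symbol index 0 encodes +1 and symbol index 1 encodes -1, so the first
#' genotype in the enumeration is the all-(+1) vector.
#'
#' @param space A binary (`K = 2`) [genotype_space()].
#' @return Numeric matrix `K^L x L` with entries +1/-1.
#' @export
spin_matrix <- function(space) {
  stopifnot(inherits(space, "genotype_space"))
  if (space$K != 2L)
    stop("the spin encoding is defined for binary (K = 2) spaces only")
  1 - 2 * genotype_index_matrix(space)
}
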