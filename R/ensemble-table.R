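#' Construct an ND GP map (ensemble table)
#'
#' The central container of the package: a sparse mapping from every genotype
#' of a [genotype_space()] to its phenotype ensemble, i.e. a probability
#' distribution over phenotype labels. Rows of `P` follow the canonical
#' genotype enumeration order; columns correspond to `labels`.
#'
#' Each genotype's ensemble must sum to 1 (within `1e-9`) *before* the
#' probability floor is applied. After the floor (see [apply_cutoff()])
#' entries below the cutoff are dropped and the remaining probabilities are
#' deliberately **not** renormalised: the frequency and robustness statistics
#' divide by `K^L` and `(K-1)L`, not by the retained mass, and silent
#' renormalisation would change those sums. The `renormalised` flag records
#' whether the alternative reading was applied.
#'
#' @param space A [genotype_space()].
#' @param P Probability matrix (`K^L x n_labels`), dense or a
#'   `Matrix::dgCMatrix`. Stored sparse.
#' @param labels Character vector of phenotype labels (unique), one per
#'   column of `P`.
#' @param undefined Label of the "undefined" placeholder phenotype, or `NA`
#'   if the map has none. The undefined phenotype occupies ensemble mass but
#'   is excluded from all property sums.
#' @param cutoff Probability floor in `[0, 1)` recorded with the map
#'   (default `1e-4`). Set `apply = TRUE` to apply it on construction.
#' @param apply Apply the cutoff to `P` on construction? Default `TRUE`.
#'   When `TRUE`, per-genotype normalisation is checked first.
#' @param renormalised Flag recording whether ensembles were renormalised
#'   after the cutoff (default `FALSE`; see Details).
#' @param provenance Free-form list describing how the map was built
#'   (model spec, seed, ...); carried through serialisation.
#' @param check Validate normalisation and probability ranges (default
#'   `TRUE`). Skipped internally when a builder has already verified them.
#'
#' @return An object of class `"gp_map"`.
#' @export
gp_map <- function(space, P, labels, undefined = NA_character_,
                   cutoff = 1e-4, apply = TRUE, renormalised = FALSE,
                   provenance = list(), check = TRUE) {
  stopifnot(inherits(space, "genotype_space"))
  if (is.matrix(P)) P <- Matrix::Matrix(P, sparse = TRUE)
  P <- methods::as(methods::as(P * 1.0, "generalMatrix"), "CsparseMatrix")
  labels <- as.character(labels)
  if (ncol(P) != length(labels))
    stop("`P` must have one column per phenotype label")
  if (nrow(P) != space$n_genotypes)
    stop("`P` must have one row per genotype (", space$n_genotypes, ")")
  if (anyDuplicated(labels))
    stop("phenotype labels must be unique")
  if (!is.na(undefined) && !(undefined %in% labels))
    stop("`undefined` label not present among phenotype labels")
  if (!is.numeric(cutoff) || cutoff < 0 || cutoff >= 1)
    stop("`cutoff` must lie in [0, 1)")
  if (check) {
    x <- P@x
    if (length(x) && (any(x <= 0) || any(x > 1 + 1e-12)))
      stop("probabilities must lie in (0, 1]")
    if (apply) {
      sums <- Matrix::rowSums(P)
      if (any(abs(sums - 1) > 1e-9))
        stop("pre-cutoff ensembles must sum to 1 within 1e-9 (worst deviation ",
             format(max(abs(sums - 1))), ")")
    }
  }
  obj <- structure(
    list(space = space, P = P, labels = labels, undefined = undefined,
         cutoff = cutoff, renormalised = isTRUE(renormalised),
         provenance = provenance),
    class = "gp_map"
  )
  if (apply && cutoff > 0) obj <- apply_cutoff(obj, cutoff) else obj
}

#' @exportS3Method base::print
print.gp_map <- function(x, ...) {
  cat("ND GP map: K =", x$space$K, ", L =", x$space$L, "->",
      x$space$n_genotypes, "genotypes,", length(x$labels), "phenotypes\n")
  cat("  stored entries:", length(x$P@x),
      sprintf("(mean ensemble size %.2f)", length(x$P@x) / nrow(x$P)), "\n")
  cat("  cutoff:", format(x$cutoff),
      if (x$renormalised) "(renormalised)" else "(not renormalised)", "\n")
  if (!is.na(x$undefined)) cat("  undefined phenotype:", x$undefined, "\n")
  invisible(x)
}

#' Apply a probability floor to an ND GP map
#'
#' Entries with probability strictly below `cutoff` are treated as 0 and
#' removed; entries exactly at the cutoff are retained. Remaining
#' probabilities are not renormalised unless `renormalise = TRUE` (see
#' [gp_map()] for why the default keeps the raw probabilities).
#'
#' @param map A [gp_map()].
#' @param cutoff Probability floor in `[0, 1)`. `0` is the identity.
#' @param renormalise Rescale each genotype's retained probabilities to sum
#'   to 1? Default `FALSE`.
#' @return The filtered `gp_map`, with `cutoff` (and `renormalised`) updated.
#' @examples
#' sp <- genotype_space(1, alphabet = c("a", "b"))
#' m <- gp_map(sp, matrix(c(0.99995, 0.9999, 0.00005, 0.0001), 2),
#'             labels = c("A", "B"), cutoff = 0, apply = FALSE)
#' apply_cutoff(m, 1e-4)  # drops the 0.00005 entry, keeps the 0.0001 one
#' @export
apply_cutoff <- function(map, cutoff = map$cutoff, renormalise = FALSE) {
  stopifnot(inherits(map, "gp_map"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 || cutoff >= 1)
    stop("`cutoff` must lie in [0, 1)")
  P <- map$P
  if (cutoff > 0) {
    P@x[P@x < cutoff] <- 0
    P <- Matrix::drop0(P)
  }
  if (renormalise) {
    s <- Matrix::rowSums(P)
    s[s == 0] <- 1
    P <- Matrix::Diagonal(x = 1 / s) %*% P
    P <- methods::as(methods::as(P, "generalMatrix"), "CsparseMatrix")
  }
  map$P <- P
  map$cutoff <- cutoff
  map$renormalised <- isTRUE(renormalise) || map$renormalised
  map
}

#' Number of phenotypes present in a map
#'
#' Counts phenotypes with non-zero stored mass (`f_p > 0`), excluding the
#' undefined placeholder. This is the `n_p` entering evolvability
#' normalisations.
#' @param map A [gp_map()].
#' @return Integer count.
#' @export
n_phenotypes_present <- function(map) {
  keep <- Matrix::colSums(map$P) > 0
  if (!is.na(map$undefined)) keep[map$labels == map$undefined] <- FALSE
  sum(keep)
}

format_probability <- function(x) sprintf("%.17g", x)

#' Write an ND GP map to a TSV file
#'
#' The format is a JSON metadata header (lines starting with `#`) carrying
#' `L`, `K`, the alphabet, the cutoff, the undefined label and the builder
#' provenance, followed by a `genotype  phenotype  probability` table with
#' probabilities at full double precision. The round trip through
#' [read_gpmap()] is lossless.
#'
#' @param map A [gp_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gpmap <- function(map, path) {
  stopifnot(inherits(map, "gp_map"))
  meta <- list(
    format = "ndgpmap/1",
    L = map$space$L, K = map$space$K, alphabet = map$space$alphabet,
    cutoff = map$cutoff, renormalised = map$renormalised,
    provenance = map$provenance
  )
  if (!is.na(map$undefined)) meta$undefined <- map$undefined
  header <- paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  gstr <- enumerate_genotypes(map$space)
  Pt <- methods::as(Matrix::t(map$P), "CsparseMatrix")  # columns = genotypes
  p <- Pt@p
  i <- Pt@i
  x <- Pt@x
  ng <- ncol(Pt)
  counts <- diff(p)
  rows_g <- rep.int(gstr, counts)
  rows_p <- map$labels[i + 1L]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, "genotype\tphenotype\tprobability"), con)
  if (length(x))
    writeLines(paste(rows_g, rows_p, format_probability(x), sep = "\t"), con)
  invisible(path)
}

#' Read an ND GP map written by [write_gpmap()]
#'
#' Parses the JSON header and the triple table, validating symbols and
#' probability ranges; malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @return A [gp_map()].
#' @export
read_gpmap <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (!length(hdr) || hdr[1] != 1L)
    stop("missing JSON header (line 1 must start with '#')")
  meta <- jsonlite::fromJSON(sub("^#", "", lines[hdr[1]]))
  body_start <- max(hdr) + 1L
  if (body_start > length(lines) ||
      !identical(lines[body_start], "genotype\tphenotype\tprobability"))
    stop("missing column header line after JSON header")
  space <- genotype_space(L = meta$L, K = meta$K, alphabet = meta$alphabet)
  data_lines <- lines[-seq_len(body_start)]
  data_lineno <- seq_along(data_lines) + body_start
  keep <- nzchar(data_lines)
  data_lines <- data_lines[keep]
  data_lineno <- data_lineno[keep]
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 3L))
    stop("malformed row (expected 3 tab-separated fields) at line ",
         data_lineno[which(nfield != 3L)[1]])
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  prob <- suppressWarnings(as.numeric(m[, 3]))
  bad <- is.na(prob) | prob <= 0 | prob > 1
  if (any(bad))
    stop("probability outside (0, 1] or unparseable at line ",
         data_lineno[which(bad)[1]], ": '", m[which(bad)[1], 3], "'")
  gidx <- tryCatch(genotype_index(m[, 1], space),
                   error = function(e) stop("bad genotype string near line ",
                                            data_lineno[1], ": ",
                                            conditionMessage(e)))
  labels <- unique(m[, 2])
  pidx <- match(m[, 2], labels)
  P <- Matrix::sparseMatrix(i = gidx + 1L, j = pidx, x = prob,
                            dims = c(space$n_genotypes, length(labels)))
  undefined <- if (is.character(meta$undefined) &&
                   length(meta$undefined) == 1L) meta$undefined
               else NA_character_
  prov <- if (!is.null(meta$provenance)) meta$provenance else list()
  gp_map(space, P, labels, undefined = undefined,
         cutoff = if (!is.null(meta$cutoff)) meta$cutoff else 0,
         apply = FALSE, renormalised = isTRUE(meta$renormalised),
         provenance = prov, check = TRUE)
}
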