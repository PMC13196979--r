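#' Enumerate all secondary structures compatible with an RNA sequence
#'
#' Exhaustive enumeration of the pseudoknot-free secondary structures whose
#' base pairs are possible for the given sequence: Watson-Crick (AU, UA,
#' GC, CG) and GU/UG wobble pairs, hairpin loops spanning at least
#' `min_hairpin` unpaired bases, pairs either nested or disjoint, no base
#' in two pairs. The open (unpaired) structure is always included.
#'
#' @param seq RNA sequence (string over A, C, G, U; length guard `<= 20` —
#'   the count grows quickly).
#' @param min_hairpin Minimum unpaired bases enclosed by a hairpin
#'   (default 3, the standard convention).
#' @return Character vector of dot-bracket strings (first element is the
#'   open structure).
#' @examples
#' enumerate_compatible_structures("GAAAC")  # ".....", "(...)"
#' @export
enumerate_compatible_structures <- function(seq, min_hairpin = 3) {
  bases <- strsplit(toupper(seq), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "U")))
    stop("sequence must be over A, C, G, U")
  L <- length(bases)
  if (L > 20) stop("length guard: enumeration supported for length <= 20")
  can_pair <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  memo <- new.env(hash = TRUE, parent = emptyenv())
  # returns list of pair matrices (m x 2) for the subsequence i..j
  enum <- function(i, j) {
    if (i >= j) return(list(matrix(0L, 0L, 2L)))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- enum(i + 1L, j)  # i unpaired
    ks <- if (i + min_hairpin + 1L <= j) seq.int(i + min_hairpin + 1L, j)
          else integer(0)
    for (k in ks) {
      if (!can_pair(bases[i], bases[k])) next
      inner <- enum(i + 1L, k - 1L)
      outer <- enum(k + 1L, j)
      for (a in inner) for (b in outer)
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
    }
    memo[[key]] <- out
    out
  }
  pairsets <- enum(1L, L)
  vapply(pairsets, function(pm) {
    db <- rep(".", L)
    if (nrow(pm)) {
      db[pm[, 1]] <- "("
      db[pm[, 2]] <- ")"
    }
    paste(db, collapse = "")
  }, character(1))
}

#' Validate a dot-bracket structure against the enumeration rules
#'
#' Checks balanced nesting, that every pair is a permitted base pair for
#' the sequence, and the minimum hairpin span.
#' @param seq RNA sequence.
#' @param db Dot-bracket string.
#' @param min_hairpin Minimum hairpin span.
#' @return `TRUE`, or a character description of the first violation.
#' @export
validate_structure <- function(seq, db, min_hairpin = 3) {
  bases <- strsplit(toupper(seq), "")[[1]]
  ch <- strsplit(db, "")[[1]]
  if (length(ch) != length(bases)) return("length mismatch")
  stack <- integer(0)
  allowed <- c("AU", "UA", "GC", "CG", "GU", "UG")
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) return("unbalanced brackets")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (i - j - 1L < min_hairpin &&
          !any(ch[(j + 1L):(i - 1L)] %in% c("(", ")")))
        return(paste0("hairpin (", j, ",", i, ") spans < ", min_hairpin))
      if (!(paste0(bases[j], bases[i]) %in% allowed))
        return(paste0("disallowed pair ", bases[j], bases[i]))
    } else if (ch[i] != ".") return("invalid character")
  }
  if (length(stack)) return("unbalanced brackets")
  TRUE
}

#' Free-energy evaluator backed by the RNAeval command-line tool
#'
#' Returns a function `(sequence, structure) -> free energy (kcal/mol)`
#' that shells out to `RNAeval`, for use with [build_rna_map()]. Errors
#' with an explicit "adapter unavailable" message when the executable is
#' not on the PATH.
#'
#' @return An energy function.
#' @export
rnaeval_energy <- function() {
  exe <- Sys.which("RNAeval")
  if (!nzchar(exe))
    stop("adapter unavailable: RNAeval executable not found on PATH")
  function(sequence, structure) {
    inp <- tempfile()
    on.exit(unlink(inp))
    writeLines(c(sequence, structure), inp)
    out <- suppressWarnings(system2(exe, stdin = inp, stdout = TRUE))
    m <- regmatches(out, regexpr("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", out))
    m <- m[nzchar(m)]
    if (!length(m)) stop("could not parse RNAeval output: ",
                         paste(out, collapse = " | "))
    as.numeric(gsub("[()[:space:]]", "", m[length(m)]))
  }
}

#' Build an RNA ND GP map from Boltzmann-weighted structure ensembles
#'
#' For each sequence, all compatible secondary structures are enumerated
#' and weighted by `exp(-G/(kBT))` with `G` supplied by the injected
#' evaluator, then normalised. The open (unfolded) structure is registered
#' as the undefined phenotype: in short sequences its prevalence is an
#' artefact of the length, so it is excluded from all property sums.
#'
#' @param sequences Character vector of RNA sequences of a common length.
#'   When they constitute the complete `4^L` space, a full [gp_map()] is
#'   returned; otherwise a list of per-sequence ensembles.
#' @param energy_fn Function `(sequence, structure) -> free energy`.
#'   Required; see [rnaeval_energy()] for the external-evaluator contract.
#' @param kBT Boltzmann factor in the evaluator's energy units
#'   (e.g. ~0.616 kcal/mol at 37C).
#' @param cutoff Probability floor (default `1e-4`).
#' @param min_hairpin Minimum hairpin span (default 3).
#' @return A [gp_map()] (complete space) or a named list of per-sequence
#'   probability vectors over dot-bracket labels.
#' @export
build_rna_map <- function(sequences, energy_fn, kBT, cutoff = 1e-4,
                          min_hairpin = 3) {
  if (missing(energy_fn) || !is.function(energy_fn))
    stop("adapter unavailable: `energy_fn` (sequence, structure) -> ",
         "free energy must be supplied")
  if (!is.numeric(kBT) || kBT <= 0) stop("`kBT` must be positive")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must share one length")
  ensembles <- lapply(sequences, function(s) {
    dbs <- enumerate_compatible_structures(s, min_hairpin)
    G <- vapply(dbs, function(db) energy_fn(s, db), numeric(1))
    if (any(!is.finite(G))) stop("energy_fn returned a non-finite energy")
    w <- exp(-(G - min(G)) / kBT)
    stats::setNames(w / sum(w), dbs)
  })
  names(ensembles) <- sequences
  space <- try(genotype_space(L, alphabet = c("A", "C", "G", "U")),
               silent = TRUE)
  complete <- !inherits(space, "try-error") &&
    length(sequences) == space$n_genotypes &&
    !anyDuplicated(sequences)
  if (!complete) return(ensembles)
  open_db <- strrep(".", L)
  labels <- unique(unlist(lapply(ensembles, names)))
  labels <- c(setdiff(labels, open_db), intersect(open_db, labels))
  gidx <- genotype_index(sequences, space)
  i_idx <- rep.int(gidx + 1L, lengths(ensembles))
  j_idx <- match(unlist(lapply(ensembles, names), use.names = FALSE), labels)
  x_val <- unlist(ensembles, use.names = FALSE)
  P <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = x_val,
                            dims = c(space$n_genotypes, length(labels)))
  gp_map(space, P, labels,
         undefined = if (open_db %in% labels) open_db else NA_character_,
         cutoff = cutoff, apply = TRUE,
         provenance = list(model = "rna", L = L, kBT = kBT))
}
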