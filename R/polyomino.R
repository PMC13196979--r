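#' Define a Polyomino tile set
#'
#' In the Polyomino model `S_{t,c}` a genotype of length `4t` over the
#' integers `0..c-1` labels the four faces (N, E, S, W) of `t` square
#' tiles. Label 0 never binds; label 1 binds 2, 3 binds 4, and so on
#' (odd-even pairing only; a label never binds itself).
#'
#' @param genotype Integer vector of length `4t` (values in `0..c-1`).
#' @param c Alphabet size (number of face labels).
#' @param t Tile count; inferred from the genotype length by default.
#' @return An object of class `"tile_set"`.
#' @export
tile_set <- function(genotype, c, t = length(genotype) / 4) {
  genotype <- as.integer(genotype)
  if (length(genotype) != 4 * t || t < 1 || t != round(t))
    stop("genotype length must be 4t")
  if (any(genotype < 0) || any(genotype >= c))
    stop("face labels must lie in 0..c-1")
  structure(list(genotype = genotype, t = as.integer(t), c = as.integer(c)),
            class = "tile_set")
}

#' @exportS3Method base::print
print.tile_set <- function(x, ...) {
  cat("Polyomino tile set S_{", x$t, ",", x$c, "}:\n", sep = "")
  for (k in seq_len(x$t)) {
    f <- x$genotype[(4 * k - 3):(4 * k)]
    cat("  tile", k, "(N,E,S,W):", paste(f, collapse = " "), "\n")
  }
  invisible(x)
}

#' Do two face labels bind?
#' @param a,b Integer face labels.
#' @return Logical.
#' @export
faces_bind <- function(a, b) {
  a > 0 & b > 0 & ifelse(a %% 2 == 1, b == a + 1, b == a - 1)
}

#' One stochastic self-assembly run
#'
#' Seeds the assembly with one copy of the first tile at the origin, then
#' repeatedly picks uniformly at random among all (empty perimeter cell,
#' tile type, rotation) placements that bind at least one adjacent occupied
#' face, and places it (irreversibly; tiles rotate but are never mirrored).
#' Assembly completes when no binding placement exists. If the assembly
#' exceeds `(4t)^2/2` cells — unbounded growth is possible — the run
#' returns the `"UNDEFINED"` placeholder.
#'
#' Uses R's RNG stream; call `set.seed()` for reproducibility.
#'
#' @param tiles A [tile_set()].
#' @return Canonical shape string (occupied cells, canonicalised under
#'   rotation and translation but not mirroring), or `"UNDEFINED"`.
#' @export
assemble_once <- function(tiles) {
  stopifnot(inherits(tiles, "tile_set"))
  poly_assemble_once(tiles$genotype, tiles$t)
}

#' Estimate a tile set's phenotype ensemble
#'
#' Repeats the stochastic assembly `n_rep` times and tallies canonical
#' shapes. Shapes observed fewer than `min_count` times cannot be
#' estimated reliably and are merged into the `"UNDEFINED"` placeholder,
#' together with runs that exceeded the maximum assembly size. The
#' returned probabilities are exact rational counts over `n_rep` and sum
#' to 1.
#'
#' @param tiles A [tile_set()].
#' @param n_rep Number of assembly repetitions (default 5000).
#' @param min_count Minimum tally for a shape to be reported as its own
#'   phenotype (default 50).
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @return Named numeric vector of probabilities (shape strings, possibly
#'   `"UNDEFINED"`), with the raw tallies as attribute `"counts"`.
#' @export
estimate_ensemble <- function(tiles, n_rep = 5000, min_count = 50,
                              seed = 1L) {
  stopifnot(inherits(tiles, "tile_set"))
  if (n_rep < min_count || min_count < 1)
    stop("need n_rep >= min_count >= 1")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  tl <- poly_assemble_tally(tiles$genotype, tiles$t, as.integer(n_rep))
  counts <- stats::setNames(tl$count, tl$shape)
  low <- names(counts)[counts < min_count & names(counts) != "UNDEFINED"]
  if (length(low)) {
    counts["UNDEFINED"] <- sum(counts[low]) +
      (if ("UNDEFINED" %in% names(counts)) counts[["UNDEFINED"]] else 0L)
    counts <- counts[setdiff(names(counts), low)]
  }
  probs <- counts / n_rep
  attr(probs, "counts") <- counts
  probs
}

#' Assembly graph and canonical key of a tile set
#'
#' The assembly graph encodes which tile faces bind which: two genotypes
#' with the same assembly graph produce the same ensemble of phenotypes, so
#' assembly needs to be simulated only once per graph class. The canonical
#' key is the lexicographic minimum, over tile permutations and per-tile
#' rotations, of the genotype after (a) zeroing every tile that the seed
#' tile cannot reach through binding interactions (such tiles never attach,
#' so their labels are irrelevant) and (b) canonical relabelling: faces
#' whose partner label occurs nowhere become 0, and binding pairs are
#' renamed `(1,2), (3,4), ...` in order of first occurrence.
#'
#' The returned graph has one vertex per face, a directed cycle per tile
#' (edge colour 1; the direction keeps mirrored tiles distinct) and a pair
#' of directed edges between mutually binding faces (edge colour 2), so
#' residual key collisions can be resolved by VF2 isomorphism.
#'
#' @param tiles A [tile_set()].
#' @return List of class `"assembly_graph"` with `key` (canonical string),
#'   `canonical_genotype` (integer vector) and `graph` (an igraph object).
#' @export
assembly_graph <- function(tiles) {
  stopifnot(inherits(tiles, "tile_set"))
  key <- poly_canonical_key(tiles$genotype, tiles$t)
  canon <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
  structure(list(key = key, canonical_genotype = canon,
                 graph = .assembly_igraph(canon, tiles$t)),
            class = "assembly_graph")
}

.assembly_igraph <- function(genotype, t) {
  n <- 4L * t
  from <- integer(0); to <- integer(0); colr <- integer(0)
  for (k in seq_len(t)) {
    base <- 4L * (k - 1L)
    for (d in 1:4) {
      from <- c(from, base + d)
      to <- c(to, base + (d %% 4L) + 1L)
      colr <- c(colr, 1L)
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && faces_bind(genotype[i], genotype[j])) {
        from <- c(from, i); to <- c(to, j); colr <- c(colr, 2L)
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to), directed = TRUE,
    vertices = data.frame(name = seq_len(n)))
  igraph::E(g)$color <- colr
  g
}

#' Build a full Polyomino ND GP map
#'
#' Enumerates all `c^(4t)` genotypes, groups them into assembly-graph
#' classes via the canonical key (with an optional VF2 isomorphism pass
#' merging residual collisions), simulates the stochastic assembly once per
#' class, and shares the estimated ensemble across the class. The
#' `"UNDEFINED"` placeholder (unbounded or sub-`min_count` assemblies) is
#' registered as the map's undefined phenotype and excluded from property
#' sums downstream. Sampling errors of a class representative propagate to
#' every genotype of the class; the per-class tally is exposed through the
#' `"classes"` attribute.
#'
#' @param t Tile count.
#' @param c Alphabet size.
#' @param n_rep Assembly repetitions per class (default 5000).
#' @param min_count Reporting threshold per shape (default 50).
#' @param seed Master RNG seed; classes consume one common stream in class
#'   order, so the whole map is reproducible.
#' @param isomorphism Merge key classes whose assembly graphs are VF2
#'   isomorphic (default `TRUE`).
#' @param max_genotypes Capacity guard on `c^(4t)`.
#' @return A [gp_map()] with canonical shape strings as phenotype labels.
#'   Attribute `"classes"`: data.frame with one row per genotype (`key`,
#'   `class`) plus per-class sizes in attribute `"class_size"`.
#' @export
build_polyomino_map <- function(t, c, n_rep = 5000, min_count = 50,
                                seed = 1L, isomorphism = TRUE,
                                max_genotypes = 1e7) {
  space <- genotype_space(L = 4L * t, K = c,
                          alphabet = as.character(0:(c - 1L)),
                          max_genotypes = max_genotypes)
  gm <- genotype_index_matrix(space)  # rows are genotypes, labels 0..c-1
  keys <- poly_canonical_keys(gm, t)
  ukeys <- unique(keys)
  class_of_key <- seq_along(ukeys)
  names(class_of_key) <- ukeys
  if (isomorphism && length(ukeys) > 1L) {
    graphs <- lapply(ukeys, function(k) {
      .assembly_igraph(as.integer(strsplit(k, ",", fixed = TRUE)[[1]]), t)
    })
    reps <- integer(0)  # indices into ukeys of class representatives
    for (i in seq_along(ukeys)) {
      hit <- 0L
      for (r in reps) {
        if (igraph::isomorphic(graphs[[i]], graphs[[r]], method = "vf2")) {
          hit <- r
          break
        }
      }
      if (hit == 0L) {
        reps <- c(reps, i)
        class_of_key[i] <- i
      } else {
        class_of_key[i] <- hit
      }
    }
  }
  cls <- class_of_key[keys]           # class id per genotype
  class_ids <- unique(cls)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ensembles <- vector("list", length(class_ids))
  names(ensembles) <- as.character(class_ids)
  for (ci in seq_along(class_ids)) {
    rep_row <- match(class_ids[ci], cls)
    tiles <- tile_set(gm[rep_row, ], c = c, t = t)
    ensembles[[ci]] <- estimate_ensemble(tiles, n_rep = n_rep,
                                         min_count = min_count, seed = NULL)
  }
  labels <- unique(unlist(lapply(ensembles, names)))
  labels <- c(setdiff(labels, "UNDEFINED"),
              intersect("UNDEFINED", labels))
  ens_i <- lapply(ensembles, function(e) match(names(e), labels))
  counts_per_g <- lengths(ensembles)[match(as.character(cls),
                                           names(ensembles))]
  i_idx <- rep.int(seq_len(nrow(gm)), counts_per_g)
  j_idx <- unlist(ens_i[match(as.character(cls), names(ensembles))],
                  use.names = FALSE)
  x_val <- unlist(ensembles[match(as.character(cls), names(ensembles))],
                  use.names = FALSE)
  P <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = x_val,
                            dims = c(nrow(gm), length(labels)))
  map <- gp_map(space, P, labels,
                undefined = if ("UNDEFINED" %in% labels) "UNDEFINED"
                            else NA_character_,
                cutoff = min_count / n_rep, apply = FALSE,
                provenance = list(model = "polyomino", t = t, c = c,
                                  n_rep = n_rep, min_count = min_count,
                                  seed = seed,
                                  n_classes = length(class_ids)))
  classes <- data.frame(key = keys, class = as.integer(cls))
  attr(classes, "class_size") <- table(cls)
  attr(map, "classes") <- classes
  map
}

#' Write the genotype-to-assembly-class index as TSV
#' @param map A Polyomino [gp_map()] from [build_polyomino_map()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_assembly_classes <- function(map, path) {
  classes <- attr(map, "classes")
  if (is.null(classes)) stop("map carries no assembly-class index")
  df <- data.frame(genotype = enumerate_genotypes(map$space),
                   class = classes$class, key = classes$key)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
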