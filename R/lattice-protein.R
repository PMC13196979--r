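#' HP contact potential
#'
#' Pairwise contact energies for the hydrophobic-polar lattice protein.
#' The defaults are the Li et al. values `cHH = -2.3`, `cHP = -1`,
#' `cPP = 0`, chosen because they produce fewer genotypes with degenerate
#' minimum-energy states than the uniform alternative. Energies are
#' dimensionless, as is `kBT` downstream.
#'
#' @param cHH,cHP,cPP Contact energies.
#' @return A 2x2 symmetric lookup matrix with dimnames `H`/`P`.
#' @export
hp_potential <- function(cHH = -2.3, cHP = -1, cPP = 0) {
  matrix(c(cHH, cHP, cHP, cPP), 2, 2,
         dimnames = list(c("H", "P"), c("H", "P")))
}

dihedral_transforms <- function(W) {
  # the 8 symmetries of the W x W grid, acting on (x, y) in 0..W-1
  w <- W - 1L
  list(
    function(x, y) cbind(x, y),
    function(x, y) cbind(y, w - x),
    function(x, y) cbind(w - x, w - y),
    function(x, y) cbind(w - y, x),
    function(x, y) cbind(w - x, y),
    function(x, y) cbind(x, w - y),
    function(x, y) cbind(y, x),
    function(x, y) cbind(w - y, w - x)
  )
}

path_contacts <- function(path) {
  # pairs (i, j), |i - j| > 1, whose lattice cells are adjacent
  L <- nrow(path)
  out <- matrix(0L, 0L, 2L)
  for (i in seq_len(L - 2L)) {
    for (j in (i + 2L):L) {
      if (abs(path[i, 1] - path[j, 1]) + abs(path[i, 2] - path[j, 2]) == 1L)
        out <- rbind(out, c(i, j))
    }
  }
  out
}

#' Enumerate compact lattice-protein conformations
#'
#' All directed Hamiltonian self-avoiding walks on the `W x W` square
#' lattice ("compact" conformations: the chain of length `W^2` fills the
#' lattice), deduplicated under the 8 rotations and mirror reflections of
#' the grid. Chain direction is *not* merged: a walk and its reversal are
#' distinct conformations (protein backbones are directional), unless a
#' grid symmetry happens to relate them. The canonical form of a walk is
#' the lexicographic minimum of its coordinate sequence over the 8
#' transforms; representatives are returned in a stable enumeration order.
#'
#' @param W Grid side (guard: `W <= 5`).
#' @return A list of class `"conformation_list"`; each element has `path`
#'   (a `W^2 x 2` 0-based coordinate matrix) and `contacts` (an `m x 2`
#'   matrix of residue index pairs `(i, j)`, `|i - j| > 1`, that are
#'   lattice-adjacent but not chain-consecutive).
#' @export
enumerate_compact_conformations <- function(W = 4) {
  if (!is.numeric(W) || W < 1 || W != round(W) || W > 5)
    stop("`W` must be an integer between 1 and 5 (capacity guard)")
  W <- as.integer(W)
  n <- W * W
  # neighbours of each cell (cells indexed 0..n-1, cell = x + W*y)
  nbrs <- vector("list", n)
  for (cell in 0:(n - 1L)) {
    x <- cell %% W
    y <- cell %/% W
    cand <- list(c(x - 1L, y), c(x + 1L, y), c(x, y - 1L), c(x, y + 1L))
    keep <- vapply(cand, function(p) all(p >= 0L & p < W), logical(1))
    nbrs[[cell + 1L]] <- vapply(cand[keep], function(p) p[1] + W * p[2],
                                integer(1))
  }
  paths <- list()
  visited <- logical(n)
  path <- integer(n)
  dfs <- function(cell, depth) {
    visited[cell + 1L] <<- TRUE
    path[depth] <<- cell
    if (depth == n) {
      paths[[length(paths) + 1L]] <<- path
    } else {
      for (nx in nbrs[[cell + 1L]]) {
        if (!visited[nx + 1L]) dfs(nx, depth + 1L)
      }
    }
    visited[cell + 1L] <<- FALSE
  }
  for (start in 0:(n - 1L)) dfs(start, 1L)
  # deduplicate under the 8 grid symmetries
  trs <- dihedral_transforms(W)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  reps <- list()
  for (p in paths) {
    x <- p %% W
    y <- p %/% W
    keys <- vapply(trs, function(tr) {
      xy <- tr(x, y)
      paste(xy[, 1] + W * xy[, 2], collapse = ",")
    }, character(1))
    canon <- min(keys)
    if (is.null(seen[[canon]])) {
      seen[[canon]] <- TRUE
      reps[[length(reps) + 1L]] <- cbind(x = x, y = y)
    }
  }
  out <- lapply(seq_along(reps), function(i) {
    list(id = i, path = reps[[i]], contacts = path_contacts(reps[[i]]))
  })
  class(out) <- "conformation_list"
  out
}

#' @exportS3Method base::print
print.conformation_list <- function(x, ...) {
  cat(length(x), "compact conformations (chain length",
      nrow(x[[1]]$path), ")\n")
  invisible(x)
}

#' Contact energy of a genotype on a conformation
#'
#' Sums the pairwise contact energies over the conformation's contact set,
#' with pair types read off the H/P genotype.
#'
#' @param g Genotype: a string like `"HPPH..."` or a character vector of
#'   `"H"`/`"P"` residues, of the conformation's chain length.
#' @param conf One element of [enumerate_compact_conformations()].
#' @param potential An [hp_potential()].
#' @return Scalar energy `G`.
#' @export
conformation_energy <- function(g, conf, potential = hp_potential()) {
  if (length(g) == 1L && nchar(g) > 1L) g <- strsplit(g, "")[[1]]
  L <- nrow(conf$path)
  if (length(g) != L)
    stop("genotype length ", length(g), " does not match chain length ", L)
  if (!all(g %in% c("H", "P"))) stop("genotype must be over {H, P}")
  if (nrow(conf$contacts) == 0L) return(0)
  sum(potential[cbind(g[conf$contacts[, 1]], g[conf$contacts[, 2]])])
}

#' Energy matrix of all genotypes against all conformations
#'
#' Exhaustively evaluates `G[g, p]` for every H/P genotype (canonical
#' enumeration order of the `K = 2` space with alphabet `H`, `P`) and every
#' conformation, vectorised over genotypes.
#'
#' @param confs A [enumerate_compact_conformations()] result.
#' @param potential An [hp_potential()].
#' @return List with `E` (`2^(W^2) x n_conf` matrix) and `space`.
#' @export
lattice_energy_matrix <- function(confs = enumerate_compact_conformations(4),
                                  potential = hp_potential()) {
  L <- nrow(confs[[1]]$path)
  space <- genotype_space(L, alphabet = c("H", "P"))
  h <- 1 - genotype_index_matrix(space)  # 1 where residue is H
  storage.mode(h) <- "double"
  n <- nrow(h)
  E <- matrix(0, n, length(confs))
  cHH <- potential["H", "H"]
  cHP <- potential["H", "P"]
  cPP <- potential["P", "P"]
  for (ci in seq_along(confs)) {
    contacts <- confs[[ci]]$contacts
    e <- numeric(n)
    for (r in seq_len(nrow(contacts))) {
      hi <- h[, contacts[r, 1]]
      hj <- h[, contacts[r, 2]]
      hh <- hi * hj
      e <- e + cHH * hh + cHP * (hi + hj - 2 * hh) +
        cPP * (1 - hi - hj + hh)
    }
    E[, ci] <- e
  }
  list(E = E, space = space)
}

row_mins <- function(M) {
  do.call(pmin, lapply(seq_len(ncol(M)), function(j) M[, j]))
}

#' Fraction of genotypes with a degenerate ground state
#'
#' The fraction of H/P genotypes whose two lowest conformation energies lie
#' within `tol` of each other — i.e. whose minimum energy is attained by
#' more than one compact conformation. With the Li et al. potential on the
#' 4x4 lattice this is about 62% of the 65536 genotypes, which is why the
#' lattice map behaves like a high-stochasticity ensemble model.
#'
#' @param E Energy matrix from [lattice_energy_matrix()] (or the list it
#'   returns).
#' @param tol Degeneracy tolerance (default `1e-4`; energies are short sums
#'   of the discrete contact values, so this is safe).
#' @return Scalar fraction in `[0, 1]`.
#' @export
ground_state_degeneracy <- function(E, tol = 1e-4) {
  if (is.list(E)) E <- E$E
  m1 <- row_mins(E)
  n_min <- rowSums(E - m1 < tol)
  mean(n_min > 1)
}

#' Build the full lattice-protein ND GP map
#'
#' Boltzmann ensembles over all compact conformations for every H/P
#' genotype, at dimensionless temperature `kBT`, with the standard
#' probability floor.
#'
#' @param kBT Dimensionless temperature (> 0). The figure temperatures of
#'   the source models are not pinned down; `c(0.5, 1, 2)` is a reasonable
#'   sweep and `1` a reasonable single choice.
#' @param potential An [hp_potential()].
#' @param confs Conformation list (4x4 by default).
#' @param cutoff Probability floor (default `1e-4`).
#' @return A [gp_map()] with conformation ids as phenotype labels; the
#'   energy matrix is attached as attribute `"E"`.
#' @export
build_lattice_map <- function(kBT = 1, potential = hp_potential(),
                              confs = enumerate_compact_conformations(4),
                              cutoff = 1e-4) {
  if (!is.numeric(kBT) || kBT <= 0) stop("`kBT` must be positive")
  em <- lattice_energy_matrix(confs, potential)
  E <- em$E
  W0 <- exp(-(E - row_mins(E)) / kBT)
  P <- W0 / rowSums(W0)
  map <- gp_map(
    em$space, P, labels = paste0("c", seq_along(confs)),
    cutoff = cutoff, apply = TRUE,
    provenance = list(model = "lattice_protein", W = sqrt(nrow(confs[[1]]$path)),
                      kBT = kBT,
                      potential = list(cHH = potential["H", "H"],
                                       cHP = potential["H", "P"],
                                       cPP = potential["P", "P"]))
  )
  attr(map, "E") <- E
  map
}

#' Export a conformation list as a TSV table
#'
#' One row per conformation: id, the 0-based path coordinates
#' (`x0,y0;x1,y1;...`) and the contact pairs (`i-j;...`).
#'
#' @param confs A [enumerate_compact_conformations()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_conformations <- function(confs, path) {
  rows <- vapply(confs, function(cf) {
    coords <- paste(cf$path[, 1], cf$path[, 2], sep = ",", collapse = ";")
    contacts <- if (nrow(cf$contacts)) {
      paste(cf$contacts[, 1], cf$contacts[, 2], sep = "-", collapse = ";")
    } else ""
    paste(cf$id, coords, contacts, sep = "\t")
  }, character(1))
  writeLines(c("id\tpath\tcontacts", rows), path)
  invisible(path)
}
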