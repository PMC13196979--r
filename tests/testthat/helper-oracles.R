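# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity with plain loops over dense matrices, sharing no
# code with the package kernels.

random_gp_map <- function(L, K, n_p, seed, cutoff = 0) {
  set.seed(seed)
  sp <- genotype_space(L, K)
  W <- matrix(stats::rexp(sp$n_genotypes * n_p), sp$n_genotypes, n_p)
  P <- W / rowSums(W)
  gp_map(sp, P, labels = as.character(seq_len(n_p) - 1L),
         cutoff = cutoff, apply = TRUE)
}

dense_P <- function(map, drop_undefined = TRUE) {
  P <- as.matrix(map$P)
  labels <- map$labels
  if (drop_undefined && !is.na(map$undefined)) {
    keep <- labels != map$undefined
    P <- P[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  colnames(P) <- labels
  P
}

# The five ensemble-map quantities by direct quadruple loops.
oracle_properties <- function(map) {
  P <- dense_P(map)
  sp <- map$space
  n <- sp$n_genotypes
  np <- ncol(P)
  nbr <- neighbour_index_matrix(sp) + 1L
  d <- ncol(nbr)
  f <- colSums(P) / n
  rho_g <- numeric(n)
  eps_g <- numeric(n)
  num_p <- numeric(np)
  for (g in seq_len(n)) {
    nb <- nbr[g, ]
    for (p in seq_len(np)) {
      s <- sum(P[nb, p])
      rho_g[g] <- rho_g[g] + P[g, p] * s
      num_p[p] <- num_p[p] + P[g, p] * s
      if (P[g, p] > 0) {
        acc <- 0
        for (p2 in seq_len(np)) {
          if (p2 == p) next
          acc <- acc + (1 - prod(1 - P[nb, p2]))
        }
        eps_g[g] <- eps_g[g] + P[g, p] * acc
      }
    }
  }
  rho_g <- rho_g / d
  rho_p <- ifelse(f > 0, num_p / (n * f * d), NA_real_)
  eps_p <- numeric(np)
  for (p in seq_len(np)) {
    for (p2 in seq_len(np)) {
      if (p2 == p) next
      lg <- 0
      for (g in seq_len(n)) {
        if (P[g, p] == 0) next
        for (g2 in nbr[g, ]) lg <- lg + log1p(-P[g, p] * P[g2, p2])
      }
      eps_p[p] <- eps_p[p] + (1 - exp(lg))
    }
  }
  list(f = f, rho_g = rho_g, rho_p = rho_p, eps_g = eps_g, eps_p = eps_p)
}

# Classic deterministic-map properties for a genotype -> phenotype
# assignment (character vector over the canonical enumeration order).
oracle_deterministic_properties <- function(assignment, space) {
  nbr <- neighbour_index_matrix(space) + 1L
  n <- space$n_genotypes
  d <- ncol(nbr)
  phen <- sort(unique(assignment))
  f <- vapply(phen, function(p) mean(assignment == p), numeric(1))
  rho_g <- vapply(seq_len(n), function(g)
    mean(assignment[nbr[g, ]] == assignment[g]), numeric(1))
  rho_p <- vapply(phen, function(p)
    mean(rho_g[assignment == p]), numeric(1))
  eps_g <- vapply(seq_len(n), function(g)
    length(setdiff(unique(assignment[nbr[g, ]]), assignment[g])),
    numeric(1))
  eps_p <- vapply(phen, function(p) {
    reach <- unique(unlist(lapply(which(assignment == p),
                                  function(g) assignment[nbr[g, ]])))
    length(setdiff(reach, p))
  }, numeric(1))
  list(phen = phen, f = f, rho_g = rho_g, rho_p = rho_p,
       eps_g = eps_g, eps_p = eps_p)
}

# Iterative (stack-based) directed Hamiltonian path enumerator on the W x W
# grid, with symmetry classes counted through an orbit set built from raw
# coordinate strings. Independent of the recursive package enumerator.
oracle_hamiltonian <- function(W) {
  n <- W * W
  adj <- vector("list", n)
  for (cell in 0:(n - 1)) {
    x <- cell %% W; y <- cell %/% W
    nb <- c()
    if (x > 0) nb <- c(nb, cell - 1)
    if (x < W - 1) nb <- c(nb, cell + 1)
    if (y > 0) nb <- c(nb, cell - W)
    if (y < W - 1) nb <- c(nb, cell + W)
    adj[[cell + 1]] <- nb
  }
  paths <- list()
  extend <- function(path, visited) {
    if (length(path) == n) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    cur <- path[length(path)]
    for (cand in adj[[cur + 1]]) {
      if (!visited[cand + 1]) {
        visited[cand + 1] <- TRUE
        extend(c(path, cand), visited)
        visited[cand + 1] <- FALSE
      }
    }
  }
  for (start in 0:(n - 1)) {
    v <- logical(n)
    v[start + 1] <- TRUE
    extend(start, v)
  }
  paths
}

# symmetry classes of directed paths under the dihedral group (direction
# kept), built from the orbit of coordinate strings
oracle_path_classes <- function(paths, W) {
  w <- W - 1
  orbit_key <- function(p) {
    x <- p %% W; y <- p %/% W
    views <- list(cbind(x, y), cbind(y, w - x), cbind(w - x, w - y),
                  cbind(w - y, x), cbind(w - x, y), cbind(x, w - y),
                  cbind(y, x), cbind(w - y, w - x))
    min(vapply(views, function(v) paste(v[, 1] + W * v[, 2],
                                        collapse = "."), character(1)))
  }
  unique(vapply(paths, orbit_key, character(1)))
}

# Brute-force RNA structure enumerator: builds every subset of candidate
# pairs and filters for compatibility (shared bases, crossings).
oracle_rna_structures <- function(seq, min_hairpin = 3) {
  bases <- strsplit(toupper(seq), "")[[1]]
  L <- length(bases)
  ok <- function(a, b) paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  cand <- list()
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (j - i > min_hairpin && ok(bases[i], bases[j]))
        cand[[length(cand) + 1]] <- c(i, j)
    }
  }
  compatible <- function(pair, chosen) {
    for (q in chosen) {
      if (any(pair %in% q)) return(FALSE)
      i <- pair[1]; j <- pair[2]; a <- q[1]; b <- q[2]
      if ((i < a && a < j && j < b) || (a < i && i < b && b < j))
        return(FALSE)
    }
    TRUE
  }
  res <- list()
  recurse <- function(k, chosen) {
    if (k > length(cand)) {
      res[[length(res) + 1]] <<- chosen
      return(invisible())
    }
    recurse(k + 1, chosen)
    if (compatible(cand[[k]], chosen)) recurse(k + 1, c(chosen, cand[k]))
  }
  recurse(1, list())
  vapply(res, function(chosen) {
    db <- rep(".", L)
    for (q in chosen) { db[q[1]] <- "("; db[q[2]] <- ")" }
    paste(db, collapse = "")
  }, character(1))
}

# direct adjacency scan for chain contacts, |i-j| > 1
path_contacts_oracle <- function(path) {
  L <- nrow(path)
  out <- matrix(0L, 0L, 2L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (j > i + 1 &&
          sum(abs(path[i, ] - path[j, ])) == 1) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  out
}
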