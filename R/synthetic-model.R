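#' Specification of a synthetic ND GP map
#'
#' The synthetic model maps each genotype, encoded as an `L`-dimensional
#' vector of +1/-1 spins, to an energy-like scalar per phenotype,
#' `G_p(g) = -(g . v_p)` (plus an optional phenotype constant), and converts
#' the `n_p` scalars of a genotype into a probability ensemble with a
#' Boltzmann-like nonlinearity controlled by the stochasticity `T`. Low `T`
#' concentrates each ensemble on the lowest-`G` phenotype; `T = Inf` is the
#' fully stochastic limit with every probability equal to `1/n_p`.
#'
#' @param L Sequence length.
#' @param n_p Number of phenotypes (`>= 1`).
#' @param T Stochasticity: a non-negative number, or `Inf` for the symbolic
#'   fully stochastic limit, or `NULL` (default) to defer to the mean-gap
#'   reference rule [reference_T()] at build time.
#' @param K Alphabet size; the standard model uses `K = 2` (spins). `K > 2`
#'   generalises the parameters to a per-(phenotype, position, symbol)
#'   coefficient tensor whose `K = 2` special case with coefficients
#'   `{+v, -v}` recovers the dot-product form exactly.
#' @param form Functional form turning `G` values into ensemble weights:
#'   one of `"boltzmann"` (default), `"linear"`, `"inverse_squared"`,
#'   `"gaussian"`, `"relu"`, `"softplus"`. See [ensemble_from_G()].
#' @param init Parameter initialisation scheme: `"normal"` (default;
#'   elementwise N(1, 1)), `"lognormal"` (meanlog 0, sdlog 1), `"uniform"`
#'   (on \[0, 1\]), `"normalized_normal"` (normal draws rescaled so every
#'   vector has the pre-rescaling mean norm), `"binary"` (0.25 or 0.75 with
#'   equal probability), `"normal_with_offset"` (normal draws plus one
#'   N(1, 1) additive constant per phenotype).
#' @param seed RNG seed (integer); the whole map is reproducible
#'   bit-for-bit given the spec and seed.
#' @param cutoff Probability floor applied to built maps (default `1e-4`).
#'
#' @return An object of class `"synthetic_spec"`.
#' @seealso [build_synthetic_map()], [init_parameter_vectors()]
#' @export
synthetic_spec <- function(L, n_p, T = NULL, K = 2, form = "boltzmann",
                           init = "normal", seed = 1L, cutoff = 1e-4) {
  form <- match.arg(form, c("boltzmann", "linear", "inverse_squared",
                            "gaussian", "relu", "softplus"))
  init <- match.arg(init, c("normal", "lognormal", "uniform",
                            "normalized_normal", "binary",
                            "normal_with_offset"))
  if (!is.numeric(n_p) || n_p < 1 || n_p != round(n_p))
    stop("`n_p` must be a positive integer")
  if (!is.null(T)) {
    if (!is.numeric(T) || length(T) != 1L || is.na(T) || T < 0)
      stop("`T` must be a non-negative number, Inf, or NULL")
  }
  structure(
    list(L = as.integer(L), K = as.integer(K), n_p = as.integer(n_p),
         T = T, form = form, init = init, seed = as.integer(seed),
         cutoff = cutoff),
    class = "synthetic_spec"
  )
}

#' @exportS3Method base::print
print.synthetic_spec <- function(x, ...) {
  cat("synthetic ND GP map spec: L =", x$L, ", K =", x$K, ", n_p =", x$n_p,
      "\n  T =", if (is.null(x$T)) "(mean-gap rule)" else format(x$T),
      ", form =", x$form, ", init =", x$init, ", seed =", x$seed, "\n")
  invisible(x)
}

#' Draw the phenotype parameter vectors
#'
#' Draws the `n_p x L` parameter matrix `V` (row `p` is `v_p`) according to
#' the spec's initialisation scheme. Draw order is fixed as phenotype-major,
#' position-minor from a single generator seeded once, so parameter sets are
#' stable across versions. For `K > 2` an `n_p x L x K` coefficient tensor
#' is drawn instead (phenotype-major, then position, then symbol).
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `"parameter_set"` with elements `V` (matrix, or
#'   3-d array when `K > 2`), `offsets` (length-`n_p` vector, only for
#'   `init = "normal_with_offset"`) and the generating `spec`.
#' @export
init_parameter_vectors <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_draw <- spec$n_p * spec$L * (if (spec$K > 2L) spec$K else 1L)
  draw <- function(n) {
    switch(spec$init,
      normal = ,
      normal_with_offset = ,
      normalized_normal = stats::rnorm(n, mean = 1, sd = 1),
      lognormal = stats::rlnorm(n, meanlog = 0, sdlog = 1),
      uniform = stats::runif(n, 0, 1),
      binary = sample(c(0.25, 0.75), n, replace = TRUE)
    )
  }
  offsets <- NULL
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  vals <- draw(n_draw)
  if (spec$K > 2L) {
    # index order: symbol fastest, then position, then phenotype
    V <- aperm(array(vals, dim = c(spec$K, spec$L, spec$n_p)), c(3, 2, 1))
  } else {
    V <- matrix(vals, nrow = spec$n_p, ncol = spec$L, byrow = TRUE)
  }
  if (spec$init == "normalized_normal") {
    if (spec$K > 2L)
      stop("normalized_normal initialisation is defined for K = 2")
    norms <- sqrt(rowSums(V^2))
    V <- V * (mean(norms) / norms)
  }
  if (spec$init == "normal_with_offset") {
    offsets <- stats::rnorm(spec$n_p, mean = 1, sd = 1)
  }
  structure(list(V = V, offsets = offsets, spec = spec),
            class = "parameter_set")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Energy-like scalars G for every genotype and phenotype
#'
#' For binary spaces, `G[g, p] = -(g . v_p) + offset_p` with `g` the +1/-1
#' spin vector of the genotype. For `K > 2`, position `i` carrying symbol
#' `s` contributes `-coef[p, i, s]`.
#'
#' @param params A `parameter_set` from [init_parameter_vectors()].
#' @param space A [genotype_space()] matching the spec's `L` and `K`.
#' @return Numeric matrix `K^L x n_p`.
#' @export
compute_G <- function(params, space) {
  stopifnot(inherits(params, "parameter_set"),
            inherits(space, "genotype_space"))
  spec <- params$spec
  if (space$L != spec$L || space$K != spec$K)
    stop("genotype space does not match the model spec (L, K)")
  if (spec$K == 2L) {
    S <- spin_matrix(space)                       # n x L
    G <- -S %*% t(params$V)                       # n x n_p
  } else {
    idx <- genotype_index_matrix(space)           # n x L, 0-based symbols
    n <- space$n_genotypes
    G <- matrix(0, n, spec$n_p)
    for (i in seq_len(space$L)) {
      # coef slice for position i: n_p x K
      ci <- params$V[, i, , drop = TRUE]
      if (is.null(dim(ci))) ci <- matrix(ci, nrow = spec$n_p)
      G <- G - t(ci)[idx[, i] + 1L, , drop = FALSE]
    }
  }
  if (!is.null(params$offsets))
    G <- sweep(G, 2L, params$offsets, "+")
  if (any(!is.finite(G))) stop("non-finite G values")
  unname(as.matrix(G))
}

#' Convert G scalars to a phenotype ensemble
#'
#' Applies one of six functional forms to a genotype's `G` values (or to a
#' whole `K^L x n_p` matrix of them, row-wise) and normalises to a
#' probability distribution. All forms are non-negative, give weakly higher
#' probability to lower `G`, and approach the uniform ensemble `1/n_p` as
#' `T` grows; `T = Inf` returns the uniform ensemble exactly.
#'
#' Forms (weights before normalisation, per genotype row):
#' * `boltzmann`: `exp(-G/T)`, computed with a minimum shift for overflow
#'   safety;
#' * `linear`: `G_max - G + T` (shifted linear numerator; nonlinear once
#'   normalised);
#' * `inverse_squared`: `(G - G_min + T)^-2`;
#' * `gaussian`: `exp(-(G - G_min)^2 / T)`;
#' * `relu`: `max(T - G, 0)`; a genotype whose weights are all zero is
#'   assigned the uniform ensemble and counted in a warning (the map stays
#'   total, mirroring the `T = Inf` convention);
#' * `softplus`: `log(1 + exp(T - G))`, evaluated stably.
#'
#' @param G Numeric vector (one genotype) or matrix (rows = genotypes).
#' @param T Stochasticity; `Inf` for the uniform limit. `T = 0` is rejected
#'   for the forms that divide by `T` — use [deterministic_projection()]
#'   for the deterministic limit.
#' @param form One of the six forms above.
#' @return Probabilities with the same shape as `G`, each genotype summing
#'   to 1 within `1e-9`.
#' @examples
#' ensemble_from_G(c(0, log(2)), T = 1, form = "boltzmann")  # 2/3, 1/3
#' @export
ensemble_from_G <- function(G, T, form = "boltzmann") {
  form <- match.arg(form, c("boltzmann", "linear", "inverse_squared",
                            "gaussian", "relu", "softplus"))
  vec <- is.null(dim(G))
  if (vec) G <- matrix(G, nrow = 1L)
  n_p <- ncol(G)
  if (is.infinite(T)) {
    W <- matrix(1 / n_p, nrow(G), n_p)
    return(if (vec) W[1L, ] else W)
  }
  if (T < 0) stop("`T` must be non-negative")
  if (T == 0 && form %in% c("boltzmann", "gaussian", "inverse_squared"))
    stop("T = 0 is the deterministic limit; use deterministic_projection()")
  rmin <- if (n_p > 1L) do.call(pmin, lapply(seq_len(n_p), function(j) G[, j]))
          else G[, 1L]
  W <- switch(form,
    boltzmann = exp(-(G - rmin) / T),
    linear = {
      rmax <- if (n_p > 1L)
        do.call(pmax, lapply(seq_len(n_p), function(j) G[, j])) else G[, 1L]
      rmax - G + T
    },
    inverse_squared = (G - rmin + T)^-2,
    gaussian = exp(-(G - rmin)^2 / T),
    relu = pmax(T - G, 0),
    softplus = {
      x <- T - G
      ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
    }
  )
  s <- rowSums(W)
  degenerate <- s == 0
  if (any(degenerate)) {
    if (form != "relu")
      stop("degenerate genotype with all-zero weights for form ", form)
    warning(sum(degenerate), " genotype(s) with all ReLU weights zero ",
            "assigned the uniform ensemble")
    W[degenerate, ] <- 1
    s[degenerate] <- n_p
  }
  W <- W / s
  if (vec) W[1L, ] else W
}

#' Mean-gap reference stochasticity
#'
#' The genotypic average of the difference between the two lowest `G`
#' values. Used as the default `T` so that maps with different `n_p` or
#' parameter initialisations have a comparable level of non-determinism.
#'
#' @param params A `parameter_set` from [init_parameter_vectors()].
#' @param space Matching [genotype_space()].
#' @return Non-negative scalar.
#' @export
reference_T <- function(params, space) {
  if (params$spec$n_p < 2L)
    stop("the mean-gap rule requires at least two phenotypes")
  G <- compute_G(params, space)
  n_p <- ncol(G)
  cols <- lapply(seq_len(n_p), function(j) G[, j])
  m1 <- do.call(pmin, cols)
  first_min <- max.col(-G, ties.method = "first")
  G2 <- G
  G2[cbind(seq_len(nrow(G)), first_min)] <- Inf
  m2 <- do.call(pmin, lapply(seq_len(n_p), function(j) G2[, j]))
  mean(m2 - m1)
}

#' Build a synthetic ND GP map
#'
#' Draws the parameters, computes `G`, applies the functional form at the
#' spec's stochasticity (or at the [reference_T()] mean-gap value when the
#' spec leaves `T = NULL`) and applies the probability floor. The realised
#' spec, seed and `T` are recorded in the map provenance.
#'
#' @param spec A [synthetic_spec()].
#' @param space Optional pre-built [genotype_space()] (constructed from the
#'   spec by default).
#' @param params Optional pre-drawn `parameter_set`.
#' @return A [gp_map()], with the `parameter_set` attached as attribute
#'   `"params"` and the realised stochasticity as attribute `"T"`.
#' @examples
#' m <- build_synthetic_map(synthetic_spec(L = 4, n_p = 3, T = 1, seed = 7))
#' @export
build_synthetic_map <- function(spec, space = NULL, params = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(space)) space <- genotype_space(spec$L, spec$K)
  if (is.null(params)) params <- init_parameter_vectors(spec)
  G <- compute_G(params, space)
  T_used <- if (is.null(spec$T)) reference_T(params, space) else spec$T
  P <- ensemble_from_G(G, T_used, spec$form)
  map <- gp_map(
    space, P, labels = as.character(seq_len(spec$n_p) - 1L),
    cutoff = spec$cutoff, apply = TRUE,
    provenance = list(model = "synthetic", L = spec$L, K = spec$K,
                      n_p = spec$n_p, T = T_used, form = spec$form,
                      init = spec$init, seed = spec$seed)
  )
  attr(map, "params") <- params
  attr(map, "T") <- T_used
  map
}

#' Deterministic (T -> 0) projection of a synthetic model
#'
#' Maps each genotype to its lowest-`G` phenotype. When the two lowest `G`
#' values differ by less than `tie_tol` the genotype is assigned the
#' "undefined" placeholder phenotype, which is excluded from all property
#' sums downstream.
#'
#' @param params A `parameter_set`.
#' @param space Matching [genotype_space()].
#' @param tie_tol Tie tolerance (default `1e-4`).
#' @return A [gp_map()] with one probability-1 entry per genotype and an
#'   `"undefined"` phenotype where ties occur.
#' @export
deterministic_projection <- function(params, space, tie_tol = 1e-4) {
  if (tie_tol < 0) stop("`tie_tol` must be non-negative")
  G <- compute_G(params, space)
  n <- nrow(G)
  n_p <- ncol(G)
  amin <- max.col(-G, ties.method = "first")
  m1 <- G[cbind(seq_len(n), amin)]
  if (n_p > 1L) {
    G2 <- G
    G2[cbind(seq_len(n), amin)] <- Inf
    m2 <- do.call(pmin, lapply(seq_len(n_p), function(j) G2[, j]))
    tied <- (m2 - m1) < tie_tol
  } else {
    tied <- rep(FALSE, n)
  }
  labels <- c(as.character(seq_len(n_p) - 1L), "undefined")
  j <- ifelse(tied, n_p + 1L, amin)
  P <- Matrix::sparseMatrix(i = seq_len(n), j = j, x = 1,
                            dims = c(n, n_p + 1L))
  keep_undef <- any(tied)
  if (!keep_undef) {
    P <- P[, seq_len(n_p), drop = FALSE]
    labels <- labels[seq_len(n_p)]
  }
  gp_map(space, P, labels,
         undefined = if (keep_undef) "undefined" else NA_character_,
         cutoff = 0, apply = FALSE,
         provenance = list(model = "synthetic_deterministic",
                           L = params$spec$L, K = params$spec$K,
                           n_p = params$spec$n_p, init = params$spec$init,
                           seed = params$spec$seed, tie_tol = tie_tol))
}
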