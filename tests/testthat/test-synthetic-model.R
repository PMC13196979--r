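test_that("parameter initialisation honours each scheme", {
  base <- function(init, n_p = 500, L = 15, seed = 5)
    init_parameter_vectors(synthetic_spec(L = L, n_p = n_p, T = 1,
                                          init = init, seed = seed))
  # normalised normal: all row norms identical (the pre-rescaling mean norm)
  V <- base("normalized_normal")$V
  norms <- sqrt(rowSums(V^2))
  expect_lt(max(norms) - min(norms), 1e-12)
  # binary: only the two discrete values
  expect_true(all(base("binary")$V %in% c(0.25, 0.75)))
  # normal: z-test of the sample mean against the declared N(1, 1)
  Vn <- base("normal")$V
  z <- (mean(Vn) - 1) / (1 / sqrt(length(Vn)))
  expect_lt(abs(z), 3)
  # lognormal draws are positive with log-scale mean near 0
  Vl <- base("lognormal")$V
  expect_true(all(Vl > 0))
  expect_lt(abs(mean(log(Vl))) / (1 / sqrt(length(Vl))), 3)
  # uniform stays in [0, 1]
  Vu <- base("uniform")$V
  expect_true(all(Vu >= 0 & Vu <= 1))
  # offsets present only for normal_with_offset
  expect_null(base("normal")$offsets)
  expect_length(base("normal_with_offset", n_p = 20)$offsets, 20L)
  # deterministic given the seed
  expect_identical(base("normal")$V, base("normal")$V)
})

test_that("G is the negated spin dot product (plus optional offset)", {
  sp <- genotype_space(3, 2)
  spec <- synthetic_spec(L = 3, n_p = 2, T = 1, seed = 1)
  params <- init_parameter_vectors(spec)
  params$V <- rbind(c(1, 1, 1), c(2, 2, 2))
  G <- compute_G(params, sp)
  expect_equal(G[1, 1], -3)              # all-(+1) genotype, v = (1,1,1)
  # (+1, -1) cancellation case via an L = 2 space
  sp2 <- genotype_space(2, 2)
  spec2 <- synthetic_spec(L = 2, n_p = 1, T = 1, seed = 1)
  p2 <- init_parameter_vectors(spec2)
  p2$V <- matrix(c(2, 2), 1)
  G2 <- compute_G(p2, sp2)
  expect_equal(G2[2, 1], 0)              # spins (+1, -1)
  # random case against an explicit elementwise loop
  spec15 <- synthetic_spec(L = 15, n_p = 7, T = 1, seed = 3)
  p15 <- init_parameter_vectors(spec15)
  sp15 <- genotype_space(15, 2)
  G15 <- compute_G(p15, sp15)
  S <- spin_matrix(sp15)
  some_g <- c(1, 999, 32768)
  for (g in some_g) for (p in 1:7) {
    acc <- 0
    for (i in 1:15) acc <- acc - S[g, i] * p15$V[p, i]
    expect_equal(G15[g, p], acc)
  }
  # offsets shift columns
  p15$offsets <- seq_len(7)
  Goff <- compute_G(p15, sp15)
  expect_equal(Goff, G15 + rep(seq_len(7), each = nrow(G15)))
})

test_that("ensemble_from_G matches closed-form examples and a per-form oracle", {
  expect_equal(ensemble_from_G(c(0, log(2)), T = 1), c(2 / 3, 1 / 3))
  expect_equal(ensemble_from_G(c(0, 1, 2), T = 1, form = "inverse_squared"),
               c(36, 9, 4) / 49)
  expect_equal(ensemble_from_G(rnorm(5), T = Inf), rep(0.2, 5))
  # slow one-phenotype-at-a-time re-evaluation of each published form
  set.seed(9)
  G <- rnorm(8, sd = 2)
  T <- 0.7
  oracle <- list(
    boltzmann = exp(-G / T),
    linear = max(G) - G + T,
    inverse_squared = (G - min(G) + T)^-2,
    gaussian = exp(-(G - min(G))^2 / T),
    relu = pmax(T - G, 0),
    softplus = log(1 + exp(T - G))
  )
  for (form in names(oracle)) {
    expect_equal(ensemble_from_G(G, T, form),
                 oracle[[form]] / sum(oracle[[form]]),
                 tolerance = 1e-12, label = form)
  }
})

test_that("all forms normalise and are monotone non-increasing in G", {
  forms <- c("boltzmann", "linear", "inverse_squared", "gaussian",
             "relu", "softplus")
  set.seed(2)
  for (form in forms) {
    for (T in c(0.3, 1, 10)) {
      G <- matrix(rnorm(50 * 8, sd = 3), 50, 8)
      P <- ensemble_from_G(G, T, form)
      expect_true(all(P >= 0))
      expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
      for (g in 1:50) {
        ord <- order(G[g, ])
        expect_true(all(diff(P[g, ord]) <= 1e-12),
                    label = paste(form, "monotone"))
      }
    }
  }
})

test_that("degenerate all-zero ReLU genotypes get the uniform ensemble with a warning", {
  G <- rbind(c(5, 6, 7), c(0, 1, 2))  # first row entirely above T
  expect_warning(P <- ensemble_from_G(G, T = 1, form = "relu"), "ReLU")
  expect_equal(P[1, ], rep(1 / 3, 3))
  expect_equal(sum(P[2, ]), 1)
})

test_that("T = 0 is rejected for forms that divide by T", {
  expect_error(ensemble_from_G(c(0, 1), T = 0, form = "boltzmann"),
               "deterministic_projection")
})

test_that("reference_T is the genotypic mean gap between the two lowest G values", {
  # identical parameter vectors: all gaps zero
  sp <- genotype_space(3, 2)
  spec <- synthetic_spec(L = 3, n_p = 3, T = 1, seed = 1)
  params <- init_parameter_vectors(spec)
  params$V <- matrix(1, 3, 3)
  expect_equal(reference_T(params, sp), 0)
  # two phenotypes, L = 1: v = (1) and (3) give gap 2 for both genotypes
  sp1 <- genotype_space(1, 2)
  spec1 <- synthetic_spec(L = 1, n_p = 2, T = 1, seed = 1)
  p1 <- init_parameter_vectors(spec1)
  p1$V <- matrix(c(1, 3), 2, 1)
  expect_equal(reference_T(p1, sp1), 2)
  # random parameters against a per-genotype sort-and-difference oracle
  spec8 <- synthetic_spec(L = 8, n_p = 6, T = 1, seed = 7)
  p8 <- init_parameter_vectors(spec8)
  sp8 <- genotype_space(8, 2)
  G <- compute_G(p8, sp8)
  gaps <- apply(G, 1, function(r) { s <- sort(r); s[2] - s[1] })
  expect_equal(reference_T(p8, sp8), mean(gaps))
  expect_error(reference_T(init_parameter_vectors(
    synthetic_spec(L = 2, n_p = 1, T = 1)), genotype_space(2, 2)),
    "two phenotypes")
})

test_that("build_synthetic_map composes G, the functional form and the cutoff", {
  spec <- synthetic_spec(L = 4, n_p = 3, T = 0.5, seed = 21)
  m <- build_synthetic_map(spec)
  params <- attr(m, "params")
  sp <- m$space
  P_o <- ensemble_from_G(compute_G(params, sp), 0.5, "boltzmann")
  P_o[P_o < 1e-4] <- 0
  expect_equal(unname(as.matrix(m$P)), P_o, tolerance = 1e-12)
  # bit-for-bit reproducibility from the same spec
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gpmap(m, f1)
  write_gpmap(build_synthetic_map(spec), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the fully stochastic limit produces exactly uniform ensembles", {
  m <- build_synthetic_map(synthetic_spec(L = 15, n_p = 100, T = Inf,
                                          seed = 2))
  expect_true(all(m$P@x == 1 / 100))
  f <- phenotypic_frequency(m)
  expect_equal(unname(f), rep(1 / 100, 100))
})

test_that("increasing T drives ensembles monotonically towards uniform", {
  spec0 <- synthetic_spec(L = 8, n_p = 20, T = 1, seed = 4)
  params <- init_parameter_vectors(spec0)
  sp <- genotype_space(8, 2)
  G <- compute_G(params, sp)
  dev <- vapply(10^(0:6), function(T)
    max(abs(ensemble_from_G(G, T, "boltzmann") - 1 / 20)), numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[length(dev)], 1e-3)
})

test_that("deterministic projection assigns argmin-G phenotypes with tie handling", {
  sp <- genotype_space(4, 2)
  spec <- synthetic_spec(L = 4, n_p = 2, T = 1, seed = 6)
  params <- init_parameter_vectors(spec)
  # identical rows: every genotype is an exact tie -> undefined
  params$V <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  dm <- deterministic_projection(params, sp)
  expect_identical(dm$undefined, "undefined")
  expect_equal(sum(dm$P[, dm$labels == "undefined"]), sp$n_genotypes)
  expect_equal(n_phenotypes_present(dm), 0L)
  # single phenotype: everything maps to phenotype 0
  spec1 <- synthetic_spec(L = 4, n_p = 1, T = 1, seed = 6)
  dm1 <- deterministic_projection(init_parameter_vectors(spec1), sp)
  expect_equal(unname(Matrix::colSums(dm1$P)[1]), sp$n_genotypes)
  # small-T limit of the full model agrees where the ensemble is decisive
  spec6 <- synthetic_spec(L = 6, n_p = 5, T = 1e-6, seed = 8)
  m <- build_synthetic_map(spec6)
  dm6 <- deterministic_projection(attr(m, "params"), genotype_space(6, 2))
  top <- apply(as.matrix(m$P), 1, which.max)
  decisive <- apply(as.matrix(m$P), 1, max) > 0.999
  proj <- apply(as.matrix(dm6$P), 1, which.max)
  expect_true(all((proj == top)[decisive & dm6$labels[proj] != "undefined"]))
})

test_that("G values of mutational neighbours correlate more than random pairs", {
  spec <- synthetic_spec(L = 10, n_p = 30, T = 1, seed = 12)
  sp <- genotype_space(10, 2)
  G <- compute_G(init_parameter_vectors(spec), sp)
  nbr <- neighbour_index_matrix(sp) + 1L
  set.seed(1)
  g <- sample.int(sp$n_genotypes, 2000, replace = TRUE)
  g2 <- nbr[cbind(g, sample.int(ncol(nbr), 2000, replace = TRUE))]
  h <- sample.int(sp$n_genotypes, 2000, replace = TRUE)
  r_nb <- cor(as.vector(G[g, ]), as.vector(G[g2, ]))
  r_null <- cor(as.vector(G[g, ]), as.vector(G[h, ]))
  expect_gt(r_nb, 0)
  expect_gt(r_nb, r_null)
})

test_that("K = 4 coefficient tensors degenerate to the spin model at K = 2", {
  # a K = 4 map builds, normalises and respects the cutoff
  spec <- synthetic_spec(L = 4, n_p = 6, T = 1, K = 4, seed = 3)
  m <- build_synthetic_map(spec)
  expect_equal(m$space$n_genotypes, 256)
  params <- attr(m, "params")
  expect_equal(dim(params$V), c(6, 4, 4))
  G <- compute_G(params, m$space)
  idx <- genotype_index_matrix(m$space)
  g <- 137
  for (p in 1:6) {
    acc <- 0
    for (i in 1:4) acc <- acc - params$V[p, i, idx[g, i] + 1]
    expect_equal(G[g, p], acc)
  }
})
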