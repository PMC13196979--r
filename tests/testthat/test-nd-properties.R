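test_that("all five map quantities equal brute-force oracles on random maps", {
  cases <- expand.grid(L = c(3, 4), K = c(2, 3), n_p = c(2, 5))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      map <- random_gp_map(L, K, n_p, seed = 100 + i, cutoff = 0)
      pr <- gp_properties(map)
      o <- oracle_properties(map)
      expect_equal(pr$phenotypes$f, unname(o$f), tolerance = 1e-9)
      expect_equal(pr$genotypes$rho_g, o$rho_g, tolerance = 1e-9)
      expect_equal(pr$phenotypes$rho, unname(o$rho_p), tolerance = 1e-9)
      expect_equal(pr$genotypes$eps_g, o$eps_g, tolerance = 1e-9)
      expect_equal(pr$phenotypes$eps, unname(o$eps_p), tolerance = 1e-9)
    })
  }
  # with the cutoff applied (sparse ensembles, no renormalisation)
  map <- random_gp_map(4, 2, 8, seed = 77, cutoff = 0.05)
  expect_lt(max(Matrix::rowSums(map$P)), 1 + 1e-12)
  pr <- gp_properties(map)
  o <- oracle_properties(map)
  expect_equal(pr$phenotypes$f, unname(o$f[o$f > 0]), tolerance = 1e-9)
  expect_equal(pr$genotypes$eps_g, o$eps_g, tolerance = 1e-9)
  expect_equal(pr$phenotypes$eps, unname(o$eps_p[o$f > 0]), tolerance = 1e-9)
})

test_that("the undefined phenotype is excluded from sums but keeps its mass", {
  sp <- genotype_space(3, 2)
  set.seed(5)
  W <- matrix(rexp(8 * 3), 8, 3)
  P <- W / rowSums(W)
  m_undef <- gp_map(sp, P, labels = c("a", "b", "undef"),
                    undefined = "undef", cutoff = 0, apply = FALSE)
  # dropping the undefined column by hand must give identical properties
  m_trunc <- gp_map(sp, P[, 1:2], labels = c("a", "b"),
                    cutoff = 0, apply = FALSE, check = FALSE)
  pr1 <- gp_properties(m_undef)
  pr2 <- gp_properties(m_trunc)
  expect_equal(pr1$phenotypes, pr2$phenotypes)
  expect_equal(pr1$genotypes, pr2$genotypes)
  expect_lt(sum(pr1$phenotypes$f), 1)  # undefined mass is not reassigned
  expect_equal(n_phenotypes_present(m_undef), 2L)
})

test_that("a deterministic map embedded as probability-1 ensembles reduces to the classic definitions", {
  sp <- genotype_space(4, 2)
  set.seed(31)
  assignment <- sample(c("x", "y", "z"), sp$n_genotypes, replace = TRUE)
  labels <- sort(unique(assignment))
  P <- Matrix::sparseMatrix(i = seq_len(sp$n_genotypes),
                            j = match(assignment, labels), x = 1,
                            dims = c(sp$n_genotypes, length(labels)))
  m <- gp_map(sp, P, labels, cutoff = 0, apply = FALSE)
  pr <- gp_properties(m)
  o <- oracle_deterministic_properties(assignment, sp)
  expect_equal(pr$phenotypes$f, unname(o$f), tolerance = 1e-9)
  expect_equal(pr$genotypes$rho_g, o$rho_g, tolerance = 1e-9)
  expect_equal(pr$phenotypes$rho, unname(o$rho_p), tolerance = 1e-9)
  expect_equal(pr$genotypes$eps_g, o$eps_g, tolerance = 1e-9)
  expect_equal(pr$phenotypes$eps, unname(o$eps_p), tolerance = 1e-9)
})

test_that("phenotypes never adjacent across genotype blocks have zero evolvability", {
  # L = 1: two genotypes that are mutual neighbours is unavoidable, so use
  # disjoint probability support instead: phenotype a only on genotype 1's
  # side never co-occurs in any neighbourhood with phenotype b's support.
  sp <- genotype_space(2, 2)
  # phenotypes: a lives on genotypes {1}, b on {4}; 1 and 4 are not
  # neighbours (Hamming distance 2), filler phenotype c elsewhere
  P <- rbind(c(1, 0, 0),
             c(0, 0, 1),
             c(0, 0, 1),
             c(0, 1, 0))
  m <- gp_map(sp, P, labels = c("a", "b", "c"), cutoff = 0, apply = FALSE)
  pr <- gp_properties(m)
  eps <- setNames(pr$phenotypes$eps, pr$phenotypes$label)
  # a's only genotype neighbours both carry c, never b
  expect_equal(unname(eps["a"]), 1)  # reaches c only
  o <- oracle_properties(m)
  expect_equal(pr$phenotypes$eps, unname(o$eps_p), tolerance = 1e-12)
})

test_that("neighbour covariance detects genetic correlations and their absence", {
  # genotype-independent map: both covariances are statistically zero
  sp <- genotype_space(5, 2)
  probs <- c(0.5, 0.3, 0.2)
  P <- matrix(probs, sp$n_genotypes, 3, byrow = TRUE)
  m_flat <- gp_map(sp, P, labels = c("a", "b", "c"), cutoff = 0,
                   apply = FALSE)
  cv <- neighbour_covariance(m_flat, n_pairs = 2000, seed = 3)
  expect_true(all(abs(cv$cov_neighbour) < 1e-12))
  expect_true(all(abs(cv$cov_null) < 1e-12))
  # low-T synthetic map: neighbour covariance exceeds the null for most
  # phenotypes
  m <- build_synthetic_map(synthetic_spec(L = 10, n_p = 30, T = 0.5,
                                          seed = 9))
  cv2 <- neighbour_covariance(m, n_pairs = 5000, seed = 4)
  expect_gt(mean(cv2$cov_neighbour > cv2$cov_null), 0.5)
  expect_gt(mean(cv2$cov_neighbour > 0), 0.5)
  # exhaustive mode equals a direct covariance over all ordered pairs
  m3 <- random_gp_map(3, 2, 3, seed = 55, cutoff = 0)
  cva <- neighbour_covariance(m3, n_pairs = "all")
  P3 <- dense_P(m3)
  nbr <- neighbour_index_matrix(m3$space) + 1L
  g <- rep(seq_len(8), each = ncol(nbr))
  g2 <- as.vector(t(nbr))
  for (p in 1:3) {
    expect_equal(cva$cov_neighbour[p], cov(P3[g, p], P3[g2, p]),
                 tolerance = 1e-12)
  }
  expect_error(neighbour_covariance(m3, n_pairs = 1), "n_pairs")
})

test_that("maps where every phenotype has rho > f show positive exhaustive covariance", {
  # two strongly clustered phenotypes: block structure gives rho_p > f_p
  sp <- genotype_space(3, 2)
  idx <- genotype_index_matrix(sp)
  blockA <- idx[, 1] == 0
  P <- cbind(ifelse(blockA, 0.9, 0.1), ifelse(blockA, 0.1, 0.9))
  m <- gp_map(sp, P, labels = c("A", "B"), cutoff = 0, apply = FALSE)
  pr <- gp_properties(m, phenotypic_evolvability = FALSE)
  expect_true(all(pr$phenotypes$rho > pr$phenotypes$f))
  cv <- neighbour_covariance(m, n_pairs = "all")
  expect_true(all(cv$cov_neighbour > 0))
})

test_that("the genotypic trade-off bound holds across map families", {
  maps <- list(
    random_gp_map(4, 2, 6, seed = 1, cutoff = 0),
    random_gp_map(3, 3, 4, seed = 2, cutoff = 1e-2),
    build_synthetic_map(synthetic_spec(L = 8, n_p = 15, T = 0.3, seed = 3)),
    build_synthetic_map(synthetic_spec(L = 8, n_p = 15, T = Inf, seed = 3))
  )
  for (m in maps) {
    pr <- gp_properties(m)
    tc <- tradeoff_check(pr)
    expect_length(tc$violations, 0)
  }
  # closed-form sanity: uniform map slack is positive
  np <- 100; d <- 15
  slack <- d * (1 - 1 / np) - (np - 1) * (1 - (1 - 1 / np)^d)
  expect_gte(slack, 0)
})

test_that("high-T closed forms for all five quantities hold to 1e-9", {
  L <- 8; np <- 20
  m <- build_synthetic_map(synthetic_spec(L = L, n_p = np, T = Inf,
                                          seed = 13))
  pr <- gp_properties(m)
  d <- (2 - 1) * L
  expect_equal(pr$phenotypes$f, rep(1 / np, np), tolerance = 1e-9)
  expect_equal(pr$phenotypes$rho, rep(1 / np, np), tolerance = 1e-9)
  expect_equal(pr$genotypes$rho_g, rep(1 / np, 2^L), tolerance = 1e-9)
  expect_equal(pr$genotypes$eps_g,
               rep((np - 1) * (1 - (1 - 1 / np)^d), 2^L),
               tolerance = 1e-9)
  expect_equal(pr$phenotypes$eps,
               rep((np - 1) * (1 - (1 - 1 / np^2)^(2^L * d)), np),
               tolerance = 1e-9)
})

test_that("vector norms link to frequency, with the normalised-init guard", {
  m <- build_synthetic_map(synthetic_spec(L = 12, n_p = 50, T = 0.8,
                                          seed = 17))
  vn <- vector_norm_frequency(m)
  params <- attr(m, "params")
  # norms match an independent sqrt-of-sum-of-squares loop
  for (r in c(1, 25, 50)) {
    acc <- 0
    for (i in 1:12) acc <- acc + params$V[r, i]^2
    expect_equal(vn$norm[vn$label == as.character(r - 1)], sqrt(acc))
  }
  expect_gt(attr(vn, "spearman"), 0)
  # normalised init: constant norms, correlation absent
  mn <- build_synthetic_map(synthetic_spec(L = 12, n_p = 50, T = 0.8,
                                           init = "normalized_normal",
                                           seed = 17))
  expect_true(is.na(attr(vector_norm_frequency(mn), "spearman")))
  # non-synthetic maps are rejected
  expect_error(vector_norm_frequency(random_gp_map(3, 2, 3, seed = 1)),
               "synthetic")
})

test_that("map summaries match a hand-rolled recomputation and its guards", {
  # uniform map: no bias, no robustness range, top prob = 1/n_p
  mu <- build_synthetic_map(synthetic_spec(L = 6, n_p = 10, T = Inf,
                                           seed = 2))
  sm <- map_summary(mu)
  expect_equal(sm$bias_logratio, 0)
  expect_equal(sm$robustness_range, 0)
  expect_equal(unname(sm$top_prob_quartiles[2]), 0.1)
  expect_true(is.na(sm$rob_evo_pearson))  # evolvability range < 1e-6
  # random map: recompute every statistic independently
  m <- random_gp_map(4, 2, 6, seed = 23, cutoff = 1e-2)
  pr <- gp_properties(m)
  sm2 <- map_summary(m, pr)
  ph <- pr$phenotypes
  expect_equal(sm2$bias_logratio, log10(max(ph$f) / min(ph$f)))
  keep <- ph$rho > 0
  expect_equal(unname(sm2$gc_logratio_quartiles[2]),
               unname(median(log10(ph$rho[keep] / ph$f[keep]))))
  expect_equal(sm2$robustness_range, max(ph$rho) - min(ph$rho))
  expect_equal(sm2$rob_evo_pearson, cor(ph$rho, ph$eps))
  expect_equal(unname(sm2$top_prob_quartiles[2]),
               unname(median(apply(as.matrix(m$P), 1, max))))
  # single-phenotype map: Pearson guard trips
  sp <- genotype_space(3, 2)
  m1 <- gp_map(sp, matrix(1, 8, 1), labels = "only", cutoff = 0,
               apply = FALSE)
  expect_true(is.na(map_summary(m1)$rob_evo_pearson))
})
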