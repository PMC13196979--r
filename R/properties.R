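#' Compute the ND GP map property suite
#'
#' Computes, for an ND GP map with ensemble probabilities `P(p|g)`:
#'
#' * phenotypic frequency `f_p = (1/K^L) sum_g P(p|g)`;
#' * genotypic robustness
#'   `rho_g = (1/((K-1)L)) sum_p P(p|g) sum_{g' in N(g)} P(p|g')`;
#' * phenotypic robustness
#'   `rho_p = (1/(K^L f_p (K-1)L)) sum_g P(p|g) sum_{g' in N(g)} P(p|g')`;
#' * genotypic evolvability
#'   `eps_g = sum_p P(p|g) sum_{p' != p} (1 - prod_{g' in N(g)} (1 - P(p'|g')))`;
#' * phenotypic evolvability
#'   `eps_p = sum_{p' != p} (1 - prod_g prod_{g' in N(g)} (1 - P(p'|g') P(p|g)))`.
#'
#' Frequencies and robustness are normalised to `[0, 1]`; evolvabilities
#' count distinct accessible alternative phenotypes (at most `n_p - 1`).
#' The undefined placeholder phenotype, if the map has one, is excluded from
#' every sum over phenotypes (its probability mass still occupies the
#' ensembles; nothing is renormalised). Phenotypes that never rise above the
#' cutoff (`f_p = 0`) are dropped from the per-phenotype table.
#'
#' Products `prod (1 - x)` are accumulated in log space with clamping at
#' `x = 1 - 1e-12`, which keeps the `eps_p` accumulator stable for the
#' `K^L (K-1) L` factors involved. Only stored (above-cutoff) entries
#' contribute non-unit factors, so the cost scales with the stored ensemble
#' sizes, not with `n_p`.
#'
#' @param map A [gp_map()].
#' @param phenotypic_evolvability Compute `eps_p` (the quadratic-cost
#'   accumulator)? Default `TRUE`; set `FALSE` for cheap frequency/
#'   robustness-only sweeps.
#' @return An object of class `"gp_properties"`: a list with
#'   * `phenotypes`: data.frame `label`, `f`, `rho`, `eps` (rows with
#'     `f > 0`, undefined excluded; `eps` is `NA` when not computed);
#'   * `genotypes`: data.frame `rho_g`, `eps_g`, `top_prob` (all `K^L`
#'     genotypes, canonical order);
#'   * `n_p`: number of phenotypes with `f > 0` (undefined excluded);
#'   * `d`: neighbourhood size `(K-1)L`, and `space`.
#' @export
gp_properties <- function(map, phenotypic_evolvability = TRUE) {
  stopifnot(inherits(map, "gp_map"))
  space <- map$space
  P <- map$P
  labels <- map$labels
  if (!is.na(map$undefined)) {
    keep <- labels != map$undefined
    P <- P[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  n <- space$n_genotypes
  d <- (space$K - 1L) * space$L
  f <- Matrix::colSums(P) / n
  Pt <- methods::as(Matrix::t(P), "CsparseMatrix")
  nbr <- neighbour_index_matrix(space)
  res <- nd_props_kernel(Pt@p, Pt@i, Pt@x, length(labels), nbr,
                         isTRUE(phenotypic_evolvability))
  rho_p <- rep(NA_real_, length(labels))
  pos <- f > 0
  rho_p[pos] <- res$rr_num[pos] / (n * f[pos] * d)
  if (isTRUE(phenotypic_evolvability)) {
    A <- res$A
    diag(A) <- 0
    eps_p <- rowSums(1 - exp(A)) - 0  # diagonal contributes 1 - exp(0) = 0
  } else {
    eps_p <- rep(NA_real_, length(labels))
  }
  phen <- data.frame(label = labels[pos], f = f[pos], rho = rho_p[pos],
                     eps = eps_p[pos], stringsAsFactors = FALSE)
  geno <- data.frame(rho_g = res$rho_g, eps_g = res$eps_g,
                     top_prob = res$top_prob)
  structure(list(phenotypes = phen, genotypes = geno,
                 n_p = sum(pos), d = d, space = space),
            class = "gp_properties")
}

#' @exportS3Method base::print
print.gp_properties <- function(x, ...) {
  cat("ND GP map properties:", x$n_p, "phenotypes present,",
      nrow(x$genotypes), "genotypes\n")
  cat(sprintf("  f_p:   [%.3g, %.3g]\n", min(x$phenotypes$f),
              max(x$phenotypes$f)))
  cat(sprintf("  rho_p: [%.3g, %.3g]\n", min(x$phenotypes$rho),
              max(x$phenotypes$rho)))
  if (!anyNA(x$phenotypes$eps))
    cat(sprintf("  eps_p: [%.3g, %.3g] (max possible %d)\n",
                min(x$phenotypes$eps), max(x$phenotypes$eps), x$n_p - 1L))
  invisible(x)
}

#' Phenotypic frequency
#' @param map A [gp_map()].
#' @return Named numeric vector `f_p` over phenotypes with `f_p > 0`
#'   (undefined excluded).
#' @export
phenotypic_frequency <- function(map) {
  P <- map$P
  labels <- map$labels
  if (!is.na(map$undefined)) {
    keep <- labels != map$undefined
    P <- P[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  f <- Matrix::colSums(P) / map$space$n_genotypes
  stats::setNames(f, labels)[f > 0]
}

#' Genotypic robustness
#' @param map A [gp_map()].
#' @return Numeric vector `rho_g` over all genotypes (canonical order).
#' @export
genotypic_robustness <- function(map) {
  gp_properties(map, phenotypic_evolvability = FALSE)$genotypes$rho_g
}

#' Phenotypic robustness
#' @param map A [gp_map()].
#' @return Named numeric vector `rho_p` over phenotypes with `f_p > 0`.
#' @export
phenotypic_robustness <- function(map) {
  pr <- gp_properties(map, phenotypic_evolvability = FALSE)$phenotypes
  stats::setNames(pr$rho, pr$label)
}

#' Genotypic evolvability
#' @param map A [gp_map()].
#' @return Numeric vector `eps_g` over all genotypes (canonical order).
#' @export
genotypic_evolvability <- function(map) {
  gp_properties(map, phenotypic_evolvability = FALSE)$genotypes$eps_g
}

#' Phenotypic evolvability
#' @param map A [gp_map()].
#' @return Named numeric vector `eps_p` over phenotypes with `f_p > 0`.
#' @export
phenotypic_evolvability <- function(map) {
  pr <- gp_properties(map, phenotypic_evolvability = TRUE)$phenotypes
  stats::setNames(pr$eps, pr$label)
}

#' Mutational-neighbour covariance diagnostic
#'
#' For each phenotype `p`, estimates the covariance of `P(p|g)` with
#' `P(p|g')` over random pairs of mutational neighbours, together with a
#' null column in which an independent uniformly random genotype `h`
#' replaces the neighbour. Genetic correlations show up as neighbour
#' covariances that are positive and exceed the null.
#'
#' @param map An ND [gp_map()] (not a deterministic projection embedded as
#'   probability-1 ensembles — the diagnostic is about ensemble shifts).
#' @param n_pairs Number of sampled pairs (default `1e4`), or `"all"` for
#'   the exhaustive set of ordered neighbour pairs (null column then pairs
#'   every genotype with every genotype).
#' @param seed RNG seed for the sampling.
#' @return An object of class `"covariance_report"`: data.frame with
#'   columns `label`, `cov_neighbour`, `cov_null`, plus attribute
#'   `n_pairs`. Sample covariances (denominator `n - 1`).
#' @export
neighbour_covariance <- function(map, n_pairs = 1e4, seed = 1L) {
  stopifnot(inherits(map, "gp_map"))
  space <- map$space
  n <- space$n_genotypes
  d <- (space$K - 1L) * space$L
  nbr <- neighbour_index_matrix(space)
  exhaustive <- identical(n_pairs, "all")
  if (!exhaustive && (!is.numeric(n_pairs) || n_pairs < 2))
    stop("`n_pairs` must be at least 2 (or \"all\")")
  if (exhaustive) {
    g <- rep(seq_len(n), each = d)
    g2 <- as.vector(t(nbr)) + 1L
    h <- rep(seq_len(n), times = n)
    g_null <- rep(seq_len(n), each = n)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    g <- sample.int(n, n_pairs, replace = TRUE)
    pick <- sample.int(d, n_pairs, replace = TRUE)
    g2 <- nbr[cbind(g, pick)] + 1L
    h <- sample.int(n, n_pairs, replace = TRUE)
    g_null <- g
  }
  P <- map$P
  labels <- map$labels
  if (!is.na(map$undefined)) {
    keep <- labels != map$undefined
    P <- P[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  colcov <- function(X, Y) {
    m <- nrow(X)
    (Matrix::colSums(X * Y) -
       Matrix::colSums(X) * Matrix::colSums(Y) / m) / (m - 1)
  }
  cov_nb <- colcov(P[g, , drop = FALSE], P[g2, , drop = FALSE])
  cov_null <- colcov(P[g_null, , drop = FALSE], P[h, , drop = FALSE])
  out <- data.frame(label = labels, cov_neighbour = as.numeric(cov_nb),
                    cov_null = as.numeric(cov_null),
                    stringsAsFactors = FALSE)
  attr(out, "n_pairs") <- if (exhaustive) length(g) else n_pairs
  class(out) <- c("covariance_report", "data.frame")
  out
}

#' Genotypic robustness-evolvability trade-off check
#'
#' A genotype's mutational neighbourhood has only `(K-1)L` members, so high
#' robustness forces low evolvability:
#' `eps_g <= (K-1)L (1 - rho_g)`. This returns the per-genotype slack
#' `(K-1)L (1 - rho_g) - eps_g`, which must be `>= -tol` everywhere
#' (the default tolerance absorbs accumulated floating-point error).
#'
#' @param props A [gp_properties()] result.
#' @param tol Numerical tolerance (default `1e-4`).
#' @return List with `slack` (numeric vector) and `violations` (indices of
#'   genotypes whose slack falls below `-tol`).
#' @export
tradeoff_check <- function(props, tol = 1e-4) {
  stopifnot(inherits(props, "gp_properties"))
  slack <- props$d * (1 - props$genotypes$rho_g) - props$genotypes$eps_g
  list(slack = slack, violations = which(slack < -tol))
}

#' Parameter-vector norm against phenotypic frequency
#'
#' For synthetic maps, phenotypes whose parameter vectors have larger norms
#' can reach lower `G` in more genotypes and are amplified by the
#' nonlinearity, so frequency should increase with the norm. Returns the
#' `(|v_p|, f_p)` pairs and their Spearman rank correlation (absent when
#' the norms are essentially constant, e.g. the normalised-normal
#' initialisation).
#'
#' @param map A synthetic [gp_map()] carrying its `"params"` attribute, or
#' @param params alternatively an explicit `parameter_set`.
#' @param props Optional precomputed [gp_properties()].
#' @return data.frame `label`, `norm`, `f` plus attribute `"spearman"`.
#' @export
vector_norm_frequency <- function(map, params = attr(map, "params"),
                                  props = NULL) {
  if (is.null(params))
    stop("map has no accessible parameter set; ",
         "vector_norm_frequency() applies to synthetic maps only")
  if (!is.matrix(params$V))
    stop("vector norms are defined for the K = 2 parameter matrix")
  f <- phenotypic_frequency(map)
  norms <- sqrt(rowSums(params$V^2))
  names(norms) <- as.character(seq_len(nrow(params$V)) - 1L)
  common <- intersect(names(f), names(norms))
  out <- data.frame(label = common, norm = norms[common], f = f[common],
                    stringsAsFactors = FALSE, row.names = NULL)
  rho <- if (stats::sd(out$norm) < 1e-12) NA_real_ else
    stats::cor(out$norm, out$f, method = "spearman")
  attr(out, "spearman") <- rho
  out
}

#' Map-level summary statistics
#'
#' Five scalar (or quartile) summaries of an ND map:
#' * `bias_logratio`: `log10(max f_p / min f_p)` over phenotypes with
#'   `f_p > 0` — a proxy for phenotypic bias;
#' * `gc_logratio`: median and quartiles of `log10(rho_p / f_p)` over
#'   phenotypes with `f_p > 0` and `rho_p > 0` — a proxy for genetic
#'   correlations;
#' * `robustness_range`: `max rho_p - min rho_p`;
#' * `rob_evo_pearson`: Pearson correlation of `rho_p` with `eps_p`,
#'   reported as `NA` when the evolvability range is below `1e-6`;
#' * `top_prob`: median and quartiles over genotypes of the largest
#'   ensemble probability.
#'
#' @param map A [gp_map()].
#' @param props Optional precomputed [gp_properties()] (with `eps`).
#' @return A list of class `"map_summary"`.
#' @export
map_summary <- function(map, props = NULL) {
  if (is.null(props)) props <- gp_properties(map, phenotypic_evolvability = TRUE)
  ph <- props$phenotypes
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  gc_keep <- ph$rho > 0
  gc_q <- if (any(gc_keep)) qs(log10(ph$rho[gc_keep] / ph$f[gc_keep]))
          else rep(NA_real_, 3)
  evo_range <- if (anyNA(ph$eps)) NA_real_ else max(ph$eps) - min(ph$eps)
  pearson <- if (is.na(evo_range) || evo_range < 1e-6) NA_real_
             else stats::cor(ph$rho, ph$eps)
  structure(list(
    bias_logratio = log10(max(ph$f) / min(ph$f)),
    gc_logratio_quartiles = gc_q,
    robustness_range = max(ph$rho) - min(ph$rho),
    rob_evo_pearson = pearson,
    top_prob_quartiles = qs(props$genotypes$top_prob),
    n_p = props$n_p
  ), class = "map_summary")
}

#' @exportS3Method base::print
print.map_summary <- function(x, ...) {
  cat(sprintf("bias_logratio      %.4f\n", x$bias_logratio))
  cat(sprintf("gc_logratio (med)  %.4f  [%.4f, %.4f]\n",
              x$gc_logratio_quartiles[2], x$gc_logratio_quartiles[1],
              x$gc_logratio_quartiles[3]))
  cat(sprintf("robustness_range   %.4f\n", x$robustness_range))
  cat(sprintf("rob_evo_pearson    %s\n",
              if (is.na(x$rob_evo_pearson)) "NA (evolvability range < 1e-6)"
              else sprintf("%.4f", x$rob_evo_pearson)))
  cat(sprintf("top_prob (med)     %.4f  [%.4f, %.4f]\n",
              x$top_prob_quartiles[2], x$top_prob_quartiles[1],
              x$top_prob_quartiles[3]))
  invisible(x)
}

#' Write per-phenotype and per-genotype property tables as TSV
#'
#' Each file carries a one-line JSON metadata header (prefixed `#`)
#' mirroring the input map's provenance.
#'
#' @param props A [gp_properties()].
#' @param path_phenotypes,path_genotypes Output paths (`NULL` to skip one).
#' @param provenance Metadata list (typically `map$provenance`).
#' @return Invisibly, the written paths.
#' @export
write_properties <- function(props, path_phenotypes = NULL,
                             path_genotypes = NULL, provenance = list()) {
  hdr <- paste0("#", jsonlite::toJSON(
    list(format = "ndgpmap-properties/1", provenance = provenance),
    auto_unbox = TRUE, digits = NA))
  wrt <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_phenotypes)) wrt(props$phenotypes, path_phenotypes)
  if (!is.null(path_genotypes)) wrt(props$genotypes, path_genotypes)
  invisible(c(path_phenotypes, path_genotypes))
}
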