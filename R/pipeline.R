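#' Assemble an experiment configuration
#'
#' A configuration names a set of maps to build and the analyses to run on
#' each. Map specs are lists with a `type` field:
#' * `type = "synthetic"`: fields of [synthetic_spec()] (`L`, `n_p`, `T`,
#'   `form`, `init`, ...);
#' * `type = "lattice"`: `kBT`, optionally `W`, potential entries;
#' * `type = "polyomino"`: `t`, `c`, `n_rep`, `min_count`;
#' * `type = "file"`: `path` of a map written by [write_gpmap()].
#'
#' Sweeps are expressed by listing one spec per combination (see
#' [sweep_synthetic()]); no figure parameter values are hard-coded.
#'
#' @param maps Named list of map specs.
#' @param out_dir Output directory (created if needed).
#' @param seed Base seed; map `i` of the run uses `seed + i - 1` unless its
#'   spec pins one.
#' @param covariance Also run [neighbour_covariance()] per map?
#' @param n_pairs Pair count for the covariance diagnostic.
#' @param write_maps Also serialise each built map via [write_gpmap()]?
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(maps, out_dir, seed = 1L, covariance = FALSE,
                              n_pairs = 1e4, write_maps = FALSE) {
  if (length(maps) &&
      (is.null(names(maps)) || any(!nzchar(names(maps)))))
    names(maps) <- paste0("map", seq_along(maps))
  structure(list(maps = maps, out_dir = out_dir, seed = as.integer(seed),
                 covariance = covariance, n_pairs = n_pairs,
                 write_maps = write_maps),
            class = "experiment_config")
}

#' Cross-product sweep of synthetic model specs
#'
#' @param L,n_p,T,form,init Vectors of values; one spec per combination.
#'   `T = NA` requests the mean-gap reference rule.
#' @param K Alphabet size.
#' @return Named list of map specs for [experiment_config()].
#' @export
sweep_synthetic <- function(L = 15, n_p = 100, T = NA, form = "boltzmann",
                            init = "normal", K = 2) {
  grid <- expand.grid(L = L, n_p = n_p, T = T, form = form, init = init,
                      K = K, stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(grid)), function(i) {
    g <- as.list(grid[i, ])
    g$type <- "synthetic"
    if (is.na(g$T)) g$T <- NULL
    g
  })
  names(specs) <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    paste0("synthetic_L", g$L, "_np", g$n_p, "_",
           g$form, "_", g$init, "_T",
           if (is.na(g$T)) "ref" else format(g$T))
  }, character(1))
  specs
}

.build_from_spec <- function(spec, seed) {
  type <- spec$type
  if (is.null(type)) stop("map spec has no `type`")
  switch(type,
    synthetic = build_synthetic_map(synthetic_spec(
      L = spec$L, n_p = spec$n_p, T = spec$T,
      K = if (is.null(spec$K)) 2 else spec$K,
      form = if (is.null(spec$form)) "boltzmann" else spec$form,
      init = if (is.null(spec$init)) "normal" else spec$init,
      seed = if (is.null(spec$seed)) seed else spec$seed,
      cutoff = if (is.null(spec$cutoff)) 1e-4 else spec$cutoff)),
    lattice = build_lattice_map(
      kBT = if (is.null(spec$kBT)) 1 else spec$kBT,
      confs = enumerate_compact_conformations(
        if (is.null(spec$W)) 4 else spec$W),
      cutoff = if (is.null(spec$cutoff)) 1e-4 else spec$cutoff),
    polyomino = build_polyomino_map(
      t = spec$t, c = spec$c,
      n_rep = if (is.null(spec$n_rep)) 5000 else spec$n_rep,
      min_count = if (is.null(spec$min_count)) 50 else spec$min_count,
      seed = if (is.null(spec$seed)) seed else spec$seed),
    file = read_gpmap(spec$path),
    stop("unknown map type: ", type)
  )
}

#' Run a configured experiment
#'
#' Builds each configured map, computes the full property suite, and
#' writes per-map phenotype/genotype property TSVs, an optional covariance
#' TSV, a run-level `summary.tsv` (one [map_summary()] row per map) and a
#' `manifest.json` recording specs, seeds, package version and wall times.
#' A failure in one map is logged in the manifest and the run continues.
#' Re-running the same configuration reproduces byte-identical tables.
#'
#' @param config An [experiment_config()].
#' @return Invisibly, the manifest list.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("ndgpmap")),
                   maps = list())
  summary_rows <- list()
  for (i in seq_along(config$maps)) {
    nm <- names(config$maps)[i]
    spec <- config$maps[[i]]
    seed_i <- config$seed + i - 1L
    t0 <- proc.time()[["elapsed"]]
    rec <- list(name = nm, spec = spec, seed = seed_i)
    ok <- tryCatch({
      map <- .build_from_spec(spec, seed_i)
      props <- gp_properties(map, phenotypic_evolvability = TRUE)
      write_properties(
        props,
        file.path(config$out_dir, paste0(nm, "_phenotypes.tsv")),
        file.path(config$out_dir, paste0(nm, "_genotypes.tsv")),
        provenance = map$provenance)
      rank <- frequency_rank_table(props)
      utils::write.table(rank,
        file.path(config$out_dir, paste0(nm, "_frequency_rank.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      if (isTRUE(config$covariance)) {
        cv <- neighbour_covariance(map, n_pairs = config$n_pairs,
                                   seed = seed_i)
        utils::write.table(cv,
          file.path(config$out_dir, paste0(nm, "_covariance.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      if (isTRUE(config$write_maps))
        write_gpmap(map, file.path(config$out_dir, paste0(nm, "_map.tsv")))
      sm <- map_summary(map, props)
      summary_rows[[nm]] <- data.frame(
        map = nm, n_p = sm$n_p,
        bias_logratio = sm$bias_logratio,
        gc_logratio_median = sm$gc_logratio_quartiles[2],
        robustness_range = sm$robustness_range,
        rob_evo_pearson = sm$rob_evo_pearson,
        top_prob_median = sm$top_prob_quartiles[2])
      TRUE
    }, error = function(e) {
      rec$error <<- conditionMessage(e)
      FALSE
    })
    rec$ok <- ok
    rec$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 3)
    manifest$maps[[nm]] <- rec
    message(sprintf("[ndgpmap] %s: %s (%.1fs)", nm,
                    if (ok) "ok" else "FAILED", rec$elapsed_s))
  }
  if (length(summary_rows)) {
    utils::write.table(do.call(rbind, summary_rows),
                       file.path(config$out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

#' Frequency-rank table
#'
#' Phenotypic frequencies sorted in descending order (ties broken by
#' phenotype label), the representation behind frequency-rank plots of
#' phenotypic bias.
#'
#' @param props A [gp_properties()] result (or a [gp_map()], from which
#'   frequencies are computed).
#' @return data.frame with columns `rank`, `label`, `f` (only `f > 0`).
#' @export
frequency_rank_table <- function(props) {
  if (inherits(props, "gp_map"))
    props <- gp_properties(props, phenotypic_evolvability = FALSE)
  ph <- props$phenotypes
  ord <- order(-ph$f, ph$label)
  data.frame(rank = seq_along(ord), label = ph$label[ord], f = ph$f[ord],
             row.names = NULL)
}
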