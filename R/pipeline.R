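# Run configuration and the end-to-end pipeline.
#
# A run configuration nests the stage configurations, a global seed and an
# output directory. All stage randomness is derived from the global seed
# through named substreams, so the same configuration always reproduces
# the same outputs byte for byte.

#' Run configuration
#'
#' @param st [st_config()] for the structure-tensor stage.
#' @param cells [cell_count_config()] for the counting stage.
#' @param fiber_spec,nissl_spec Generator specifications for `--simulate`
#'   runs (seeds are overridden from the global seed).
#' @param n_sham,n_mtbi Cohort group sizes.
#' @param fdr_family t-table FDR family, see [analyze_cohort()].
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(st = st_config(), cells = cell_count_config(),
                       fiber_spec = fiber_image_spec(),
                       nissl_spec = nissl_image_spec(),
                       n_sham = 6L, n_mtbi = 8L,
                       fdr_family = "per_measure",
                       seed = 1L, out_dir = "histotensor_out",
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  structure(list(st = st, cells = cells, fiber_spec = fiber_spec,
                 nissl_spec = nissl_spec, n_sham = as.integer(n_sham),
                 n_mtbi = as.integer(n_mtbi), fdr_family = fdr_family,
                 seed = as.integer(seed), out_dir = out_dir,
                 log_level = log_level),
            class = "run_config")
}

#' Save / load a run configuration as JSON
#'
#' The JSON round trip is exact (`load_run_config(save_run_config(cfg))`
#' equals `cfg`); unknown keys in the file are rejected.
#'
#' @param cfg A [run_config].
#' @param path JSON file path.
#' @return `save_run_config`: `path` invisibly; `load_run_config`: a
#'   [run_config].
#' @export
save_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass_deep(cfg), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  template <- run_config()
  check_keys <- function(got, want, where) {
    extra <- setdiff(names(got), names(want))
    if (length(extra)) {
      stop("unknown configuration key(s) in ", where, ": ",
           paste(extra, collapse = ", "))
    }
  }
  check_keys(raw, template, "run_config")
  for (nm in c("st", "cells", "fiber_spec", "nissl_spec")) {
    if (!is.null(raw[[nm]])) check_keys(raw[[nm]], template[[nm]], nm)
  }
  cfg <- utils::modifyList(unclass_deep(template), raw)
  cfg$st <- do.call(st_config, cfg$st)
  cfg$cells <- do.call(cell_count_config, cfg$cells)
  cfg$fiber_spec <- do.call(fiber_image_spec, cfg$fiber_spec)
  cfg$nissl_spec <- do.call(nissl_image_spec, cfg$nissl_spec)
  do.call(run_config, cfg[setdiff(names(cfg), character(0))])
}

pipeline_log <- function(cfg, ...) {
  if (cfg$log_level == "info") message("[histotensor] ", ...)
}

#' Run the full simulated pipeline
#'
#' Mirrors the study's analysis flow on synthetic data: a fiber image is
#' analyzed with the ST stage (AI map + per-tile table), a Nissl image is
#' counted (density row + component table), a known tensor is fitted from
#' simulated signals (scalar row), and a synthetic cohort is analyzed into
#' the two statistics tables plus the chi scatter table. All outputs are
#' written as CSV/JSON under `cfg$out_dir` with a run-metadata file
#' carrying the seed and configuration.
#'
#' @param cfg A [run_config].
#' @return List with the stage results, invisibly.
#' @export
run_full_pipeline <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  # stage seeds from the global seed
  fspec <- cfg$fiber_spec; fspec$seed <- stage_seed(cfg$seed, "fibers")
  nspec <- cfg$nissl_spec; nspec$seed <- stage_seed(cfg$seed, "nissl")
  ccfg <- cfg$cells; ccfg$rng_seed <- stage_seed(cfg$seed, "chanvese")

  pipeline_log(cfg, "ST stage (", fspec$size, "x", fspec$size, " fiber image)")
  fib <- gen_fiber_image(fspec)
  st <- st_analyze(fib$image, cfg$st)
  utils::write.csv(st$tiles, file.path(cfg$out_dir, "st_tiles.csv"),
                   row.names = FALSE)

  pipeline_log(cfg, "cell-counting stage (", nspec$n_cells, " planted cells)")
  nis <- gen_nissl_image(nspec)
  dens <- count_and_density(nis$image, cfg = ccfg)
  utils::write.csv(dens$segmentation$components,
                   file.path(cfg$out_dir, "cell_components.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(N = dens$N, A_um2 = dens$A_um2, rho = dens$rho,
                              rho_x1e2 = dens$rho_x1e2, planted = nis$count),
                   file.path(cfg$out_dir, "cell_density.csv"),
                   row.names = FALSE)

  pipeline_log(cfg, "DTI stage (tensor fit + scalars)")
  evals <- c(1.7, 0.3, 0.3) * 1e-3
  prot <- dwi_protocol()
  sig <- gen_dwi(evals, protocol = prot, snr = Inf)
  fit <- fit_tensor(sig, prot)
  sc <- scalars_from_eigenvalues(sort(fit$evals, decreasing = TRUE))
  utils::write.csv(cbind(data.frame(l1 = fit$evals[1], l2 = fit$evals[2],
                                    l3 = fit$evals[3]), as.data.frame(sc)),
                   file.path(cfg$out_dir, "dti_scalars.csv"),
                   row.names = FALSE)

  pipeline_log(cfg, "statistics stage (cohort of ", cfg$n_sham, " + ",
               cfg$n_mtbi, ")")
  coh <- gen_cohort(cohort_spec(cfg$n_sham, cfg$n_mtbi,
                                seed = stage_seed(cfg$seed, "cohort")))
  stats_out <- analyze_cohort(coh, fdr_family = cfg$fdr_family)
  utils::write.csv(stats_out$t_table,
                   file.path(cfg$out_dir, "group_contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(stats_out$regression_table,
                   file.path(cfg$out_dir, "regressions.csv"), row.names = FALSE)
  utils::write.csv(stats_out$chi_table,
                   file.path(cfg$out_dir, "chi_scatter.csv"), row.names = FALSE)

  meta <- list(package = "histotensor",
               version = as.character(utils::packageVersion("histotensor")),
               seed = cfg$seed,
               config_hash = config_hash(cfg))
  jsonlite::write_json(meta, file.path(cfg$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(st = st, density = dens, tensor_fit = fit, scalars = sc,
                 cohort = coh, stats = stats_out, metadata = meta))
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass_deep(cfg), auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash; provenance only, not cryptographic
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
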