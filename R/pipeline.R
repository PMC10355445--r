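# End-to-end orchestration: synthetic scenes -> mixture fits -> staple
# reduction; length samples -> census -> bootstrap SEs; gradient replicates
# -> shape + reproducibility. Everything is seeded and every reported
# number is also written as a per-stage artifact on disk.

#' Pipeline configuration
#'
#' Assembles and validates the inputs for [run_pipeline()]. In synthetic
#' mode (the default and only packaged mode; user data enters by calling
#' the stage functions directly) each enabled stage carries its own
#' generator settings, and all randomness derives from `seed`.
#'
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @param outdir output directory (created if missing).
#' @param stages character subset of `c("mixture", "census", "gradient")`;
#'   must be non-empty.
#' @param scene_before,scene_after [scene_spec()]s for the unpurified /
#'   purified AFM fields (mixture stage). Their `seed` fields are
#'   overridden from `seed` so the whole run is reproducible from one
#'   number.
#' @param sample_before,sample_after lists with elements `n` and
#'   `dimer_fraction` (and optionally `length_cv`) for the counted
#'   particle samples (census stage).
#' @param gradient list with `n_replicates`, `shape`, `n_points`,
#'   `noise_sd` (gradient stage).
#' @param n_restarts mixture-fit restarts.
#' @param n_resamples bootstrap subsets.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, outdir,
                            stages = c("mixture", "census", "gradient"),
                            scene_before = scene_spec(n_staples = 2000L),
                            scene_after = scene_spec(n_staples = 400L),
                            sample_before = list(n = 273L, dimer_fraction = 0.21),
                            sample_after = list(n = 114L, dimer_fraction = 0.63),
                            gradient = list(n_replicates = 20L, shape = "linear",
                                            n_points = 101L, noise_sd = 0.05),
                            n_restarts = 3L, n_resamples = 10000L) {
  if (length(stages) == 0L) {
    stop("at least one stage must be enabled", call. = FALSE)
  }
  stages <- match.arg(stages, c("mixture", "census", "gradient"),
                      several.ok = TRUE)
  assert_count(seed, "seed")
  structure(
    list(seed = as.integer(seed), outdir = outdir, stages = stages,
         scene_before = scene_before, scene_after = scene_after,
         sample_before = sample_before, sample_after = sample_after,
         gradient = gradient,
         n_restarts = assert_count(n_restarts, "n_restarts", 1L),
         n_resamples = assert_count(n_resamples, "n_resamples", 1L)),
    class = "pipeline_config"
  )
}

# small FNV-1a style fingerprint of the serialized config, for provenance;
# the output directory is not part of the scientific configuration
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL
  bytes <- as.integer(serialize(cfg, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

run_stage <- function(name, manifest_path, expr) {
  result <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  cat(name, "\n", file = manifest_path, append = TRUE)
  result
}

#' Run the purity-analysis pipeline
#'
#' Executes the enabled stages in order and writes per-stage artifacts
#' plus a single machine-readable `report.json` under `config$outdir`.
#' Completed stages are appended to `MANIFEST` as they finish, so a
#' failed run leaves its partial outputs identifiable. Identical
#' config (including seed) reproduces identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return the report, invisibly: a list of class `purity_report` with
#'   `mixture` (fits before/after and `staple_reduction_fold`), `census`
#'   (counts, fractions and bootstrap SEs before/after), `gradient`
#'   (shape classifications and the reproducibility report), and
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config", call. = FALSE)
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(config$outdir, "MANIFEST")
  cat("", file = manifest)
  report <- list(mixture = NULL, census = NULL, gradient = NULL)

  if ("mixture" %in% config$stages) {
    report$mixture <- run_stage("mixture", manifest, {
      sb <- config$scene_before; sb$seed <- derive_seed(config$seed, "scene_before")
      sa <- config$scene_after;  sa$seed <- derive_seed(config$seed, "scene_after")
      scene_b <- generate_afm_scene(sb)
      scene_a <- generate_afm_scene(sa)
      write_height_map(scene_b$map, file.path(config$outdir, "scene_before.tif"))
      write_height_map(scene_a$map, file.path(config$outdir, "scene_after.tif"))
      fit_b <- fit_height_mixture(scene_b$map, n_restarts = config$n_restarts,
                                  seed = derive_seed(config$seed, "fit_before"))
      fit_a <- fit_height_mixture(scene_a$map, n_restarts = config$n_restarts,
                                  seed = derive_seed(config$seed, "fit_after"))
      write_mixture_fit(fit_b, file.path(config$outdir, "fit_before.json"))
      write_mixture_fit(fit_a, file.path(config$outdir, "fit_after.json"))
      list(
        fit_before = fit_b, fit_after = fit_a,
        truth_staple_before = unname(scene_b$truth$pixel_fractions["staple"]),
        truth_staple_after = unname(scene_a$truth$pixel_fractions["staple"]),
        staple_reduction_fold = staple_reduction(fit_b, fit_a)
      )
    })
  }

  if ("census" %in% config$stages) {
    report$census <- run_stage("census", manifest, {
      one_arm <- function(sample_cfg, tag) {
        lcv <- if (is.null(sample_cfg$length_cv)) 0.05 else sample_cfg$length_cv
        s <- generate_length_sample(
          sample_cfg$n, sample_cfg$dimer_fraction, length_cv = lcv,
          seed = derive_seed(config$seed, paste0("sample_", tag))
        )
        labels <- classify_by_length(s$length_nm)
        cen <- census(labels)
        utils::write.csv(cbind(s, assigned = labels),
                         file.path(config$outdir, paste0("census_", tag, ".csv")),
                         row.names = FALSE)
        boot <- half_subset_se(as.integer(labels == "dimer"),
                               n_resamples = config$n_resamples,
                               seed = derive_seed(config$seed, paste0("boot_", tag)))
        jsonlite::write_json(unclass(boot),
                             file.path(config$outdir, paste0("boot_", tag, ".json")),
                             auto_unbox = TRUE, digits = NA)
        list(census = cen, bootstrap = boot)
      }
      list(before = one_arm(config$sample_before, "before"),
           after = one_arm(config$sample_after, "after"))
    })
  }

  if ("gradient" %in% config$stages) {
    report$gradient <- run_stage("gradient", manifest, {
      g <- config$gradient
      profs <- generate_gradient_replicates(
        g$n_replicates, g$shape, g$n_points, g$noise_sd,
        seed = derive_seed(config$seed, "gradient")
      )
      write_gradient_profiles(profs, file.path(config$outdir, "gradient_profiles.csv"))
      shapes <- vapply(profs, classify_profile, "")
      rep_ <- mean_absolute_deviation(profs)
      jsonlite::write_json(
        c(unclass(rep_), list(shapes = shapes)),
        file.path(config$outdir, "gradient_report.json"),
        auto_unbox = TRUE, digits = NA
      )
      list(shapes = shapes, repro = rep_)
    })
  }

  report$provenance <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("rzcpurity"))
  )
  class(report) <- "purity_report"
  report_json <- report_to_json_list(report)
  jsonlite::write_json(report_json, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

report_to_json_list <- function(report) {
  out <- list(provenance = report$provenance)
  if (!is.null(report$mixture)) {
    m <- report$mixture
    out$mixture <- list(
      p_staple_before = unname(m$fit_before$params$p["staple"]),
      p_staple_after = unname(m$fit_after$params$p["staple"]),
      truth_staple_before = m$truth_staple_before,
      truth_staple_after = m$truth_staple_after,
      staple_reduction_fold = m$staple_reduction_fold,
      converged = m$fit_before$converged && m$fit_after$converged
    )
  }
  if (!is.null(report$census)) {
    arm <- function(a) list(
      n_monomer = a$census$n_monomer, n_dimer = a$census$n_dimer,
      n_other = a$census$n_other,
      dimer_fraction = a$census$dimer_fraction,
      se = a$bootstrap$se, n = a$bootstrap$n,
      subset_size = a$bootstrap$subset_size,
      n_resamples = a$bootstrap$n_resamples, seed = a$bootstrap$seed
    )
    out$census <- list(before = arm(report$census$before),
                       after = arm(report$census$after))
  }
  if (!is.null(report$gradient)) {
    out$gradient <- list(
      shapes = report$gradient$shapes,
      mean_mad = report$gradient$repro$mean_mad,
      sd_mad = report$gradient$repro$sd_mad,
      n_replicates = report$gradient$repro$n_replicates
    )
  }
  out
}

#' @export
print.purity_report <- function(x, ...) {
  cat("<purity_report>\n")
  if (!is.null(x$mixture)) {
    cat(sprintf("  mixture: p_staple %.3f -> %.3f, reduction %.2fx\n",
                x$mixture$fit_before$params$p["staple"],
                x$mixture$fit_after$params$p["staple"],
                x$mixture$staple_reduction_fold))
  }
  if (!is.null(x$census)) {
    cat(sprintf("  census: dimer content %.1f%% +/- %.1f%% -> %.1f%% +/- %.1f%%\n",
                100 * x$census$before$census$dimer_fraction,
                100 * x$census$before$bootstrap$se,
                100 * x$census$after$census$dimer_fraction,
                100 * x$census$after$bootstrap$se))
  }
  if (!is.null(x$gradient)) {
    cat(sprintf("  gradient: %s; deviation %.1f +/- %.1f%% (N = %d)\n",
                paste(unique(x$gradient$shapes), collapse = "/"),
                x$gradient$repro$mean_mad, x$gradient$repro$sd_mad,
                x$gradient$repro$n_replicates))
  }
  invisible(x)
}
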