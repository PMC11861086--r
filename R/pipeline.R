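# End-to-end pipeline: generate phantoms -> record scripted planning
# trajectories -> build the training set -> train the six networks -> run the
# guided planning loop with static and trained controllers -> evaluate.

#' Record planning trajectories over a set of phantoms
#'
#' Runs the guided planning loop with the given controller (typically the
#' [scripted_policy()] planner stand-in) on each phantom and binds the
#' recorded trajectories.
#'
#' @param phantoms List of `phantom` objects.
#' @param beams A `beamset`.
#' @param controller Controller passed to [gip_run()].
#' @param levels,config,kernel See [gip_run()].
#' @param ids Optional phantom identifiers.
#' @return A trajectory tibble covering all phantoms.
#' @export
plan_trajectories <- function(phantoms, beams, controller = scripted_policy(),
                              levels = gip_levels("cshape"),
                              config = gip_control(),
                              kernel = engine_kernel(), ids = NULL) {
  ids <- ids %||% sprintf("ph%03d", seq_along(phantoms))
  dplyr::bind_rows(purrr::map2(phantoms, ids, function(ph, id) {
    gip_run(ph, beams, controller, levels, config, phantom_id = id,
            kernel = kernel)$trajectory
  }))
}

#' Train the six plan-parameter networks
#'
#' Fits one network per plan parameter, each starting from the static
#' controller's parameters for that target.
#'
#' @param samples Training samples from [build_dataset()].
#' @param control An [anfis_control()].
#' @param init Named list of starting networks (default the static set).
#' @return List: `networks` (named list of trained networks) and `fits`
#'   (named list of `anfis_fit` objects).
#' @export
train_networks <- function(samples, control = anfis_control(),
                           init = fis_network_set()) {
  fits <- lapply(TPP_TARGETS, function(tg) {
    anfis_train(init[[tg]], samples, control)
  })
  names(fits) <- TPP_TARGETS
  list(networks = lapply(fits, `[[`, "network"), fits = fits)
}

#' Compare static and trained controllers over a phantom cohort
#'
#' Runs the guided planning loop with both controllers on every phantom and
#' reports the achieved prescription level (lower is more restrictive, i.e.
#' better) and the final mean doses.
#'
#' @param phantoms List of phantoms.
#' @param beams A `beamset`.
#' @param fis_networks,anfis_networks Named lists of six networks each.
#' @param levels,config,kernel See [gip_run()].
#' @param ids Optional phantom identifiers.
#' @return Tibble: `phantom_id`, `system`, `achieved_level`, `mean_ptv`,
#'   `mean_oar`, `mean_nt`.
#' @export
compare_controllers <- function(phantoms, beams, fis_networks, anfis_networks,
                                levels = gip_levels("cshape"),
                                config = gip_control(),
                                kernel = engine_kernel(), ids = NULL) {
  ids <- ids %||% sprintf("ph%03d", seq_along(phantoms))
  systems <- list(fis = fis_networks, anfis = anfis_networks)
  out <- list()
  for (i in seq_along(phantoms)) {
    for (sys in names(systems)) {
      res <- gip_run(phantoms[[i]], beams, systems[[sys]], levels, config,
                     phantom_id = ids[i], kernel = kernel)
      oar_structs <- setdiff(names(res$means), c("ptv", "nt"))
      out[[length(out) + 1L]] <- tibble(
        phantom_id = ids[i], system = sys,
        achieved_level = res$achieved_level,
        mean_ptv = unname(res$means["ptv"]),
        mean_oar = mean(res$means[oar_structs]),
        mean_nt = unname(res$means["nt"])
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Pipeline configuration
#'
#' Every stochastic stage carries an explicit seed derived from the global
#' seed unless overridden. Validation fails before any compute when a seed is
#' missing.
#'
#' @param seed Global integer seed.
#' @param site `"cshape"` or `"prostate"`.
#' @param grid_shape Phantom grid (voxels per axis).
#' @param n_phantoms Number of generated variant phantoms.
#' @param n_eval Number of phantoms held out for controller comparison.
#' @param beams List `n`, `interval`, `start` defining the beam arrangement
#'   (defaults: nine beams at 40 degrees for the C-shape site, seven at 50 for
#'   the prostate site).
#' @param levels_preset Prescription preset name for [gip_levels()].
#' @param train An [anfis_control()].
#' @param gip A [gip_control()].
#' @param kernel Engine kernel parameters.
#' @param variant Variant ranges: `shift_frac`, `scale_range`,
#'   `stretch_range`.
#' @param seeds Optional per-stage seed overrides (`phantoms`, `split`,
#'   `train`).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, site = "cshape",
                            grid_shape = c(48L, 48L), n_phantoms = 12L,
                            n_eval = 4L,
                            beams = NULL, levels_preset = "evaluation",
                            train = NULL, gip = gip_control(),
                            kernel = engine_kernel(),
                            variant = list(shift_frac = 0.12,
                                           scale_range = c(0.85, 1.2),
                                           stretch_range = c(1, 1.2)),
                            seeds = list()) {
  site <- match.arg(site, c("cshape", "prostate"))
  beams <- beams %||% if (site == "cshape") {
    list(n = 9L, interval = 40, start = 0)
  } else {
    list(n = 7L, interval = 50, start = 0)
  }
  seeds <- utils::modifyList(
    list(phantoms = seed * 1000L + 1L, split = seed * 1000L + 2L,
         train = seed * 1000L + 3L),
    seeds
  )
  cfg <- list(seed = as.integer(seed), site = site,
              grid_shape = as.integer(grid_shape),
              n_phantoms = as.integer(n_phantoms),
              n_eval = as.integer(n_eval), beams = beams,
              levels_preset = levels_preset,
              train = train %||% anfis_control(seed = seeds$train),
              gip = gip, kernel = kernel, variant = variant, seeds = seeds)
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param cfg A pipeline configuration list.
#' @export
validate_pipeline_config <- function(cfg) {
  need <- c("seed", "site", "grid_shape", "n_phantoms", "n_eval", "beams",
            "levels_preset", "train", "gip", "kernel", "variant", "seeds")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    abort(paste("Pipeline config is missing:", paste(miss, collapse = ", ")),
          class = "fuzzyplan_error_config")
  }
  for (s in c("phantoms", "split", "train")) {
    if (is.null(cfg$seeds[[s]]) || !is.finite(cfg$seeds[[s]])) {
      abort(sprintf("Pipeline config is missing the '%s' stage seed.", s),
            class = "fuzzyplan_error_config")
    }
  }
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Executes all stages in order and writes versioned artifacts (phantoms,
#' dataset, trained models, comparison results) plus a manifest of seeds and
#' content fingerprints. Rerunning with the same configuration reproduces an
#' identical manifest.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if missing). `NULL` skips writing.
#' @return List: `phantoms`, `trajectories`, `samples`, `fits`, `networks`,
#'   `comparison`, `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  validate_pipeline_config(cfg)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  base <- if (cfg$site == "cshape") {
    phantom_cshape(cfg$grid_shape)
  } else {
    phantom_prostate(cfg$grid_shape)
  }
  phantoms <- phantom_variants(base, cfg$n_phantoms, cfg$seeds$phantoms,
                               shift_frac = cfg$variant$shift_frac,
                               scale_range = cfg$variant$scale_range,
                               stretch_range = cfg$variant$stretch_range)
  ids <- sprintf("ph%03d", seq_along(phantoms))
  eval_idx <- with_seed(cfg$seeds$split,
                        sort(sample(seq_along(phantoms), cfg$n_eval)))
  train_idx <- setdiff(seq_along(phantoms), eval_idx)

  beams <- beamset(cfg$beams$n, cfg$beams$interval, cfg$beams$start %||% 0)
  levels <- gip_levels(cfg$site, cfg$levels_preset)

  trajectories <- plan_trajectories(phantoms[train_idx], beams,
                                    scripted_policy(), levels, cfg$gip,
                                    cfg$kernel, ids = ids[train_idx])
  samples <- build_dataset(trajectories)
  trained <- train_networks(samples, cfg$train)
  fis_nets <- fis_network_set()
  comparison <- compare_controllers(phantoms[eval_idx], beams, fis_nets,
                                    trained$networks, levels, cfg$gip,
                                    cfg$kernel, ids = ids[eval_idx])

  manifest <- list(
    config = cfg[c("seed", "site", "grid_shape", "n_phantoms", "n_eval",
                   "levels_preset", "seeds")],
    n_samples = nrow(samples),
    train_phantoms = ids[train_idx],
    eval_phantoms = ids[eval_idx],
    networks = lapply(trained$networks, function(nw) {
      list(a = nw$a, b = nw$b, consequents = nw$consequents)
    }),
    comparison = comparison
  )
  if (!is.null(out_dir)) {
    for (i in seq_along(phantoms)) {
      write_phantom_json(phantoms[[i]],
                         file.path(out_dir, paste0(ids[i], ".json")))
    }
    write_dataset_csv(samples, file.path(out_dir, "samples.csv"))
    for (tg in names(trained$networks)) {
      write_network_json(trained$networks[[tg]],
                         file.path(out_dir, paste0("network_", tg, ".json")))
    }
    readr::write_csv(comparison, file.path(out_dir, "comparison.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  list(phantoms = phantoms, trajectories = trajectories, samples = samples,
       fits = trained$fits, networks = trained$networks,
       comparison = comparison, manifest = manifest)
}
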