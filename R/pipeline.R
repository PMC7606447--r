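# End-to-end driver: simulate (or load) -> screen -> mesh -> fit -> select ->
# validate -> predict, with derived per-stage seeds and a hashed artifact
# manifest so a rerun with the same config is verifiably identical.

default_run_config <- function() {
  list(
    out_dir = tempfile("sdm_run_"),
    seed = 1L,
    data_path = NULL,                 # read observations instead of simulating
    sim = list(),                     # sim_config() overrides
    screen = list(enabled = TRUE, r_max = 0.6, vif_max = 5),
    mesh = list(inner_max_edge = 4, outer_max_edge = 10, cutoff = NULL,
                extension_width = NULL),
    model = list(),                   # model_spec() overrides
    selection = list(enabled = FALSE, n_samples = 300),
    cv = list(enabled = FALSE, k = 5, repeats = 5, n_samples = 200,
              threshold = 0.5),
    prediction = list(cell_size = 1, n_samples = 500,
                      settype_scenario = "Dolphin", month_scenario = 1L),
    control = list()                  # fit/optimizer control
  )
}

validate_config <- function(config) {
  def <- default_run_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop_sdm("unknown config key(s): ", paste(unknown, collapse = ", "),
             class = "sdm_config_error")
  modifyList(def, config)
}

#' Read and validate an observation CSV
#'
#' Requires columns lon, lat, presence, set_type and either month or a date
#' column (month is then derived). Presence must be 0/1 and set-type labels
#' must be Dolphin / FloatingObject / School.
#'
#' @param path CSV path.
#' @return validated observation data.frame.
#' @export
read_observations <- function(path) {
  if (!file.size(path) > 0) stop_sdm("empty observation file",
                                     class = "sdm_data_error")
  obs <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(obs)) stop_sdm("empty observation file", class = "sdm_data_error")
  need <- c("lon", "lat", "presence", "set_type")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop_sdm("missing required column(s): ",
                             paste(miss, collapse = ", "),
                             class = "sdm_data_error")
  if (!all(obs$presence %in% 0:1))
    stop_sdm("presence must be 0/1", class = "sdm_data_error")
  if (!"month" %in% names(obs)) {
    if (!"date" %in% names(obs))
      stop_sdm("need a month or date column", class = "sdm_data_error")
    obs$month <- as.integer(format(as.Date(obs$date), "%m"))
  }
  if (!all(obs$month %in% 1:12))
    stop_sdm("month must be in 1..12", class = "sdm_data_error")
  bad <- !obs$set_type %in% set_type_levels
  if (any(bad))
    stop_sdm("unknown set-type label(s): ",
             paste(unique(obs$set_type[bad]), collapse = ", "),
             "; valid: ", paste(set_type_levels, collapse = ", "),
             class = "sdm_data_error")
  obs$set_type <- factor(obs$set_type, levels = set_type_levels)
  obs
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order and writes every artifact under
#' `config$out_dir` together with `manifest.json` (file hashes + stage seeds)
#' and `run_report.json`. Deterministic stages hash identically across reruns
#' with the same config.
#'
#' @param config named list; see `spdeSDM:::default_run_config()` for keys and
#'   defaults. Unknown keys raise a config error naming the key.
#' @return list of class `run_report`: artifact paths, stage summaries,
#'   manifest.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list(); summary <- list(); warnings <- list()
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      manifest_write(cfg, artifacts, summary, partial = name)
      stop_sdm("stage '", name, "' failed: ", conditionMessage(e),
               class = "sdm_stage_error")
    })
  }

  # --- data ------------------------------------------------------------------
  obs <- stage("data", function() {
    if (!is.null(cfg$data_path)) return(read_observations(cfg$data_path))
    sc <- do.call(sim_config, modifyList(list(seed = derive_seed(cfg$seed, "sim")),
                                         cfg$sim))
    grids <- generate_covariate_fields(sc)
    sim <- simulate_observations(sc, grids)
    write_observations(sim$obs, file.path(cfg$out_dir, "observations.csv"))
    write_truth(sim$truth, file.path(cfg$out_dir, "truth.json"))
    for (v in names(grids))
      write_raster(grids[[v]], file.path(cfg$out_dir, paste0("cov_", v, ".asc")))
    artifacts$observations <<- file.path(cfg$out_dir, "observations.csv")
    artifacts$truth <<- file.path(cfg$out_dir, "truth.json")
    attr(sim$obs, "grids") <- grids
    sim$obs
  })
  summary$n_obs <- nrow(obs)
  summary$prevalence <- mean(obs$presence)

  # --- screening -------------------------------------------------------------
  covnames <- setdiff(names(obs), c("lon", "lat", "presence", "set_type"))
  if (isTRUE(cfg$screen$enabled) && length(covnames) >= 2) {
    rep_ <- stage("screen", function()
      screen_covariates(obs[covnames], cfg$screen$r_max, cfg$screen$vif_max))
    write_screening_report(rep_, file.path(cfg$out_dir, "screening"))
    artifacts$screening <- file.path(cfg$out_dir, "screening", "screening.json")
    summary$screen_retained <- rep_$retained
  }

  # --- mesh ------------------------------------------------------------------
  spec <- do.call(model_spec, cfg$model)
  mesh <- NULL
  if (spec$include_spatial) {
    mesh <- stage("mesh", function()
      build_mesh(cbind(obs$lon, obs$lat),
                 inner_max_edge = cfg$mesh$inner_max_edge,
                 outer_max_edge = cfg$mesh$outer_max_edge,
                 cutoff = cfg$mesh$cutoff %||% (cfg$mesh$inner_max_edge / 5),
                 extension_width = cfg$mesh$extension_width))
    mesh_path <- file.path(cfg$out_dir, "mesh.json")
    jsonlite::write_json(list(vertices = mesh$loc, triangles = mesh$tri,
                              inner = mesh$inner),
                         mesh_path, digits = NA)
    artifacts$mesh <- mesh_path
    summary$mesh <- c(vertices = nrow(mesh$loc), triangles = nrow(mesh$tri))
  }

  # --- fit -------------------------------------------------------------------
  ctl <- modifyList(list(seed = derive_seed(cfg$seed, "fit")), cfg$control)
  fit <- stage("fit", function() fit_sdm(obs, spec, mesh, control = ctl))
  write_summary_table(fit, file.path(cfg$out_dir, "posterior_summaries.csv"))
  artifacts$summaries <- file.path(cfg$out_dir, "posterior_summaries.csv")
  d <- dic(fit, 500, derive_seed(cfg$seed, "dic"))
  cp <- cpo_lcpo(fit, 500, derive_seed(cfg$seed, "cpo"))
  summary$fit <- list(theta_hat = fit$theta_hat, DIC = d$DIC, pD = d$pD,
                      LCPO = cp$lcpo)

  # --- selection -------------------------------------------------------------
  if (isTRUE(cfg$selection$enabled)) {
    sel <- stage("select", function()
      score_candidates(obs, enumerate_candidates(spec), mesh,
                       n_samples = cfg$selection$n_samples,
                       seed = derive_seed(cfg$seed, "select"), control = ctl))
    write.csv(sel$table, file.path(cfg$out_dir, "selection_table.csv"),
              row.names = FALSE)
    artifacts$selection <- file.path(cfg$out_dir, "selection_table.csv")
    summary$best_option <- sel$best_option
  }

  # --- validation ------------------------------------------------------------
  if (isTRUE(cfg$cv$enabled)) {
    cv <- stage("validate", function()
      cross_validate(obs, spec, mesh, k = cfg$cv$k, repeats = cfg$cv$repeats,
                     seed = derive_seed(cfg$seed, "cv"),
                     threshold = cfg$cv$threshold,
                     n_samples = cfg$cv$n_samples, control = ctl))
    write.csv(cv$per_fold, file.path(cfg$out_dir, "cv_metrics.csv"),
              row.names = FALSE)
    artifacts$cv <- file.path(cfg$out_dir, "cv_metrics.csv")
    summary$cv_mean <- as.list(cv$mean)
    warnings$failed_folds <- cv$failed_folds
  }

  # --- prediction ------------------------------------------------------------
  grids <- attr(obs, "grids")
  if (!is.null(grids)) {
    surf <- stage("predict", function() {
      bb <- list(lon = range(obs$lon), lat = range(obs$lat))
      grid <- prediction_grid(bb, cfg$prediction$cell_size)
      predict_surface(fit, grid, grids,
                      n_samples = cfg$prediction$n_samples,
                      seed = derive_seed(cfg$seed, "predict"),
                      settype_scenario = cfg$prediction$settype_scenario,
                      month_scenario = cfg$prediction$month_scenario)
    })
    write_surface(surf, file.path(cfg$out_dir, "surfaces"))
    for (nm in intersect(c("mean", "sd", "q025", "q975", "field_mean",
                           "field_sd"), names(surf)))
      artifacts[[paste0("surface_", nm)]] <-
        file.path(cfg$out_dir, "surfaces", paste0(nm, ".asc"))
    warnings$clamped_cells <- surf$clamped
  }

  manifest <- manifest_write(cfg, artifacts, summary)
  structure(list(artifacts = artifacts, summary = summary,
                 warnings = warnings, manifest = manifest,
                 out_dir = cfg$out_dir, fit = fit),
            class = "run_report")
}

manifest_write <- function(cfg, artifacts, summary, partial = NULL) {
  files <- unlist(artifacts)
  hashes <- if (length(files)) as.list(tools::md5sum(files)) else list()
  names(hashes) <- names(artifacts)
  man <- list(seed = cfg$seed, partial_at_stage = partial,
              files = hashes, summary = summary)
  jsonlite::write_json(man, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  man
}

#' @exportS3Method base::print
print.run_report <- function(x, ...) {
  cat("<run_report>", x$out_dir, "\n")
  cat(" artifacts:", paste(names(x$artifacts), collapse = ", "), "\n")
  str(x$summary, max.level = 2, give.attr = FALSE)
  invisible(x)
}
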