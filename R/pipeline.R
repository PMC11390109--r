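# End-to-end orchestration of the synthetic-mode analysis: world ->
# tracks -> segmentation -> dispersal -> stratified sampling -> model ->
# energy landscape, with a manifest for bit-reproducible reruns.

#' Run the full synthetic-mode pipeline
#'
#' Executes the stages in order on a synthetic world: simulate tracks,
#' derive flight altitude and ground speed, fit the population-level
#' behaviour model and label points, detect emigration and assign weeks,
#' extract commuting bouts and observed steps, fit the movement kernels,
#' build the stratified used/available dataset (data-derived z-transform),
#' screen correlations, fit the conditional logit, and build the weekly
#' energy-landscape series. Every stochastic stage derives its stream from
#' the config seed, so identical configs give identical outputs.
#'
#' @param config a [sim_config()].
#' @param n_alternatives alternatives per stratum.
#' @param threshold flyability cutoff for the landscape series.
#' @param weeks weeks for the landscape series; defaults to the simulated range.
#' @param mixed also fit the random-slope model (slower).
#' @param radius_m,min_days dispersal-detection rule (see [detect_emigration()]).
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @return a list with every stage's outputs plus a `manifest` of row counts.
#' @export
run_pipeline <- function(config, n_alternatives = 50, threshold = 0.7,
                         weeks = NULL, mixed = FALSE,
                         radius_m = 7000, min_days = 14, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  world <- build_world(config)
  tracks <- simulate_tracks(world)
  tracks <- compute_flight_altitude(tracks, world$dem, config$geoid_offset)
  tracks <- compute_ground_speed(tracks)
  model <- fit_behavior_model(tracks)
  tracks <- classify_behavior(tracks, model)
  disp <- detect_emigration_all(tracks, world$nests, radius_m = radius_m,
                                min_days = min_days,
                                max_week = config$post_emigration_weeks)
  tracks <- disp$tracks
  bouts <- extract_commuting_bouts(tracks)
  if (!nrow(bouts$bouts)) stop("pipeline halted at segmentation: no commuting bouts found")
  pts <- bouts$points[!is.na(bouts$points$week), , drop = FALSE]
  steps <- steps_from_bouts(pts)
  kernels <- fit_movement_kernels(steps)
  strata <- with_seed(derive_seed(config$seed, 9000L),
                      build_strata(steps, kernels, world$terrain, n_alternatives))
  ann <- annotate_and_transform(strata)
  screen <- correlation_screen(ann$strata)
  fit <- fit_conditional_logit(build_design(ann$strata))
  fit_mixed <- if (mixed) fit_mixed_conditional_logit(ann$strata) else NULL
  nrmse <- normalized_rmse(fit, ann$strata)
  if (is.null(weeks)) weeks <- seq_len(config$post_emigration_weeks)
  series <- landscape_series(fit, world$terrain, steps, weeks, threshold, ann$params)
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("eaglescape")),
    n_individuals = config$n_individuals,
    n_fixes = nrow(tracks),
    n_dispersed = sum(vapply(disp$results, function(r) r$status == "dispersed", TRUE)),
    n_bouts = nrow(bouts$bouts),
    n_steps = nrow(steps),
    n_strata = length(unique(strata$stratum_id)),
    rows_per_stratum = unname(sort(unique(table(strata$stratum_id)))),
    n_model_rows = nrow(ann$strata),
    converged = fit$converged,
    nrmse = nrmse,
    flagged_correlations = nrow(screen$flagged))
  result <- list(world = world, tracks = tracks, behavior_model = model,
                 dispersal = disp$results, bouts = bouts, steps = steps,
                 kernels = kernels, strata = ann$strata, tparams = ann$params,
                 screen = screen, fit = fit, fit_mixed = fit_mixed,
                 nrmse = nrmse, landscape = series, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write the pipeline artifacts as plain-text files
#'
#' Tracks, steps, stratified dataset and area series as CSV; the model fit
#' and the manifest as JSON; the flyability layers are recomputed on demand
#' rather than stored.
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$tracks, file.path(out_dir, "tracks_labeled.csv"),
                   row.names = FALSE)
  utils::write.csv(result$steps, file.path(out_dir, "steps.csv"), row.names = FALSE)
  utils::write.csv(result$strata, file.path(out_dir, "strata.csv"), row.names = FALSE)
  utils::write.csv(result$landscape$areas, file.path(out_dir, "flyable_area_series.csv"),
                   row.names = FALSE)
  utils::write.csv(coef_table(result$fit), file.path(out_dir, "coefficients.csv"),
                   row.names = FALSE)
  jsonlite::write_json(ssf_fit_to_list(result$fit, result$tparams),
                       file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Serialize a step-selection fit (with its transform constants) to a list
#'
#' The JSON round trip preserves everything needed to re-create prediction
#' maps: term names, estimates, SEs, CIs, the z-transform constants, and
#' diagnostics.
#'
#' @param fit an `ssf_fit`.
#' @param params the associated [transform_params()].
#' @return a plain list suitable for [jsonlite::write_json()].
#' @export
ssf_fit_to_list <- function(fit, params) {
  list(terms = names(fit$coefficients),
       estimate = unname(fit$coefficients), se = unname(fit$se),
       ci_lower = unname(fit$ci_lower), ci_upper = unname(fit$ci_upper),
       loglik = fit$loglik, converged = fit$converged, method = fit$method,
       dropped_terms = fit$dropped_terms, n_strata = fit$n_strata,
       random_effects = if (!is.null(fit$random_effects))
         list(sd_tri = fit$random_effects$sd_tri,
              sd_dist = fit$random_effects$sd_dist) else NULL,
       transform = lapply(unclass(params), as.list))
}

#' Rebuild a fit and its transform constants from the serialized list
#' @param x a list as produced by [ssf_fit_to_list()] (e.g. read back from JSON).
#' @return list with `fit` (an `ssf_fit`) and `params`.
#' @export
ssf_fit_from_list <- function(x) {
  cf <- setNames(as.numeric(x$estimate), x$terms)
  se <- setNames(as.numeric(x$se), x$terms)
  fit <- structure(list(
    coefficients = cf, se = se,
    ci_lower = setNames(as.numeric(x$ci_lower), x$terms),
    ci_upper = setNames(as.numeric(x$ci_upper), x$terms),
    vcov = NULL, loglik = x$loglik, null_loglik = NA_real_,
    converged = isTRUE(x$converged), iterations = NA_integer_,
    dropped_terms = unlist(x$dropped_terms), n_strata = x$n_strata,
    random_effects = NULL, method = x$method), class = "ssf_fit")
  tp <- x$transform
  params <- transform_params(
    tri = unlist(tp$tri), dist_ridge = unlist(tp$dist_ridge),
    step_length = unlist(tp$step_length), week = unlist(tp$week))
  list(fit = fit, params = params)
}
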