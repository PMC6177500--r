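WT_MODELS <- list(full = c("wss", "d", "wss_d"), wss = "wss", d = "d",
                  interaction = "wss_d")

#' Run the full synthetic-cohort analysis pipeline
#'
#' simulate -> per-subject maps -> shared geometry -> correlation
#' statistics -> bootstrap regressions -> wall-thickness prediction ->
#' evaluation.  Per subject, wall thickness is measured as the
#' lumen-to-outer-wall distance, the diameter from the traced centerline,
#' and WSS from the (background-corrected) velocity volume; maps are then
#' resampled to the shared geometry for the cohort-level statistics.  All
#' randomness flows from `config$seed` and `seed`, so a rerun writes
#' byte-identical tables.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional output directory; when given, CSV tables, the
#'   summary JSON and the resolved configuration are written there.
#' @param B bootstrap size (study default 1000).
#' @param seed seed for the bootstrap resampling plan (default: derived
#'   from `config$seed`).
#' @param use `"measured"` runs the estimators on meshes and velocity
#'   volumes; `"truth"` uses the generator's analytic maps (no velocity
#'   stage), useful for statistical validation at scale.
#' @param models named list of term sets to fit/predict (default: the full
#'   model and the three single-term reductions).
#' @param verbose print stage progress.
#' @return a list with `subjects_maps`, `shared`, `map_set`, `individual`
#'   (per-pair correlation summaries + per-subject fits), `bootstrap`
#'   (correlation results + `beta_ensemble` per model), `prediction`
#'   (per-subject evaluation table) and `summary` (the JSON-ready list).
#' @export
run_pipeline <- function(config, out_dir = NULL, B = 1000L, seed = NULL,
                         use = c("measured", "truth"), models = WT_MODELS,
                         verbose = TRUE) {
  use <- match.arg(use)
  if (is.null(seed)) seed <- rng_child_seeds(config$seed, 2L)[2L]
  say <- function(...) if (verbose) message(sprintf(...))

  say("stage 1/6: simulating %d subjects", config$n_subjects)
  subjects <- generate_cohort(config, velocity = use == "measured")

  say("stage 2/6: per-subject maps (%s)", use)
  maps <- lapply(subjects, function(s) subject_maps(s, config, use = use))

  say("stage 3/6: shared geometry + cohort map matrices")
  shared <- build_shared_geometry(lapply(subjects, function(s) s$lumen))
  map_set <- build_cohort_maps(shared, maps)

  say("stage 4/6: individual correlations and regressions")
  pair_tab <- lapply(names(MAP_PAIRS), function(p) {
    qq <- MAP_PAIRS[[p]]
    r <- individual_correlations(lapply(maps, `[[`, qq[1]),
                                 lapply(maps, `[[`, qq[2]))
    c(list(pair = p), r[c("mean_rho", "sd_rho", "p_value")],
      list(per_subject_rho = r$per_subject_rho))
  })
  names(pair_tab) <- names(MAP_PAIRS)
  linearity <- vapply(seq_along(maps), function(i)
    isTRUE(linearity_check(as.numeric(maps[[i]]$wss),
                           as.numeric(maps[[i]]$wt))$adequate), logical(1))
  indiv_fits <- lapply(names(models), function(mn) {
    lapply(seq_along(maps), function(i)
      fit_wt_regression(maps[[i]]$wt, maps[[i]]$wss, maps[[i]]$d,
                        terms = models[[mn]],
                        source = subjects[[i]]$subject_id))
  })
  names(indiv_fits) <- names(models)

  say("stage 5/6: bootstrap (B = %d)", B)
  multisets <- bootstrap_multisets(config$n_subjects, B, seed)
  boot_cor <- bootstrap_correlations(map_set, multisets = multisets, seed = seed)
  boot_beta <- lapply(models, function(tt)
    fit_bootstrap_regressions(map_set, terms = tt, multisets = multisets,
                              seed = seed))

  say("stage 6/6: wall-thickness prediction and evaluation")
  pred_rows <- list()
  for (mn in names(models)) {
    for (i in seq_along(maps)) {
      self_eval <- evaluate_prediction(maps[[i]]$wt,
                                       predict(indiv_fits[[mn]][[i]]))
      coh_pred <- predict_wt_map(maps[[i]]$wss, maps[[i]]$d,
                                 coef(boot_beta[[mn]]), terms = models[[mn]])
      coh_eval <- evaluate_prediction(maps[[i]]$wt, coh_pred)
      pred_rows[[length(pred_rows) + 1L]] <- data.frame(
        subject = subjects[[i]]$subject_id, model = mn,
        source = c("individual", "cohort"),
        rho = c(self_eval$spearman_rho, coh_eval$spearman_rho),
        mean_diff = c(self_eval$mean_difference, coh_eval$mean_difference),
        loa = c(self_eval$loa, coh_eval$loa),
        max_wt_orig = c(self_eval$max_wt_original, coh_eval$max_wt_original),
        max_wt_pred = c(self_eval$max_wt_predicted, coh_eval$max_wt_predicted))
    }
  }
  prediction <- do.call(rbind, pred_rows)

  summary_list <- pipeline_summary(pair_tab, linearity, boot_cor, boot_beta,
                                   prediction, config, B, seed, use)
  out <- list(subjects = subjects, maps = maps, shared = shared,
              map_set = map_set,
              individual = list(correlations = pair_tab, fits = indiv_fits,
                                linearity_adequate = linearity),
              bootstrap = list(correlations = boot_cor, beta = boot_beta,
                               multisets = multisets),
              prediction = prediction, summary = summary_list)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, config)
  invisible(out)
}

## Measured or truth maps for one subject, as a named list (wt, wss, d).
subject_maps <- function(subject, config, use = "measured") {
  if (use == "truth") {
    return(list(wt = subject$truth$wt, wss = subject$truth$wss,
                d = subject$truth$diameter))
  }
  lumen <- subject$lumen
  wt <- compute_wall_thickness(lumen, subject$outer_wall)
  cl <- compute_centerline(lumen)
  d <- compute_diameter_map(lumen, cl)
  img <- subject$velocity
  mask <- static_tissue_mask(img, lumen, margin = 5)
  img <- correct_background_offset(img, mask)
  wss <- compute_wss_map(lumen, img, d, viscosity = config$viscosity)
  list(wt = wt, wss = wss, d = d)
}

pipeline_summary <- function(pair_tab, linearity, boot_cor, boot_beta,
                             prediction, config, B, seed, use) {
  agg <- function(df) {
    data.frame(rho_mean = mean(df$rho, na.rm = TRUE),
               rho_sd = stats::sd(df$rho),
               p_value = fisher_z_test(df$rho)$p_value,
               mean_diff = mean(df$mean_diff), loa_mean = mean(df$loa),
               max_wt_orig = mean(df$max_wt_orig),
               max_wt_pred = mean(df$max_wt_pred))
  }
  pred_by <- split(prediction, list(prediction$model, prediction$source))
  model_table <- do.call(rbind, lapply(names(pred_by), function(k) {
    cbind(data.frame(model_source = k), agg(pred_by[[k]]))
  }))
  list(
    n_subjects = config$n_subjects, bootstrap_B = B, seed = seed, maps = use,
    viscosity = config$viscosity,
    individual = lapply(pair_tab, function(p)
      p[c("pair", "mean_rho", "sd_rho", "p_value")]),
    linearity_adequate_fraction = mean(linearity),
    bootstrap = lapply(boot_cor, function(b)
      list(pair = b$pair, mean_rho = b$mean_rho, ci95 = b$ci95,
           significant = b$significant)),
    beta = lapply(boot_beta, function(be)
      list(mean = as.list(be$mean_beta),
           ci_lo = as.list(be$ci95[1, ]), ci_hi = as.list(be$ci95[2, ]))),
    model_comparison = model_table
  )
}

write_pipeline_outputs <- function(out, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  irho <- do.call(rbind, lapply(out$summary$individual, function(p)
    data.frame(pair = p$pair, mean_rho = p$mean_rho, sd_rho = p$sd_rho,
               p_value = p$p_value)))
  w(irho, "individual_correlations.csv")
  per_subj <- do.call(rbind, lapply(out$individual$correlations, function(p)
    data.frame(pair = p$pair,
               subject = seq_along(p$per_subject_rho),
               rho = p$per_subject_rho)))
  w(per_subj, "individual_correlations_per_subject.csv")
  brho <- do.call(rbind, lapply(out$bootstrap$correlations, function(b)
    data.frame(pair = b$pair, mean_rho = b$mean_rho, ci_lo = b$ci95[1],
               ci_hi = b$ci95[2], significant = b$significant, B = b$B)))
  w(brho, "bootstrap_correlations.csv")
  reps <- do.call(cbind, lapply(out$bootstrap$correlations,
                                function(b) b$rho_per_bootstrap))
  w(data.frame(replicate = seq_len(nrow(reps)), reps),
    "bootstrap_correlations_replicates.csv")
  beta_tab <- do.call(rbind, lapply(names(out$bootstrap$beta), function(mn) {
    s <- summary(out$bootstrap$beta[[mn]])
    cbind(model = mn, s)
  }))
  w(beta_tab, "bootstrap_beta.csv")
  w(out$prediction, "prediction_per_subject.csv")
  w(out$summary$model_comparison, "model_comparison.csv")
  jsonlite::write_json(out$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write a synthetic cohort to disk
#'
#' Per subject: lumen and outer-wall meshes as ASCII PLY, truth maps as
#' CSV, the velocity volume as 4D NIfTI, plus a JSON cohort manifest.
#'
#' @param subjects list of subjects from [generate_cohort()].
#' @param dir destination directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(subjects, function(s) {
    id <- s$subject_id
    write_mesh(s$lumen, file.path(dir, paste0(id, "_lumen.ply")))
    write_mesh(s$outer_wall, file.path(dir, paste0(id, "_outer.ply")))
    for (q in names(s$truth))
      write_map_csv(s$truth[[q]], file.path(dir, paste0(id, "_truth_", q, ".csv")))
    if (!is.null(s$velocity))
      write_velocity_nifti(s$velocity, file.path(dir, paste0(id, "_velocity.nii")))
    list(subject_id = id, truth_beta = s$truth_beta,
         n_vertices = nrow(s$lumen$vertices),
         has_velocity = !is.null(s$velocity))
  })
  jsonlite::write_json(manifest, file.path(dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
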