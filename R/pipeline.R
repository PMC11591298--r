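#' Default pipeline configuration
#'
#' Assembles the configuration for a desk-scale end-to-end run: 15
#' synthetic in vivo subjects (3 fluoroscopic trials each), 10 synthetic
#' in vitro specimens, 101 cycle nodes, the three activities, default
#' virtual-knee parameters, the 2.0 mm tuning tolerance, and SPM at
#' alpha 0.05 with the per-activity comparison family.
#'
#' @param seed master seed for every random draw of the run.
#' @return a nested list of class `"run_config"`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    activities = c("gait", "stair_descent", "sit_stand"),
    n_nodes = 101L,
    cohort = list(n_subjects = 15L, n_trials = 3L, trial_sd_mm = 0.3,
                  sd_medial = 1.2, sd_lateral = 1.9,
                  body_mass_mean = 80, body_mass_sd = 10,
                  implant_size_mean = 62, implant_size_sd = 3),
    intercondylar_distance = 49,
    knee = list(),                         # overrides for virtual_knee_params()
    specimens = list(n_specimens = 10L, stiffness_jitter = 0.15,
                     compliance_jitter = 0.25, dwell_jitter_mm = 0.3),
    cams = list(ap_scale = 1.8, ap_shift_mm = 2.0),
    tuning = list(tol_mm = 2.0, max_iter = 50L, gain = 0.7),
    stats = list(alpha = 0.05, family_size = 4L, n_perm = 200L),
    report = TRUE), class = "run_config")
}

pipeline_stage <- function(name, out_dir, expr) {
  message(sprintf("[kneebc] stage: %s", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s (partial outputs under %s)",
                 name, conditionMessage(e), out_dir), call. = FALSE))
}

lowpoint_series_to_waveforms <- function(lp, activity) {
  list(medial_lowpoint_ap = waveform(lp$percent_cycle, lp$medial_ap,
                                     "medial_lowpoint_ap", "mm", activity),
       lateral_lowpoint_ap = waveform(lp$percent_cycle, lp$lateral_ap,
                                      "lateral_lowpoint_ap", "mm", activity))
}

# Build the per-activity synthetic in vivo dataset and displacement BCs.
generate_activity_inputs <- function(cfg, activity_name) {
  act <- activity_spec(activity_name, cfg$n_nodes)
  ch <- cfg$cohort
  subjects <- with_seed(substream_seed(cfg$seed, "cohort", activity_name), {
    lapply(seq_len(ch$n_subjects), function(i)
      subject_spec(sprintf("S%02d", i),
                   body_mass = max(40, stats::rnorm(1, ch$body_mass_mean,
                                                    ch$body_mass_sd)),
                   implant_ap_size = max(50, stats::rnorm(1, ch$implant_size_mean,
                                                          ch$implant_size_sd)),
                   seed = cfg$seed))
  })
  trajs <- gen_lowpoint_trajectories(act, subjects,
                                     sd_medial = ch$sd_medial,
                                     sd_lateral = ch$sd_lateral,
                                     intercondylar_distance =
                                       cfg$intercondylar_distance)
  sizes <- vapply(subjects, `[[`, numeric(1), "implant_ap_size")
  names(sizes) <- names(trajs)
  # trial-level replicates around each subject's trajectory
  make_trials <- function(col, quantity) {
    out <- lapply(names(trajs), function(s) {
      base <- trajs[[s]][[col]]
      with_seed(substream_seed(cfg$seed, "trials", activity_name, s, col), {
        lapply(seq_len(ch$n_trials), function(k)
          waveform(trajs[[s]]$percent_cycle,
                   base + stats::rnorm(length(base), 0, ch$trial_sd_mm),
                   quantity, "mm", activity_name))
      })
    })
    names(out) <- names(trajs)
    out
  }
  avg_med <- average_cohort(make_trials("medial_ap", "medial_lowpoint_ap"),
                            implant_sizes = sizes)
  avg_lat <- average_cohort(make_trials("lateral_ap", "lateral_lowpoint_ap"),
                            implant_sizes = sizes)
  target <- data.frame(percent_cycle = trajs[[1L]]$percent_cycle,
                       medial_ap = avg_med$mean$values,
                       lateral_ap = avg_lat$mean$values)
  class(target) <- c("lowpoint_series", "data.frame")
  loads <- gen_load_waveforms(act)
  flexion <- default_flexion_waveform(act)
  trans <- lowpoints_to_ie_ap(target$medial_ap, target$lateral_ap,
                              cfg$intercondylar_distance)
  disp_set <- assemble_boundary_conditions(
    "implant_specific_displacement",
    list(fluoro_fe = flexion,
         fluoro_ie = waveform(flexion$percent_cycle, trans$internal_external,
                              "ie_rotation", "deg", activity_name),
         fluoro_ap = waveform(flexion$percent_cycle, trans$anterior_posterior,
                              "ap_translation", "mm", activity_name),
         orthoload_si = loads$tf_compression,
         mocap_quad = loads$quadriceps))
  list(act = act, subjects = subjects, trajs = trajs, target = target,
       loads = loads, flexion = flexion, disp_set = disp_set,
       band = list(medial = avg_med, lateral = avg_lat))
}

jittered_knee_params <- function(cfg, specimen, activity_name) {
  base <- do.call(virtual_knee_params, cfg$knee)
  sj <- cfg$specimens
  with_seed(substream_seed(cfg$seed, "specimen", activity_name, specimen), {
    virtual_knee_params(
      ap_stiffness_per_compression = base$ap_stiffness_per_compression *
        exp(stats::rnorm(1, 0, sj$stiffness_jitter)),
      ie_stiffness_per_compression = base$ie_stiffness_per_compression *
        exp(stats::rnorm(1, 0, sj$stiffness_jitter)),
      baseline_ap_stiffness = base$baseline_ap_stiffness *
        exp(stats::rnorm(1, 0, sj$stiffness_jitter)),
      baseline_ie_stiffness = base$baseline_ie_stiffness *
        exp(stats::rnorm(1, 0, sj$stiffness_jitter)),
      fixture_compliance_ap = base$fixture_compliance_ap *
        exp(stats::rnorm(1, 0, sj$compliance_jitter)),
      fixture_compliance_ie = base$fixture_compliance_ie *
        exp(stats::rnorm(1, 0, sj$compliance_jitter)),
      dwell_ap_of_flexion = base$dwell_ap_of_flexion +
        c(stats::rnorm(1, 0, sj$dwell_jitter_mm), 0),
      quad_to_compression_gain_of_flexion =
        base$quad_to_compression_gain_of_flexion,
      extensor_moment_arm_of_flexion = base$extensor_moment_arm_of_flexion,
      pf_wrap_coefs = base$pf_wrap_coefs)
  })
}

specimen_curves <- function(cfg, bc_set, activity_name) {
  lapply(seq_len(cfg$specimens$n_specimens), function(j) {
    params <- jittered_knee_params(cfg, sprintf("K%02d", j), activity_name)
    sim <- simulate_load_control(bc_set, params)
    lp <- achieved_lowpoints(sim, cfg$intercondylar_distance)
    list(lowpoints = lp,
         ap = sim$achieved$anterior_posterior,
         ie = sim$achieved$internal_external,
         flexion = sim$achieved$flexion)
  })
}

evaluate_bc_variant <- function(cfg, inputs, bc_set, label, activity_name,
                                eval_dir) {
  curves <- specimen_curves(cfg, bc_set, activity_name)
  grid <- inputs$target$percent_cycle
  # synchronize specimen cycles on most extended flexion at cycle start
  flex_wfs <- lapply(curves, function(cu)
    waveform(grid, cu$flexion, "flexion", "deg", activity_name))
  cyc_sets <- lapply(curves, function(cu) list(
    medial_lowpoint_ap = waveform(grid, cu$lowpoints$medial_ap,
                                  "medial_lowpoint_ap", "mm", activity_name),
    lateral_lowpoint_ap = waveform(grid, cu$lowpoints$lateral_ap,
                                   "lateral_lowpoint_ap", "mm", activity_name),
    ap_translation = waveform(grid, cu$ap, "ap_translation", "mm",
                              activity_name),
    ie_rotation = waveform(grid, cu$ie, "ie_rotation", "deg", activity_name)))
  sync <- synchronize(cyc_sets, flex_wfs)
  quantities <- names(cyc_sets[[1L]])
  vitro_groups <- lapply(quantities, function(q)
    do.call(rbind, lapply(sync$cycles, function(s) s[[q]]$values)))
  names(vitro_groups) <- quantities
  # in vivo per-subject curve groups for the same quantities
  d <- cfg$intercondylar_distance
  vivo_groups <- list(
    medial_lowpoint_ap = do.call(rbind, lapply(inputs$trajs, `[[`, "medial_ap")),
    lateral_lowpoint_ap = do.call(rbind, lapply(inputs$trajs, `[[`, "lateral_ap")))
  vivo_trans <- lapply(inputs$trajs, function(tr)
    lowpoints_to_ie_ap(tr$medial_ap, tr$lateral_ap, d))
  vivo_groups$ap_translation <- do.call(rbind, lapply(vivo_trans, `[[`,
                                                      "anterior_posterior"))
  vivo_groups$ie_rotation <- do.call(rbind, lapply(vivo_trans, `[[`,
                                                   "internal_external"))
  # mean-vs-mean phase-partitioned RMSE report
  mk_wf <- function(vals, q, un) waveform(grid, vals, q, un, activity_name)
  units_of <- c(medial_lowpoint_ap = "mm", lateral_lowpoint_ap = "mm",
                ap_translation = "mm", ie_rotation = "deg")
  vivo_means <- lapply(quantities, function(q)
    mk_wf(colMeans(vivo_groups[[q]]), q, units_of[[q]]))
  names(vivo_means) <- quantities
  vitro_means <- lapply(quantities, function(q)
    mk_wf(colMeans(vitro_groups[[q]]), q, units_of[[q]]))
  names(vitro_means) <- quantities
  report <- rmse_report(vivo_means, vitro_means, activity_name)
  # SPM per quantity, Bonferroni over the comparison family
  spm_rows <- list(); cluster_rows <- list()
  for (q in quantities) {
    res <- spm_ttest2_1d(vivo_groups[[q]], vitro_groups[[q]],
                         alpha = cfg$stats$alpha,
                         n_comparisons = cfg$stats$family_size)
    spm_rows[[q]] <- data.frame(quantity = q, fwhm_nodes = res$fwhm,
                                critical_t = res$critical_t,
                                percent_significant = res$percent_significant,
                                n_clusters = nrow(res$clusters))
    if (nrow(res$clusters) > 0L)
      cluster_rows[[q]] <- cbind(quantity = q, res$clusters)
  }
  spm_table <- do.call(rbind, spm_rows)
  clusters <- if (length(cluster_rows)) do.call(rbind, cluster_rows)
              else data.frame(quantity = character(0),
                              start_percent = numeric(0),
                              end_percent = numeric(0))
  # persist
  vitro_df <- do.call(rbind, lapply(seq_along(sync$cycles), function(j)
    do.call(rbind, lapply(sync$cycles[[j]], function(w)
      cbind(as.data.frame(w)[1L], subject = sprintf("K%02d", j),
            as.data.frame(w)[-1L])))))
  utils::write.csv(vitro_df, file.path(eval_dir,
                                       sprintf("invitro_%s.csv", label)),
                   row.names = FALSE)
  utils::write.csv(report, file.path(eval_dir, sprintf("rmse_%s.csv", label)),
                   row.names = FALSE)
  utils::write.csv(spm_table, file.path(eval_dir, sprintf("spm_%s.csv", label)),
                   row.names = FALSE)
  utils::write.csv(clusters,
                   file.path(eval_dir, sprintf("spm_clusters_%s.csv", label)),
                   row.names = FALSE)
  list(report = report, spm = spm_table, clusters = clusters,
       vivo_means = vivo_means, vitro_means = vitro_means,
       vivo_groups = vivo_groups, vitro_groups = vitro_groups)
}

#' Run the full desk-scale pipeline
#'
#' Executes generate -> assemble (implant-specific displacement) -> tune
#' (implant-specific load) -> derive an alternative high-conformity-style
#' ("CAMS-like") load variant -> evaluate (phase-partitioned RMSE tables
#' and SPM significance bars against the synthetic in vivo cohort) ->
#' report, writing every artifact under `out_dir` together with a
#' manifest (seed, config, output hashes) that allows an exact rerun.
#'
#' @param config a [default_run_config()]-style list.
#' @param out_dir writable output directory.
#' @return invisibly, a list of per-activity results (`tuning`,
#'   `evaluation`) plus the manifest path.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  knee_params <- do.call(virtual_knee_params, config$knee)
  knee <- virtual_knee_provider(knee_params)
  results <- list()
  for (activity_name in config$activities) {
    adir <- file.path(out_dir, activity_name)
    dir.create(adir, showWarnings = FALSE)

    inputs <- pipeline_stage(paste0("generate/", activity_name), out_dir, {
      inp <- generate_activity_inputs(config, activity_name)
      vivo_wfs <- unlist(lapply(names(inp$trajs), function(s) {
        wfs <- lowpoint_series_to_waveforms(inp$trajs[[s]], activity_name)
        lapply(wfs, function(w) { attr(w, "subject") <- s; w })
      }), recursive = FALSE)
      df <- do.call(rbind, lapply(vivo_wfs, function(w)
        cbind(as.data.frame(w)[1L], subject = attr(w, "subject"),
              as.data.frame(w)[-1L])))
      utils::write.csv(df, file.path(adir, "invivo_lowpoints.csv"),
                       row.names = FALSE)
      utils::write.csv(inp$target, file.path(adir, "target_lowpoints.csv"),
                       row.names = FALSE)
      write_bc_set(inp$disp_set, file.path(adir, "bc_displacement"), "disp")
      inp
    })

    tune <- pipeline_stage(paste0("tune/", activity_name), out_dir, {
      tr <- derive_load_profiles(inputs$target, inputs$disp_set, knee,
                                 intercondylar_distance =
                                   config$intercondylar_distance,
                                 tol_mm = config$tuning$tol_mm,
                                 max_iter = config$tuning$max_iter,
                                 gain = config$tuning$gain)
      write_tuning_result(tr, file.path(adir, "tuning"))
      tr
    })

    cams_set <- pipeline_stage(paste0("cams/", activity_name), out_dir, {
      # high-conformity-style alternative: loads tuned to a distorted
      # target with exaggerated anterior excursion
      distorted <- inputs$target
      distorted$medial_ap <- distorted$medial_ap * config$cams$ap_scale +
        config$cams$ap_shift_mm
      distorted$lateral_ap <- distorted$lateral_ap * config$cams$ap_scale +
        config$cams$ap_shift_mm
      tr_cams <- derive_load_profiles(distorted, inputs$disp_set, knee,
                                      intercondylar_distance =
                                        config$intercondylar_distance,
                                      tol_mm = config$tuning$tol_mm,
                                      max_iter = config$tuning$max_iter,
                                      gain = config$tuning$gain)
      cams <- assemble_boundary_conditions(
        "cams",
        list(cams_fe = inputs$flexion,
             cams_ie = tr_cams$load_profiles[["I-E"]]$waveform,
             cams_ap = tr_cams$load_profiles[["A-P"]]$waveform,
             orthoload_si = inputs$loads$tf_compression,
             mocap_quad = inputs$loads$quadriceps))
      write_bc_set(cams, file.path(adir, "bc_cams"), "cams")
      cams
    })

    evaluation <- pipeline_stage(paste0("evaluate/", activity_name), out_dir, {
      eval_dir <- file.path(adir, "evaluation")
      dir.create(eval_dir, showWarnings = FALSE)
      list(implant_specific = evaluate_bc_variant(
             config, inputs, tune$load_profiles, "implant_specific",
             activity_name, eval_dir),
           cams = evaluate_bc_variant(
             config, inputs, cams_set, "cams", activity_name, eval_dir))
    })

    results[[activity_name]] <- list(tuning = tune, evaluation = evaluation)
  }

  if (isTRUE(config$report))
    pipeline_stage("report", out_dir, make_report(out_dir))

  manifest <- pipeline_stage("manifest", out_dir, {
    files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
    files <- files[grepl("\\.(csv|yaml)$", files) & files != "manifest.yaml"]
    hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
    names(hashes) <- files
    path <- file.path(out_dir, "manifest.yaml")
    yaml::write_yaml(list(seed = config$seed, outputs = hashes), path)
    path
  })
  invisible(list(results = results, manifest = manifest))
}

#' Generate report tables and plots from a completed run
#'
#' Reads the evaluation outputs under `out_dir` and writes combined
#' RMSE tables (one per boundary-condition variant, activities in rows)
#' plus per-activity overlay plots of the condylar low-point kinematics
#' with mean +/- SD bands and horizontal significance bars.
#'
#' @param out_dir a directory written by [run_pipeline()].
#' @return invisibly, the report directory.
#' @export
make_report <- function(out_dir) {
  cfg_path <- file.path(out_dir, "config.yaml")
  if (!file.exists(cfg_path))
    stop("incomplete run: config.yaml missing under ", out_dir)
  cfg <- yaml::read_yaml(cfg_path)
  rep_dir <- file.path(out_dir, "report")
  dir.create(rep_dir, showWarnings = FALSE)
  for (label in c("implant_specific", "cams")) {
    rows <- lapply(cfg$activities, function(a) {
      f <- file.path(out_dir, a, "evaluation", sprintf("rmse_%s.csv", label))
      if (!file.exists(f))
        stop("incomplete run: missing ", f)
      cbind(activity = a, utils::read.csv(f))
    })
    # per-activity phase labels differ; bind with generic phase columns
    rows <- lapply(rows, function(r) {
      names(r)[4:5] <- c("phase1", "phase2")
      r
    })
    utils::write.csv(do.call(rbind, rows),
                     file.path(rep_dir, sprintf("rmse_table_%s.csv", label)),
                     row.names = FALSE)
  }
  for (a in cfg$activities) {
    eval_dir <- file.path(out_dir, a, "evaluation")
    tgt <- utils::read.csv(file.path(out_dir, a, "target_lowpoints.csv"))
    png_path <- file.path(rep_dir, sprintf("lowpoints_%s.png", a))
    grDevices::png(png_path, width = 1400, height = 600, res = 120)
    graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    for (q in c("medial_lowpoint_ap", "lateral_lowpoint_ap")) {
      graphics::plot(tgt$percent_cycle,
                     tgt[[sub("_lowpoint_ap", "_ap", q)]], type = "l",
                     lwd = 2, xlab = "% cycle", ylab = paste(q, "(mm)"),
                     main = a)
      cols <- c(implant_specific = "blue", cams = "red")
      for (label in names(cols)) {
        d <- utils::read.csv(file.path(eval_dir,
                                       sprintf("invitro_%s.csv", label)))
        d <- d[d$quantity == q, ]
        m <- tapply(d$value, d$percent_cycle, mean)
        s <- tapply(d$value, d$percent_cycle, stats::sd)
        x <- as.numeric(names(m))
        graphics::polygon(c(x, rev(x)), c(m + s, rev(m - s)), border = NA,
                          col = grDevices::adjustcolor(cols[label], 0.2))
        graphics::lines(x, m, col = cols[label], lwd = 2)
        cl <- utils::read.csv(file.path(eval_dir,
                                        sprintf("spm_clusters_%s.csv", label)))
        cl <- cl[cl$quantity == q, , drop = FALSE]
        if (nrow(cl) > 0) {
          y0 <- graphics::par("usr")[3] +
            0.04 * diff(graphics::par("usr")[3:4]) *
            match(label, names(cols))
          graphics::segments(cl$start_percent, y0, cl$end_percent, y0,
                             col = cols[label], lwd = 4)
        }
      }
    }
    grDevices::dev.off()
  }
  invisible(rep_dir)
}
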