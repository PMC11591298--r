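#' Per-condyle low-point RMSE between achieved and target series
#'
#' @param achieved,target `lowpoint_series` data frames on a common
#'   grid (columns `medial_ap`, `lateral_ap`).
#' @param phase_mask optional logical vector selecting cycle nodes.
#' @return named numeric `c(medial, lateral)` in mm.
#' @export
lowpoint_rmse <- function(achieved, target, phase_mask = NULL) {
  if (nrow(achieved) != nrow(target))
    stop("achieved and target series are not on a common grid")
  if (is.null(phase_mask)) phase_mask <- rep(TRUE, nrow(target))
  if (!any(phase_mask)) stop("empty phase mask")
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  c(medial = rmse(achieved$medial_ap[phase_mask], target$medial_ap[phase_mask]),
    lateral = rmse(achieved$lateral_ap[phase_mask], target$lateral_ap[phase_mask]))
}

achieved_lowpoints <- function(sim, intercondylar_distance) {
  lp <- ie_ap_to_lowpoints(sim$achieved$internal_external,
                           sim$achieved$anterior_posterior,
                           intercondylar_distance)
  df <- data.frame(percent_cycle = sim$achieved$percent_cycle,
                   medial_ap = lp$medial_ap, lateral_ap = lp$lateral_ap)
  class(df) <- c("lowpoint_series", "data.frame")
  df
}

replace_loads <- function(load_profiles, f_ap, t_ie) {
  load_profiles[["A-P"]]$waveform <- wf_with(load_profiles[["A-P"]]$waveform, f_ap)
  load_profiles[["I-E"]]$waveform <- wf_with(load_profiles[["I-E"]]$waveform, t_ie)
  load_profiles
}

#' Derive load-controlled profiles from displacement-controlled ones
#'
#' The displacement-to-load conversion loop: (1) run the
#' displacement-controlled profiles on the knee and record the A-P force
#' and I-E torque the actuator applied; (2) replay the recorded loads in
#' load control, compute the achieved condylar low points, and the
#' per-condyle RMSE against the target; (3) while the RMSE exceeds the
#' tolerance, correct each load waveform node by `gain` times the
#' kinematic error mapped through a locally estimated stiffness (secant
#' from the last two iterates; a small probe simulation seeds the first
#' estimate), and replay. If the worst-condyle RMSE increases, the gain
#' is halved once before the loop gives up.
#'
#' @param target_lowpoints `lowpoint_series` data frame (columns
#'   `percent_cycle`, `medial_ap`, `lateral_ap`) on the profile grid.
#' @param displacement_profiles a `"bc_profile_set"` of variant
#'   `"implant_specific_displacement"`.
#' @param knee a response provider, e.g. [virtual_knee_provider()].
#' @param intercondylar_distance mm, for the low-point <-> (I-E, A-P)
#'   transform.
#' @param tol_mm convergence tolerance on both condylar RMSEs (default
#'   2.0 mm).
#' @param max_iter maximum load-control iterations (default 50).
#' @param gain proportional correction gain (default 0.7).
#' @return a `"tuning_result"`: `load_profiles` (variant
#'   `"implant_specific_load"`), `rmse_history` (iterations x 2 matrix,
#'   mm), `iterations`, `converged`, `gain_halved`.
#' @export
derive_load_profiles <- function(target_lowpoints, displacement_profiles,
                                 knee = virtual_knee_provider(),
                                 intercondylar_distance = 49,
                                 tol_mm = 2.0, max_iter = 50L, gain = 0.7) {
  stopifnot(inherits(displacement_profiles, "bc_profile_set"))
  grid <- displacement_profiles[["F-E"]]$waveform$percent_cycle
  if (nrow(target_lowpoints) != length(grid))
    stop("target low points and profiles are not on a common cycle grid")
  tgt <- lowpoints_to_ie_ap(target_lowpoints$medial_ap,
                            target_lowpoints$lateral_ap,
                            intercondylar_distance)

  # Step 1: displacement control, record actuator loads.
  rec <- knee$displacement_control(displacement_profiles)
  f_ap <- rec$recorded$ap_force$values
  t_ie <- rec$recorded$ie_torque$values

  load_profiles <- assemble_boundary_conditions(
    "implant_specific_load",
    list(fluoro_fe = displacement_profiles[["F-E"]]$waveform,
         orthoload_si = displacement_profiles[["S-I"]]$waveform,
         mocap_quad = displacement_profiles[["Quad"]]$waveform,
         derived_ap = rec$recorded$ap_force,
         derived_ie = rec$recorded$ie_torque))

  run <- function(f, t) {
    sim <- knee$load_control(replace_loads(load_profiles, f, t))
    lp <- achieved_lowpoints(sim, intercondylar_distance)
    list(sim = sim, lp = lp, rmse = lowpoint_rmse(lp, target_lowpoints))
  }

  # Step 2: initial replay.
  cur <- run(f_ap, t_ie)
  history <- matrix(cur$rmse, 1L, 2L,
                    dimnames = list(NULL, c("medial", "lateral")))
  iterations <- 1L
  gain_halved <- FALSE

  if (max(cur$rmse) > tol_mm && max_iter > 1L) {
    # probe for initial per-node stiffness estimates
    dF <- 5; dT <- 200
    probe <- run(f_ap + dF, t_ie + dT)
    s_ap <- dF / pmax(probe$sim$achieved$anterior_posterior -
                        cur$sim$achieved$anterior_posterior, 1e-9)
    s_ie <- dT / pmax(probe$sim$achieved$internal_external -
                        cur$sim$achieved$internal_external, 1e-9)
    prev <- NULL
    while (iterations < max_iter && max(cur$rmse) > tol_mm) {
      e_ap <- tgt$anterior_posterior - cur$sim$achieved$anterior_posterior
      e_ie <- tgt$internal_external - cur$sim$achieved$internal_external
      f_new <- f_ap + gain * s_ap * e_ap
      t_new <- t_ie + gain * s_ie * e_ie
      nxt <- run(f_new, t_new)
      # secant stiffness update where the kinematics actually moved
      dxa <- nxt$sim$achieved$anterior_posterior -
        cur$sim$achieved$anterior_posterior
      dxe <- nxt$sim$achieved$internal_external -
        cur$sim$achieved$internal_external
      upd_a <- abs(dxa) > 1e-9
      upd_e <- abs(dxe) > 1e-9
      s_ap[upd_a] <- (f_new - f_ap)[upd_a] / dxa[upd_a]
      s_ie[upd_e] <- (t_new - t_ie)[upd_e] / dxe[upd_e]
      f_ap <- f_new; t_ie <- t_new
      prev <- cur; cur <- nxt
      history <- rbind(history, cur$rmse)
      iterations <- iterations + 1L
      if (max(cur$rmse) > max(prev$rmse) + 1e-12) {
        if (!gain_halved) {
          gain <- gain / 2
          gain_halved <- TRUE
        } else break
      }
    }
  }

  structure(list(load_profiles = replace_loads(load_profiles, f_ap, t_ie),
                 rmse_history = history,
                 iterations = iterations,
                 converged = max(cur$rmse) <= tol_mm,
                 gain_halved = gain_halved,
                 final_rmse = cur$rmse,
                 achieved_lowpoints = cur$lp),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf(paste0("<tuning_result> %s after %d iteration(s); final RMSE ",
                     "medial %.3f mm, lateral %.3f mm\n"),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$final_rmse["medial"], x$final_rmse["lateral"]))
  invisible(x)
}
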