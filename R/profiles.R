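#' Construct a boundary-condition profile
#'
#' One row of a simulator boundary-condition set: a degree of freedom,
#' its control mode (displacement or load), the data source the profile
#' was built from, and the command waveform.
#'
#' @param dof one of `"F-E"`, `"Ad-Ab"`, `"I-E"`, `"M-L"`, `"A-P"`,
#'   `"S-I"`, `"Quad"`.
#' @param control_mode `"displacement"` or `"load"`.
#' @param source one of `"Fluoro"`, `"OrthoLoad"`, `"MoCap"`, `"CAMS"`,
#'   `"Derived"`, `"Zero"`.
#' @param wf the command [waveform()].
#' @return an object of class `"bc_profile"`.
#' @export
bc_profile <- function(dof, control_mode, source, wf) {
  dof <- match.arg(dof, c("F-E", "Ad-Ab", "I-E", "M-L", "A-P", "S-I", "Quad"))
  control_mode <- match.arg(control_mode, c("displacement", "load"))
  source <- match.arg(source, c("Fluoro", "OrthoLoad", "MoCap", "CAMS",
                                "Derived", "Zero"))
  stopifnot(is_waveform(wf))
  if (source == "Zero" && any(wf$values != 0))
    stop("Zero-source profiles must carry identically-zero waveforms")
  structure(list(dof = dof, control_mode = control_mode, source = source,
                 waveform = wf), class = "bc_profile")
}

#' @export
print.bc_profile <- function(x, ...) {
  cat(sprintf("<bc_profile> %-5s %-12s %-9s [%s]\n", x$dof, x$control_mode,
              x$source, x$waveform$units))
  invisible(x)
}

#' Average waveforms across trials and subjects with implant-size scaling
#'
#' The cohort-averaging rule for fluoroscopic kinematics: waveforms are
#' averaged across all trials for a subject, translational quantities are
#' normalized to the mean implant size (multiplied by
#' `mean_size / subject_size`), and the per-subject means are then
#' averaged (unweighted) across subjects. A pointwise SD band across
#' subjects is returned alongside the mean.
#'
#' @param trials named list (by subject id) of lists of [waveform()]s,
#'   all on a common grid and of one quantity.
#' @param implant_sizes named numeric vector of femoral A-P implant
#'   sizes (mm) per subject id.
#' @param mean_size reference implant size (mm); defaults to the mean of
#'   `implant_sizes`.
#' @param scale_translations apply implant-size normalization; defaults
#'   to `TRUE` when the waveform units are `"mm"` (rotations and loads
#'   are not size-scaled).
#' @return list with `mean` and `sd` [waveform()]s and `n_subjects`.
#' @export
average_cohort <- function(trials, implant_sizes = NULL, mean_size = NULL,
                           scale_translations = NULL) {
  if (length(trials) == 0L) stop("empty subject group")
  if (any(vapply(trials, length, integer(1)) == 0L))
    stop("a subject has no trials")
  tmpl <- trials[[1L]][[1L]]
  grid <- do.call(wf_common_grid, unlist(trials, recursive = FALSE))
  if (is.null(scale_translations)) scale_translations <- tmpl$units == "mm"
  if (scale_translations && is.null(implant_sizes))
    stop("implant_sizes required to normalize translational quantities")
  if (is.null(mean_size) && !is.null(implant_sizes))
    mean_size <- mean(implant_sizes)
  per_subject <- vapply(names(trials) %||% seq_along(trials), function(s) {
    m <- rowMeans(vapply(trials[[s]], `[[`, numeric(length(grid)), "values"))
    if (scale_translations) {
      size <- implant_sizes[[s]]
      if (is.null(size) || is.na(size)) stop("missing implant size for ", s)
      m <- m * mean_size / size
    }
    m
  }, numeric(length(grid)))
  mu <- rowMeans(per_subject)
  sdv <- if (ncol(per_subject) > 1L) apply(per_subject, 1L, stats::sd)
         else rep(0, length(grid))
  list(mean = wf_with(tmpl, mu),
       sd = wf_with(tmpl, sdv, quantity = paste0(tmpl$quantity, "_sd")),
       n_subjects = length(trials))
}

#' Scale a load waveform to a reference body mass
#'
#' Body-weight normalization followed by rescaling to a reference
#' person: values are multiplied by `target_mass / subject_mass` (mass
#' and weight ratios are numerically identical).
#'
#' @param wf a force or moment [waveform()].
#' @param subject_mass subject body mass, kg, `> 0`.
#' @param target_mass reference body mass, kg (default 66).
#' @return the scaled [waveform()], units preserved.
#' @export
#' @examples
#' wf <- waveform(c(0, 100), c(500, 500), "tf_compression", "N")
#' scale_to_body_weight(wf, 76.3)$values   # 432.5 N
scale_to_body_weight <- function(wf, subject_mass, target_mass = 66) {
  stopifnot(is_waveform(wf))
  if (!is.finite(subject_mass) || subject_mass <= 0)
    stop("subject_mass must be > 0")
  if (!is.finite(target_mass) || target_mass <= 0)
    stop("target_mass must be > 0")
  wf_with(wf, wf$values * target_mass / subject_mass)
}

#' Concatenate stand-to-sit and sit-to-stand into one sit-stand cycle
#'
#' The stand-to-sit movement occupies 0-50% of the combined cycle and
#' sit-to-stand 50-100%. At the junction the two endpoint values are
#' averaged; the result is resampled onto a uniform grid.
#'
#' @param stand_to_sit,sit_to_stand [waveform()]s of the same quantity
#'   and units.
#' @param n_nodes nodes of the combined cycle grid (default 101).
#' @return a [waveform()] with `activity = "sit_stand"`.
#' @export
concatenate_sit_stand <- function(stand_to_sit, sit_to_stand, n_nodes = 101L) {
  stopifnot(is_waveform(stand_to_sit), is_waveform(sit_to_stand))
  if (stand_to_sit$units != sit_to_stand$units ||
      stand_to_sit$quantity != sit_to_stand$quantity)
    stop("quantity/unit mismatch between the two movement halves")
  x1 <- stand_to_sit$percent_cycle / 2
  x2 <- 50 + sit_to_stand$percent_cycle / 2
  v1 <- stand_to_sit$values
  v2 <- sit_to_stand$values
  junction <- (v1[length(v1)] + v2[1L]) / 2
  keep1 <- x1 < 50 - 1e-9
  keep2 <- x2 > 50 + 1e-9
  x <- c(x1[keep1], 50, x2[keep2])
  v <- c(v1[keep1], junction, v2[keep2])
  grid <- seq(0, 100, length.out = n_nodes)
  waveform(grid, stats::approx(x, v, xout = grid, rule = 2)$y,
           quantity = stand_to_sit$quantity, units = stand_to_sit$units,
           activity = "sit_stand")
}

#' Synchronize cycles on the most extended flexion at cycle start
#'
#' Each cycle is circularly shifted so that the minimum knee flexion
#' within the leading window (default +/- 25% around 0%) lands at 0% of
#' the cycle. Cycles are treated as periodic: the first and last grid
#' node are the same instant, so the shifted trace is re-closed.
#'
#' @param cycles list of [waveform()] sets (each a named list of
#'   waveforms sharing one grid), one per specimen/trial.
#' @param flexion list of flexion [waveform()]s paired with `cycles`.
#' @param window half-width of the leading search window, percent.
#' @return list with `cycles` (aligned sets), `shifts` (nodes shifted),
#'   and `flat` (logical: flexion trace flat, alignment skipped).
#' @export
synchronize <- function(cycles, flexion, window = 25) {
  if (length(cycles) != length(flexion))
    stop("each cycle set needs a paired flexion trace")
  shifts <- integer(length(cycles))
  flat <- logical(length(cycles))
  out <- vector("list", length(cycles))
  for (i in seq_along(cycles)) {
    fl <- flexion[[i]]
    stopifnot(is_waveform(fl))
    n <- length(fl$values)
    core <- fl$values[-n]               # node n duplicates node 1
    if (max(core) - min(core) < 1e-12) {
      flat[i] <- TRUE
      out[[i]] <- cycles[[i]]
      next
    }
    pct <- fl$percent_cycle[-n]
    in_window <- pct <= window | pct >= 100 - window
    cand <- which(in_window)
    k <- cand[which.min(core[cand])] - 1L
    shifts[i] <- k
    out[[i]] <- if (k == 0L) cycles[[i]] else lapply(cycles[[i]], function(w) {
      v <- w$values[-n]
      v <- c(v[(seq_len(n - 1L) + k - 1L) %% (n - 1L) + 1L])
      wf_with(w, c(v, v[1L]))
    })
  }
  if (any(flat))
    warning("flat flexion trace(s): no flexion minimum, cycle(s) left unshifted")
  list(cycles = out, shifts = shifts, flat = flat)
}

#' Split a waveform into activity phases
#'
#' Gait and stair descent split into stance and swing at toe-off (60% of
#' the cycle); sit-stand splits into the stand-to-sit and sit-to-stand
#' halves at 50%. The node at the boundary belongs to the earlier phase.
#'
#' @param wf a [waveform()].
#' @param activity activity name; defaults to the waveform's own label.
#' @return named list of two [waveform()] segments; names are the phase
#'   labels (`stance`/`swing` or `stand_sit`/`sit_stand`).
#' @export
split_phases <- function(wf, activity = wf$activity) {
  stopifnot(is_waveform(wf))
  if (!activity %in% c("gait", "stair_descent", "sit_stand"))
    stop("unknown activity: ", activity)
  cut <- if (activity == "sit_stand") 50 else 60
  labels <- if (activity == "sit_stand") c("stand_sit", "sit_stand")
            else c("stance", "swing")
  first <- wf$percent_cycle <= cut + 1e-9
  if (sum(first) < 2L || sum(!first) < 2L)
    stop("phase split leaves a segment with fewer than 2 nodes")
  out <- list(
    waveform(wf$percent_cycle[first], wf$values[first], wf$quantity,
             wf$units, activity),
    waveform(wf$percent_cycle[!first], wf$values[!first], wf$quantity,
             wf$units, activity))
  names(out) <- labels
  out
}

# Table-1-style control-mode/source schema per boundary-condition variant.
bc_schema <- function(variant) {
  rows <- switch(variant,
    implant_specific_displacement = list(
      c("F-E", "displacement", "Fluoro", "fluoro_fe"),
      c("Ad-Ab", "load", "Zero", ""),
      c("I-E", "displacement", "Fluoro", "fluoro_ie"),
      c("M-L", "load", "Zero", ""),
      c("A-P", "displacement", "Fluoro", "fluoro_ap"),
      c("S-I", "load", "OrthoLoad", "orthoload_si"),
      c("Quad", "load", "MoCap", "mocap_quad")),
    implant_specific_load = list(
      c("F-E", "displacement", "Fluoro", "fluoro_fe"),
      c("Ad-Ab", "load", "Zero", ""),
      c("I-E", "load", "Derived", "derived_ie"),
      c("M-L", "load", "Zero", ""),
      c("A-P", "load", "Derived", "derived_ap"),
      c("S-I", "load", "OrthoLoad", "orthoload_si"),
      c("Quad", "load", "MoCap", "mocap_quad")),
    cams = list(
      c("F-E", "displacement", "CAMS", "cams_fe"),
      c("Ad-Ab", "load", "Zero", ""),
      c("I-E", "load", "CAMS", "cams_ie"),
      c("M-L", "load", "Zero", ""),
      c("A-P", "load", "CAMS", "cams_ap"),
      c("S-I", "load", "OrthoLoad", "orthoload_si"),
      c("Quad", "load", "MoCap", "mocap_quad")),
    stop("unknown boundary-condition variant: ", variant))
  do.call(rbind, lapply(rows, function(r)
    data.frame(dof = r[1], control_mode = r[2], source = r[3], input = r[4],
               stringsAsFactors = FALSE)))
}

#' Assemble a simulator boundary-condition set
#'
#' Builds the complete seven-row profile set (six degrees of freedom
#' plus the quadriceps actuator) for one of the three variants:
#' `"implant_specific_displacement"` (F-E, I-E, A-P displacement-control
#' from fluoroscopy), `"implant_specific_load"` (I-E, A-P load-control
#' from derived actuator loads), or `"cams"` (F-E, I-E, A-P from a
#' telemetric high-conformity dataset). Medial-lateral force and
#' adduction-abduction moment rows are always load-controlled at zero
#' and inserted automatically.
#'
#' @param variant boundary-condition variant name.
#' @param inputs named list of [waveform()]s; required names depend on
#'   the variant (e.g. `fluoro_fe`, `fluoro_ie`, `fluoro_ap`,
#'   `orthoload_si`, `mocap_quad` for the displacement variant;
#'   `derived_ie`, `derived_ap` replace the fluoroscopic transverse
#'   rows for the load variant; `cams_*` for the CAMS variant).
#' @return a named list of [bc_profile()]s (by DoF) of class
#'   `"bc_profile_set"` with the variant recorded as an attribute.
#' @export
assemble_boundary_conditions <- function(variant = c("implant_specific_displacement",
                                                     "implant_specific_load",
                                                     "cams"),
                                         inputs) {
  variant <- match.arg(variant)
  schema <- bc_schema(variant)
  grid_src <- inputs[[schema$input[schema$dof == "F-E"]]]
  if (is.null(grid_src))
    stop("missing required source waveform for DoF F-E")
  profiles <- lapply(seq_len(nrow(schema)), function(i) {
    row <- schema[i, ]
    if (row$source == "Zero") {
      zero_units <- if (row$dof == "Ad-Ab") "Nmm" else "N"
      wf <- waveform(grid_src$percent_cycle,
                     rep(0, length(grid_src$percent_cycle)),
                     quantity = paste0(row$dof, "_zero"), units = zero_units,
                     activity = grid_src$activity)
    } else {
      wf <- inputs[[row$input]]
      if (is.null(wf))
        stop("missing required source waveform for DoF ", row$dof,
             " (input '", row$input, "')")
      stopifnot(is_waveform(wf))
    }
    bc_profile(row$dof, row$control_mode, row$source, wf)
  })
  names(profiles) <- schema$dof
  structure(profiles, class = c("bc_profile_set", "list"), variant = variant)
}

#' @export
print.bc_profile_set <- function(x, ...) {
  cat(sprintf("<bc_profile_set> variant: %s\n", attr(x, "variant")))
  for (p in x) print(p)
  invisible(x)
}

#' Tabulate the control-mode/source schema of a profile set
#'
#' @param set a `"bc_profile_set"`.
#' @return data frame with columns `dof`, `control_mode`, `source`.
#' @export
bc_schema_table <- function(set) {
  stopifnot(inherits(set, "bc_profile_set"))
  do.call(rbind, lapply(unname(set), function(p)
    data.frame(dof = p$dof, control_mode = p$control_mode, source = p$source,
               stringsAsFactors = FALSE)))
}
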