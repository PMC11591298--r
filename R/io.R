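#' Read and write waveforms as tidy CSV
#'
#' The package's waveform CSV dialect has columns `activity`, `subject`,
#' `quantity`, `percent_cycle`, `value`, `units`; one row per cycle node.
#'
#' @param wfs a [waveform()], or a (possibly named) list of them.
#' @param path CSV file path.
#' @param subject optional subject label column value.
#' @return `write_waveform_csv()` returns `path` invisibly;
#'   `read_waveform_csv()` returns a named list of [waveform()]s keyed
#'   by `subject.quantity` (or `quantity` when subject is empty).
#' @export
write_waveform_csv <- function(wfs, path, subject = "") {
  if (is_waveform(wfs)) wfs <- list(wfs)
  df <- do.call(rbind, lapply(wfs, function(w) {
    d <- as.data.frame(w)
    cbind(d[1L], subject = subject, d[-1L])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("activity", "quantity", "percent_cycle", "value", "units")
  if (!all(need %in% names(df)))
    stop("not a waveform CSV: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(df$subject)) df$subject <- ""
  df$subject <- as.character(df$subject)
  df$subject[is.na(df$subject)] <- ""
  key <- ifelse(df$subject == "", df$quantity,
                paste(df$subject, df$quantity, sep = "."))
  lapply(split(df, key), function(d) {
    d <- d[order(d$percent_cycle), ]
    waveform(d$percent_cycle, d$value, d$quantity[1L], d$units[1L],
             d$activity[1L])
  })
}

#' Serialize a boundary-condition set to a directory
#'
#' Writes one waveform CSV per profile plus a YAML manifest recording
#' the control-mode/source schema (`dof`, `control_mode`, `source`,
#' `file`) and the variant.
#'
#' @param set a `"bc_profile_set"`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the manifest path, invisibly.
#' @export
write_bc_set <- function(set, dir, prefix = "bc") {
  stopifnot(inherits(set, "bc_profile_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(unname(set), function(p) {
    fname <- sprintf("%s_%s.csv", prefix, gsub("[^A-Za-z]", "", p$dof))
    write_waveform_csv(p$waveform, file.path(dir, fname))
    list(dof = p$dof, control_mode = p$control_mode, source = p$source,
         file = fname)
  })
  manifest <- file.path(dir, paste0(prefix, "_manifest.yaml"))
  yaml::write_yaml(list(variant = attr(set, "variant"), profiles = entries),
                   manifest)
  invisible(manifest)
}

#' @rdname write_bc_set
#' @param manifest path to a manifest written by `write_bc_set()`.
#' @export
read_bc_set <- function(manifest) {
  m <- yaml::read_yaml(manifest)
  dir <- dirname(manifest)
  profiles <- lapply(m$profiles, function(e) {
    wf <- read_waveform_csv(file.path(dir, e$file))[[1L]]
    bc_profile(e$dof, e$control_mode, e$source, wf)
  })
  names(profiles) <- vapply(m$profiles, `[[`, character(1), "dof")
  structure(profiles, class = c("bc_profile_set", "list"),
            variant = m$variant)
}

#' Read and write calibration matrices as CSV
#'
#' Row-major CSV with a header row naming the channel order and row
#' names giving the output order.
#'
#' @param cal a [calibration_matrix()].
#' @param path CSV path.
#' @return `write_calibration_csv()` returns `path` invisibly;
#'   `read_calibration_csv()` a [calibration_matrix()].
#' @export
write_calibration_csv <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_matrix"))
  m <- cal$matrix
  dimnames(m) <- list(cal$outputs, cal$channels)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L)
  calibration_matrix(as.matrix(df))
}

#' Serialize a tuning result to a directory
#'
#' Writes the converged load-controlled profile set ([write_bc_set()]),
#' the per-iteration RMSE history CSV, and a YAML summary.
#'
#' @param result a `"tuning_result"`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_tuning_result <- function(result, dir) {
  stopifnot(inherits(result, "tuning_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bc_set(result$load_profiles, dir, prefix = "load")
  hist <- data.frame(iteration = seq_len(nrow(result$rmse_history)),
                     medial_rmse_mm = result$rmse_history[, "medial"],
                     lateral_rmse_mm = result$rmse_history[, "lateral"])
  utils::write.csv(hist, file.path(dir, "rmse_history.csv"), row.names = FALSE)
  yaml::write_yaml(list(converged = result$converged,
                        iterations = result$iterations,
                        gain_halved = result$gain_halved,
                        final_rmse_mm = as.list(result$final_rmse)),
                   file.path(dir, "tuning_summary.yaml"))
  invisible(dir)
}
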