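# Plain-text I/O: two-column CSV waveforms (time_s, value), JSON sidecars for
# ground truth and fit results, and cohort directories with a manifest.

#' Read and write waveforms as two-column CSV
#'
#' The on-disk dialect is a header line `time_s,value` followed by one row per
#' sample. On read, the sampling rate is inferred from the time column (which
#' must be uniform); alternatively a single-column file may be read with a
#' declared `fs`.
#'
#' @param w a [waveform] to write.
#' @param path file path.
#' @param label signal kind attached on read.
#' @param fs sampling rate; required when the file has a single `value`
#'   column, ignored otherwise.
#' @return `read_waveform_csv` returns a [waveform]; `write_waveform_csv`
#'   returns `path` invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(is.waveform(w))
  utils::write.csv(as.data.frame(w), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path, label = "signal", fs = NULL) {
  df <- utils::read.csv(path)
  if (ncol(df) >= 2L && "time_s" %in% names(df)) {
    tt <- df$time_s
    dts <- diff(tt)
    if (length(dts) < 1L) stop("waveform file too short", call. = FALSE)
    if (max(abs(dts - dts[1L])) > 1e-6 * dts[1L])
      stop("time column is not uniformly sampled", call. = FALSE)
    waveform(df$value, fs = 1 / dts[1L], t0 = tt[1L], label = label)
  } else {
    if (is.null(fs))
      stop("single-column file: a sampling rate 'fs' must be declared",
           call. = FALSE)
    waveform(df[[1L]], fs = fs, t0 = 0, label = label)
  }
}

#' Write / read a synthetic subject
#'
#' A subject is stored as `<stem>_P.csv` and `<stem>_U.csv` (two-column CSV)
#' plus a JSON sidecar `<stem>_truth.json` holding the [subject_truth] and
#' the generator seed.
#'
#' @param subject a `synthetic_subject`.
#' @param stem path stem (directory + basename without suffix).
#' @return `write_subject` returns `stem` invisibly; `read_subject` returns a
#'   list with `P`, `U` ([waveform]s) and `truth` ([subject_truth]).
#' @export
write_subject <- function(subject, stem) {
  stopifnot(inherits(subject, "synthetic_subject"))
  write_waveform_csv(subject$P, paste0(stem, "_P.csv"))
  write_waveform_csv(subject$U, paste0(stem, "_U.csv"))
  side <- c(unclass(subject$truth), list(seed = subject$seed))
  jsonlite::write_json(side, paste0(stem, "_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_subject
#' @export
read_subject <- function(stem) {
  truth_raw <- jsonlite::read_json(paste0(stem, "_truth.json"),
                                   simplifyVector = TRUE)
  seed <- truth_raw$seed
  truth_raw$seed <- NULL
  truth <- do.call(subject_truth, truth_raw)
  list(P = read_waveform_csv(paste0(stem, "_P.csv"), label = "pressure"),
       U = read_waveform_csv(paste0(stem, "_U.csv"), label = "velocity"),
       truth = truth, seed = seed)
}

#' Write a synthetic cohort to a directory
#'
#' One subject per `subject_<i>_{P,U}.csv` + truth sidecar, plus a
#' `manifest.json` listing the subjects and the master seed.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir` invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stems <- sprintf("subject_%03d", seq_along(cohort$subjects))
  for (i in seq_along(cohort$subjects))
    write_subject(cohort$subjects[[i]], file.path(dir, stems[i]))
  jsonlite::write_json(
    list(n = length(cohort$subjects), seed = cohort$seed, stems = stems),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Serialize a reservoir fit
#'
#' Writes the fitted parameters and diagnostics as JSON and the decomposed
#' series (`time_s`, `P`, `Pr`, `Pex`) as CSV.
#'
#' @param fit a `reservoir_fit`.
#' @param P the measured pressure [waveform] the fit was computed from.
#' @param stem path stem; writes `<stem>.json` and `<stem>_series.csv`.
#' @return `stem` invisibly.
#' @export
write_reservoir_fit <- function(fit, P, stem) {
  stopifnot(inherits(fit, "reservoir_fit"))
  pars <- list(a = fit$a, b = fit$b, Pinf = fit$Pinf, Pn_bar = fit$Pn_bar,
               Pn = fit$Pn, X2 = fit$X2, converged = fit$converged,
               dof = fit$config$dof, window = fit$config$window)
  jsonlite::write_json(pars, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  df <- data.frame(time_s = wf_time(fit$Pr), P = P$values,
                   Pr = fit$Pr$values, Pex = fit$Pex$values)
  utils::write.csv(df, paste0(stem, "_series.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(stem)
}
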