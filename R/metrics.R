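#' Fluorescence from field snapshots
#'
#' The spark read-out: for each bound-dye (Fluo-4) field snapshot, the
#' maximum over voxels of the field optionally convolved with a 3D
#' Gaussian point-spread function (default FWHM 410 x 410 x 800 nm).
#' Voxels outside the cytosol carry no dye and contribute zero; the
#' convolution is zero-padded at the cube faces.
#'
#' @param snapshots list of full-grid bound-dye vectors (or a single
#'   [init_state()] field state, whose Fluo-4 field is used).
#' @param grid the grid.
#' @param psf list `(enabled, fwhm_nm)`; disabled means the raw voxel
#'   maximum.
#' @param radius_vox optional kernel truncation radius override (voxels).
#' @return numeric vector of F samples, one per snapshot.
#' @export
fluorescence_trace <- function(snapshots, grid,
                               psf = list(enabled = TRUE,
                                          fwhm_nm = c(410, 410, 800)),
                               radius_vox = NULL) {
  if (inherits(snapshots, "field_state")) snapshots <- list(snapshots$b[[4]])
  pv <- psf_voxels(list(psf = psf), grid)
  if (!is.null(radius_vox)) pv$radius <- rep_len(as.integer(radius_vox), 3)
  vapply(snapshots, function(f) {
    stopifnot(length(f) == grid$n^3)
    if (pv$on) f <- cpp_gaussian_blur(f, grid$n, pv$sigma, pv$radius)
    max(f)
  }, numeric(1))
}

#' Spark metrics from a record
#'
#' Amplitude is the peak relative fluorescence change, time to peak (TTP)
#' the time of the first maximum, success the amplitude reaching the
#' detection threshold (inclusive), duration the termination time (1 ms
#' after the last channel closure), and `n_opened` the number of distinct
#' channels that opened at least once.
#'
#' @param record a [run_spark()] record.
#' @param threshold spark detection threshold on peak dF/F0 (default 0.3).
#' @return a `spark_metrics` list: `success`, `amplitude`, `ttp`,
#'   `duration`, `n_opened`, `capped`.
#' @export
evaluate_spark <- function(record, threshold = 0.3) {
  stopifnot(inherits(record, "spark_record"), length(record$dFF0) > 0)
  amp <- max(record$dFF0)
  ttp <- record$times[which.max(record$dFF0)]  # first maximum on ties
  structure(list(
    success = amp >= threshold,
    amplitude = amp,
    ttp = ttp,
    duration = record$termination_time,
    n_opened = sum(vapply(record$open_intervals, nrow, 1L) > 0),
    capped = isTRUE(record$capped)
  ), class = "spark_metrics")
}

#' Per-channel statistics over a batch of records
#'
#' Activation map (per-record first-opening time per channel; NA if the
#' channel never opened), mean total open time per channel across records,
#' and the histogram of distinct-opened-channel counts.
#'
#' @param records list of spark records from one configuration.
#' @return list with `activation` (records x channels matrix of first
#'   opening times), `mean_open_time` (per channel, ms),
#'   `opened_histogram` (table over the number of opened channels).
#' @export
channel_statistics <- function(records) {
  stopifnot(length(records) >= 1)
  nch <- length(records[[1]]$open_intervals)
  first_open <- t(vapply(records, function(r)
    vapply(r$open_intervals, function(iv)
      if (nrow(iv)) iv[1, 1] else NA_real_, numeric(1)), numeric(nch)))
  open_time <- t(vapply(records, function(r)
    vapply(r$open_intervals, function(iv) {
      if (!nrow(iv)) return(0)
      tc <- ifelse(is.na(iv[, 2]), r$termination_time, iv[, 2])
      sum(tc - iv[, 1])
    }, numeric(1)), numeric(nch)))
  n_opened <- vapply(records, function(r)
    sum(vapply(r$open_intervals, nrow, 1L) > 0), numeric(1))
  list(activation = first_open,
       mean_open_time = colMeans(open_time),
       opened_histogram = table(factor(n_opened, levels = 0:nch)))
}

#' Export a spark record as CSV
#'
#' Writes the fluorescence trace (`time_ms,F,dFF0`) and, alongside it, a
#' per-channel open-interval table (`ryr_id,t_open_ms,t_close_ms`; an
#' unclosed final interval has an empty close time).
#'
#' @param record a [run_spark()] record.
#' @param path output path for the trace CSV; the interval table goes to
#'   `<path base>_intervals.csv`.
#' @export
write_record_csv <- function(record, path) {
  stopifnot(inherits(record, "spark_record"))
  utils::write.csv(data.frame(time_ms = record$times, F = record$F,
                              dFF0 = record$dFF0),
                   path, row.names = FALSE)
  iv <- do.call(rbind, lapply(seq_along(record$open_intervals), function(k) {
    m <- record$open_intervals[[k]]
    if (!nrow(m)) return(NULL)
    data.frame(ryr_id = k, t_open_ms = m[, 1], t_close_ms = m[, 2])
  }))
  utils::write.csv(iv, sub("(\\.[^.]+)?$", "_intervals\\1",
                           path, perl = TRUE), row.names = FALSE)
  invisible(record)
}

#' Per-run metrics table
#'
#' @param records list of spark records.
#' @param threshold detection threshold.
#' @return data frame `run_id, seed, success, amplitude, ttp_ms,
#'   duration_ms, n_opened, capped`.
#' @export
metrics_table <- function(records, threshold = 0.3) {
  rows <- lapply(seq_along(records), function(i) {
    m <- evaluate_spark(records[[i]], threshold)
    data.frame(run_id = i, seed = records[[i]]$seed, success = m$success,
               amplitude = m$amplitude, ttp_ms = m$ttp,
               duration_ms = m$duration, n_opened = m$n_opened,
               capped = m$capped)
  })
  do.call(rbind, rows)
}
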