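# Spike-train response quantification for single-sensillum recordings.
# The response of a trial is the A-neuron spike count during the 500 ms
# stimulus window minus the count during the 500 ms pre-stimulus window;
# solvent subtraction and doubling convert counts to spikes/s.

#' Label spikes as A or B unit by amplitude
#'
#' The two neurons housed in a sensillum are separated by spike amplitude:
#' the A neuron fires large spikes, the B neuron small ones. With
#' `boundary = "auto"` the amplitudes are split by an exact 1-D two-class
#' partition (minimal within-class sum of squares over all splits of the
#' sorted amplitudes) and the boundary is the midpoint between the
#' classes. If the two classes are not separated (difference of class
#' means below twice the sum of the class standard deviations) the
#' amplitudes are treated as unimodal: a warning is raised and all
#' spikes are labeled A.
#'
#' @param trial An `ssr_trial`.
#' @param boundary Numeric amplitude cutoff (spikes strictly above are A),
#'   or `"auto"`.
#' @return The trial with `spikes$unit` filled in ("A"/"B").
#' @export
sort_units_by_amplitude <- function(trial, boundary = "auto") {
  stopifnot(inherits(trial, "ssr_trial"))
  amps <- trial$spikes$amplitude
  if (length(amps) == 0) return(trial)
  if (identical(boundary, "auto")) {
    boundary <- amplitude_boundary(amps)
    if (is.na(boundary)) {
      warning("amplitude distribution looks unimodal; labeling all spikes A")
      trial$spikes$unit <- "A"
      return(trial)
    }
  }
  trial$spikes$unit <- ifelse(amps > boundary, "A", "B")
  trial
}

# exact two-class 1-D partition; returns the midpoint boundary or NA when
# the classes are not separated
amplitude_boundary <- function(amps) {
  if (length(amps) < 2) return(NA_real_)
  x <- sort(amps)
  n <- length(x)
  css <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  ss <- vapply(seq_len(n - 1), function(k)
    css(x[1:k]) + css(x[(k + 1):n]), numeric(1))
  k <- which.min(ss)
  lo <- x[1:k]; hi <- x[(k + 1):n]
  s_of <- function(v) if (length(v) < 2) 0 else sd(v)
  # a genuinely bimodal split leaves both classes tight relative to the
  # gap; splitting a unimodal sample does not
  if (mean(hi) - mean(lo) <= 2 * (s_of(lo) + s_of(hi))) return(NA_real_)
  (max(lo) + min(hi)) / 2
}

# A-unit spike count in the half-open window [t0, t1)
a_count <- function(trial, t0, t1) {
  sp <- trial$spikes
  sum(sp$unit == "A" & sp$time >= t0 & sp$time < t1, na.rm = TRUE)
}

check_pre_window <- function(trial) {
  if (trial$onset - trial$duration < 0)
    stop(sprintf("trial %s: no %g s pre-stimulus window before onset",
                 trial$trial_id %||% trial$odor, trial$duration))
  if (any(is.na(trial$spikes$unit)))
    stop(sprintf("trial %s: unit labels missing; run sort_units_by_amplitude",
                 trial$trial_id %||% trial$odor))
  invisible(trial)
}

#' Net spike-count response of a trial
#'
#' A-neuron spikes during the stimulus window `[onset, onset + 0.5 s)`
#' minus A-neuron spikes during the equally long pre-stimulus window
#' `[onset - 0.5 s, onset)`. Windows are half-open so no spike is counted
#' twice. Negative values indicate inhibition and are retained.
#'
#' @param trial An `ssr_trial` with unit labels assigned.
#' @return Integer net spike count.
#' @export
count_response <- function(trial) {
  check_pre_window(trial)
  a_count(trial, trial$onset, trial$onset + trial$duration) -
    a_count(trial, trial$onset - trial$duration, trial$onset)
}

#' Solvent-subtracted response in spikes/s
#'
#' The mean solvent (blank) net count of the same fly is subtracted from
#' the odor net count and the difference is doubled, converting the 500 ms
#' count difference to spikes/s.
#'
#' @param odor_response Net spike count of the odor trial.
#' @param fly_solvent_responses Net spike counts of the fly's solvent
#'   trials (at least one).
#' @return Response in spikes/s (an even integer when counts are integer).
#' @export
solvent_subtracted_response <- function(odor_response,
                                        fly_solvent_responses) {
  if (length(fly_solvent_responses) < 1)
    stop("at least one solvent trial is required per fly")
  2 * (odor_response - mean(fly_solvent_responses))
}

#' Spontaneous activity of a trial in spikes/s
#'
#' Twice the A-neuron spike count in the 500 ms before stimulus onset.
#'
#' @param trial An `ssr_trial` with unit labels.
#' @return Spontaneous rate in spikes/s.
#' @export
spontaneous_activity <- function(trial) {
  check_pre_window(trial)
  2 * a_count(trial, trial$onset - trial$duration, trial$onset)
}

#' Per-trial solvent-subtracted responses of a session
#'
#' Convenience wrapper running unit sorting, net counts, per-fly solvent
#' means and doubling over all trials of a session.
#'
#' @param session An `ssr_session`.
#' @param units `"auto"` resorts spikes by amplitude; `"truth"` uses the
#'   generator's latent labels (synthetic sessions only).
#' @return Data frame with one row per non-solvent trial: `unit`
#'   (receptor), `fly`, `odor`, `dilution`, `net_count`, `response_hz`,
#'   `spontaneous_hz`, `truth_rate`.
#' @export
session_responses <- function(session, units = c("truth", "auto")) {
  units <- match.arg(units)
  trials <- session$trials
  if (units == "auto")
    trials <- lapply(trials, function(tr) {
      tr$spikes$unit <- NA_character_
      suppressWarnings(sort_units_by_amplitude(tr, "auto"))
    })
  counts <- vapply(trials, count_response, numeric(1))
  fly <- vapply(trials, `[[`, character(1), "fly")
  solvent <- vapply(trials, `[[`, logical(1), "solvent")
  solv_mean <- tapply(counts[solvent], fly[solvent], mean)
  if (!all(unique(fly) %in% names(solv_mean)))
    stop("every fly needs at least one solvent trial")
  keep <- !solvent
  data.frame(
    unit = vapply(trials[keep], `[[`, character(1), "sensillum"),
    fly = fly[keep],
    odor = vapply(trials[keep], `[[`, character(1), "odor"),
    dilution = vapply(trials[keep], `[[`, numeric(1), "dilution"),
    net_count = counts[keep],
    response_hz = 2 * (counts[keep] - solv_mean[fly[keep]]),
    spontaneous_hz = vapply(trials[keep], spontaneous_activity, numeric(1)),
    truth_rate = vapply(trials[keep], `[[`, numeric(1), "truth_rate"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Median response matrix across trials
#'
#' Aggregates per-trial solvent-subtracted responses into a units x odors
#' matrix of medians (the tuning summary used for classification and
#' sparseness). Cells without any trial are `NA` (missing, not zero);
#' per-cell sample sizes are retained in the `n` attribute.
#'
#' @param responses Data frame as from [session_responses()] (or any with
#'   the three named columns).
#' @param unit_col,odor_col,value_col Column names.
#' @param odors Optional odor ordering for the columns.
#' @return A numeric matrix of class `response_matrix` with attribute `n`.
#' @export
aggregate_median_responses <- function(responses, unit_col = "unit",
                                       odor_col = "odor",
                                       value_col = "response_hz",
                                       odors = NULL) {
  u <- unique(responses[[unit_col]])
  o <- odors %||% unique(responses[[odor_col]])
  m <- matrix(NA_real_, length(u), length(o), dimnames = list(u, o))
  n <- matrix(0L, length(u), length(o), dimnames = list(u, o))
  med <- tapply(responses[[value_col]],
                list(factor(responses[[unit_col]], u),
                     factor(responses[[odor_col]], o)),
                median)
  cnt <- tapply(responses[[value_col]],
                list(factor(responses[[unit_col]], u),
                     factor(responses[[odor_col]], o)),
                length)
  m[] <- med
  n[!is.na(cnt)] <- cnt[!is.na(cnt)]
  attr(m, "n") <- n
  class(m) <- c("response_matrix", class(m))
  m
}

#' EAG peak response
#'
#' Maximum decrease in antennal voltage after stimulus onset, relative to
#' a baseline. By default the baseline is the trace value at onset; the
#' mean over a pre-onset window of the same length as the search window is
#' available as an alternative.
#'
#' @param voltage Voltage trace (mV). @param time Sample times (s).
#' @param onset Stimulus onset (s); must lie inside the trace.
#' @param window Post-onset search window length (s); default to trace end.
#' @param baseline `"onset"` or `"pre_mean"`.
#' @return Peak voltage decrease in mV (>= 0).
#' @export
eag_peak <- function(voltage, time, onset, window = NULL,
                     baseline = c("onset", "pre_mean")) {
  baseline <- match.arg(baseline)
  stopifnot(length(voltage) == length(time))
  if (onset < min(time) || onset > max(time))
    stop("stimulus onset lies outside the trace")
  t_end <- if (is.null(window)) max(time) else onset + window
  post <- voltage[time >= onset & time <= t_end]
  if (length(post) == 0) stop("no samples after stimulus onset")
  b <- if (baseline == "onset")
    voltage[which.min(abs(time - onset))]
  else
    mean(voltage[time < onset & time >= onset - (t_end - onset)])
  max(0, max(b - post))
}
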