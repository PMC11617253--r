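# Tuning-breadth statistics on median response matrices: response
# classification, lifetime sparseness, responsive fraction, best-ligand
# selection and dose-response summaries.

#' Classify median responses per receptor
#'
#' Each cell of a median response matrix is assigned one of three
#' categories relative to its receptor's maximum median response:
#' `"none"` below the response threshold (default 10 spikes/s, which also
#' covers inhibitory negative medians), `"ge_halfmax"` at or above half
#' the receptor's maximum (and at or above the threshold), `"sub_halfmax"`
#' in between. Boundaries are inclusive for `>=` comparisons, so a lone
#' response of exactly 10 spikes/s is its receptor's best ligand.
#'
#' @param mat `response_matrix` (units x odors medians); `NA` = missing.
#' @param threshold Response threshold in spikes/s.
#' @return Character matrix of the same shape (`NA` kept for missing).
#' @export
classify_responses <- function(mat, threshold = 10) {
  out <- matrix(NA_character_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (i in seq_len(nrow(mat))) {
    r <- mat[i, ]
    if (all(is.na(r)))
      stop(sprintf("unit %s has no non-missing responses",
                   rownames(mat)[i] %||% i))
    mx <- max(r, na.rm = TRUE)
    cls <- ifelse(r < threshold, "none",
                  ifelse(r >= mx / 2, "ge_halfmax", "sub_halfmax"))
    out[i, ] <- cls
  }
  out
}

#' Lifetime sparseness of a tuning profile
#'
#' Tuning-breadth statistic on the non-negative median responses
#' \eqn{r_i} of one receptor to a panel of \eqn{N} odors:
#' \deqn{S = \frac{1 - (\sum r_i / N)^2 / (\sum r_i^2 / N)}{1 - 1/N}}
#' S ranges from 0 (identical response to every odor) to 1 (response to a
#' single odor). Negative (inhibitory) medians are clipped to 0 before
#' the computation, since the statistic is defined for non-negative
#' rates. `N` defaults to the profile length and should be the full panel
#' size, counting non-responsive odors.
#'
#' @param responses Numeric vector of median responses (spikes/s).
#' @param n Panel size `N` (default `length(responses)`); must be >= 2.
#' @return S in `[0, 1]`, or `NA` with a warning when all clipped
#'   responses are zero (undefined).
#' @export
lifetime_sparseness <- function(responses, n = length(responses)) {
  stopifnot(n >= 2)
  r <- pmax(responses[!is.na(responses)], 0)
  if (sum(r) == 0) {
    warning("all responses are zero after clipping; sparseness undefined")
    return(NA_real_)
  }
  (1 - (sum(r) / n)^2 / (sum(r^2) / n)) / (1 - 1 / n)
}

#' Fraction of the panel a receptor responds to
#'
#' Percentage of panel odors whose median response reaches the response
#' threshold, rounded half-up to an integer percent.
#'
#' @param responses Median responses of one receptor (spikes/s); `NA`s
#'   count as non-responsive unless dropped upstream.
#' @param threshold Response threshold (spikes/s).
#' @param n Panel size (default `length(responses)`).
#' @return Integer percent.
#' @export
responsive_fraction <- function(responses, threshold = 10,
                                n = length(responses)) {
  k <- sum(responses >= threshold, na.rm = TRUE)
  as.integer(round_half_up(100 * k / n))
}

#' Best ligands of a receptor
#'
#' Odors whose median response is at least half the receptor's maximum
#' median response (and at least the response threshold), ranked by
#' decreasing response. Ties at the half-maximum boundary are included.
#'
#' @param responses Named vector of median responses (spikes/s).
#' @param threshold Response threshold (spikes/s).
#' @return Data frame `odor`, `response`, ordered by decreasing response.
#' @export
best_ligands <- function(responses, threshold = 10) {
  cls <- classify_responses(matrix(responses, 1,
                                   dimnames = list("u", names(responses))),
                            threshold)[1, ]
  keep <- which(cls == "ge_halfmax")
  keep <- keep[order(-responses[keep])]
  data.frame(odor = names(responses)[keep] %||% as.character(keep),
             response = unname(responses[keep]),
             stringsAsFactors = FALSE)
}

#' Dose-response summary table
#'
#' Summarizes per-trial responses by odor and dilution: median,
#' interquartile range, range, outliers by the 1.5 x IQR rule, and an
#' `active` flag for medians at or above the response threshold.
#'
#' @param responses Data frame with columns `odor`, `dilution` (log10)
#'   and `response_hz` (per-trial spikes/s).
#' @param threshold Activity threshold on the median (spikes/s).
#' @return Data frame: odor, dilution, n, median, q1, q3, min, max,
#'   n_outliers, active; ordered by odor then decreasing dilution.
#' @export
dose_response_summary <- function(responses, threshold = 10) {
  stopifnot(all(c("odor", "dilution", "response_hz") %in% names(responses)))
  groups <- split(responses,
                  list(responses$odor, responses$dilution), drop = TRUE)
  rows <- lapply(groups, function(g) {
    x <- g$response_hz
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
    fence <- c(q[1] - 1.5 * (q[3] - q[1]), q[3] + 1.5 * (q[3] - q[1]))
    data.frame(odor = g$odor[1], dilution = g$dilution[1],
               n = length(x), median = q[2], q1 = q[1], q3 = q[3],
               min = min(x), max = max(x),
               n_outliers = sum(x < fence[1] | x > fence[2]),
               active = q[2] >= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$odor, -out$dilution), ]
  rownames(out) <- NULL
  out
}
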