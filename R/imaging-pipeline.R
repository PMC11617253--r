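# Calcium-imaging processing chain for antennal-lobe movies. The stage
# order is fixed: delta F/F -> bleaching correction -> spatial median
# filter -> movement correction -> glomerular response extraction. Every
# stage returns a new stack and leaves its input unmodified. Frame
# numbers are 1-based throughout (frames 1-40 of a 10 s trial at 4 Hz).

#' Movie stack container
#'
#' One imaging trial: a T x H x W fluorescence array plus acquisition
#' metadata. Frames are indexed 1-based; the stimulus window defaults to
#' frames 9-16 (2 s odor in a 10 s trial at 4 Hz).
#'
#' @param data Numeric array `c(frames, height, width)`.
#' @param rate Sampling rate in Hz. @param stim_frames First and last
#'   stimulus frame (1-based). @param px_size Pixel size in um.
#' @param meta List of trial metadata (`animal`, `odor`, `solvent`, ...).
#' @param truth Optional generator ground truth.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(data, rate = 4, stim_frames = c(9, 16),
                        px_size = 4, meta = list(), truth = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (stim_frames[1] < 1 || stim_frames[2] > dim(data)[1])
    stop("stimulus window outside the recorded frames")
  structure(list(data = data, rate = rate, stim_frames = stim_frames,
                 px_size = px_size, meta = meta, truth = truth),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("movie_stack: %d frames, %d x %d px (%g um/px, %g Hz), odor %s\n",
              d[1], d[2], d[3], x$px_size, x$rate,
              x$meta$odor %||% "?"))
  invisible(x)
}

#' Glomerulus map
#'
#' Named square regions of interest on the antennal-lobe image plane.
#' The default side of 15 px corresponds to 60 um x 60 um at 4 um/px,
#' the footprint of a small to medium-sized glomerulus.
#'
#' @param roi ROI names. @param cy,cx Center coordinates in px (row,
#'   column). @param side Square side in px (odd recommended; recycled).
#' @param height,width Image bounds used for validation (optional).
#' @return Data frame of class `glomerulus_map`.
#' @export
glomerulus_map <- function(roi, cy, cx, side = 15, height = NULL,
                           width = NULL) {
  stopifnot(length(roi) == length(cy), length(cy) == length(cx),
            !anyDuplicated(roi))
  m <- data.frame(roi = as.character(roi), cy = cy, cx = cx,
                  side = rep_len(side, length(roi)),
                  stringsAsFactors = FALSE)
  if (!is.null(height) && !is.null(width)) {
    half <- (m$side - 1) / 2
    bad <- m$cy - half < 1 | m$cy + half > height |
      m$cx - half < 1 | m$cx + half > width
    if (any(bad))
      stop("ROI outside image bounds: ", paste(m$roi[bad], collapse = ", "))
  }
  class(m) <- c("glomerulus_map", class(m))
  m
}

roi_indices <- function(map, i, dims) {
  half <- (map$side[i] - 1) / 2
  rows <- max(1, round(map$cy[i] - half)):min(dims[1], round(map$cy[i] + half))
  cols <- max(1, round(map$cx[i] - half)):min(dims[2], round(map$cx[i] + half))
  list(rows = rows, cols = cols)
}

#' Relative fluorescence change (delta F/F)
#'
#' Step 1 of the processing chain. The background fluorescence F is the
#' per-pixel mean of the pre-stimulus frames (default frames 3-7,
#' 1-based); it is subtracted from every frame and the difference is
#' divided by F.
#'
#' @param stack A `movie_stack` of raw fluorescence.
#' @param background_frames 1-based frames averaged into F.
#' @return A new `movie_stack` in dF/F units.
#' @export
deltaF_over_F <- function(stack, background_frames = 3:7) {
  stopifnot(inherits(stack, "movie_stack"))
  d <- stack$data
  if (max(background_frames) > dim(d)[1])
    stop("background frames exceed the recording")
  f0 <- apply(d[background_frames, , , drop = FALSE], c(2, 3), mean)
  if (any(f0 <= 0)) {
    bad <- which(f0 <= 0, arr.ind = TRUE)
    stop(sprintf(
      "non-positive background fluorescence at %d pixel(s), first at (row %d, col %d)",
      nrow(bad), bad[1, 1], bad[1, 2]))
  }
  out <- stack
  for (t in seq_len(dim(d)[1])) out$data[t, , ] <- (d[t, , ] - f0) / f0
  out
}

#' Photobleaching correction
#'
#' Step 2. An exponential decay `b(t) = a * exp(-t / tau) + c` is fitted
#' by least squares to the spatial-mean dF/F trace over the frames before
#' and after stimulus and response (default frames 3-7 and 26-40) and
#' subtracted from every frame, leaving the fit-frame residual mean at
#' approximately zero. If the nonlinear fit fails or yields a
#' non-positive time constant, a linear fit is used instead with a
#' warning. Set `per_pixel = TRUE` to fit and subtract each pixel's own
#' trace (slow; useful when bleaching is spatially inhomogeneous).
#'
#' @param stack dF/F `movie_stack`.
#' @param fit_frames 1-based frames used for the fit.
#' @param per_pixel Fit per pixel instead of the spatial mean.
#' @return Corrected `movie_stack`.
#' @export
bleach_correct <- function(stack, fit_frames = c(3:7, 26:40),
                           per_pixel = FALSE) {
  stopifnot(inherits(stack, "movie_stack"))
  d <- stack$data
  nt <- dim(d)[1]
  if (max(fit_frames) > nt) stop("fit frames exceed the recording")
  out <- stack
  if (per_pixel) {
    for (i in seq_len(dim(d)[2])) for (j in seq_len(dim(d)[3])) {
      b <- fit_bleach_curve(d[, i, j], fit_frames, nt)
      out$data[, i, j] <- d[, i, j] - b
    }
  } else {
    y <- apply(d, 1, mean)
    b <- fit_bleach_curve(y, fit_frames, nt)
    for (t in seq_len(nt)) out$data[t, , ] <- d[t, , ] - b[t]
  }
  out
}

# fit a*exp(-t/tau)+c on the fit frames of a trace, return b(t) for all t
fit_bleach_curve <- function(y, fit_frames, nt) {
  t_fit <- fit_frames
  yf <- y[fit_frames]
  t_all <- seq_len(nt)
  if (sd(yf) == 0) return(rep(mean(yf), nt))
  fit <- tryCatch({
    span <- max(abs(yf[1] - yf[length(yf)]), 1e-12)
    m <- minpack.lm::nlsLM(
      yf ~ a * exp(-t_fit / tau) + c0,
      start = list(a = yf[1] - yf[length(yf)], tau = nt / 2,
                   c0 = yf[length(yf)]),
      lower = c(a = -Inf, tau = 1e-6, c0 = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- coef(m)
    if (p[["tau"]] <= 0) stop("non-positive time constant")
    p[["a"]] * exp(-t_all / p[["tau"]]) + p[["c0"]]
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("exponential bleaching fit failed; falling back to a linear fit")
    lf <- lm(yf ~ t_fit)
    fit <- coef(lf)[1] + coef(lf)[2] * t_all
  }
  unname(fit)
}

#' Spatial median filter
#'
#' Step 3. A per-frame 2-D median filter with an odd window width
#' (default 7 px) removes single-pixel outliers. Edges are handled by
#' symmetric reflection (edge row/column duplicated).
#'
#' @param stack A `movie_stack`. @param width Odd window width in px.
#' @return Filtered `movie_stack`.
#' @export
spatial_median_filter <- function(stack, width = 7) {
  stopifnot(inherits(stack, "movie_stack"))
  if (width %% 2 != 1) stop("filter width must be odd")
  out <- stack
  for (t in seq_len(dim(stack$data)[1]))
    out$data[t, , ] <- medfilt2(stack$data[t, , ], width)
  out
}

# vectorized 2-D median filter with symmetric reflection padding
medfilt2 <- function(img, width) {
  if (width == 1) return(img)
  p <- (width - 1) / 2
  h <- nrow(img); w <- ncol(img)
  ridx <- c(rev(seq_len(min(p, h))), seq_len(h),
            rev(seq_len(h))[seq_len(min(p, h))])
  cidx <- c(rev(seq_len(min(p, w))), seq_len(w),
            rev(seq_len(w))[seq_len(min(p, w))])
  pad <- img[ridx, cidx, drop = FALSE]
  k <- width * width
  neigh <- matrix(0, h * w, k)
  col <- 1L
  for (dy in 0:(width - 1)) for (dx in 0:(width - 1)) {
    neigh[, col] <- as.vector(pad[dy + seq_len(h), dx + seq_len(w)])
    col <- col + 1L
  }
  # vectorized row medians: sort within rows, take the middle order stat
  sorted <- matrix(neigh[order(row(neigh), neigh)], ncol = k, byrow = TRUE)
  matrix(sorted[, (k + 1) / 2], h, w)
}

#' Rigid movement correction across trials
#'
#' Step 4. Builds the median trial (per-pixel median across trials) at
#' the reference frame (default frame 20) and translates every trial by
#' the integer shift that maximizes the normalized cross-correlation of
#' its reference frame with the median reference frame, searching
#' `[-max_shift, max_shift]^2`. Ties prefer the smaller shift; flat
#' (zero-variance) frames get zero shift with a warning.
#'
#' @param trials List of `movie_stack`s with identical geometry.
#' @param reference_frame 1-based frame used for alignment.
#' @param max_shift Search radius in px.
#' @return List with `trials` (aligned stacks) and `shifts` (data frame
#'   `trial`, `dy`, `dx` of the applied corrections).
#' @export
movement_correct <- function(trials, reference_frame = 20, max_shift = 10) {
  stopifnot(length(trials) >= 2)
  dims <- lapply(trials, function(s) dim(s$data))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("all trials must share the same geometry")
  refs <- vapply(trials, function(s) s$data[reference_frame, , ],
                 matrix(0, dims[[1]][2], dims[[1]][3]))
  med_ref <- apply(refs, c(1, 2), median)
  shifts <- data.frame(trial = seq_along(trials), dy = 0L, dx = 0L)
  aligned <- trials
  for (i in seq_along(trials)) {
    s <- best_shift(trials[[i]]$data[reference_frame, , ], med_ref, max_shift)
    shifts$dy[i] <- s[1]; shifts$dx[i] <- s[2]
    if (any(s != 0L)) {
      for (t in seq_len(dims[[i]][1]))
        aligned[[i]]$data[t, , ] <-
          shift_image(trials[[i]]$data[t, , ], s[1], s[2])
    }
    aligned[[i]]$meta$applied_shift <- s
  }
  list(trials = aligned, shifts = shifts)
}

# integer shift of `img` maximizing correlation with `ref` over the
# interior region; candidates ordered by radius so ties pick small shifts
best_shift <- function(img, ref, max_shift) {
  h <- nrow(img); w <- ncol(img)
  m <- min(max_shift, (h - 1) %/% 2, (w - 1) %/% 2)
  rows <- (m + 1):(h - m); cols <- (m + 1):(w - m)
  refv <- as.vector(ref[rows, cols])
  if (sd(as.vector(img)) == 0 || sd(refv) == 0) {
    warning("flat reference frame; using zero shift")
    return(c(0L, 0L))
  }
  grid <- expand.grid(dy = -m:m, dx = -m:m)
  grid <- grid[order(grid$dy^2 + grid$dx^2, abs(grid$dy), abs(grid$dx)), ]
  best <- c(0L, 0L); best_r <- -Inf
  for (g in seq_len(nrow(grid))) {
    dy <- grid$dy[g]; dx <- grid$dx[g]
    v <- as.vector(img[rows - dy, cols - dx])
    if (sd(v) == 0) next
    r <- cor(v, refv)
    if (r > best_r + 1e-12) {
      best_r <- r; best <- c(dy, dx)
    }
  }
  as.integer(best)
}

#' Extract glomerular responses from a processed stack
#'
#' For each ROI the spatial-mean dF/F trace is smoothed with a centered
#' 3-frame moving average (window shrinking at the trace edges). The
#' maximum of the smoothed trace at or after stimulus onset is located,
#' and the response is the mean of that maximum and its two neighbors
#' (available neighbors only at trace boundaries, flagged in the output).
#'
#' @param stack Processed dF/F `movie_stack`.
#' @param map [glomerulus_map()].
#' @param onset_frame First frame of the search window (default first
#'   stimulus frame of the stack).
#' @return List with `responses` (data frame `roi`, `response`,
#'   `peak_frame`, `edge`) and `traces` (frames x ROI matrix of smoothed
#'   traces).
#' @export
extract_response <- function(stack, map,
                             onset_frame = stack$stim_frames[1]) {
  stopifnot(inherits(stack, "movie_stack"), inherits(map, "glomerulus_map"))
  d <- stack$data
  nt <- dim(d)[1]
  traces <- matrix(0, nt, nrow(map), dimnames = list(NULL, map$roi))
  res <- data.frame(roi = map$roi, response = NA_real_,
                    peak_frame = NA_integer_, edge = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(map))) {
    idx <- roi_indices(map, i, dim(d)[2:3])
    raw <- vapply(seq_len(nt),
                  function(t) mean(d[t, idx$rows, idx$cols]), numeric(1))
    sm <- smooth3(raw)
    traces[, i] <- sm
    m <- which.max(sm[onset_frame:nt]) + onset_frame - 1L
    lo <- max(1L, m - 1L); hi <- min(nt, m + 1L)
    res$response[i] <- mean(sm[lo:hi])
    res$peak_frame[i] <- m
    res$edge[i] <- m == 1L || m == nt
  }
  list(responses = res, traces = traces)
}

# centered 3-frame moving average, window shrinking at the edges
smooth3 <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - 1):min(n, i + 1)]), numeric(1))
}

#' Subtract solvent responses from glomerular responses
#'
#' Per animal and ROI, the mean response over the animal's solvent
#' (mineral-oil) trials is subtracted from every odor response.
#'
#' @param responses Data frame with columns `animal`, `roi`, `odor`,
#'   `solvent` (logical) and `response`.
#' @return The non-solvent rows with an added `net_response` column.
#' @export
solvent_subtract_imaging <- function(responses) {
  need <- c("animal", "roi", "odor", "solvent", "response")
  stopifnot(all(need %in% names(responses)))
  key <- interaction(responses$animal, responses$roi, drop = TRUE)
  out <- responses[!responses$solvent, , drop = FALSE]
  for (k in levels(key)) {
    sel <- key == k & responses$solvent
    if (!any(sel)) {
      an <- unique(responses$animal[key == k])
      stop(sprintf("animal %s has no solvent trial", an))
    }
  }
  solv <- tapply(responses$response[responses$solvent],
                 droplevels(key[responses$solvent]), mean)
  out$net_response <- out$response -
    as.numeric(solv[as.character(key[!responses$solvent])])
  rownames(out) <- NULL
  out
}

#' Build a glomerulus map from diagnostic-odor responses
#'
#' Projects the maximum dF/F over the stimulus window and across the
#' diagnostic trials, then greedily selects local maxima in decreasing
#' order of intensity, suppressing candidates closer than one ROI side to
#' an already selected center, until `n_rois` ROIs are found (23 dorsal
#' glomeruli in the intended use). Returns fewer ROIs with a warning if
#' the projection does not support the requested count.
#'
#' @param stacks List of processed dF/F `movie_stack`s (diagnostic
#'   odors), or H x W response matrices.
#' @param n_rois Number of ROIs to select.
#' @param side ROI side in px.
#' @param min_value Minimal projection value for a candidate center;
#'   default one tenth of the projection maximum.
#' @return A [glomerulus_map()] (possibly empty, with a warning).
#' @export
build_glomerulus_map <- function(stacks, n_rois = 23, side = 15,
                                 min_value = NULL) {
  imgs <- lapply(stacks, function(s) {
    if (inherits(s, "movie_stack"))
      apply(s$data[s$stim_frames[1]:s$stim_frames[2], , , drop = FALSE],
            c(2, 3), max)
    else s
  })
  proj <- Reduce(pmax, imgs)
  h <- nrow(proj); w <- ncol(proj)
  half <- (side - 1) / 2
  if (is.null(min_value)) min_value <- max(0, 0.1 * max(proj))
  cand <- which(proj > min_value, arr.ind = TRUE)
  # keep ROI fully inside the image
  cand <- cand[cand[, 1] > half & cand[, 1] <= h - half &
                 cand[, 2] > half & cand[, 2] <= w - half, , drop = FALSE]
  ord <- order(proj[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  centers <- matrix(numeric(0), 0, 2)
  for (k in seq_len(nrow(cand))) {
    if (nrow(centers) >= n_rois) break
    p <- cand[k, ]
    # cheap pre-screen: a candidate within one ROI side of an accepted
    # center belongs to an already selected spot
    if (nrow(centers) > 0 &&
        any(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2) < side))
      next
    # activity spots can be plateaus wider than one pixel: re-center the
    # candidate on the intensity centroid of its suprathreshold
    # surroundings before the distance test, so one spot yields one ROI
    p <- spot_centroid(proj, p, side, half)
    if (nrow(centers) == 0 ||
        all(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2) >= side))
      centers <- rbind(centers, p)
  }
  if (nrow(centers) == 0) {
    warning("no activity spots found; returning an empty map")
    m <- glomerulus_map(character(0), numeric(0), numeric(0), side)
    return(m)
  }
  if (nrow(centers) < n_rois)
    warning(sprintf("found only %d of %d requested activity spots",
                    nrow(centers), n_rois))
  glomerulus_map(sprintf("glom%02d", seq_len(nrow(centers))),
                 cy = centers[, 1], cx = centers[, 2], side = side,
                 height = h, width = w)
}

# intensity centroid of the pixels within one ROI side of `p` whose
# projection exceeds 60% of the candidate value, clamped so the ROI stays
# inside the image
spot_centroid <- function(proj, p, side, half) {
  h <- nrow(proj); w <- ncol(proj)
  peak <- proj[p[1], p[2]]
  rows <- max(1, p[1] - 2 * side):min(h, p[1] + 2 * side)
  cols <- max(1, p[2] - 2 * side):min(w, p[2] + 2 * side)
  sub <- proj[rows, cols, drop = FALSE]
  mask <- sub >= 0.6 * peak
  # keep only the connected suprathreshold component containing the
  # candidate, so a brighter neighboring spot cannot drag the centroid
  comp <- flood_fill(mask, c(p[1] - rows[1] + 1L, p[2] - cols[1] + 1L))
  wts <- sub * comp
  if (sum(wts) > 0)
    p <- round(c(sum(rows * rowSums(wts)) / sum(wts),
                 sum(cols * colSums(wts)) / sum(wts)))
  c(min(max(p[1], half + 1), h - half), min(max(p[2], half + 1), w - half))
}

# 8-connected component of TRUE cells containing `start`, grown by
# repeated binary dilation restricted to the mask
flood_fill <- function(mask, start) {
  h <- nrow(mask); w <- ncol(mask)
  comp <- matrix(FALSE, h, w)
  if (!mask[start[1], start[2]]) return(comp)
  comp[start[1], start[2]] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-h, ]
    grown[-h, ] <- grown[-h, ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | grown[, -w]
    grown[, -w] <- grown[, -w] | grown[, -1]
    grown <- grown & mask
    if (identical(grown, comp)) return(comp)
    comp <- grown
  }
}

#' Run the full imaging chain on a set of trials
#'
#' Applies delta F/F, bleaching correction, spatial median filtering and
#' movement correction to all trials of one animal, then extracts per-ROI
#' responses.
#'
#' @param trials List of raw `movie_stack`s (one animal).
#' @param map [glomerulus_map()].
#' @param filter_width Median filter width (px).
#' @param max_shift Movement-correction search radius (px).
#' @param align Skip movement correction with `align = FALSE` (e.g.,
#'   single-trial use).
#' @return Data frame: `animal`, `trial`, `odor`, `solvent`, `roi`,
#'   `response`, `shift_y`, `shift_x`.
#' @export
process_imaging_trials <- function(trials, map, filter_width = 7,
                                   max_shift = 10, align = TRUE) {
  proc <- lapply(trials, function(s)
    spatial_median_filter(bleach_correct(deltaF_over_F(s)), filter_width))
  if (align && length(proc) >= 2) {
    mc <- movement_correct(proc, max_shift = max_shift)
    proc <- mc$trials
    shifts <- mc$shifts
  } else {
    shifts <- data.frame(trial = seq_along(proc), dy = 0L, dx = 0L)
  }
  rows <- lapply(seq_along(proc), function(i) {
    er <- extract_response(proc[[i]], map)
    data.frame(animal = proc[[i]]$meta$animal %||% "animal1",
               trial = i,
               odor = proc[[i]]$meta$odor %||% sprintf("trial%d", i),
               solvent = isTRUE(proc[[i]]$meta$solvent),
               roi = er$responses$roi,
               response = er$responses$response,
               shift_y = shifts$dy[i], shift_x = shifts$dx[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
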