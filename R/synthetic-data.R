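# Synthetic-data generators. Every downstream stage of the pipeline can be
# exercised on data produced here, with the latent parameters (true driven
# rates, response amplitudes, applied shifts, unit labels) carried along as
# ground truth.

#' Build an odor panel
#'
#' An odor panel names the odorants tested against each receptor, their
#' chemical class, and the dilution used. The default panel has 80 odors
#' spread over common chemical classes of plant volatiles, mirroring a
#' broad ecological screening panel.
#'
#' @param n Panel size (default 80).
#' @param classes Chemical classes to cycle odors through.
#' @param dilution log10 v/v dilution applied to every odor (default -2).
#' @return A data frame with columns `odor`, `class`, `dilution`.
#' @export
odor_panel <- function(n = 80,
                       classes = c("ester", "aldehyde", "alcohol", "aromatic",
                                   "terpene", "ketone", "acid", "amine"),
                       dilution = -2) {
  stopifnot(n >= 1)
  cls <- rep_len(classes, n)
  # order odors by class so panels look like the screening convention
  cls <- sort(cls)
  data.frame(
    odor = sprintf("odor%02d_%s", seq_len(n), cls),
    class = cls,
    dilution = dilution,
    stringsAsFactors = FALSE
  )
}

#' Ground-truth receptor tuning over an odor panel
#'
#' Draws, per receptor, the true mean stimulus-driven firing rate for each
#' odor of the panel and a spontaneous rate. `breadth` controls the
#' fraction of odors with a nonzero driven rate and maps monotonically to
#' tuning breadth: `breadth = 1/n` gives a specialist, `breadth = 1` a
#' fully broad receptor.
#'
#' @param panel Odor panel from [odor_panel()].
#' @param receptors Character vector of receptor names.
#' @param breadth Fraction (scalar or per receptor) of odors with a
#'   nonzero driven rate; must be in (0, 1].
#' @param max_rate Maximal driven rate in spikes/s for the best ligand.
#' @param spontaneous Spontaneous rate(s) in spikes/s (recycled).
#' @param seed Integer seed; identical seed and arguments give identical
#'   ground truth.
#' @return An object of class `tuning_truth`: list with `receptors`,
#'   `driven` (receptor x odor matrix, spikes/s) and `spontaneous`.
#' @export
tuning_ground_truth <- function(panel, receptors = paste0("OR", 1:5),
                                breadth = 0.35, max_rate = 150,
                                spontaneous = 10, seed = 1) {
  stopifnot(all(breadth > 0), all(breadth <= 1), max_rate >= 0,
            all(spontaneous >= 0))
  n <- nrow(panel)
  breadth <- rep_len(breadth, length(receptors))
  spontaneous <- rep_len(spontaneous, length(receptors))
  set.seed(seed)
  driven <- matrix(0, length(receptors), n,
                   dimnames = list(receptors, panel$odor))
  for (i in seq_along(receptors)) {
    k <- max(1L, round(breadth[i] * n))
    lig <- sample.int(n, k)
    # geometric fall-off from the best ligand keeps tuning curves peaked
    rates <- max_rate * exp(-seq(0, 3, length.out = k)) * runif(k, 0.7, 1)
    driven[i, lig] <- rates
  }
  structure(list(receptors = receptors, driven = driven,
                 spontaneous = setNames(spontaneous, receptors)),
            class = "tuning_truth")
}

#' Simulation configuration
#'
#' Collects the acquisition parameters shared by the generators. The
#' defaults mirror the study conditions of the recordings the pipeline is
#' designed for: 500 ms odor stimulus in SSR with at least 500 ms
#' pre-stimulus window; calcium movies of 40 frames at 4 Hz (10 s trials:
#' clean air frames 1-8, odor frames 9-16, clean air frames 17-40),
#' 344 x 260 px at 4 um/px.
#'
#' @param seed Master seed; identical seed + config give bit-identical
#'   generator output.
#' @param stim_duration,pre_window SSR stimulus length and pre-stimulus
#'   recording available before onset, in seconds.
#' @param a_amp,b_amp,amp_sd Mean spike amplitudes of the A (large) and B
#'   (small) unit and their common s.d. (arbitrary units).
#' @param b_spontaneous Spontaneous rate of the B unit in spikes/s.
#' @param frames,height,width,px_size,rate Movie geometry: frame count,
#'   pixels, pixel size (um) and sampling rate (Hz).
#' @param stim_frames Two 1-based frame numbers: first and last odor frame.
#' @param baseline Mean resting fluorescence (a.u.).
#' @param bleach_tau Photobleaching time constant in frames (`Inf`
#'   disables bleaching).
#' @param bleach_amplitude Fraction of the baseline that bleaches (1 =
#'   pure exponential decay to zero).
#' @param decay_tau Decay constant (frames) of the calcium transient after
#'   stimulus offset.
#' @param noise_sd S.d. of additive Gaussian imaging noise (a.u.).
#' @param shift_range Maximal absolute inter-trial rigid translation in px.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       stim_duration = 0.5, pre_window = 1,
                       a_amp = 1, b_amp = 0.35, amp_sd = 0.05,
                       b_spontaneous = 25,
                       frames = 40, height = 260, width = 344,
                       px_size = 4, rate = 4, stim_frames = c(9, 16),
                       baseline = 1000, bleach_tau = 60,
                       bleach_amplitude = 1, decay_tau = 4,
                       noise_sd = 5, shift_range = 3) {
  stopifnot(stim_duration > 0, pre_window >= stim_duration,
            frames >= 1, stim_frames[1] >= 1, stim_frames[2] <= frames,
            stim_frames[1] <= stim_frames[2],
            bleach_tau > 0, decay_tau > 0, noise_sd >= 0, shift_range >= 0,
            bleach_amplitude >= 0, bleach_amplitude <= 1)
  cfg <- list(seed = as.integer(seed),
              stim_duration = stim_duration, pre_window = pre_window,
              a_amp = a_amp, b_amp = b_amp, amp_sd = amp_sd,
              b_spontaneous = b_spontaneous,
              frames = frames, height = height, width = width,
              px_size = px_size, rate = rate, stim_frames = stim_frames,
              baseline = baseline, bleach_tau = bleach_tau,
              bleach_amplitude = bleach_amplitude, decay_tau = decay_tau,
              noise_sd = noise_sd, shift_range = shift_range)
  class(cfg) <- "sim_config"
  cfg
}

# homogeneous Poisson event times on [t0, t1) at `rate` events/s
poisson_times <- function(rate, t0, t1) {
  n <- rpois(1, rate * (t1 - t0))
  sort(runif(n, t0, t1))
}

new_ssr_trial <- function(spikes, onset, duration, fly, sensillum, odor,
                          dilution, solvent, truth_rate = NA_real_,
                          trial_id = NA_character_) {
  structure(list(spikes = spikes, onset = onset, duration = duration,
                 fly = fly, sensillum = sensillum, odor = odor,
                 dilution = dilution, solvent = solvent,
                 truth_rate = truth_rate, trial_id = trial_id),
            class = "ssr_trial")
}

#' Construct a single SSR trial from spike times
#'
#' @param times Spike times in seconds (sorted internally).
#' @param amplitude Spike amplitudes (recycled).
#' @param unit Optional unit labels ("A"/"B"); `NA` for unsorted spikes.
#' @param onset Stimulus onset (s). @param duration Stimulus duration (s).
#' @param fly,odor,dilution,solvent Trial metadata.
#' @return An `ssr_trial`.
#' @export
ssr_trial <- function(times, amplitude = 1, unit = NA_character_,
                      onset = 1, duration = 0.5, fly = "fly1",
                      odor = "odor", dilution = -2, solvent = FALSE) {
  o <- order(times)
  spikes <- data.frame(time = as.numeric(times)[o],
                       amplitude = rep_len(amplitude, length(times))[o],
                       unit = rep_len(unit, length(times))[o],
                       stringsAsFactors = FALSE)
  new_ssr_trial(spikes, onset, duration, fly, "s1", odor, dilution, solvent)
}

#' Simulate a single-sensillum recording session
#'
#' For every receptor in `truth` and every fly, all panel odors are
#' presented once in random order, with solvent (blank) stimulations
#' interleaved at the beginning, middle and end of the experiment. Each
#' trial holds Poisson spike trains of the large-amplitude A neuron
#' (spontaneous rate plus, during the 500 ms stimulus, the true driven
#' rate of the presented odor) and of the small-amplitude B neuron
#' (spontaneous only). Spike amplitudes are drawn from two separated
#' Gaussians; the latent unit labels are retained as ground truth.
#'
#' @param truth [tuning_ground_truth()] object.
#' @param panel Odor panel.
#' @param n_flies Flies per receptor (scalar or per receptor).
#' @param cfg [sim_config()].
#' @return An `ssr_session`: list with `trials` (list of `ssr_trial`),
#'   `truth`, `panel` and `config`.
#' @export
simulate_ssr_session <- function(truth, panel, n_flies = 10,
                                 cfg = sim_config()) {
  if (any(!is.finite(truth$driven)) || any(truth$driven < 0) ||
      any(truth$spontaneous < 0))
    stop("driven and spontaneous rates must be finite and non-negative")
  n_flies <- rep_len(n_flies, length(truth$receptors))
  if (any(n_flies < 1)) stop("n_flies must be at least 1 per receptor")
  set.seed(cfg$seed)
  onset <- cfg$pre_window
  t_end <- onset + cfg$stim_duration + 1  # 1 s post-stimulus tail recorded
  trials <- list()
  for (r in seq_along(truth$receptors)) {
    rec <- truth$receptors[r]
    for (f in seq_len(n_flies[r])) {
      fly <- sprintf("%s_fly%02d", rec, f)
      odors <- sample(panel$odor)
      # solvent stimulations at beginning, middle and end of the experiment
      seq_odors <- append(odors, "solvent", after = length(odors) %/% 2)
      seq_odors <- c("solvent", seq_odors, "solvent")
      for (k in seq_along(seq_odors)) {
        od <- seq_odors[k]
        solvent <- od == "solvent"
        driven <- if (solvent) 0 else truth$driven[rec, od]
        a_times <- c(poisson_times(truth$spontaneous[rec], 0, t_end),
                     poisson_times(driven, onset, onset + cfg$stim_duration))
        b_times <- poisson_times(cfg$b_spontaneous, 0, t_end)
        spikes <- data.frame(
          time = c(a_times, b_times),
          amplitude = c(rnorm(length(a_times), cfg$a_amp, cfg$amp_sd),
                        rnorm(length(b_times), cfg$b_amp, cfg$amp_sd)),
          unit = rep(c("A", "B"), c(length(a_times), length(b_times))),
          stringsAsFactors = FALSE)
        spikes <- spikes[order(spikes$time), , drop = FALSE]
        rownames(spikes) <- NULL
        dil <- if (solvent) NA_real_ else
          panel$dilution[match(od, panel$odor)]
        trials[[length(trials) + 1L]] <- new_ssr_trial(
          spikes, onset, cfg$stim_duration, fly, rec, od, dil, solvent,
          truth_rate = driven,
          trial_id = sprintf("%s_t%03d", fly, k))
      }
    }
  }
  structure(list(trials = trials, truth = truth, panel = panel,
                 config = cfg),
            class = "ssr_session")
}

#' @export
print.ssr_session <- function(x, ...) {
  cat("ssr_session:", length(x$trials), "trials,",
      length(x$truth$receptors), "receptors,",
      nrow(x$panel), "odors\n")
  invisible(x)
}

# flat-top glomerulus profile: 1 inside the ROI square (plus a margin
# absorbing the spatial median filter's edge erosion), Gaussian fall-off
# outside, so the pipeline's ROI spatial mean equals the configured
# amplitude
glomerulus_blob <- function(height, width, cy, cx, side, margin = 3) {
  half <- (side - 1) / 2 + margin
  dy <- pmax(abs(seq_len(height) - cy) - half, 0)
  dx <- pmax(abs(seq_len(width) - cx) - half, 0)
  d2 <- outer(dy^2, dx^2, `+`)
  exp(-d2 / (2 * (side / 3)^2))
}

# replicate-padded integer translation: content moves by (dy, dx)
shift_image <- function(img, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  src_r <- pmin(pmax(seq_len(h) - dy, 1L), h)
  src_c <- pmin(pmax(seq_len(w) - dx, 1L), w)
  img[src_r, src_c, drop = FALSE]
}

#' Simulate one calcium-imaging trial
#'
#' Generates a fluorescence movie of `cfg$frames` frames: a resting image
#' with Gaussian-blob glomeruli whose fluorescence decays exponentially
#' (photobleaching), a response transient (plateau during the odor
#' frames, exponential tail after offset) whose per-ROI amplitude is
#' expressed in dF/F units of the unbleached resting image, additive
#' Gaussian noise, and an integer rigid inter-trial translation which is
#' stored as ground truth.
#'
#' @param map [glomerulus_map()] with ROI centers and side length.
#' @param amplitudes Per-ROI true response amplitude in dF/F units
#'   (recycled; each must be >= -1).
#' @param cfg [sim_config()]; geometry must contain all ROIs.
#' @param shift Integer `c(dy, dx)` translation, or `NULL` to draw it
#'   uniformly from `[-shift_range, shift_range]^2`.
#' @param animal,odor,solvent Trial metadata.
#' @param seed Optional seed overriding `cfg$seed` (use to vary trials
#'   within one configuration).
#' @return A [movie_stack()] whose `truth` field holds the amplitudes,
#'   applied shift and bleaching parameters.
#' @export
simulate_calcium_trial <- function(map, amplitudes, cfg = sim_config(),
                                   shift = NULL, animal = "animal1",
                                   odor = "odor", solvent = FALSE,
                                   seed = cfg$seed) {
  stopifnot(inherits(map, "glomerulus_map"))
  if (any(amplitudes < -1)) stop("amplitudes must be >= -1")
  amplitudes <- rep_len(amplitudes, nrow(map))
  half <- (map$side - 1) / 2
  if (any(map$cy - half < 1 | map$cy + half > cfg$height |
          map$cx - half < 1 | map$cx + half > cfg$width))
    stop("ROI outside image bounds for this geometry")
  set.seed(seed)
  h <- cfg$height; w <- cfg$width; tt <- cfg$frames
  blobs <- lapply(seq_len(nrow(map)), function(i)
    glomerulus_blob(h, w, map$cy[i], map$cx[i], map$side[i]))
  base <- matrix(cfg$baseline, h, w)
  for (b in blobs) base <- base + 0.3 * cfg$baseline * b
  resp <- matrix(0, h, w)
  for (i in seq_along(blobs)) resp <- resp + amplitudes[i] * blobs[[i]]
  kern <- transient_kernel(tt, cfg$stim_frames, cfg$decay_tau)
  bleach <- (1 - cfg$bleach_amplitude) +
    cfg$bleach_amplitude * exp(-(seq_len(tt) - 1) / cfg$bleach_tau)
  if (is.null(shift)) {
    shift <- if (cfg$shift_range > 0)
      sample(seq(-cfg$shift_range, cfg$shift_range), 2, replace = TRUE)
    else c(0L, 0L)
  }
  shift <- as.integer(shift)
  data <- array(0, dim = c(tt, h, w))
  # bleaching affects the resting fluorescence; the response increment is
  # specified directly in dF/F units of the pre-stimulus baseline so the
  # configured amplitude is the quantity the processing chain estimates
  for (t in seq_len(tt)) {
    frame <- base * (bleach[t] + resp * kern[t])
    if (any(shift != 0L)) frame <- shift_image(frame, shift[1], shift[2])
    if (cfg$noise_sd > 0) frame <- frame + rnorm(h * w, 0, cfg$noise_sd)
    data[t, , ] <- frame
  }
  movie_stack(data, rate = cfg$rate, stim_frames = cfg$stim_frames,
              px_size = cfg$px_size,
              meta = list(animal = animal, odor = odor, solvent = solvent),
              truth = list(amplitudes = setNames(amplitudes, map$roi),
                           shift = shift, bleach_tau = cfg$bleach_tau,
                           kernel = kern))
}

# 1-based response kernel: 0 before odor onset, 1 during the odor frames,
# exponential decay afterwards
transient_kernel <- function(frames, stim_frames, decay_tau) {
  t <- seq_len(frames)
  k <- numeric(frames)
  k[t >= stim_frames[1] & t <= stim_frames[2]] <- 1
  after <- t > stim_frames[2]
  k[after] <- exp(-(t[after] - stim_frames[2]) / decay_tau)
  k
}

#' Simulate a toy multi-exon gene model
#'
#' Builds a random protein-coding gene whose coding sequence (start codon,
#' sense codons, one terminal stop codon) is split across exons of the
#' requested lengths, separated by canonical GT..AG introns.
#'
#' @param exon_lengths Exon lengths in bp; their sum is the CDS length and
#'   must be divisible by 3 (and at least 6 to fit start and stop).
#' @param seed Integer seed.
#' @param intron_lengths Intron lengths (recycled; default random 60-150).
#' @return A [gene_model()].
#' @export
simulate_gene_model <- function(exon_lengths, seed = 1,
                                intron_lengths = NULL) {
  total <- sum(exon_lengths)
  if (total %% 3 != 0) stop("total CDS length must be divisible by 3")
  if (total < 6) stop("CDS too short for start and stop codons")
  set.seed(seed)
  codons <- as.vector(outer(c("A", "C", "G", "T"),
                            as.vector(outer(c("A", "C", "G", "T"),
                                            c("A", "C", "G", "T"),
                                            paste0)), paste0))
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  n_codon <- total / 3
  cds <- paste0("ATG",
                paste(sample(sense, n_codon - 2, replace = TRUE),
                      collapse = ""),
                "TAA")
  n_ex <- length(exon_lengths)
  if (is.null(intron_lengths) && n_ex > 1)
    intron_lengths <- sample(60:150, n_ex - 1, replace = TRUE)
  if (n_ex > 1) intron_lengths <- rep_len(intron_lengths, n_ex - 1)
  ex_seq <- substring(cds,
                      cumsum(c(1, exon_lengths[-n_ex])),
                      cumsum(exon_lengths))
  pieces <- character(0)
  starts <- integer(n_ex); pos <- 1L
  for (i in seq_len(n_ex)) {
    pieces <- c(pieces, ex_seq[i])
    starts[i] <- pos
    pos <- pos + nchar(ex_seq[i])
    if (i < n_ex) {
      il <- intron_lengths[i]
      if (il < 4) stop("introns must be at least 4 bp (GT..AG)")
      intron <- paste0("GT",
                       paste(sample(c("A", "C", "G", "T"), il - 4,
                                    replace = TRUE), collapse = ""),
                       "AG")
      pieces <- c(pieces, intron)
      pos <- pos + il
    }
  }
  gene_model(paste(pieces, collapse = ""),
             exons = data.frame(start = starts,
                                end = starts + exon_lengths - 1L))
}

#' Mask a fraction of matrix entries as missing
#'
#' Marks exactly `round(fraction * length(x))` entries of a per-recording
#' response matrix as `NA`, at seed-reproducible positions. Used to
#' emulate odors missing from individual recordings.
#'
#' @param x Numeric matrix. @param fraction Missing fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return `x` with `NA`s inserted; attribute `n_missing` holds the count.
#' @export
inject_missing <- function(x, fraction, seed = 1) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n_miss <- round(fraction * length(x))
  set.seed(seed)
  idx <- sample.int(length(x), n_miss)
  x[idx] <- NA
  attr(x, "n_missing") <- n_miss
  x
}

#' Simulate a glomerular response matrix linked to receptor truth
#'
#' Builds a glomeruli x odor median-response matrix in dF/F units in which
#' each receptor drives one target glomerulus (a scaled copy of its true
#' tuning plus noise) and the remaining glomeruli respond with unrelated
#' random tuning. Used to test receptor-to-glomerulus correlation mapping
#' against a known assignment.
#'
#' @param truth [tuning_ground_truth()].
#' @param n_glomeruli Number of glomeruli (default 23).
#' @param gain dF/F produced per spikes/s of receptor drive.
#' @param noise_sd S.d. of additive noise on the glomerular responses
#'   (dF/F units).
#' @param seed Integer seed.
#' @return List with `responses` (matrix) and `assignment` (named vector
#'   mapping each receptor to its target glomerulus).
#' @export
simulate_glomerular_matrix <- function(truth, n_glomeruli = 23,
                                       gain = 0.001, noise_sd = 0.005,
                                       seed = 1) {
  stopifnot(n_glomeruli >= length(truth$receptors))
  set.seed(seed)
  odors <- colnames(truth$driven)
  gloms <- sprintf("glom%02d", seq_len(n_glomeruli))
  target <- sample(gloms, length(truth$receptors))
  m <- matrix(pmax(rnorm(n_glomeruli * length(odors), 0.01, 0.02), 0),
              n_glomeruli, length(odors), dimnames = list(gloms, odors))
  for (i in seq_along(truth$receptors))
    m[target[i], ] <- gain * truth$driven[i, ] +
      rnorm(length(odors), 0, noise_sd)
  list(responses = m,
       assignment = setNames(target, truth$receptors))
}

#' Simulate per-animal glomerular responses for two genotypes
#'
#' Generates net glomerular responses (dF/F) of a control and a knockout
#' genotype over a ligand set: both genotypes share the same odor means
#' except for the knockout-diagnostic odor, whose response is abolished in
#' the knockout group.
#'
#' @param odors Odor names; `ko_odor` must be among them.
#' @param ko_odor The diagnostic odor lost in the knockout.
#' @param n_control,n_knockout Animals per genotype (defaults 8 and 10).
#' @param mean_response Mean response of responsive odors (dF/F).
#' @param noise_sd Between-animal s.d.
#' @param seed Integer seed.
#' @return Data frame: `animal`, `genotype` ("control"/"knockout"),
#'   `odor`, `response`.
#' @export
simulate_knockout_responses <- function(odors, ko_odor = odors[1],
                                        n_control = 8, n_knockout = 10,
                                        mean_response = 0.05,
                                        noise_sd = 0.01, seed = 1) {
  stopifnot(ko_odor %in% odors)
  set.seed(seed)
  build <- function(genotype, n) {
    do.call(rbind, lapply(seq_len(n), function(a) {
      mu <- rep(mean_response, length(odors))
      if (genotype == "knockout") mu[odors == ko_odor] <- 0
      data.frame(animal = sprintf("%s%02d", genotype, a),
                 genotype = genotype, odor = odors,
                 response = rnorm(length(odors), mu, noise_sd),
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(build("control", n_control), build("knockout", n_knockout))
}
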