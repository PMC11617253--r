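# Imaging chain: each stage against closed forms and the generator's
# ground truth, plus the cross-stage invariants (purity, translation
# equivariance, bounds conservation).

test_that("delta F/F uses the frame 3-7 background per pixel", {
  d <- array(100, dim = c(10, 6, 6))
  st <- movie_stack(d, stim_frames = c(3, 5))
  expect_equal(max(abs(deltaF_over_F(st)$data)), 0)
  d2 <- d; d2[9, , ] <- 200
  st2 <- movie_stack(d2, stim_frames = c(3, 5))
  expect_equal(deltaF_over_F(st2)$data[9, 1, 1], 1.0)
  # per-pixel background: hand-computed on an uneven pixel
  d3 <- d; d3[3:7, 2, 3] <- c(10, 20, 30, 40, 50)   # mean 30
  d3[9, 2, 3] <- 45
  st3 <- movie_stack(d3, stim_frames = c(3, 5))
  expect_equal(deltaF_over_F(st3)$data[9, 2, 3], (45 - 30) / 30)
  # non-positive background names the pixel
  d4 <- d; d4[3:7, 2, 3] <- 0
  expect_error(deltaF_over_F(movie_stack(d4, stim_frames = c(3, 5))),
               "row 2, col 3")
})

test_that("bleach correction flattens a pure exponential decay", {
  tt <- 40
  decay <- 0.9 + 0.4 * exp(-(seq_len(tt)) / 35)
  d <- array(rep(decay * 500, 36), dim = c(tt, 6, 6))
  st <- movie_stack(d)
  corr <- bleach_correct(deltaF_over_F(st))
  expect_lt(max(abs(corr$data)), 1e-6)
  # zero bleaching: correction approximately zero everywhere
  flat <- movie_stack(array(500, dim = c(tt, 6, 6)))
  cf <- bleach_correct(deltaF_over_F(flat))
  expect_lt(max(abs(cf$data)), 1e-8)
})

test_that("generator movie amplitude is recovered through the pipeline", {
  map <- interior_map(1)
  # tau = 60 frames, amplitude 0.05: recovered within 10%
  cfg <- quick_movie_cfg(seed = 21, bleach_tau = 60)
  tr <- simulate_calcium_trial(map, 0.05, cfg, shift = c(0, 0))
  p <- spatial_median_filter(bleach_correct(deltaF_over_F(tr)), 7)
  r <- extract_response(p, map)$responses$response[1]
  expect_equal(r, 0.05, tolerance = 0.1)
  # no bleaching, no noise: closed-form smoothed boxcar response; the
  # 3-frame smoothing at the onset edge gives exactly 8/9 of the plateau
  cfg0 <- quick_movie_cfg(seed = 22, bleach_amplitude = 0)
  tr0 <- simulate_calcium_trial(map, 0.05, cfg0, shift = c(0, 0))
  p0 <- suppressWarnings(
    spatial_median_filter(bleach_correct(deltaF_over_F(tr0)), 7))
  r0 <- extract_response(p0, map)$responses$response[1]
  expect_equal(r0, 0.05 * 8 / 9, tolerance = 5e-3)
  # within one smoothing-induced step (A/9) of the configured amplitude
  expect_lt(abs(r0 - 0.05), 0.05 / 9 + 5e-4)
})

test_that("spatial median filter matches a naive oracle and conserves bounds", {
  expect_error(spatial_median_filter(
    movie_stack(array(1, c(3, 5, 5)), stim_frames = c(1, 2)), width = 4),
    "odd")
  set.seed(9)
  img <- matrix(rnorm(15 * 12), 15, 12)
  st <- movie_stack(array(img, c(1, 15, 12)), stim_frames = c(1, 1))
  got <- spatial_median_filter(st, 5)$data[1, , ]
  expect_equal(got, oracle_median_filter(img, 5))
  # constant frame unchanged; impulse removed
  cst <- matrix(3, 10, 10)
  expect_equal(medfilt_via_stack(cst, 7), cst)
  imp <- cst; imp[5, 5] <- 100
  expect_equal(medfilt_via_stack(imp, 7), cst)
  # bounds conservation on noisy input
  expect_gte(min(got), min(img)); expect_lte(max(got), max(img))
})

test_that("movement correction recovers integer inter-trial shifts", {
  map <- interior_map(2)
  cfg <- quick_movie_cfg(seed = 31, noise_sd = 2)
  mk <- function(sh, sd) simulate_calcium_trial(map, c(0.05, 0.03), cfg,
                                                shift = sh, seed = sd)
  trials <- list(mk(c(0, 0), 1), mk(c(0, 0), 2), mk(c(3, -2), 3),
                 mk(c(0, 0), 4))
  mc <- movement_correct(trials, max_shift = 10)
  expect_equal(mc$shifts$dy, c(0, 0, -3, 0))
  expect_equal(mc$shifts$dx, c(0, 0, 2, 0))
  # identical trials: all shifts zero
  same <- list(mk(c(0, 0), 5), mk(c(0, 0), 5), mk(c(0, 0), 5))
  mc0 <- movement_correct(same)
  expect_true(all(mc0$shifts$dy == 0 & mc0$shifts$dx == 0))
  # flat frames: zero shift with warning
  flat <- lapply(1:2, function(i) movie_stack(array(1, c(40, 20, 20))))
  expect_warning(expect_warning(mcf <- movement_correct(flat), "flat"))
  expect_true(all(mcf$shifts$dy == 0))
})

test_that("median trial of two trials is their per-pixel midpoint", {
  a <- matrix(c(1, 5, 2, 8), 2); b <- matrix(c(3, 1, 10, 0), 2)
  expect_equal(apply(simplify2array(list(a, b)), c(1, 2), median),
               (a + b) / 2)
})

test_that("response extraction averages around the smoothed maximum", {
  # constant trace: response equals the constant
  d <- array(0.37, dim = c(40, 20, 20))
  st <- movie_stack(d)
  m <- glomerulus_map("g", 10, 10, side = 5, height = 20, width = 20)
  er <- extract_response(st, m)
  expect_equal(er$responses$response, 0.37)
  # isolated triangular peak: hand computation on the 40-point trace
  tr <- rep(0, 40); tr[11:13] <- c(0.2, 0.6, 0.2)
  d2 <- array(0, dim = c(40, 20, 20))
  for (t in 1:40) d2[t, , ] <- tr[t]
  sm <- vapply(1:40, function(i) mean(tr[max(1, i - 1):min(40, i + 1)]),
               numeric(1))
  peak <- which.max(sm[9:40]) + 8
  expected <- mean(sm[(peak - 1):(peak + 1)])
  er2 <- extract_response(movie_stack(d2), m)
  expect_equal(er2$responses$response, expected)
  expect_false(er2$responses$edge)
  # maximum at the trace end uses available neighbors and is flagged
  d3 <- array(0, dim = c(40, 20, 20))
  for (t in 1:40) d3[t, , ] <- t / 40
  er3 <- extract_response(movie_stack(d3), m)
  expect_true(er3$responses$edge)
  expect_equal(er3$responses$peak_frame, 40)
})

test_that("solvent subtraction works per animal and ROI", {
  df <- data.frame(animal = "a1", roi = "g1",
                   odor = c("oil", "oil", "odorX"),
                   solvent = c(TRUE, TRUE, FALSE),
                   response = c(0.01, 0.03, 0.10))
  out <- solvent_subtract_imaging(df)
  expect_equal(out$net_response, 0.08)
  df2 <- df; df2$response[3] <- 0.02
  expect_equal(solvent_subtract_imaging(df2)$net_response, 0)
  df3 <- df[df$solvent == FALSE, ]
  expect_error(solvent_subtract_imaging(df3), "no solvent")
})

test_that("glomerulus map building finds disjoint blobs at their centers", {
  map5 <- glomerulus_map(paste0("g", 1:5),
                         cy = c(25, 25, 95, 95, 60),
                         cx = c(25, 105, 25, 105, 65),
                         side = 15, height = 120, width = 130)
  cfg <- sim_config(seed = 2, height = 120, width = 130, noise_sd = 0,
                    shift_range = 0, bleach_amplitude = 0)
  tr <- simulate_calcium_trial(map5, c(.05, .04, .06, .05, .03), cfg,
                               shift = c(0, 0))
  p <- suppressWarnings(
    spatial_median_filter(bleach_correct(deltaF_over_F(tr)), 7))
  bm <- build_glomerulus_map(list(p), n_rois = 5, side = 15)
  expect_equal(nrow(bm), 5)
  found <- bm[order(bm$cy, bm$cx), ]
  want <- map5[order(map5$cy, map5$cx), ]
  expect_true(all(abs(found$cy - want$cy) <= 1))
  expect_true(all(abs(found$cx - want$cx) <= 1))
  # blank movie: empty map with warning
  blank <- movie_stack(array(0, c(10, 30, 30)), stim_frames = c(3, 6))
  expect_warning(bm0 <- build_glomerulus_map(list(blank), n_rois = 3),
                 "no activity")
  expect_equal(nrow(bm0), 0)
  # two blobs closer than one ROI side merge into one ROI
  map2 <- glomerulus_map(c("a", "b"), cy = c(60, 66), cx = c(60, 68),
                         side = 15, height = 120, width = 130)
  tr2 <- simulate_calcium_trial(map2, c(.05, .05), cfg, shift = c(0, 0))
  p2 <- suppressWarnings(
    spatial_median_filter(bleach_correct(deltaF_over_F(tr2)), 7))
  expect_warning(bm2 <- build_glomerulus_map(list(p2), n_rois = 2,
                                             side = 15),
                 "only 1")
  expect_equal(nrow(bm2), 1)
})

test_that("stages are pure and the chain is translation equivariant", {
  map <- interior_map(1)
  cfg <- quick_movie_cfg(seed = 41, noise_sd = 0)
  base <- simulate_calcium_trial(map, 0.05, cfg, shift = c(0, 0), seed = 7)
  snapshot <- base$data
  out <- spatial_median_filter(bleach_correct(deltaF_over_F(base)), 7)
  expect_identical(base$data, snapshot)        # input unmodified
  # the same movie shifted by (4, -3) among unshifted companions yields
  # the same extracted responses after movement correction
  companions <- lapply(1:3, function(k)
    simulate_calcium_trial(map, 0.05, cfg, shift = c(0, 0), seed = 10 + k))
  shifted <- simulate_calcium_trial(map, 0.05, cfg, shift = c(4, -3),
                                    seed = 7)
  resp_ref <- process_imaging_trials(c(companions, list(base)), map,
                                     align = TRUE)
  resp_shift <- process_imaging_trials(c(companions, list(shifted)), map,
                                       align = TRUE)
  r1 <- resp_ref$response[resp_ref$trial == 4]
  r2 <- resp_shift$response[resp_shift$trial == 4]
  expect_equal(r2, r1, tolerance = 1e-3)
  expect_equal(resp_shift$shift_y[resp_shift$trial == 4][1], -4L)
  expect_equal(resp_shift$shift_x[resp_shift$trial == 4][1], 3L)
})
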