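# Generators: determinism, validation, and agreement between the latent
# parameters and what the simulated data actually contain.

test_that("generators are deterministic under a fixed seed", {
  panel <- tiny_panel()
  truth <- tuning_ground_truth(panel, receptors = c("R1", "R2"), seed = 4)
  s1 <- simulate_ssr_session(truth, panel, n_flies = 2,
                             cfg = sim_config(seed = 9))
  s2 <- simulate_ssr_session(truth, panel, n_flies = 2,
                             cfg = sim_config(seed = 9))
  expect_identical(s1$trials, s2$trials)

  cfg <- quick_movie_cfg(seed = 3, noise_sd = 2, shift_range = 2)
  map <- interior_map()
  m1 <- simulate_calcium_trial(map, 0.05, cfg)
  m2 <- simulate_calcium_trial(map, 0.05, cfg)
  expect_identical(m1$data, m2$data)
  expect_identical(m1$truth$shift, m2$truth$shift)

  g1 <- simulate_gene_model(c(120, 90, 90), seed = 5)
  g2 <- simulate_gene_model(c(120, 90, 90), seed = 5)
  expect_identical(g1$sequence, g2$sequence)

  x <- matrix(rnorm(200), 10, 20)
  expect_identical(inject_missing(x, 0.2, seed = 2),
                   inject_missing(x, 0.2, seed = 2))
})

test_that("generator inputs are validated", {
  panel <- tiny_panel()
  truth <- tuning_ground_truth(panel, receptors = "R1", seed = 1)
  bad <- truth; bad$driven[1, 1] <- -5
  expect_error(simulate_ssr_session(bad, panel, 2), "non-negative")
  expect_error(simulate_ssr_session(truth, panel, 0), "n_flies")
  expect_error(inject_missing(matrix(1, 2, 2), 1), "fraction")
  expect_error(simulate_gene_model(c(100, 102)), "divisible by 3")
  map <- glomerulus_map("g", cy = 5, cx = 5, side = 15)
  expect_error(simulate_calcium_trial(map, 0.05, quick_movie_cfg()),
               "bounds")
})

test_that("each fly gets solvent trials at start, middle and end", {
  panel <- tiny_panel(6)
  truth <- tuning_ground_truth(panel, receptors = "R1", seed = 2)
  sess <- simulate_ssr_session(truth, panel, n_flies = 3,
                               cfg = sim_config(seed = 2))
  per_fly <- split(sess$trials,
                   vapply(sess$trials, `[[`, character(1), "fly"))
  for (trs in per_fly) {
    solv <- which(vapply(trs, `[[`, logical(1), "solvent"))
    expect_length(solv, 3)
    expect_equal(solv[1], 1)                      # beginning
    expect_equal(solv[3], length(trs))            # end
    expect_gt(solv[2], 1); expect_lt(solv[2], length(trs))  # middle
  }
})

test_that("simulated spike trains match their Poisson ground truth", {
  # no stimulus effect: driven rate 0, spontaneous 10 spikes/s
  panel <- tiny_panel(2)
  truth <- tuning_ground_truth(panel, receptors = "R1", breadth = 0.5,
                               max_rate = 0, spontaneous = 10, seed = 1)
  truth$driven[] <- 0
  sess <- simulate_ssr_session(truth, panel, n_flies = 150,
                               cfg = sim_config(seed = 11))
  resp <- session_responses(sess)
  pre_counts <- resp$spontaneous_hz / 2
  expect_equal(mean(pre_counts), 5, tolerance = 0.05)      # ~5 per 500 ms
  expect_lt(abs(mean(resp$net_count)), 0.3)                # ~0 difference

  # driven 100 spikes/s on one odor: recovered mean response within
  # 2 spikes/s of 100 over many trials
  panel1 <- odor_panel(1)
  t2 <- tuning_ground_truth(panel1, receptors = "R1", breadth = 1,
                            spontaneous = 10, seed = 1)
  t2$driven[1, 1] <- 100
  sess2 <- simulate_ssr_session(t2, panel1, n_flies = 2500,
                                cfg = sim_config(seed = 12))
  resp2 <- session_responses(sess2)
  expect_equal(mean(resp2$response_hz), 100, tolerance = 2 / 100)
})

test_that("A and B units are separated in amplitude", {
  panel <- tiny_panel(4)
  truth <- tuning_ground_truth(panel, receptors = "R1", seed = 3)
  sess <- simulate_ssr_session(truth, panel, n_flies = 2,
                               cfg = sim_config(seed = 5))
  sp <- do.call(rbind, lapply(sess$trials, `[[`, "spikes"))
  expect_gt(min(sp$amplitude[sp$unit == "A"]),
            max(sp$amplitude[sp$unit == "B"]))
})

test_that("calcium movies carry exact ground truth", {
  map <- interior_map(1)
  cfg <- quick_movie_cfg(bleach_amplitude = 0)
  # zero amplitude, no bleaching, no noise: constant in time
  m0 <- simulate_calcium_trial(map, 0, cfg, shift = c(0, 0))
  for (t in 2:40) expect_identical(m0$data[t, , ], m0$data[1, , ])
  expect_equal(dim(m0$data), c(40, 80, 100))
  # configured shift stored as ground truth
  ms <- simulate_calcium_trial(map, 0.05, cfg, shift = c(3, -2))
  expect_identical(ms$truth$shift, c(3L, -2L))
  # ROI mean of the response field equals the configured amplitude
  m1 <- simulate_calcium_trial(map, 0.05, cfg, shift = c(0, 0))
  dff <- deltaF_over_F(m1)
  half <- (map$side[1] - 1) / 2
  rows <- (map$cy[1] - half):(map$cy[1] + half)
  cols <- (map$cx[1] - half):(map$cx[1] + half)
  plateau <- mean(dff$data[12, rows, cols])
  expect_equal(plateau, 0.05, tolerance = 1e-10)
})

test_that("zero-amplitude zero-noise movie is flat after bleach correction", {
  map <- interior_map(1)
  cfg <- quick_movie_cfg(bleach_tau = 50)
  m <- simulate_calcium_trial(map, 0, cfg, shift = c(0, 0))
  corr <- bleach_correct(deltaF_over_F(m))
  expect_lt(max(abs(corr$data)), 1e-6)
})

test_that("inject_missing marks the exact requested count reproducibly", {
  x <- matrix(rnorm(4240), 53, 80)
  expect_identical(inject_missing(x, 0, seed = 1)[, ], x[, ])
  masked <- inject_missing(x, 156 / 4240, seed = 7)
  expect_equal(sum(is.na(masked)), 156)
  expect_equal(attr(masked, "n_missing"), 156)
  # untouched cells unchanged
  expect_identical(masked[!is.na(masked)], x[!is.na(masked)])
})

test_that("synthetic gene models translate to the expected protein", {
  g <- simulate_gene_model(300, seed = 8)   # single exon
  expect_equal(translate_cds(splice(g))$length, 99)  # stop removed
  g2 <- simulate_gene_model(c(60, 120, 120), seed = 8)
  expect_true(all(g2$introns$canonical))
  expect_equal(translate_cds(splice(g2))$length, 99)
})

test_that("glomerular matrix and knockout generators embed their truth", {
  panel <- odor_panel(30)
  truth <- tuning_ground_truth(panel, receptors = paste0("R", 1:4),
                               seed = 2)
  g <- simulate_glomerular_matrix(truth, n_glomeruli = 10, seed = 2)
  expect_equal(dim(g$responses), c(10, 30))
  expect_setequal(names(g$assignment), truth$receptors)
  ko <- simulate_knockout_responses(paste0("od", 1:5), ko_odor = "od3",
                                    seed = 3)
  expect_equal(nrow(ko), (8 + 10) * 5)
  med <- tapply(ko$response, list(ko$genotype, ko$odor), median)
  expect_lt(med["knockout", "od3"], 0.02)
  expect_gt(med["control", "od3"], 0.03)
})
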