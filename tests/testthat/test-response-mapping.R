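# Profile mapping: imputation, rank correlation, ANOSIM, NMDS and the
# knockout comparison, each against an independent oracle where one
# exists.

test_that("group-median imputation fills only the missing cells", {
  x <- matrix(c(4, NA, 8, 1, 2, 3), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  out <- impute_group_median(x, groups = c("g", "g", "g"))
  expect_equal(unname(out$data[2, "a"]), 6)
  expect_equal(out$n_imputed, 1L)
  expect_identical(out$data[, "b"], x[, "b"])
  # nothing missing: unchanged, count 0
  full <- impute_group_median(x[, 2, drop = FALSE], groups = rep("g", 3))
  expect_equal(full$n_imputed, 0L)
  # an entirely missing (group, odor) cannot be imputed
  x2 <- x; x2[, "a"] <- NA
  expect_error(impute_group_median(x2, groups = rep("g", 3)),
               "all values missing")
})

test_that("imputation count equals the injected mask cardinality", {
  set.seed(4)
  prof <- matrix(rnorm(53 * 80, 30, 20), 53, 80,
                 dimnames = list(NULL, paste0("o", 1:80)))
  groups <- rep(paste0("OR", 1:5), c(10, 11, 11, 11, 10))
  masked <- inject_missing(prof, 156 / 4240, seed = 5)
  out <- impute_group_median(masked, groups)
  expect_equal(out$n_imputed, 156L)
  expect_false(anyNA(out$data))
  keep <- !is.na(masked)
  expect_identical(out$data[keep], prof[keep])
})

test_that("Spearman heatmap matches hand-ranked correlations", {
  or_m <- rbind(R1 = c(5, 3, 9, 1, 7))
  colnames(or_m) <- paste0("o", 1:5)
  glom_m <- rbind(G1 = c(5, 3, 9, 1, 7),        # identical ranking
                  G2 = c(5, 7, 1, 9, 3),        # strictly reversed ranking
                  G3 = c(2.5, 1, 6, 0.3, 4))    # same ranks as R1
  colnames(glom_m) <- paste0("o", 1:5)
  h <- spearman_matrix(or_m, glom_m)
  expect_equal(h$rho["R1", "G1"], 1)
  expect_equal(h$rho["R1", "G2"], -1)
  expect_equal(h$rho["R1", "G3"], 1)
  # brute-force rank formula (average ranks on ties) as oracle
  a <- c(2, 2, 5, 7, 1); b <- c(3, 9, 9, 4, 0)
  ra <- rank(a); rb <- rank(b)
  manual <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  am <- rbind(u = a); bm <- rbind(v = b)
  colnames(am) <- colnames(bm) <- paste0("o", 1:5)
  expect_equal(spearman_matrix(am, bm)$rho[1, 1], manual)
  expect_error(spearman_matrix(or_m[, 1:2, drop = FALSE], glom_m),
               "3 shared")
})

test_that("rank correlation is invariant to monotone transforms", {
  set.seed(8)
  a <- rbind(u = rexp(12)); colnames(a) <- paste0("o", 1:12)
  b <- rbind(v = rnorm(12)); colnames(b) <- paste0("o", 1:12)
  base <- spearman_matrix(a, b)$rho[1, 1]
  expect_equal(spearman_matrix(exp(a), b)$rho[1, 1], base)
  expect_equal(spearman_matrix(a, rbind(v = b[1, ]^3))$rho[1, 1], base)
  # constant vector: undefined, flagged as NA with warning
  cc <- rbind(w = rep(2, 12)); colnames(cc) <- colnames(a)
  expect_warning(h <- spearman_matrix(cc, b), "undefined|constant")
  expect_true(is.na(h$rho[1, 1]))
})

test_that("ANOSIM equals its defining rank formula and vegan", {
  set.seed(11)
  x <- matrix(rnorm(10 * 4), 10, 4)
  g <- rep(c("a", "b"), each = 5)
  x[g == "b", ] <- x[g == "b", ] + 1.5
  got <- anosim(x, g, n_perm = 199, seed = 1)
  expect_equal(got$statistic, oracle_anosim_R(x, g), tolerance = 1e-12)
  ref <- vegan::anosim(dist(x), factor(g), permutations = 99)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  # perfectly separated groups: R = 1
  y <- rbind(matrix(rnorm(8, 0, 0.01), 4), matrix(rnorm(8, 10, 0.01), 4))
  expect_equal(anosim(y, rep(1:2, each = 4), n_perm = 99)$statistic, 1)
  # validation
  expect_error(anosim(x, c("a", rep("b", 9)), n_perm = 99), "singleton")
  expect_error(anosim(x, rep("a", 10), n_perm = 99), "2 groups")
})

test_that("ANOSIM p-values behave under the null and satisfy their bound", {
  set.seed(21)
  n_sig <- 0
  for (k in 1:40) {
    x <- matrix(rnorm(10 * 3), 10, 3)          # one homogeneous cloud
    g <- sample(rep(c("a", "b"), each = 5))
    res <- anosim(x, g, n_perm = 999, seed = k)
    if (res$p.value <= 0.05) n_sig <- n_sig + 1
    expect_gte(res$p.value, 1 / (1 + 999))
  }
  expect_lte(n_sig / 40, 0.15)   # near-nominal false-positive rate
})

test_that("ANOSIM is invariant to monotone transforms of the distances", {
  set.seed(31)
  x <- matrix(rnorm(8 * 3), 8, 3)
  g <- rep(c("a", "b"), each = 4)
  d <- dist(x)
  r1 <- anosim(d, g, n_perm = 99, seed = 2)$statistic
  r2 <- anosim(d^2, g, n_perm = 99, seed = 2)$statistic   # monotone map
  expect_equal(r1, r2)
})

test_that("NMDS embeds planar data exactly and is seed-reproducible", {
  set.seed(5)
  pts <- cbind(rnorm(12), rnorm(12))
  fit <- suppressWarnings(nmds(pts, dims = 2, restarts = 5, seed = 3))
  expect_lt(fit$stress, 0.01)
  expect_equal(unname(colMeans(fit$points)), c(0, 0), tolerance = 1e-8)
  # generic high-dimensional cloud cannot keep all distance ranks in 2-D
  set.seed(6)
  hi <- matrix(rnorm(10 * 6), 10, 6)
  fit_hi <- suppressWarnings(nmds(hi, dims = 2, restarts = 5, seed = 3))
  expect_gt(fit_hi$stress, 0.01)
  # same seed, same coordinates
  f1 <- suppressWarnings(nmds(pts, restarts = 5, seed = 11))
  f2 <- suppressWarnings(nmds(pts, restarts = 5, seed = 11))
  expect_equal(f1$points, f2$points)
  expect_error(nmds(pts[1:3, ]), "at least")
  expect_error(nmds(cbind(c(1, NA, 3), 1:3)), "complete")
})

test_that("genotype comparison flags only truly different odors", {
  # exact p for small untied samples, against enumeration
  df <- data.frame(genotype = rep(c("het", "hom"), each = 3),
                   odor = "x",
                   response = c(1, 2, 3, 10, 11, 12))
  out <- compare_genotypes(df)
  expect_equal(out$U, 0)
  expect_equal(out$p, 0.1)
  expect_equal(out$p, oracle_mann_whitney_p(c(1, 2, 3), c(10, 11, 12)))
  # identical samples: p = 1 with note
  df2 <- data.frame(genotype = rep(c("het", "hom"), each = 4),
                    odor = "x", response = rep(2, 8))
  out2 <- compare_genotypes(df2)
  expect_equal(out2$p, 1)
  expect_match(out2$note, "tied")
  expect_error(compare_genotypes(
    data.frame(genotype = c("a", "a", "b"), odor = "x",
               response = 1:3)), "fewer than")
})

test_that("simulated knockouts are detected odor-specifically", {
  hits <- 0; false_hits <- 0
  for (s in 1:20) {
    sim <- simulate_knockout_responses(sprintf("od%02d", 1:12),
                                       ko_odor = "od07", seed = s)
    tab <- compare_genotypes(sim)
    if (tab$significant[tab$odor == "od07"]) hits <- hits + 1
    false_hits <- false_hits + sum(tab$significant[tab$odor != "od07"])
  }
  expect_gte(hits / 20, 0.95)
  # 11 null odors x 20 seeds at alpha 0.05: expect few flags
  expect_lte(false_hits, 25)
})

test_that("best-match glomerulus identification recovers the assignment", {
  correct <- 0; total <- 0
  for (s in 1:10) {
    panel <- odor_panel(80)
    truth <- tuning_ground_truth(panel, receptors = paste0("R", 1:5),
                                 seed = s)
    glom <- simulate_glomerular_matrix(truth, n_glomeruli = 23, seed = s)
    h <- spearman_matrix(truth$driven, glom$responses)
    correct <- correct + sum(h$best_match == glom$assignment)
    total <- total + length(h$best_match)
  }
  expect_gte(correct / total, 0.95)
})
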