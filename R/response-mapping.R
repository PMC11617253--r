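# Relating receptor response profiles to glomerular profiles and testing
# profile distinctness: group-median imputation, Spearman correlation
# mapping, ANOSIM, NMDS and knockout-versus-control comparison.

#' Per-recording profile matrix of a session
#'
#' Pivots per-trial responses into one row per recording (receptor x
#' fly), columns ordered by the panel, for ordination and ANOSIM. Odors
#' not presented in a recording are `NA`.
#'
#' @param responses Data frame from [session_responses()].
#' @param odors Column (odor) order; default the odors present.
#' @return Numeric matrix with attribute `groups` (receptor per row).
#' @export
profile_matrix <- function(responses, odors = NULL) {
  odors <- odors %||% unique(responses$odor)
  rec <- interaction(responses$unit, responses$fly, drop = TRUE)
  rows <- levels(rec)
  m <- matrix(NA_real_, length(rows), length(odors),
              dimnames = list(rows, odors))
  m[cbind(match(rec, rows), match(responses$odor, odors))] <-
    responses$response_hz
  groups <- vapply(rows, function(r)
    responses$unit[match(r, rec)], character(1))
  attr(m, "groups") <- unname(groups)
  m
}

#' Replace missing profile entries by the group median
#'
#' Each missing value is replaced by the median of the non-missing values
#' of the same group (receptor) for the same odor.
#'
#' @param x Recordings x odors matrix with `NA` for missing entries.
#' @param groups Group label per row.
#' @return List with `data` (completed matrix) and `n_imputed`.
#' @export
impute_group_median <- function(x, groups = attr(x, "groups")) {
  stopifnot(length(groups) == nrow(x))
  n_imputed <- 0L
  for (g in unique(groups)) {
    rows <- which(groups == g)
    for (j in seq_len(ncol(x))) {
      v <- x[rows, j]
      miss <- is.na(v)
      if (!any(miss)) next
      if (all(miss))
        stop(sprintf("group %s, odor %s: all values missing, cannot impute",
                     g, colnames(x)[j] %||% j))
      x[rows[miss], j] <- median(v[!miss])
      n_imputed <- n_imputed + sum(miss)
    }
  }
  list(data = x, n_imputed = n_imputed)
}

#' Spearman correlation heatmap of receptors versus glomeruli
#'
#' Rank-correlates every receptor's median odor responses with every
#' glomerulus' median odor responses over the shared odors (average ranks
#' on ties, pairwise-complete observations) and reports the best-matching
#' glomerulus per receptor.
#'
#' @param or_matrix Receptors x odors median response matrix.
#' @param glom_matrix Glomeruli x odors median response matrix; must
#'   share at least 3 odor columns with `or_matrix`.
#' @return List of class `correlation_heatmap`: `rho` (receptors x
#'   glomeruli), `best_match` (named vector), `n_shared`.
#' @export
spearman_matrix <- function(or_matrix, glom_matrix) {
  shared <- intersect(colnames(or_matrix), colnames(glom_matrix))
  if (length(shared) < 3) stop("need at least 3 shared odors")
  a <- or_matrix[, shared, drop = FALSE]
  b <- glom_matrix[, shared, drop = FALSE]
  rho <- suppressWarnings(
    cor(t(a), t(b), method = "spearman", use = "pairwise.complete.obs"))
  dimnames(rho) <- list(rownames(or_matrix), rownames(glom_matrix))
  if (any(is.na(rho)))
    warning("undefined correlations (constant profile) flagged as NA")
  best <- apply(rho, 1, function(r)
    if (all(is.na(r))) NA_character_ else colnames(rho)[which.max(r)])
  structure(list(rho = rho, best_match = best,
                 n_shared = length(shared)),
            class = "correlation_heatmap")
}

#' @export
print.correlation_heatmap <- function(x, ...) {
  cat("correlation_heatmap:", nrow(x$rho), "receptors x", ncol(x$rho),
      "glomeruli over", x$n_shared, "shared odors\n")
  cat("best matches:\n")
  print(x$best_match)
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group distances exceed
#' within-group distances. With ranks (average on ties) of all pairwise
#' distances among n observations,
#' \deqn{R = \frac{\bar r_{between} - \bar r_{within}}{n (n - 1) / 4}}
#' R is close to 0 when grouping is irrelevant and 1 when all
#' within-group distances are smaller than any between-group distance.
#' The p-value is one-tailed over label permutations:
#' `p = (1 + #\{R* >= R\}) / (1 + n_perm)`.
#'
#' @param x Observations x variables matrix, or a `dist`.
#' @param groups Group label per observation (>= 2 groups, each with >= 2
#'   members).
#' @param n_perm Number of label permutations (>= 99; default 9999).
#' @param seed Optional seed for the permutations.
#' @param distance Distance metric passed to [stats::dist()] when `x` is
#'   a matrix (default Euclidean).
#' @return List of class `anosim_test`: `statistic` (R), `p.value`,
#'   `n_perm`, `perm_stats`.
#' @export
anosim <- function(x, groups, n_perm = 9999, seed = NULL,
                   distance = "euclidean") {
  d <- if (inherits(x, "dist")) x else dist(x, method = distance)
  n <- attr(d, "Size")
  groups <- as.character(groups)
  stopifnot(length(groups) == n, n_perm >= 99)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("singleton group(s): ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  rk <- rank(as.vector(d))
  pair_i <- rep(seq_len(n - 1), (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  denom <- n * (n - 1) / 4
  stat_for <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(rk[!within]) - mean(rk[within])) / denom
  }
  observed <- stat_for(groups)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(k) stat_for(sample(groups)),
                 numeric(1))
  p <- (1 + sum(perm >= observed)) / (1 + n_perm)
  structure(list(statistic = observed, p.value = p, n_perm = n_perm,
                 perm_stats = perm, groups = tab),
            class = "anosim_test")
}

#' @export
print.anosim_test <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, p = %.4g (%d permutations)\n",
              x$statistic, x$p.value, x$n_perm))
  invisible(x)
}

#' Non-metric multidimensional scaling of response profiles
#'
#' Embeds the profiles in `dims` dimensions by NMDS (Kruskal stress-1,
#' multiple random restarts via [vegan::metaMDS()]) on Euclidean
#' distances, and reports the final stress. Coordinates are centered;
#' they are defined up to rotation and reflection.
#'
#' @param x Completed (no missing values) observations x variables
#'   matrix, or a `dist`.
#' @param dims Embedding dimension (default 2).
#' @param restarts Random restarts (default 20).
#' @param seed Optional seed, for reproducible coordinates.
#' @param distance Distance metric when `x` is a matrix.
#' @return List: `points` (n x dims), `stress` (Kruskal stress-1, as a
#'   proportion), `converged`.
#' @export
nmds <- function(x, dims = 2, restarts = 20, seed = NULL,
                 distance = "euclidean") {
  d <- if (inherits(x, "dist")) x else {
    if (anyNA(x)) stop("profiles must be complete; impute upstream")
    dist(x, method = distance)
  }
  n <- attr(d, "Size")
  if (n < dims + 2) stop("need at least dims + 2 observations")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::metaMDS(d, k = dims, try = restarts,
                        trymax = max(restarts, 20), trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  pts <- scale(fit$points, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  list(points = pts, stress = fit$stress,
       converged = isTRUE(fit$converged) || fit$converged > 0)
}

#' Per-odor genotype comparison of glomerular responses
#'
#' Compares net responses between two genotypes odor by odor with a
#' two-sided Mann-Whitney U test (exact p where feasible, i.e., small
#' samples without ties; normal approximation with tie correction
#' otherwise), reporting medians and interquartile ranges per genotype
#' and flagging odors with p below `alpha`. Per-odor p-values are
#' reported unadjusted.
#'
#' @param responses Data frame with columns `genotype` (exactly two
#'   levels), `odor`, `response` (one row per animal and odor).
#' @param alpha Significance threshold for the flag.
#' @param min_n Minimal animals per genotype per odor (default 3).
#' @return Data frame, one row per odor: sample sizes, medians, IQRs, U,
#'   `p`, `significant`, `note`.
#' @export
compare_genotypes <- function(responses, alpha = 0.05, min_n = 3) {
  stopifnot(all(c("genotype", "odor", "response") %in% names(responses)))
  gts <- unique(responses$genotype)
  if (length(gts) != 2) stop("exactly two genotypes are required")
  rows <- lapply(unique(responses$odor), function(od) {
    x <- responses$response[responses$odor == od &
                              responses$genotype == gts[1]]
    y <- responses$response[responses$odor == od &
                              responses$genotype == gts[2]]
    if (length(x) < min_n || length(y) < min_n)
      stop(sprintf("odor %s: fewer than %d animals in a genotype",
                   od, min_n))
    note <- ""
    if (length(unique(c(x, y))) == 1) {
      u <- length(x) * length(y) / 2
      p <- 1
      note <- "all values tied"
    } else {
      ties <- any(duplicated(c(x, y)))
      wt <- suppressWarnings(
        wilcox.test(x, y, exact = !ties && length(x) + length(y) <= 20,
                    correct = TRUE))
      u <- unname(wt$statistic)
      p <- wt$p.value
      if (ties) note <- "ties; normal approximation"
    }
    data.frame(odor = od,
               n_1 = length(x), n_2 = length(y),
               median_1 = median(x), iqr_1 = stats::IQR(x),
               median_2 = median(y), iqr_2 = stats::IQR(y),
               U = u, p = p, significant = p < alpha, note = note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("_1$", paste0("_", gts[1]), names(out))
  names(out) <- sub("_2$", paste0("_", gts[2]), names(out))
  rownames(out) <- NULL
  out
}
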