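# End-to-end report pipeline: simulate -> SSR quantification -> tuning
# metrics -> imaging -> receptor/glomerulus mapping -> genotype
# comparison -> mutant model. Every output file records the seed and the
# configuration hash that produced it.

#' Run the end-to-end synthetic report pipeline
#'
#' Executes the configured stages on synthetic data with known ground
#' truth and writes a JSON + TSV bundle plus a provenance log. Identical
#' configurations produce bit-identical bundles.
#'
#' @param cfg A [run_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results of each stage.
#' @export
run_report <- function(cfg = run_config(), outdir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  log_lines <- c(sprintf("olfactr report | seed %d | config %s",
                         cfg$seed, hash),
                 sprintf("stages: %s", paste(cfg$stages, collapse = ", ")))
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  results <- list(config = cfg, hash = hash)
  run_stage <- function(stage, fn) {
    if (!stage %in% cfg$stages) {
      say("stage %s: disabled in config, skipped", stage)
      return(NULL)
    }
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage %s failed (seed %d, config %s): %s",
                   stage, cfg$seed, hash, conditionMessage(e)),
           call. = FALSE))
  }
  stamp <- function(df) {
    attr(df, "provenance") <- sprintf("seed=%d config=%s", cfg$seed, hash)
    df
  }
  tsv <- function(df, file) {
    path <- file.path(outdir, file)
    con <- file(path, "w")
    writeLines(sprintf("# olfactr seed=%d config=%s", cfg$seed, hash), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    close(con)
    say("wrote %s", file)
  }
  jsn <- function(x, file) {
    x$provenance <- list(seed = cfg$seed, config = hash)
    jsonlite::write_json(x, file.path(outdir, file), auto_unbox = TRUE,
                         digits = NA, null = "null")
    say("wrote %s", file)
  }

  # --- SSR stage -------------------------------------------------------
  results$ssr <- run_stage("ssr", function() {
    panel <- odor_panel(cfg$n_odors)
    truth <- tuning_ground_truth(
      panel, receptors = sprintf("OR%02d", seq_len(cfg$n_receptors)),
      breadth = seq(0.25, 0.45, length.out = cfg$n_receptors),
      seed = cfg$seed)
    session <- simulate_ssr_session(truth, panel, n_flies = cfg$n_flies,
                                    cfg = sim_config(seed = cfg$seed))
    resp <- session_responses(session)
    mat <- aggregate_median_responses(resp, odors = panel$odor)
    tsv(resp, "responses.tsv")
    write_response_matrix(mat, file.path(outdir, "matrix.tsv"))
    say("wrote matrix.tsv")
    list(panel = panel, truth = truth, responses = stamp(resp),
         matrix = mat)
  })

  # --- tuning stage ----------------------------------------------------
  results$tuning <- run_stage("tuning", function() {
    if (is.null(results$ssr)) stop("tuning requires the ssr stage")
    mat <- results$ssr$matrix
    cls <- classify_responses(mat, cfg$response_threshold)
    spars <- apply(mat, 1, lifetime_sparseness)
    frac <- apply(mat, 1, responsive_fraction,
                  threshold = cfg$response_threshold)
    lig <- lapply(rownames(mat), function(r)
      best_ligands(mat[r, ], cfg$response_threshold)$odor)
    names(lig) <- rownames(mat)
    tsv(data.frame(unit = rownames(cls), cls, check.names = FALSE),
        "classification.tsv")
    jsn(list(lifetime_sparseness = as.list(spars),
             responsive_percent = as.list(frac),
             best_ligands = lig),
        "tuning.json")
    list(classification = cls, sparseness = spars,
         responsive_percent = frac, best_ligands = lig)
  })

  # --- mapping stage ---------------------------------------------------
  results$mapping <- run_stage("mapping", function() {
    if (is.null(results$ssr)) stop("mapping requires the ssr stage")
    prof <- profile_matrix(results$ssr$responses,
                           odors = results$ssr$panel$odor)
    groups <- attr(prof, "groups")
    masked <- inject_missing(prof, cfg$missing_fraction,
                             seed = cfg$seed)
    imp <- impute_group_median(masked, groups)
    an <- anosim(imp$data, groups, n_perm = cfg$n_perm, seed = cfg$seed)
    nm <- nmds(imp$data, restarts = cfg$nmds_restarts, seed = cfg$seed)
    glom <- simulate_glomerular_matrix(results$ssr$truth,
                                       seed = cfg$seed)
    heat <- spearman_matrix(results$ssr$matrix, glom$responses)
    tsv(data.frame(unit = rownames(heat$rho), heat$rho,
                   best_match = heat$best_match, check.names = FALSE),
        "heatmap.tsv")
    jsn(list(anosim = list(R = an$statistic, p = an$p.value,
                           n_perm = an$n_perm),
             nmds = list(stress = nm$stress,
                         points = as.data.frame(nm$points)),
             imputed = imp$n_imputed,
             best_match = as.list(heat$best_match)),
        "mapping.json")
    list(profiles = imp$data, groups = groups, anosim = an, nmds = nm,
         heatmap = heat, glomerular_truth = glom,
         n_imputed = imp$n_imputed)
  })

  # --- imaging stage ---------------------------------------------------
  results$imaging <- run_stage("imaging", function() {
    icfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$imaging))
    map <- default_glomerulus_map(icfg, cfg$roi_side)
    odors <- c("solvent", "odorA", "odorB", "solvent")
    amp <- list(0, c(0.05, rep(0.01, nrow(map) - 1)),
                c(rep(0.01, nrow(map) - 1), 0.05), 0)
    trials <- lapply(seq_along(odors), function(i)
      simulate_calcium_trial(map, amp[[i]], icfg,
                             animal = "animal1", odor = odors[i],
                             solvent = odors[i] == "solvent",
                             seed = icfg$seed + i))
    resp <- process_imaging_trials(trials, map,
                                   filter_width = cfg$filter_width,
                                   max_shift = cfg$max_shift)
    net <- solvent_subtract_imaging(resp)
    tsv(net, "imaging_responses.tsv")
    list(map = map, responses = net)
  })

  # --- genotype stage --------------------------------------------------
  results$genotype <- run_stage("genotype", function() {
    odors <- sprintf("ligand%02d", 1:12)
    sim <- simulate_knockout_responses(odors, ko_odor = odors[1],
                                       seed = cfg$seed)
    tab <- compare_genotypes(sim)
    tsv(tab, "genotype.tsv")
    list(responses = sim, table = tab)
  })

  # --- mutant stage ----------------------------------------------------
  results$mutant <- run_stage("mutant", function() {
    gene <- example_or_gene()
    start <- gene$introns$end[3]
    rep_ <- knockout_report(gene, start, gene$exons$start[4] + 6L)
    jsn(list(deleted_interval = as.list(rep_$deleted_interval),
             deletion_bp = rep_$deletion_bp,
             junction_disrupted = rep_$junction_disrupted,
             skipped_exons = rep_$skipped_exons,
             mrna_deletion_bp = rep_$mrna_deletion_bp,
             wt_protein_length = rep_$wt_protein_length,
             mut_protein_length = rep_$mut_protein_length,
             aa_removed = rep_$aa_removed,
             percent_removed = rep_$percent_removed,
             in_frame = rep_$in_frame),
        "allele.json")
    rep_
  })

  writeLines(log_lines, file.path(outdir, "report.log"))
  invisible(results)
}

# evenly spaced ROI grid fitting the configured geometry
default_glomerulus_map <- function(icfg, side = 15, n = 4) {
  margin <- side  # keep ROIs and their blob tails inside the frame
  cy <- round(seq(margin + 1, icfg$height - margin, length.out = n))
  cx <- round(seq(margin + 1, icfg$width - margin, length.out = n))
  grid <- expand.grid(cy = cy, cx = cx)
  keep <- seq_len(min(nrow(grid), n * n))
  glomerulus_map(sprintf("glom%02d", keep), grid$cy[keep], grid$cx[keep],
                 side = side, height = icfg$height, width = icfg$width)
}
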