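# Readers and writers for the pipeline's on-disk formats: tab-separated
# response matrices and tidy tables (UTF-8, "." decimal, empty cell =
# missing), CSV spike tables, multi-frame TIFF movies with a JSON
# metadata sidecar, gene models as JSON (with GFF3 + FASTA export), and
# YAML run configurations.

#' Write / read a response matrix as TSV
#'
#' Units are rows (first column `unit`), odors are columns in panel
#' order; missing cells are written as empty strings and read back as
#' `NA` (missing, never zero).
#'
#' @param mat `response_matrix` (or any units x odors numeric matrix).
#' @param path Output file.
#' @return `write_response_matrix` returns `path` invisibly;
#'   `read_response_matrix` returns a `response_matrix`.
#' @export
write_response_matrix <- function(mat, path) {
  df <- data.frame(unit = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_response_matrix
#' @export
read_response_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "")
  odors <- names(df)[-1]
  if (anyDuplicated(odors))
    stop("duplicate odor columns: ",
         paste(unique(odors[duplicated(odors)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$unit
  class(m) <- c("response_matrix", class(m))
  m
}

#' Write / read an SSR session as a tidy spike CSV
#'
#' One row per spike: `trial_id`, `fly_id`, `sensillum_id`, `odor`,
#' `dilution`, `solvent`, `stimulus_onset_s`, `stimulus_duration_s`,
#' `unit`, `spike_time_s`, `amplitude`. Trials without spikes are
#' preserved as a single row with an empty `spike_time_s`.
#'
#' @param session An `ssr_session` (or plain list of `ssr_trial`s).
#' @param path Output CSV file.
#' @export
write_spike_table <- function(session, path) {
  trials <- if (inherits(session, "ssr_session")) session$trials
  else session
  rows <- lapply(trials, function(tr) {
    sp <- tr$spikes
    if (nrow(sp) == 0)
      sp <- data.frame(time = NA_real_, amplitude = NA_real_,
                       unit = NA_character_)
    data.frame(trial_id = tr$trial_id, fly_id = tr$fly,
               sensillum_id = tr$sensillum, odor = tr$odor,
               dilution = tr$dilution, solvent = tr$solvent,
               stimulus_onset_s = tr$onset,
               stimulus_duration_s = tr$duration,
               unit = sp$unit, spike_time_s = sp$time,
               amplitude = sp$amplitude, stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  trials <- lapply(split(df, factor(df$trial_id, unique(df$trial_id))),
                   function(g) {
    has_spikes <- !is.na(g$spike_time_s)
    sp <- data.frame(time = g$spike_time_s[has_spikes],
                     amplitude = g$amplitude[has_spikes],
                     unit = g$unit[has_spikes], stringsAsFactors = FALSE)
    new_ssr_trial(sp, g$stimulus_onset_s[1], g$stimulus_duration_s[1],
                  g$fly_id[1], g$sensillum_id[1], g$odor[1],
                  g$dilution[1], g$solvent[1],
                  trial_id = g$trial_id[1])
  })
  names(trials) <- NULL
  structure(list(trials = trials, truth = NULL, panel = NULL,
                 config = NULL),
            class = "ssr_session")
}

#' Write / read a movie as multi-frame TIFF with JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages scaled into `[0, 1]`;
#' the sidecar (`<path>.json`) keeps the scaling, acquisition metadata
#' and, for synthetic movies, the generator ground truth.
#'
#' @param stack A `movie_stack`. @param path TIFF output file.
#' @export
write_movie <- function(stack, path) {
  d <- stack$data
  lo <- min(d); hi <- max(d)
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(dim(d)[1]),
                   function(t) (d[t, , ] - lo) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  sidecar <- list(offset = lo, scale = scale, rate = stack$rate,
                  stim_frames = stack$stim_frames,
                  px_size = stack$px_size, meta = stack$meta,
                  truth = stack$truth)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- array(0, dim = c(length(frames), nrow(frames[[1]]),
                        ncol(frames[[1]])))
  for (t in seq_along(frames))
    d[t, , ] <- frames[[t]] * sc$scale + sc$offset
  truth <- sc$truth
  if (!is.null(truth$shift)) truth$shift <- as.integer(truth$shift)
  movie_stack(d, rate = sc$rate, stim_frames = sc$stim_frames,
              px_size = sc$px_size, meta = as.list(sc$meta),
              truth = truth)
}

#' Write / read a gene model as JSON; export GFF3 and protein FASTA
#'
#' JSON is the round-trip format (sequence plus exon coordinates). The
#' GFF3 export writes gene/exon features over the packaged sequence for
#' interchange with genome browsers.
#'
#' @param gene A [gene_model()]. @param path Output file.
#' @param name Feature name used in GFF3/FASTA headers.
#' @export
write_gene_model_json <- function(gene, path) {
  jsonlite::write_json(list(sequence = gene$sequence,
                            exons = gene$exons[, c("start", "end")]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gene_model_json
#' @export
read_gene_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gene_model(x$sequence, as.data.frame(x$exons))
}

#' @rdname write_gene_model_json
#' @export
write_gene_model_gff3 <- function(gene, path, name = "gene1") {
  glen <- nchar(gene$sequence)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", name, glen),
             sprintf("%s\tolfactr\tgene\t1\t%d\t.\t+\t.\tID=%s",
                     name, glen, name))
  for (i in seq_len(nrow(gene$exons)))
    lines <- c(lines, sprintf(
      "%s\tolfactr\texon\t%d\t%d\t.\t+\t.\tID=%s.exon%d;Parent=%s",
      name, gene$exons$start[i], gene$exons$end[i], name, i, name))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gene_model_json
#' @export
write_protein_fasta <- function(protein, path, name = "protein1") {
  chunks <- substring(protein, seq(1, nchar(protein), 60),
                      pmin(seq(1, nchar(protein), 60) + 59,
                           nchar(protein)))
  writeLines(c(paste0(">", name), chunks), path)
  invisible(path)
}

#' Run configuration
#'
#' Assembles (and round-trips through YAML) the knobs of the end-to-end
#' report pipeline. All defaults equal the pipeline's standard values:
#' response threshold 10 spikes/s, ROI side 15 px, median filter width
#' 7 px, 9999 ANOSIM permutations, 20 NMDS restarts.
#'
#' @param seed Master seed.
#' @param n_receptors,n_flies,n_odors SSR study size.
#' @param response_threshold Spikes/s threshold for a response.
#' @param roi_side,filter_width,max_shift Imaging parameters (px).
#' @param n_perm,nmds_restarts Mapping parameters.
#' @param missing_fraction Fraction of profile cells masked as missing
#'   before imputation (emulating odors lost from single recordings).
#' @param stages Character vector of stages to run, from
#'   `c("ssr", "tuning", "mapping", "imaging", "genotype", "mutant")`.
#'   The imaging stage simulates and processes full-size movies; reduce
#'   the geometry through `imaging` for quick runs.
#' @param imaging Optional sub-list overriding [sim_config()] fields for
#'   simulated movies (e.g., smaller geometry).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, n_receptors = 5, n_flies = 10,
                       n_odors = 80, response_threshold = 10,
                       roi_side = 15, filter_width = 7, max_shift = 10,
                       n_perm = 9999, nmds_restarts = 20,
                       missing_fraction = 156 / 4240,
                       stages = c("ssr", "tuning", "mapping", "imaging",
                                  "genotype", "mutant"),
                       imaging = list()) {
  cfg <- list(seed = as.integer(seed), n_receptors = n_receptors,
              n_flies = n_flies, n_odors = n_odors,
              response_threshold = response_threshold,
              roi_side = roi_side, filter_width = filter_width,
              max_shift = max_shift, n_perm = n_perm,
              nmds_restarts = nmds_restarts,
              missing_fraction = missing_fraction,
              stages = stages, imaging = imaging)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

# stable fingerprint of a configuration (md5 of its YAML serialization)
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}
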