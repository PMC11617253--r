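# Molecular model of a splice-junction-disrupting genomic deletion:
# deletion -> disrupted intron/exon junction -> exon skipping -> mutant
# transcript and protein, with the deletion arithmetic of the allele
# report. Coordinates are 1-based inclusive on the + strand.

#' Gene model
#'
#' An ordered set of exons on a genomic sequence; introns are the gaps
#' between consecutive exons. Introns are checked for the canonical GT..AG
#' boundary dinucleotides (non-canonical introns are flagged, not
#' rejected, since deletions can destroy them).
#'
#' @param sequence Genomic sequence (character, ACGT).
#' @param exons Data frame with `start`, `end` (1-based inclusive,
#'   ascending, non-overlapping).
#' @return Object of class `gene_model`: `sequence`, `exons`, `introns`
#'   (with `canonical` flag), `cds_length`.
#' @export
gene_model <- function(sequence, exons) {
  sequence <- toupper(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1,
            all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), c("start", "end")]
  if (any(exons$end < exons$start)) stop("exon end before start")
  if (any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons overlap or touch; introns must separate them")
  if (exons$start[1] < 1 || exons$end[nrow(exons)] > nchar(sequence))
    stop("exons outside the sequence")
  exons$length <- exons$end - exons$start + 1L
  n <- nrow(exons)
  introns <- if (n > 1) {
    data.frame(start = exons$end[-n] + 1L, end = exons$start[-1] - 1L)
  } else data.frame(start = integer(0), end = integer(0))
  if (nrow(introns) > 0) {
    introns$length <- introns$end - introns$start + 1L
    introns$canonical <- substring(sequence, introns$start,
                                   introns$start + 1L) == "GT" &
      substring(sequence, introns$end - 1L, introns$end) == "AG"
  } else {
    introns$length <- integer(0); introns$canonical <- logical(0)
  }
  structure(list(sequence = sequence, exons = exons, introns = introns,
                 cds_length = sum(exons$length)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %d bp genomic, %d exons (CDS %d bp%s)\n",
              nchar(x$sequence), nrow(x$exons), x$cds_length,
              if (x$cds_length %% 3 == 0) "" else ", out of frame"))
  invisible(x)
}

exon_sequences <- function(gene) {
  substring(gene$sequence, gene$exons$start, gene$exons$end)
}

#' Apply a genomic deletion to a gene model
#'
#' Removes the closed interval `[start, end]` from the genomic sequence
#' and re-threads all feature coordinates. A splice junction counts as
#' disrupted when the deletion touches its critical positions: for an
#' acceptor, the intron's final two nucleotides (AG) or the exon's first
#' nucleotide; for a donor, the exon's last nucleotide or the intron's
#' first two nucleotides (GT). Exons with a disrupted junction are
#' expected to be skipped during splicing of the mutant gene (the
#' modeling rule mirroring observed exon-skipping alleles; this is not a
#' splicing predictor).
#'
#' @param gene A [gene_model()].
#' @param start,end Deleted interval, 1-based inclusive.
#' @return List: `gene` (mutant model), `disrupted_exons` (indices in the
#'   wildtype exon numbering), `junctions` (data frame of the affected
#'   splice sites).
#' @export
apply_genomic_deletion <- function(gene, start, end) {
  stopifnot(inherits(gene, "gene_model"))
  glen <- nchar(gene$sequence)
  if (start < 1 || end > glen || end < start)
    stop("deletion interval outside the gene")
  hit <- function(pos) pos >= start & pos <= end
  n <- nrow(gene$exons)
  junctions <- list()
  disrupted <- integer(0)
  for (i in seq_len(nrow(gene$introns))) {
    intr <- gene$introns[i, ]
    # donor of exon i: exon's last nt + intron's first 2 nt (GT)
    if (any(hit(c(gene$exons$end[i], intr$start, intr$start + 1L)))) {
      junctions[[length(junctions) + 1]] <-
        data.frame(intron = i, site = "donor", exon = i)
      disrupted <- c(disrupted, i)
    }
    # acceptor of exon i+1: intron's last 2 nt (AG) + exon's first nt
    if (any(hit(c(intr$end - 1L, intr$end, gene$exons$start[i + 1L])))) {
      junctions[[length(junctions) + 1]] <-
        data.frame(intron = i, site = "acceptor", exon = i + 1L)
      disrupted <- c(disrupted, i + 1L)
    }
  }
  del_len <- end - start + 1L
  shift <- function(pos) {
    ifelse(pos < start, pos,
           ifelse(pos > end, pos - del_len, NA_integer_))
  }
  new_seq <- paste0(substring(gene$sequence, 1, start - 1),
                    substring(gene$sequence, end + 1, glen))
  new_exons <- gene$exons[, c("start", "end")]
  for (i in seq_len(n)) {
    s <- gene$exons$start[i]; e <- gene$exons$end[i]
    if (hit(s)) s <- end + 1L        # left edge deleted: shrink from left
    if (hit(e)) e <- start - 1L      # right edge deleted: shrink from right
    if (s > e) { new_exons$start[i] <- NA; new_exons$end[i] <- NA; next }
    new_exons$start[i] <- shift(s); new_exons$end[i] <- shift(e)
  }
  lost <- which(is.na(new_exons$start))
  if (length(lost) > 0) {
    disrupted <- sort(unique(c(disrupted, lost)))
    new_exons <- new_exons[-lost, , drop = FALSE]
  }
  mut <- gene_model(new_seq, new_exons)
  list(gene = mut,
       disrupted_exons = sort(unique(disrupted)),
       junctions = if (length(junctions)) do.call(rbind, junctions)
       else data.frame(intron = integer(0), site = character(0),
                       exon = integer(0)))
}

#' Splice a gene model into mRNA
#'
#' Concatenates the exon sequences in order, omitting the exons in
#' `skip`.
#'
#' @param gene A [gene_model()].
#' @param skip Integer indices of exons skipped during splicing.
#' @return mRNA sequence (character).
#' @export
splice <- function(gene, skip = integer(0)) {
  stopifnot(inherits(gene, "gene_model"))
  n <- nrow(gene$exons)
  skip <- unique(as.integer(skip))
  if (length(skip) > 0 && (min(skip) < 1 || max(skip) > n))
    stop("skip set contains exon indices outside the model")
  keep <- setdiff(seq_len(n), skip)
  if (length(keep) == 0) stop("cannot skip every exon")
  paste(exon_sequences(gene)[keep], collapse = "")
}

#' Translate a coding sequence
#'
#' Standard genetic-code translation up to (and excluding) the first stop
#' codon. The sequence is expected to start with ATG; a trailing partial
#' codon (out-of-frame transcript) is dropped and reported.
#'
#' @param mrna Coding sequence (character, ACGT).
#' @return List: `protein` (character), `length` (aa), `in_frame`
#'   (length divisible by 3), `truncated` (a stop codon occurred before
#'   the final codon), `starts_with_atg`.
#' @export
translate_cds <- function(mrna) {
  mrna <- toupper(mrna)
  n <- nchar(mrna)
  in_frame <- n %% 3 == 0
  usable <- substring(mrna, 1, n - n %% 3)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(usable),
                                           no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  protein <- if (stop_at > 0) substring(aa, 1, stop_at - 1) else aa
  list(protein = protein,
       length = nchar(protein),
       in_frame = in_frame,
       truncated = stop_at > 0 && stop_at < nchar(aa),
       starts_with_atg = substring(mrna, 1, 3) == "ATG")
}

#' Deletion arithmetic between wildtype and mutant proteins
#'
#' @param wt_protein,mut_protein Amino-acid sequences (characters); the
#'   mutant must derive from the wildtype by one internal deletion and
#'   cannot be longer.
#' @return List: `wt_length`, `mut_length`, `aa_removed`,
#'   `percent_removed` (integer percent, rounded half-up).
#' @export
deletion_summary <- function(wt_protein, mut_protein) {
  lw <- nchar(wt_protein); lm <- nchar(mut_protein)
  if (lm > lw) stop("mutant protein longer than wildtype")
  removed <- lw - lm
  list(wt_length = lw, mut_length = lm, aa_removed = removed,
       percent_removed = as.integer(round_half_up(100 * removed / lw)))
}

#' Full allele report for a splice-disrupting deletion
#'
#' Chains the molecular model: apply the genomic deletion, skip the
#' junction-disrupted exons during splicing of the mutant gene, translate
#' wildtype and mutant transcripts, and summarize the consequence.
#'
#' @param gene Wildtype [gene_model()].
#' @param start,end Deleted genomic interval (1-based inclusive).
#' @return List of class `allele_report`: deleted interval and length,
#'   `junction_disrupted`, `skipped_exons`, `mrna_deletion_bp` (wildtype
#'   mRNA length minus mutant mRNA length), wildtype and mutant protein
#'   lengths, `aa_removed`, `percent_removed`, `in_frame`.
#' @export
knockout_report <- function(gene, start, end) {
  del <- apply_genomic_deletion(gene, start, end)
  wt_mrna <- splice(gene)
  mut_mrna <- splice(del$gene, skip = del$disrupted_exons)
  wt <- translate_cds(wt_mrna)
  mut <- translate_cds(mut_mrna)
  ds <- deletion_summary(wt$protein, mut$protein)
  structure(list(
    deleted_interval = c(start = start, end = end),
    deletion_bp = end - start + 1L,
    junction_disrupted = nrow(del$junctions) > 0,
    junctions = del$junctions,
    skipped_exons = del$disrupted_exons,
    mrna_deletion_bp = nchar(wt_mrna) - nchar(mut_mrna),
    wt_protein_length = ds$wt_length,
    mut_protein_length = ds$mut_length,
    aa_removed = ds$aa_removed,
    percent_removed = ds$percent_removed,
    in_frame = mut$in_frame,
    wt_protein = wt$protein,
    mut_protein = mut$protein
  ), class = "allele_report")
}

#' @export
print.allele_report <- function(x, ...) {
  cat(sprintf(
    "allele_report: %d bp genomic deletion [%d, %d]%s\n",
    x$deletion_bp, x$deleted_interval["start"], x$deleted_interval["end"],
    if (x$junction_disrupted) ", splice junction disrupted" else ""))
  if (length(x$skipped_exons))
    cat(sprintf("  exon(s) %s skipped: %d bp missing from the mRNA\n",
                paste(x$skipped_exons, collapse = ", "),
                x$mrna_deletion_bp))
  cat(sprintf("  protein: %d -> %d aa (%d aa = %d%% removed, %s)\n",
              x$wt_protein_length, x$mut_protein_length, x$aa_removed,
              x$percent_removed,
              if (x$in_frame) "in frame" else "frameshift"))
  invisible(x)
}

#' Synthetic six-exon odorant-receptor gene model
#'
#' A packaged example emulating a moth OR gene: a 1224 bp CDS (407 amino
#' acids plus the stop codon) split over six exons, with exon 4 exactly
#' 105 bp long, so that skipping exon 4 removes 35 residues (9% of the
#' protein). All facts beyond these printed constraints (exact exon
#' boundaries, intron lengths, sequence) are synthetic.
#'
#' @param seed Seed for the random sequence content.
#' @return A [gene_model()].
#' @export
example_or_gene <- function(seed = 36) {
  simulate_gene_model(c(100L, 120L, 97L, 105L, 200L, 602L), seed = seed)
}
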