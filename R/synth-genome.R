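#' Generate a toy genome fixture with genes, peaks and footprints
#'
#' Builds a strand-balanced, non-overlapping gene set on the supplied
#' chromosomes, a random peak set (a configurable fraction marked
#' differential), transcription-factor footprint records (some planted in
#' promoters of differentially expressed genes with a fold change beyond
#' the threshold), and DEG/DSG lists. The truth record states, computed by
#' a direct quadratic interval scan at generation time, which genes carry
#' a differential peak within `flank` bp (the planted DPG set) and which
#' DEGs carry a promoter footprint passing the fold-change filter.
#'
#' All coordinates are 0-based half-open (BED convention).
#'
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @param n_genes,n_peaks number of genes / peaks.
#' @param gene_length_range,peak_length_range length ranges (bp).
#' @param frac_diff_peaks fraction of peaks marked differential.
#' @param n_deg,n_dsg sizes of the DEG / DSG lists.
#' @param motif_ids motif identifiers for footprint records.
#' @param n_footprints number of footprint records.
#' @param flank gene-proximal window half-width used for the planted DPG
#'   truth (default 5000).
#' @param prom_up,prom_down promoter window extent used for the planted
#'   footprint truth (defaults 1000/100).
#' @param fc_threshold footprint fold-change threshold used for the truth
#'   (raw-ratio scale, default 2).
#' @param seed integer seed.
#' @return List with `genes`, `peaks`, `diff_peaks`, `footprints` (data
#'   frames), `deg_ids`, `dsg_ids`, and `truth` (planted DPG genes and
#'   footprint-filtered DEGs).
#' @export
gen_genome_fixture <- function(chrom_sizes = c(chr1 = 1e6L),
                               n_genes = 50L, n_peaks = 200L,
                               gene_length_range = c(1000L, 5000L),
                               peak_length_range = c(150L, 600L),
                               frac_diff_peaks = 0.3,
                               n_deg = 15L, n_dsg = 10L,
                               motif_ids = c("CEBPA", "CEBPB", "CEBPD"),
                               n_footprints = 120L,
                               flank = 5000L, prom_up = 1000L,
                               prom_down = 100L, fc_threshold = 2,
                               seed = 1L) {
  if (is.null(names(chrom_sizes)) || any(chrom_sizes <= 0))
    stop_input("gen_genome_fixture: chrom_sizes must be a named positive vector")
  n_genes <- chk_count(n_genes, "n_genes")
  with_derived_seed(seed, "genome", {
    # distribute genes over chromosomes proportionally to length, then
    # place each gene inside its own equal-width slot so genes never
    # overlap by construction
    alloc <- stats::setNames(
      pmax(1L, round(n_genes * chrom_sizes / sum(chrom_sizes))),
      names(chrom_sizes))
    while (sum(alloc) > n_genes) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
    while (sum(alloc) < n_genes) alloc[which.min(alloc)] <- alloc[which.min(alloc)] + 1L
    genes <- list()
    gi <- 0L
    for (ch in names(chrom_sizes)) {
      ng <- alloc[[ch]]
      if (ng == 0L) next
      slot <- floor(chrom_sizes[[ch]] / ng)
      if (slot < gene_length_range[2] + 2L)
        stop_input("gen_genome_fixture: cannot place %d non-overlapping genes on %s",
                   ng, ch)
      for (j in seq_len(ng)) {
        gi <- gi + 1L
        len <- sample(gene_length_range[1]:gene_length_range[2], 1L)
        lo <- (j - 1L) * slot
        start <- as.integer(lo + sample.int(slot - len, 1L) - 1L)
        genes[[gi]] <- data.frame(
          chrom = ch, start = start, end = start + len,
          gene_id = sprintf("g%03d", gi),
          score = 0L,
          strand = sample(c("+", "-"), 1L),
          stringsAsFactors = FALSE)
      }
    }
    genes <- do.call(rbind, genes)

    peaks <- NULL
    if (n_peaks > 0L) {
      ch <- sample(names(chrom_sizes), n_peaks, replace = TRUE,
                   prob = chrom_sizes / sum(chrom_sizes))
      len <- sample(peak_length_range[1]:peak_length_range[2], n_peaks,
                    replace = TRUE)
      start <- vapply(seq_len(n_peaks), function(i)
        sample.int(chrom_sizes[[ch[i]]] - len[i], 1L) - 1L, integer(1))
      peaks <- data.frame(
        chrom = ch, start = start, end = start + len,
        name = sprintf("peak%04d", seq_len(n_peaks)),
        score = sample(100:1000, n_peaks, replace = TRUE),
        strand = ".",
        signalValue = round(stats::runif(n_peaks, 1, 30), 3),
        pValue = round(stats::runif(n_peaks, 2, 40), 3),
        qValue = round(stats::runif(n_peaks, 2, 30), 3),
        peak = as.integer(floor(len / 2)),
        stringsAsFactors = FALSE)
    }

    n_diff <- if (n_peaks > 0L) round(frac_diff_peaks * n_peaks) else 0L
    diff_peaks <- if (n_diff > 0L) {
      sel <- sort(sample.int(n_peaks, n_diff))
      dp <- peaks[sel, c("chrom", "start", "end", "name")]
      dp$log2fc <- round(stats::rnorm(n_diff, 0, 2), 3)
      dp$fdr <- signif(stats::runif(n_diff, 1e-6, 0.05), 3)
      rownames(dp) <- NULL
      dp
    } else {
      data.frame(chrom = character(), start = integer(), end = integer(),
                 name = character(), log2fc = numeric(), fdr = numeric())
    }

    deg_ids <- sort(sample(genes$gene_id, min(n_deg, n_genes)))
    dsg_ids <- sort(sample(genes$gene_id, min(n_dsg, n_genes)))

    # promoter windows (strand-aware) used both for planting footprints
    # and for the truth record
    prom <- promoter_windows(genes, up = prom_up, down = prom_down,
                             chrom_sizes = chrom_sizes)

    footprints <- NULL
    if (n_footprints > 0L) {
      # half the footprints are planted inside DEG promoters, the rest
      # are scattered at random
      n_in <- floor(n_footprints / 2)
      rows <- list()
      deg_prom <- prom[prom$gene_id %in% deg_ids, , drop = FALSE]
      for (i in seq_len(n_footprints)) {
        if (i <= n_in && nrow(deg_prom) > 0L) {
          w <- deg_prom[sample.int(nrow(deg_prom), 1L), ]
          len <- sample(8:20, 1L)
          span <- max(w$end - w$start - len, 1L)
          st <- w$start + sample.int(span, 1L) - 1L
          chrom <- w$chrom
        } else {
          chrom <- sample(names(chrom_sizes), 1L)
          len <- sample(8:20, 1L)
          st <- sample.int(chrom_sizes[[chrom]] - len, 1L) - 1L
        }
        score_a <- round(stats::runif(1, 0.1, 10), 4)
        lfc <- round(stats::rnorm(1, 0, 1.6), 4)
        rows[[i]] <- data.frame(
          motif_id = sample(motif_ids, 1L),
          chrom = chrom, start = st, end = st + len,
          score_condA = score_a,
          score_condB = round(score_a * 2^lfc, 4),
          log2fc = lfc, stringsAsFactors = FALSE)
      }
      footprints <- do.call(rbind, rows)
    } else {
      footprints <- data.frame(motif_id = character(), chrom = character(),
                               start = integer(), end = integer(),
                               score_condA = numeric(),
                               score_condB = numeric(), log2fc = numeric())
    }

    # ---- truth by direct quadratic scans ----
    overlaps <- function(a_start, a_end, b_start, b_end)
      a_start < b_end & b_start < a_end
    flank_lo <- pmax(0L, genes$start - flank)
    flank_hi <- pmin(chrom_sizes[genes$chrom], genes$end + flank)
    dpg_truth <- character(0)
    for (i in seq_len(nrow(genes))) {
      hit <- FALSE
      for (j in seq_len(nrow(diff_peaks))) {
        if (genes$chrom[i] == diff_peaks$chrom[j] &&
            overlaps(flank_lo[i], flank_hi[i],
                     diff_peaks$start[j], diff_peaks$end[j])) {
          hit <- TRUE; break
        }
      }
      if (hit) dpg_truth <- c(dpg_truth, genes$gene_id[i])
    }
    fp_truth <- character(0)
    for (g in deg_ids) {
      w <- prom[prom$gene_id == g, ]
      for (j in seq_len(nrow(footprints))) {
        if (footprints$chrom[j] == w$chrom &&
            overlaps(w$start, w$end,
                     footprints$start[j], footprints$end[j]) &&
            2^abs(footprints$log2fc[j]) > fc_threshold) {
          fp_truth <- c(fp_truth, g); break
        }
      }
    }

    list(genes = genes, peaks = peaks, diff_peaks = diff_peaks,
         footprints = footprints, deg_ids = deg_ids, dsg_ids = dsg_ids,
         chrom_sizes = chrom_sizes,
         truth = list(dpg_genes = sort(dpg_truth),
                      footprint_degs = sort(fp_truth),
                      flank = flank, prom_up = prom_up,
                      prom_down = prom_down, fc_threshold = fc_threshold,
                      seed = seed))
  })
}
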