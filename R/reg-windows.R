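# Strand-aware regulatory-window construction and peak/footprint
# intersection. All data-frame coordinates are 0-based half-open (BED
# convention); GRanges used internally are converted at the boundary.

# data frame (chrom, start, end [, strand]) -> GRanges (1-based closed)
.df_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df))
      sub("^\\.$", "*", df$strand) else "*")
}

.check_genes_df <- function(genes, chrom_sizes) {
  need <- c("chrom", "start", "end", "strand", "gene_id")
  if (!all(need %in% names(genes)))
    stop_input("genes must have columns %s", paste(need, collapse = ", "))
  unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(unknown))
    stop_input("gene(s) on unknown chromosome(s): %s",
               paste(unknown, collapse = ", "))
  invisible(TRUE)
}

#' Gene-proximal (flank) windows
#'
#' The gene body extended by `flank` bp on both sides (bedtools `slop`
#' semantics, strand-independent), clipped to the chromosome.
#'
#' @param genes data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id` (0-based half-open).
#' @param flank extension in bp (default 5000).
#' @param chrom_sizes named vector of chromosome lengths.
#' @return Data frame `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
gene_flank_windows <- function(genes, flank = 5000L, chrom_sizes) {
  .check_genes_df(genes, chrom_sizes)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0L, genes$start - as.integer(flank)),
             end = pmin(unname(chrom_sizes[genes$chrom]),
                        genes$end + as.integer(flank)),
             stringsAsFactors = FALSE)
}

#' Strand-aware promoter windows
#'
#' From `up` bp upstream to `down` bp downstream of the gene start site
#' (bedtools `flank`-style, strand-aware): `[start - up, start + down)`
#' on the + strand and `[end - down, end + up)` on the - strand, clipped
#' to the chromosome.
#'
#' @inheritParams gene_flank_windows
#' @param up,down upstream / downstream extents in bp (defaults 1000/100).
#' @return Data frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
promoter_windows <- function(genes, up = 1000L, down = 100L, chrom_sizes) {
  .check_genes_df(genes, chrom_sizes)
  up <- as.integer(up); down <- as.integer(down)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$start - up, genes$end - down)
  end <- ifelse(plus, genes$start + down, genes$end + up)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0L, start),
             end = pmin(unname(chrom_sizes[genes$chrom]), end),
             strand = genes$strand, stringsAsFactors = FALSE)
}

#' Classify differential peak-associated genes (DPGs)
#'
#' Genes whose window overlaps at least one differential peak by >= 1 bp
#' (half-open overlap: `a.start < b.end && b.start < a.end`).
#'
#' @param diff_peaks data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param gene_windows data frame from [gene_flank_windows()] (or any
#'   window table keyed by `gene_id`).
#' @return Sorted character vector of associated gene ids.
#' @export
classify_dpg <- function(diff_peaks, gene_windows) {
  if (nrow(diff_peaks) == 0L || nrow(gene_windows) == 0L)
    return(character(0))
  # suppressed warning: disjoint chromosome namespaces (e.g. peaks on a
  # chromosome without genes) are legitimate and simply do not overlap
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(.df_to_gr(gene_windows),
                                .df_to_gr(diff_peaks),
                                minoverlap = 1L, ignore.strand = TRUE))
  sort(unique(gene_windows$gene_id[S4Vectors::queryHits(hits)]))
}

#' Fraction of genes with at least one overlapping peak
#'
#' @param gene_list character vector of gene ids (must all be present in
#'   `gene_windows`).
#' @param peaks data frame with `chrom`, `start`, `end`.
#' @param gene_windows window table keyed by `gene_id`.
#' @return Fraction in \[0, 1\].
#' @export
peak_coverage_fraction <- function(gene_list, peaks, gene_windows) {
  unknown <- setdiff(gene_list, gene_windows$gene_id)
  if (length(unknown))
    stop_input("peak_coverage_fraction: unknown gene id(s): %s",
               paste(unknown, collapse = ", "))
  if (length(gene_list) == 0L) return(NA_real_)
  covered <- classify_dpg(peaks, gene_windows)
  mean(gene_list %in% covered)
}

#' Filter DEGs by promoter footprint fold change
#'
#' Returns the differentially expressed genes that carry at least one
#' footprint of any listed motif inside their promoter window with an
#' absolute fold change exceeding `fc_threshold` (strict, raw-ratio
#' scale: a log2 fold change `l` passes when `2^|l| > fc_threshold`).
#' Results are the union over motif ids (family-level filtering).
#'
#' @param deg_ids character vector of DEG ids.
#' @param footprints data frame with `motif_id`, `chrom`, `start`, `end`
#'   and either `log2fc` or `fold_change` (raw ratio).
#' @param promoter_windows window table from [promoter_windows()].
#' @param motif_ids motifs to consider; absent ids produce a warning and
#'   are skipped.
#' @param fc_threshold raw-ratio fold-change cutoff (default 2).
#' @return Sorted character vector of gene ids.
#' @export
footprint_promoter_filter <- function(deg_ids, footprints,
                                      promoter_windows, motif_ids,
                                      fc_threshold = 2) {
  if (length(deg_ids) == 0L) return(character(0))
  missing_motifs <- setdiff(motif_ids, unique(footprints$motif_id))
  if (length(missing_motifs))
    warning(sprintf("footprint_promoter_filter: motif(s) not in table: %s",
                    paste(missing_motifs, collapse = ", ")))
  motif_ids <- setdiff(motif_ids, missing_motifs)
  fp <- footprints[footprints$motif_id %in% motif_ids, , drop = FALSE]
  if ("log2fc" %in% names(fp)) {
    pass <- 2^abs(fp$log2fc) > fc_threshold
  } else if ("fold_change" %in% names(fp)) {
    r <- fp$fold_change
    pass <- pmax(r, 1 / r) > fc_threshold
  } else {
    stop_input("footprint_promoter_filter: footprints need 'log2fc' or 'fold_change'")
  }
  fp <- fp[pass, , drop = FALSE]
  if (nrow(fp) == 0L) return(character(0))
  w <- promoter_windows[promoter_windows$gene_id %in% deg_ids, ,
                        drop = FALSE]
  intersect(sort(unique(deg_ids)), classify_dpg(fp, w))
}
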