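# Readers and writers for the tabular and genomic formats the package
# consumes and produces. Genomic text formats go through rtracklayer;
# coordinates in data frames are 0-based half-open (BED convention).

#' Write / read the long-format trait table
#'
#' Columns: `individual_id`, `group`, `kind`, `temperature_c`,
#' `performance_ms`, `ramp_rate_c_per_min`.
#'
#' @param traits data frame as produced by [gen_thermal_dataset()].
#' @param path file path.
#' @return `read_trait_csv` returns the data frame.
#' @export
write_trait_csv <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trait_csv
#' @export
read_trait_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "group", "kind", "temperature_c",
            "performance_ms")
  if (!all(need %in% names(df)))
    stop_input("read_trait_csv: missing column(s) %s",
               paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Write / read a genes-by-samples count matrix as TSV
#'
#' First column `gene_id`, remaining columns one per sample.
#'
#' @param counts integer matrix with row and column names.
#' @param path file path.
#' @return `read_counts_tsv` returns the integer matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read BED6 gene records
#'
#' @param genes data frame with `chrom`, `start`, `end`, `gene_id`,
#'   `score`, `strand` (0-based half-open).
#' @param path file path.
#' @return `read_bed6` returns such a data frame.
#' @export
write_bed6 <- function(genes, path) {
  utils::write.table(
    genes[, c("chrom", "start", "end", "gene_id", "score", "strand")],
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             gene_id = gr$name,
             score = if (!is.null(gr$score)) gr$score else 0L,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write / read gene records as GFF3
#'
#' Written as `gene` features with `ID` attributes; GFF3 1-based closed
#' coordinates are converted to/from the package's 0-based half-open
#' convention on the way through.
#'
#' @inheritParams write_bed6
#' @export
write_gff3 <- function(genes, path) {
  gr <- .df_to_gr(genes)
  gr$ID <- genes$gene_id
  gr$type <- "gene"
  gr$source <- "thermoplast"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             gene_id = gr$ID,
             score = 0L,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

.narrowpeak_cols <- c("chrom", "start", "end", "name", "score", "strand",
                      "signalValue", "pValue", "qValue", "peak")

#' Write / read ENCODE narrowPeak (BED6+4) records
#'
#' @param peaks data frame with the ten narrowPeak columns (0-based
#'   half-open).
#' @param path file path.
#' @return `read_narrowpeak` returns such a data frame.
#' @export
write_narrowpeak <- function(peaks, path) {
  utils::write.table(peaks[, .narrowpeak_cols], path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_narrowpeak
#' @export
read_narrowpeak <- function(path) {
  gr <- rtracklayer::import(
    path, format = "BED",
    extraCols = c(signalValue = "numeric", pValue = "numeric",
                  qValue = "numeric", peak = "integer"))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = gr$name, score = gr$score,
             strand = ".",
             signalValue = gr$signalValue, pValue = gr$pValue,
             qValue = gr$qValue, peak = gr$peak,
             stringsAsFactors = FALSE)
}

#' Write / read a footprint score table
#'
#' Tab-separated with columns `motif_id`, `chrom`, `start`, `end`,
#' `score_condA`, `score_condB`, `log2fc`.
#'
#' @param footprints data frame.
#' @param path file path.
#' @export
write_footprints_tsv <- function(footprints, path) {
  utils::write.table(footprints, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_footprints_tsv
#' @export
read_footprints_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("motif_id", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop_input("read_footprints_tsv: missing column(s) %s",
               paste(setdiff(need, names(df)), collapse = ", "))
  df
}
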