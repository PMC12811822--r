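chr <- c(chr1 = 1000000L)
genes_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), strand = r[[4]],
               gene_id = r[[5]], stringsAsFactors = FALSE)))
}

test_that("flank windows extend the gene body and clip at chromosome edges", {
  g <- genes_df(list("chr1", 10000, 12000, "+", "gA"),
                list("chr1", 2000, 3000, "-", "gB"),
                list("chr1", 997000, 999000, "+", "gC"))
  w <- gene_flank_windows(g, flank = 5000, chrom_sizes = chr)
  expect_equal(w$start, c(5000, 0, 992000))
  expect_equal(w$end, c(17000, 8000, 1000000))
  # strand reversal leaves flank windows unchanged
  g2 <- g; g2$strand <- ifelse(g$strand == "+", "-", "+")
  expect_equal(gene_flank_windows(g2, 5000, chr)[, c("start", "end")],
               w[, c("start", "end")])
  expect_error(gene_flank_windows(
    genes_df(list("chrX", 1, 10, "+", "gX")), 5000, chr), "chrX")
})

test_that("promoter windows are strand-aware and mirror under strand flip", {
  g <- genes_df(list("chr1", 50000, 60000, "+", "gA"),
                list("chr1", 30000, 40000, "-", "gB"),
                list("chr1", 500, 5000, "+", "gC"))
  w <- promoter_windows(g, up = 1000, down = 100, chrom_sizes = chr)
  expect_equal(w$start[w$gene_id == "gA"], 49000)
  expect_equal(w$end[w$gene_id == "gA"], 50100)
  expect_equal(w$start[w$gene_id == "gB"], 39900)
  expect_equal(w$end[w$gene_id == "gB"], 41000)
  expect_equal(w$start[w$gene_id == "gC"], 0)  # left clip
  # flipping a + gene makes the window sit at its other end
  gf <- g; gf$strand[1] <- "-"
  wf <- promoter_windows(gf, 1000, 100, chr)
  expect_equal(wf$start[wf$gene_id == "gA"], 59900)
  expect_equal(wf$end[wf$gene_id == "gA"], 61000)
})

test_that("DPG classification uses strict half-open overlap semantics", {
  w <- data.frame(gene_id = "gA", chrom = "chr1", start = 1000L,
                  end = 2000L)
  abut <- data.frame(chrom = "chr1", start = 2000L, end = 2100L)
  expect_identical(classify_dpg(abut, w), character(0))
  leftabut <- data.frame(chrom = "chr1", start = 900L, end = 1000L)
  expect_identical(classify_dpg(leftabut, w), character(0))
  onebp <- data.frame(chrom = "chr1", start = 1999L, end = 2100L)
  expect_identical(classify_dpg(onebp, w), "gA")
  other_chrom <- data.frame(chrom = "chr2", start = 1500L, end = 1600L)
  expect_identical(classify_dpg(other_chrom, w), character(0))
  expect_identical(classify_dpg(abut[0, ], w), character(0))
})

test_that("window overlap equals a brute-force quadratic scan on random fixtures", {
  for (s in 1:5) {
    g <- gen_genome_fixture(chrom_sizes = c(chr1 = 4e5L, chr2 = 3e5L),
                            n_genes = 30, n_peaks = 120, seed = s)
    w <- gene_flank_windows(g$genes, 5000, g$chrom_sizes)
    expect_identical(classify_dpg(g$diff_peaks, w),
                     brute_overlap_genes(w, g$diff_peaks))
    expect_identical(classify_dpg(g$peaks, w),
                     brute_overlap_genes(w, g$peaks))
    # coverage fraction equals the brute-force count
    brute_frac <- mean(g$deg_ids %in% brute_overlap_genes(w, g$peaks))
    expect_equal(peak_coverage_fraction(g$deg_ids, g$peaks, w),
                 brute_frac)
  }
})

test_that("coverage fraction handles empty peak sets and unknown genes", {
  g <- gen_genome_fixture(seed = 2)
  w <- gene_flank_windows(g$genes, 5000, g$chrom_sizes)
  empty <- g$peaks[0, ]
  expect_equal(peak_coverage_fraction(g$deg_ids, empty, w), 0)
  body_peaks <- data.frame(chrom = g$genes$chrom,
                           start = g$genes$start,
                           end = g$genes$end)
  expect_equal(peak_coverage_fraction(g$genes$gene_id, body_peaks, w), 1)
  expect_error(peak_coverage_fraction("nope", g$peaks, w), "nope")
})

test_that("footprint filtering applies the strict fold-change rule per scale", {
  g <- genes_df(list("chr1", 50000, 60000, "+", "gA"),
                list("chr1", 80000, 90000, "+", "gB"))
  pr <- promoter_windows(g, 1000, 100, chr)
  fp <- data.frame(
    motif_id = c("CEBPA", "CEBPA", "CEBPB", "CEBPA"),
    chrom = "chr1",
    start = c(49500L, 79500L, 49600L, 200000L),
    end = c(49520L, 79520L, 79620L, 200020L),
    log2fc = c(1.3, log2(2), -1.5, 3))  # gA passes; gB exactly 2 fails
  got <- footprint_promoter_filter(c("gA", "gB"), fp, pr, "CEBPA")
  expect_identical(got, "gA")
  # raw-ratio input: downregulation 1/r beyond the threshold passes
  fp2 <- data.frame(motif_id = "CEBPA", chrom = "chr1", start = 79500L,
                    end = 79520L, fold_change = 0.4)
  expect_identical(
    footprint_promoter_filter(c("gA", "gB"), fp2, pr, "CEBPA"), "gB")
  # empty DEG list, missing motif
  expect_identical(footprint_promoter_filter(character(0), fp, pr,
                                             "CEBPA"), character(0))
  expect_warning(
    none <- footprint_promoter_filter("gA", fp, pr, c("CEBPA", "NOPE")),
    "NOPE")
  expect_identical(none, "gA")
})

test_that("planted footprint truth is recovered from the generated fixture", {
  for (s in c(3, 8)) {
    g <- gen_genome_fixture(seed = s)
    pr <- promoter_windows(g$genes, g$truth$prom_up, g$truth$prom_down,
                           g$chrom_sizes)
    got <- footprint_promoter_filter(g$deg_ids, g$footprints, pr,
                                     unique(g$footprints$motif_id),
                                     fc_threshold = g$truth$fc_threshold)
    expect_identical(got, g$truth$footprint_degs)
  }
})

test_that("0-based half-open coordinates survive the 1-based closed round trip", {
  g <- gen_genome_fixture(seed = 5)
  gr <- thermoplast:::.df_to_gr(g$genes)
  expect_equal(GenomicRanges::start(gr), g$genes$start + 1L)
  expect_equal(GenomicRanges::end(gr), g$genes$end)
  back <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr))
  expect_equal(back$start, g$genes$start)
  expect_equal(back$end, g$genes$end)
  expect_equal(GenomicRanges::width(gr), g$genes$end - g$genes$start)
})
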