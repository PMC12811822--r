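# shared fixture builders; everything is generated in code at test time

small_thermal <- function(seed = 7, n_ind = 8, groups = 1) {
  pops <- list(tpc_params(6.5, 42.5, 0.786, 0.09, 0.886),
               tpc_params(8.0, 44.5, 0.918, 0.09, 0.761))[seq_len(groups)]
  gen_thermal_dataset(synth_thermal_config(
    n_groups = groups, n_individuals_per_group = n_ind,
    pop_params_per_group = pops, seed = seed))
}

small_expression <- function(seed = 3, ...) {
  gen_expression_dataset(synth_expr_config(seed = seed, ...))
}

# expression matrix with three planted modules among the most variable
# genes, plus the planted truth restricted to it
module_fixture <- function(seed = 3, top_n = 800, ...) {
  d <- small_expression(seed = seed, ...)
  expr <- top_variable(filter_and_transform(d$counts), top_n)
  list(expr = expr, truth = d$truth$module[rownames(expr)],
       samples = d$samples, full = d)
}

# brute-force quadratic interval scan (0-based half-open)
brute_overlap_genes <- function(windows, peaks) {
  hits <- character(0)
  for (i in seq_len(nrow(windows))) {
    for (j in seq_len(nrow(peaks))) {
      if (windows$chrom[i] == peaks$chrom[j] &&
          windows$start[i] < peaks$end[j] &&
          peaks$start[j] < windows$end[i]) {
        hits <- c(hits, windows$gene_id[i])
        break
      }
    }
  }
  sort(unique(hits))
}

adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  # contingency-based fallback
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
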