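#' Configuration for the synthetic expression generator
#'
#' Describes a two-group RNA-seq experiment with planted co-expression
#' modules: genes in a module share a latent factor (pairwise latent
#' correlation `within_module_corr`), and the first module's factor mean is
#' shifted by `module_group_effect` (latent SD units) in the second group,
#' making it trait-associated.
#'
#' @param n_genes total genes.
#' @param n_samples_per_group samples in each of the two groups.
#' @param module_sizes integer vector, one entry per planted module; the
#'   remaining genes are independent background.
#' @param module_group_effect latent mean shift of module 1 in group 2.
#' @param within_module_corr target pairwise latent correlation in \[0, 1).
#' @param module_var_boost scale factor applied to module-gene latent
#'   variation (default 2): planted modules are more variable than
#'   background genes, as trait-responsive modules are in real data, so
#'   they survive variance-based gene selection. Pairwise within-module
#'   correlation is unaffected.
#' @param library_size mean total counts per sample.
#' @param dispersion negative-binomial dispersion (1/size); 0 gives
#'   Poisson counts.
#' @param seed integer seed.
#' @return A list of class `synth_expr_config`.
#' @export
synth_expr_config <- function(n_genes = 2000L, n_samples_per_group = 12L,
                              module_sizes = c(100L, 100L, 100L),
                              module_group_effect = 2,
                              within_module_corr = 0.8,
                              module_var_boost = 2,
                              library_size = 2e6, dispersion = 0,
                              seed = 1L) {
  n_genes <- chk_count(n_genes, "n_genes")
  n_spg <- chk_count(n_samples_per_group, "n_samples_per_group", min = 2L)
  if (sum(module_sizes) > n_genes)
    stop_input("configuration error: 'module_sizes' sum exceeds n_genes")
  if (any(module_sizes < 2L))
    stop_input("configuration error: each module needs >= 2 genes")
  if (within_module_corr < 0 || within_module_corr >= 1)
    stop_input("configuration error: 'within_module_corr' must be in [0, 1)")
  if (dispersion < 0)
    stop_input("configuration error: 'dispersion' must be >= 0")
  if (module_var_boost <= 0)
    stop_input("configuration error: 'module_var_boost' must be > 0")
  structure(list(n_genes = n_genes, n_samples_per_group = n_spg,
                 n_modules = length(module_sizes),
                 module_sizes = as.integer(module_sizes),
                 module_group_effect = as.numeric(module_group_effect),
                 within_module_corr = as.numeric(within_module_corr),
                 module_var_boost = as.numeric(module_var_boost),
                 library_size = as.numeric(library_size),
                 dispersion = as.numeric(dispersion),
                 seed = as.integer(seed)),
            class = "synth_expr_config")
}

#' Generate a synthetic count matrix with planted modules
#'
#' Latent structure: module factor f_m ~ N(0, 1) per sample; gene g in
#' module m has latent `sqrt(rho) * f_m + sqrt(1 - rho) * noise`, giving
#' pairwise latent correlation rho; background genes are independent
#' N(0, 1). Counts are sampled Poisson (or negative-binomial) around
#' `baseline_g * exp(0.7 * latent)`, column-scaled to the target library
#' size. Module 1's factor mean is shifted by `module_group_effect` in
#' group "G2".
#'
#' @param cfg a [synth_expr_config()].
#' @return List with `counts` (genes x samples integer matrix), `samples`
#'   (data frame sample_id, group), `truth` (module labels, latent matrix,
#'   config echo).
#' @export
gen_expression_dataset <- function(cfg) {
  if (!inherits(cfg, "synth_expr_config"))
    stop_input("gen_expression_dataset: cfg must be a synth_expr_config")
  with_derived_seed(cfg$seed, "expression", {
    n_s <- 2L * cfg$n_samples_per_group
    group <- rep(c("G1", "G2"), each = cfg$n_samples_per_group)
    sample_id <- sprintf("%s_s%02d", group,
                         c(seq_len(cfg$n_samples_per_group),
                           seq_len(cfg$n_samples_per_group)))
    gene_id <- sprintf("gene%04d", seq_len(cfg$n_genes))
    module <- rep("unassigned", cfg$n_genes)
    idx <- 1L
    for (m in seq_len(cfg$n_modules)) {
      module[idx:(idx + cfg$module_sizes[m] - 1L)] <- paste0("planted", m)
      idx <- idx + cfg$module_sizes[m]
    }

    rho <- cfg$within_module_corr
    latent <- matrix(stats::rnorm(cfg$n_genes * n_s), cfg$n_genes, n_s,
                     dimnames = list(gene_id, sample_id))
    for (m in seq_len(cfg$n_modules)) {
      f <- stats::rnorm(n_s)
      if (m == 1L)
        f <- f + cfg$module_group_effect * (group == "G2")
      sel <- module == paste0("planted", m)
      latent[sel, ] <- cfg$module_var_boost *
        (sqrt(rho) * matrix(f, sum(sel), n_s, byrow = TRUE) +
           sqrt(1 - rho) * latent[sel, ])
    }

    # lognormal baselines span silent to highly expressed genes
    baseline <- exp(stats::rnorm(cfg$n_genes, log(50), 2.0))
    mu <- baseline * exp(0.7 * latent)
    mu <- sweep(mu, 2, colSums(mu), "/") * cfg$library_size
    counts <- if (cfg$dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / cfg$dispersion),
             nrow(mu), ncol(mu))
    } else {
      matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    }
    dimnames(counts) <- dimnames(mu)

    list(counts = counts,
         samples = data.frame(sample_id = sample_id, group = group,
                              stringsAsFactors = FALSE),
         truth = list(module = stats::setNames(module, gene_id),
                      latent = latent, config = cfg))
  })
}
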