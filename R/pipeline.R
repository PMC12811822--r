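# Orchestration: validated configuration, staged execution, reproducible
# end-to-end runs on synthetic or user data.

# allowed configuration keys (nested); unknown keys are rejected by name
.config_schema <- list(
  seed = NULL, out_dir = NULL, stages = NULL,
  thermal = c("n_groups", "n_individuals_per_group", "sd_obs",
              "test_temperatures"),
  expression = c("n_genes", "n_samples_per_group", "module_sizes",
                 "module_group_effect", "within_module_corr",
                 "library_size", "dispersion"),
  genome = c("n_genes", "n_peaks", "chrom_size", "n_deg", "n_dsg",
             "n_footprints"),
  tpc = c("n_chains", "n_warmup", "n_sampling"),
  perm = c("m"),
  coexpr = c("cpm_min", "min_frac", "top_n", "powers", "r2_target",
             "min_size", "merge_height", "n_boot", "height_cutoff"),
  windows = c("flank", "prom_up", "prom_down", "fc_threshold")
)

.all_stages <- c("simulate", "tpc", "perm", "coexpr", "windows")

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list; rejects unknown keys by
#' name and fills defaults.
#'
#' @param config path to a YAML file, or a list.
#' @return The completed configuration list.
#' @export
load_run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_input("config must be a list or YAML path")
  unknown <- setdiff(names(config), names(.config_schema))
  if (length(unknown))
    stop_input("config error: unknown key(s): %s",
               paste(unknown, collapse = ", "))
  for (blk in intersect(names(config), names(.config_schema))) {
    allowed <- .config_schema[[blk]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[blk]]), allowed)
    if (length(bad))
      stop_input("config error: unknown key(s) in '%s': %s", blk,
                 paste(bad, collapse = ", "))
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% file.path(tempdir(), "thermoplast_run")
  config$stages <- config$stages %||% .all_stages
  bad_stage <- setdiff(config$stages, .all_stages)
  if (length(bad_stage))
    stop_input("config error: unknown stage(s): %s",
               paste(bad_stage, collapse = ", "))
  config
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the selected stages in dependency order (`simulate` first,
#' then `tpc`, `perm`, `coexpr`, `windows`), with every stage's
#' randomness derived from the global seed, so identical configurations
#' produce byte-identical outputs. A failed stage is recorded and its
#' dependent stages are skipped.
#'
#' @param config path to a YAML config or a list (see
#'   [load_run_config()]).
#' @return List of class `run_report`: `report` (one row per executed
#'   stage: status, seconds, outputs, warnings), `digests` (md5 per
#'   output file), `results` (in-memory stage results).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  report <- list(); results <- list(); outputs <- character(0)
  failed <- character(0)

  run_stage <- function(name, deps, fun) {
    if (!(name %in% cfg$stages)) return()
    if (length(intersect(deps, failed))) {
      report[[name]] <<- data.frame(
        stage = name, status = "skipped", seconds = 0,
        n_outputs = 0L,
        warnings = sprintf("dependency failed: %s",
                           paste(intersect(deps, failed), collapse = ",")),
        stringsAsFactors = FALSE)
      return()
    }
    t0 <- Sys.time()
    warns <- character(0)
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) structure(list(msg = conditionMessage(e)),
                                                    class = "stage_error")),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    secs <- as.numeric(Sys.time() - t0, units = "secs")
    if (inherits(res, "stage_error")) {
      failed <<- c(failed, name)
      report[[name]] <<- data.frame(
        stage = name, status = "failed", seconds = round(secs, 2),
        n_outputs = 0L, warnings = res$msg, stringsAsFactors = FALSE)
    } else {
      results[[name]] <<- res$value
      outputs <<- c(outputs, res$files)
      report[[name]] <<- data.frame(
        stage = name, status = "ok", seconds = round(secs, 2),
        n_outputs = length(res$files),
        warnings = paste(warns, collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }

  out <- function(...) file.path(cfg$out_dir, ...)

  run_stage("simulate", character(0), function() {
    th <- do.call(synth_thermal_config,
                  c(cfg$thermal %||% list(),
                    list(seed = derive_seed(seed, "thermal"))))
    thermal <- gen_thermal_dataset(th)
    ex <- do.call(synth_expr_config,
                  c(cfg$expression %||% list(),
                    list(seed = derive_seed(seed, "expression"))))
    expression <- gen_expression_dataset(ex)
    gn_args <- cfg$genome %||% list()
    if (!is.null(gn_args$chrom_size)) {
      gn_args$chrom_sizes <- c(chr1 = as.integer(gn_args$chrom_size))
      gn_args$chrom_size <- NULL
    }
    genome <- do.call(gen_genome_fixture,
                      c(gn_args, list(seed = derive_seed(seed, "genome"))))
    files <- c(
      write_trait_csv(thermal$traits, out("traits.csv")),
      write_counts_tsv(expression$counts, out("counts.tsv")),
      { utils::write.csv(expression$samples, out("samples.csv"),
                         row.names = FALSE, quote = FALSE)
        out("samples.csv") },
      write_bed6(genome$genes, out("genes.bed")),
      write_gff3(genome$genes, out("genes.gff3")),
      write_narrowpeak(genome$peaks, out("peaks.narrowPeak")),
      { utils::write.table(genome$diff_peaks, out("diff_peaks.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        out("diff_peaks.tsv") },
      write_footprints_tsv(genome$footprints, out("footprints.tsv")),
      { writeLines(genome$deg_ids, out("deg_ids.txt")); out("deg_ids.txt") },
      { writeLines(genome$dsg_ids, out("dsg_ids.txt")); out("dsg_ids.txt") },
      { jsonlite::write_json(
          list(thermal_population = thermal$truth$population,
               expression_modules = as.list(table(expression$truth$module)),
               genome = genome$truth),
          out("truth.json"), auto_unbox = TRUE, digits = NA)
        out("truth.json") })
    list(value = list(thermal = thermal, expression = expression,
                      genome = genome), files = files)
  })

  run_stage("tpc", "simulate", function() {
    sim <- results$simulate
    tp <- cfg$tpc %||% list()
    traits <- sim$thermal$traits
    files <- character(0)
    fits <- list()
    for (g in sort(unique(traits$group))) {
      tr <- traits[traits$group == g, ]
      fit <- fit_hierarchical_tpc(
        tr,
        n_chains = tp$n_chains %||% 4L,
        n_warmup = tp$n_warmup %||% 1000L,
        n_sampling = tp$n_sampling %||% 1000L,
        seed = derive_seed(seed, paste0("tpc-", g)))
      summ <- summarise_tpc_fit(fit)
      bands <- posterior_curve_bands(fit, seq(5, 46, by = 0.5))
      f1 <- out(sprintf("tpc_summary_%s.json", g))
      jsonlite::write_json(
        list(group = g, summary = summ,
             max_rhat = max(fit$diagnostics$rhat, na.rm = TRUE),
             min_ess = min(fit$diagnostics$ess, na.rm = TRUE),
             converged = fit$converged,
             divergences = fit$divergences),
        f1, auto_unbox = TRUE, digits = 10, dataframe = "rows")
      f2 <- out(sprintf("tpc_bands_%s.csv", g))
      utils::write.csv(bands, f2, row.names = FALSE)
      fits[[g]] <- fit
      files <- c(files, f1, f2)
    }
    list(value = fits, files = files)
  })

  run_stage("perm", "simulate", function() {
    sim <- results$simulate
    m <- (cfg$perm %||% list())$m %||% 50000L
    traits <- sim$thermal$traits
    pseed <- derive_seed(seed, "perm")
    ct <- traits[traits$kind == "ctmin_anchor", ]
    ancova <- perm_ancova(ct$temperature_c, ct$group,
                          ct$ramp_rate_c_per_min, m = m, seed = pseed)
    sp_dat <- traits[traits$kind == "sprint", ]
    sp <- perm_splitplot(sp_dat$performance_ms, sp_dat$individual_id,
                         sp_dat$group, sp_dat$temperature_c, m = m,
                         seed = pseed)
    ph <- posthoc_simple_effects(sp_dat$performance_ms,
                                 sp_dat$individual_id, sp_dat$group,
                                 sp_dat$temperature_c, m = m, seed = pseed)
    strip <- function(r) r[c("statistic", "df_num", "df_den", "n_perm",
                             "exceed_count", "p_est", "p_floor",
                             "below_floor", "seed")]
    f <- out("perm_report.json")
    jsonlite::write_json(
      list(ctmin_ancova = strip(ancova),
           sprint_splitplot = lapply(
             sp[c("between", "within", "interaction")], strip),
           sprint_posthoc = ph),
      f, auto_unbox = TRUE, digits = 10, dataframe = "rows")
    list(value = list(ancova = ancova, splitplot = sp, posthoc = ph),
         files = f)
  })

  run_stage("coexpr", "simulate", function() {
    sim <- results$simulate
    cx <- cfg$coexpr %||% list()
    counts <- sim$expression$counts
    samples <- sim$expression$samples
    expr <- filter_and_transform(counts, cpm_min = cx$cpm_min %||% 1,
                                 min_frac = cx$min_frac %||% 0.2)
    if (!is.null(cx$height_cutoff))
      expr <- remove_outlier_samples(expr, cx$height_cutoff)
    expr <- top_variable(expr, n = cx$top_n %||% 5000L)
    sp <- pick_soft_power(expr, powers = cx$powers %||% 1:20,
                          r2_target = cx$r2_target %||% 0.80)
    assign <- detect_modules(expr, sp$power,
                             min_size = cx$min_size %||% 30L,
                             merge_height = cx$merge_height %||% 0.25)
    me <- module_eigengenes(expr, assign)
    km <- kme(expr, me)
    groups <- samples$group[match(colnames(expr), samples$sample_id)]
    mt <- module_trait(me, groups)
    hubs <- hub_genes(km, assign)
    stab <- bootstrap_stability(expr, assign,
                                n_boot = cx$n_boot %||% 50L,
                                seed = derive_seed(seed, "coexpr-boot"))
    files <- c(
      { utils::write.table(
          data.frame(gene_id = names(assign), module = assign),
          out("modules.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
        out("modules.tsv") },
      { utils::write.table(
          data.frame(module = rownames(me), me, check.names = FALSE),
          out("eigengenes.tsv"), sep = "\t", row.names = FALSE,
          quote = FALSE)
        out("eigengenes.tsv") },
      { utils::write.csv(mt, out("module_trait.csv"), row.names = FALSE)
        out("module_trait.csv") },
      { jsonlite::write_json(
          list(soft_power = sp$power, reached_target = sp$reached_target,
               stability_score = stab$score, n_boot = stab$n_boot,
               hubs = hubs),
          out("coexpr_summary.json"), auto_unbox = TRUE, digits = 10)
        out("coexpr_summary.json") })
    list(value = list(expr = expr, power = sp, assignment = assign,
                      eigengenes = me, kme = km, module_trait = mt,
                      hubs = hubs, stability = stab),
         files = files)
  })

  run_stage("windows", "simulate", function() {
    sim <- results$simulate
    wd <- cfg$windows %||% list()
    gn <- sim$genome
    flanks <- gene_flank_windows(gn$genes, flank = wd$flank %||% 5000L,
                                 chrom_sizes = gn$chrom_sizes)
    proms <- promoter_windows(gn$genes, up = wd$prom_up %||% 1000L,
                              down = wd$prom_down %||% 100L,
                              chrom_sizes = gn$chrom_sizes)
    dpg <- classify_dpg(gn$diff_peaks, flanks)
    cov_deg <- peak_coverage_fraction(gn$deg_ids, gn$peaks, flanks)
    fp_degs <- footprint_promoter_filter(
      gn$deg_ids, gn$footprints, proms,
      motif_ids = unique(gn$footprints$motif_id),
      fc_threshold = wd$fc_threshold %||% 2)
    f <- out("windows_summary.json")
    jsonlite::write_json(
      list(n_dpg = length(dpg), dpg_genes = dpg,
           deg_peak_coverage = cov_deg,
           footprint_filtered_degs = fp_degs),
      f, auto_unbox = TRUE, digits = 10)
    list(value = list(flanks = flanks, promoters = proms, dpg = dpg,
                      coverage = cov_deg, footprint_degs = fp_degs),
         files = f)
  })

  report_df <- do.call(rbind, report)
  rownames(report_df) <- NULL
  digests <- tools::md5sum(outputs)
  structure(list(report = report_df, digests = digests,
                 results = results, config = cfg),
            class = "run_report")
}

#' Validate input files against their declared formats
#'
#' @param paths character vector of file paths.
#' @param formats matching vector of formats: `"bed6"`, `"narrowpeak"`,
#'   `"gff3"`, `"trait_csv"`, `"counts_tsv"`, `"footprint_tsv"`.
#' @return Data frame: `file`, `format`, `pass`, `message` (first
#'   offending line where applicable).
#' @export
validate_inputs <- function(paths, formats) {
  stopifnot(length(paths) == length(formats))
  check_one <- function(path, format) {
    if (!file.exists(path)) return("file does not exist")
    tryCatch({
      switch(
        format,
        bed6 = {
          ln <- readLines(path)
          ln <- ln[nzchar(ln)]
          for (i in seq_along(ln)) {
            f <- strsplit(ln[i], "\t")[[1]]
            if (length(f) < 6L)
              return(sprintf("line %d: %d columns (6 required)", i,
                             length(f)))
            s <- suppressWarnings(as.numeric(f[2]))
            e <- suppressWarnings(as.numeric(f[3]))
            if (is.na(s) || is.na(e) || s >= e)
              return(sprintf("line %d: invalid interval [%s, %s)", i,
                             f[2], f[3]))
          }
          NA_character_
        },
        narrowpeak = {
          ln <- readLines(path)
          ln <- ln[nzchar(ln)]
          for (i in seq_along(ln)) {
            f <- strsplit(ln[i], "\t")[[1]]
            if (length(f) != 10L)
              return(sprintf("line %d: %d columns (10 required)", i,
                             length(f)))
            s <- suppressWarnings(as.numeric(f[2]))
            e <- suppressWarnings(as.numeric(f[3]))
            if (is.na(s) || is.na(e) || s >= e)
              return(sprintf("line %d: invalid interval [%s, %s)", i,
                             f[2], f[3]))
          }
          NA_character_
        },
        gff3 = { read_gff3(path); NA_character_ },
        trait_csv = { read_trait_csv(path); NA_character_ },
        counts_tsv = {
          m <- read_counts_tsv(path)
          if (any(is.na(m)) || any(m < 0))
            return("negative or missing counts")
          NA_character_
        },
        footprint_tsv = { read_footprints_tsv(path); NA_character_ },
        sprintf("unknown format '%s'", format))
    }, error = function(e) conditionMessage(e))
  }
  msg <- mapply(check_one, paths, formats)
  data.frame(file = paths, format = formats,
             pass = is.na(msg),
             message = unname(msg), stringsAsFactors = FALSE,
             row.names = NULL)
}
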