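# Signed co-expression network statistics: biweight midcorrelation,
# soft-power selection by scale-free fit, topological-overlap modules,
# eigengenes, kME, module-trait association and bootstrap stability.

# biweight-midcorrelation standardisation of one vector: returns the
# weighted, centred vector scaled to unit norm; falls back to Pearson
# standardisation (with a warning) when the MAD is zero
.bicor_std <- function(x, warn = TRUE) {
  med <- stats::median(x)
  madx <- stats::mad(x, constant = 1)
  if (madx == 0) {
    if (warn)
      warning("bicor: zero MAD, falling back to Pearson for this vector",
              call. = FALSE)
    xc <- x - mean(x)
    nrm <- sqrt(sum(xc^2))
    if (nrm == 0)
      stop_input("bicor: undefined correlation (constant vector)")
    return(xc / nrm)
  }
  u <- (x - med) / (9 * madx)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xt <- (x - med) * w
  nrm <- sqrt(sum(xt^2))
  if (nrm == 0)
    stop_input("bicor: zero weighted norm")
  xt / nrm
}

#' Biweight midcorrelation
#'
#' Robust correlation based on median/MAD biweights: observations further
#' than 9 MADs from the median get zero weight. Values in \[-1, 1\];
#' invariant to increasing affine transforms of either argument. Falls
#' back to Pearson (with a warning) for a vector with zero MAD.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Scalar correlation.
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_input("bicor: x and y must have equal length >= 3")
  sum(.bicor_std(x) * .bicor_std(y))
}

# rows of X are variables; returns matrix with bicor-standardised rows
.bicor_std_rows <- function(X, warn = TRUE) {
  out <- t(apply(X, 1, .bicor_std, warn = warn))
  dimnames(out) <- dimnames(X)
  out
}

# all pairwise bicor between rows of X and rows of Y
bicor_matrix <- function(X, Y = X, warn = TRUE) {
  tcrossprod(.bicor_std_rows(X, warn), .bicor_std_rows(Y, warn))
}

#' Select the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the signed adjacency
#' `((1 + cor) / 2)^power` (Pearson correlation at this step) gives
#' connectivities `k`; the scale-free fit R^2 is the squared Pearson
#' correlation of log10 frequency versus log10 mean connectivity over 10
#' connectivity bins. The lowest power with R^2 above `r2_target` is
#' returned; if none reaches it, the power with maximal R^2 is returned
#' with a warning flag.
#'
#' @param expr genes x samples matrix (>= 50 genes).
#' @param powers candidate powers.
#' @param r2_target required fit (default 0.80).
#' @param n_bins connectivity bins for the fit (default 10).
#' @return List with `power`, `fit` (data frame power/r2/mean_k),
#'   `reached_target`.
#' @export
pick_soft_power <- function(expr, powers = 1:20, r2_target = 0.80,
                            n_bins = 10L) {
  if (nrow(expr) < 50L)
    stop_input("pick_soft_power: need >= 50 genes")
  cmat <- stats::cor(t(expr))
  sim <- (1 + cmat) / 2
  diag(sim) <- 0
  r2 <- mk <- rep(NA_real_, length(powers))
  for (i in seq_along(powers)) {
    k <- rowSums(sim^powers[i])
    mk[i] <- mean(k)
    r2[i] <- scale_free_r2(k, n_bins)
  }
  fit <- data.frame(power = powers, r2 = r2, mean_k = mk)
  hit <- which(!is.na(r2) & r2 > r2_target)
  if (length(hit)) {
    list(power = powers[hit[1]], fit = fit, reached_target = TRUE)
  } else {
    warning(sprintf(
      "pick_soft_power: no power reached R^2 > %.2f; using the best (R^2 = %.2f)",
      r2_target, max(r2, na.rm = TRUE)), call. = FALSE)
    list(power = powers[which.max(r2)], fit = fit, reached_target = FALSE)
  }
}

#' Scale-free topology fit index
#'
#' Bins connectivities into `n_bins` equal-width bins, drops empty bins,
#' and returns the squared Pearson correlation between log10 bin frequency
#' and log10 bin mean connectivity. `NA` for degenerate (all equal)
#' connectivities.
#'
#' @param k connectivity vector.
#' @param n_bins number of bins.
#' @return Scalar R^2 in \[0, 1\] or `NA`.
#' @export
scale_free_r2 <- function(k, n_bins = 10L) {
  if (length(unique(k)) < 2L) return(NA_real_)
  br <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  mean_k <- tapply(k, bin, mean)[seq_len(n_bins)]
  ok <- freq > 0 & !is.na(mean_k) & mean_k > 0
  if (sum(ok) < 3L) return(NA_real_)
  stats::cor(log10(freq[ok]), log10(mean_k[ok]))^2
}

#' Detect co-expression modules from a signed TOM
#'
#' Builds the signed biweight-midcorrelation adjacency
#' `((1 + bicor) / 2)^power`, converts it to topological-overlap
#' similarity, clusters `1 - TOM` by average linkage, applies a static cut
#' at the `cut_quantile` of the dissimilarity values, discards branches
#' smaller than `min_size` to "unassigned", and iteratively merges modules
#' whose eigengene correlation is at least `1 - merge_height`.
#'
#' @param expr genes x samples matrix.
#' @param power soft-thresholding power (>= 1).
#' @param min_size minimum module size (default 30).
#' @param merge_height eigengene-dissimilarity merge cut (default 0.25).
#' @param cut_quantile static tree-cut dissimilarity quantile (default
#'   0.05).
#' @param cut_height absolute cut height overriding `cut_quantile` when
#'   supplied.
#' @return Named character vector: gene id -> module label ("M1", "M2",
#'   ... by decreasing size, or "unassigned").
#' @export
detect_modules <- function(expr, power, min_size = 30L,
                           merge_height = 0.25, cut_quantile = 0.05,
                           cut_height = NULL) {
  if (power < 1) stop_input("detect_modules: power must be >= 1")
  A <- ((1 + bicor_matrix(expr, warn = FALSE)) / 2)^power
  diag(A) <- 0
  tom <- tom_similarity(A)
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cut_h <- cut_height %||%
    stats::quantile(diss[upper.tri(diss)], cut_quantile)
  cl <- stats::cutree(hc, h = cut_h)
  sizes <- table(cl)
  lab <- ifelse(sizes[as.character(cl)] >= min_size,
                paste0("C", cl), "unassigned")
  names(lab) <- rownames(expr)
  if (all(lab == "unassigned")) {
    warning("detect_modules: no branch reached min_size; all genes unassigned")
    return(lab)
  }

  # iterative merging of modules with correlated eigengenes
  repeat {
    mods <- setdiff(unique(lab), "unassigned")
    if (length(mods) < 2L) break
    me <- module_eigengenes(expr, lab)
    cc <- stats::cor(t(me))
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) < 1 - merge_height) break
    lab[lab == rownames(cc)[top[2]]] <- rownames(cc)[top[1]]
  }

  # relabel by decreasing size
  mods <- setdiff(unique(lab), "unassigned")
  sz <- sort(table(lab[lab != "unassigned"]), decreasing = TRUE)
  newname <- stats::setNames(paste0("M", seq_along(sz)), names(sz))
  out <- ifelse(lab == "unassigned", "unassigned", newname[lab])
  names(out) <- rownames(expr)
  out
}

#' Topological overlap similarity from an adjacency matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal; `a` must have a zero diagonal.
#'
#' @param A symmetric adjacency with zero diagonal, entries in \[0, 1\].
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(A) {
  k <- rowSums(A)
  L <- A %*% A
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  tom
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right-singular vector (sample
#' loadings) of the module's gene-standardised expression, sign-oriented
#' so it correlates positively with the module's mean expression profile.
#'
#' @param expr genes x samples matrix.
#' @param assignment named vector gene -> module (label "unassigned"
#'   skipped).
#' @return Matrix modules x samples, unit-norm rows.
#' @export
module_eigengenes <- function(expr, assignment) {
  mods <- setdiff(unique(assignment), "unassigned")
  if (!length(mods)) stop_input("module_eigengenes: no modules")
  out <- matrix(NA_real_, length(mods), ncol(expr),
                dimnames = list(mods, colnames(expr)))
  for (m in mods) {
    genes <- names(assignment)[assignment == m]
    if (length(genes) < 2L)
      stop_input("module_eigengenes: module %s has < 2 genes", m)
    X <- expr[genes, , drop = FALSE]
    sds <- apply(X, 1, stats::sd)
    if (any(sds == 0))
      stop_input("module_eigengenes: constant gene(s) in module %s", m)
    Xs <- (X - rowMeans(X)) / sds
    sv <- svd(Xs, nu = 0, nv = 1)
    eg <- sv$v[, 1]
    if (stats::cor(eg, colMeans(Xs)) < 0) eg <- -eg
    out[m, ] <- eg
  }
  out
}

#' Module membership (kME)
#'
#' Biweight midcorrelation of each gene's expression with each module
#' eigengene.
#'
#' @param expr genes x samples matrix.
#' @param eigengenes modules x samples matrix (see [module_eigengenes()]).
#' @return Matrix genes x modules with values in \[-1, 1\].
#' @export
kme <- function(expr, eigengenes) {
  if (ncol(expr) != ncol(eigengenes))
    stop_input("kme: expr and eigengenes must share samples")
  bicor_matrix(expr, eigengenes, warn = FALSE)
}

#' Module-trait association
#'
#' Each experimental group is encoded as a one-vs-rest binary indicator;
#' the association of each module eigengene with each indicator is the
#' biweight midcorrelation, with a two-sided p-value from the Student
#' approximation `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 df, and
#' Benjamini-Hochberg adjustment across all module x trait cells.
#'
#' @param eigengenes modules x samples matrix.
#' @param group_labels group label per sample.
#' @return Data frame: `module`, `trait`, `r`, `t`, `p`, `q`.
#' @export
module_trait <- function(eigengenes, group_labels) {
  n <- ncol(eigengenes)
  if (n < 4L) stop_input("module_trait: need >= 4 samples")
  if (length(group_labels) != n)
    stop_input("module_trait: one group label per sample required")
  groups <- sort(unique(as.character(group_labels)))
  rows <- list()
  for (g in groups) {
    if (sum(group_labels == g) < 2L) {
      warning(sprintf("module_trait: group %s has < 2 samples; skipped", g))
      next
    }
    ind <- as.numeric(group_labels == g)
    for (m in rownames(eigengenes)) {
      r <- bicor(eigengenes[m, ], ind)
      tt <- if (abs(r) >= 1) Inf * sign(r)
      else r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
      rows[[length(rows) + 1L]] <-
        data.frame(module = m, trait = g, r = r, t = tt, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}

#' Hub genes of each module
#'
#' Genes assigned to a module whose absolute membership to that module
#' exceeds `threshold` (strict).
#'
#' @param kme_matrix genes x modules kME matrix.
#' @param assignment named vector gene -> module.
#' @param threshold |kME| cutoff (default 0.8).
#' @param modules modules to report (default: all in the kME matrix).
#' @return Named list of character vectors.
#' @export
hub_genes <- function(kme_matrix, assignment, threshold = 0.8,
                      modules = colnames(kme_matrix)) {
  out <- list()
  for (m in modules) {
    genes <- names(assignment)[assignment == m]
    genes <- intersect(genes, rownames(kme_matrix))
    out[[m]] <- genes[abs(kme_matrix[genes, m]) > threshold]
  }
  out
}

#' Bootstrap stability of a module assignment
#'
#' Samples are resampled with replacement `n_boot` times; module
#' eigengenes are recomputed on each bootstrap matrix while keeping the
#' original module assignment, each assigned gene's kME to its own module
#' is computed, and the mean across genes is recorded. The stability score
#' is the average of these per-bootstrap means. Draws with fewer than 3
#' distinct samples are redrawn (counted in `n_redraws`).
#'
#' @param expr genes x samples matrix (>= 4 samples).
#' @param assignment named vector gene -> module.
#' @param n_boot bootstrap iterations (default 50).
#' @param seed RNG seed.
#' @param indices optional list of pre-specified bootstrap column indices
#'   (overrides random draws; for reproducibility checks).
#' @return List of class `stability_report`: `score`, `per_boot`, `n_boot`,
#'   `seed`, `n_redraws`.
#' @export
bootstrap_stability <- function(expr, assignment, n_boot = 50L, seed = 1L,
                                indices = NULL) {
  n <- ncol(expr)
  if (n < 4L) stop_input("bootstrap_stability: need >= 4 samples")
  assigned <- names(assignment)[assignment != "unassigned"]
  if (!length(assigned))
    stop_input("bootstrap_stability: no assigned genes")
  if (is.null(indices)) {
    n_redraws <- 0L
    indices <- withr::with_seed(derive_seed(seed, "bootstrap"), {
      lapply(seq_len(n_boot), function(b) {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(idx)) >= 3L) return(idx)
          n_redraws <<- n_redraws + 1L
        }
      })
    })
  } else {
    n_redraws <- 0L
    n_boot <- length(indices)
  }
  per_boot <- vapply(indices, function(idx) {
    bx <- expr[, idx, drop = FALSE]
    me <- suppressWarnings(module_eigengenes(bx, assignment))
    km <- suppressWarnings(kme(bx[assigned, , drop = FALSE], me))
    mean(km[cbind(assigned, assignment[assigned])])
  }, numeric(1))
  structure(list(score = mean(per_boot), per_boot = per_boot,
                 n_boot = n_boot, seed = seed, n_redraws = n_redraws),
            class = "stability_report")
}
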