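# Group-level evaluation: arithmetic group averaging, ROC analysis with
# vertically averaged bootstrap confidence bands on a fixed 101-point false-
# positive-rate grid, AUC confidence intervals, and cohort summaries.

#' Voxelwise arithmetic group average
#'
#' @param maps List of subject volumes (3D arrays on one grid).
#' @param source_tag Optional label (e.g. "cnn-320", "cnn-100", "task").
#' @return Object of class `group_map`: `mean` volume, `n_subjects`,
#'   `source`.
#' @export
group_average <- function(maps, source_tag = NA_character_) {
  stopifnot(length(maps) >= 1)
  d <- dim(maps[[1]])
  for (m in maps) if (!identical(dim(m), d))
    stopf("shape error: group maps are not on a common grid")
  structure(list(mean = Reduce(`+`, maps) / length(maps),
                 n_subjects = length(maps), source = source_tag),
            class = "group_map")
}

# scores/labels extraction shared by the ROC functions
roc_inputs <- function(scores, truth, eval_mask = NULL) {
  if (inherits(scores, "group_map")) scores <- scores$mean
  if (!is.null(dim(scores))) {
    if (is.null(eval_mask)) eval_mask <- array(TRUE, dim(scores))
    s <- as.numeric(scores[eval_mask])
    y <- as.logical(truth[eval_mask])
  } else {
    s <- as.numeric(scores)
    y <- as.logical(truth)
  }
  if (anyNA(s) || anyNA(y)) stopf("scores/truth contain missing values")
  if (!any(y) || all(y))
    stopf("degeneracy error: truth must contain both classes in the evaluation mask")
  list(scores = s, labels = y)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' voxel outscores a random negative one, ties counted 1/2.
#'
#' @param scores Numeric vector or volume of method scores.
#' @param truth Logical vector or volume of ground-truth labels.
#' @param eval_mask Optional logical volume restricting the evaluation.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth, eval_mask = NULL) {
  io <- roc_inputs(scores, truth, eval_mask)
  r <- rank(io$scores)
  n1 <- sum(io$labels)
  n0 <- length(io$labels) - n1
  (sum(r[io$labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC vertices of one sample given per-voxel unique-score group ids
# (1 = highest score); returns cumulative fpr/tpr starting at (0,0)
roc_vertices <- function(gpos, gneg, n_unique) {
  cp <- cumsum(tabulate(gpos, nbins = n_unique))
  cn <- cumsum(tabulate(gneg, nbins = n_unique))
  list(fpr = c(0, cn / cn[n_unique]), tpr = c(0, cp / cp[n_unique]))
}

# linear interpolation of a ROC polyline onto an FPR grid; vertical
# segments (repeated fpr) contribute their upper tpr
interp_tpr <- function(fpr, tpr, grid) {
  last <- rev(!duplicated(rev(fpr)))
  approx(fpr[last], tpr[last], xout = grid, method = "linear",
         rule = 2, ties = max)$y
}

#' ROC curve with vertically averaged bootstrap confidence bands
#'
#' Voxels are resampled with replacement; each replicate's ROC curve is
#' linearly interpolated onto a fixed grid of `n_grid` false-positive-rate
#' points, the true-positive rates are averaged vertically across
#' replicates, and pointwise percentile bands at level `alpha` are attached.
#' The AUC confidence interval comes from the replicate (trapezoidal) AUC
#' distribution; the point-estimate AUC is the rank-based AUC of the full
#' sample.
#'
#' @inheritParams roc_auc
#' @param n_grid Number of FPR grid points (default 101).
#' @param n_boot Bootstrap iterations (default 10,000; must be >= 10).
#' @param alpha Two-sided confidence level parameter (default 0.05).
#' @param seed RNG seed for the resampling.
#' @param source_tag,truth_tag Optional labels carried into comparisons.
#' @return Object of class `roc_result`: `fpr_grid`, `tpr` (full-sample
#'   curve), `tpr_mean`, `tpr_lo`, `tpr_hi`, `auc`, `auc_ci`, `n_boot`,
#'   `alpha`, `n_pos`, `n_neg`, `source`, `truth_tag`.
#' @export
roc_curve_vertical <- function(scores, truth, eval_mask = NULL, n_grid = 101,
                               n_boot = 10000, alpha = 0.05, seed = 0,
                               source_tag = NA_character_,
                               truth_tag = NA_character_) {
  if (n_boot < 10) stopf("parameter error: n_boot must be >= 10")
  io <- roc_inputs(scores, truth, eval_mask)
  n <- length(io$scores)
  uniq <- sort(unique(io$scores), decreasing = TRUE)
  g <- match(io$scores, uniq)
  grid <- seq(0, 1, length.out = n_grid)
  lab <- io$labels

  full <- roc_vertices(g[lab], g[!lab], length(uniq))
  tpr_full <- interp_tpr(full$fpr, full$tpr, grid)

  tpr_boot <- matrix(0, n_boot, n_grid)
  auc_boot <- numeric(n_boot)
  with_seed(seed, {
    for (i in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        yl <- lab[idx]
        if (any(yl) && !all(yl)) break
      }
      v <- roc_vertices(g[idx][yl], g[idx][!yl], length(uniq))
      tpr_boot[i, ] <- interp_tpr(v$fpr, v$tpr, grid)
      auc_boot[i] <- sum(diff(v$fpr) * (head(v$tpr, -1) + v$tpr[-1]) / 2)
    }
  })
  qs <- c(alpha / 2, 1 - alpha / 2)
  band <- apply(tpr_boot, 2, quantile, probs = qs, names = FALSE)
  structure(list(fpr_grid = grid,
                 tpr = tpr_full,
                 tpr_mean = colMeans(tpr_boot),
                 tpr_lo = band[1, ], tpr_hi = band[2, ],
                 auc = roc_auc(io$scores, io$labels),
                 auc_ci = quantile(auc_boot, qs, names = FALSE),
                 n_boot = n_boot, alpha = alpha,
                 n_pos = sum(lab), n_neg = sum(!lab),
                 source = source_tag, truth_tag = truth_tag),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC%s: AUC = %.4f [%.4f, %.4f] (%d bootstrap, alpha = %g; %d pos / %d neg voxels)\n",
              if (is.na(x$source)) "" else paste0(" [", x$source, "]"),
              x$auc, x$auc_ci[1], x$auc_ci[2], x$n_boot, x$alpha,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, add = FALSE, col = "steelblue", ...) {
  if (!add) {
    graphics::plot(x$fpr_grid, x$tpr_mean, type = "n", xlim = c(0, 1),
                   ylim = c(0, 1), xlab = "false positive rate",
                   ylab = "true positive rate", ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  }
  graphics::polygon(c(x$fpr_grid, rev(x$fpr_grid)), c(x$tpr_lo, rev(x$tpr_hi)),
                    border = NA, col = grDevices::adjustcolor(col, 0.25))
  graphics::lines(x$fpr_grid, x$tpr_mean, col = col, lwd = 2)
  invisible(x)
}

#' Compare two ROC results
#'
#' Reports the AUC difference and whether the two AUC confidence intervals
#' overlap (the overlap criterion used when comparing full-length vs
#' shortened resting-state inputs).
#'
#' @param result_a,result_b `roc_result` objects computed against the same
#'   ground truth.
#' @return Object of class `roc_comparison`: `auc_diff` (a - b),
#'   `ci_overlap`, and the two AUC/CI summaries.
#' @export
compare_methods <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "roc_result"), inherits(result_b, "roc_result"))
  if (!is.na(result_a$truth_tag) && !is.na(result_b$truth_tag) &&
      !identical(result_a$truth_tag, result_b$truth_tag))
    stopf("comparison error: results use different ground truths ('%s' vs '%s')",
          result_a$truth_tag, result_b$truth_tag)
  overlap <- result_a$auc_ci[1] <= result_b$auc_ci[2] &&
    result_b$auc_ci[1] <= result_a$auc_ci[2]
  structure(list(auc_diff = result_a$auc - result_b$auc,
                 ci_overlap = overlap,
                 a = list(source = result_a$source, auc = result_a$auc,
                          ci = result_a$auc_ci),
                 b = list(source = result_b$source, auc = result_b$auc,
                          ci = result_b$auc_ci)),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("AUC %s = %.4f vs %s = %.4f; difference %.4f; 95%% CIs %s\n",
              x$a$source %||% "A", x$a$auc, x$b$source %||% "B", x$b$auc,
              x$auc_diff, if (x$ci_overlap) "overlap" else "do not overlap"))
  invisible(x)
}

#' Evaluation mask for one language ROI
#'
#' Default negative-class convention: all brain-mask voxels of the left
#' hemisphere (x at or below the grid midline) excluding the other language
#' ROI; set `hemisphere = "both"` for whole-mask negatives.
#'
#' @param brain_mask Logical brain mask.
#' @param exclude Optional logical volume removed from the evaluation
#'   (typically the other ROI).
#' @param hemisphere `"left"` or `"both"`.
#' @return Logical evaluation mask.
#' @export
make_eval_mask <- function(brain_mask, exclude = NULL,
                           hemisphere = c("left", "both")) {
  hemisphere <- match.arg(hemisphere)
  m <- brain_mask
  if (hemisphere == "left")
    m <- m & (slice.index(m, 1) <= dim(m)[1] / 2)
  if (!is.null(exclude)) m <- m & !exclude
  m
}

#' Summarize a cohort table
#'
#' @param table A `cohort_table` from [load_cohort_table()].
#' @return Object of class `cohort_summary`: `n_patients`, per-patient total
#'   lesion volume statistics (`mean_volume_ml`, `min_volume_ml`,
#'   `max_volume_ml`), `by_pathology` and `by_hemisphere` counts.
#' @export
summarize_cohort <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  p <- table$patients
  structure(list(n_patients = nrow(p),
                 mean_volume_ml = mean(p$total_volume_ml),
                 min_volume_ml = min(p$total_volume_ml),
                 max_volume_ml = max(p$total_volume_ml),
                 by_pathology = sort(table(p$pathology), decreasing = TRUE),
                 by_hemisphere = table(p$hemisphere)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("%d patients; total lesion volume mean %.1f mL (range %.1f-%.0f mL)\n",
              x$n_patients, x$mean_volume_ml, x$min_volume_ml, x$max_volume_ml))
  cat("By hemisphere:", paste(sprintf("%s %d", names(x$by_hemisphere),
                                      x$by_hemisphere), collapse = ", "), "\n")
  invisible(x)
}
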