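#' Confusion matrix
#'
#' @param tp,fp,fn,tn Nonnegative counts of true positives, false positives,
#'   false negatives and true negatives.
#' @return An object of class `dexa_confusion`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn = 0) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(as.list(counts), class = "dexa_confusion")
}

#' @export
print.dexa_confusion <- function(x, ...) {
  cat(sprintf("<dexa_confusion> tp=%g fp=%g fn=%g tn=%g\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' F1 score
#'
#' `F1 = TP / (TP + 0.5 (FP + FN))`. True negatives do not enter the
#' formula; a score of 1 requires `FP = FN = 0` with at least one true
#' positive.
#'
#' @param cm A [confusion_matrix()], or the `tp` count when `fp`/`fn` are
#'   given directly.
#' @param fp,fn Counts when calling with scalars.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' f1_score(confusion_matrix(tp = 271, fp = 5, fn = 25, tn = 187))
f1_score <- function(cm, fp = NULL, fn = NULL) {
  if (!inherits(cm, "dexa_confusion"))
    cm <- confusion_matrix(tp = cm, fp = fp, fn = fn)
  denom <- cm$tp + 0.5 * (cm$fp + cm$fn)
  if (denom == 0) stop("F1 undefined: tp + fp + fn = 0")
  cm$tp / denom
}

#' Pixel-level confusion matrix of a segmentation
#'
#' Counts per-pixel agreement between a predicted defect mask and the ground
#' truth, restricted to the object mask when one is given.
#'
#' @param pred,truth Logical matrices of equal shape.
#' @param mask Optional logical matrix restricting the counted pixels.
#' @return A [confusion_matrix()].
#' @export
pixel_confusion <- function(pred, truth, mask = NULL) {
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pred), ncol(pred))
  p <- pred[mask]; t <- truth[mask]
  confusion_matrix(tp = sum(p & t), fp = sum(p & !t),
                   fn = sum(!p & t), tn = sum(!p & !t))
}

#' Sample-level confusion matrix of the inspection procedure
#'
#' Matches per-sample verdicts against ground-truth labels by `sample_id`
#' and counts a true positive when a sample with a defect is marked
#' defected, a true negative when a normal sample is marked normal, and so
#' on. Also reports sensitivity `tp/(tp+fn)` (defect samples caught) and
#' specificity `tn/(tn+fp)` (normal samples passed).
#'
#' @param results Data frame with columns `sample_id` and `verdict`
#'   (`"defected"`/`"normal"`), or a list of `dexa_detection` objects.
#' @param labels Data frame with columns `sample_id` and `has_defect`.
#' @return A [confusion_matrix()] with attributes `sensitivity` and
#'   `specificity`.
#' @export
sample_confusion <- function(results, labels) {
  if (is.list(results) && !is.data.frame(results))
    results <- data.frame(
      sample_id = vapply(results, function(r) as.character(r$sample_id),
                         character(1)),
      verdict = vapply(results, `[[`, character(1), "verdict"),
      stringsAsFactors = FALSE)
  if (nrow(results) == 0L) stop("empty results")
  m <- match(results$sample_id, labels$sample_id)
  if (any(is.na(m))) stop("sample id mismatch between results and labels")
  has <- labels$has_defect[m]
  det <- results$verdict == "defected"
  cm <- confusion_matrix(tp = sum(det & has), fp = sum(det & !has),
                         fn = sum(!det & has), tn = sum(!det & !has))
  attr(cm, "sensitivity") <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn)
                             else NA_real_
  attr(cm, "specificity") <- if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp)
                             else NA_real_
  cm
}

#' Penalty-weight grid sweep
#'
#' Runs the full pipeline (pre-processing, segmentation, clustering,
#' verdict) for every `(mu, nu)` combination over a dataset manifest and
#' scores each combination. In `"pixel"` mode the score is the mean
#' per-image pixel F1 over defect-containing samples only (segmentation
#' accuracy); in `"sample"` mode it is the single dataset-level F1 of the
#' defected/normal verdicts (detection accuracy). Failures on individual
#' samples are logged as warnings and the sample is excluded.
#'
#' @param manifest Manifest data frame from [generate_dataset()].
#' @param dir Dataset directory the manifest paths are relative to.
#' @param mu_values,nu_values Penalty grids (the reference experiments used
#'   a grid step of 2).
#' @param cfg Base [pipeline_config()]; `mu`/`nu` are overridden per cell.
#' @param mode `"sample"` or `"pixel"`.
#' @return An object of class `dexa_sweep`: `grid` (data frame `mu`, `nu`,
#'   `f1`, and in sample mode `sensitivity`/`specificity`), `best` (row with
#'   maximal F1; ties to the first in grid order), `mode`, and in pixel mode
#'   `by_class` (per-defect-class mean F1 at the best cell).
#' @export
sweep_penalties <- function(manifest, dir, mu_values, nu_values,
                            cfg = pipeline_config(),
                            mode = c("sample", "pixel")) {
  mode <- match.arg(mode)
  if (!length(mu_values) || !length(nu_values)) stop("empty penalty grid")
  use <- if (mode == "pixel") manifest[manifest$has_defect, , drop = FALSE]
         else manifest
  if (nrow(use) == 0L) stop("no samples to evaluate")

  pairs <- lapply(seq_len(nrow(use)), function(i) read_pair(dir, use[i, ]))
  grid <- expand.grid(mu = mu_values, nu = nu_values)
  rows <- vector("list", nrow(grid))
  best_by_class <- NULL

  for (g in seq_len(nrow(grid))) {
    cfg_g <- cfg
    cfg_g$chanvese$mu <- grid$mu[g]
    cfg_g$chanvese$nu <- grid$nu[g]
    per_f1 <- rep(NA_real_, nrow(use))
    verdicts <- rep(NA_character_, nrow(use))
    for (i in seq_len(nrow(use))) {
      res <- tryCatch(detect(pairs[[i]], cfg_g, sample_id = use$sample_id[i]),
                      error = function(e) {
                        warning(sprintf("sample %s failed: %s",
                                        use$sample_id[i], conditionMessage(e)))
                        NULL
                      })
      if (is.null(res)) next
      verdicts[i] <- res$verdict
      if (mode == "pixel") {
        pp <- attr(res, "preprocess")
        kept <- matrix(FALSE, nrow(pairs[[i]]$m1), ncol(pairs[[i]]$m1))
        for (cl in res$clusters_kept) kept[cl$pixels] <- TRUE
        cm <- pixel_confusion(kept, pairs[[i]]$truth, mask = pp$mask)
        per_f1[i] <- if (cm$tp + cm$fp + cm$fn > 0) f1_score(cm) else NA_real_
      }
    }
    ok <- !is.na(verdicts)
    if (mode == "pixel") {
      rows[[g]] <- data.frame(mu = grid$mu[g], nu = grid$nu[g],
                              f1 = mean(per_f1[ok], na.rm = TRUE))
    } else {
      cm <- sample_confusion(
        data.frame(sample_id = use$sample_id[ok], verdict = verdicts[ok]),
        use)
      rows[[g]] <- data.frame(mu = grid$mu[g], nu = grid$nu[g],
                              f1 = f1_score(cm),
                              sensitivity = attr(cm, "sensitivity"),
                              specificity = attr(cm, "specificity"))
    }
    rows[[g]]$.per_f1 <- I(list(per_f1))
  }
  out <- do.call(rbind, rows)
  bi <- which.max(out$f1)
  if (mode == "pixel") {
    pf <- out$.per_f1[[bi]]
    best_by_class <- vapply(split(pf, use$defect_class), mean,
                            numeric(1), na.rm = TRUE)
  }
  out$.per_f1 <- NULL
  structure(
    list(grid = out, best = out[bi, , drop = FALSE], mode = mode,
         by_class = best_by_class),
    class = "dexa_sweep"
  )
}

#' @export
print.dexa_sweep <- function(x, ...) {
  cat(sprintf("<dexa_sweep> %s mode, %d cells; best mu=%g nu=%g (F1 %.3f)\n",
              x$mode, nrow(x$grid), x$best$mu, x$best$nu, x$best$f1))
  invisible(x)
}
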