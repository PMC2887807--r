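# Confusion-matrix bookkeeping, assessment metrics, ROC points, Q3 and the
# ratio x window x residue experiment grid.

#' Tally a confusion matrix from hard labels
#'
#' @param truth numeric vector over {+1, -1}.
#' @param predicted numeric vector over {+1, -1}, same length.
#' @return Object of class `confusion_counts` with fields `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
score_labels <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop_data("truth and predicted label vectors differ in length (",
              length(truth), " vs ", length(predicted), ")")
  }
  if (length(truth) && (!all(truth %in% c(-1, 1)) ||
                        !all(predicted %in% c(-1, 1)))) {
    stop_data("labels must be +1 or -1")
  }
  confusion_counts(TP = sum(truth > 0 & predicted > 0),
                   FP = sum(truth < 0 & predicted > 0),
                   TN = sum(truth < 0 & predicted < 0),
                   FN = sum(truth > 0 & predicted < 0))
}

#' Construct confusion counts directly
#' @param TP,FP,TN,FN non-negative integer counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_data("confusion counts must be non-negative integers")
  }
  counts <- as.integer(counts)
  structure(list(TP = counts[1L], FP = counts[2L], TN = counts[3L],
                 FN = counts[4L]),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Assessment metrics from confusion counts
#'
#' Computes the standard binary assessment panel:
#' \deqn{Sn = TP/(TP+FN), \quad Sp = TN/(TN+FP), \quad
#'       Ac = (TP+TN)/(TP+FP+TN+FN),}
#' \deqn{Mcc = (TP \cdot TN - FP \cdot FN) /
#'       \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}, \quad FPR = FP/(FP+TN).}
#' `Ac`, `Sn`, `Sp` are returned as percentages; `Mcc` is dimensionless in
#' [-1, 1]; `FPR` is a rate in [0, 1] (so `FPR = 1 - Sp/100`).  When a
#' denominator is zero the affected rate is reported as 0 and flagged in
#' the `undefined` field; `Mcc` is defined as 0 when any factor of its
#' denominator vanishes.
#'
#' @param counts a `confusion_counts` object.
#' @return Object of class `metrics_report` with fields `Ac`, `Sn`, `Sp`,
#'   `Mcc`, `FPR`, the original counts, and `undefined` (character vector
#'   of rates with empty denominators).
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total <= 0L) stop_data("empty confusion matrix")
  undefined <- character()
  rate <- function(num, den, name) {
    if (den == 0L) {
      undefined <<- c(undefined, name)
      0
    } else {
      num / den
    }
  }
  sn <- rate(TP, TP + FN, "Sn")
  sp <- rate(TN, TN + FP, "Sp")
  fpr <- rate(FP, FP + TN, "FPR")
  denom_factors <- c(TP + FP, TP + FN, TN + FP, TN + FN)
  mcc <- if (any(denom_factors == 0)) 0 else {
    (TP * TN - FP * FN) / sqrt(prod(as.numeric(denom_factors)))
  }
  structure(list(Ac = 100 * (TP + TN) / total, Sn = 100 * sn,
                 Sp = 100 * sp, Mcc = mcc, FPR = fpr,
                 counts = counts, undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> Ac=%.2f%% Sn=%.2f%% Sp=%.2f%% Mcc=%.2f FPR=%.2f\n",
              x$Ac, x$Sn, x$Sp, x$Mcc, x$FPR))
  invisible(x)
}

#' Q3 benchmark score
#'
#' The fraction of annotated positive benchmark sites that the classifier
#' predicts positive — benchmark sensitivity on the annotated set, the
#' standard single-number comparison between site predictors.
#'
#' @param annotations data.frame of annotated positive benchmark sites
#'   (`protein_id`, `position`).
#' @param predictions data.frame with `protein_id`, `position`, `label`
#'   (+1/-1) covering at least every annotated site.
#' @return List with `correct`, `total` and `percent` (one decimal,
#'   half-up).
#' @export
q3_score <- function(annotations, predictions) {
  key <- function(d) paste(d$protein_id, d$position)
  pk <- key(predictions)
  ak <- key(annotations)
  miss <- setdiff(ak, pk)
  if (length(miss)) {
    stop_data("no prediction for annotated site(s): ",
              paste(utils::head(miss, 5L), collapse = "; "),
              if (length(miss) > 5L) " ..." else "")
  }
  lab <- predictions$label[match(ak, pk)]
  correct <- sum(lab > 0)
  total <- length(ak)
  list(correct = correct, total = total,
       percent = round_half_up(100 * correct / total, 1L))
}

#' @noRd
average_reports <- function(reports) {
  avg <- function(f) mean(vapply(reports, `[[`, numeric(1), f))
  structure(list(Ac = avg("Ac"), Sn = avg("Sn"), Sp = avg("Sp"),
                 Mcc = avg("Mcc"), FPR = avg("FPR"),
                 counts = NULL, undefined = character()),
            class = "metrics_report")
}

#' @noRd
pool_reports <- function(reports) {
  tot <- function(f) sum(vapply(reports, function(r) r$counts[[f]],
                                numeric(1)))
  compute_metrics(confusion_counts(tot("TP"), tot("FP"), tot("TN"),
                                   tot("FN")))
}

#' Stratified k-fold cross-validation
#'
#' Splits the instances with [split_folds()], trains an SVM on each
#' training fold, scores the held-out fold, and combines the per-fold
#' metric panels.  The default combination is the arithmetic mean of each
#' metric across folds; `combine = "pooled"` instead sums the confusion
#' counts and recomputes the metrics once.
#'
#' @param instances an [instance_set()] with both classes.
#' @param config a [model_config()].
#' @param folds number of folds (default 3).
#' @param seed RNG seed for the fold split.
#' @param combine `"average"` (default) or `"pooled"`.
#' @return List with `overall` (a `metrics_report`), `per_fold` (list of
#'   `metrics_report`), `fold_models` (list of `model_bundle`), `folds`
#'   and `seed`.
#' @export
cross_validate <- function(instances, config, folds = 3L, seed = 1L,
                           combine = c("average", "pooled")) {
  combine <- match.arg(combine)
  fold_idx <- split_folds(instances, folds = folds, seed = seed)
  per_fold <- vector("list", length(fold_idx))
  fold_models <- vector("list", length(fold_idx))
  for (f in seq_along(fold_idx)) {
    tr <- subset_instances(instances, fold_idx[[f]]$train)
    te <- subset_instances(instances, fold_idx[[f]]$test)
    m <- train_model(tr, config, seed = seed)
    pred <- predict(m, te)
    per_fold[[f]] <- compute_metrics(score_labels(te$target, pred))
    fold_models[[f]] <- m
  }
  overall <- if (combine == "average") average_reports(per_fold)
             else pool_reports(per_fold)
  list(overall = overall, per_fold = per_fold, fold_models = fold_models,
       folds = fold_idx, seed = seed, combine = combine)
}

#' Run the full ratio x window x residue evaluation grid
#'
#' For each requested residue type and window size, instances are built
#' once; for each balance factor the negatives are thinned with
#' [balance()] and a stratified cross-validation is run.  Each grid cell
#' yields the five-metric panel plus its ROC point `(FPR, Sn)`.
#'
#' @param profiles named list of [pssm_profile()] objects.
#' @param annotations positive annotation data.frame.
#' @param ratios balance factors (default `c(2, 1.5, 1, 0.5)` negatives
#'   per positive).
#' @param windows odd window sizes (default `c(7, 9, 11, 13, 15)`).
#' @param residues residue types (default S, T, Y).
#' @param folds CV folds (default 3).
#' @param seed RNG seed.
#' @param distance exclusion radius for labeling (default 50).
#' @param combine per-fold combination rule, see [cross_validate()].
#' @return data.frame with one row per (residue, W, ratio) cell: metric
#'   columns `Ac`, `Sn`, `Sp`, `Mcc`, `FPR`, instance counts and the ROC
#'   coordinates `roc_fpr`, `roc_tpr`.
#' @export
experiment_grid <- function(profiles, annotations,
                            ratios = c(2, 1.5, 1, 0.5),
                            windows = c(7L, 9L, 11L, 13L, 15L),
                            residues = PHOSPHO_RESIDUES,
                            folds = 3L, seed = 1L, distance = 50L,
                            combine = c("average", "pooled")) {
  combine <- match.arg(combine)
  rows <- list()
  for (residue in residues) {
    for (W in windows) {
      built <- build_instances(profiles, annotations, residue, W,
                               distance = distance)
      p <- n_instances(built$positives)
      n <- n_instances(built$negatives)
      for (ratio in ratios) {
        plan <- balance_plan(p, n, ratio)
        neg <- balance(built$negatives, plan)
        merged <- merge_instances(built$positives, neg)
        cfg <- model_config(residue, W)
        cv <- cross_validate(merged, cfg, folds = folds, seed = seed,
                             combine = combine)
        ov <- cv$overall
        rows[[length(rows) + 1L]] <- data.frame(
          residue = residue, W = W, ratio = ratio,
          n_positive = p, n_negative_kept = n_instances(neg),
          Ac = ov$Ac, Sn = ov$Sn, Sp = ov$Sp, Mcc = ov$Mcc, FPR = ov$FPR,
          roc_fpr = ov$FPR, roc_tpr = ov$Sn / 100,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Render a metrics grid the way assessment tables are usually printed
#'
#' @param grid data.frame from [experiment_grid()].
#' @param digits decimals for the percentage columns (default 2).
#' @return data.frame with rounded (half-up) display columns.
#' @export
format_grid <- function(grid, digits = 2L) {
  out <- grid
  for (col in c("Ac", "Sn", "Sp")) {
    out[[col]] <- round_half_up(out[[col]], digits)
  }
  out$Mcc <- round_half_up(out$Mcc, 2L)
  out$FPR <- round_half_up(out$FPR, 2L)
  out
}
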