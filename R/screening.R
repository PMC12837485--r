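#' @include AllClasses.R indices.R
NULL

#' Build a screening table from batch index results
#'
#' Turns the long per-volume output of \code{\link{indexCohort}} into the
#' screening table consumed by the ROC stage: one value per (case, model,
#' index). Ground-truth rows get model_name \code{"ground_truth"}. When a
#' case has several sweep videos and \code{unit = "case"}, the per-video
#' index values are aggregated by their arithmetic mean (the screening
#' decision is per case); \code{unit = "video"} keeps one row per video.
#'
#' @param indexDf data.frame from \code{\link{indexCohort}}.
#' @param unit aggregation unit, \code{"case"} (default) or \code{"video"}.
#' @return data.frame: case_id, model_name, index_name, value, group (and
#'   video_id when unit = "video").
#' @export
buildScreeningTable <- function(indexDf, unit = c("case", "video")) {
  unit <- match.arg(unit)
  df <- indexDf[is.na(indexDf$error) & !is.na(indexDf$value), ]
  if (!nrow(df)) stopValidation("no usable index rows")
  df$model_name <- ifelse(df$role == "ground_truth", "ground_truth",
                          df$model_name)
  if (unit == "video") {
    out <- df[, c("case_id", "video_id", "model_name", "index_name",
                  "value", "group")]
  } else {
    out <- stats::aggregate(value ~ case_id + model_name + index_name + group,
                            data = df, FUN = mean)
  }
  validateScreeningTable(out)
  out
}

validateScreeningTable <- function(table) {
  required <- c("case_id", "model_name", "index_name", "value", "group")
  miss <- setdiff(required, names(table))
  if (length(miss))
    stopSchema(paste0("screening table missing column(s): ",
                      paste(miss, collapse = ", ")))
  if (any(!table$index_name %in% c("PLD", "PLA")))
    stopValidation("index_name must be PLD or PLA")
  if (any(!table$group %in% c("normal", "TAPVC")))
    stopValidation("group must be normal or TAPVC")
  pld <- table$value[table$index_name == "PLD"]
  if (length(pld) && any(pld < 1 - 1e-9))
    stopValidation("PLD values must be >= 1")
  pla <- table$value[table$index_name == "PLA"]
  if (length(pla) && any(pla < -1e-9 | pla > 90 + 1e-9))
    stopValidation("PLA values must lie in [0, 90]")
  key <- paste(table$case_id, table[["video_id"]] %||% "", table$model_name,
               table$index_name, sep = "\r")
  if (anyDuplicated(key))
    stopValidation("duplicate (case_id, model_name, index_name) rows")
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group summaries of the screening indices
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of each index per
#' (model, index, group) - the "standard values" of the indices for the
#' normal and TAPVC groups. Cells with a single value report NA for the SD.
#'
#' @param table screening table (\code{\link{buildScreeningTable}}).
#' @return data.frame: model_name, index_name, group, mean, sd, n.
#' @export
groupSummary <- function(table) {
  validateScreeningTable(table)
  out <- stats::aggregate(value ~ model_name + index_name + group,
    data = table,
    FUN = function(x) c(mean = mean(x),
                        sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
                        n = length(x)))
  cbind(out[, 1:3],
        mean = out$value[, "mean"], sd = out$value[, "sd"],
        n = as.integer(out$value[, "n"]))
}

#' Mean absolute error of model indices against ground truth
#'
#' For every model, index and group: the mean over cases of the absolute
#' difference between the model's index value and the ground-truth value of
#' the same case. Every model row must have a ground-truth partner.
#'
#' @param table screening table containing \code{ground_truth} rows.
#' @return data.frame: model_name, index_name, group, mae, n.
#' @export
maeVsGroundTruth <- function(table) {
  validateScreeningTable(table)
  gt <- table[table$model_name == "ground_truth", ]
  if (!nrow(gt)) stopValidation("no ground_truth rows in the screening table")
  md <- table[table$model_name != "ground_truth", ]
  if (!nrow(md)) stopValidation("no model rows in the screening table")
  gtKey <- paste(gt$case_id, gt$index_name, sep = "\r")
  mdKey <- paste(md$case_id, md$index_name, sep = "\r")
  orphan <- !(mdKey %in% gtKey)
  if (any(orphan))
    stopValidation(paste0("model rows without a ground-truth partner: ",
                          paste(unique(md$case_id[orphan]), collapse = ", ")))
  md$abs_err <- abs(md$value - gt$value[match(mdKey, gtKey)])
  out <- stats::aggregate(abs_err ~ model_name + index_name + group,
                          data = md, FUN = mean)
  n <- stats::aggregate(abs_err ~ model_name + index_name + group,
                        data = md, FUN = length)
  names(out)[names(out) == "abs_err"] <- "mae"
  out$n <- as.integer(n$abs_err)
  out
}

#' ROC curve and AUC for TAPVC screening
#'
#' Sweeps a decision threshold over the index values of one model and
#' computes the ROC curve with TAPVC as the positive class and the fixed
#' decision direction "higher index means more likely TAPVC" (both PLD and
#' PLA are elevated in TAPVC, so the direction is not estimated from the
#' data; a model that inverts the relationship correctly yields AUC below
#' 0.5). The AUC is the trapezoidal integral of TPR over FPR and is
#' cross-checked internally against the tie-corrected Mann-Whitney
#' statistic U/(n1 n2) (ties counted 1/2); the two must agree to 1e-12.
#'
#' @param table screening table.
#' @param model model_name to evaluate (\code{"ground_truth"} allowed).
#' @param index \code{"PLD"} or \code{"PLA"}.
#' @return Object of class \code{pvlaROC}: list with thresholds, tpr, fpr,
#'   auc, model, index, positive_class, direction, n_pos, n_neg.
#' @export
rocCurve <- function(table, model, index) {
  validateScreeningTable(table)
  sub <- table[table$model_name == model & table$index_name == index, ]
  pos <- sub$value[sub$group == "TAPVC"]
  neg <- sub$value[sub$group == "normal"]
  if (!length(pos) || !length(neg))
    stopValidation(sprintf(
      "ROC needs both groups; model '%s', index %s has %d TAPVC and %d normal case(s)",
      model, index, length(pos), length(neg)))
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(pos >= t), numeric(1L)))
  fpr <- c(0, vapply(thr, function(t) mean(neg >= t), numeric(1L)))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  ## Mann-Whitney cross-check: P(pos > neg) + 0.5 P(pos == neg)
  r <- rank(c(pos, neg))
  n1 <- length(pos); n2 <- length(neg)
  aucMW <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  if (abs(auc - aucMW) > 1e-12)
    stop(sprintf("internal inconsistency: trapezoid AUC %.15f != Mann-Whitney AUC %.15f",
                 auc, aucMW))
  structure(list(thresholds = c(Inf, thr), tpr = tpr, fpr = fpr, auc = auc,
                 model = model, index = index, positive_class = "TAPVC",
                 direction = "higher-value-is-positive",
                 n_pos = n1, n_neg = n2),
            class = "pvlaROC")
}

#' @export
print.pvlaROC <- function(x, ...) {
  cat(sprintf("ROC %s / %s: AUC = %.4f (positive = %s, %s; %d TAPVC vs %d normal)\n",
              x$model, x$index, x$auc, x$positive_class, x$direction,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare screening AUCs across models
#'
#' Per-model AUC for each index, sorted by AUC (descending) with ties
#' broken by model name for determinism.
#'
#' @param table screening table.
#' @param models model names to rank; default all present.
#' @param indices indices to evaluate; default both.
#' @return data.frame: index_name, model_name, auc, rank.
#' @export
compareModels <- function(table, models = NULL,
                          indices = c("PLD", "PLA")) {
  validateScreeningTable(table)
  if (is.null(models)) models <- sort(unique(table$model_name))
  rows <- list()
  for (index in indices) {
    aucs <- vapply(models, function(m) rocCurve(table, m, index)$auc,
                   numeric(1L))
    o <- order(-aucs, models)
    rows[[index]] <- data.frame(index_name = index, model_name = models[o],
                                auc = aucs[o], rank = seq_along(models),
                                stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Bootstrap confidence interval for a screening AUC
#'
#' Optional seeded case-resampling bootstrap (stratified by group) of the
#' AUC; off the default analysis path.
#'
#' @param table screening table.
#' @param model,index as in \code{\link{rocCurve}}.
#' @param n number of bootstrap resamples.
#' @param level confidence level.
#' @param seed RNG seed.
#' @return List with auc, lower, upper, level, n.
#' @export
aucBootstrapCI <- function(table, model, index, n = 1000, level = 0.95,
                           seed = 1L) {
  base <- rocCurve(table, model, index)
  sub <- table[table$model_name == model & table$index_name == index, ]
  pos <- sub$value[sub$group == "TAPVC"]
  neg <- sub$value[sub$group == "normal"]
  set.seed(seed)
  boot <- vapply(seq_len(n), function(i) {
    p <- sample(pos, replace = TRUE); g <- sample(neg, replace = TRUE)
    r <- rank(c(p, g))
    (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
      (length(p) * length(g))
  }, numeric(1L))
  a <- (1 - level) / 2
  qs <- stats::quantile(boot, c(a, 1 - a), names = FALSE, type = 7)
  list(auc = base$auc, lower = qs[1L], upper = qs[2L], level = level, n = n)
}
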