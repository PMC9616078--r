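#' Label groupings used for reporting
#'
#' Three groupings of the four categories: the four-tier identity, the
#' screening grouping NED vs the rest, and the treatment-relevant grouping
#' NED+LGD vs HGD+IIN.
#'
#' @param name `"four-tier"`, `"ned-vs-rest"` or `"nedlgd-vs-hgdiin"`.
#' @return An object of class `wsi_grouping`: the name, a named mapping
#'   from the four categories to group labels, the group level order and
#'   the positive group (for binary groupings).
#' @export
wsi_grouping <- function(name = c("four-tier", "ned-vs-rest",
                                  "nedlgd-vs-hgdiin")) {
  name <- match.arg(name)
  map <- switch(name,
    "four-tier" = setNames(wsi_categories(), wsi_categories()),
    "ned-vs-rest" = c(NED = "NED", LGD = "positive", HGD = "positive",
                      IIN = "positive"),
    "nedlgd-vs-hgdiin" = c(NED = "NED+LGD", LGD = "NED+LGD",
                           HGD = "HGD+IIN", IIN = "HGD+IIN"))
  levels <- unique(unname(map))
  structure(list(name = name, map = map, levels = levels,
                 positive = if (length(levels) == 2) levels[2] else NA),
            class = "wsi_grouping")
}

apply_grouping <- function(labels, grouping) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), names(grouping$map))
  if (length(bad)) stop("unknown label: ", bad[1])
  factor(unname(grouping$map[labels]), levels = grouping$levels)
}

#' Confusion matrix under a grouping
#'
#' Rows are truth, columns are prediction; the total equals the number of
#' slides.
#'
#' @param predictions,truths Equal-length label vectors (four-tier labels;
#'   they are collapsed through the grouping).
#' @param grouping A [wsi_grouping()] (default four-tier).
#' @return A K x K contingency table.
#' @export
confusion_matrix <- function(predictions, truths,
                             grouping = wsi_grouping("four-tier")) {
  if (length(predictions) != length(truths))
    stop("predictions and truths differ in length")
  table(truth = apply_grouping(truths, grouping),
        prediction = apply_grouping(predictions, grouping))
}

#' Sensitivity, specificity, accuracy and NPV for one positive group
#'
#' Collapses the confusion matrix to positive-vs-rest for the given group
#' and reports sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/total and NPV TN/(TN+FN). A metric whose margin is empty is
#' reported as `NA` (never as 0).
#'
#' @param cm A confusion table from [confusion_matrix()] (truth in rows).
#' @param positive The group label treated as positive.
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`,
#'   `npv`.
#' @export
binary_metrics <- function(cm, positive) {
  if (!positive %in% rownames(cm)) stop("unknown positive group: ", positive)
  tp <- sum(cm[positive, positive])
  fn <- sum(cm[positive, colnames(cm) != positive])
  fp <- sum(cm[rownames(cm) != positive, positive])
  tn <- sum(cm[rownames(cm) != positive, colnames(cm) != positive])
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = rate(tp, tp + fn), specificity = rate(tn, tn + fp),
    accuracy = rate(tp + tn, sum(cm)), npv = rate(tn, tn + fn))
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores with trapezoidal AUC, equivalent
#' to the Mann--Whitney statistic with ties counted 1/2. Higher scores are
#' read as more positive.
#'
#' @param scores Numeric scores.
#' @param truths Binary truth (logical, or a factor/character with exactly
#'   two levels where `positive` names the positive one).
#' @param positive Positive label when `truths` is not logical.
#' @return List of class `roc_result`: `curve` (data.frame with columns
#'   `threshold`, `sensitivity`, `specificity`) and `auc`.
#' @export
roc_auc <- function(scores, truths, positive = NULL) {
  if (is.logical(truths)) {
    y <- truths
  } else {
    truths <- as.character(truths)
    lev <- unique(truths)
    if (is.null(positive)) {
      if (length(lev) != 2) stop("need a 'positive' label for >2 levels")
      positive <- lev[2]
    }
    y <- truths == positive
  }
  if (length(unique(y)) < 2)
    stop("both classes must be present to compute a ROC curve")
  r <- pROC::roc(response = y, predictor = scores, levels = c(FALSE, TRUE),
                 direction = "<", quiet = TRUE)
  curve <- data.frame(threshold = r$thresholds, sensitivity = r$sensitivities,
                      specificity = r$specificities)
  structure(list(curve = curve, auc = as.numeric(r$auc)),
            class = "roc_result")
}

#' Cohen's kappa with the published descriptive bands
#'
#' Unweighted kappa `(p_o - p_e)/(1 - p_e)` or quadratically weighted kappa
#' with agreement weights `w_ij = 1 - ((i - j)/(K - 1))^2` on the severity
#' ordering of the categories. The descriptive band uses the cut-points
#' 0.20, 0.40, 0.60, 0.80 (boundaries belong to the upper band, so 0.80 is
#' "very good").
#'
#' @param a,b Equal-length rating vectors.
#' @param categories Ordered category set (default the four severity-ordered
#'   tiers).
#' @param weighting `"none"` or `"quadratic"`.
#' @return An object of class `kappa_result`: `kappa`, `weighting`, `band`
#'   (NA with a flag when chance agreement is 1 and kappa is undefined).
#' @export
cohens_kappa <- function(a, b, categories = wsi_categories(),
                         weighting = c("none", "quadratic")) {
  weighting <- match.arg(weighting)
  if (length(a) != length(b)) stop("rating vectors differ in length")
  a <- factor(as.character(a), levels = categories)
  b <- factor(as.character(b), levels = categories)
  if (anyNA(a) || anyNA(b)) stop("rating outside the category set")
  K <- length(categories)
  tab <- table(a, b) / length(a)
  i <- matrix(seq_len(K), K, K)
  j <- t(i)
  w <- if (weighting == "quadratic") 1 - ((i - j) / (K - 1))^2
       else (i == j) * 1
  pr <- rowSums(tab); pc <- colSums(tab)
  po <- sum(w * tab)
  pe <- sum(w * outer(pr, pc))
  if (abs(1 - pe) < 1e-12) {
    warning("degenerate constant ratings: kappa undefined")
    return(structure(list(kappa = NA_real_, weighting = weighting,
                          band = NA_character_, undefined = TRUE),
                     class = "kappa_result"))
  }
  k <- (po - pe) / (1 - pe)
  structure(list(kappa = k, weighting = weighting, band = kappa_band(k),
                 undefined = FALSE),
            class = "kappa_result")
}

#' Descriptive agreement band for a kappa value
#'
#' poor < 0.20 <= fair < 0.40 <= moderate < 0.60 <= good < 0.80 <= very good.
#'
#' @param k Kappa value.
#' @return Band label.
#' @export
kappa_band <- function(k) {
  if (!is.finite(k)) return(NA_character_)
  cuts <- c(0.20, 0.40, 0.60, 0.80)
  c("poor", "fair", "moderate", "good", "very good")[sum(k >= cuts) + 1]
}

#' Full evaluation report
#'
#' The metric battery for a set of slide predictions: confusion matrix
#' under the requested grouping, one-vs-rest sensitivity/specificity/
#' accuracy/NPV per group, percent agreement, Cohen's kappa (unweighted and
#' quadratically weighted, the latter on the four-tier severity ordering),
#' and -- when scores are supplied and the grouping is binary -- the ROC
#' curve and AUC. An optional `centers` vector adds a per-center breakdown
#' (pooled overall, as merging the per-center sets).
#'
#' @param predictions,truths Four-tier label vectors.
#' @param grouping A [wsi_grouping()] or its name.
#' @param scores Optional scores for the ROC (higher = more positive group).
#' @param centers Optional per-slide center ids.
#' @return An object of class `wsi_eval_report`.
#' @export
evaluate_predictions <- function(predictions, truths,
                                 grouping = "four-tier", scores = NULL,
                                 centers = NULL) {
  if (is.character(grouping)) grouping <- wsi_grouping(grouping)
  cm <- confusion_matrix(predictions, truths, grouping)
  groups <- grouping$levels
  metrics <- t(vapply(groups, function(g) binary_metrics(cm, g), numeric(4)))
  rownames(metrics) <- groups
  agree <- mean(apply_grouping(predictions, grouping) ==
                  apply_grouping(truths, grouping))
  kap <- cohens_kappa(predictions, truths)
  kap_q <- cohens_kappa(predictions, truths, weighting = "quadratic")
  roc <- NULL
  if (!is.null(scores) && length(groups) == 2) {
    roc <- roc_auc(scores, apply_grouping(truths, grouping) ==
                     grouping$positive)
  }
  per_center <- NULL
  if (!is.null(centers)) {
    per_center <- lapply(split(seq_along(centers), centers), function(idx) {
      cmc <- confusion_matrix(predictions[idx], truths[idx], grouping)
      mc <- t(vapply(groups, function(g) binary_metrics(cmc, g), numeric(4)))
      rownames(mc) <- groups
      list(confusion = cmc, metrics = mc,
           agreement = mean(apply_grouping(predictions[idx], grouping) ==
                              apply_grouping(truths[idx], grouping)))
    })
  }
  structure(list(grouping = grouping$name, confusion = cm, metrics = metrics,
                 percent_agreement = agree, kappa = kap,
                 kappa_quadratic = kap_q, roc = roc,
                 per_center = per_center, n = length(truths)),
            class = "wsi_eval_report")
}

#' @export
print.wsi_eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report (%s grouping, n = %d)\n", x$grouping, x$n))
  cat("\nConfusion matrix (rows = truth):\n")
  print(x$confusion)
  cat("\nPer-group metrics:\n")
  print(round(x$metrics, 4))
  cat(sprintf("\nPercent agreement: %.2f%%\n", 100 * x$percent_agreement))
  cat(sprintf("Cohen's kappa: %.3f (%s); quadratically weighted: %.3f (%s)\n",
              x$kappa$kappa, x$kappa$band,
              x$kappa_quadratic$kappa, x$kappa_quadratic$band))
  if (!is.null(x$roc)) cat(sprintf("AUC: %.4f\n", x$roc$auc))
  invisible(x)
}

#' @export
print.kappa_result <- function(x, ...) {
  if (x$undefined) cat("kappa undefined (degenerate constant ratings)\n")
  else cat(sprintf("kappa = %.4f (%s, %s weighting)\n", x$kappa, x$band,
                   x$weighting))
  invisible(x)
}
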