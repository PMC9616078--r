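test_that("confusion matrices count pairs under each grouping", {
  pred <- c("NED", "NED", "HGD")
  truth <- c("NED", "NED", "IIN")
  cm <- confusion_matrix(pred, truth)
  expect_equal(sum(cm), 3)
  expect_equal(unname(cm["NED", "NED"]), 2)
  expect_equal(unname(cm["IIN", "HGD"]), 1)

  # perfect predictions give a diagonal matrix
  cmd <- confusion_matrix(truth, truth)
  expect_equal(sum(cmd) - sum(diag(cmd)), 0)

  # random vectors vs a loop oracle, including collapse equivalence
  set.seed(9)
  for (rep in 1:5) {
    p <- sample(wsi_categories(), 40, replace = TRUE)
    t <- sample(wsi_categories(), 40, replace = TRUE)
    cm4 <- confusion_matrix(p, t)
    for (i in wsi_categories()) for (j in wsi_categories())
      expect_equal(unname(cm4[i, j]), sum(t == i & p == j))
    grp <- wsi_grouping("nedlgd-vs-hgdiin")
    cm2 <- confusion_matrix(p, t, grp)
    collapse <- function(x) ifelse(x %in% c("NED", "LGD"), "NED+LGD", "HGD+IIN")
    expect_equal(unname(cm2["HGD+IIN", "NED+LGD"]),
                 sum(collapse(t) == "HGD+IIN" & collapse(p) == "NED+LGD"))
  }
  expect_error(confusion_matrix(c("NED", "bad"), c("NED", "NED")),
               "unknown label")
})

test_that("binary metrics follow the hand formulas, with NA for empty margins", {
  cm <- matrix(c(5, 2, 0, 3), 2, 2,
               dimnames = list(c("positive", "NED"), c("positive", "NED")))
  # TP=5 FN=0 FP=2 TN=3
  m <- binary_metrics(as.table(cm), "positive")
  expect_equal(unname(m["sensitivity"]), 1.0)
  expect_equal(unname(m["specificity"]), 0.6)
  expect_equal(unname(m["accuracy"]), 0.8)
  expect_equal(unname(m["npv"]), 1.0)  # FN = 0, TN > 0

  # no true positives at all: sensitivity undefined, reported NA
  cm0 <- as.table(matrix(c(0, 1, 0, 9), 2, 2,
                         dimnames = list(c("positive", "NED"),
                                         c("positive", "NED"))))
  m0 <- binary_metrics(cm0, "positive")
  expect_true(is.na(m0["sensitivity"]))
  expect_false(is.na(m0["specificity"]))

  set.seed(12)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 5) + 1, 2, 2,
                  dimnames = list(c("positive", "NED"),
                                  c("positive", "NED")))
    m <- binary_metrics(as.table(tab), "positive")
    tp <- tab[1, 1]; fn <- tab[1, 2]; fp <- tab[2, 1]; tn <- tab[2, 2]
    expect_equal(unname(m["sensitivity"]), tp / (tp + fn))
    expect_equal(unname(m["specificity"]), tn / (tn + fp))
    expect_equal(unname(m["accuracy"]), (tp + tn) / sum(tab))
    expect_equal(unname(m["npv"]), tn / (tn + fn))
  }
})

test_that("AUC equals the Mann-Whitney pairwise concordance", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  set.seed(14)
  for (rep in 1:10) {
    sc <- round(runif(20), 1)  # ties likely
    y <- runif(20) < 0.5
    if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
    expect_equal(roc_auc(sc, y)$auc, auc_oracle(sc, y))
  }
  expect_error(roc_auc(runif(5), rep(TRUE, 5)), "both classes")
})

test_that("Cohen's kappa matches an independent oracle and frozen references", {
  same <- sample(wsi_categories(), 30, replace = TRUE)
  k1 <- cohens_kappa(same, same)
  expect_equal(k1$kappa, 1)
  expect_equal(k1$band, "very good")

  # frozen reference for a fixed 4x4 table (independent implementation)
  M <- matrix(c(10, 2, 0, 0,
                3, 8, 1, 0,
                0, 2, 6, 1,
                0, 0, 2, 5), 4, 4, byrow = TRUE)
  a <- rep(rep(wsi_categories(), rowSums(M)), 1)
  a <- c(); b <- c()
  for (i in 1:4) for (j in 1:4) {
    a <- c(a, rep(wsi_categories()[i], M[i, j]))
    b <- c(b, rep(wsi_categories()[j], M[i, j]))
  }
  expect_equal(cohens_kappa(a, b)$kappa, 0.6261682242990654, tolerance = 1e-12)
  expect_equal(cohens_kappa(a, b, weighting = "quadratic")$kappa,
               0.8785871964679912, tolerance = 1e-12)

  set.seed(15)
  for (rep in 1:5) {
    x <- sample(wsi_categories(), 50, replace = TRUE)
    y <- ifelse(runif(50) < 0.6, x, sample(wsi_categories(), 50, TRUE))
    expect_equal(cohens_kappa(x, y)$kappa,
                 kappa_oracle(x, y, wsi_categories()))
    expect_equal(cohens_kappa(x, y, weighting = "quadratic")$kappa,
                 kappa_oracle(x, y, wsi_categories(), quadratic = TRUE))
  }

  # unweighted kappa is invariant to consistent relabeling
  x <- sample(wsi_categories(), 40, replace = TRUE)
  y <- sample(wsi_categories(), 40, replace = TRUE)
  relab <- c(NED = "IIN", LGD = "HGD", HGD = "LGD", IIN = "NED")
  expect_equal(cohens_kappa(relab[x], relab[y])$kappa,
               cohens_kappa(x, y)$kappa)

  expect_warning(kd <- cohens_kappa(rep("NED", 5), rep("NED", 5)),
                 "degenerate")
  expect_true(kd$undefined)
})

test_that("kappa bands use the published cut-points, upper-inclusive", {
  expect_equal(kappa_band(0.10), "poor")
  expect_equal(kappa_band(0.20), "fair")
  expect_equal(kappa_band(0.40), "moderate")
  expect_equal(kappa_band(0.60), "good")
  expect_equal(kappa_band(0.80), "very good")
  expect_equal(kappa_band(0.880), "very good")
  expect_equal(kappa_band(1.00), "very good")
})

test_that("evaluation reports collapse groupings consistently", {
  set.seed(16)
  truth <- sample(wsi_categories(), 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, truth, sample(wsi_categories(), 60, TRUE))
  scores <- runif(60)
  centers <- sample(c("A", "B"), 60, replace = TRUE)

  rep4 <- evaluate_predictions(pred, truth)
  expect_equal(sum(rep4$confusion), 60)
  expect_equal(rep4$percent_agreement, mean(pred == truth))

  grp <- wsi_grouping("ned-vs-rest")
  rep2 <- evaluate_predictions(pred, truth, grouping = grp,
                               scores = scores, centers = centers)
  # collapsing first equals computing on pre-collapsed labels
  pc <- ifelse(pred == "NED", "NED", "positive")
  tc <- ifelse(truth == "NED", "NED", "positive")
  expect_equal(unname(rep2$metrics["positive", "sensitivity"]),
               sum(pc == "positive" & tc == "positive") / sum(tc == "positive"))
  expect_s3_class(rep2$kappa, "kappa_result")
  expect_false(is.null(rep2$roc))
  expect_named(rep2$per_center, c("A", "B"))
  out <- capture.output(print(rep2))
  expect_true(any(grepl("Confusion", out)))
})
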