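make_graphs <- function(n_graphs, seed = 1, sep = 3) {
  # grade/feature-separated graphs, one label per category cycling
  set.seed(seed)
  cats <- rep(wsi_categories(), length.out = n_graphs)
  graphs <- lapply(seq_len(n_graphs), function(i) {
    k <- match(cats[i], wsi_categories()) - 1
    nn <- sample(4:8, 1)
    X <- matrix(rnorm(nn * 6, mean = k * sep), nn, 6)
    build_graph(X, pmin(1, pmax(0, k / 4 + runif(nn, 0, 0.2))),
                graph_config(n = 8, gamma = Inf), slide_id = paste0("g", i))
  })
  list(graphs = graphs, labels = cats)
}

test_that("focal loss matches its closed forms", {
  p1 <- c(NED = 1, LGD = 0, HGD = 0, IIN = 0)
  expect_equal(focal_loss(p1, "NED"), 0)

  p <- c(NED = 0.2, LGD = 0.3, HGD = 0.4, IIN = 0.1)
  expect_equal(focal_loss(p, "HGD", gamma_f = 0, alpha = 1), -log(0.4))

  ph <- c(NED = 0.5, LGD = 0.3, HGD = 0.1, IIN = 0.1)
  expect_equal(focal_loss(ph, "NED", gamma_f = 2, alpha = 1), 0.25 * log(2))

  expect_error(focal_loss(p, "bad"), "invalid class")
  expect_error(focal_loss(c(0.5, 0.5, 0.5, 0.5), "NED"), "simplex")
})

test_that("GCN training is seeded and fits separable graphs", {
  d <- make_graphs(24, seed = 3)
  cfg <- gcn_train_config(epochs = 60, seed = 9)
  m1 <- train_gcn(d$graphs, d$labels, cfg)
  m2 <- train_gcn(d$graphs, d$labels, cfg)
  expect_identical(m1$params, m2$params)

  acc <- mean(vapply(d$graphs, function(g)
    classify_four_tier(predict_four_tier(m1, g)), "") == d$labels)
  expect_gte(acc, 0.9)

  # single-node graphs train and predict without error
  single <- lapply(1:4, function(i)
    build_graph(matrix(rnorm(6, i), 1, 6), 0.5, graph_config(n = 1)))
  ms <- train_gcn(single, wsi_categories(),
                  gcn_train_config(epochs = 5, seed = 2))
  expect_s3_class(ms, "gcn_model")
  expect_equal(sum(predict_four_tier(ms, single[[1]])), 1, tolerance = 1e-9)

  expect_error(train_gcn(d$graphs, rep("bad", 24)), "unknown label")
})

test_that("GCN gradients agree with numerical differentiation", {
  set.seed(8)
  g <- build_graph(matrix(rnorm(20), 5, 4), runif(5),
                   graph_config(n = 5, gamma = 1))
  p <- slidegraph:::gcn_init_params(5, 6)
  fw <- slidegraph:::gcn_forward(p, g, keep = TRUE)
  gr <- slidegraph:::gcn_backward(p, fw$cache, 2L, 2, 1.5)
  loss_of <- function(pp)
    focal_loss(slidegraph:::gcn_forward(pp, g)$probs, "LGD", 2, 1.5)
  eps <- 1e-6
  for (nm in c("l1", "l2", "out")) {
    p2 <- p; v0 <- p[[nm]]$W[2, 1]
    p2[[nm]]$W[2, 1] <- v0 + eps; up <- loss_of(p2)
    p2[[nm]]$W[2, 1] <- v0 - eps; dn <- loss_of(p2)
    expect_equal(gr[[nm]]$W[2, 1], (up - dn) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("predictions are simplexes invariant to node permutation", {
  d <- make_graphs(8, seed = 5)
  m <- train_gcn(d$graphs, d$labels, gcn_train_config(epochs = 10, seed = 1))
  for (g in d$graphs) {
    p <- predict_four_tier(m, g)
    expect_equal(sum(p), 1, tolerance = 1e-6)
    perm <- sample(nrow(g$features))
    g2 <- g
    g2$features <- g$features[perm, , drop = FALSE]
    g2$grades <- g$grades[perm]
    g2$adjacency <- g$adjacency[perm, perm]
    expect_equal(predict_four_tier(m, g2), p, tolerance = 1e-12)
  }
  # untrained random-init model still emits a valid simplex
  p0 <- slidegraph:::gcn_init_params(7, 4)
  pr <- slidegraph:::gcn_forward(p0, d$graphs[[1]])$probs
  expect_equal(sum(pr), 1, tolerance = 1e-9)
})

test_that("four-tier calls take the argmax with severity tie-breaks", {
  expect_equal(classify_four_tier(c(NED = 0.7, LGD = 0.1, HGD = 0.1,
                                    IIN = 0.1)), "NED")
  expect_equal(classify_four_tier(c(NED = 0.25, LGD = 0.25, HGD = 0.25,
                                    IIN = 0.25)), "IIN")
  expect_equal(classify_four_tier(c(NED = 0.1, LGD = 0.4, HGD = 0.4,
                                    IIN = 0.1)), "HGD")
  set.seed(4)
  for (i in 1:25) {
    p <- random_simplex()
    expect_equal(classify_four_tier(p),
                 wsi_categories()[which.max(p + 1e-9 * (1:4))])
  }
})

test_that("screening calibration maximizes yield under the zero-miss rule", {
  cfg <- calibrate_screening_threshold(c(0.1, 0.2, 0.6, 0.9),
                                       c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cfg$t, 0.2)
  expect_equal(cfg$n_screened_out, 2)

  # positives dominating the benign scores: nothing screened out
  cfg2 <- calibrate_screening_threshold(c(0.8, 0.9, 0.3, 0.5),
                                        c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cfg2$n_screened_out, 0)

  cfg3 <- calibrate_screening_threshold(0.4, TRUE)
  expect_equal(cfg3$t, 0.4)

  expect_error(calibrate_screening_threshold(c(0.2, 0.3), c(FALSE, FALSE)),
               "refused")

  # brute force: no threshold with zero missed positives screens out more
  set.seed(6)
  for (rep in 1:10) {
    p <- runif(30); pos <- runif(30) < 0.4
    if (!any(pos)) pos[1] <- TRUE
    cfg <- calibrate_screening_threshold(p, pos)
    expect_equal(sum(pos & p > cfg$t), 0)
    for (t in unique(p)) {
      if (sum(pos & p > t) == 0)
        expect_lte(sum(!pos & p > t), cfg$n_screened_out)
    }
  }
})

test_that("the screening decision is a strict monotone step in p_NED", {
  cfg <- calibrate_screening_threshold(c(0.3, 0.5), c(TRUE, TRUE))
  expect_equal(screen_slide(0.5, cfg), "retained-for-review")   # p == t
  expect_equal(screen_slide(c(NED = 1.0, LGD = 0, HGD = 0, IIN = 0), cfg),
               "benign-screened-out")
  dec <- vapply(seq(0, 1, 0.05), function(p) screen_slide(p, cfg), "")
  flips <- sum(dec[-1] != dec[-length(dec)])
  expect_lte(flips, 1)
  expect_equal(dec[1], "retained-for-review")
  expect_equal(dec[length(dec)], "benign-screened-out")
})

test_that("screening configs round-trip through JSON", {
  cfg <- calibrate_screening_threshold(c(0.1, 0.8), c(TRUE, FALSE), "val")
  f <- withr::local_tempfile(fileext = ".json")
  write_screening_config(cfg, f)
  cfg2 <- read_screening_config(f)
  expect_equal(cfg2$t, cfg$t)
  expect_equal(cfg2$n_positives, cfg$n_positives)
})
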