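#' Focal loss for one four-tier prediction
#'
#' `-alpha_c * (1 - p_t)^gamma_f * log(p_t)` where `p_t` is the predicted
#' probability of the true class, floored at 1e-12 before the log. With
#' `gamma_f = 0` and `alpha = 1` this reduces to cross-entropy.
#'
#' @param probs Named numeric simplex over the four categories (sums to 1
#'   within 1e-6).
#' @param true_class One of `wsi_categories()`.
#' @param gamma_f Focusing exponent (>= 0).
#' @param alpha Class-balance weight for the true class (> 0).
#' @return Non-negative loss value.
#' @export
focal_loss <- function(probs, true_class, gamma_f = 2, alpha = 1) {
  check_simplex(probs)
  if (!true_class %in% wsi_categories()) stop("invalid class: ", true_class)
  if (gamma_f < 0 || alpha <= 0) stop("gamma_f must be >= 0, alpha > 0")
  pt <- max(probs[[true_class]], 1e-12)
  -alpha * (1 - pt)^gamma_f * log(pt)
}

check_simplex <- function(probs, tol = 1e-6) {
  if (length(probs) != 4 || any(!is.finite(probs)) ||
      any(probs < -tol) || abs(sum(probs) - 1) > tol)
    stop("probs must be a length-4 probability simplex (sum 1 within 1e-6)")
  invisible(probs)
}

#' GCN training configuration
#'
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs Passes over the training graphs.
#' @param hidden Width of the two message-passing layers.
#' @param gamma_f Focal-loss focusing exponent.
#' @param alpha `"balanced"` (weights inversely proportional to class
#'   frequency, normalized to mean 1) or a named positive vector per
#'   category.
#' @param seed Integer seed.
#' @return An object of class `gcn_train_config`.
#' @export
gcn_train_config <- function(lr = 1e-3, epochs = 800, hidden = 32,
                             gamma_f = 2, alpha = "balanced", seed = 1L) {
  if (lr <= 0) stop("learning rate must be positive")
  if (epochs < 1) stop("epochs must be >= 1")
  if (gamma_f < 0) stop("gamma_f must be >= 0")
  if (is.numeric(alpha) && any(alpha <= 0)) stop("alpha weights must be > 0")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 hidden = as.integer(hidden), gamma_f = gamma_f,
                 alpha = alpha, seed = as.integer(seed)),
            class = "gcn_train_config")
}

# Node input features: segmenter feature vector plus the abnormality grade.
gcn_node_matrix <- function(graph) {
  cbind(graph$features, grade = graph$grades)
}

# Row-normalized adjacency (self-loops guarantee nonzero row sums when on;
# otherwise isolated rows are left as zero rows).
gcn_norm_adjacency <- function(A) {
  rs <- rowSums(A)
  rs[rs == 0] <- 1
  A / rs
}

gcn_init_params <- function(din, hidden) {
  gl <- function(a, b) matrix(rnorm(a * b, 0, sqrt(2 / (a + b))), a, b)
  list(l1 = list(W = gl(din, hidden), b = rep(0, hidden)),
       l2 = list(W = gl(hidden, hidden), b = rep(0, hidden)),
       out = list(W = gl(hidden, 4), b = rep(0, 4)))
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

gcn_forward <- function(params, graph, keep = FALSE) {
  X <- gcn_node_matrix(graph)
  Ah <- gcn_norm_adjacency(graph$adjacency)
  M1 <- Ah %*% X %*% params$l1$W
  M1 <- sweep(M1, 2, params$l1$b, `+`)
  H1 <- relu(M1)
  M2 <- Ah %*% H1 %*% params$l2$W
  M2 <- sweep(M2, 2, params$l2$b, `+`)
  H2 <- relu(M2)
  h <- colMeans(H2)
  z <- drop(h %*% params$out$W) + params$out$b
  p <- softmax(z)
  names(p) <- wsi_categories()
  out <- list(probs = p)
  if (keep) out$cache <- list(X = X, Ah = Ah, M1 = M1, H1 = H1, M2 = M2,
                              H2 = H2, h = h, z = z, p = p)
  out
}

# Gradient of the focal loss w.r.t. the logits, then backprop through mean
# pooling and the two message-passing layers.
gcn_backward <- function(params, cache, true_idx, gamma_f, alpha_c) {
  p <- unname(cache$p)
  pt <- max(p[true_idx], 1e-12)
  dL_dpt <- -alpha_c * (-gamma_f * (1 - pt)^(max(gamma_f - 1, 0)) * log(pt) +
                          (1 - pt)^gamma_f / pt)
  ind <- numeric(4); ind[true_idx] <- 1
  dz <- dL_dpt * pt * (ind - p)
  n <- nrow(cache$H2)
  g <- list()
  g$out <- list(W = unname(outer(unname(cache$h), dz)), b = unname(dz))
  dh <- drop(params$out$W %*% dz)
  dH2 <- matrix(rep(dh / n, each = n), n)
  dM2 <- dH2 * (cache$M2 > 0)
  AH1 <- cache$Ah %*% cache$H1
  g$l2 <- list(W = unname(t(AH1) %*% dM2), b = unname(colSums(dM2)))
  dH1 <- t(cache$Ah) %*% dM2 %*% t(params$l2$W)
  dM1 <- dH1 * (cache$M1 > 0)
  AX <- cache$Ah %*% cache$X
  g$l1 <- list(W = unname(t(AX) %*% dM1), b = unname(colSums(dM1)))
  g
}

#' Train the slide-level GCN
#'
#' Two message-passing layers (row-normalized adjacency with self-loops,
#' ReLU) followed by mean global pooling over nodes and a 4-way softmax
#' head, trained with focal loss and Adam. Pooling makes the prediction
#' invariant to node ordering.
#'
#' @param graphs List of `slide_graph` objects.
#' @param labels Character/factor vector of true categories, one per graph;
#'   every represented class needs at least one graph.
#' @param cfg A [gcn_train_config()].
#' @return An object of class `gcn_model` with the parameters, input
#'   dimension, focal-loss settings, per-epoch loss trace, seed and version.
#'   Deterministic for a fixed seed.
#' @export
train_gcn <- function(graphs, labels, cfg = gcn_train_config()) {
  stopifnot(inherits(cfg, "gcn_train_config"))
  if (length(graphs) < 1 || length(graphs) != length(labels))
    stop("need one label per graph")
  labels <- as.character(labels)
  if (!all(labels %in% wsi_categories())) stop("unknown label in labels")
  freq <- table(factor(labels, levels = wsi_categories()))
  present <- names(freq)[freq > 0]
  if (length(present) == 0) stop("no represented class")
  if (identical(cfg$alpha, "balanced")) {
    w <- ifelse(freq > 0, 1 / pmax(freq, 1), 0)
    alpha <- w / mean(w[w > 0])
  } else {
    alpha <- rep_len(1, 4); names(alpha) <- wsi_categories()
    alpha[names(cfg$alpha)] <- cfg$alpha
  }
  names(alpha) <- wsi_categories()
  din <- ncol(gcn_node_matrix(graphs[[1]]))
  with_local_seed(cfg$seed, {
    params <- gcn_init_params(din, cfg$hidden)
    state <- adam_init(params)
    t <- 0
    trace <- numeric(cfg$epochs)
    tidx <- match(labels, wsi_categories())
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(graphs))
      losses <- numeric(length(ord))
      for (k in seq_along(ord)) {
        i <- ord[k]
        fw <- gcn_forward(params, graphs[[i]], keep = TRUE)
        l <- focal_loss(fw$probs, labels[i], cfg$gamma_f, alpha[[tidx[i]]])
        if (!is.finite(l)) stop("non-finite focal loss; aborting")
        losses[k] <- l
        gr <- gcn_backward(params, fw$cache, tidx[i], cfg$gamma_f,
                           alpha[[tidx[i]]])
        t <- t + 1
        upd <- adam_step(params, gr, state, cfg$lr, t)
        params <- upd$params; state <- upd$state
      }
      trace[ep] <- mean(losses)
    }
    structure(list(params = params, din = din, hidden = cfg$hidden,
                   gamma_f = cfg$gamma_f, alpha = alpha, trace = trace,
                   seed = cfg$seed, version = "0.1.0"),
              class = "gcn_model")
  })
}

#' Four-tier probabilities for one slide graph
#'
#' @param model A `gcn_model`.
#' @param graph A `slide_graph` whose feature dimension matches the model.
#' @return Named numeric vector `(p_NED, p_LGD, p_HGD, p_IIN)` summing to 1
#'   within 1e-6; deterministic per model state and invariant to node
#'   permutation.
#' @export
predict_four_tier <- function(model, graph) {
  stopifnot(inherits(model, "gcn_model"), inherits(graph, "slide_graph"))
  if (ncol(gcn_node_matrix(graph)) != model$din)
    stop("graph feature dimension does not match the model")
  gcn_forward(model$params, graph)$probs
}

#' Four-tier call from a probability simplex
#'
#' Argmax over the four categories; exact ties are resolved toward the more
#' severe category (IIN > HGD > LGD > NED) to avoid under-calling
#' malignancy.
#'
#' @param probs Named simplex as returned by [predict_four_tier()].
#' @return One of `wsi_categories()`.
#' @export
classify_four_tier <- function(probs) {
  check_simplex(probs)
  probs <- probs[wsi_categories()]
  cand <- which(probs == max(probs))
  wsi_categories()[max(cand)]
}

#' Calibrate the NED-screening threshold
#'
#' Sets `t` to the maximum `p_NED` over positive (LGD/HGD/IIN) slides in
#' the calibration set. Under the screening rule "benign iff p_NED > t"
#' (strict), no positive slide can be screened out, so sensitivity for
#' positives and the negative predictive value are exactly 100% on the
#' calibration set, for any model quality; among all thresholds with this
#' guarantee, this `t` screens out the largest number of benign slides.
#'
#' @param p_ned Numeric vector of predicted NED probabilities.
#' @param positive Logical vector: `TRUE` where the slide's truth is
#'   positive (LGD, HGD or IIN). At least one positive is required.
#' @param set_id Optional calibration-set identifier stored as metadata.
#' @return An object of class `screening_config`: `t`, counts and metadata.
#' @export
calibrate_screening_threshold <- function(p_ned, positive, set_id = NULL) {
  stopifnot(length(p_ned) == length(positive))
  stopifnot_prob(p_ned, "p_ned")
  if (!any(positive)) stop("calibration refused: no positive slide, t undefined")
  t <- max(p_ned[positive])
  structure(list(t = t, n_positives = sum(positive),
                 n_benign = sum(!positive),
                 n_screened_out = sum(!positive & p_ned > t),
                 calibration_set = set_id, date = format(Sys.Date())),
            class = "screening_config")
}

#' Screening decision for one slide
#'
#' Benign (screened out) exactly when `p_NED > t`, strictly; a slide at the
#' threshold is retained for review.
#'
#' @param probs Named simplex (or a single `p_NED` value).
#' @param cfg A `screening_config` from [calibrate_screening_threshold()].
#' @return `"benign-screened-out"` or `"retained-for-review"`.
#' @export
screen_slide <- function(probs, cfg) {
  stopifnot(inherits(cfg, "screening_config"))
  p <- if (length(probs) == 1) probs else { check_simplex(probs); probs[["NED"]] }
  if (p > cfg$t) "benign-screened-out" else "retained-for-review"
}

#' Save / load the screening configuration as JSON
#' @param cfg A `screening_config`.
#' @param path JSON path.
#' @export
write_screening_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "screening_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_screening_config
#' @export
read_screening_config <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "screening_config")
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf("<gcn_model> input dim %d, hidden %d, final focal loss %.4f\n",
              x$din, x$hidden, x$trace[length(x$trace)]))
  invisible(x)
}
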