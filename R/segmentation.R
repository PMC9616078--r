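#' Soft dice loss
#'
#' `1 - 2*sum(p*g) / (sum(p^2) + sum(g^2) + eps)` with `eps = 1e-6`. Equals
#' ~0 for a perfect binary prediction and 1 for disjoint prediction and
#' target.
#'
#' @param pred Numeric raster of probabilities in `[0, 1]`.
#' @param target Binary raster of the same shape.
#' @param eps Stabilizer added to the denominator.
#' @return Loss value in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, eps = 1e-6) {
  if (!identical(dim(pred), dim(target)) ||
      length(pred) != length(target))
    stop("pred and target must have the same shape")
  stopifnot_prob(pred, "pred")
  if (!all(target %in% c(0, 1))) stop("target must be binary")
  1 - 2 * sum(pred * target) / (sum(pred^2) + sum(target^2) + eps)
}

dice_loss_grad <- function(pred, target, eps = 1e-6) {
  s1 <- sum(pred * target)
  s2 <- sum(pred^2) + sum(target^2) + eps
  (-2 * target * s2 + 4 * s1 * pred) / s2^2
}

#' Segmenter training configuration
#'
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs Number of passes over the training patches.
#' @param batch_size Patches per gradient step.
#' @param seed Integer seed controlling initialization and shuffling.
#' @param augment Optional [augment_config()] applied to training patches.
#' @return An object of class `seg_train_config`.
#' @export
seg_train_config <- function(lr = 1e-3, epochs = 5, batch_size = 8,
                             seed = 1L, augment = NULL) {
  if (lr <= 0) stop("learning rate must be positive")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 augment = augment),
            class = "seg_train_config")
}

# ---- network definition -----------------------------------------------

seg_arch <- function(patch_size = 128, levels = 3, width = 8) {
  widths <- width * 2^(seq_len(levels) - 1)
  list(patch_size = as.integer(patch_size), levels = as.integer(levels),
       width = as.integer(width), widths = as.integer(widths),
       d = as.integer(widths[levels]))
}

seg_init_params <- function(arch) {
  he <- function(k, cin, cout)
    matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
           k * k * cin, cout)
  L <- arch$levels; wd <- arch$widths
  p <- list()
  cin <- 3L
  for (i in seq_len(L)) {
    p[[paste0("enc", i)]] <- list(W = he(3, cin, wd[i]), b = rep(0, wd[i]))
    cin <- wd[i]
  }
  for (i in seq_len(L - 1)) {
    p[[paste0("dec", i)]] <- list(W = he(3, wd[i + 1] + wd[i], wd[i]),
                                  b = rep(0, wd[i]))
  }
  # head starts small and biased negative: abnormal pixels are the minority
  # class, so the untrained network leans firmly toward background
  p$head <- list(W = he(1, wd[1], 1) * 0.1, b = -2)
  p
}

relu <- function(x) { x[x < 0] <- 0; x }

cat_channels <- function(a, b)
  array(c(a, b), dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))

# Forward pass; x is an H x W x 3 array on the 0..1 scale. Returns the
# probability map, the global-average-pooled bottleneck feature and, when
# keep = TRUE, the caches needed for backprop.
seg_forward <- function(params, arch, x, keep = FALSE) {
  L <- arch$levels; wd <- arch$widths
  enc_in <- vector("list", L); enc_mask <- vector("list", L)
  a <- vector("list", L)
  cur <- x
  for (i in seq_len(L)) {
    enc_in[[i]] <- cur
    z <- cpp_conv2d_fw(cur, params[[paste0("enc", i)]]$W,
                       params[[paste0("enc", i)]]$b, 3L)
    if (keep) enc_mask[[i]] <- z > 0
    a[[i]] <- relu(z)
    if (i < L) cur <- cpp_avgpool2_fw(a[[i]])
  }
  bottleneck <- a[[L]]
  feature <- apply(bottleneck, 3, mean)

  dec_in <- vector("list", L - 1); dec_mask <- vector("list", L - 1)
  u <- bottleneck
  for (i in rev(seq_len(L - 1))) {
    up <- cpp_upsample2_fw(u)
    cat_i <- cat_channels(up, a[[i]])
    dec_in[[i]] <- if (keep) cat_i else NULL
    z <- cpp_conv2d_fw(cat_i, params[[paste0("dec", i)]]$W,
                       params[[paste0("dec", i)]]$b, 3L)
    if (keep) dec_mask[[i]] <- z > 0
    u <- relu(z)
  }
  head_in <- u
  zh <- cpp_conv2d_fw(u, params$head$W, params$head$b, 1L)
  prob <- 1 / (1 + exp(-zh[, , 1]))
  out <- list(prob = prob, feature = feature)
  if (keep)
    out$cache <- list(enc_in = enc_in, enc_mask = enc_mask, a = a,
                      dec_in = dec_in, dec_mask = dec_mask,
                      head_in = head_in, prob = prob)
  out
}

# Backward pass from dL/dprob; returns gradients with the same structure as
# the parameter list.
seg_backward <- function(params, arch, cache, gprob) {
  L <- arch$levels; wd <- arch$widths
  g <- list()
  p <- cache$prob
  gz_head <- array(gprob * p * (1 - p), dim = c(dim(p), 1L))
  bwh <- cpp_conv2d_bw(cache$head_in, params$head$W, gz_head, 1L)
  g$head <- list(W = bwh$gW, b = bwh$gb)
  g_u <- bwh$gx

  g_a <- vector("list", L)
  for (i in seq_len(L - 1)) {
    gz <- g_u * cache$dec_mask[[i]]
    bw <- cpp_conv2d_bw(cache$dec_in[[i]], params[[paste0("dec", i)]]$W, gz, 3L)
    g[[paste0("dec", i)]] <- list(W = bw$gW, b = bw$gb)
    cup <- wd[i + 1]
    g_up <- bw$gx[, , seq_len(cup), drop = FALSE]
    g_a[[i]] <- bw$gx[, , cup + seq_len(wd[i]), drop = FALSE]
    g_u <- cpp_upsample2_bw(g_up)
  }
  g_a[[L]] <- g_u

  for (i in rev(seq_len(L))) {
    gz <- g_a[[i]] * cache$enc_mask[[i]]
    bw <- cpp_conv2d_bw(cache$enc_in[[i]], params[[paste0("enc", i)]]$W, gz, 3L)
    g[[paste0("enc", i)]] <- list(W = bw$gW, b = bw$gb)
    if (i > 1) g_a[[i - 1]] <- g_a[[i - 1]] + cpp_avgpool2_bw(bw$gx)
  }
  g
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params)
  lapply(params, function(l) lapply(l, function(x) list(m = x * 0, v = x * 0)))

adam_step <- function(params, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    for (f in names(params[[nm]])) {
      gr <- grads[[nm]][[f]]
      st <- state[[nm]][[f]]
      st$m <- b1 * st$m + (1 - b1) * gr
      st$v <- b2 * st$v + (1 - b2) * gr^2
      mh <- st$m / (1 - b1^t)
      vh <- st$v / (1 - b2^t)
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * mh / (sqrt(vh) + eps)
      state[[nm]][[f]] <- st
    }
  }
  list(params = params, state = state)
}

# ---- training / inference --------------------------------------------

binarize_labels <- function(labels) (labels >= 2) * 1

#' Train the patch segmenter
#'
#' Trains a small V-Net-style 2-D encoder--decoder (default 3 levels,
#' base width 8, bottleneck/feature dimension 32) with the soft dice loss
#' and the Adam optimizer to predict, per pixel, the probability that
#' tissue is abnormal (LGD, HGD or IIN; mask labels 2--4). The network is
#' fully convolutional, so any patch size divisible by `2^(levels-1)` works.
#'
#' @param patches List of training patches: each element needs `img`
#'   (`P x P x 3`, 0..255) and `labels` (integer label matrix 0..4, or an
#'   already-binary abnormal mask).
#' @param cfg A [seg_train_config()].
#' @param arch Optional architecture override from `seg_arch()`
#'   (patch_size, levels, width).
#' @return An object of class `seg_model`: parameters, architecture,
#'   per-epoch mean dice loss trace, seed and version tag. Training is
#'   deterministic for a fixed seed.
#' @export
train_segmenter <- function(patches, cfg = seg_train_config(), arch = NULL) {
  if (length(patches) < 1) stop("need at least one training pair")
  stopifnot(inherits(cfg, "seg_train_config"))
  P <- dim(patches[[1]]$img)[1]
  arch <- arch %||% seg_arch(patch_size = P)
  if (P %% 2^(arch$levels - 1) != 0)
    stop("patch size must be divisible by 2^(levels-1)")
  with_local_seed(cfg$seed, {
    params <- seg_init_params(arch)
    state <- adam_init(params)
    t <- 0
    trace <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(patches))
      ep_losses <- numeric(0)
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        grads <- NULL
        bl <- 0
        for (j in idx) {
          pt <- patches[[j]]
          if (!is.null(cfg$augment))
            pt <- augment_patch(pt, cfg$augment,
                                seed = child_seed(cfg$seed, ep * 1e5 + j))
          x <- pt$img / 255
          gmask <- binarize_labels(pt$labels)
          fw <- seg_forward(params, arch, x, keep = TRUE)
          l <- dice_loss(fw$prob, gmask)
          if (!is.finite(l))
            stop("non-finite dice loss at epoch ", ep, "; aborting")
          bl <- bl + l
          gp <- dice_loss_grad(fw$prob, gmask) / length(idx)
          gr <- seg_backward(params, arch, fw$cache, gp)
          grads <- if (is.null(grads)) gr else
            mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                   grads, gr, SIMPLIFY = FALSE)
        }
        t <- t + 1
        upd <- adam_step(params, grads, state, cfg$lr, t)
        params <- upd$params; state <- upd$state
        ep_losses <- c(ep_losses, bl / length(idx))
      }
      trace[ep] <- mean(ep_losses)
    }
    structure(list(params = params, arch = arch, trace = trace,
                   seed = cfg$seed, version = "0.1.0"),
              class = "seg_model")
  })
}

#' Run the segmenter on one patch
#'
#' @param model A `seg_model` from [train_segmenter()].
#' @param patch A patch from [tile_slide()] or a bare `P x P x 3` array
#'   (0..255).
#' @return List with `prob` (P x P probability map in `[0, 1]`) and
#'   `feature` (the global-average-pooled bottleneck activation, length
#'   `model$arch$d`). Deterministic for a fixed model state.
#' @export
infer_patch <- function(model, patch) {
  stopifnot(inherits(model, "seg_model"))
  img <- if (is.array(patch)) patch else patch$img
  if (dim(img)[1] %% 2^(model$arch$levels - 1) != 0)
    stop("patch size does not match the model's downsampling factor")
  fw <- seg_forward(model$params, model$arch, img / 255, keep = FALSE)
  list(prob = fw$prob, feature = fw$feature)
}

#' Stitch per-patch probability maps into a slide-level map
#'
#' Each canvas block is set to its source patch's values, pixel-exact, with
#' no interpolation or blending; grid cells whose patches were dropped at
#' tiling time are left at probability 0.
#'
#' @param maps List of P x P probability matrices.
#' @param index Data frame with one row per map: columns `x0`, `y0` (0-based
#'   patch origins, multiples of P).
#' @param canvas_dim Integer `c(H, W)` of the padded canvas.
#' @return Numeric `H x W` matrix in `[0, 1]`.
#' @export
stitch_probability_map <- function(maps, index, canvas_dim) {
  H <- canvas_dim[1]; W <- canvas_dim[2]
  out <- matrix(0, H, W)
  if (length(maps) == 0) return(out)
  P <- nrow(maps[[1]])
  filled <- matrix(FALSE, max(1L, H %/% P), max(1L, W %/% P))
  for (i in seq_along(maps)) {
    x0 <- index$x0[i]; y0 <- index$y0[i]
    if (x0 %% P != 0 || y0 %% P != 0)
      stop("patch origin is not aligned to the grid")
    if (y0 + P > H || x0 + P > W || x0 < 0 || y0 < 0)
      stop("patch falls outside the canvas")
    r <- y0 %/% P + 1L; cc <- x0 %/% P + 1L
    if (filled[r, cc]) stop("overlapping patches at grid cell (", r, ",", cc, ")")
    filled[r, cc] <- TRUE
    out[y0 + seq_len(P), x0 + seq_len(P)] <- maps[[i]]
  }
  out
}

#' Segment a whole slide: tile, infer, stitch
#'
#' Convenience wrapper running the segmenter over every retained patch of a
#' slide and returning per-patch maps, features and abnormality grades plus
#' the stitched slide-level probability map.
#'
#' @param model A `seg_model`.
#' @param image Slide image array (0..255); ignored when `patches` is
#'   supplied.
#' @param mask Tissue mask (or `NULL` to compute one).
#' @param patch_size,min_tissue_fraction Tiling parameters.
#' @param slide_id Identifier.
#' @param patches Optional pre-tiled `patch_set` (skips masking/tiling).
#' @return List with `patches` (the `patch_set`), `maps`, `features`
#'   (matrix n x d), `grades`, `index` (patch grid positions), `stitched`
#'   and `canvas`.
#' @export
infer_slide <- function(model, image = NULL, mask = NULL, patch_size = 128,
                        min_tissue_fraction = 0.05, slide_id = "slide",
                        patches = NULL) {
  if (is.null(patches)) {
    if (is.null(mask)) mask <- extract_tissue_mask(image)
    patches <- tile_slide(image, mask, patch_size = patch_size,
                          min_tissue_fraction = min_tissue_fraction,
                          slide_id = slide_id)
  }
  n <- length(patches)
  if (n == 0)
    return(list(patches = patches, maps = list(),
                features = matrix(0, 0, model$arch$d), grades = numeric(0),
                index = data.frame(), stitched = matrix(0, attr(patches, "canvas")[1],
                                                        attr(patches, "canvas")[2]),
                canvas = attr(patches, "canvas")))
  maps <- vector("list", n)
  feats <- matrix(0, n, model$arch$d)
  for (i in seq_len(n)) {
    r <- infer_patch(model, patches[[i]])
    maps[[i]] <- r$prob
    feats[i, ] <- r$feature
  }
  index <- data.frame(row = vapply(patches, `[[`, integer(1), "row"),
                      col = vapply(patches, `[[`, integer(1), "col"),
                      x0 = vapply(patches, `[[`, integer(1), "x0"),
                      y0 = vapply(patches, `[[`, integer(1), "y0"))
  grades <- vapply(maps, abnormality_grade, numeric(1))
  list(patches = patches, maps = maps, features = feats, grades = grades,
       index = index,
       stitched = stitch_probability_map(maps, index, attr(patches, "canvas")),
       canvas = attr(patches, "canvas"))
}

#' Save / load a segmenter model
#'
#' The parameter blob is written as a flat binary of doubles with a JSON
#' sidecar describing the architecture, seed and version.
#'
#' @param model A `seg_model`.
#' @param path Output path for the binary blob; the sidecar gets `.json`
#'   appended.
#' @export
save_seg_model <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  flat <- unlist(lapply(model$params, function(l) c(l$W, l$b)))
  writeBin(as.numeric(flat), path)
  shapes <- lapply(model$params, function(l) list(W = dim(l$W), b = length(l$b)))
  jsonlite::write_json(list(arch = model$arch, seed = model$seed,
                            version = model$version, trace = model$trace,
                            shapes = shapes),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_seg_model
#' @return `load_seg_model()` returns the restored `seg_model`, which
#'   reproduces identical outputs on identical inputs.
#' @export
load_seg_model <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- readBin(path, "numeric", n = file.size(path) / 8)
  params <- list(); pos <- 0
  for (nm in names(meta$shapes)) {
    dW <- meta$shapes[[nm]]$W; nb <- meta$shapes[[nm]]$b
    nW <- prod(dW)
    W <- matrix(flat[pos + seq_len(nW)], dW[1], dW[2]); pos <- pos + nW
    b <- flat[pos + seq_len(nb)]; pos <- pos + nb
    params[[nm]] <- list(W = W, b = b)
  }
  arch <- meta$arch
  arch[c("patch_size", "levels", "width", "widths", "d")] <-
    lapply(arch[c("patch_size", "levels", "width", "widths", "d")], as.integer)
  structure(list(params = params, arch = arch, trace = meta$trace,
                 seed = meta$seed, version = meta$version),
            class = "seg_model")
}
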