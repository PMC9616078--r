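#' Fit the two-step whole-slide classifier
#'
#' End-to-end training of the two-stage system on a slide manifest:
#' \enumerate{
#'   \item tissue masking and stain normalization of every slide toward
#'     target channel statistics averaged over the training slides;
#'   \item training of the patch segmenter (dice loss) on patches sampled
#'     from the annotated label masks;
#'   \item inference over all patches of every slide, top-n discriminative
#'     patch selection, slide-graph construction with the Chebyshev edge
#'     rule;
#'   \item training of the slide-level GCN (focal loss) on the graphs.
#' }
#'
#' Slides are streamed from disk, so memory stays flat in the number of
#' slides.
#'
#' @param manifest Manifest `data.frame` (or CSV path) with columns
#'   `slide_id`, `image_path`, `mask_path`, `center`, `label`.
#' @param patch_size Patch side in pixels.
#' @param min_tissue_fraction Tiling drop threshold.
#' @param normalize Apply stain normalization (default `TRUE`).
#' @param seg_cfg A [seg_train_config()].
#' @param gcn_cfg A [gcn_train_config()].
#' @param graph_cfg A [graph_config()].
#' @param seg_patches_per_slide Number of lesion-bearing patches sampled
#'   per non-NED slide (plus one random tissue patch; NED slides contribute
#'   two random tissue patches).
#' @param max_seg_patches Cap on the total segmenter training set.
#' @param seed Master seed; the stage seeds in `seg_cfg`/`gcn_cfg` are
#'   derived from it unless those configs were passed explicitly.
#' @param verbose Print stage progress.
#' @return An object of class `wsi_model` bundling the fitted segmenter,
#'   the fitted GCN, the stain-normalization target statistics and the
#'   preprocessing/graph configuration, with `print()`, `summary()`,
#'   `predict()` and `plot()` methods.
#' @seealso [predict.wsi_model()], [calibrate_screening()]
#' @export
wsi_train <- function(manifest, patch_size = 128, min_tissue_fraction = 0.05,
                      normalize = TRUE,
                      seg_cfg = NULL, gcn_cfg = NULL,
                      graph_cfg = graph_config(),
                      seg_patches_per_slide = 2, max_seg_patches = 320,
                      seed = 1L, verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(nrow(manifest) >= 1)
  seg_cfg <- seg_cfg %||% seg_train_config(seed = child_seed(seed, 1))
  gcn_cfg <- gcn_cfg %||% gcn_train_config(seed = child_seed(seed, 2))
  say <- function(...) if (verbose) message(sprintf(...))

  # pass 1: tissue masks, per-slide channel statistics, segmenter patch
  # sampling (raw patches; normalized once target statistics are known)
  say("pass 1: channel statistics and segmenter patches (%d slides)",
      nrow(manifest))
  n_sl <- nrow(manifest)
  src_stats <- vector("list", n_sl)
  keep_idx <- vector("list", n_sl)     # retained patch grid indices
  keep_tf <- vector("list", n_sl)      # their tissue fractions
  seg_patches <- list()
  seg_patch_slide <- integer(0)
  for (i in seq_len(n_sl)) {
    img <- read_slide_image(manifest$image_path[i])
    lab <- read_label_mask(manifest$mask_path[i])
    tm <- extract_tissue_mask(img)
    if (tm$tissue_fraction > 0)
      src_stats[[i]] <- compute_channel_stats(img, tm, "source")
    pt <- tile_slide(img, tm, label_mask = lab, patch_size = patch_size,
                     min_tissue_fraction = 0, slide_id = manifest$slide_id[i])
    tf <- vapply(pt, `[[`, numeric(1), "tissue_fraction")
    keep <- which(tf >= min_tissue_fraction)
    keep_idx[[i]] <- keep
    keep_tf[[i]] <- tf[keep]
    if (length(keep) == 0) next
    abfrac <- vapply(pt[keep], function(p) mean(p$labels >= 2), numeric(1))
    take <- with_local_seed(child_seed(seed, i, salt = 3L), {
      sel <- integer(0)
      if (manifest$label[i] != "NED" && any(abfrac > 0.02)) {
        sel <- order(-abfrac)[seq_len(min(seg_patches_per_slide,
                                          sum(abfrac > 0.02)))]
      }
      extra <- setdiff(seq_along(keep), sel)
      n_extra <- if (manifest$label[i] == "NED") 2L else 1L
      if (length(extra)) sel <- c(sel, sample(extra, min(n_extra,
                                                         length(extra))))
      sel
    })
    seg_patches <- c(seg_patches, pt[keep[take]])
    seg_patch_slide <- c(seg_patch_slide, rep(i, length(take)))
  }
  kept_stats <- Filter(Negate(is.null), src_stats)
  if (length(kept_stats) == 0) stop("no tissue found in any training slide")
  agg <- Reduce(`+`, lapply(kept_stats, function(s) cbind(s$mean, s$sd))) /
    length(kept_stats)
  target_stats <- structure(data.frame(channel = c("R", "G", "B"),
                                       mean = agg[, 1], sd = agg[, 2]),
                            role = "target",
                            class = c("channel_stats", "data.frame"))
  if (length(seg_patches) > max_seg_patches) {
    keep <- with_local_seed(child_seed(seed, 0, salt = 4L),
                            sort(sample(seq_along(seg_patches),
                                        max_seg_patches)))
    seg_patches <- seg_patches[keep]
    seg_patch_slide <- seg_patch_slide[keep]
  }
  if (normalize) {
    for (k in seq_along(seg_patches)) {
      st <- src_stats[[seg_patch_slide[k]]]
      if (is.null(st) || any(st$sd <= 0)) next
      seg_patches[[k]]$img <- normalize_stain(seg_patches[[k]]$img,
                                              mask = NULL, target_stats,
                                              source = st)
    }
  }
  say("training segmenter on %d patches", length(seg_patches))
  seg <- train_segmenter(seg_patches, seg_cfg,
                         arch = seg_arch(patch_size = patch_size))

  # pass 2: per-slide inference and graph construction (normalization
  # reuses the per-slide statistics from pass 1)
  say("pass 2: building slide graphs")
  graphs <- vector("list", n_sl)
  for (i in seq_len(n_sl)) {
    if (length(keep_idx[[i]]) == 0)
      stop("no tissue patches in slide ", manifest$slide_id[i])
    img <- read_slide_image(manifest$image_path[i])
    if (normalize && !is.null(src_stats[[i]]) && all(src_stats[[i]]$sd > 0))
      img <- normalize_stain(img, mask = NULL, target_stats,
                             source = src_stats[[i]])
    pt <- tile_slide(img, NULL, patch_size = patch_size,
                     min_tissue_fraction = 0,
                     slide_id = manifest$slide_id[i])
    sub <- pt[keep_idx[[i]]]
    for (k in seq_along(sub)) sub[[k]]$tissue_fraction <- keep_tf[[i]][k]
    attr(sub, "canvas") <- attr(pt, "canvas")
    attr(sub, "patch_size") <- attr(pt, "patch_size")
    class(sub) <- "patch_set"
    inf <- infer_slide(seg, img, patches = sub,
                       slide_id = manifest$slide_id[i])
    graphs[[i]] <- slide_graph_from_inference(inf, graph_cfg,
                                              slide_id = manifest$slide_id[i])
  }
  say("training GCN on %d graphs", length(graphs))
  gcn <- train_gcn(graphs, manifest$label, gcn_cfg)

  structure(list(seg = seg, gcn = gcn, target_stats = target_stats,
                 patch_size = as.integer(patch_size),
                 min_tissue_fraction = min_tissue_fraction,
                 normalize = normalize, graph_cfg = graph_cfg,
                 seg_cfg = seg_cfg, gcn_cfg = gcn_cfg,
                 n_train = nrow(manifest),
                 train_labels = table(factor(manifest$label,
                                             wsi_categories())),
                 seed = seed),
            class = "wsi_model")
}

# Shared inference path: slide image -> normalized -> graph -> simplex.
wsi_slide_probs <- function(object, image, slide_id = "slide",
                            return_graph = FALSE) {
  tm <- extract_tissue_mask(image)
  if (object$normalize && tm$tissue_fraction > 0)
    image <- normalize_stain(image, tm, object$target_stats)
  inf <- infer_slide(object$seg, image, tm, object$patch_size,
                     object$min_tissue_fraction, slide_id = slide_id)
  if (length(inf$maps) == 0) stop("no tissue patches in slide ", slide_id)
  g <- slide_graph_from_inference(inf, object$graph_cfg, slide_id = slide_id)
  p <- predict_four_tier(object$gcn, g)
  if (return_graph) list(probs = p, graph = g, inference = inf) else p
}

#' Predict four-tier probabilities, calls and screening decisions
#'
#' Runs the full pipeline (normalize, segment, graph, GCN) on every slide
#' of a manifest.
#'
#' @param object A fitted `wsi_model`.
#' @param manifest Manifest `data.frame` or CSV path; only `slide_id` and
#'   `image_path` are required.
#' @param screening Optional `screening_config`; adds the NED-screening
#'   decision per slide.
#' @param ... Unused.
#' @return A `data.frame` with columns `slide_id`, `p_NED`, `p_LGD`,
#'   `p_HGD`, `p_IIN`, `call` and, when screening is requested,
#'   `screened_out`.
#' @export
predict.wsi_model <- function(object, manifest, screening = NULL, ...) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    img <- read_slide_image(manifest$image_path[i])
    p <- wsi_slide_probs(object, img, manifest$slide_id[i])
    rows[[i]] <- data.frame(slide_id = manifest$slide_id[i],
                            p_NED = p[["NED"]], p_LGD = p[["LGD"]],
                            p_HGD = p[["HGD"]], p_IIN = p[["IIN"]],
                            call = classify_four_tier(p),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if ("center" %in% names(manifest)) out$center <- manifest$center
  if (!is.null(screening))
    out$screened_out <- out$p_NED > screening$t
  out
}

#' Calibrate the NED-screening threshold from a manifest
#'
#' Predicts `p_NED` for every calibration slide and sets the screening
#' threshold to the maximum `p_NED` over positive (non-NED) slides, so that
#' sensitivity for positives and NPV are exactly 100% on this set.
#'
#' @param object A fitted `wsi_model`.
#' @param manifest Calibration manifest (needs truth `label`).
#' @param set_id Optional identifier stored in the config.
#' @return A `screening_config`; the prediction table is attached as
#'   attribute `predictions`.
#' @export
calibrate_screening <- function(object, manifest, set_id = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  preds <- predict(object, manifest)
  cfg <- calibrate_screening_threshold(preds$p_NED,
                                       manifest$label != "NED", set_id)
  attr(cfg, "predictions") <- preds
  cfg
}

#' @export
print.wsi_model <- function(x, ...) {
  cat("Two-step whole-slide classifier (segmenter + patch-graph GCN)\n")
  cat(sprintf("  trained on %d slides (%s)\n", x$n_train,
              paste(sprintf("%s=%d", names(x$train_labels), x$train_labels),
                    collapse = ", ")))
  cat(sprintf("  patch %d px, min tissue %.2f, stain normalization %s\n",
              x$patch_size, x$min_tissue_fraction,
              if (x$normalize) "on" else "off"))
  cat(sprintf("  segmenter: %d levels, width %d, feature dim %d; final dice loss %.4f\n",
              x$seg$arch$levels, x$seg$arch$width, x$seg$arch$d,
              x$seg$trace[length(x$seg$trace)]))
  cat(sprintf("  graph: top n = %d, gamma = %s; GCN hidden %d, final focal loss %.4f\n",
              x$graph_cfg$n, format(x$graph_cfg$gamma), x$gcn$hidden,
              x$gcn$trace[length(x$gcn$trace)]))
  invisible(x)
}

#' @export
summary.wsi_model <- function(object, ...) {
  print(object)
  cat("\nStain-normalization target statistics:\n")
  print(object$target_stats, row.names = FALSE)
  cat("\nSegmenter dice-loss trace:\n")
  print(round(object$seg$trace, 4))
  cat("GCN focal-loss trace (last 10 epochs):\n")
  print(round(utils::tail(object$gcn$trace, 10), 4))
  invisible(object)
}

#' @export
plot.wsi_model <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(x$seg$trace, type = "b", xlab = "epoch", ylab = "mean dice loss",
       main = "Segmenter training")
  plot(x$gcn$trace, type = "l", xlab = "epoch", ylab = "mean focal loss",
       main = "GCN training")
  invisible(x)
}

#' Render a stitched probability map as a heatmap PNG
#'
#' Trivial export for review: probability 0 maps to white, 1 to saturated
#' red.
#'
#' @param map Probability matrix in `[0, 1]`.
#' @param path Output PNG path.
#' @export
write_heatmap <- function(map, path) {
  stopifnot_prob(map, "map")
  h <- dim(map)[1]; w <- dim(map)[2]
  img <- array(1, dim = c(h, w, 3))
  img[, , 2] <- 1 - map
  img[, , 3] <- 1 - map
  png::writePNG(img, path)
  invisible(path)
}
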