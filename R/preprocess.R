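#' Extract a tissue mask by automatic thresholding
#'
#' Tissue is separated from the near-white background by Otsu thresholding
#' of the saturation channel (near-white pixels have saturation close to 0,
#' stained tissue does not), followed by removal of connected components
#' smaller than `min_object_px` pixels.
#'
#' @param image Numeric array `h x w x 3`, values 0..255.
#' @param min_object_px Connected components smaller than this are dropped.
#' @return An object of class `tissue_mask`: list with `mask` (logical
#'   matrix) and `tissue_fraction`. A degenerate single-valued image yields
#'   an empty mask with a warning.
#' @export
extract_tissue_mask <- function(image, min_object_px = 64) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  sat <- cpp_saturation(image)
  if (diff(range(sat)) < 1e-8) {
    warning("degenerate image: saturation is constant; returning empty mask")
    return(structure(list(mask = matrix(FALSE, h, w), tissue_fraction = 0),
                     class = "tissue_mask"))
  }
  thr <- EBImage::otsu(EBImage::Image(sat), range = c(0, 1))
  mask <- sat > thr
  # Otsu always splits; when the two sides are not genuinely different
  # (slide with no background, or background only) fall back to an absolute
  # saturation floor: near-white background sits well below it.
  if (!any(mask) || all(mask) ||
      mean(sat[mask]) - mean(sat[!mask]) < 0.08) mask <- sat > 0.1
  if (min_object_px > 0) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= min_object_px)
    mask <- matrix(as.integer(lab) %in% keep, h, w)
  }
  structure(list(mask = mask, tissue_fraction = mean(mask)),
            class = "tissue_mask")
}

#' Per-channel tissue color statistics
#'
#' Computes the mean and standard deviation of each RGB channel over tissue
#' pixels. With `role = "source"` a single slide is summarized; with
#' `role = "target"` the statistics are the average over slides of the
#' per-slide tissue-pixel means and standard deviations, as used for the
#' stain-normalization target.
#'
#' @param images A single image array or list of image arrays (0..255).
#' @param masks Matching logical tissue matrix or list thereof (a
#'   `tissue_mask` object is also accepted).
#' @param role `"source"` (one slide) or `"target"` (average over slides).
#' @return An object of class `channel_stats`: data.frame with columns
#'   `channel`, `mean`, `sd` and a `role` attribute.
#' @export
compute_channel_stats <- function(images, masks, role = c("source", "target")) {
  role <- match.arg(role)
  if (!is.list(images) || length(dim(images[[1]])) != 3)
    if (length(dim(images)) == 3) { images <- list(images); masks <- list(masks) }
  stopifnot(length(images) == length(masks))
  if (role == "source" && length(images) != 1)
    stop("source statistics summarize exactly one slide")
  per_slide <- lapply(seq_along(images), function(i) {
    m <- masks[[i]]
    if (inherits(m, "tissue_mask")) m <- m$mask
    if (!any(m)) return(NULL)
    vapply(1:3, function(c) {
      v <- images[[i]][, , c][m]
      c(mean(v), if (length(v) > 1) sd(v) else 0)
    }, numeric(2))
  })
  per_slide <- Filter(Negate(is.null), per_slide)
  if (length(per_slide) == 0) stop("no tissue pixels in any slide")
  agg <- Reduce(`+`, per_slide) / length(per_slide)
  structure(data.frame(channel = c("R", "G", "B"),
                       mean = agg[1, ], sd = agg[2, ]),
            role = role, class = c("channel_stats", "data.frame"))
}

#' Stain normalization by channel-wise linear transfer
#'
#' Each channel of the whole image is linearly mapped so that the source
#' tissue statistics `(mu, sigma)` become the target statistics
#' `(mu_T, sigma_T)`:
#' \deqn{Z = (X - \mu)/\sigma \cdot \sigma_T + \mu_T}
#' applied independently per channel, then the channels are merged and the
#' result clipped to 0..255. Statistics are computed over tissue pixels, but
#' the transform is applied to every pixel of the image.
#'
#' @param image Numeric array `h x w x 3`, 0..255.
#' @param mask Tissue mask (logical matrix or `tissue_mask`) used to compute
#'   source statistics; may be `NULL` when `source` is supplied.
#' @param target Target [channel_stats][compute_channel_stats].
#' @param source Optional source statistics; computed from `image`/`mask`
#'   when omitted. All source standard deviations must be positive.
#' @return Normalized image array (0..255, rounded).
#' @export
normalize_stain <- function(image, mask, target, source = NULL) {
  if (is.null(source)) source <- compute_channel_stats(image, mask, "source")
  if (any(source$sd <= 0))
    stop("degenerate source: channel standard deviation is zero")
  a <- target$sd / source$sd
  b <- target$mean - source$mean * a
  cpp_affine_clip255(image, a, b)
}

#' Tile a slide into a non-overlapping patch grid
#'
#' The slide is padded right/bottom with background white (255) to a
#' multiple of `patch_size`, cut into a row-major grid of `patch_size` x
#' `patch_size` patches, and patches whose tissue fraction falls below
#' `min_tissue_fraction` are dropped. Patch origins are 0-based, half-open,
#' x rightward and y downward.
#'
#' @param image Numeric array `h x w x 3`, 0..255.
#' @param mask Logical tissue matrix or `tissue_mask` (used for tissue
#'   fractions); `NULL` means all pixels count as tissue.
#' @param label_mask Optional integer label matrix carried along (cropped
#'   with each patch) for segmenter training.
#' @param patch_size Patch side P (>= 16).
#' @param min_tissue_fraction Patches below this tissue fraction are dropped.
#' @param slide_id Identifier stored on each patch.
#' @return List of class `patch_set`: elements are patches (lists with
#'   `slide_id`, `row`, `col`, `x0`, `y0`, `img`, `tissue_fraction`,
#'   optionally `labels`); attributes `canvas` (padded h, w) and
#'   `patch_size`.
#' @export
tile_slide <- function(image, mask = NULL, label_mask = NULL,
                       patch_size = 128, min_tissue_fraction = 0.05,
                       slide_id = "slide") {
  P <- as.integer(patch_size)
  if (P < 16) stop("patch_size must be >= 16")
  h <- dim(image)[1]; w <- dim(image)[2]
  if (inherits(mask, "tissue_mask")) mask <- mask$mask
  nr <- max(1L, as.integer(ceiling(h / P)))
  nc <- max(1L, as.integer(ceiling(w / P)))
  H <- nr * P; W <- nc * P
  canvas <- array(255, dim = c(H, W, 3))
  canvas[1:h, 1:w, ] <- image
  mcanvas <- matrix(FALSE, H, W)
  mcanvas[1:h, 1:w] <- if (is.null(mask)) TRUE else mask
  lcanvas <- NULL
  if (!is.null(label_mask)) {
    lcanvas <- matrix(0L, H, W)
    lcanvas[1:h, 1:w] <- label_mask
  }
  patches <- list(); k <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      ys <- ((r - 1L) * P + 1L):(r * P)
      xs <- ((cc - 1L) * P + 1L):(cc * P)
      tf <- mean(mcanvas[ys, xs])
      if (tf < min_tissue_fraction) next
      k <- k + 1L
      p <- list(slide_id = slide_id, row = r - 1L, col = cc - 1L,
                x0 = (cc - 1L) * P, y0 = (r - 1L) * P,
                img = canvas[ys, xs, , drop = FALSE], tissue_fraction = tf)
      if (!is.null(lcanvas)) p$labels <- lcanvas[ys, xs]
      patches[[k]] <- p
    }
  }
  structure(patches, canvas = c(H, W), patch_size = P, class = "patch_set")
}

#' Reassemble tiled patches onto the padded canvas
#'
#' Inverse of [tile_slide()] at threshold 0: places each patch back at its
#' origin. Grid cells without a patch are filled with background white.
#'
#' @param patches A `patch_set` from [tile_slide()].
#' @return Numeric array (padded canvas, 0..255).
#' @export
reassemble_patches <- function(patches) {
  canvas_dim <- attr(patches, "canvas"); P <- attr(patches, "patch_size")
  out <- array(255, dim = c(canvas_dim, 3))
  for (p in patches) {
    out[p$y0 + seq_len(P), p$x0 + seq_len(P), ] <- p$img
  }
  out
}

#' Augmentation configuration
#'
#' Spatial (flip, 90-degree rotation, random erasing) and color (brightness,
#' saturation, contrast) augmentations used while training the patch
#' segmenter. All draws come from the supplied seed, so augmentation is
#' bit-reproducible; spatial transforms are applied identically to a
#' supplied label crop so training pairs stay aligned.
#'
#' @param flip,rotate Enable random horizontal/vertical flips and k*90
#'   rotations.
#' @param erase_prob Probability of random erasing.
#' @param erase_area Length-2 range of the erased area fraction.
#' @param brightness,saturation,contrast Half-widths of the multiplicative
#'   jitter `U(1-j, 1+j)` per color property (0 disables).
#' @param seed Integer seed.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(flip = TRUE, rotate = TRUE, erase_prob = 0.25,
                           erase_area = c(0.05, 0.15), brightness = 0.1,
                           saturation = 0.1, contrast = 0.1, seed = 1L) {
  if (erase_prob < 0 || erase_prob > 1) stop("erase_prob must be in [0,1]")
  if (any(!is.finite(c(erase_area, brightness, saturation, contrast))))
    stop("jitter ranges must be finite")
  structure(list(flip = flip, rotate = rotate, erase_prob = erase_prob,
                 erase_area = sort(erase_area), brightness = brightness,
                 saturation = saturation, contrast = contrast,
                 seed = as.integer(seed)),
            class = "augment_config")
}

rot90k <- function(m, k) {
  k <- k %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- if (length(dim(m)) == 3)
    aperm(m, c(2, 1, 3))[dim(m)[2]:1, , , drop = FALSE]
  else t(m)[ncol(m):1, , drop = FALSE]
  m
}

#' Augment a patch (and its label crop) reproducibly
#'
#' @param patch A patch from [tile_slide()] or a bare `P x P x 3` array.
#' @param cfg An [augment_config()].
#' @param seed Optional seed overriding `cfg$seed` (used to vary draws
#'   across training steps while staying reproducible).
#' @return The augmented patch (same shape as the input; for a patch-list
#'   input the `img` and, if present, `labels` elements are transformed
#'   together).
#' @export
augment_patch <- function(patch, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "augment_config"))
  bare <- is.array(patch)
  img <- if (bare) patch else patch$img
  lab <- if (!bare) patch$labels else NULL
  P1 <- dim(img)[1]; P2 <- dim(img)[2]
  with_local_seed(seed %||% cfg$seed, {
    if (cfg$flip && runif(1) < 0.5) {
      img <- img[, P2:1, , drop = FALSE]
      if (!is.null(lab)) lab <- lab[, P2:1, drop = FALSE]
    }
    if (cfg$rotate) {
      k <- sample(0:3, 1)
      img <- rot90k(img, k)
      if (!is.null(lab)) lab <- rot90k(lab, k)
    }
    if (cfg$erase_prob > 0 && runif(1) < cfg$erase_prob) {
      area <- runif(1, cfg$erase_area[1], cfg$erase_area[2]) *
        dim(img)[1] * dim(img)[2]
      asp <- exp(runif(1, log(0.5), log(2)))
      eh <- max(1L, min(dim(img)[1], round(sqrt(area * asp))))
      ew <- max(1L, min(dim(img)[2], round(area / eh)))
      y0 <- sample.int(dim(img)[1] - eh + 1L, 1)
      x0 <- sample.int(dim(img)[2] - ew + 1L, 1)
      img[y0:(y0 + eh - 1L), x0:(x0 + ew - 1L), ] <-
        array(runif(eh * ew * 3, 0, 255), dim = c(eh, ew, 3))
    }
    if (cfg$brightness > 0)
      img <- img * runif(1, 1 - cfg$brightness, 1 + cfg$brightness)
    if (cfg$contrast > 0) {
      f <- runif(1, 1 - cfg$contrast, 1 + cfg$contrast)
      img <- (img - mean(img)) * f + mean(img)
    }
    if (cfg$saturation > 0) {
      f <- runif(1, 1 - cfg$saturation, 1 + cfg$saturation)
      rgbm <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                    as.vector(img[, , 3]))
      hsvm <- rgb2hsv(clip255(rgbm), maxColorValue = 255)
      hsvm[2, ] <- clip01(hsvm[2, ] * f)
      rgb2 <- col2rgb(hsv(hsvm[1, ], hsvm[2, ], hsvm[3, ]))
      for (c in 1:3) img[, , c] <- matrix(rgb2[c, ], dim(img)[1], dim(img)[2])
    }
    img <- clip255(img)
  })
  if (bare) return(img)
  patch$img <- img
  if (!is.null(lab)) patch$labels <- lab
  patch
}
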