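#' Specification of one synthetic slide
#'
#' Describes a slide-like image to be drawn by [generate_slide()]: its
#' category, size, how many lesion blobs it carries and what fraction of the
#' tissue area they should cover. NED slides carry no lesions by definition.
#'
#' @param category One of `"NED"`, `"LGD"`, `"HGD"`, `"IIN"`.
#' @param width,height Image size in pixels (>= 128).
#' @param lesion_count Number of lesion blobs; must be 0 for NED. Defaults to
#'   0 for NED and 3 otherwise.
#' @param lesion_area_fraction Target lesion area as a fraction of the tissue
#'   area, in `[0, 0.6]`; must be 0 exactly for NED. Defaults to 0.25 for
#'   non-NED slides.
#' @param center_id Identifier of the originating center (stain style).
#' @param seed Integer seed; a fixed spec draws a bit-identical slide.
#' @return An object of class `slide_spec`.
#' @seealso [generate_slide()], [generate_dataset()]
#' @export
slide_spec <- function(category, width = 1024, height = 1024,
                       lesion_count = NULL, lesion_area_fraction = NULL,
                       center_id = "C1", seed = 1L) {
  category <- match.arg(category, wsi_categories())
  if (is.null(lesion_count))
    lesion_count <- if (category == "NED") 0L else 3L
  if (is.null(lesion_area_fraction))
    lesion_area_fraction <- if (category == "NED") 0 else 0.25
  if (!is_count(lesion_count)) stop("lesion_count must be a non-negative integer")
  if (width < 128 || height < 128)
    stop("width and height must be at least 128 (the configured patch size)")
  if (lesion_area_fraction < 0 || lesion_area_fraction > 0.6)
    stop("lesion_area_fraction must lie in [0, 0.6]")
  if (category == "NED" && (lesion_count > 0 || lesion_area_fraction > 0))
    stop("NED slides cannot carry lesions")
  if (category != "NED" && (lesion_count == 0 || lesion_area_fraction == 0))
    stop("non-NED slides must carry at least one lesion blob of positive area")
  structure(list(category = category, width = as.integer(width),
                 height = as.integer(height),
                 lesion_count = as.integer(lesion_count),
                 lesion_area_fraction = lesion_area_fraction,
                 center_id = center_id, seed = as.integer(seed)),
            class = "slide_spec")
}

#' Center-specific stain style
#'
#' A simple linear color model of between-center stain variation: per-channel
#' multiplicative gain and additive offset, plus i.i.d. Gaussian pixel noise.
#' The identity style (`gain = 1`, `offset = 0`, `noise = 0`) leaves an image
#' unchanged.
#'
#' @param gain Length-3 positive multiplicative gains (R, G, B).
#' @param offset Length-3 additive offsets in gray levels.
#' @param noise Standard deviation of added Gaussian noise (gray levels).
#' @return An object of class `center_style`.
#' @export
center_style <- function(gain = c(1, 1, 1), offset = c(0, 0, 0), noise = 0) {
  gain <- rep_len(as.numeric(gain), 3)
  offset <- rep_len(as.numeric(offset), 3)
  if (any(gain <= 0)) stop("gains must be positive")
  if (noise < 0) stop("noise level must be >= 0")
  structure(list(gain = gain, offset = offset, noise = noise),
            class = "center_style")
}

#' Apply a center stain style to an image
#'
#' @param image Numeric array `h x w x 3` with values in 0..255.
#' @param style A [center_style()].
#' @param seed Seed for the style's pixel noise (ignored when `noise = 0`).
#' @return Styled image, clipped to 0..255 and rounded.
#' @export
apply_center_style <- function(image, style, seed = 1L) {
  stopifnot(inherits(style, "center_style"), length(dim(image)) == 3)
  out <- image
  for (c in 1:3)
    out[, , c] <- out[, , c] * style$gain[c] + style$offset[c]
  if (style$noise > 0)
    out <- out + with_local_seed(seed, array(rnorm(length(out), 0, style$noise),
                                             dim = dim(out)))
  round(clip255(out))
}

# Paint filled discs of a given radius and RGB color onto the three channel
# matrices at the provided pixel indices (centers), in place-ish.
paint_spots <- function(ch, centers_rc, radius, color, h, w) {
  if (nrow(centers_rc) == 0) return(ch)
  off <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  off <- off[off$dy^2 + off$dx^2 <= radius^2, ]
  for (s in seq_len(nrow(centers_rc))) {
    ys <- centers_rc[s, 1] + off$dy
    xs <- centers_rc[s, 2] + off$dx
    ok <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
    idx <- cbind(ys[ok], xs[ok])
    for (c in 1:3) ch[[c]][idx] <- color[c]
  }
  ch
}

# Wavy closed boundary (radial cosine harmonics) used for the tissue
# fragments and lesion blobs. Rasterized only inside the blob's bounding
# window, then placed into a full-size logical matrix.
wavy_region <- function(h, w, cx, cy, r0, amps, phases) {
  rmax <- r0 * (1 + sum(abs(amps)))
  y0 <- max(1L, floor(cy - rmax)); y1 <- min(h, ceiling(cy + rmax))
  x0 <- max(1L, floor(cx - rmax)); x1 <- min(w, ceiling(cx + rmax))
  out <- matrix(FALSE, h, w)
  if (y1 < y0 || x1 < x0) return(out)
  ys <- y0:y1; xs <- x0:x1
  yy <- matrix(ys, length(ys), length(xs))
  xx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  theta <- atan2(yy - cy, xx - cx)
  rr2 <- (xx - cx)^2 + (yy - cy)^2
  bound <- r0 * (1 + Reduce(`+`, Map(function(k, a, p) a * cos(k * theta + p),
                                     seq_along(amps), amps, phases)))
  out[ys, xs] <- rr2 < bound^2 & bound > 0
  out
}

#' Draw one synthetic slide with its per-pixel category mask
#'
#' Produces a slide-like RGB image: near-white background (all channels
#' >= 240), a wavy eosin-pink tissue region textured with small dark "nuclei"
#' spots and Gaussian noise, and -- for non-NED categories -- lesion blobs
#' whose texture grows more disordered with severity (denser and larger
#' spots, darker and more purple chroma). The paired mask holds labels
#' 0 = background, 1 = NED tissue, 2 = LGD, 3 = HGD, 4 = IIN.
#'
#' The drawn lesion area is corrected iteratively so the measured
#' lesion/tissue pixel ratio lands within about 20% of
#' `spec$lesion_area_fraction`. Output is bit-identical for a fixed spec.
#'
#' @param spec A [slide_spec()].
#' @return A list of class `synthetic_slide` with elements `image` (numeric
#'   array `h x w x 3`, 0..255), `mask` (integer matrix, labels 0..4) and
#'   `spec`.
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  with_local_seed(spec$seed, {
    h <- spec$height; w <- spec$width

    # tissue: a few small wavy fragments, as in endoscopic pinch biopsies,
    # together covering roughly 20% of the slide
    n_frag <- sample(2:4, 1)
    frag_r <- sqrt(0.20 * h * w / (n_frag * pi))
    tissue <- matrix(FALSE, h, w)
    frag_centers <- matrix(0, n_frag, 2)  # (y, x)
    for (f in seq_len(n_frag)) {
      for (try in 1:20) {
        cy <- runif(1, 0.18 * h, 0.82 * h)
        cx <- runif(1, 0.18 * w, 0.82 * w)
        if (f == 1 || all(sqrt((frag_centers[seq_len(f - 1), 1] - cy)^2 +
                               (frag_centers[seq_len(f - 1), 2] - cx)^2) >
                          1.8 * frag_r)) break
      }
      frag_centers[f, ] <- c(cy, cx)
      tissue <- tissue | wavy_region(h, w, cx, cy,
                                     frag_r * runif(1, 0.85, 1.15),
                                     amps = runif(3, 0.03, 0.12),
                                     phases = runif(3, 0, 2 * pi))
    }
    tissue_area <- sum(tissue)
    if (tissue_area == 0) stop("degenerate spec: no tissue drawn")

    mask <- matrix(0L, h, w)
    mask[tissue] <- 1L

    # lesion blobs, clipped to tissue, radius rescaled until the measured
    # area fraction is close to target
    if (spec$lesion_count > 0) {
      cand <- which(tissue)
      centers <- cand[sample.int(length(cand), spec$lesion_count,
                                 replace = length(cand) < spec$lesion_count)]
      crc <- cbind((centers - 1L) %% h + 1L, (centers - 1L) %/% h + 1L)
      target <- spec$lesion_area_fraction * tissue_area
      r0 <- sqrt(target / (spec$lesion_count * pi))
      amps <- replicate(spec$lesion_count, runif(2, 0.05, 0.20),
                        simplify = FALSE)
      phases <- replicate(spec$lesion_count, runif(2, 0, 2 * pi),
                          simplify = FALSE)
      draw_lesions <- function(scale) {
        les <- matrix(FALSE, h, w)
        for (b in seq_len(spec$lesion_count)) {
          les <- les | wavy_region(h, w, crc[b, 2], crc[b, 1], r0 * scale,
                                   amps[[b]], phases[[b]])
        }
        les & tissue
      }
      scale <- 1
      lesion <- draw_lesions(scale)
      for (it in 1:4) {
        got <- sum(lesion)
        if (got > 0 && abs(got - target) / target < 0.05) break
        scale <- scale * sqrt(target / max(got, 1))
        lesion <- draw_lesions(scale)
      }
      mask[lesion] <- category_label(spec$category)
    }

    # rendering: background, tissue base color, nuclei spots, lesion texture
    base_jit <- runif(3, -4, 4)
    ch <- list(matrix(250, h, w), matrix(250, h, w), matrix(250, h, w))
    tissue_col <- c(225, 172, 196) + base_jit
    for (c in 1:3) ch[[c]][tissue] <- tissue_col[c]

    # lesion base chroma: darker and more purple with severity s = 1..3
    if (spec$lesion_count > 0) {
      s <- category_label(spec$category) - 1L
      les_col <- c(215 - 10 * s, 172 - 25 * s, 196 + 2 * s) + base_jit
      les_px <- mask >= 2L
      for (c in 1:3) ch[[c]][les_px] <- les_col[c]
    }

    # nuclei spots: sparse in normal tissue, denser/larger/darker in lesions
    spot_at <- function(region_idx, density, radius, color) {
      n <- round(length(region_idx) * density)
      if (n == 0 || length(region_idx) == 0) return(NULL)
      ctr <- region_idx[sample.int(length(region_idx), min(n, length(region_idx)))]
      rc <- cbind((ctr - 1L) %% h + 1L, (ctr - 1L) %/% h + 1L)
      ch <<- paint_spots(ch, rc, radius, color, h, w)
      NULL
    }
    spot_at(which(mask == 1L), density = 0.0020, radius = 2,
            color = c(150, 110, 170))
    if (spec$lesion_count > 0) {
      s <- category_label(spec$category) - 1L
      spot_at(which(mask >= 2L), density = 0.002 + 0.002 * s,
              radius = 1 + s, color = c(110 - 10 * s, 70 - 10 * s, 150))
    }

    # pixel noise: sd 6 in tissue, sd 1.5 on the near-white background
    img <- array(0, dim = c(h, w, 3))
    bg_idx <- which(mask == 0L)
    ti_idx <- which(mask != 0L)
    for (c in 1:3) {
      plane <- ch[[c]]
      plane[ti_idx] <- plane[ti_idx] + rnorm(length(ti_idx), 0, 6)
      plane[bg_idx] <- pmax(plane[bg_idx] + rnorm(length(bg_idx), 0, 1.5), 241)
      img[, , c] <- plane
    }
    img <- cpp_affine_clip255(img, rep(1, 3), rep(0, 3))

    structure(list(image = img, mask = mask, spec = spec),
              class = "synthetic_slide")
  })
}

#' Generate a multicenter synthetic dataset on disk
#'
#' Draws slides per category and center, applies each center's stain style
#' after synthesis (emulating between-center stain variation), and writes
#' images, label masks and a CSV manifest.
#'
#' Images are written as RGB PNG (or TIFF); masks as 8-bit grayscale PNG in
#' which the pixel value is the category label 0--4.
#'
#' @param counts Named list: center id -> named integer vector of slide
#'   counts per category, e.g. `list(C1 = c(NED = 2, LGD = 1))`.
#' @param styles Named list of [center_style()] per center; identity styles
#'   are used for centers not listed.
#' @param out_dir Output directory (created if missing).
#' @param seed Base seed; every slide derives its own child seed from it.
#' @param width,height Slide size in pixels.
#' @param lesion_count_range Integer range from which each non-NED slide's
#'   blob count is drawn.
#' @param lesion_area_range Range from which each non-NED slide's lesion
#'   area fraction is drawn.
#' @param format `"png"` or `"tiff"` for the slide images.
#' @return Invisibly, the manifest `data.frame` with columns `slide_id`,
#'   `image_path`, `mask_path`, `center`, `label` (also written to
#'   `manifest.csv` in `out_dir`).
#' @export
generate_dataset <- function(counts, styles = NULL, out_dir, seed = 1L,
                             width = 1024, height = 1024,
                             lesion_count_range = c(2L, 4L),
                             lesion_area_range = c(0.15, 0.35),
                             format = c("png", "tiff")) {
  format <- match.arg(format)
  if (!is.list(counts) || is.null(names(counts)))
    stop("counts must be a named list: center -> named vector per category")
  centers <- names(counts)
  styles <- styles %||% list()
  for (ct in centers) {
    if (is.null(styles[[ct]])) styles[[ct]] <- center_style()
    if (!inherits(styles[[ct]], "center_style"))
      stop(sprintf("missing or invalid style for center '%s'", ct))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory")

  rows <- list(); i <- 0L
  for (ct in centers) {
    cnt <- counts[[ct]]
    bad <- setdiff(names(cnt), wsi_categories())
    if (length(bad)) stop("unknown category in counts: ", bad[1])
    for (cat in names(cnt)) {
      for (k in seq_len(cnt[[cat]])) {
        i <- i + 1L
        par_seed <- child_seed(seed, i, salt = 1L)
        pars <- with_local_seed(par_seed, list(
          count = sample(seq(lesion_count_range[1], lesion_count_range[2]), 1),
          frac = runif(1, lesion_area_range[1], lesion_area_range[2])))
        spec <- if (cat == "NED")
          slide_spec("NED", width, height, center_id = ct,
                     seed = child_seed(seed, i))
        else
          slide_spec(cat, width, height, lesion_count = pars$count,
                     lesion_area_fraction = pars$frac, center_id = ct,
                     seed = child_seed(seed, i))
        sl <- generate_slide(spec)
        img <- apply_center_style(sl$image, styles[[ct]],
                                  seed = child_seed(seed, i, salt = 2L))
        id <- sprintf("%s_%s_%03d", ct, cat, k)
        ipath <- file.path(out_dir, paste0(id, ".", format))
        mpath <- file.path(out_dir, paste0(id, "_mask.png"))
        write_slide_image(img, ipath)
        write_label_mask(sl$mask, mpath)
        rows[[i]] <- data.frame(slide_id = id, image_path = ipath,
                                mask_path = mpath, center = ct, label = cat,
                                stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("<synthetic_slide> %s, %d x %d, lesion px %d / tissue px %d\n",
              x$spec$category, x$spec$width, x$spec$height,
              sum(x$mask >= 2), sum(x$mask >= 1)))
  invisible(x)
}
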