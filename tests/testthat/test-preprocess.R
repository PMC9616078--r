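test_that("tissue masking recovers the synthetic tissue region", {
  sl <- small_slide("LGD", seed = 3)
  tm <- extract_tissue_mask(sl$image)
  gt <- sl$mask >= 1
  iou <- sum(tm$mask & gt) / sum(tm$mask | gt)
  expect_gte(iou, 0.95)
  expect_equal(tm$tissue_fraction, mean(tm$mask))
})

test_that("tissue masking handles degenerate and background-free images", {
  white <- array(255, dim = c(64, 64, 3))
  expect_warning(tm <- extract_tissue_mask(white), "degenerate")
  expect_equal(tm$tissue_fraction, 0)

  # noisy near-white background only: empty mask, no tissue
  bg <- with_seed_helper(1, array(pmin(255, 250 + rnorm(64 * 64 * 3, 0, 1.5)),
                                  dim = c(64, 64, 3)))
  expect_equal(extract_tissue_mask(bg)$tissue_fraction, 0)

  # all-tissue image with no background at all
  tis <- with_seed_helper(2, {
    a <- array(0, dim = c(64, 64, 3))
    base <- c(225, 172, 196)
    for (c in 1:3) a[, , c] <- pmax(0, pmin(255, base[c] + rnorm(64 * 64, 0, 6)))
    a
  })
  expect_gte(extract_tissue_mask(tis, min_object_px = 0)$tissue_fraction, 0.99)
})

test_that("channel statistics match a brute-force recomputation", {
  # uniform gray region
  img <- array(128, dim = c(32, 32, 3))
  mask <- matrix(TRUE, 32, 32)
  st <- compute_channel_stats(img, mask, "source")
  expect_equal(st$mean, rep(128, 3))
  expect_equal(st$sd, rep(0, 3))

  # target statistics are the mean of per-slide statistics
  img2 <- array(100, dim = c(32, 32, 3)); img3 <- array(140, dim = c(32, 32, 3))
  tg <- compute_channel_stats(list(img2, img3), list(mask, mask), "target")
  expect_equal(tg$mean, rep(120, 3))

  # random slide vs per-pixel oracle
  sl <- small_slide("HGD", seed = 5)
  tm <- sl$mask >= 1
  st <- compute_channel_stats(sl$image, tm, "source")
  for (c in 1:3) {
    v <- sl$image[, , c][tm]
    expect_equal(st$mean[c], mean(v))
    expect_equal(st$sd[c], sd(v))
  }
})

test_that("stain normalization applies the channel-wise linear transfer", {
  src <- data.frame(channel = c("R", "G", "B"), mean = rep(100, 3),
                    sd = rep(10, 3))
  tgt <- data.frame(channel = c("R", "G", "B"), mean = rep(120, 3),
                    sd = rep(20, 3))
  img <- array(110, dim = c(8, 8, 3))
  out <- normalize_stain(img, mask = NULL, target = tgt, source = src)
  expect_equal(unique(as.vector(out)), 140)  # (110-100)/10*20+120

  # identity when source equals target
  sl <- small_slide("LGD", seed = 9)
  tm <- extract_tissue_mask(sl$image)
  st <- compute_channel_stats(sl$image, tm, "source")
  expect_equal(normalize_stain(sl$image, tm, target = st, source = st),
               sl$image)

  # linear pre-clipping on a random unclipped image
  set.seed(4)
  img <- array(runif(16 * 16 * 3, 80, 120), dim = c(16, 16, 3))
  out <- normalize_stain(img, mask = NULL, target = tgt, source = src)
  expected <- round((img - 100) / 10 * 20 + 120)
  expect_true(max(abs(out - expected)) <= 1e-8)

  src0 <- src; src0$sd[2] <- 0
  expect_error(normalize_stain(img, NULL, tgt, src0), "degenerate source")
})

test_that("normalization pulls styled centers onto the shared target", {
  a <- small_slide("LGD", seed = 11)
  b <- small_slide("LGD", seed = 12)
  bimg <- apply_center_style(b$image, center_style(gain = c(1.15, 0.95, 1.05),
                                                   offset = c(-10, 6, 3)),
                             seed = 1)
  tma <- extract_tissue_mask(a$image); tmb <- extract_tissue_mask(bimg)
  tgt <- compute_channel_stats(list(a$image, bimg), list(tma, tmb), "target")
  na <- normalize_stain(a$image, tma, tgt)
  nb <- normalize_stain(bimg, tmb, tgt)
  ma <- vapply(1:3, function(c) mean(na[, , c][tma$mask]), 0)
  mb <- vapply(1:3, function(c) mean(nb[, , c][tmb$mask]), 0)
  expect_true(all(abs(ma - mb) < 2))
  # and each lands on the target within 1 gray level
  expect_true(all(abs(ma - tgt$mean) <= 1))
  sa <- vapply(1:3, function(c) sd(na[, , c][tma$mask]), 0)
  expect_true(all(abs(sa - tgt$sd) <= 1))
})

test_that("tiling produces the padded row-major grid and drops empty patches", {
  img <- array(200, dim = c(256, 256, 3))
  pt <- tile_slide(img, NULL, patch_size = 64, min_tissue_fraction = 0)
  expect_length(pt, 16)
  expect_equal(attr(pt, "canvas"), c(256, 256))
  expect_equal(pt[[2]]$x0, 64)  # row-major: second patch moves right
  expect_equal(pt[[2]]$y0, 0)

  # remainder padding: 250x250 with P = 64 -> ceiling to 4x4
  img2 <- array(200, dim = c(250, 250, 3))
  pt2 <- tile_slide(img2, NULL, patch_size = 64, min_tissue_fraction = 0)
  expect_length(pt2, 16)
  expect_equal(attr(pt2, "canvas"), c(256, 256))
  # padded strip is background white
  expect_equal(unique(as.vector(pt2[[16]]$img[59:64, 59:64, ])), 255)

  # tissue confined to one quadrant survives alone at threshold 0.05
  mask <- matrix(FALSE, 256, 256); mask[1:128, 1:128] <- TRUE
  pt3 <- tile_slide(img, mask, patch_size = 64, min_tissue_fraction = 0.05)
  expect_length(pt3, 4)
  expect_true(all(vapply(pt3, function(p) p$x0 < 128 && p$y0 < 128, TRUE)))

  # patch larger than the slide: a single padded patch, not an error
  pt4 <- tile_slide(array(200, dim = c(40, 40, 3)), NULL, patch_size = 64,
                    min_tissue_fraction = 0)
  expect_length(pt4, 1)

  expect_error(tile_slide(img, NULL, patch_size = 8), ">= 16")
})

test_that("tiling then reassembly is the identity on the padded canvas", {
  sl <- small_slide("HGD", seed = 6)
  pt <- tile_slide(sl$image, NULL, patch_size = 64, min_tissue_fraction = 0)
  expect_identical(reassemble_patches(pt), sl$image)
})

test_that("augmentation is seeded, label-aligned and honors its config", {
  sl <- small_slide("IIN", seed = 8, size = 128)
  pt <- tile_slide(sl$image, NULL, label_mask = sl$mask, patch_size = 64,
                   min_tissue_fraction = 0)[[2]]

  off <- augment_config(flip = FALSE, rotate = FALSE, erase_prob = 0,
                        brightness = 0, saturation = 0, contrast = 0)
  expect_identical(augment_patch(pt, off), pt)

  # same seed, same result, bit-exact
  cfg <- augment_config(seed = 99)
  expect_identical(augment_patch(pt, cfg), augment_patch(pt, cfg))

  # spatial transforms act identically on image and labels
  rot <- augment_config(flip = TRUE, rotate = TRUE, erase_prob = 0,
                        brightness = 0, saturation = 0, contrast = 0,
                        seed = 17)
  out <- augment_patch(pt, rot)
  hit <- FALSE
  for (fl in c(FALSE, TRUE)) for (k in 0:3) {
    img <- pt$img; lab <- pt$labels
    if (fl) { img <- img[, 64:1, , drop = FALSE]; lab <- lab[, 64:1] }
    img <- slidegraph:::rot90k(img, k); lab <- slidegraph:::rot90k(lab, k)
    if (identical(img, out$img)) { hit <- TRUE; expect_identical(lab, out$labels) }
  }
  expect_true(hit)

  # random erasing with p = 1 alters the configured area fraction
  er <- augment_config(flip = FALSE, rotate = FALSE, erase_prob = 1,
                       erase_area = c(0.10, 0.20), brightness = 0,
                       saturation = 0, contrast = 0, seed = 31)
  out2 <- augment_patch(pt, er)
  frac <- mean(apply(out2$img != pt$img, c(1, 2), any))
  expect_gte(frac, 0.095)
  expect_lte(frac, 0.205)
})
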