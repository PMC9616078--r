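# Shared fixtures: small synthetic slides and tiny network configs so unit
# tests stay fast. All randomness is seeded.

small_slide <- function(category, seed = 1L, size = 256,
                        lesion_area_fraction = 0.25, lesion_count = 2L) {
  if (category == "NED")
    generate_slide(slide_spec("NED", size, size, seed = seed))
  else
    generate_slide(slide_spec(category, size, size,
                              lesion_count = lesion_count,
                              lesion_area_fraction = lesion_area_fraction,
                              seed = seed))
}

tiny_arch <- function(patch_size = 32) {
  slidegraph:::seg_arch(patch_size = patch_size, levels = 2, width = 2)
}

# Lesion-rich training patches cut from small synthetic slides: returns a
# list of patches with img and labels in which lesions are well represented,
# so a few dozen gradient steps show clear learning.
training_patches <- function(n_slides = 10, seed = 70) {
  out <- list()
  for (i in seq_len(n_slides)) {
    sl <- generate_slide(slide_spec("IIN", 128, 128, lesion_count = 1,
                                    lesion_area_fraction = 0.4,
                                    seed = seed + i))
    pt <- tile_slide(sl$image, sl$mask >= 1, label_mask = sl$mask,
                     patch_size = 32, min_tissue_fraction = 0.5,
                     slide_id = paste0("s", i))
    ab <- vapply(pt, function(p) mean(p$labels >= 2), numeric(1))
    out <- c(out, pt[ab > 0.05 & ab < 0.75])
  }
  out
}

seg_test_arch <- function() {
  slidegraph:::seg_arch(patch_size = 32, levels = 2, width = 8)
}

with_seed_helper <- function(seed, expr) {
  set.seed(seed)
  expr
}

random_simplex <- function() {
  x <- -log(runif(4))
  p <- x / sum(x)
  names(p) <- wsi_categories()
  p
}

# Independent O(n^2) Mann-Whitney AUC oracle with ties counted 1/2.
auc_oracle <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Independent Cohen's kappa oracle using explicit double loops.
kappa_oracle <- function(a, b, categories, quadratic = FALSE) {
  K <- length(categories)
  n <- length(a)
  tab <- matrix(0, K, K)
  for (s in seq_len(n)) {
    i <- match(a[s], categories); j <- match(b[s], categories)
    tab[i, j] <- tab[i, j] + 1
  }
  tab <- tab / n
  po <- 0; pe <- 0
  for (i in seq_len(K)) for (j in seq_len(K)) {
    w <- if (quadratic) 1 - ((i - j) / (K - 1))^2 else as.numeric(i == j)
    po <- po + w * tab[i, j]
    pe <- pe + w * sum(tab[i, ]) * sum(tab[, j])
  }
  (po - pe) / (1 - pe)
}
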