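# slidegraph

Two-step whole-slide classification of endoscopic gastric biopsies, at desk
scale, in R.

Pathology services grade gastric biopsies on the WHO (5th edition) four-tier
scale — negative for dysplasia (NED), low-grade dysplasia (LGD), high-grade
dysplasia (HGD), intramucosal invasive neoplasia (IIN) — from whole-slide
images (WSIs). `slidegraph` is for people who want to study, teach or extend
the *two-step* architecture used for this task without gigapixel data or a
GPU:

1. **Patch segmenter.** A small V-Net-style encoder–decoder, trained with
   the soft dice loss, predicts a per-pixel abnormality probability for each
   tile of the slide (after Otsu tissue masking and stain normalization
   `Z = (X − μ)/σ · σ_T + μ_T` per channel) and doubles as a feature
   extractor (global-average bottleneck, 32-d).
2. **Patch-graph GCN.** The top-n tiles by abnormality grade (mean of the
   tile's probability map) become graph nodes; an edge joins nodes whose
   features sit strictly closer than γ in Chebyshev distance
   (`E_mn = 1 iff max_k |x_mk − x_nk| < γ`, so γ = 0 means no edges and
   γ = ∞ a complete graph). A two-layer GCN with mean pooling and focal
   loss `−α(1−p_t)^2 log p_t` emits four-tier probabilities that sum to 1.

Two clinical output modes sit on top: **four-tier** (argmax, ties toward
the more severe grade) and **NED screening**, whose threshold is calibrated
as `t = max p_NED over positive slides` so that, under the strict rule
"benign iff p_NED > t", sensitivity for positives and NPV are exactly 100%
on the calibration set for any model quality. A synthetic slide generator
(fragmented biopsy-like tissue, severity-graded lesion textures, per-center
stain styles, per-pixel label masks) makes the whole pipeline trainable and
testable from nothing.

## Worked example

A three-minute quick start on 24 small synthetic slides:

```r
library(slidegraph)

dir <- tempfile("demo")
man <- generate_dataset(
  list(A = c(NED = 6, LGD = 6, HGD = 6, IIN = 6)),
  out_dir = dir, seed = 31, width = 512, height = 512)

fit <- wsi_train(man, patch_size = 128, seed = 5,
                 seg_cfg = seg_train_config(epochs = 4, seed = 51),
                 gcn_cfg = gcn_train_config(epochs = 1500, seed = 52))
print(fit)
#> Two-step whole-slide classifier (segmenter + patch-graph GCN)
#>   trained on 24 slides (NED=6, LGD=6, HGD=6, IIN=6)
#>   patch 128 px, min tissue 0.05, stain normalization on
#>   segmenter: 3 levels, width 8, feature dim 32; final dice loss 0.6940
#>   graph: top n = 64, gamma = auto; GCN hidden 32, final focal loss 0.4882

preds <- predict(fit, man)
head(preds[, c("slide_id", "p_NED", "p_IIN", "call")], 3)
#>    slide_id p_NED p_IIN call
#> 1 A_NED_001 0.275 0.291  HGD
#> 2 A_NED_002 0.308 0.164  NED
#> 3 A_NED_003 0.332 0.105  NED
mean(preds$call == man$label)
#> [1] 0.6666667

scr <- calibrate_screening(fit, man, set_id = "demo")
scr$t            # largest p_NED seen on a dysplastic slide
#> [1] 0.3882
scr$n_screened_out  # benign slides the screening mode removes here
#> [1] 0
```

`p_NED`…`p_IIN` is the four-tier probability simplex for each slide (rows
sum to 1); `call` is its argmax. `scr$t` is the screening threshold: any
slide with `p_NED > t` is set aside as benign, and on the calibration set
this provably never discards a dysplastic slide (here the model is too
under-trained for any benign slide to clear the threshold, so the mode
safely screens out nothing). A quick start is all this is: at the
desk-scale conditions the test suite uses — 120 training slides at
1024 × 1024 from two stain-shifted centers, 40 held-out slides — held-out
four-tier accuracy reaches the 0.8–0.95 range and the screening guarantee
holds by construction.

Evaluation battery:

```r
rep <- evaluate_predictions(preds$call, man$label, grouping = "ned-vs-rest",
                            scores = 1 - preds$p_NED)
rep$metrics          # sensitivity/specificity/accuracy/NPV per group
rep$kappa_quadratic  # quadratically weighted Cohen's kappa, with band
rep$roc$auc
```

A thin command-line wrapper over the same functions lives in
`inst/exec/slidegraph-cli.R` (subcommands `generate`, `train`, `calibrate`,
`infer`, `evaluate`).

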