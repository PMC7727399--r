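# msl — multi-region saliency-aware translation for cross-domain placenta segmentation

Gross examination of the placenta starts from a photograph, and automated
analysis starts from segmenting that photograph into four regions:
background, placenta disc, umbilical cord, and the ruler used for scale. A
segmenter trained at one hospital fails at another — the disc and cord look
the same everywhere, but the ruler style and the background cloth differ
drastically across sites — and the new site typically has no pixel labels
to retrain with.

`msl` implements unsupervised domain adaptation for exactly this setting.
Target-domain photographs are translated into a source-like appearance by an
attention-guided, cycle-consistent adversarial model, then segmented with
the source-trained model. Two semantic constraints make the multi-region
translation trustworthy:

* **Attention consistency** — attention networks `A_S`, `A_T` confine
  translation to the domain-discriminative regions (ruler + background) via
  the composition `x_att · G(x) + (1 − x_att) · x`, so foreground tissue
  pixels pass through bit-exactly; in the labeled source domain the
  attention map is supervised by the label-derived attended mask.
* **Saliency consistency** — a dice-style loss ties the frequency-tuned
  saliency `S(i,j) = ‖I_blur(i,j) − I_μ‖₂` of the translated image to the
  binarized saliency of the original, preventing "label flipping" (ruler
  and background exchanging appearance during translation).

The total objective combines least-squares adversarial, cycle (λ = 5),
attention-consistency (λ = 2 source, 4 target) and saliency-consistency
(λ = 1 each) terms, trained in a three-stage curriculum in which the
discriminators see full images, then saliency-masked images (threshold
0.7), then attention-masked images (threshold 0.2). Evaluation uses pixel
accuracy, mean class accuracy and mean IoU from pixel-wise confusion
matrices.

Since clinical photographs cannot be distributed, the package includes a
synthetic two-domain scene generator that reproduces the structure of the
domain shift (shared disc/cord appearance; domain-specific ruler and
background), so the entire pipeline is testable end to end. A compact CPU
convolutional-network engine (BLAS-based convolutions, analytic backprop,
Adam) powers the networks; all gradients are finite-difference tested.

## Worked example

Render a synthetic source-domain scene, inspect its labels and confirm the
ruler is the salient object:

```r
library(msl)
sc <- make_scene(random_scene_spec(64, "source", seed = 3), domain = "source")
sc$label
#> <msl_labelmap 64 x 64; px per class: background=2863 disc=509 cord=84 ruler=640>

s <- normalize_saliency(ft_saliency(sc$image))
lab <- unclass(sc$label)
sprintf("median saliency: ruler %.2f, background %.2f",
        median(unclass(s)[lab == 3]), median(unclass(s)[lab == 0]))
#> "median saliency: ruler 0.62, background 0.24"
```

Run the full desk-scale adaptation study for one seed — generate 8 labeled
source and 8 unlabeled target scenes, train the source segmenter, train the
translation model (2 + 1 + 5 epoch curriculum), then segment the target set
with and without translation:

```r
ex <- run_adaptation_experiment(tiny_config(seed = 101), n = 8)
ex$adapted$mean_iou    # translate-then-segment
#> [1] 0.6931
ex$baseline$mean_iou   # source model applied directly to target images
#> [1] 0.6034
```

Adaptation raises target-domain mean IoU; across seeds the margin varies
(adversarial training on 8 images is stochastic) but the direction is
consistent. An ablation table over the loss terms is available via
`run_ablation(cfg, variants = c("full", "no_att", "no_sal", "no_cyc",
"no_adaptation"))`.

A thin command-line front end for the data/saliency/evaluation utilities is
installed at `inst/scripts/msl.R`:

```sh
Rscript inst/scripts/msl.R synth --n 20 --out data/ --domain source --seed 1
Rscript inst/scripts/msl.R saliency img.png sal.png --thresh 0.7
Rscript inst/scripts/msl.R evaluate --gt-dir labels/ --pred-dir preds/ --out report.json
```

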