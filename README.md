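# caafseg

Segmentation of pulmonary nodules in 2-D CT patches with **CAAF-ResUNet** —
a residual U-Net whose channel-attention and position-attention branches are
fused per sample by adaptive weights from a self-attention controller, and
which trains on boundary-aware composite losses. The package is aimed at
researchers studying attention fusion and boundary-sensitive objectives in
medical image segmentation who want a fully testable, CPU-only reference
implementation: every component — the network, its training loop, the losses,
the metrics, and a synthetic nodule generator — is exercised offline without
any external dataset.

## The method

**Adaptive attention fusion.** Given a feature map $X$, channel attention
($X_{CA}$, "which feature maps matter") and position attention ($X_{PA}$,
"which locations matter") are combined per sample as

$$X_{AAF} = w_1\,X_{PA} + w_2\,X_{CA},\qquad (w_1,w_2)=\mathrm{softmax}(z),$$

where the logits $z$ come from the Adaptive Attention Controller: the stem
feature map is average-pooled to an $8\times 8$ grid, passed through
single-head scaled dot-product self-attention
($A=\mathrm{softmax}(QK^\top/\sqrt{C})$), averaged over positions, and mapped
through a $C \to C/2 \to 2$ perceptron. One weight pair per sample drives
every fusion block in the encoder and decoder.

**Boundary-aware losses.** Training minimizes
$L = L_{Dice} + L_{boundary}$ with the boundary term selected from

- Sobel: $\frac{1}{N}\sum_{i,j} \lvert M_P - M_G \rvert$, the L1 gap between
  gradient-magnitude maps $M = \sqrt{(I * S_x)^2 + (I * S_y)^2}$;
- Laplacian: $\frac{1}{N}\sum_{i,j} \lvert \nabla^2 P - \nabla^2 G \rvert$
  with the 5-point stencil;
- EDT-Hausdorff: $d(P \to G) + d(G \to P)$, the symmetric mean of
  Euclidean-distance-transform values of each mask's foreground under the
  other mask's distance map, with a differentiable soft relaxation of the
  prediction direction.

**Evaluation.** Pixel confusion counts give Dice $2TP/(2TP+FN+FP)$, IoU,
sensitivity, Miss Rate ($FN/(TP+FN)$), and specificity, reported as
mean ± SD across cases; matched model variants (adaptive vs fixed 0.5/0.5
fusion) are compared by a two-tailed paired t-test on per-case Dice.

The network trains on a small reverse-mode autodiff engine written for this
package (R tape, RcppArmadillo conv/pool/attention kernels) — see the
methods vignette (`vignettes/caafseg-methods.Rmd`) for the model layout,
numerical conventions, and the design decisions taken where the method
description was open.

## Worked example

```r
library(caafseg)

# 40 synthetic nodule patches across the five morphologies
fixtures <- generate_dataset(40, image_size = 64, seed = 1)
sp <- split_indices(40, seed = 1)

cfg <- train_config(epochs = 40, batch_size = 8, lr = 1e-3,
                    loss_variant = "hausdorff", seed = 1)
rec <- train_model(cfg, fixtures[sp$train], val_data = fixtures[sp$val])
ev  <- evaluate_model(rec, fixtures[sp$test])

round(100 * colMeans(ev$table[, c("dice", "iou", "sensitivity",
                                  "miss_rate", "specificity")]), 2)
ev$mean_weights
```

```
       dice         iou sensitivity   miss_rate specificity
      42.05       30.25       83.27       16.73       92.91

        w1         w2
0.01970958 0.98029042
```

The first row is the held-out segmentation quality in percent. Sensitivity
83% with Miss Rate 17% says the model finds most true nodule pixels after
this short schedule (160 optimizer steps), while the moderate Dice/IoU and
specificity show it still over-segments — it has not yet learned to reject
the vessel-like distractors, which full-length training addresses.
`mean_weights` is the average fusion pair $(w_1, w_2)$ the controller
assigned: here it leans almost entirely on channel attention. Numbers
quantify behaviour on synthetic fixtures at CPU scale, not clinical CT
performance.

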