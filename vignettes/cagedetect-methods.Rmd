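---
title: "Occlusion-aware caged-poultry detection: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occlusion-aware caged-poultry detection: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Commercial caged housing stacks cages in tiers. The upper tier sits close to
the luminaires and photographs well; the lower tier and the depth of every
cage are dim, and birds are routinely cut into fragments by water pipes, feed
troughs, and each other. Detectors trained on free-range or laboratory imagery
collapse in this setting. Because whole-body outlines fragment under
occlusion and heads alone disappear behind trough rims, the annotation target
used throughout this package is the *joint head--neck region*, which stays
spatially continuous for almost every visible bird.

`cagedetect` re-implements, natively in R, a single-class anchor-free
detector for this environment: a nano-scale CSP substrate (stacked
conv--batchnorm--SiLU blocks, split-transform-merge stages, SPPF, one
attention stage, and a decoupled detect head with distribution-focal box
regression) plus three occlusion/illumination-oriented replacements:

* **MSEIExtractor** -- backbone stages whose transform path pools the feature
  map to a 3/6/9/12 pyramid, boosts high-frequency residuals (feather edges,
  comb contours), projects and fuses the scales, and passes the result
  through a dual-domain (spatial + spectral) selective attention;
* **CGDown** -- context-guided downsampling replacing every stride-2
  convolution from P2 onward in backbone and neck: a stride-2 CBS followed by
  a depthwise local branch and a dilated (rate 2) context branch, SiLU + 1x1
  joint reduction, and squeeze-excitation channel attention;
* **DHMSEAM** -- a detect head whose second box convolution and second
  depthwise-separable class block are replaced by MultiSEAM, a three-branch
  patch-embedding attention (kernel = stride = 3/5/7) with pooled
  concatenation, a squeezed fully connected re-expansion and a sigmoid gate
  multiplying the features.

There is no deep-learning framework in the supported environment, so the
whole network stack -- tensors, layers, reverse-mode autodiff, SGD, parameter
and FLOP profiling -- is implemented in R with two small C++ kernels
(`im2col`/`col2im`). This is deliberate: the architecture arithmetic *is* the
package's testable substance.

## Budget conventions (and how an ambiguity was resolved)

Deployment budgets are quoted against the published tables: baseline
2.58 M / 6.3 G, extractor-only 2.57 M, +CGDown 3.53 M, +DHMSEAM 4.59 M, full
model 5.53 M / 9.0 G.

Counting raw training-graph weights at one class gives 2,590,019 parameters
for the baseline -- which rounds to 2.59, not 2.58. Folding each convolution
into its batch norm (the convolution gains a bias; the norm disappears), the
count is 2,582,331, i.e. 2.58 M. The printed figures therefore refer to the
**fused inference graph**, which is also what the upstream tooling reports
after validation-time fusion. All budget APIs (`model_summary()`,
`scripts/acceptance.R`) use the fused convention; `count_params()` on a raw
module still counts the weights as built (a 3->16 CBS block has
3*16*9 + 2*16 = 464 trainable weights).

FLOPs are multiply-accumulates times two, accumulated over convolution and
fully connected layers only during a real forward pass at 640x640;
normalisation and activations are fused/free and attention matrix products
are not counted -- the convention that reproduces the printed 6.3 G for the
nano baseline at one class. `profile_flops()` is exact under this convention
and scales exactly with H*W for the fully convolutional parts.

## Frozen internal widths

The papers' figures pin the *outer* contracts of the three blocks but not
every inner width. The free constants below were calibrated once against the
printed parameter/GFLOPs tables and then frozen; all eight ablation variants
reproduce both printed columns at printed precision.

| constant | value | lives in |
|---|---|---|
| DSM spatial gate | 5x5 CBS to width 14, 3x3 conv back, sigmoid | `msei_constants()` |
| DSM frequency branch | radial high-pass, cutoff 0.25 cycles/px, per-channel gain | `msei_constants()` |
| EIEnhance | one shared 1x1 projection across the four scales | `nn_mseiselect()` |
| MSEI replacement sites | the four backbone stages only | `model_config()` |
| CGDown context width | `min(c2/2 + 40, 136)` | `cg_constants()` |
| CGDown squeeze ratio | 2 | `cg_constants()` |
| MultiSEAM FC squeeze | channels / 16 (SE-style) | `mseam_constants()` |
| reg_max | 16 distribution-focal bins | `build_model()` |
| BN eps / momentum | 1e-3 / 0.03 | `nn_bn2d()` |

Three structural readings were genuinely open and were decided as follows.
(1) The MSEIExtractor *replaces* the bottleneck stack on the CSP transform
path rather than adding to it -- the only reading consistent with the
extractor-only variant having *fewer* parameters than the baseline. (2) The
neck's two downsampling convolutions do not double channels in the substrate,
so `nn_cgdown(c1, c2)` takes an explicit output width there; the doubling
invariant is the backbone convention. (3) MultiSEAM's three branch maps have
incompatible spatial sizes, so branch maps and the original features are
globally average-pooled to per-channel vectors *before* concatenation, as in
the face-occlusion design this block descends from.

Identity-at-initialisation is enforced throughout the novel paths: the DSM
fuses through learnable per-channel gates initialised to (residual 1,
spatial 0, frequency 0), and MSEISelect re-enters through a zero-initialised
output gate. An ablation variant therefore starts exactly at baseline
behaviour and the novel branches fade in through training.

## Annotation enhancement

The enhancement pipeline exists to make dark, occluded birds *annotatable*;
enhanced frames are never training inputs, and the label-transfer step pairs
annotations back to original frames purely by filename stem (enhancement
never moves geometry). The stage order is fixed: directional HSV saturation
boost (gain 1.4 inside the 330-30 degree comb-red hue band, 1.15 elsewhere),
gamma brightening (gamma 0.6), CLAHE on the L plane of CIE Lab (clip 2.0,
8x8 tiles), and bilateral edge-aware denoising (sigma_s 1.5 px, sigma_r 20
intensity levels). None of these constants is published; they are this
package's documented defaults. CLAHE runs in Lab rather than HSV-V because
the L plane is stable under the preceding hue/saturation edits. Images are
read and written as ASCII portable pixmaps (PPM): the supported environment
has no binary image codec, and text images diff cleanly in fixtures.

## The synthetic world

The farm imagery behind the published results is not deposited, so every
downstream stage is exercised on procedurally generated scenes
(`generate_scene()`): feather-textured body ellipses with head--neck capsules
and red combs, wire mesh, a tier-dependent illumination gradient decaying
toward the cage rear, and the three occluder types (pipe, trough,
conspecific crowding). Determinism is a contract: identical spec + seed give
identical bytes. A bird is labelled when at least 15% of its head--neck
region stays visible -- the published annotation rule is qualitative, so this
threshold is repo policy, stated here once.

The generator emulates the *structure* of the dataset (tiers, illumination
ordering, occlusion geometry, single class, 7:2:1 split arithmetic, two
100-image special sets), not its photometric realism: no plumage variation,
no pose dynamics, no motion blur, no camera noise model beyond Gaussian
grain. A green test therefore establishes that the pipeline's mechanisms are
correct on data with the stated structure -- it does not establish field
accuracy, and the published mAP values on real imagery are explicitly out of
scope.

The 7:2:1 split uses the floor/floor/remainder rule, the only rounding that
reproduces the published 2695/770/386 from 3851 items.

## Training, losses and evaluation

`train_config()` defaults are the published recipe: SGD, learning rate 0.01,
momentum 0.937, weight decay 5e-4, batch 32, 400 epochs at 640 px, early
stopping patience 50, with translation/scaling/flipping/Mosaic/Mixup online
augmentation. Defaults the recipe does not state and that are this package's
choices: 3 warmup epochs; Mosaic probability 0.5 (4-image grid), Mixup
probability 0.15 with Beta(8,8) mixing; translation within 10%, scaling
0.5-1.5, horizontal flip 0.5; confidence/NMS thresholds 0.25/0.7.

Target assignment is center-based: a cell is a candidate for a ground truth
when its center lies inside the box and all four distances are representable
within reg_max - 1 stride units; each ground truth keeps its six closest
candidates across levels and conflicts go to the nearer object. The loss is
binary cross-entropy on the class map, distribution-focal cross-entropy on
the two-hot bin targets, and an IoU term on the decoded expectations (gains
0.5 / 1.5 / 7.5). This keeps the published loss family (box + classification
+ distribution-focal); the complete-IoU refinement of the box term is
deliberately simplified to plain IoU -- at overfit scale the distribution
term dominates box geometry, and the simplification keeps the backward pass
closed-form.

Two evaluation conventions the source leaves open: the integral under the
precision-recall curve is computed with 101-point interpolation (switchable
to all-point), and P/R are reported at the confidence that maximises F1.
Both are stated in the function documentation and tested against an
independent brute-force evaluator.

Batch-norm running statistics trail batch statistics by roughly 1/momentum
optimizer steps, which makes eval-mode metrics lag badly in few-step desk
runs; before each evaluation the training loop therefore recalibrates the
running statistics with one full-batch pass ("precise BN"). This changes no
trainable weight.

## Desk-scale mechanism exercise

The acceptance suite trains **every** ablation variant to train-split
mAP50 > 90 on a synthetic fixture. The stated full protocol (16 images,
320 px, up to 300 epochs) does not fit a 25-minute CPU budget in a pure-R
stack, so the suite runs a documented reduction: width multiplier 1/16,
8 scenes at 224 px (the smallest side at which the 7x7 occlusion-attention
patches exist on the P5 map), fixture learning rate 0.03, early exit at the
first evaluation above 90. The protocol is a fixture definition, not a tuned
quantity: the pass criterion (mAP50 > 90) is the stated one, and
`train_config()` defaults remain the published recipe.

## Known limitations

* Pure-R training is desk-scale only; the full 640-px, 400-epoch recipe is
  executable but impractically slow without a GPU framework.
* The spectral branch of the DSM uses a fixed radial cutoff; learned
  frequency filters are out of scope.
* The synthetic world omits photometric realism (see above); transferring
  any trained weights to real imagery is not supported.
* The task-aligned assignment of the reference family is replaced by the
  simpler center-based scheme described above; at overfit scale this is
  inconsequential, at field scale it would matter.
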