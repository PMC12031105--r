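---
title: "Band-resolved brain networks and graph-attention workload classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-resolved brain networks and graph-attention workload classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(workloadnet)
```

# The problem

Mental workload changes the large-scale coordination of cortical
activity, not just the power at single electrodes. `workloadnet`
implements a task-independent workload classification pipeline built
on that premise: multichannel EEG is decomposed into the four
classical frequency bands (delta 1–3 Hz, theta 4–8 Hz, alpha
8–12 Hz, beta 12–30 Hz), a functional brain network is estimated per
band and per 3-s epoch, and a stacked graph-attention + convolution
network (SGATCN) classifies each epoch's four-band *discrete graph*
into one of three workload levels (low / medium / high). Evaluation
is leave-one-task-out: the classifier is trained on epochs from two
task paradigms (e.g. N-back and mental arithmetic) and tested on the
held-out third (e.g. Sternberg), so the learned representation must
generalize across tasks, not merely across trials.

Because real workload recordings of this kind are typically private,
the package ships a protocol-faithful synthetic-EEG generator with
*known* band-specific phase coupling and level-dependent band
amplitudes. Every stage of the pipeline is therefore testable
against ground truth, and the test suite and acceptance script run
entirely on generated data.

# The synthetic generator

Each channel is a sum over the four bands of a band-limited
oscillation plus white Gaussian noise. The oscillator is a
*phase-diffusion sinusoid*: the phase advances by
$2\pi f/f_s$ per sample plus i.i.d. Gaussian jitter (default SD 0.1
rad/sample). This model was chosen over filtered noise because the
instantaneous phase is known by construction, which gives
closed-form ground truth for the phase-based connectivity
estimators.

Coupling between a channel pair $(i, j)$ in one band is implemented
per sample: on a Bernoulli($c$) subset of samples channel $j$ copies
channel $i$'s phase (offset by a fixed lag), and elsewhere it
follows its own independent phase walk. The expected phase-locking
value of the pair then approximates the coupling strength $c$, and
equals 1 exactly at $c = 1$.

Two design points deserve comment:

* **Band confinement.** A phase-diffusion oscillator has a
  Lorentzian line shape whose tails extend well beyond its nominal
  band. If the workload level modulates theta amplitude, those tails
  deposit level-dependent power into the neighbouring analysis bands
  — a leak that is physically real but defeats controlled masking
  experiments. Each band component is therefore confined to its own
  band at generation time by applying the squared magnitude response
  of the order-4 Butterworth band-pass in the frequency domain
  (`band_confine()`). This is the same magnitude response a
  forward–backward time-domain application would have, is exactly
  zero-phase (so pairwise phase relations are untouched in the
  passband), and is applied to all channels of a block in two FFTs.

* **Default study conditions.** The default protocol mirrors the
  acquisition design the package targets: 59 channels, 3 rounds × 3
  tasks × 3 levels, 120-s blocks, 1000 Hz acquisition (generation
  directly at the 200 Hz analysis rate is supported and leaves all
  coupling ground truth unchanged). The default coupling
  specification confines the workload signal to the theta band: a
  set of eight fronto-central channel pairs whose coupling rises
  with level (0.2 / 0.55 / 0.9) and a theta amplitude that rises
  with level (8 / 12 / 16 µV), while delta, alpha and beta carry
  level-invariant background coupling (strength 0.5) and constant
  amplitudes (12 / 10 / 6 µV) over a common noise floor (SD 5 µV).
  Concentrating the signal in one band is what makes the
  band-masking ablation informative: masking theta should remove
  essentially all class information, masking any other band almost
  none. Subjects are simulated independently with per-subject seed
  `base_seed + subject`.

What the generator does *not* emulate: volume conduction and a
forward head model (couplings are placed directly between channels),
ocular/muscle artifacts, non-stationarity within blocks, and 1/f
background spectra. Tests passing on this data therefore validate
the *computational* pipeline — estimator correctness, metric
correctness, learnability of band-localized network structure — not
robustness to the artifacts of real recordings.

# Preprocessing

`preprocess_recording()` applies, in order: polyphase resampling to
200 Hz, a zero-phase order-4 Butterworth band-pass (1–75 Hz)
followed by a band-stop notch (49–51 Hz), common-average
re-referencing, order-4 zero-phase Butterworth decomposition into
the four bands, and segmentation into non-overlapping 3-s windows
with the trailing partial window discarded (so a 120-s block yields
exactly 40 epochs, and a default session 27 × 40 = 1080 epochs per
subject). The applied step order is recorded in the returned
object's `pipeline` attribute.

Choices made where the procedure was genuinely open:

* Filter order 4, applied forward–backward (`signal::filtfilt`), is
  the conventional EEG choice; only the filter family was fixed a
  priori.
* The theta–alpha boundary is nominally 8 Hz in both bands; the
  bands are implemented exactly as stated (overlapping edge), since
  analog-design band-passes make no interval-arithmetic claim.
* Artifact removal (ICA, bad-channel repair) is out of scope; the
  pipeline accepts externally cleaned data.

# Node features

Per epoch, band and channel the node feature vector is
(band power, differential entropy):

* **Band power** is computed by averaging periodograms of
  non-overlapping 1-s Hamming-windowed segments (three per 3-s
  epoch) with one-sided density normalisation, then integrating over
  the band bins. The normalisation is fixed by two oracles enforced
  in the tests: an in-band sinusoid of amplitude $A$ yields
  $\approx A^2/2$, and the full-range integral of white noise equals
  its variance (Parseval).
* **Differential entropy** uses the Gaussian closed form
  $\tfrac12\ln(2\pi e\,\sigma^2)$ in nats, with $\sigma^2$ the
  sample variance of the band-filtered epoch. Natural log is used
  because the closed form is standard in nats; the base only
  rescales the feature.

Each band snapshot carries its own band's 2-vector (band-local node
information); a classifier consuming all four snapshots still sees
every band. Feature z-scoring statistics are fitted on training
folds only and reused at prediction time.

# Connectivity estimators

Four estimators build the channel × channel matrix per band and
epoch, each symmetric with zero diagonal:

* **PLV**: $|\langle e^{i(\phi_x - \phi_y)}\rangle|$ on analytic
  phases from the FFT half-spectrum method. Offset-invariant, 1 at
  perfect synchrony.
* **PLI**: $|\langle \mathrm{sign}(\Delta\phi)\rangle|$ with the
  phase difference wrapped to $(-\pi, \pi]$ and
  $\mathrm{sign}(0)=0$. The absolute value is taken so the index
  lies in $[0,1]$, the convention under which it is reported in the
  EEG literature; without it the index is signed.
* **PCC**: Pearson correlation of the amplitude time series, stored
  as $|\rho|$ so that proportional thresholding by "strongest
  connections" is comparable across estimators; the signed matrix is
  kept in an attribute.
* **MI**: plug-in histogram estimate $H(X)+H(Y)-H(X,Y)$ in bits,
  16 equal-width bins per signal over its observed range. The
  plug-in estimator has a known positive bias of roughly
  $(B-1)^2/(2N\ln 2)$ bits under independence (≈ 0.27 bits at 600
  samples and 16 bins); the tests bound the null at values frozen
  from a Monte-Carlo oracle rather than pretending the bias away.

Connectivity is computed per 3-s epoch (one graph sample per epoch);
`average_epochs = TRUE` provides session-level matrices for the
statistical analyses.

# Brain-network analysis

Connectivity matrices are binarized by proportional thresholding:
the `floor(s · n(n−1)/2)` strongest upper-triangle weights become
edges (ties broken lexicographically, so the graph is
deterministic). At the default sparsity 0.3 on 59 channels this is
exactly 513 edges.

Graph metrics follow the standard binary-graph definitions: node
clustering $C_i = 2t_i/(k_i(k_i-1))$ (0 for degree < 2);
characteristic path length $L$ as the mean shortest-path length over
connected pairs; global efficiency as the mean reciprocal
shortest-path length with $1/\infty = 0$; local efficiency as global
efficiency of each node's neighbour-induced subgraph; and the
small-world coefficient $\sigma = (CC/CC_r)/(L/L_r)$ against
degree-preserving double-edge-swap surrogates (default 100
surrogates, 10·|E| swap attempts, seeded). Shortest paths and edge
swaps are delegated to `igraph`; the metric conventions themselves
are implemented in the package and verified against brute-force
enumeration and Floyd–Warshall oracles in the tests. On a
disconnected graph, $\sigma$ is computed on the largest component
with a warning.

Level statistics use one-way ANOVA: per-epoch global metrics across
levels, per-node local metrics with the fraction of nodes at
p < 0.05 reported (no multiplicity correction by default, matching
the descriptive use; Benjamini–Hochberg is available). Pairwise
connectivity features (all channel pairs × four bands, 6844 features
on the 59-channel montage) are ranked by a vectorised closed-form
ANOVA F across levels — the package's concrete realization of a
feature "contribution rate" — and a top-5 % mask (342 features) is
returned.

# The SGATCN classifier

The model input is the discrete graph
$DG = \{G_{\delta}, G_{\theta}, G_{\alpha}, G_{\beta}\}$, each
snapshot $G = (V, E)$ a binary adjacency plus the band's node
features. The architecture is:

1. **Stacked GAT.** Two graph-attention layers are applied to each
   snapshot. Attention logits are
   $e_{ij} = \mathrm{LeakyReLU}_{0.2}(a^\top [W h_i \,\|\, W h_j])$
   for $j$ in the closed neighbourhood of $i$ (self-loops are added
   so isolated nodes are defined), normalized by a softmax over that
   neighbourhood; the node update is
   $h_i' = \mathrm{ELU}(\sum_j \alpha_{ij} W h_j)$. One parameter
   set is shared across the four snapshots — "stacking" is read as
   applying the same layer across the band snapshots; per-band
   parameter sets were considered and rejected as quadrupling
   parameters without a corresponding signal, but the code isolates
   the choice in one place. Layer sizes default to 2 → 16 → 8 with a
   single head.
2. **Convolution.** The four per-band embeddings (nodes × 8) are
   stacked as channels of a valid 2-D convolution (8 filters, 3×3
   kernel, ReLU; cross-correlation indexing, the deep-learning
   convention — equivalent to true convolution up to a kernel flip).
   This is the stage that mixes information *across* bands.
3. **Head.** Flatten, fully connected layer, softmax over the three
   levels.

Training minimizes cross-entropy with Adam (lr 0.001, batch 30, 800
epochs by default; gradient-norm clipping at 5). Initialization is
Glorot-uniform and fully seeded: identical data and seed give
bit-identical loss curves. No dropout is applied: the package
prioritizes the deterministic-training contract and exact
finite-difference gradient checks, and on the small synthetic
training sets used here dropout mainly added variance.

The forward and backward passes are hand-derived and implemented in
RcppArmadillo; correctness rests on three oracle families in the
test suite: a step-by-step plain-R evaluation of the attention
equations, a quadruple-loop convolution oracle, and central
finite-difference gradient checks at 1e-4 relative error across all
parameter groups. The GAT stage is also checked for permutation
equivariance.

# Evaluation harness

`cross_task_cv()` builds one fold per task: train on the other
tasks' epochs, test on the held-out task, with feature scaling
fitted per fold on its training graphs only and per-fold seeds
derived from the base seed. Metrics are accuracy, macro precision
and macro F1 (macro averaging is the natural choice for the balanced
three-class design; a class never predicted contributes zero
precision, with a warning). `sparsity_sweep()` re-runs the CV across
sparsities via a cached builder that re-thresholds precomputed
connectivity; `band_masking()` zeroes one band's adjacency and
features in train and test alike (masking rather than removal keeps
model shapes unchanged); `permutation_null_cv()` shuffles labels to
expose the chance floor. Subjects are pooled into one dataset per
fold; a per-subject analysis can be run by filtering recordings
before graph construction.

# Numerical choices and degenerate inputs

* Constant signals: differential entropy and instantaneous phase
  raise errors; MI returns 0 with a warning (single occupied bin);
  PCC raises on zero variance.
* Softmax and attention are computed with max-subtraction;
  probabilities are floored at 1e-300 inside the loss.
* Proportional-threshold ties and surrogate randomization are
  deterministic under a seed.
* An edgeless graph has global efficiency 0 by the stated
  convention, while the characteristic path length is undefined and
  raises.

# Problem sizes used by the tests and acceptance script

The protocol defaults above define the study conditions; the
end-to-end classification checks run them at a reduced scale chosen
once: one synthetic subject with 24-s blocks (8 three-second epochs
per block, 216 graphs), 200 training epochs, and five training
seeds, with the unmasked cross-task accuracy and the masked-theta
accuracy summarized by their medians. The analytic counts (1080
epochs per subject, 6844 pairwise features) are computed at the full
default protocol. The 1000 → 200 Hz resampling path is exercised on
single recordings; full sessions are generated directly at 200 Hz,
which leaves every counted or estimated quantity unchanged.

# Known limitations

* Synthetic validation only: no claim is made about accuracy on real
  EEG, where volume conduction, artifacts and non-stationarity
  matter; PLV in particular is sensitive to zero-lag mixing that the
  generator does not produce.
* The GAT stage is single-head; multi-head concatenation is not
  implemented.
* Graph metrics are binary-graph variants; weighted analogues are
  out of scope.
* The MI estimator is the plain plug-in histogram; its positive bias
  is documented and bounded, not corrected.
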