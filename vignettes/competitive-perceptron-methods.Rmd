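---
title: "Bio-inspired homeostatic neurons and the Competitive Perceptron: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bio-inspired homeostatic neurons and the Competitive Perceptron: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(competitron)
```

## The neuron model

`competitron` implements rate-coding artificial neurons: all signals are
firing probabilities in $[0, 1]$, and spike timing is deliberately out of
scope. A neuron $j$ fires with probability

$$O_j = \frac{1}{1 + e^{-k\,(\mathrm{net}_j + 0.5 - 2 s_j)}},$$

where $\mathrm{net}_j = \sum_i w_{ij} x_i$ is the input weighted by synaptic
efficacies $w_{ij} \in [0,1]$, $k > 0$ sets the sigmoid steepness, and
$s_j \in [0,1]$ is the sigmoid's position. The activation threshold — the net
input at which $O_j = 1/2$ — is the affine map $T_j = 2 s_j - 0.5$, so
thresholds range over $[-0.5, 1.5]$. Competitive neurons use $k = 500$, which
makes them effectively binary: two outputs can differ by less than machine
precision while the underlying excitations $\mathrm{net}_j - T_j$ differ
meaningfully, which is why every winner readout in this package compares
excitations, never outputs (`wta_winner()`). The sigmoid is evaluated via
`stats::plogis()`, which is stable for arguments far beyond $k \cdot
\mathrm{net} = 5 \times 10^6$.

### Intrinsic plasticity

After producing output $O$, the sigmoid position moves homeostatically:

$$s_j(t) = \frac{\nu\, O_t + s_j(t-1)}{1 + \nu}, \qquad \nu \ge 0 .$$

This is a convex combination, so $s_j$ can never leave $[0,1]$, and under a
constant output it converges geometrically to that output with ratio
$(1+\nu)^{-1}$ — the closed form $s_t = O + (s_0 - O)(1+\nu)^{-t}$ is verified
to $10^{-12}$ in the test suite. Highly active neurons drift rightwards
(raising their threshold, moderating future activity); silent neurons drift
leftwards and become more excitable. $\nu$ is the velocity of this
homeostasis; the competitive networks default to $\nu = 0.1$, and the cluster
experiments use $\nu = 0.02$ (see *Parameter choices*).

Within a time step the order is: compute net $\rightarrow$ compute output
(with the pre-update shift) $\rightarrow$ update the shift. The model treats
shifting as a consequence of the activity just produced; the alternative
order (output computed after the shift update) is not distinguishable from
any stated property of the model, so this choice is a design decision.
Boundary shifts $s \in \{0, 1\}$ are admitted as closure points; any output
in $(0,1)$ immediately restores strict interiority.

### Presynaptic learning and metaplasticity

Synaptic efficacies learn by the incremental presynaptic (Grossberg-type)
rule

$$\Delta w = \eta\, I\, (O - w),$$

with $I$ and $O$ the pre- and postsynaptic firing probabilities. Writing the
update as $w' = w(1 - \eta I) + \eta I O$ shows that $[0,1]$ is invariant and
that updates vanish as $w \to O$: already-adapted synapses change less, a
form of metaplasticity built into the rule itself. Setting the expected
update to zero gives the fixed point

$$w^* = \frac{E[I\,O]}{E[I]} = P(O = 1 \mid I = 1),$$

so a weight driven by a stationary binary stream estimates the conditional
probability that the postsynaptic neuron fires given that its input fired.
`presynaptic_fixed_point()` reproduces this with the time-averaged weight
over the final fifth of a $10^5$-step stream; the stationary fluctuation at
$\eta = 0.02$ has standard deviation $\approx 0.05$, and the time average is
accurate to about $\pm 0.01$.

Artificial metaplasticity (AMP) additionally makes the learning *rate*
depend on pattern frequency: rare patterns, which produced little prior
firing, should induce larger updates. The implemented form is

$$\eta_{\mathrm{eff}}(x) = \mathrm{clip}\!\left(
  \eta_0\,\frac{\bar p}{\varepsilon + \hat p(x)},\;
  \eta_0 c_{\min},\; \eta_0 c_{\max}\right),$$

where $\hat p$ is an estimated pattern probability (exact histogram for
discrete patterns, product-Gaussian kernel density with Silverman bandwidth
for continuous ones) and $\bar p$ its mean over the training set. The
normalization by $\bar p$ makes AMP collapse to the constant rate $\eta_0$
on uniform data, and the clip bounds (default $[0.1\,\eta_0, 10\,\eta_0]$)
keep rates finite for unseen patterns. The inverse-probability form is a
design decision: the literature this model descends from specifies only the
qualitative property "learn more from infrequent patterns", which this form
satisfies monotonically (tested on random frequency tables). The rate is
evaluated once per pattern presentation, not per weight, because frequency
is a property of the pattern. A minimal logistic MLP with mean-squared-error
backpropagation (`amp_mlp()`, `amp_backprop_step()`) demonstrates the
mechanism; with $c_{\min} = c_{\max} = 1$ it is bit-identical to standard
backpropagation, which the tests assert via 100-step weight trajectories.

## Lateral inhibition and emergent winner-take-all

A competitive layer connects every neuron to every other with *fixed*
inhibitory weights (gain $g$, default 1, never learned) and optionally to
itself with a plastic autapse. One synchronous step computes

$$\mathrm{net}_j = \sum_i w_{ji} x_i + a_j\,O_j^{(t-1)}
  - g \sum_{m \ne j} O_m^{(t-1)},$$

and `settle()` iterates from a silent state until exactly one neuron fires
($O \ge \theta_{\mathrm{fire}} = 0.9$, all others $\le 0.1$), the state
stagnates, or a step budget (default 60) is exhausted. With $k = 500$ the
value of $\theta_{\mathrm{fire}}$ is uncritical. Stagnation requires the
*whole* state to be stable: when intrinsic plasticity is active a silent
layer is not stagnant — its thresholds keep falling until the most driven
neuron fires, which is precisely how a winner emerges from small random
weights. Both stopping rules, the step budget, and synchronous (rather than
sequential) updating are design decisions; synchronous updates make the
dynamics order-independent and reproducible. Ties in the final
excitation readout break to the lowest index.

## The Competitive Perceptron

The Competitive Perceptron (CP) is a single-layer network: an input-coding
front end, one competitive layer, and a neuron-to-class map.

**Input coding.** Raw inputs in $[0,1]^d$ are complement coded
($x \mapsto (x, 1-x)$) and divisively normalized by the component sum plus
$\varepsilon = 10^{-6}$. Complement coding keeps total input activity
constant (so the all-zero pattern remains representable) and the division
mirrors the shunting normalization of the koniocortex-like circuit. The
encoded vector always sums to $\approx 1$.

**Training.** Per presentation: encode, settle with intrinsic plasticity
active, then update every excitatory weight (presynaptic signal = encoded
component) and every autapse (presynaptic signal = the neuron's own settled
output) by the presynaptic rule. The postsynaptic learning signal is the
neuron's own settled output in unsupervised mode, or the one-hot class
target in supervised mode (the dynamics still run and adapt the thresholds;
only the learning signal is clamped). Weight initialization is
$U(0, 0.1)$ from a mandatory seed; initial shift 0.5 (threshold 0.5);
autapse initialization 0.3. With AMP enabled the rate is modulated per
presentation by `amp_rate()`.

**Evaluation.** `cp_predict()` settles a *copy* of the layer on the encoded
input and reads the winner from the final excitations. Two modes exist:
frozen (`adapt = FALSE`, the default) and adaptive (`adapt = TRUE`), in
which intrinsic plasticity acts during the evaluation settling. Both are
deterministic and side-effect free; the distinction matters scientifically
(next section).

### Why XOR needs the adaptive readout

With frozen shifts a settle from silence reduces, for near-binary neurons,
to $\mathrm{argmax}_j(\mathrm{net}_j - T_j)$ — an affine function of the
encoded input. Complement coding makes the four encoded XOR patterns satisfy
$e_{00} + e_{11} = e_{01} + e_{10}$, so for any affine readout the summed
scores of the two classes are equal and a frozen two-neuron CP cannot reach
4/4. This is the classical linear-separability limitation, and the shipped
ablated control (complement coding off, autapses off, one settling step,
frozen shifts) demonstrates it: it never exceeds 3/4 on any seed.

With adaptive evaluation the readout is no longer affine: while the layer is
silent every threshold decays multiplicatively, so the time at which a
neuron first fires is an integer-quantized, logarithmic race between
$(\mathrm{net}_j + 0.5)$ and $2 s_j$, with collisions resolved through
rounds of mutual inhibition and further homeostatic adjustment. This
step-quantized, history-dependent competition is what lets two neurons
implement a non-linearly-separable dichotomy. The shipped XOR configuration
(`xor_config()`: $\eta = 0.6$, $\nu = 0.1$, $g = 1$, 30 epochs, fixed
presentation order, supervised, adaptive evaluation) was found by a small
grid search over $\eta$, $\nu$ and epochs and achieves 4/4 on 100% of 50
seeds in this package's tests; the hyperparameter basin is narrow (e.g.
$\eta = 0.5$ or $\nu = 0.2$ fail), which is consistent with the delicacy of
the race mechanism. Whether the original formulation of the model used the
same ingredients is unknown; the trained threshold values reported for it
($T_0 = 0.15$, $T_1 = 0.05$) come from an unspecified protocol and are not
reproduced as numbers, only the qualitative readout ordering (excitations
0.13 vs 0.07, first neuron wins) is.

## The koniocortex-like network

`kln_train()` prepends two stages to the same competitive layer:
thalamocortical (TC) neurons, one per input component, with a graded sigmoid
($k_{\mathrm{TC}} = 4$; a steep TC sigmoid would discard the amplitude
information the mean-tracking shift needs) and intrinsic plasticity that
makes each TC shift converge to the long-run mean output of its channel; and
a shunting stage that divides the competitive layer's drive by the summed TC
activity, $\;\mathrm{net}_j = \sum_i w_{ji}\,\mathrm{tc}_i / (\sum_i
\mathrm{tc}_i + \varepsilon)$, bounding it in $[0,1]$ and making it
invariant under rescaling of TC activity. Basket-cell inhibition is folded
into the layer's fixed inhibition gain rather than simulated as separate
units — inhibitory synapses are non-modifiable in the source circuit, so
explicit units would add no testable behaviour at this fidelity. With both
stages configured to identity the KLN reduces bit-for-bit to a CP without
input coding, which the tests assert. The classical sizing (15 inputs, 10
competitive neurons) is a default preset only.

## Synthetic data

All inputs are generated in-package from seeds: the XOR truth table,
correlated Bernoulli firing streams with prescribed conditional
probabilities, Gaussian clusters with deterministic means on a
$\{0.2, 0.5, 0.8\}^d$ lattice (corners first; placement depends only on the
cluster count and dimension, so experiments are stable across seeds), and
frequency-skewed pattern streams for metaplasticity. Generation is
bit-identical per seed and datasets round-trip through CSV exactly (17
significant digits). The clusters emulate well-separated isotropic classes;
they do not emulate overlapping classes, correlated features, label noise,
or non-stationary drift, so passing cluster tests demonstrates competence on
clean prototypes only.

## Parameter choices and problem sizes

| Parameter | Default | Why |
|---|---|---|
| $k$ (competitive) | 500 | near-binary firing, as in the source model |
| $k$ (TC) | 4 | graded output so shifts can track channel means |
| $\nu$ | 0.1 (XOR), 0.02 (clusters) | XOR needs fast homeostasis for the race; cluster quantization needs slow thresholds so similarity dominates |
| $\eta$ | 0.6 (XOR), 0.2 (clusters) | grid-searched (XOR); cluster value balances prototype tracking vs churn |
| $g$ | 1 | fixed inhibitory weight of the source circuit |
| $\theta_{\mathrm{fire}}$ | 0.9 | uncritical at $k = 500$ |
| settle budget | 60 steps | covers the slowest threshold-decay races at $\nu = 0.02$ |
| weight init | $U(0, 0.1)$ | "random and small" |

Experiment sizes (chosen once as representative desk-scale conditions):
presynaptic recovery uses $10^5$-step streams; XOR robustness uses 50 seeds;
cluster experiments use 3 clusters $\times$ 30 patterns in 2-D at spread
0.05, 20 seeds for consistency and 10 for quantization scaling.

## Known limitations

* **Consistency is not specialization.** The cluster tests measure
  *cluster consistency* — patterns from one cluster receiving the same
  winner. This does not imply that different clusters get *different*
  winners. In extensive experiments the unsupervised CP does not robustly
  form distinct per-cluster specialists: an always-winning neuron's weights
  saturate towards 1 on the (all-positive) complement-coded support rather
  than towards the cluster prototype, and homeostatic rotation then churns
  winner identity. Permutation-matched assignment accuracy peaks around 0.7
  across broad hyperparameter ranges. Quantization error still improves
  with neuron count, and consistency is high, but users should not read
  either as one-neuron-per-cluster coding.
* **Winner identity is not stable across continued training.** Under
  continual exposure the homeostatic mechanism can migrate a cluster from
  one neuron to another while keeping the partition intact. The
  continuous-learning tests therefore measure retention as per-cluster
  consistency, not as fidelity to the old neuron labels. Exposing the
  network to *only* a new cluster (without replaying old ones) collapses
  frozen readouts for the old clusters, because unused neurons' thresholds
  drift to their floor; the tests model the realistic setting where the
  environment gains a cluster while the old ones remain.
* **The XOR configuration is a narrow basin**, and the adaptive-evaluation
  requirement means the network is not a frozen classifier on that task.
* Rate coding only: no spike timing, refractoriness, or membrane dynamics.
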