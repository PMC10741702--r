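# competitron

Rate-coding artificial neurons with three homeostatic properties that
biological neurons have and classical perceptrons lack — **intrinsic
plasticity** (the activation function shifts with past activity),
**metaplasticity** (plasticity itself depends on prior activity and pattern
frequency), and **lateral inhibition** (winner-take-all competition emerging
from network dynamics rather than an external argmax) — assembled into the
**Competitive Perceptron**, a single-layer network that escapes the linear
separability limitation, and a simplified **koniocortex-like network** with
thalamocortical preprocessing and shunting normalization.

The package is aimed at computational-neuroscience and machine-learning
researchers who want a small, fully tested, reproducible implementation of
these mechanisms to study, extend, or compare against.

## The model in brief

A neuron fires with probability

    O_j = 1 / (1 + exp(-k (net_j + 0.5 - 2 s_j)))

where `net_j = Σ_i w_ij x_i`, the shift `s_j ∈ [0,1]` sets the activation
threshold `T_j = 2 s_j − 0.5`, and `k` (default 500) makes competitive
neurons near-binary. Three update rules do all the work:

* intrinsic plasticity: `s(t) = (ν O_t + s(t−1)) / (1 + ν)` — active neurons
  raise their threshold, silent neurons lower it;
* presynaptic rule: `Δw = η I (O − w)` — the weight converges to
  `P(O = 1 | I = 1)`, the conditional firing probability;
* metaplastic rate: `η_eff(x) = clip(η₀ p̄ / (ε + p̂(x)))` — rarer patterns
  learn more.

A competitive layer adds fixed lateral inhibition (gain `g = 1`) and plastic
autapses; a winner emerges while the layer settles on an input. The winner
readout compares excitations `net_j − T_j`, never the saturated outputs.

## Worked example: XOR with two neurons

A two-neuron Competitive Perceptron, trained supervised with the shipped
configuration, classifies all four XOR patterns — impossible for any affine
single-layer readout:

```r
library(competitron)
fit  <- cp_train(xor_dataset(), xor_config(seed = 1))
for (i in 1:4) print(cp_predict(fit$model, xor_dataset()$patterns[i, ])$class)
```

or from the command line (`inst/cli/competitron`):

```
$ competitron demo xor --seeds 50 --seed 1
XOR 4/4 success fraction over 50 seeds: 1.000
pattern  label  winner  class
(0, 0)    0      1      0
(0, 1)    1      2      1
(1, 0)    1      2      1
(1, 1)    0      1      0
```

Each row shows a pattern, its XOR label, the neuron that won the competitive
settling, and the predicted class; the success fraction counts seeds whose
trained network classifies 4/4. The nonlinearity comes from evaluating with
intrinsic plasticity active: thresholds decay while the layer is silent, so
the winner is decided by a step-quantized race rather than a fixed linear
score (see the methods vignette, `vignettes/`). An ablated control
(complement coding off, one settling step, frozen shifts) never exceeds 3/4.

The second demo shows the presynaptic rule estimating a conditional
probability from a correlated binary firing stream:

```
$ competitron demo presyn --pI 0.8 --pOI1 0.6
long-run mean weight: 0.5909 (analytic P(O=1|I=1) = 0.6000)
```

## Command-line interface

```
competitron train   --data patterns.csv --neurons 2 --mode supervised \
                    --eta 0.6 --nu 0.1 --epochs 30 --seed 7 --out run1/
competitron predict --model run1/model.json --data patterns.csv --out pred.csv
competitron demo    xor|presyn [options]
```

Datasets are CSV with feature columns `x1..xd` and an optional `label`
column; models are versioned JSON; traces are CSV. All floats use 17
significant digits, so reruns with the same seed are byte-identical.

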