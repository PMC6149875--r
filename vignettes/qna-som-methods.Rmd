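---
title: "QNA descriptors and site-of-metabolism classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QNA descriptors and site-of-metabolism classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qnasom)
```

## The problem

Cytochrome P450 enzymes oxidise xenobiotics at specific atoms — the sites
of metabolism (SOM). Predicting which atom will be attacked is the first
step of metabolite prediction. `qnasom` casts this as atom-level binary
classification: each heavy atom of each substrate is one instance,
described by exactly two whole-molecule-aware features, and labelled 1
(SOM) or 0 (non-SOM).

## QNA descriptors

The molecule is reduced to its hydrogen-suppressed graph with 0/1
connectivity matrix $C$; bond order is discarded because the descriptor is
defined on topological connectivity. Each element contributes two
electronic constants in electron-volts, the ground-state ionization
potential $IP$ and electron affinity $EA$, from which the per-atom terms

$$A_i = \tfrac{1}{2}(IP_i + EA_i), \qquad B_i = (IP_i - EA_i)^{-1/2}$$

are formed ($A$ is the Mulliken electronegativity; $B^{-2}$ the
hardness gap, so $IP > EA$ is required and holds for every packaged
element, including nitrogen whose EA is slightly negative). With the
graph kernel $E = \exp(-C/2)$,

$$P_i = B_i \sum_k E_{ik} B_k, \qquad Q_i = B_i \sum_k E_{ik} A_k B_k .$$

Because $E$ is a function of the whole adjacency matrix, every atom's
$(P, Q)$ pair responds to the entire molecular composition and topology,
which is what makes two features per atom competitive at all.

**Numerics.** $C$ is real symmetric, so $\exp(-C/2)$ is computed by
symmetric eigendecomposition, $V\,\mathrm{diag}(e^{-\lambda/2})\,V^\top$,
re-symmetrised after reassembly to remove last-bit asymmetry. The tests
cross-check it against a 40-term Taylor series (agreement better than
$10^{-9}$ on graphs up to 12 atoms) and against the $2\times 2$ closed
form $\cosh/\sinh(1/2)$ to $10^{-12}$. Scaling-and-squaring would work
too; the eigenroute is exact for symmetric input and simpler.

**Hydrogens.** Descriptors are computed on the same hydrogen-suppressed
graph that supplies the instances, so one graph serves labelling and
featurisation. Whether the original QNA formulation included hydrogens in
$C$ is genuinely open; computing on heavy atoms only is the choice made
here and is applied consistently, so models and descriptors are always
mutually coherent.

**Normalization.** "Normalized P and Q" is realised as z-scoring: mean
and *population* standard deviation are estimated on the training
partition only and applied to held-out rows, preventing feature-scaling
leakage. A zero-variance feature maps to 0. Range scaling would also have
been defensible; z-scoring is the convention for the downstream
classifiers.

## Datasets, grouping, imbalance

`build_dataset()` emits one row per heavy atom in molecule-then-atom
order. Records carry optional reaction-type (seven categories: aliphatic
and aromatic hydroxylation; C-, N-, S-oxidation; N-, O-dealkylation) and
CYP-isoform annotations, and `filter_by_group()` compiles the
reaction-type and isoform-reaction modeling subsets from them. Atoms of
molecules without any SOM annotation enter as negatives, consistent with
treating every non-SOM heavy atom as class 0. Typical real sets have
SOM:non-SOM ratios at or below 0.05.

## SMOTE balancing

Classic SMOTE in the two-dimensional normalized descriptor space:
each synthetic point is $x + \delta\,(x_{nn} - x)$, $\delta \sim U[0,1]$,
with $x_{nn}$ one of the $k = 5$ nearest minority neighbours (Euclidean,
minority points only). Defaults target a minority:majority ratio of 1, so
the SOM class ends at 48–50% of the balanced training set. The synthetic
budget is spread evenly over minority points with the remainder assigned
at random; neighbour ties break toward the lower row index, making a
seeded run bit-reproducible. Synthetic rows carry `synthetic = TRUE` and a
reserved `SMOTE_*` molecule namespace, and balancing is applied *inside*
each training fold only — the evaluation functions fit the normalizer,
then balance, then fit the model, so no synthetic point can reach a test
or validation fold.

## Classifiers

All four configurations sit behind `som_classifier()` /
`fit_som_model()` / `predict_proba()`:

* **Gaussian naive Bayes** — the features are continuous, so Gaussian
  class-conditionals are the natural likelihood (the alternative of
  discretisation was not pursued).
* **Random forest** — 100 trees; "70% bagging" is interpreted as each
  tree drawing a bootstrap sample of size $0.7\,n$ with replacement,
  the closest standard semantics.
* **RBF network** — unsupervised pre-training by k-means with $k = 2$
  clusters; each basis function is Gaussian with width equal to its
  cluster's RMS radius (floored at $10^{-6}$ for degenerate clusters);
  activations below $10^{-8}$ are clamped to zero; a logistic output
  layer maps the two activations to a probability.
* **MLP** — two hidden layers of 10 tanh units, sigmoid output,
  cross-entropy loss, Adam (learning rate 0.01, up to 400 epochs), early
  stopping with patience 25 on a 20% random carve-out of the training
  rows. No installed R package provides a two-hidden-layer perceptron,
  so the network is implemented here in vectorised base R; at two input
  features and 20 hidden units this is fast.

A convolutional variant is deliberately absent: a convolution over a
two-feature input is not well defined, and guessing an architecture would
not be meaningful.

## Evaluation protocol

Metrics are Se $= TP/(TP+FN)$, Sp $= TN/(TN+FP)$, BA $= (Se+Sp)/2$ and
rank-based (Mann–Whitney) AUC with ties counted one half — identical to
trapezoidal ROC integration, which the tests verify to $10^{-12}$ against
an independent ROC implementation. BA is the headline metric because raw
accuracy saturates on 95%-negative data.

Splits are **molecule-level**: all atoms of a molecule land on one side.
Atom-level splitting would place near-duplicate descriptors of the same
molecule on both sides and inflate every metric; molecule-level splitting
is the conservative standard in SOM prediction. `repeated_split_eval()`
repeats the 2:1 split five times and reports per-repeat metrics with mean
± SD (AUC is averaged per repeat, matching a protocol that averages
results over repeats); `loo_eval()` leaves one molecule out per fold and
computes a single AUC on the pooled out-of-fold scores, since per-fold
AUC is undefined when a fold holds one molecule. `top_k_hit_rate()`
reports the percentage of molecules whose $k$ top-scoring atoms contain a
true SOM, with ties broken toward the lower atom index; molecules without
a SOM are excluded with a warning.

## The synthetic generator

`generate_molecules()` emulates the *statistical shape* of SOM modeling
sets, not their chemistry: random spanning trees over C/N/O/S with
element weights (0.70/0.12/0.13/0.05), ring-closing edges (one with
probability 0.4, a second at 0.2), valence caps C:4, N:3, O:2, S:2, and
6–24 heavy atoms per molecule — drug-like sizes. Reaction-type and
isoform annotations are uniform draws, giving the grouped-subset
machinery something to group on. The default SOM:non-SOM target of 0.05
mirrors the imbalance of real compilations.

Labels come from a threshold rule in true descriptor space: an atom is a
SOM when its $Q$ exceeds the empirical quantile of the pooled $Q$
distribution chosen so the global positive fraction is
`som_ratio / (1 + som_ratio)` (the exact value bisection would converge
to). The rule is deterministic in the features, so classifier recovery
has a known ceiling of BA 1 at zero label noise, and the optional flip
noise degrades it in a controlled way. A `random` rule provides the
matching null.

What passing tests therefore show: the pipeline is leak-free, the
descriptors are computed correctly, the balancing hits its contract, and
the classifiers can recover a recoverable signal. What they do not show:
accuracy on real substrates, whose SOM labels are not a function of
$(P, Q)$ alone and whose graphs are not random trees.

## Problem sizes and runtime choices

The test suite and acceptance script run at desk scale by design: 150–500
molecules (roughly 2,000–7,500 atoms) for balancing and recovery checks,
100 split repetitions for the leakage audit, 20 seeds for the
label-permutation null, and LOO over 500 molecules for pooled-AUC
recovery. These sizes give stable Monte-Carlo estimates (binomial SE
under 2 percentage points on the recovery metrics) while keeping a full
run in minutes on one CPU.

## Known limitations

* Two descriptors bound model capacity; on real data this ceiling is much
  lower than on rule-labelled synthetic data.
* Bond order, stereochemistry, 3-D geometry, tautomers and protonation
  states are ignored by construction.
* Multi-fragment records are reduced to their largest component; whether
  reference implementations kept counter-ions is unknown.
* Whether a molecule metabolised by several reactions should contribute
  its non-SOM atoms to every reaction subset is unresolved in the field;
  here each annotated record contributes wholly to its own subset.
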