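---
title: "Simulating federated learning with attentive aggregation and proximal Adam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating federated learning with attentive aggregation and proximal Adam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedsim)
```

## The problem

Medical institutions cannot pool raw records, so a classifier has to be
trained *federatedly*: a server repeatedly broadcasts global model
parameters $\theta_t$, a random subset of clients runs local gradient
updates on private data, and the server aggregates the uploaded parameters.
When client data are not identically distributed (label skew, feature
skew, wildly unequal sample sizes), the classic recipe — local SGD plus
sample-size weighted averaging (FedAvg) — converges slowly and unstably.
`fedsim` implements, as a single-process simulator, the two orthogonal
remedies this package exists to study, and every pairwise combination of
them.

## The algorithms

**Weighted averaging.** With clients $k \in S_t$ holding $n_k$ training
samples, the baseline server update is
$\theta_{t+1} = \sum_{k \in S_t} (n_k / m_t)\,\theta_{t+1}^k$,
$m_t = \sum_{k\in S_t} n_k$.

**Attention aggregation.** Instead of size weights, the server scores each
upload by its parameter-space distance from the current global model,
$s_k = \lVert \theta_t - \theta_{t+1}^k \rVert_2$, normalizes the scores
with a softmax, $\alpha_k = e^{s_k} / \sum_j e^{s_j}$, and takes a step of
size $\lambda$ against the attention-weighted displacement:
$$\theta_{t+1} = \theta_t - \lambda \sum_k \alpha_k\,(\theta_t - \theta_{t+1}^k).$$
Two conventions deserve comment because the literature is loose about
both:

* *Sign of the score.* Softmaxing raw distances gives **more** weight to
  clients that moved further from the global model. The prose around this
  construction usually says "similarity", which suggests the opposite
  sign, but the formula as published uses the distances directly, and that
  is what `attention_weights()` does by default. The alternative is one
  flag away (`negate_scores = TRUE`) and is covered by the tests; the
  package default reproduces the published formula.
* *Softmax grouping.* The update can be applied with one softmax over
  whole-model distances or one per layer. The attentive-aggregation
  lineage this follows works layer-wise, so `scope = "per_layer"` is the
  default; `"whole_model"` matches the formula as written over whole
  parameter vectors and is also tested. At $\lambda = 1$ with equidistant
  clients both collapse to the plain mean — one of the exact identities in
  the test-suite.

**Proximal (perturbed) local updates.** Heterogeneous clients pull the
model toward their private optima. The proximal remedy augments the local
objective with a quadratic anchor to the round-start global model,
$H(\theta, \theta_t) = F_k(\theta) + \tfrac{\mu}{2}\lVert\theta -
\theta_t\rVert^2$, i.e. gradient $\nabla F_k(\theta) + \mu(\theta -
\theta_t)$. The anchor is frozen for the whole round. One published
formulation omits the gradient operator on $F_k$ in the perturbed-gradient
line; `perturbed_grad()` implements the gradient of $H$, which is the only
reading consistent with the surrounding update equations. Note the
explicit-step stability constraint $\eta\mu < 2$: the proximal recursion
diverges for larger products (which is why the tests exercise large-but-
stable $\mu$ rather than astronomically large ones).

**Adam and PAdam.** Adam keeps exponential moving averages $m_t, v_t$ of
the gradient and squared gradient, corrects their initialization bias
($\hat m_t = m_t/(1-\beta_1^t)$, $\hat v_t = v_t/(1-\beta_2^t)$) and steps
$\theta \leftarrow \theta - \eta\,\hat m_t / (\sqrt{\hat v_t} +
\varepsilon)$. PAdam is Adam applied to the perturbed gradient. Two exact
identities pin the implementation down: for constant gradient $g$ the
bias corrections telescope so every step moves by exactly $\eta g/(|g| +
\varepsilon)$, and at $\mu = 0$ PAdam is bit-identical to Adam (likewise
PGD to SGD). These hold over 100-step trajectories in the tests, not just
one step.

**The nine presets.** Crossing aggregators and optimizers:
`fedavg`/`fedprox` (weighted averaging + SGD/PGD), `fedatt`/`fedpa`
(attention + SGD/PGD), `fedavgs`/`fedavgt` (weighted + Adam),
`fedproxp` (weighted + PAdam), `fedatts` (attention + Adam), `fedpap`
(attention + PAdam). The `fedavgs`/`fedavgt` pair exists in the
literature to validate a hand-written Adam against a library one; the
mathematics is identical, so this package runs one Adam for both and
covers the validation burden with the closed-form tests above.

## Optimizer state discipline

Optimizer state (moments, step counter, anchor) is created fresh at the
start of every `client_update()` and never leaks across rounds: the
broadcast global model overwrites the local parameters each round, so
moments from the previous round would describe a different trajectory.
Two identical `client_update()` calls are therefore bit-identical, which
the tests assert.

## Hyperparameters

The defaults in `federated_config()` are the benchmark settings used for
all synthetic experiments:

| key | default | meaning |
|---|---|---|
| `learning_rate` | 0.01 (SGD) / 0.001 (Adam presets) | local step size |
| `num_rounds` | 100 | communication rounds |
| `clients_per_round` | 10 | sampled uniformly without replacement |
| `num_epochs`, `num_iters` | 10, 20 | local loop (see below) |
| `batch_size` | 10 | minibatch size |
| `eval_every` | 1 | evaluation cadence |
| `mu` | 1 (`fedprox`); presets use 0.03 for the PAdam/attention variants | proximal weight |
| `stepsize` | 1.2; presets use 4 (synthetic) and 9 (text) | attention step λ |
| `seed` | 0 | training stream (sampling, batching) |

The benchmark lists both a local epoch count and an iterations-per-epoch
count without defining their interaction; this package takes their
product as the number of local steps (`iter_mode = "product"`, batches
drawn by shuffled cycling, reshuffled each epoch) and exposes
`"epoch_pass"` (one full pass per epoch) as the alternative.

Evaluation uses **all** clients' test sets every `eval_every` rounds, not
only the sampled subset: the weighted accuracy is a property of the
global model, and evaluating on the sampled subset would confound it with
the sampling noise. The reported loss is the test cross-entropy for
consistency with the accuracy metric (`loss_on = "train"` gives the
alternative; published loss curves do not state which split they used).

## The synthetic(α, β) generator

`generate_synthetic()` draws, per client $k$: a sample size
$n_k = 50 + \lfloor \mathrm{LogNormal}(4, 2)\rfloor$ (heavy-tailed — a
few clients dominate, as in the published partitions); a client effect
$u_k \sim N(0, \alpha)$ and teacher model $W_k, b_k \sim N(u_k, 1)$; a
feature location $B_k \sim N(0,\beta)$, $v_{kj} \sim N(B_k, 1)$; samples
$x \sim N(v_k, \Sigma)$ with $\Sigma_{jj} = j^{-1.2}$; labels
$y = \arg\max(W_k^\top x + b_k)$ (the softmax is monotone, so the argmax
of the scores is the argmax of the probabilities). With `iid = TRUE` a
single shared teacher and feature location replaces the per-client draws.
Every constant (50, 4, 2, the 1.2 exponent, the 90/10 split) is a
`synthetic_spec()` field, and the training size is
$\lfloor 0.9\,n_k \rfloor$ per client.

Seeding is by named substreams: one root seed spawns independent streams
for sizes, teachers, features, samples and splits, *per client*, so
enlarging `n_clients` or changing α never reshuffles earlier clients'
draws. Two consequences are worth stating plainly. First, the generator
is bit-reproducible and α-ablations are paired. Second, the package's
seed-0 realization is *not* the published benchmark partition: those
printed totals (7926 training samples for α = β = 0, a largest client of
4185) came from one draw of an unpublished random stream, and probing the
published lineage's own reference code shows its seed-0 draw does not
reproduce them either. The partition statistics are therefore
distribution-level quantities here: the law is the published one; the
realization is this package's documented stream (seed-0 totals 5146/590,
largest client 1683, smallest 45 — that last value is the law's floor,
$\lfloor 0.9 \cdot 50\rfloor$, and is reproduced by essentially every
draw). A further consequence of the substream design is that the α = 0
and α = 0.5 datasets share their size draws exactly, which is what makes
the ablations paired.

What the generator does and does not emulate: it produces label skew,
feature skew and size imbalance with one tunable knob each, and even at
α = β = 0 each client keeps its own teacher model, so per-client class
distributions are extremely imbalanced — the published observation about
the "no-skew" dataset, which `label_heterogeneity()` quantifies (mean
pairwise total-variation distance ≈ 0.88 at α = 0, rising with α). It
does not emulate covariate shift within a class, temporal drift, or
annotation noise; passing tests on it says nothing about those.

## The dialogue-text path

`read_imcs()` parses doctor–patient dialogue JSON (fields `example_id`,
`dialogue` → `sentence_id`/`speaker`/`sentence`/`symptom_type`), dropping
and counting unlabelled sentences. `build_federated_text()` assigns
*whole dialogues* to clients (seeded round-robin over a shuffled order):
a consultation is the natural federation unit, and splitting one across
clients would leak near-duplicate context between train partitions. Each
labelled sentence becomes one (token-sequence, label) sample, padded or
truncated to `max_len` with index 0 reserved for padding.

Because the real corpus is an external resource, `generate_imcs_fixture()`
emits a synthetic corpus in the same JSON layout: Poisson sentence counts,
alternating speakers, fixed-width synthetic tokens concatenated without
separators (so the greedy longest-match tokenizer is exercised the way an
unsegmented-language pipeline would be), class-conditional token
distributions (70% of each class's mass on its own vocabulary block —
enough signal that a linear bag-of-tokens model beats the majority class,
which a test asserts), and per-dialogue class priors whose concentration
is controlled by `label_skew` (0 = one shared prior; the text analogue of
α). The fixture is byte-reproducible given its seed. It does *not*
emulate natural language: no syntax, no discourse structure, no
class-ambiguous sentences; LSTM results on fixtures demonstrate that the
federated text pipeline trains and ranks algorithms, not that any
accuracy level transfers to a real corpus.

The LSTM client is deliberately minimal — trainable embedding, one LSTM
layer, last-unmasked-timestep state, dense softmax — because no
architecture details are published for the text experiments; all
dimensions are `lstm_spec()` fields. Padding freezes the recurrent state,
so appending padding never changes the output (tested). Gradients are
hand-derived backpropagation through time, verified against central
finite differences to 1e-4 relative (with an absolute floor at the
finite-difference noise scale, since coordinates with gradients of order
1e-8 cannot be compared relatively at h = 1e-5).

## Numerical choices

* Softmax (both in cross-entropy and in attention weights) subtracts the
  maximum score before exponentiating.
* Argmax prediction breaks ties toward the lowest class index, making
  degenerate models (all-zero logistic parameters) deterministic.
* Logistic regression initializes at zero — the problem is convex, so a
  deterministic start costs nothing; the LSTM initializes
  uniform(−0.08, 0.08) from a named substream of `init_seed`.
* A batch size exceeding a client's training set degrades to full-set
  batches with a warning.
* Parameter serialization writes `%.17g`, which round-trips IEEE doubles
  exactly through text.
* All parameter algebra is pure; aggregation formulas reference
  $\theta_t$ and $\theta_{t+1}^k$ simultaneously, so nothing mutates in
  place.
* Exact run-to-run reproducibility assumes a single-threaded BLAS. A
  multithreaded BLAS may reorder floating-point reductions; the resulting
  last-bit perturbations are amplified by tens of rounds of training into
  visibly different (though statistically equivalent) trajectories.

## Scale of the shipped experiments

The test-suite and the acceptance script run everything at desk scale,
chosen so a full pass fits comfortably on one CPU core: the synthetic
comparisons use the 30-client benchmark datasets with 50–100 communication
rounds and the Table-7 local loop (10 × 20 steps, batch 10); the ordering
comparison across Adam-family algorithms uses 50 rounds × 5 dataset seeds;
the text experiments use a 60-dialogue fixture, vocabulary 500, embedding
16, hidden size 32, 20 rounds and 10 local steps per client per round.
These sizes are the package's reproduction conditions; anyone with more
patience can turn the same presets up.

## Known limitations

* Single process, no transport: communication cost appears only as
  wall-time instrumentation (`elapsed_ms`), which is hardware-bound and
  not a reproducible quantity.
* No system heterogeneity (stragglers, dropouts), no privacy mechanisms
  (secure aggregation, differential privacy), no learning-rate schedules
  or momentum-SGD variants.
* The attention weights use only the L2-distance/softmax instantiation;
  dot-product and additive scoring kernels are out of scope.
* Published accuracies on the real dialogue corpus are not reproduction
  targets here: the corpus, its client partitioning, vocabulary and
  sequence caps are all external or unpublished. The text path is
  validated on fixtures by construction-known properties instead.
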