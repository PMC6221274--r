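---
title: "Classifying impaired speech from n-gram language spaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying impaired speech from n-gram language spaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mild cognitive impairment (MCI) and Alzheimer-type dementia alter how
people compose spoken language long before they are reliably picked up by
screening instruments. A standard elicitation task asks the participant to
describe a busy kitchen picture; the transcribed descriptions are short —
a few dozen sentences per speaker, a few dozen speakers per arm — and the
question is whether the *sequential word statistics* of those transcripts
separate impaired speakers from healthy controls.

`dementialm` implements a complete pipeline for that question:

1. **Corpus handling** — reading plain or minimally CHAT-formatted
   transcripts, tokenizing, and seeded stratified splitting.
2. **Higher-order n-gram spaces** — each transcript becomes a sparse
   binary (or count) vector over the corpus's distinct 4-grams or 5-grams.
3. **SVD rank reduction** — the document by n-gram matrix is decomposed
   and each transcript represented by its leading left-singular
   coordinates, a dense low-dimensional "language space" embedding.
4. **A feed-forward neural language-model classifier** — tanh hidden
   layers and a softmax output trained by minibatch SGD with L1/L2
   penalties.
5. **Evaluation** — percent error, base-2 perplexity, and leave-pair-out
   cross-validated AUC with closed-form variance, confidence interval and
   p-value.
6. **A synthetic-corpus generator** used to validate the whole chain at
   clinical scale.

## Model

### Features

For order $n$, every sentence of length $L$ contributes its
$\max(0, L-n+1)$ contiguous n-grams; n-grams never cross sentence
boundaries and no start/end padding is used — the simplest reading of an
n-gram as a within-utterance word sequence. The vocabulary is the ordered
set of distinct n-grams (first occurrence order), and a transcript is a
binary presence vector over it. With only tens of transcripts and
thousands of n-grams these vectors are overwhelmingly zero, which is
exactly the sparse clinical regime the method targets: higher-order
n-grams are informative but individually rare.

An *instance* here is a transcript. The admissible SVD rank is therefore
bounded by the number of fitted rows, which is why a 38-transcript corpus
yields at most a few dozen continuous features per instance. `svd_reduce`
represents row $i$ by $U_k D_k$ (equivalently $X V_k$), the standard
latent-semantic-analysis document coordinates, and projects held-out rows
through the fitted right-singular basis $V_k$ so that test data never
influence the basis. The default rank is the full admissible
$\min(\#\text{fit rows}, \#\text{columns})$; smaller values are
configurable.

Two fitting scopes are provided. `train_only` (default) builds the
vocabulary and the SVD basis from training rows only and projects the
rest; out-of-vocabulary n-grams in held-out transcripts simply contribute
nothing. `full_corpus` fits the decomposition on all rows before
splitting. The second mimics a common but leakage-prone protocol; in our
synthetic experiments it generalizes *worse*, because with near-disjoint
document vocabularies the trailing singular dimensions act as
per-document indicators that the network then overfits. It is kept as an
explicit, logged option.

### Network

With input features $c_l$, each hidden layer computes
$d_j = \tanh(\sum_l M_{jl} c_l + b_j)$, and the output layer
$o_i = \sum_j V_{ij} d_j + k_i$ feeds a softmax
$p_i = e^{o_i} / \sum_l e^{o_l}$, the class-membership probability. One
hidden layer is the classic feed-forward neural language-model
configuration; three hidden layers give the deep variants, either on raw
sparse n-gram vectors or on the SVD coordinates. For the reduced model the
SVD coordinates *are* the continuous projection layer — no extra linear
layer is inserted.

Training minimizes the regularized cross-entropy error
$E = -\tfrac1m \sum_i t_i \log p_i
  + \lambda_1 \sum |w| + \lambda_2 (\sum M^2 + \sum V^2)$
by minibatch SGD. (Written as a quantity to *minimize*, the data term is
the negative log-likelihood; biases are not penalized.) Defaults follow
the small-regularization regime: $\lambda_1 = \lambda_2 = 10^{-4}$,
constant learning rate 0.01, 500 epochs, seeded Glorot-uniform
initialization, seeded epoch shuffling, last short minibatch kept. All
randomness is drawn on the R side from the configuration seed, so training
is bitwise reproducible; the SGD loop itself is compiled (RcppArmadillo).
Backpropagation is verified against central finite differences at
relative tolerance $10^{-4}$ across 1-5 layer architectures in the test
suite.

Percent error is the held-out misclassification rate of the argmax
prediction — on the small test sets typical of this problem its
granularity is coarse (one error among nine files is 11.1%). A grid
search over hidden-unit counts and batch sizes selects the cell with the
lowest validation percent error; ties break to lower perplexity, then
fewer hidden units, then smaller batches. Selection uses the validation
set and reports on the test set (passing the test set for selection is
possible but not the default).

**Standardization.** The SVD document coordinates carry the scale of the
singular values (row norms around 10 at the default corpus size). Fed
raw to a Glorot-initialized tanh layer they start deep in saturation and
some seeds underfit badly. The pipeline therefore centers and scales each
coordinate by its *training-row* mean and standard deviation (no
leakage) before network training; `run_config(standardize = FALSE)`
disables it. Raw sparse binary inputs are left untouched.

### Baseline

The conventional baseline is a class-conditional n-gram language model:
per-class counts over the pooled unique n-gram vocabulary with add-one
smoothing, $P(g \mid c) = (\mathrm{count}_c(g) + 1)/(\mathrm{total}_c +
|V|)$. These probabilities sum to one over the vocabulary; a test n-gram
unseen in training receives the add-one mass $1/(\mathrm{total}_c + |V|)$
of a single unseen bucket (without renormalization — the bucket sits
outside the training support by construction). A transcript's score under
a class is its mean per-n-gram $\log_2$ probability; the decision rule is
the likelihood ratio, with exact ties resolved to control. The choice
between probability-ratio and perplexity-ratio formulations is moot
under mean-log scoring: both induce the same ranking.

## Evaluation

**Perplexity** is $2^{B(q)}$ with
$B(q) = -\tfrac1N \sum_i \log_2 q(x_i)$, where $q(x_i)$ is the
probability the model assigned to the true class of example $i$. For
binary outcomes, 1 is perfect and 2 is uninformative; models
systematically worse than chance can exceed 2.

**Leave-pair-out cross-validation (LPOCV)** enumerates every
(positive, negative) pair, refits the full feature-and-model chain on the
remaining $|P|+|N|-2$ transcripts, and scores the held-out pair. A pair
contributes 1 when the positive member scores strictly higher; ties
contribute 0 under the literal comparison rule implemented as default
(a conventional half-credit mode is a flag). The average over all
$|P|\times|N|$ pairs is the Wilcoxon–Mann–Whitney AUC estimate — exactly
equal, for tie-free scores, to the rank-statistic computed by
`wilcox.test`, which the tests verify on 200 random score sets.
Per-round training seeds are derived deterministically from a master
seed, and an optional seeded subsample of rounds is available for
expensive trainers (the default is the full enumeration).

**Uncertainty.** The AUC variance uses the Hanley–McNeil (1982) closed
form with $Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$. The standard deviation is
$\sqrt{\sigma^2}$ on the natural probability scale. For the standard
error we provide three conversions — divide by $\sqrt{n_P+n_N}$
(default), by $\sqrt{n_P n_N}$, or use the sd directly (the conventional
interpretation of the Hanley–McNeil variance). Confidence intervals are
normal, reported *unclipped* (a lower bound may be negative), with an
optional display truncation at [0, 1]; the p-value is a two-sided z-test
of the AUC against the uninformative 0.5.

## The synthetic generator

Real clinical transcripts are access-controlled, so validation runs on
synthetic corpora whose *scale and sparsity* mirror the clinical regime:
two groups of 19 transcripts, 8-15 sentences of 4-12 words each (about
440 sentences in total), over a 60-word picture-description vocabulary.
Sentences are first-order Markov walks; transition rows are drawn from a
sparse Dirichlet (concentration 0.1), giving the low-entropy, formulaic
phrasing of picture descriptions and a 4-gram vocabulary in the
1,500-2,500 range — the same order as real corpora of this size. The
control group walks on the base matrix; the positive group walks on
$(1-\delta)\,\text{base} + \delta\,\text{perturbation}$, where the
perturbation re-draws the outgoing rows of half the words and $\delta$
is the planted divergence. $\delta = 0$ makes the groups statistically
identical; $\delta = 1$ with a disjoint-support perturbation makes their
bigram inventories provably disjoint.

What the generator does *not* emulate: discourse structure, disfluencies
and repairs, speaker-specific vocabulary size, interviewer turns, or any
acoustic phenomena. A first-order chain also cannot plant effects that
exist *only* at the 4-gram level while leaving bigram statistics intact.
Passing the end-to-end checks therefore demonstrates that the pipeline
recovers planted sequential-statistics differences at clinical scale and
stays at chance when there are none — not that it attains any particular
accuracy on real clinical data.

## Numerical choices and degenerate inputs

- Probabilities are floored at $10^{-12}$ before perplexity; an exact
  zero upstream is an error, not a silent clamp.
- Softmax and the cross-entropy use the log-sum-exp stabilization.
- Non-finite training loss aborts with a diagnostic naming the epoch.
- Transcripts empty after cleaning are excluded with a warning;
  transcripts with no n-grams of the model order are an error at
  classification time.
- Split sizes use largest-remainder rounding per class, so the three sets
  always partition the corpus and each class is within one transcript of
  its target fraction.
- Exact score ties: AUC pairs score 0 (literal rule); the baseline
  classifier predicts control.
- `svd_reduce` errors when the requested rank exceeds
  $\min(\#\text{fit rows}, \#\text{columns})$.

## Problem sizes used in validation

The shipped checks run the full chain at the generator's default scale:
361-round LPOCV on 19+19 transcripts with a three-layer network and a
hidden-unit grid of {5, 11, 19}, averaged over three seeds, at planted
divergence 0.8 (signal) and 0 (null); a depth sweep over 2-5 hidden
layers; and property tests (gradient checks, AUC/rank-statistic
equivalence, variance closed forms) at small n. These sizes keep a full
validation run in the tens of minutes on one core while still exercising
every round of the clinical-scale cross-validation protocol.

## Known limitations

- The held-out percent error on 9-10 test transcripts is inherently
  coarse and seed-sensitive; the LPOCV AUC is the stable summary at this
  scale.
- The planted divergence itself is a random quantity at this corpus
  size: the perturbation redraws transition rows for half the word
  types, so individual generator seeds can realize a weaker effective
  signal (visible as higher between-group n-gram overlap), and both the
  deep model and the count-based baseline drop together on such seeds.
  Averages over a few seeds inherit that variability.
- Add-one smoothing is the only baseline smoother (no Katz/Kneser-Ney
  backoff).
- The CHAT reader is deliberately minimal: speaker-prefixed utterance
  lines only, annotation codes stripped, dependent tiers dropped. It is
  not a general CHAT parser.
- The sd→SE conversions are provided as options because published
  small-sample AUC tables are not always internally consistent about
  which scaling was used; choose explicitly when comparing to external
  numbers.
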