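---
title: "The scoring card method for protein solubility prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The scoring card method for protein solubility prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solscm)
```

## The problem and the model

Proteins overexpressed in *Escherichia coli* frequently misfold into
insoluble inclusion bodies. Whether a given sequence will express solubly is
strongly influenced by its primary structure, and dipeptide composition —
the fractions of the 400 ordered residue pairs among a sequence's
overlapping windows — carries much of that signal. The scoring card method
turns this into a deliberately simple, interpretable classifier:

1. **Score card.** Each of the 400 dipeptides gets a propensity score
   $S_i \in [0, 1000]$; larger scores mean "more soluble".
2. **Sequence score.** A sequence $P$ of length $L$ has composition weights
   $w_i = \mathrm{count}_i / (L - 1)$ over its $L-1$ overlapping dipeptide
   windows, and solubility score
   $$S(P) = \sum_{i=1}^{400} w_i S_i.$$
   Since the weights sum to one, $S(P)$ always lies between the smallest and
   largest card entry.
3. **Decision rule.** $P$ is called soluble iff $S(P) > t$ for a threshold
   $t$ chosen to maximize training accuracy; a score exactly at the
   threshold is called insoluble (strict inequality).

The card itself is estimated in a coarse-to-fine manner. The **initial
statistical card** sets the raw propensity of dipeptide $i$ to the
difference of its class compositions,
$$\mathrm{raw}_i = \frac{n_i^{\mathrm{sol}}}{N^{\mathrm{sol}}} -
                   \frac{n_i^{\mathrm{ins}}}{N^{\mathrm{ins}}},$$
where $n_i$ is the pooled overlapping count in a class and $N$ the class's
total dipeptide count, and then min–max normalizes the 400 raw values onto
$[0, 1000]$. The **optimized card** refines these 400 values with a genetic
algorithm (below).

Amino-acid propensities are derived from a dipeptide card by averaging, for
residue $A$, the 40 entries $\{S_{AX}\} \cup \{S_{XA}\}$ over all residues
$X$. The homodipeptide $AA$ appears in both sets and therefore contributes
twice to the mean. Whether that average should de-duplicate $AA$ is a
genuinely open convention; we chose the literal 40-term mean and keep it
fixed everywhere (`amino_acid_scores()`).

## The optimizer

`optimize_ssm()` implements a genetic algorithm over the 400 real-valued
scores with an *orthogonal-array crossover*, suited to large parameter
vectors. Its fitness is the weighted sum
$$\mathrm{Fit} = W_1 \cdot \mathrm{AUC} + W_2 \cdot R,$$
with defaults $(W_1, W_2) = (0.9, 0.1)$. AUC is estimated by stratified
10-fold cross-validation of the candidate card's sequence scores on the
training set (the card needs no per-fold refitting; only its evaluation is
cross-validated), aggregated as the mean of the per-fold validation AUCs —
an aggregation choice we fixed since mean-vs-pooled is not dictated by the
method. $R$ is the Pearson correlation between the candidate's derived
amino-acid scores and the initial card's: it anchors the optimized card to
the statistically estimated propensities so the search improves accuracy
without discarding the interpretable signal.

AUC is computed rank-based (Mann–Whitney with tie correction), which is
exact under ties and avoids a threshold grid. The classification threshold
is selected by exhaustive scan over midpoints between consecutive distinct
scores plus sentinels beyond the extremes; ties in accuracy go to the
smallest candidate. Midpoints give margin-symmetric cut-points; the method
itself prescribes no rule here.

The crossover partitions the 400 genes into `oa_factors = 15` contiguous
blocks and uses the two-level orthogonal array $L_{16}(2^{15})$ over blocks
(level = inherit the block from parent 1 or parent 2). All 16 array rows are
evaluated; the best row becomes one child and the main-effect prediction
(per block, the level whose rows average better fitness) becomes the
second. Every child gene equals one parent's gene at that locus, so gene
range closure is inherited, and with 15 two-level factors the 16-run array
is the smallest orthogonal design — hence the default block count.

Each generation, a linear-rank mating pool of size $P_s \cdot N_{pop}$
(defaults $P_s = 1$, $N_{pop} = 40$) is drawn; every pool member is crossed
with the incumbent best individual. The published outline keeps "the best
two of the two parents and two children"; with the incumbent participating
in every pairing this leaves the population-update rule underdetermined, so
we fixed it as: the best of the four takes (or keeps) the incumbent slot and
the runner-up takes the pool member's slot. This keeps the population size
constant and makes the best fitness provably non-decreasing. Mutation then
redraws each gene uniformly from $[0, 1000]$ with probability $P_m = 0.01$,
sparing the incumbent. The run stops after 20 generations by default.

Because genetic algorithms are stochastic, `multi_run_select()` repeats the
optimization with consecutive seeds and keeps the card with the highest
training accuracy, logging a per-run summary table with mean and
standard-deviation rows. One master seed drives population initialization,
folds, selection, crossover and mutation, so a run is exactly reproducible.

A note on reporting: the cross-validated AUC inside the fitness and the
confusion-matrix metrics reported next to it are computed on different
partitions of the training data (CV folds vs. the pooled refit), so the
logged fitness need not equal $W_1$ times the logged AUC plus $W_2$ times
the logged $R$ recomputed from the same row; we log both rather than force
agreement. Reported training accuracy is the refit-on-full-training-set
accuracy at the selected threshold, and is labeled as such.

## Abstention

Scores near the threshold are the least reliable. `predict_with_uncertainty()`
abstains when $|S(P) - t| \le \mathrm{region\_size}/2$ — `region_size` is
the *full* width of the uncertainty band, so a width of 40 abstains within
20 points of the threshold. `uncertainty_accuracy_curve()` traces the
coverage/accuracy trade-off over a set of widths; accuracy on the retained
sequences typically rises as the band widens because classification errors
concentrate near the threshold, but this is an empirical tendency, not an
invariant, and the curve reports `NA` accuracy once nothing is classified.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `npop` | 40 | population size |
| `ps` | 1.0 | fraction of the population entering the mating pool |
| `pm` | 0.01 | per-gene mutation probability (≈ 4 of 400 genes per chromosome) |
| `generations` | 20 | stopping condition |
| `w1`, `w2` | 0.9, 0.1 | fitness weights on AUC and conservation R |
| `k_folds` | 10 | cross-validation folds inside the fitness |
| `oa_factors` | 15 | crossover blocks (pairs with the 16-run array) |

These defaults are the published protocol for this method; the weights were
reported there as the best of the tested pairs, with the conservation term
keeping $R > 0.9$ at almost no accuracy cost.

## The synthetic-data generator

Real curated solubility datasets require external downloads, so validation
uses `generate_planted_dataset()`: a first-order Markov chain over residues
whose transition weight into dipeptide $d$ is proportional to
$\exp(\pm\,\mathrm{effect\_size} \cdot \mathrm{propensity}(d))$, positive
for the soluble class and negative for the insoluble one. First-order
generation (rather than i.i.d. residues) makes dipeptide structure genuinely
plantable; base residue usage is uniform. Defaults — standard-normal planted
propensities, sequence lengths uniform on 100–300 (typical bacterial protein
lengths), effect size 1 for "strong" signal and 0 for the exchangeable null
— are fixed study conditions, not tuning knobs.

What the generator emulates: two sequence classes separated only through
dipeptide composition, with realistic length variation. What it does not
emulate: real amino-acid background frequencies, homology structure between
sequences, fusion tags, or any experimental-condition covariates (pH,
temperature, additives). Passing tests therefore demonstrate that the
estimator recovers planted dipeptide signal and that the optimizer improves
a valid objective — not that any particular accuracy carries over to real
expression data, where published results require the original curated
corpora.

`recovery_report()` quantifies recovery as the Spearman rank correlation
between planted propensities and learned scores, restricted to dipeptides
observed at least 5 times in the training data: a never-observed dipeptide's
learned score is an artifact of normalization and would only add noise.

## Numerical choices and degenerate inputs

* Normalization divides before scaling, `(raw - min) / (max - min) * 1000`,
  so both endpoints land on 0 and 1000 exactly in floating point.
* An all-equal raw vector (e.g. identical class compositions) raises a
  degenerate-data error instead of silently producing a constant card.
* Scores are kept as doubles throughout and only rounded in reports.
* Card files store scores with 17 significant digits so a write/read cycle
  is bit-exact.
* Stratified splitting rounds per-class training counts half-up; published
  dataset splits made without a recorded seed are documented but not
  reconstructible, and the package does not attempt to reproduce them.
* FASTA records containing residues outside the 20-letter alphabet are
  dropped with a warning by default (mirroring the upstream curation of the
  reference corpora), or rejected outright in strict mode.
* Property scales with any missing residue value are skipped and marked,
  never silently imputed.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to exercise every code path while staying desk-scale: 400
training and 200 held-out sequences of length 100–300 for the planted
recovery and null-calibration experiments, and a 10-individual,
5-generation optimizer configuration for the end-to-end improvement check.
The defaults above remain the published protocol; the reduced optimizer
setting is used only where the check's purpose is monotonicity and
non-regression, which do not depend on population size.

## Known limitations

* The card is condition-specific: propensities estimated at one set of
  expression conditions transfer poorly across datasets collected under
  different ones, so cards should be retrained per condition family.
* The method uses dipeptide composition only; tripeptides were reported not
  to help, and no reduced-alphabet or physicochemical encodings are used
  for classification (they appear only in the propensity analysis).
* The fallback of classifying uncertainty-region sequences with a secondary
  classifier is out of scope; the package abstains instead.

## A minimal session

```{r example, eval = FALSE}
library(solscm)

model <- planted_model(effect_size = 1, seed = 1)
train <- generate_planted_dataset(200, 200, model)

card <- fit_threshold(build_initial_ssm(train), train)
opt <- optimize_ssm(card, train, iga_config(npop = 10, generations = 5, seed = 1))

predict_solubility("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", opt$card)
rank_dipeptides(opt$card, 10)
amino_acid_scores(opt$card)
```
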