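---
title: "Negative-sampling bias in AMP prediction benchmarks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Negative-sampling bias in AMP prediction benchmarks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Classifiers that predict antimicrobial peptides (AMPs) are trained on a
positive set of experimentally verified AMPs and a negative set of
presumed non-AMPs. There is no database of verified non-AMPs, so every
published tool *samples* its negatives from an annotated protein database
using its own rule set: exclude records carrying certain function
keywords, restrict lengths or cut fragments matching the positive length
distribution, restrict subcellular localization, remove redundancy with
identity clustering, screen against near-matches to known AMPs, and
balance (or not) the class sizes.

`ampbench` implements eleven such published rule sets as one configurable
engine, ten classical AMP-prediction architectures, and the experiment
that exposes the consequence: every architecture is trained on negatives
from each sampling method and evaluated against benchmark negatives from
*every* method. If benchmarks were neutral, the AUC of a model would not
depend on which method generated the benchmark negatives. It does: models
systematically score higher when the benchmark negatives come from the
same sampling method as their training negatives (the *diagonal effect*),
which means published head-to-head comparisons of AMP predictors are
biased in favour of whichever tool's sampling method was used to build
the benchmark.

## The synthetic study system

Everything runs at desk scale on a seeded synthetic stand-in for the real
data, generated by `synthetic_config()`, `generate_positives()` and
`generate_background()`:

* **Positives** are short cationic/hydrophobic peptides: lengths follow a
  shifted negative binomial (shift 5, size 2, mean 16; median 18,
  truncated to 5–190 residues, matching the field's mature-AMP length
  profile), residues are i.i.d. from a database-average composition with
  K and R boosted 3× and L, W, I, F boosted 1.8×.
* **The background database** mimics a reviewed protein database: lengths
  are a log-normal mixture (82% with median ≈ 290 residues; 18% a
  small-protein/peptide component with median ≈ 27) truncated to 5–2000.
  A single log-normal calibrated to the database median would leave the
  10–40 and 5–100 length-range sampling methods without material at desk
  scale; real databases contain a sizeable small-protein fraction.
  Records carry function keywords (antimicrobial, antibiotic, secreted,
  transmembrane, toxin, …) and localization labels (cytoplasm, secreted,
  mitochondria, …) at configurable prevalences.
* **Annotation–composition coupling** gives the keyword screens something
  real to do: "secreted" and "antimicrobial" are positively associated
  (odds ratio 4); half of the antimicrobial-keyword records have fully
  AMP-like composition (annotated AMPs hiding in the negative pool); a
  0.5% rate of records are AMP-like *without* any AMP keyword
  (mislabelled AMPs that no keyword screen can catch); transmembrane
  records lean hydrophobic; secreted records lean toward the positive
  composition; cytoplasmic records lean acidic. These couplings are what
  makes different keyword/localization screens produce *compositionally
  different* negative pools — the mechanism behind the bias.
* A latent `oracle_amp` label records which background records are
  AMP-like by construction, so architecture AUCs are meaningful.

What the generator does **not** emulate: real protein grammar (motifs,
domains, signal peptides), phylogenetic redundancy, and the exact length
histograms of any database release. Passing tests therefore demonstrate
that the *pipeline machinery and the bias mechanism* behave as described,
not that any particular real-data AUC is reproduced; the headline
real-data numbers depend on databases this package deliberately does not
download.

## The eleven sampling methods

`builtin_specs()` encodes each published method as a `sampling_spec`
(excluded keywords; length policy; clustering threshold; localization
whitelist; cysteine-free fragments; potential-AMP screen; similarity
screen; balance). Assembly applies stages in a fixed order: keyword
filter → localization filter → potential-AMP screen → length policy →
cysteine rule → clustering → positive-similarity screen →
positive-overlap removal → size targeting → train/bench partition.
Filters come before samplers; clustering follows fragment extraction for
the "similar" methods, which is exactly why those end up slightly
imbalanced.

Decisions taken where the published descriptions are qualitative:

* **Imbalance ratios** (negatives : positives) for the unbalanced
  methods: Wang 2:1, iAMP-2L 2:1, Gabere&Noble 10:1 (highly imbalanced),
  AMAP 1.2:1, dbAMP 1.2:1 (slightly imbalanced), ampir-mature 0.8:1
  (negatives in the minority). All configurable.
* **Leakage prevention.** The positive 80/20 split precedes all negative
  sampling; train negatives are sampled against the positive training
  length multiset and bench negatives against the benchmark multiset, so
  the two cannot share a fragment; fragment provenance (parent id,
  0-based half-open coordinates) is recorded and duplicate fragments are
  never emitted; any negative equal to a positive sequence is rejected.
* **Split rounding.** The training size is `floor(0.8 n + 0.5)`. At the
  real positive-set size this gives 4152/1038 rather than the widely
  quoted 4151/1039; the one-sequence difference comes down to an
  unspecified rounding convention and is documented rather than
  reverse-engineered.

### The clustering stand-in

Published methods use CD-HIT. Running an external binary is out of scope,
so redundancy removal is a transparent reimplementation of its contract:
greedy longest-first clustering in which a sequence joins the first
cluster whose representative it matches at or above the identity
threshold, with identity defined as the number of matched positions on an
optimal-score global alignment divided by the shorter sequence length.

Two numerical choices matter and are deliberate:

* **Affine gaps** (match +2, mismatch −3, gap run of length *g* costs
  16 + 2*g*, banded around the length-difference diagonal with margin
  16). With linear gap costs, the optimal-score global alignment of
  sequences of very different lengths degenerates into scattered
  single-residue matches — identity of a random 5-mer against a random
  60-mer approaches 1 — and every short sequence collapses into long
  clusters. Affine costs keep alignments compact, so identity reflects
  contiguous agreement, as in CD-HIT.
* **Minimum evidence.** A join additionally requires at least
  `min(8, shorter length)` matched residues. Without this rule, at a 0.4
  threshold the chance identity of short peptides (≤ ~16 residues)
  against *some* member of a several-hundred-sequence sample approaches
  certainty, making the methods that combine CD-HIT 0.4 with an exact
  positive length multiset (Witten&Witten) infeasible as a
  constraint-satisfaction problem. Word-filtered heuristic tools never
  face this because they only test candidate pairs that share seed
  words. Identical short duplicates still cluster (their match count is
  the whole sequence).

For length-range methods (whole-record negatives) the clustering runs on
a seeded random pre-subsample of about 1.3× the target sample size,
expanded (up to the whole filtered pool) if the survivors fall short.
Clustering the entire filtered database is quadratic and contributes
nothing to the sampled result beyond what the pre-subsample provides.
For "equal"-length methods with clustering, removed fragments are
refilled with freshly sampled fragments that stay below the threshold,
so the negative length multiset matches the positive one exactly.

### The BLAT stand-in

The similarity screen removes any candidate sharing a contiguous exact
10-mer with any positive (plus exact full-sequence matches). This is
deterministic, dependency-free and strictly conservative relative to a
heuristic local aligner at these peptide lengths.

## The ten architectures

`registry()` binds each published architecture's feature extractor,
selector and classifier:

| architecture | features (dim) | selector | classifier |
|---|---|---|---|
| AMAP | amino-acid composition (20) | — | linear SVM |
| AmPEP | reduced CTD distribution (23) | — | random forest |
| AmPEPpy | CTD distribution (105) | — | random forest |
| AmpGram | binary n-grams (data-dependent) | QuiPT | random forest |
| ampir | PseAAC λ=2 + physicochemical (27) | — | RBF SVM |
| CS-AMPPred | structural/physicochemical (9) | PCA | RBF SVM |
| iAMP-2L | PseAAC λ=20 (40) | — | fuzzy k-NN |
| MACREL | group/global descriptors (22) | — | random forest |
| MLAMP | AAC + grey-model coefficients (30) | — | random forest |
| SVM-LZ | LZ76 similarity profile (panel size) | — | RBF SVM |

Parameter choices where the sources are silent, all configurable:

* Random forests: 500 trees (`ranger`, single-threaded, seeded). SVMs:
  cost 1, `gamma = 1/p`, RBF kernel (linear for AMAP, following its
  original); scores are calibrated by a sigmoid fitted on training
  decision values so ROC curves are comparable across classifiers.
  FKNN: k = 5, fuzzifier m = 2, Euclidean distance on standardized
  features, exact-match short-circuit.
* PseAAC uses Chou's classic scale trio (hydrophobicity, hydrophilicity,
  side-chain mass), weight 0.05. The iAMP-2L architecture sets
  `cap_to_length = TRUE`: order factors beyond the peptide length are
  zero, keeping the 40-dimensional contract while allowing peptides of
  ≤ 20 residues — which are the *majority* of AMPs — to be scored. The
  bare `pseaac()` function keeps the strict error contract.
* The reduced AmPEP subset (23 of the 105 CTD descriptors) and the exact
  22-slot MACREL layout are configuration constants: the full
  hydrophobicity block, the cationic-charge class and part of the
  solvent-accessibility space for AmPEP; first-occurrence and fraction
  descriptors over two 3-group alphabets plus ten global descriptors for
  MACREL. Published sources give only counts and descriptor families;
  both defaults are explicit package choices and overridable.
* MLAMP's grey models are GM(1,1) fits (closed-form least squares on the
  accumulated series) of five per-residue property series
  (hydrophobicity, hydrophilicity, side-chain mass, pK1, pK2).
* QuiPT selects n-grams at Benjamini–Hochberg 0.05 with a cap on the
  selected count; the p-value is exact (hypergeometric enumeration of
  contingency tables, ties included in the rejection region at 1e-12
  tolerance). Note that for a feature identical to the labels the
  rejection region contains both deterministic tables (equal information
  gain), so the exact p is `2/choose(n, k)`.
* SVM-LZ's reference panel is 500 positives + 500 negatives sampled from
  the training data (seeded). LZ76 complexity is the exhaustive-history
  phrase count.
* CTD distribution descriptors use the standard 7-attribute × 3-class
  alphabet; a class absent from a peptide contributes zeros (keeping the
  dimension fixed). Net charge is Henderson–Hasselbalch at pH 7 with
  EMBOSS-style pK values; the isoelectric point is found by bisection;
  the hydrophobic moment is the Eisenberg vector sum at 100° per residue.
* The two deep-learning architectures of the original roster are
  registered (`registry(include_deep = TRUE)`) for grid planning — the
  full design counts 12 × 11 × 5 = 660 models — but are not trained:
  deep models are unstable at this data scale and sit outside this
  package's core.

## The grid and the diagnostics

`plan_grid()` / `run_grid()` train one model per (architecture, training
sampling method, replicate) and evaluate each against the shared positive
benchmark plus every method's benchmark negatives. Replicate pairing is
`paired_replicate` by default (train replicate *r* is scored against
bench replicate *r*; `full_cross` is available): reporting a mean AUC
over five replicates is consistent with paired evaluation, and nothing
in the replicated-benchmark design forces one choice over the other.

AUC is the Mann–Whitney statistic with half-credit for ties. Diagnostics:

* `bias_summary()`: per-architecture diagonal vs off-diagonal mean AUC
  and percentage improvement; per-cell replicate SD.
* `compute_distances()` + `correlation_analyses()`: Spearman correlation
  of cell-mean AUC (averaged over architectures, at (TSM, BSM, replicate)
  granularity — the grouping granularity behind the published
  correlations is not stated, and this choice is configurable by
  recomputing from the grid table) against the training/benchmark
  composition distance (Euclidean distance of pooled residue-frequency
  vectors), the absolute median-length difference, and the signed
  benchmark negative-vs-positive median-length difference.
* `mad_ratio()`: between-group MAD of group medians over the median of
  within-group MADs, unscaled (no 1.4826 consistency factor). Several
  constructions go by the name "MAD ratio"; this one is isolated behind
  a single function so it can be swapped.
* `group_tests()`: per-architecture Kruskal–Wallis (same vs different
  method) with Bonferroni across architectures; pairwise paired Wilcoxon
  within the architecture/TSM/BSM families (pairing on the complementary
  keys, Bonferroni within family). Spearman p-values use the exact
  distribution below n = 10 and the t approximation above.

## Problem sizes and determinism

The package's default experiment (`run_config()`) uses 1000 positives, a
20 000-record background, all 11 methods, the 10 classical
architectures and 2 replicates; the sampler invariants are additionally
exercised at 5 replicates. Two run-scale knobs are reduced relative to
the architectures' nominal settings: the SVM-LZ panel (200 instead of
1000 references) and the QuiPT cap (1000 instead of 5000 n-grams).
These sizes keep a full run in the tens of minutes on one core; the
dimension contracts are still asserted at the nominal panel size, and
both knobs are plain arguments for larger studies.

Every stochastic stage derives its seed from a single master seed via a
stable string hash (`derive_seed(master, stage, replicate)`), so the full
pipeline is bit-reproducible: identical config + seed give byte-identical
FASTA files, sampled datasets, grid tables and diagnostic tables, which
the test suite asserts end to end.

## Known limitations

* The synthetic generator's i.i.d. residues mean fragment negatives and
  whole-record negatives share a composition law except through the
  annotation couplings; real data separates them more strongly, so the
  desk-scale diagonal effect is, if anything, conservative.
* The clustering stand-in is exhaustive rather than word-filtered; its
  minimum-evidence rule is an explicit model of the heuristic behaviour
  of production tools, not a reimplementation of any specific one.
* Real-data AUC values, the deep-learning rows of the roster, and
  multiclass second stages of iAMP-2L/MLAMP are out of scope.
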