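---
title: "Calibrating glocal and local profile-HMM E-values through false-positive ranks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating glocal and local profile-HMM E-values through false-positive ranks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcal)
```

## The problem

Protein domain annotation searches a query sequence against a library of
domain models (profile HMMs built from curated seed alignments). Two search
regimes coexist. A *glocal* search is global over the model and local over
the sequence: every model position is traversed, so a hit asserts the
presence of the complete domain — the unit on which function transfer is
justified. A *multihit local* search may enter and exit the model anywhere;
it is much better suited to fast filtering but reports fragments, and its
score statistics differ. The practical consequence is that E-values produced
for the *same* model by the two builds are not comparable: a 1e-5 from one
build and a 1e-5 from the other correspond to very different error rates.

`xcal` makes them comparable by calibrating both builds of every model
against the same empirical null — the consensus sequences of every *other*
model in the library — and expressing any E-value as a *false-positive rank*
(FP): the position its score would take in the ascending sort of negative
E-values. FP divided by the number of negatives is the false-positive rate
(FPR), the cross-build common currency. On top of the calibrated library sit
(i) a per-model *build selection* (which build is more sensitive?), (ii) a
three-stage annotation workflow (fast local scan, glocal re-alignment of the
detected hits, FPR assignment), and (iii) a concordance screen that flags
hits whose two builds disagree about the error rate.

## The engine

Both builds are estimated from the same seed alignment. Every alignment
column becomes a match position, so the model length L equals the alignment
width; match emissions are add-pseudocount frequencies over the 20-letter
alphabet (default pseudocount 1, uniform background 1/20, both overridable);
rows passing through a gap follow the delete path and contribute
match/delete transition counts. Insert states carry background emissions and
pure-pseudocount transitions, since with all-columns-as-match the seed
contains no insert observations. Ambiguity codes (`X` and friends) score as
background — zero log-odds — wherever they are aligned.

The two builds share all emissions and internal transitions and differ only
in topology:

* **glocal** — entry only at position 1 (match or delete, with probabilities
  estimated from column-1 occupancy), exit only after position L; flanking
  sequence is scored at background (zero bits).
* **local (multihit)** — uniform entry probability 1/L into any match state,
  free exit after any match state, restart probability 0.5 between domains.
  Delete states are internal only. These are documented conventions, not
  estimates; a natural alternative (the L(L+1)/2 entry convention) differs
  only by a constant and would cancel in the rank-based calibration.

Alignment is by Viterbi dynamic programming in log2-odds space (compiled
code under `src/`), with deterministic tie-breaking in the traceback.
Viterbi — not Forward — is used as the score statistic for both modes: the
calibration framework needs one consistent statistic per build, and the
rank-based FP mapping absorbs any systematic offset between statistics.
The test suite proves both modes equal to exhaustive max-over-paths
enumeration on all small instances (models up to L = 3 against every
sequence of length up to 4 over a 4-letter alphabet).

E-values follow a Gumbel null, `E = Z (1 - exp(-exp(-lambda (s - mu))))`,
with `mu`, `lambda` fitted per model and build by maximum likelihood (Newton
iteration on the profile-likelihood equation for the scale) to Viterbi
scores of background-sampled sequences. Null lengths are uniform over
`[0.5 L, 2 L]`, bracketing typical query envelopes. For the local build the
fitted score is the best *untruncated* exit score: the reported multihit
total is clipped at zero (a sequence with no positive-scoring domain has no
alignment), and fitting the clipped statistic would degenerate for weak
models. `Z` defaults to the library size, mirroring a scan of one query
against the whole library.

## Calibration and the FP grid

For each model the query set is its own seed sequences, degapped (the alpha
positives), plus the consensus sequences of all other models (the
`n_total - 1` negatives). Both builds search this set at a permissive
capture cutoff of E <= 1000. Hits are stratified per query: the local hit
with maximal model-span overlap against the glocal hit is *paired* (ties to
the smaller model start); the rest are orphaned. For every paired hit the
glocal alignment is *reconstructed* over the local counterpart's model
window — its stored per-position and within-window transition contributions
are re-summed, the entry/exit terms included only when the window reaches
position 1/L — and the truncated score is converted to an E-value under the
unchanged glocal Gumbel parameters. The identity window `[1, L]` therefore
reproduces the original score exactly, which the tests assert for every
paired hit. Keeping the original null for the truncated score is the
package's convention for mimicking score dissection; with it, the glocal
build is compared to the local build on alignments of the same extent.

Per-query best E-values (undetected queries carry +Inf and are never
detected at any threshold) yield, per build, the calibration table: sorted
negative E-values (rank = FP), ROC and precision–recall points over the
distinct observed thresholds (ties absorbed together), and the boundary
E-value at each FP of the grid — the FP-th order statistic of the negatives.
The default grid is `1, 5, 10, 15, 20, 25, 30, 40, ..., 100`; with 16294
negatives its FPR values run from 6.14e-5 to 6.14e-3. The FPR denominator is
always the number of negatives (`n_total - 1`).

## Build selection

Sensitivity is compared by the partial area under the ROC staircase up to a
FP count x, normalized by the evaluation rectangle: the difference
`(AUC_H2 - AUC_H3) / (x / n_total)` is computed at every x of an FP set A
(default `1, 5, 10, 20, ..., 100`). The published normalization divides by
the library size while the FPR axis divides by the negative count; both are
exposed (`norm_n`), the sign — all that the criterion uses — is invariant to
the choice. Integration is right-continuous step integration of the
staircase (the TPR attained with r false positives holds on the r-th
interval; flat extension past the last detected negative); a trapezoid rule
would smear mass across the staircase's jumps and was rejected.

`count_y` counts the x at which the difference is strictly positive. The
glocal build is selected only when `count_y = |A|`; a zero count selects the
local build; anything between is *undetermined* — the model's relative
sensitivity fluctuates with the error level, and no single-build claim is
safe. The printed equations pairing zero counts with "undetermined" are
internally inconsistent with the accompanying prose and the published
totals, which require the mapping used here; a `literal_eq_mapping` flag
restores the printed pairing for comparison. Ties (difference exactly zero,
e.g. two builds with identical tables) fall to the local build, the faster
default, and undetermined models are likewise assigned the local build in
the workflow. Dropping small x values from A can only grow both decided
totals — the suffix sweep reported by `select_library()` makes that
monotonicity visible.

## The three-stage workflow

Stage 1 scans each query against the local-selected sub-library (M models)
at E <= 0.1 and the glocal-selected sub-library (N models) at E <= 24 — the
defaults correspond, on the published calibration, to the maximum sampled FP
values of the two builds, i.e. the cutoffs at which the smaller glocal
search space is captured. Stage 2 re-aligns every (query, model) pair
detected by the local scan — K distinct models — glocally, so *every* final
record spans the full model. Stage 3 assigns each hit's E-value a
standardized FP: the nearer margin, in log10 E-value, of the grid interval
containing it (an exact midpoint goes to the larger-FP margin — the
conservative error report); E-values below the first boundary are `FP<1`,
above the last defined boundary `beyond-grid`. Linear-E nearness was the
other candidate; log10 was chosen because boundary E-values span orders of
magnitude and the published profiles are read on log axes.

At the extremes the workflow degenerates exactly: all-glocal reproduces a
pure glocal annotation, all-local reproduces the local scan's detection set
with every record re-aligned ("glocal-mode" behavior from a local engine).
`top_n_override` keeps only the n highest-ranked glocal-selected models
(by `count_y`, then mean normalized AUC difference) to trade sensitivity
for speed.

The speed model is `f = M_h2 / (M_h3 + K_h2)` — glocal time over the M
local-selected models divided by local time over the same M plus
re-alignment time over the K detected models — bounded above by
`M_h2 / M_h3`. One published display writes the denominator's re-alignment
term with a local-time subscript; the definition fixes it as glocal time,
which is what is implemented. In this package both modes run the same
compiled kernel, so measured `f` is modest (~1.1); the dramatic published
speedups come from the asymmetry of the original engines (a SIMD-vectorized
local filter versus an unvectorized glocal implementation), which this
re-implementation deliberately does not reproduce. Timings are reported,
never asserted.

Paired FP assignments feed the concordance screen: `|FP_H2 - FP_H3| <= 4`
is concordant (FP values are rounded to grid margins, so small differences
are expected), and `FP_H2 - FP_H3 < -4` — the local build claiming a worse
error rate than the glocal build for the same hit — is flagged for
scrutiny. Sentinel-valued pairs are excluded from the histogram and counted
separately.

## The synthetic study conditions

Everything is testable offline through the fixture generator. A family is a
uniform-random consensus of length 60–90 with alpha = 8 seed rows copying
the consensus per column with probability 0.95 (a typical curated-seed
conservation level); queries implant one noisy domain copy each between
background linkers of 15–40 residues, plus 20% implant-free decoys; the
background is uniform, matching the engine's null, so implant log-odds are
calibration-consistent. All generation is deterministic per seed. Test
problem sizes: a 10-model library for the calibration/selection/workflow
suites, a 30-model library for the end-to-end recovery check, 100–200 null
samples per Gumbel fit — sizes at which every property under test is
already expressed.

The `weakened_local` flag exists to force glocal selection for chosen
models. Per-column substitution noise below 1.0 turned out not to work as a
weakening device: a weak-but-consistent emission signal over 50+ columns
still separates positives from negatives perfectly, and the rank-based
criterion sees a tie. The flag therefore resamples every column of the
local build's seed copy (an uninformative local build), the one regime that
breaks separation at desk scale.

What the fixtures do *not* emulate: realistic amino-acid composition,
indel-rich evolution, repeats, non-globular segments, clan-style
relatedness between families. Passing tests demonstrate the calibration
machinery and its invariants, not performance on real libraries; on real
data the FPRs remain worst-case estimates because a "false" consensus hit
can be a genuinely related domain.

## Numerical choices and limitations

* All dynamic programming in log2 space; traceback ties resolved in a fixed
  state order, so identical inputs and seeds give bit-identical outputs.
* Gumbel fitting centers scores first (location equivariance to
  floating-point accuracy) and falls back to bracketed root finding if the
  Newton iteration stalls; constant score samples are an error.
* Per-domain E-values of a multihit alignment are computed from the
  per-domain bit score under the sequence-level null — a documented
  simplification; the calibration consumes per-query best E-values only.
* One glocal re-alignment is produced per (query, model) pair even when the
  local scan reported several domains: glocal output is unique per pair.
* A hit against a model whose table has no detected negative (hence no grid
  boundary) is reported as `FP<1`: it beats every observed negative.
* Parity with the original HMMER programs is not attempted: no
  Dirichlet-mixture priors, no Forward scores, no save-file parsing, no
  bit-exact scores, no logistic high-score tail. The contribution
  implemented here is the calibration, selection and workflow layer, which
  is engine-agnostic by construction.
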