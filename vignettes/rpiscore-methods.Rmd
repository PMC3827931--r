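---
title: "rpiscore: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rpiscore: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`rpiscore` scores the interaction propensity of an (RNA, protein) sequence
pair with a sum of bilinear forms over fixed-length channel encodings.

**Encoding.** Each RNA sequence is turned into three per-residue numeric
profiles: a secondary-structure pairedness count (how many of $n$ folded
structures pair each base; $n = 6$ by default), and hydrogen-bonding and
Van der Waals per-base contact propensities. Each protein is turned into
five profiles: a Chou–Fasman propensity selected per residue by a
predicted 3-state secondary structure, plus Grantham and Zimmerman
polarity (hydrogen-bonding proxies) and Kyte–Doolittle and Bull–Breese
hydropathy (Van der Waals proxies).

**Compression.** Profiles have sequence-dependent length $L$, so each is
compressed to its first $m = 10$ cosine-series terms,
$$X'_k = \frac{2}{L}\sum_{n=0}^{L-1} X_n
\cos\Big(\frac{\pi}{L}\big(n+\tfrac12\big)\big(k+\tfrac12\big)\Big),
\qquad k = 0,\dots,m-1,$$
a scaled DCT-IV. The printed form of this sum has an upper bound that
would index one element past the series; we sum to $L-1$, the only
reading under which every term exists. No other normalization is applied,
and $L < m$ is allowed (no zero-padding).

**Pair features and scoring.** For a channel pairing, the protein vector
$p$ and RNA vector $r$ are combined into the outer-product vector
$x = (p_1r_1, p_1r_2, \dots, p_{10}r_{10})$, so any bilinear score
$p^\top M r$ is the inner product $k \cdot x$ with $k$ the row-major
flattening of $M$. Five pairings are scored — structure × structure,
Grantham × hbond, Zimmerman × hbond, Kyte–Doolittle × VdW, Bull–Breese ×
VdW — matching each protein channel with the RNA channel carrying the
same kind of physical information. Cross-kind terms (e.g. protein
structure against RNA hydrogen bonding) are deliberately never formed.

**Training.** Per channel, $k$ is the Fisher discriminant direction
maximizing $J(k) = (m_1-m_2)^2/(s_1^2+s_2^2)$ of the projected training
features, computed in closed form as $(S_W + \lambda I)^{-1}(m_1 - m_2)$
and oriented so the interactive class projects higher.

**Calibration and fusion.** Raw channel scores have incomparable
magnitudes, so each is mapped to the open interval $(0,100)$ by
$$Y = \frac{100}{\pi}\arctan\Big(\frac{2(X-c)}{c_1-c_2}\Big) + 50,$$
with $c_1 = k\cdot m_1$, $c_2 = k\cdot m_2$, $c = (c_1+c_2)/2$ fixed from
the training class means. $Y(c) = 50$, $Y(c_1) = 75$, $Y(c_2) = 25$, and
any positive rescaling of $k$ leaves $Y$ unchanged. The final score is
the arithmetic mean of the five calibrated scores (an alternative
weighting, 1/3 on structure and 1/6 elsewhere, is available via
`model_config()` but is not the default: equal weights predict better). A
pair is called interactive only when its final score is strictly over 50;
exactly 50 is non-interactive.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_struct` | 6 | folded structures summed into the pairedness channel; values 5–8 perform equivalently, 6 is the cheapest of the plateau |
| `n_terms` | 10 | compressed dimension per channel (100-D pair features); higher dimensions cost quadratically and gain little |
| `ridge` | 1 | relative shrinkage $\lambda = \mathrm{ridge}\cdot\mathrm{tr}(S_W)/d$ added to the scatter before inversion (see below) |
| `threshold` | 50 | classification cutoff on the calibrated scale; strict |
| `distance_cutoff` | 5 Å | least-atom-distance labeling cutoff for training-set construction (7 Å reproduces the alternative regime) |
| `min_rna_len` | 100 nt | keep pairs whose RNA is *strictly* longer; the boundary reading is ambiguous in the source material, so it is configurable |
| `max_rna_len` | 4095 nt | input limit of the reference suboptimal folder, mirrored by the built-in folder's policy (`error` or `truncate`) |
| identity cutoffs | 0.9 / 0.9 | redundancy removal drops a pair only when **both** its protein and its RNA match a retained pair at or above cutoff |

## Why the ridge is large

The pair features are products of DCT coefficients. Their covariance is
extremely anisotropic: the leading coefficient pair carries most of the
variance and many cross-coordinates are nearly degenerate. With $d = 100$
and a few hundred training pairs, the within-class scatter is effectively
singular, and a token ridge (relative size $10^{-6}$) produces a weight
vector dominated by sampling noise in the near-null space: in our
planted-data experiments, two discriminants trained on independent
datasets from the *same* generative process were close to orthogonal
(cosine ≈ −0.07). Projections still classify tolerably (noise components
self-cancel in $k\cdot x$), but the vector itself is meaningless — and
held-out performance is measurably worse. Sweeping the relative ridge
from $10^{-6}$ to 2 improves estimator self-consistency, held-out
cross-validated DP and planted-direction recovery monotonically and
together, stabilizing once $\lambda$ reaches the average eigenvalue
$\mathrm{tr}(S_W)/d$. The default is therefore `ridge = 1`: the
heavy-shrinkage regime standard when the feature dimension is of the
order of the class sizes. Dominant, well-estimated eigendirections are
still whitened (their eigenvalues exceed $\lambda$); near-null directions
are damped instead of amplified. `ridge` is an explicit argument
everywhere, with `ridge = 0` giving the textbook unregularized closed
form (used by the oracle tests), and a pseudo-inverse as a final
fallback.

## Backends

The reference method folds RNA with an external thermodynamic
suboptimal-structure program and predicts protein secondary structure
with a legacy external tool. Both are replaced by desk-scale built-ins
behind narrow interfaces, and both can be swapped for adapters replaying
real external output (`rna_folder_precomputed()`,
`protein_ss_precomputed()`):

* the built-in folder is Nussinov-style maximum base-pairing (Watson–
  Crick + GU wobble, minimum hairpin loop 3) with enumeration of
  co-optimal structures, deduplicated, pair count standing in for free
  energy. If fewer than `n` distinct structures exist, the best one is
  repeated to reach `n`, keeping the channel magnitude comparable across
  sequences. The structure list is returned best-first, so the
  pairedness profile is monotone when more structures are requested from
  a nested list.
* the built-in 3-state predictor applies Chou–Fasman-style
  window-averaged helix/sheet propensities with nucleation threshold 1;
  it is deliberately coarse — the encoding only consumes a plausible
  `{H,E,C}` string, and every correctness test injects a mock predictor.

Two encoding conventions the source material leaves open: the coil/other
state is encoded with the **turn** propensity table (the classic tables
have no coil class; the mapping is exposed in `encode_protein_structure`),
and ambiguity letters encode as the unbiased arithmetic mean of their
compatible residues (`B` over D/N, `Z` over E/Q, `X`/`U` over all 20, RNA
`N` over A/C/G/U).

The per-base RNA hydrogen-bonding and Van der Waals tables are a special
case: the method derives them from contact statistics over 41 RNA–protein
complexes, but the numbers themselves are not printed in any source
available offline. The shipped tables
(`inst/extdata/scales/rna_*_synthetic.tsv`) are provisional synthetic
stand-ins encoding only the purine > pyrimidine contact trend; they are
plainly labelled as such, are editable data files, and no test depends on
their values.

## Evaluation

Discriminative power counts ordered (interactive, non-interactive) score
comparisons with $\theta(0) = 1$ **in both sums**, so a tie contributes to
numerator and the reverse count simultaneously. This differs from
rank-based AUC (which splits ties): an all-tied score set gives exactly
0.5, and $DP(\text{pos},\text{neg}) + DP(\text{neg},\text{pos}) \ge 1$
with equality only without ties. DP is invariant under any strictly
increasing transform, so calibration never changes it. MCC uses the
standard zero-denominator → 0 convention; reported MCC/accuracy use the
strict threshold 50 (the source material does not state whether its
values used an optimized threshold; we do not optimize). Cross-validation
is stratified by label with a mandatory seed, trains on $k-1$ folds,
scores the held-out fold, and reports the mean per-fold DP plus pooled
MCC/accuracy; calibration constants are always re-estimated from the
training folds only.

## Dataset construction

From PDB-format complexes: chains are typed by majority residue kind;
within-complex chains with identical sequences are collapsed per polymer
kind (cross-kind collapsing never happens), and a collapsed
representative is labeled interactive if **any** of its copies is within
the cutoff of any copy of the partner (conflicts are logged). Labeling
uses the least atom distance over *all* atoms (a heavy-atom-only switch
exists; hydrogens are absent from typical crystal structures anyway) and
is strictly `< cutoff`. The built-in sequence identity is a global
alignment fraction (match 1, mismatch 0, linear gap 1) — an approximation
of the word-based clustering tool the reference pipeline uses; its
`.clstr` output can be ingested for exact reproduction. Redundancy
removal scans greedily in input order and never re-sorts silently.
NPInter-style evidence codes classify as direct ({1, 5, 6}) or indirect;
shuffled negative sets re-pair RNAs against a seeded permutation of the
proteins, redrawing (up to 100 times) when an original pair reappears.

## The synthetic generator: what it emulates and what it does not

`planted_pair_dataset()` produces the dataset the discriminant stage is
validated on. Design, in order of the decisions taken:

1. **Labels are planted in feature space, realized in sequence space.**
   Positive pairs draw residues with probabilities
   $\propto e^{+\beta z}$ along the Grantham (protein) and RNA
   hydrogen-bonding scales, negatives $\propto e^{-\beta z}$; the signal
   is therefore genuine sequence composition, traversing the real
   encoding pipeline, not injected numbers.
2. **The tilt $\beta$ is calibrated to the requested separation.** Class
   means of compressed channels are analytic for i.i.d. sequences (mean
   propensity times a fixed length-averaged compression pattern); the
   feature covariance comes from a large seeded reference sample. A root
   search sets $\beta$ so the class means sit `separation` pooled SDs
   apart along the planted direction (default 4, with realized values
   landing within ~10%).
3. **The planted direction is the population ridged Fisher direction**
   of this generative model — the direction an ideal trainer of the same
   family should recover. Defining it as, say, the raw mean-difference
   would make "recovery" compare two estimators of *different* targets.
   With labels assigned by thresholding the noisy projection
   $w\cdot x + \text{noise}\cdot\sigma\varepsilon$ (top half →
   interactive, so the class split is exactly even), population theory
   makes the Fisher direction proportional to $w$ itself.
4. **Noise** perturbs the labeling projection; at the default 0.1 it
   flips essentially no labels at separation 4, and at separation 0 the
   generator degenerates to random balanced labels (requesting separation
   0 with noise 0 is an error).

All generators are pure functions of (spec, seed); nothing touches the
caller's RNG stream.

What a green planted-recovery test establishes: the encoding →
compression → outer-product → shrunken-Fisher → calibration → fusion
chain recovers a composition-level signal of the stated strength from
400 pairs, with cross-validated DP ≥ 0.95 and direction cosine ≥ 0.9,
while permuted labels stay at chance. What it does **not** establish:
performance on real PDB-derived training sets (ribosome-dominated
composition, structural signal, far stronger length heterogeneity), the
quality of the provisional RNA contact tables, or the fidelity of the
built-in folder to a thermodynamic ensemble. The headline published
numbers (DP ≈ 0.90/0.94, MCC 0.74/0.83, NPInter DP 0.917) require the
original external downloads and are intentionally outside the test
surface; `build_dataset()` + `train_model()` + `evaluate` reproduce that
workflow when the complexes are supplied.

## Numerical conventions, in one place

* Summation bound of the compression formula: $n = 0 \dots L-1$.
* Fisher orientation: $k$ flipped if needed so $c_1 > c_2$; scale of $k$
  irrelevant downstream.
* Degenerate training (identical class means) is an error naming the
  channel, not a silent zero.
* Classification at exactly the threshold is non-interactive.
* Calibration constants come from training-set means only, fixed at
  training time.
* Model archives are JSON with 17 significant digits, which round-trips
  IEEE doubles bit-exactly; the archive embeds config and all propensity
  tables, so a model file is self-contained.
* RNA length filter: strictly greater than `min_rna_len`, at most
  `max_rna_len`.
* `sample()`-style scalar pitfalls are avoided (`sample.int` over
  explicit choice vectors), so degenerate length ranges are exact.

## Known limitations

* The built-in folder is $O(L^3)$ and maximum-pairing, not thermodynamic;
  beyond ~500 nt it is slow and the ensemble proxy is crude. Use the
  precomputed adapter with real suboptimal-folder output for long RNAs.
* The built-in secondary-structure predictor is a caricature of the
  legacy tool it stands in for; its only contract is a well-formed
  3-state string.
* The provisional RNA contact tables make absolute default-scale scores
  biologically uninterpretable until replaced with measured values —
  relative scores and everything the tests assert are unaffected.
* mmCIF, multi-model averaging and biological-assembly expansion are out
  of scope; only the first model of a PDB file is read.
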