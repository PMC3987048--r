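---
title: "Methods: coevolution-based contact prediction"
author: "coevcontact developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coevolution-based contact prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Residue pairs that are in contact in a protein's native structure tend to
mutate in a correlated way across the protein family: a destabilising
substitution at one position is compensated at its spatial neighbour. Given
a deep multiple sequence alignment (MSA), the covariation structure of its
columns therefore carries a signal about the contact map. The difficulty is
that raw correlation mixes direct interactions with chains of indirect ones;
the two method families implemented here both *deconvolve* the correlation
matrix to recover direct couplings:

* **Mean-field direct coupling analysis (mfDCA)** treats the empirical
  site-state covariance matrix
  $C_{(i,a),(j,b)} = f_{ij}(a,b) - f_i(a) f_j(b)$
  as the correlation matrix of a Potts model and obtains couplings as its
  (negative) inverse, $\Gamma = C^{-1}$, computed by dense Cholesky
  inversion.
* **Sparse inverse covariance estimation** assumes the precision matrix is
  sparse -- most position pairs do not interact -- and estimates it by the
  graphical lasso: maximise
  $\log\det\Gamma - \mathrm{tr}(C\Gamma) - \rho\,\lVert\Gamma\rVert_{1,\mathrm{off}}$.

Both share the same upstream statistics (sequence weighting, pseudocounted
frequencies, covariance construction) and the same downstream scoring
(per-pair block norms with average product correction), which is why a
single pipeline can serve as a drop-in implementation of either family via
the `parprof` profiles.

## Pipeline stages and their parameters

### Alphabet and gap handling

Sequences are encoded over 21 states: the 20 canonical amino acids
(`A`..`Y`, codes 0--19) plus a pooled state (code 20) holding gaps *and*
every non-canonical symbol (`B J O U X Z`, lowercase, `.`). Pooling keeps
the state count fixed and treats rare ambiguity codes as missing data,
which is what a 21-state frequency model does naturally. Decoding maps the
pooled state back to `-`. Target gap columns are *not* removed; the
alignment is assumed target-matched by the upstream alignment tool.

### Sequence weighting (`clustpc`, `comparison`)

Each sequence is down-weighted by the size of its identity cluster:
$w_m = 1/\lvert\{m' : \mathrm{id}(m, m') \ge \texttt{clustpc}\}\rvert$,
and $M_\mathrm{eff} = \sum_m w_m$ is the effective number of sequences.
Identity is counted over the full alignment length with gap treated as a
21st symbol (gap--gap matches, gap--residue mismatches); the original
tools do not document their convention, so this package states its own
loudly and tests it against a per-pair brute-force oracle, bit-identically.
The comparison is `>=` by default; `>` is provided because the two
semantics differ exactly on alignments holding a pair at the threshold
identity, a boundary the test suite constructs explicitly. An alignment
with $M_\mathrm{eff}$ below `min_meff` (default 1.5: one effective
sequence carries no covariation signal) aborts with a dedicated
insufficient-weight condition, exit code 2 at the command line.

### Frequencies and pseudocounts (`pseudocnt`, `pscount_weight`)

Weighted counts are regularised with an effective pseudocount mass
$\lambda' = \lambda\,(\texttt{pscount\_weight}\cdot M_\mathrm{eff} +
(1 - \texttt{pscount\_weight}))$, split uniformly over states:
$f_i(a) = (\lambda'/q + c_i(a))/(\lambda' + M_\mathrm{eff})$ and
$f_{ij}(a,b) = (\lambda'/q^2 + c_{ij}(a,b))/(\lambda' + M_\mathrm{eff})$.
The interpolation reduces to the classic fixed pseudocount at weight 0
(the sparse-inverse-covariance convention) and to the
$M_\mathrm{eff}$-proportional pseudocount at weight 1 (the mfDCA
convention), which is how the two profiles use it. The parameter name
"pseudo-count for sequence weighting" in the original tool's option table
is, in the standard DCA formulation, a frequency regulariser; this package
adopts the standard role and flags the naming discrepancy here. Sharing
$\lambda'$ between the single and pair tables makes the marginalisation
identity $\sum_b f_{ij}(a,b) = f_i(a)$ exact, which the tests assert at
1e-9.

### Gap masking (`apply_gapth`, `gapth`) and covariance (`cov20`)

Columns whose *weighted* gap frequency exceeds `gapth` (strictly) are
excluded from the covariance matrix and can never appear in output
contacts. The gap frequency is computed from raw weighted counts, before
pseudocounting -- otherwise an all-gap column could pass a threshold near
1. Whether the original implementation masks before or after
pseudocounting is undocumented; this choice is ours.

With `cov20 = TRUE` one state per site is dropped so the covariance is not
overdetermined (each site's 21 frequencies sum to 1, so the 21-state
blocks are rank-deficient without pseudocount). The dropped state is the
pooled gap state, keeping the retained 20-by-20 blocks purely amino-acid;
the original description says only that "one amino acid is left out".

### Inference

*Shrinkage.* The covariance is blended toward a scaled identity,
$C' = (1-\alpha) C + \alpha\,\overline{\mathrm{diag}(C)}\, I$, taking the
smallest $\alpha \in \{0, 0.05, \dots, 1\}$ whose Cholesky factorisation
succeeds. The original tool names the step but not the rule; step 0.05
with a Cholesky test is our reconstruction and is recorded in the run log.

*Dense inversion* (`estimate_ivcov = FALSE`) uses the Cholesky factor and
reports the residual $\lVert C\Gamma - I\rVert_\max$ (asserted below 1e-6).

*Graphical lasso* (`estimate_ivcov = TRUE`) is implemented from scratch in
C++ as block coordinate descent on the covariance with soft-thresholded
inner coordinate descent, an active-set strategy, warm starts, and exact
zeros in the off-diagonal support (so the reported density is not
tolerance-dependent). The penalty applies off-diagonal only. With a
`density` target, $\rho$ is adjusted from `rho` by geometric bracketing
(factor 2) and log-space bisection until the achieved off-diagonal density
is within 20% relative of the target or 12 adjustment rounds have
elapsed -- the search procedure is not documented in print, so these
constants are package choices. The timeout (`icme_timeout`, default
1800 s) is cooperative: wall time is checked between column updates, the
abort leaves a consistent state, and a dedicated timeout condition maps to
exit code 3.

### Scoring (`norm`, `mincontsep`)

The coupling matrix is collapsed to one raw score per column pair as the
norm of the corresponding 20x20 (or 21x21 when `include_gap_state = TRUE`)
block: Frobenius in the mfDCA profile (corrected-norm convention), L1 in
the sparse profiles. The original publications name the score families but
not the norms; the choices follow the cited methods and are switchable.
Scores then receive the **average product correction**
$\mathrm{CN}_{ij} = S_{ij} - \bar S_i \bar S_j / \bar S$, which removes
background and phylogenetic signal shared across a row. The means exclude
the (structurally zero) diagonal by default. A subtlety worth recording:
the classic motivation -- APC exactly annihilates a rank-one background
$S_{ij} = u_i u_j$ -- holds exactly only when the diagonal participates in
the means; under diagonal-excluding means only constant matrices are exact
fixed points (for $u = (1,2,3,4)$ the residual correction is $-26/35$ at
entry (1,2), a value frozen in the tests). `apc(S, exclude_diagonal =
FALSE)` exposes the exact-annihilation variant; the default matches the
zero-diagonal score matrices the pipeline produces. Pairs at separation
$j - i \ge$ `mincontsep` (inclusive) are reported, sorted by corrected
score, ties broken by ascending $(i, j)$ for byte-stable output.

### Profiles

`evfold`: inversion path, `cov20 = TRUE`, `clustpc = 70`,
Meff-proportional pseudocount, no gap masking, Frobenius norms.
`psicov`: graphical lasso with density target 0.03 from `rho = 0.001`,
`cov20 = FALSE`, `clustpc = 62`, fixed pseudocount, gap masking at 0.9,
L1 norms. `psicov-sd`: as `psicov` with fixed `rho` (no density search).
**All numeric profile constants are reconstructions** from the cited
methods: the original tool defines them in its distributed README, which
is not part of the published record. They are echoed into the run log so
any run documents its own parameterisation.

## Evaluation module

Truth contacts follow the CASP convention: C$\beta$--C$\beta$ distance
(C$\alpha$ for glycine) strictly below 8 Å, read from `ATOM` records of
the first model, altloc resolved by highest occupancy then alphabetical.
Precision is reported for the top $\lfloor L/n\rfloor$ predictions,
$n \in \{1,2,5,10\}$, within separation bands $j - i > \mathrm{sep}$,
$\mathrm{sep} \in \{4,8,11,23\}$. Note the deliberate asymmetry, preserved
from the conventions of the respective sources: the *evaluator* filters
strictly (`>`), the *predictor's* `mincontsep` inclusively (`>=`). Cells
with no admissible pairs are reported missing rather than 0, so short
proteins are not penalised. Rounding of $L/n$ is floor (undocumented in
the source conventions; ours). Prediction indices are assumed to map to
structure residues by chain-order identity -- there is no SIFTS-style
renumbering.

## The synthetic generator: what a green test establishes

`planted_model()` / `sample_alignment()` draw sequences from a Potts-like
distribution $p(x) \propto \exp(\sum_i h_i(x_i) + \sum_{(i,j)\in E}
\beta\,[x_i = x_j])$ by single-site Gibbs sampling (single chain, burn-in
`100 * L` sweeps, one sequence recorded every `thin = 10` sweeps;
implemented in C++ on R's RNG so runs are reproducible under a seed).
The same-state-bonus coupling is deliberately minimal -- two parameters
create detectable covariation -- and `add_redundancy()` plants known
cluster structure for the weighting stage. What this emulates: planted
direct couplings, field biases, redundant subfamilies. What it does not:
phylogenetic tree correlation, alignment errors, gap stretches from
indels, or contact-density patterns of real structures. A green
planted-pair recovery test therefore establishes that the inference
machinery deconvolves *direct* couplings at realistic depth
($M = 3000$, $L = 30$, $\beta = 2$), not that field performance on real
families matches any published benchmark -- those benchmarks require the
external 140-protein test set and are out of scope by design.

## Numerical choices

Double precision throughout (the original's single-precision paths were a
speed optimisation on 2014 hardware; the glasso and inversion here are
fast enough in double). Glasso convergence: max working-covariance change
below `tol` times the mean absolute off-diagonal of the input; inner
coordinate descent at a tenth of that. Shrinkage step 0.05. Density
tolerance 20% relative, 12 rounds. Degenerate inputs (mean diagonal
$\le 0$, all columns masked, non-finite model parameters) raise typed
conditions rather than propagating NaNs. The pipeline accepts a `threads`
argument for interface compatibility but is single-threaded; the contract
-- results independent of thread count, byte-identical reruns -- is
asserted in the acceptance suite.

## Known limitations

No A3M/Stockholm input (pre-aligned FASTA or flat only); no direct
information scores (corrected norms replace them by design); no
pseudolikelihood (plmDCA-style) inference; profile constants are
reconstructions, not canonical; evaluation assumes identity
residue mapping.
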