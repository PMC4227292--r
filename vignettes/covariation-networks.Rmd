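---
title: "Covariation dependency networks: model, refinement, scoring, and realignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariation dependency networks: model, refinement, scoring, and realignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covarnet)
```

## The model

covarnet analyzes fixed-length categorical alignments: `n` sequences
by `L` positions, every cell a single-character category (nucleotide,
amino acid, gap, or any custom symbol set).  Three distributions
summarize such a family:

* the **marginal** $p_j(M)$ — the frequency of category $M$ at
  position $j$ (the columns of a PSSM);
* the **joint** $p_{jk}(M, N)$ — how often $M$ at $j$ co-occurs with
  $N$ at $k$ across sequences;
* the **residual** $r_{jk}(M, N) = p_{jk}(M, N) - p_j(M)\,p_k(N)$ —
  the signed departure of the joint from what independent positions
  would give.

A positive residual means the pair co-occurs above expectation (drawn
solid), a negative one below (drawn dashed).  Because both terms share
the same margins, every residual matrix sums to zero globally and
along each row and column; the package asserts this identity at
`1e-12` whenever the pseudocount is zero, which is why raw counts
(not smoothed frequencies) are used for all statistics.

The data structure holding all of this is a *metagraph*: one node per
position, one weighted *subnode* per observed category within the
node, and edges only between subnodes of different positions.  Each
edge carries the joint count, the residual, and a two-sided Fisher
exact p-value obtained by collapsing the pair to the 2x2 table
"($M$ at $j$?) x ($N$ at $k$?)".  The two-sided convention is the
point-probability sum — all tables with the observed margins whose
point probability does not exceed the observed one, with a relative
tolerance of `1e-9` so that floating-point ties resolve conservatively
(toward the larger p).  Category pairs never observed together
produce no edge; the complete bipartite structure is implicit.

Long-range dependencies are the entire point: a stem-loop pairs
sequence-distant columns through Watson–Crick complementarity and
produces the characteristic X-shaped quartet of subnode edges between
the paired positions, invisible to any model that assumes positional
independence or first-order (Markov) structure.

## Refinement

A raw scan of all $L(L-1)/2$ position pairs (36 for a 9-column
family; 44,850 for 300 positions) yields far too many edges to train
a model on.  `filter_edges()` applies the three thresholds of a
`filter_spec` — minimum $|r|$, maximum p, minimum joint count — and
retains an edge when it passes all of them *or* is pinned.  Pinning
(`pin_edge()`) encodes domain knowledge: a biologist keeps the
Watson–Crick edges of a known stem regardless of their weights.
`remove_edge()` is the complementary manual edit.  All operations
append to a replayable history, so an interactive refinement session
is reproducible as a script; `replay_history()` on a freshly rebuilt
metagraph restores the retained set exactly.

Filtering always re-evaluates the full non-removed edge set, making
it idempotent and monotone (tightening a threshold can only shrink
the retained set, up to pinned edges).  Subnodes and their weights
are never touched by filtering — the node layer describes the data,
not the analyst's current view of it.

Cycle detection (`detect_cycles()`) defaults to the *node-level
projection*, where positions are adjacent if any retained edge joins
their subnodes: cycles at this level are what make a graphical model
expensive to train, and the X-shaped stem quartet correctly projects
to a single (multi-)edge with no cycle.  Subnode-level detection is
available via the `level` argument.  `label_components()` gives each
disjoint subnetwork a deterministic label (ordered by smallest member
position, then category order) so that coherent groups of weak
dependencies can be retained together.

## CRF scoring

`build_crf()` converts a refined metagraph into an unnormalized
pairwise conditional-random-field scorer.  Node potentials are logs
of additively smoothed marginals; for every position pair carrying at
least one retained edge, the edge potential table is

$$\phi_{jk}(M,N) = \log\frac{\tilde p_{jk}(M,N)}{\tilde p_j(M)\,\tilde p_k(N)},$$

with joint smoothing $\alpha/(n + \alpha|A|^2)$ and marginal
smoothing $\alpha/(n + \alpha|A|)$.  The default $\alpha = 0.5$
(Jeffreys-style) guarantees finite scores for unseen pairs; it is a
flag, not a constant.  Potentials are read directly from counts — no
iterative training — because the model's job here is comparative
scoring over a user-refined structure, not density estimation; a
partition function is deliberately not computed, and all reported
scores are log-potential sums or fold ratios against a reference
(`relative_score()`, which returns exactly 1 for the reference
itself).  With no retained edges the model reduces to a smoothed
PSSM, which is also the baseline the package tests against: on
stem-loop families the full-edge CRF ranks every
complementarity-consistent double mutant above every equal-Hamming
violating mutant, while the PSSM cannot (with near-uniform paired
columns its node terms are essentially blind to the pairing).

Candidate sequences must be pre-aligned to the model length; there
are no insertion or deletion states.

## Echo detection and dependency-guided realignment

When a subset of sequences carries a motif shifted by a few columns,
the column-frame marginals blur, but the *dependency* between motif
positions survives — repeated once per shifted subset: the same
category pair at the same lag at consecutive start columns.
`detect_echoes()` finds these runs among retained edges, grouping by
`(M, N, lag)` and keeping maximal consecutive runs of length at least
`min_run` (default 3: under the null, same-pair same-lag significant
edges at 2 consecutive columns arise too easily).  Runs are ordered
by length, then lag (a longer lag spans more consensus columns and is
the more specific fingerprint), then start.  Gap-category edges are
excluded by default: translation padding trivially correlates gaps at
consecutive columns.

`assign_shifts()` implements "aligning the dependencies rather than
the symbols" with explicit, logged heuristics (the interactive
selection the original workflow left to the analyst has no published
algorithm, so the package commits to one):

1. candidate offsets are `-1 .. run_length - 1` — run members sit at
   non-negative offsets from the anchor, with one negative slot in
   case the leading member fell below the filter;
2. sequences matching the pattern pair at exactly one offset are
   anchored there;
3. anchored sequences define a motif-frame consensus (columns around
   the pair whose modal symbol reaches 0.6);
4. sequences with several full matches take the full-match offset
   that best agrees with the consensus (ties: smallest `|s|`, then
   negative);
5. sequences with no full pair match anywhere keep offset 0 — moving
   a partial matcher would inflate the pattern's marginals without
   adding joint mass and dilute the very dependency being aligned;
6. offsets are re-centered on the participants' modal offset, so the
   densest subset stays put and iteration repairs stragglers instead
   of translating the whole family.

`apply_shifts()` translates rows rigidly, gap-filling vacated cells
(`trim` keeps length `L`; `extend` widens to keep every symbol), and
`iterative_realign()` loops build → filter → detect → assign → apply
until no qualifying echo remains, an assignment exactly reverses the
previous one (oscillation guard), or `max_iter` (default 10).  The
realignment filter default is `filter_spec(0.02, 0.001, 0)`: the
residual of one echo copy is roughly `occupancy / n_shifts` times the
non-co-occurrence rate, about 0.05–0.07 under the generator defaults
below, so the threshold sits at about half the expected copy signal;
the p-value does the statistical gatekeeping.

Because the realigned frame is only defined up to a global
translation, recovery of planted offsets is measured modulo a
constant shift.

## The cylinder layout

`compute_layout()` arranges the position axes uniformly around a
cylinder, `theta_j = 2*pi*(j-1)/L` plus a deterministic per-position
jitter of magnitude `min(0.1 * 2*pi/L, 0.02)` rad derived from the
golden ratio (no randomness — layouts are reproducible bytes).
Categories take fixed, strictly increasing heights in alphabet order,
and glyph *area* is proportional to marginal weight so that visual
weight is linear in probability (the scaling law is this package's
choice).  The layout is a function of the dimensions, alphabet, and
marginals only — never of the filter state — so coordinates stay
stable while edges are refined.

`check_occlusion()` certifies that no edge is colinear with and
overlaps another (relative tolerance `1e-9`).  A design note: with
all axes on one circle of common radius, three distinct axis points
are never colinear, and a chord's supporting line is fixed by its two
endpoint heights, so two distinct subnode edges cannot be
colinear-overlapping in this layout family at all — the certificate
holds by construction, and the test suite verifies it empirically for
`L` from 4 to 60 with and without jitter.  The jitter and the
certificate are kept because both matter the moment a user overrides
angles or radii (the check accepts any layout object), and the
positive control in the tests exercises exactly such a hand-built
degenerate layout.  `export_scene()` writes a JSON scene (glyphs,
edge segments, solid/dashed sign styling, component and cycle
annotations) or a Wavefront OBJ line set; re-export is
byte-identical.

## Synthetic families

The generators exist so every pipeline stage is testable against
planted truth, and their defaults are the package's study conditions:

* `generate_independent_family()` — null columns, default n = 200,
  L = 20, uniform A/C/G/T.  Used for calibration: at p < 0.001 the
  flagged fraction over all subnode pairs should sit near 0.001
  (the exact test's discreteness makes it conservative, so the
  observed fraction runs below nominal; the tests allow a
  3-binomial-SD band).
* `generate_stemloop_family()` — default n = 500, four disjoint
  paired positions, uniform 5' symbol complemented at the partner,
  per-symbol noise 0.05 (resampled uniformly).  The uniform paired
  distribution keeps all 16 Watson–Crick subnode edges strong enough
  to outrank every spurious edge, and makes paired-column marginals
  uninformative — exactly the regime where the PSSM baseline fails.
* `generate_echo_family()` — default n = 400, L = 30, motif
  consensus `TCA` (a forced T···A pair at lag 2 with a conserved
  interior base) at anchor column 14, carried by 40% of rows at
  offsets uniform on 0..3, noise 0.02.  The 40% occupancy mirrors a
  motif "occurring in several subsets" of a family: after
  realignment the dependency *concentrates* (the non-carrier rows
  keep it from degenerating into pure conservation), which is what
  the ≥ 2x residual-concentration test measures at n = 2000 (the
  larger n tames the sampling noise in the pre-alignment maximum
  over run members).
* `toy_nine_column_family()` — a packaged 60 x 9 family built
  deterministically in code: stem pairs (6,9) and (7,8) plus a
  correlated triple across columns 2–4 whose three variants carry
  information a per-column logo misses entirely.  It reproduces the
  planted dependency *topology* of the archaeal tRNA endonuclease
  motif used throughout the documentation, not any real sequence
  set; with real data the identical pipeline applies unchanged.

All generators are deterministic in their `seed` and restore the
caller's RNG state.

What the generators deliberately do not emulate: phylogenetic
correlation between sequences (rows are exchangeable), realistic
substitution processes, indels (only rigid translations, which is all
the realigner corrects), or higher-order (3+) dependencies.  Passing
tests therefore demonstrate correctness of the statistics and
algorithms under exchangeable noise, not robustness to tree-structured
confounding — on real families, shared ancestry inflates apparent
covariation and the p-values should be read as exploratory weights,
not calibrated error rates.

## Numerical and design choices

* Residuals default to plain probability differences; Pearson-scaled
  residuals and count units are flags on `compute_residuals()` /
  `scan_all_pairs()`.
* Raw p-values are thresholded as-is (matching the exploratory
  workflow the tool supports); no multiplicity correction is applied
  by default — with `count_position_pairs(L) * |A|^2` tests, a user
  wanting family-wise control should divide `max_p` accordingly.
* Pair storage is canonical (`j < k`); symmetric queries transpose.
* Deterministic ordering everywhere (position, then alphabet order),
  so exports are byte-stable and diffable.
* TSV outputs round floats to 6 significant digits for portable
  golden files; JSON model files keep full precision.
* Degenerate inputs: the all-zero 2x2 table has p = 1; an empty
  margin gives p = 1; an alignment must have at least 1 sequence and
  2 positions; `L = 1` has no cylinder layout.
* Problem sizes in the test suite (null calibration at n = 200 x 10
  seeds, recovery at n = 500, realignment at n = 400 x 5 seeds,
  concentration at n = 2000, layouts to L = 60) are the package's
  desk-scale study conditions; each runs in seconds to about a
  minute.

## Known limitations

Pairwise only — no triple interactions, though the metagraph could in
principle carry them.  No automatic threshold selection: choosing the
refinement point is left to the analyst (components and cycle flags
are surfaced to support that judgment).  The CRF is a scorer, not a
generative model: scores compare candidates against each other and a
reference, and have no absolute probabilistic interpretation.  The
realignment handles rigid shifts of one dominant motif per iteration;
families with several interleaved misaligned motifs of equal strength
may need manual shift files (supported by the CLI) or tighter
filters.
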