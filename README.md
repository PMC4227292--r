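# covarnet

Covariation dependency networks, CRF scoring, and dependency-guided
realignment for fixed-length categorical sequence alignments.

## The problem

Biological sequence families routinely violate the assumptions of the
standard motif models.  A position-specific scoring matrix treats
columns as independent; Markov-chain models only see adjacent
columns.  But an RNA stem pairs sequence-distant columns through
Watson–Crick complementarity, protein residues covary through
three-dimensional contacts, and a motif shared by differently-aligned
subsets of a family leaves no usable column-wise signal at all.  In
each case the information lives in the *joint* behavior of position
pairs, not in any single column.

covarnet is for analysts who need to see and use that pairwise
structure: extract it, prune it to something statistically defensible
and computationally tractable, score candidate sequences with it, and
exploit it to fix misaligned families.

## What it computes

For an alignment with `n` sequences and `L` positions over alphabet
`A`, and for every one of the `L(L-1)/2` position pairs `(j, k)` and
every category pair `(M, N)`:

- marginals `p_j(M)` and joints `p_jk(M, N)`;
- the signed residual `r_jk(M, N) = p_jk(M, N) − p_j(M) p_k(N)`,
  positive where a pair co-occurs above the independence expectation;
- a two-sided Fisher exact p-value for the collapsed 2×2 table
  `(M at j?) × (N at k?)`.

These populate a **metagraph** — position nodes containing weighted
category subnodes, with residual-weighted, significance-annotated
edges between subnodes of different positions.  The metagraph is then

- **refined**: threshold filters (`|r|`, p, joint count), pinning,
  manual removals, cycle flags, and disjoint-component labels, with
  an append-only replayable edit history;
- **compiled into a pairwise CRF scorer**: node potentials are logs
  of smoothed marginals, edge potentials are smoothed log
  joint/product ratios over the retained pairs, and candidates are
  reported as log scores and fold ratios relative to a reference
  sequence (the reference scores exactly 1);
- **mined for echoes**: the same category-pair dependency at the same
  lag repeated at consecutive start columns is the fingerprint of a
  misaligned subset, and `iterative_realign()` corrects it by
  aligning the dependencies rather than the symbols;
- **laid out on a cylinder**: parallel categorical axes with fixed
  per-category heights, marginal-scaled glyphs, deterministic jitter,
  an occlusion certificate, and JSON/OBJ scene export.

Synthetic generators (independent nulls, Watson–Crick stem-loops,
shifted-motif echo families, and a packaged nine-column toy) provide
planted ground truth for every stage.

## Worked example

```r
library(covarnet)

toy <- toy_nine_column_family()   # 60 x 9 family: stem pairs (6,9), (7,8),
aln <- toy$alignment              # and a correlated triple at columns 2-4
g   <- build_metagraph(aln)
g
#> <cn_metagraph> L=9, 33 subnodes, 437 edges (437 retained, 0 pinned, 0 removed), 0 history step(s)

gf <- label_components(filter_edges(g, filter_spec(0.1, 0.001, 3)))
ret <- gf$edges[gf$edges$retained, c("j","k","M","N","count","residual","p","component_id")]
head(ret[order(-abs(ret$residual)), ], 8)
#>  j k M N count residual        p component_id
#>  2 4 G T    27    0.248 1.14e-17            3
#>  2 3 G C    26    0.231 1.01e-14            3
#>  3 4 C T    26    0.231 1.01e-14            3
#>  2 4 C A    19    0.216 4.89e-16            2
#>  2 3 C G    19    0.211 9.78e-15            2
#>  3 4 G A    19    0.211 9.78e-15            2
#>  6 9 T A    19    0.211 9.78e-15            7
#>  7 8 G C    20    0.211 5.51e-14           10
```

The filter keeps 17 of 437 observed edges: the correlated triple at
columns 2–4 (components of linked triplets) and the X-shaped
Watson–Crick quartets at the stem pairs (6,9) and (7,8).  Residuals
are probability differences — `+0.211` for `(T6, A9)` means that
combination occurs 21 percentage points more often than independent
columns would produce.

Scoring against this structure separates mutations that respect the
pairing from mutations that break it, which no per-column model can:

```r
m    <- build_crf(gf, aln)
ref  <- c("A","G","C","T","A","G","C","G","C")      # respects both stem pairs
swap <- ref; swap[6] <- "C"; swap[9] <- "G"         # pair replaced consistently
brk  <- ref; brk[6]  <- "C"                         # pair broken
relative_score(m, swap, ref)
#> [1] 0.613
relative_score(m, brk, ref)
#> [1] 0.0323
```

The consistent double substitution costs less than a two-fold drop;
breaking one Watson–Crick pair costs thirty-fold.

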