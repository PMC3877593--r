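---
title: "Conservation and mutation of splice-site hexanucleotides in orthologous introns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation and mutation of splice-site hexanucleotides in orthologous introns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronhex)
```

## The question

In canonical U2-type introns the first six nucleotides (the 5' splice site,
starting with the invariant GT) and the last six (the 3' splice site, ending
with the invariant AG) carry most of the positional information that guides
the spliceosome. When two species descend from a recent common ancestor --
mouse and human diverged roughly 65--85 million years ago -- each orthologous
intron couple provides one observation of how strongly each splice-site
position resisted mutation. `intronhex` implements the comparative analysis
of such couples: which nucleotides, and which *combinations* of nucleotides,
are conserved beyond what independent per-position evolution would predict?

The package takes two FASTA files (one intron per species, sense strand,
5'->3') plus a pairing manifest, and compares the two members of each couple
ungapped, position by position. All coordinates are 1-based; terminal
hexanucleotides are indexed left-to-right h1..h6 so that h5h6 is the
invariant AG, and the 3' identity profile counts positions backwards from
the intron's last nucleotide.

## The random-association model

For a base $b$ at a variable position $p$, let $f^A_{p,b}$ and $f^B_{p,b}$
be its frequencies among the two species' hexanucleotides. Under random
association the chance that both species carry $b$ at $p$ is the product

$$r_{p,b} = f^A_{p,b} \cdot f^B_{p,b},$$

while the *actual* conservation $a_{p,b}$ is the observed fraction of
couples carrying $b$ at $p$ in both species. The conservation of a group of
nucleotides (a wildcard pattern such as `GTGAGx` or `TTxxAG`) is modelled,
under mutual evolutionary independence of neighbouring positions, as the
product of the per-position actual conservation values of its fixed
nucleotides:

$$r(\text{pattern}) = \prod_{p \in \text{fixed}} a_{p, b_p}.$$

The observed count $k$ of couples conserving the whole pattern (both
species match every fixed position) is compared against
$\mathrm{Binomial}(n, r)$ with an exact one-tailed test -- upper tail when
the observed frequency exceeds $r$, lower tail otherwise; the observed value
is included in the tail. `motif_scan()` enumerates all
$\sum_k \binom{4}{k} 4^k = 624$ patterns per end. Reported uncertainty for a
pattern is the count-scale binomial standard deviation
$\sqrt{n\,r(1-r)}$. No multiple-testing correction is applied in the
default scan, matching the original procedure; a Benjamini--Hochberg column
is emitted alongside the raw p-values, clearly as an extension, for modern
use.

Two interpretive notes. First, the null probability is a *plug-in*
estimate computed from the same data's marginal conservation values; with
624 discrete exact tests this makes the scan mildly conservative (measured
type-I flag rate about 0.04 at $\alpha = 0.05$ on null simulations).
Second, an excess of actual over random conservation is the *finding*, not
an invariant: on data generated with independent positions the two agree
within sampling error.

A bundled table of printed-precision reference values
(`reference_conservation()`, $n = 216$ mouse/human cytokine-receptor intron
couples) lets all the desk-checkable arithmetic be reproduced exactly, e.g.
`motif_random_probability("GTAAGT", reference_conservation("five_prime"))`
= `r round(motif_random_probability("GTAAGT", reference_conservation("five_prime")), 4)`.
One worked single-position example uses 0.570 for the human frequency of A
at 5' position 3 while the reference table prints 0.575; the package keeps
both: the example's own inputs are honoured when reproducing it, the table
value everywhere else.

## U1 pairing and variant classification

The U1 snRNA 5' element (written `ACTTAC` in DNA alphabet) base-pairs
antiparallel with the 5' splice site, so position $i$ of the site faces U1
position $7-i$; a perfect site is `GTAAGT`. `u1_match_vector()` scores
strict Watson--Crick matches only -- G.U wobble is available behind a flag
but off by default, because the aggregate match statistics this analysis
reproduces treat G-vs-A at position 3 as a mismatch. `u1_best_register()`
additionally slides the element up to three nucleotides into the exon tail
(registers $-3..0$, ties resolved toward the canonical register 0), since
optimal ungapped pairing occasionally involves the exon's last codon.

`classify_variant()` compares a variant transcript's exon intervals against
the canonical structure on a shared gene axis and reports the catalogued
event types: exon skipping (canonical exons with no overlapping variant
exon; consecutive absences merge into one ranged event), and alternative
3'/5' splice sites (one shared exon boundary, signed nucleotide offset,
negative = upstream). Every event carries a frame flag
(`length_change %% 3 == 0`). Anything else -- intron retention, novel
exons, alternative first/last exons, double-boundary shifts -- is surfaced
as `unrecognized` rather than forced into a category or dropped; in
particular, swapping the canonical and variant arguments of a skipping case
yields an `unrecognized` inclusion, never a mislabel.

## The synthetic-data generator

`generate_pairs()` emulates the generative process the analysis assumes:

1. an ancestral hexanucleotide per end, drawn either from a usage map
   (default: the reference frequent-hexanucleotide lists, which cover 64.5%
   of 5' and 36.8% of 3' mass, with the remainder spread uniformly over the
   other canonical hexanucleotides -- the full empirical distributions are
   not available) or, for a factorized independence null, per-position from
   a composition matrix;
2. per variable position, retention of the ancestral base in both lineages
   with the configured conservation probability (defaults: the reference
   actual-conservation totals 0.8426, 0.9028, 0.9352, 0.736 at 5' and
   0.7221, 0.7268, 0.5973, 0.7731 at 3'). At a non-conserved position a
   fair coin decides which lineage keeps the ancestral base and the other
   is forced onto one of the three alternatives, so cross-species identity
   at the position fails with certainty and equals the configured
   conservation exactly in expectation. (Resampling both lineages uniformly
   would re-create identity by chance in 1/4 of non-conserved draws and
   bias the realized conservation upward; forcing exactly one lineage off,
   chosen by coin flip, removes the bias while keeping the two species
   exchangeable.);
3. intron bodies with zone-wise cross-species identity: 0.631 at positions
   7--21 from the 3' end, 0.560 at 22--50, and 0.554 elsewhere -- the three
   identity plateaus of the reference profiles. One intron length per
   couple, shared by both species, is drawn uniformly from
   `intron_length_range` (default 100--300 nt, short but realistic for
   compact genes; the ungapped end-anchored comparison makes the body
   length statistically inert);
4. optionally, `correlated_motifs`: ancestors matching a pattern retain
   their *whole* hexanucleotide intact in both lineages with the given
   probability, creating correlated conservation in excess of the
   random-association null -- the minimal mechanism for the
   `GTGAGx`-style finding.

All draws flow from one seeded generator stream; output is bit-reproducible
from `(config, seed)` and the caller's RNG state is restored.

What the generator does *not* emulate: indels (members of a couple share
their length), substitution-rate heterogeneity beyond the three body zones,
branch-point and polypyrimidine-tract structure, and any within-species
correlation between hexanucleotide positions other than what the usage map
and the retention boost induce. Passing tests on synthetic data therefore
validate the statistical machinery and its calibration, not the biological
claims about real mouse/human introns.

## Numerical and design choices

- **Exact tails.** `binomial_tail_test()` uses `stats::pbinom`, which
  accumulates the tail in stable arithmetic; tests verify equality with a
  direct `choose()`/power summation for every $k$ at $n \le 50$. Degenerate
  nulls ($p_0 \in \{0, 1\}$) return 1 when the observation is the only
  consistent outcome, else 0.
- **Counts, not percentages.** Where raw couples are available the observed
  count is an exact integer; only when consuming printed percentage-level
  inputs is $k = \mathrm{round}(f \cdot n)$ used.
- **Ambiguity.** Couples with `N` inside either hexanucleotide are excluded
  from all censuses (a four-letter composition must sum to 1); in identity
  profiles an `N` counts as non-identical but stays in the denominator.
  Introns shorter than 12 nt are excluded so the two hexanucleotides are
  disjoint.
- **Between-species tests.** Which species provides the null for the
  composition comparison is not canonical; `species_composition_test()`
  tests the larger count against the smaller species' proportion, making
  the result symmetric in its arguments, and that choice is isolated in one
  function.
- **Detection power.** With the retention boost at weight 0.8 on `GTGAGx`
  under a realistic factorized composition, the realized excess over the
  plug-in null is ~3 points (the boost also inflates the marginal
  per-position conservation, which feeds the null product) and the exact
  test detects it in >90% of replicates at $n = 1000$; at the reference
  sample size of 216 the same injection is detected in roughly a third of
  replicates, which is consistent with the modest significance levels such
  sample sizes support. The power property is therefore tested at
  $n = 1000$.
- **Problem sizes in the test suite** (chosen to exercise the asymptotics
  the assertions rely on): parameter recovery at $n = 5000$ couples,
  plateau recovery at $n = 2000$, type-I calibration over 200 replicates of
  $n = 1000$ couples with minimal-length introns, usage convergence at
  $n = 10000$ ancestors.
- **Stable outputs.** Pipeline TSVs format fractions to 4 dp and
  percentages to 1--2 dp with fixed sort orders, so re-running on identical
  inputs is byte-identical.

## Limitations

The package analyses hexanucleotides only: the branch site, the
polypyrimidine tract (whose rightmost nucleotides may overlap terminal
positions h1--h2) and exonic splicing elements are out of scope, as are
non-canonical GC--AG / AT--AC and U12-type introns, ortholog detection and
alignment. Dataset-level frequencies from any particular published survey
are not reproduced from raw data -- the raw couples are not
redistributable -- but every step of the statistical machinery applied to
the bundled printed inputs is, exactly.
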