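---
title: "Methods: clonotype diversity analysis of naive antibody libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonotype diversity analysis of naive antibody libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naiverep)
```

`naiverep` analyses deep-sequenced antibody display libraries: it filters
reads, assigns germline V/J genes, clusters CDR3s into clonotypes under a
Hamming criterion with singleton rescue, and summarises diversity, clonal
structure, primer specificity and CDR biophysics. This vignette is the
package's account of the underlying models, the parameters that matter, the
numerical conventions, and what the tests do and do not demonstrate.

## The synthetic repertoire model

Raw sequencing data for a naive single-donor library is rarely shareable,
so the package ships a generator whose defaults encode the statistical
structure such libraries exhibit. It is first-class, tested code — every
downstream stage is validated against its ground truth.

**Clonal abundance.** Clone copy numbers are drawn from a discrete power
law `P(k) ∝ k^(−α)` truncated at 10^4. The default exponent α = 2 gives a
singleton fraction of ~0.6, inside the 58–72% per-pool range seen in
heavy-chain data, and a heavy tail in which a handful of clones carry a
disproportionate share of reads. The tail matters: with α = 2 the
*effective* number of independent clones behind 20,000 reads sampled
proportionally to copy number is only ~10², which is why usage-recovery
checks sample clones uniformly (below).

**V/J usage.** J segments default to the documented pool-mixing
proportions (heavy IGHJ1/2 5%, IGHJ3 10%, IGHJ4/5 60%, IGHJ6 25%; kappa
29/26/10/26/9%; lambda 21%, 77% split evenly across IGLJ2/IGLJ3, 2%);
V genes default to uniform across the reference, reflecting the equimolar
pooling of primer products. Both are overridable per gene.

**Junctions.** A clone is a germline V up to and including its 2nd-Cys
anchor codon, an inserted junction, and a germline J from its Trp/Phe
anchor codon onward. The junction is a random amino-acid string
reverse-translated with uniform codon choice; no D-segment bookkeeping is
attempted because nothing downstream consumes D calls and short-read data
cannot resolve them. CDR3 length is a rounded normal (median 14 aa,
σ = 3.73 aa) truncated to the observable 3–42 aa range. A configurable
fraction of clones (default 11%, matching the ~89% productivity of
heavy-chain ORFs) carries either an internal stop codon or a 1–2 nt
junction frameshift.

**Sequencing error.** Errors are substitutions only, Bernoulli per base
(Illumina amplicon error is substitution-dominated; indels and chimeras are
deliberately out of scope). Per-base qualities come from a two-regime
model: good reads mix Q40/Q37, and a `p_bad = 0.08` fraction of reads drop
40% of bases to Q12. The regimes are chosen so that both shipped QC
criteria actually discriminate — a bad read fails the 90%-at-Q≥25 fraction
filter *and* the lower-quartile-Q≥37 filter, a good read passes both.

**What the generator does not emulate.** PCR chimeras, indels, UMI
consensus structure, position-dependent error profiles, family-specific
CDR3 length differences, and somatic hypermutation lineage structure.
Passing tests therefore demonstrate correctness of the *algorithms* under
substitution noise and heavy-tailed abundance, not robustness to every
artefact of real NovaSeq data.

All randomness flows from one integer seed through `withr::with_seed`;
sub-streams (clones, reads, subsampling) are derived from the master seed
with distinct labels, so no global RNG state leaks and identical
configurations are bitwise reproducible.

## Quality filtering

Two published criteria are exposed through `qc_config()`: the fraction
filter (≥ 90% of bases at Q ≥ 25), which is the default because it
describes the pipeline as run, and the lower-quartile filter (Q25 ≥ 37).
"Lower quartile" uses the nearest-rank (type-1) percentile — unambiguous
for short reads, where interpolated definitions differ. Empty reads never
pass and are counted separately. The filter is idempotent and monotone in
the threshold; both properties are asserted in the tests.

## Germline assignment

The aligner is intentionally simple: ungapped scoring (+1 match, −1
mismatch) of each reference V against the read over candidate start
offsets, and end-anchored matching of each J's post-anchor suffix against
the read tail. With substitution-only errors this is exact; a gapped or
seeded aligner would add complexity without changing the quantities the
package is about, which are the *acceptance thresholds*:

- identity ≥ 0.90, computed only over the germline framework + CDR1/2
  region (the CDR3 is excluded from the denominator);
- an e-value-like statistic `E = K·m·n·exp(−λS)` with fixed constants
  λ = 1.33 and K = 0.621, m the read length and n the total reference
  length. The constants are documented, not fitted; they make the 1e−12
  and 1e−14 thresholds exercisable and keep E monotone in the score.
  The default threshold is 1e−12; 1e−14 (quoted for the MiSeq runs) is one
  `annotate_config()` argument away. Both thresholds appear in the source
  material and the discrepancy is surfaced rather than resolved.

Ties in the best V call are broken by higher identity, then lexicographic
gene name — determinism over cleverness. Coordinates are 0-based half-open
internally; the AIRR-style TSV output is the interchange surface.

## Hierarchical clonotyping

Unique keys are split into abundant (count ≥ 2) and singletons. Abundant
keys seed clonotypes; each singleton is absorbed into an abundant clonotype
when an abundant key of equal length lies within Hamming distance h, and
otherwise survives as a true singleton. Three conventions are fixed where
the procedure is silent:

- **Tie-break:** a singleton within h of several abundant keys joins the
  most abundant one, ties by lexicographically smallest key.
- **Singleton–singleton merging never happens** — only rescued-vs-abundant
  comparisons — which makes the result independent of input order.
- **Unequal lengths never merge:** Hamming distance is undefined across
  lengths, so length acts as an infinite-distance barrier. Neighbour search
  is a length-bucketed scan with early-exit mismatch counting (C++); at
  desk scale nothing faster is needed, and an index would be an
  optimisation, not a semantic change.

Absorbed singleton counts are added to the absorbing clonotype, so read
counts are conserved; the abundance-only criterion (N ≥ 2) instead drops
singletons outright. The implementation is checked against an independent
all-pairs brute-force oracle on tables up to 200 keys, and for monotonicity
of clonotype counts over h = 0 → 3.

Key schemes: plain CDR3; merged CDR1+CDR3 (compared positionally as one
string); and CDR3-with-germline, where the Hamming comparison applies to
the CDR3 part only and absorption additionally requires an identical V
call.

## Diversity

Hill numbers use the closed form except at q = 1, where the limit
`exp(−Σ p_i ln p_i)` replaces the singular expression. Accumulation curves
subsample reads *without* replacement (rarefaction convention), re-cluster
each subsample, and average replicates. The asymptote comes from least
squares on `S(n) = S_max(1 − e^(−n/τ))` — the canonical negative
exponential, documented as an assumption since only the model family is
named in the source material. Fitting uses Levenberg–Marquardt
(`minpack.lm`) with `S_max` initialised at 1.1× the largest observed
richness, τ at the half-maximum sample size, convergence at relative
change < 1e−8 within 500 iterations; an exactly flat curve short-circuits
to `S_max = mean(S_obs)` (the saturated limit), and non-convergence is
flagged on the result object instead of raised. The fit is run on the
replicate-averaged curve; per-replicate values are retained for
uncertainty.

## Primer analysis

Degenerate positions match on nucleotide-set intersection (primer K
anneals to G or T, so K vs G counts as a match). This makes the distance
symmetric with zero diagonal but *not* a metric — the triangle inequality
fails by construction, which is documented rather than patched. Ward
clustering uses the Lance–Williams minimum-variance recurrence, i.e.
`hclust(method = "ward.D")` on squared distances, with primers sorted
lexicographically first so the dendrogram is input-order invariant.

The tree can be cut at a requested k or below the largest merge-height
gap. On the packaged 12-primer heavy panel the largest gap separates only
the highly distinct IGHV2 pair (k = 2); the three predominant cross-family
clusters — {IGHV1a–d, IGHV3a–c, IGHV5a}, {IGHV2a, IGHV2b}, {IGHV4,
IGHV6a} — appear at k = 3, which is the documented choice for that panel.

The amplification model is explicitly qualitative: predicted capture of
gene g by primer p is `abundance(g) · exp(−β · weighted mismatches)`, with
the three 3′-terminal positions triple-weighted (β = 2 and the ×3 end
weight are config-exposed artefact decisions, motivated by polymerase
extension being most sensitive at the 3′ end). It reproduces the two
qualitative drivers of promiscuity — similarity and underlying abundance —
and is not a thermodynamic annealing model.

## Biophysics

Net charge is the sum of signed Henderson–Hasselbalch fractional charges
over ionizable side chains on the Lehninger pK scale at pH 7. Two
conventions are fixed: histidine *is* included (pK 6.0 contributes ~+0.09
per His at pH 7; excluding it would bias near-neutral medians), and the
terminal groups are excluded because CDRs are internal peptide segments —
both overridable. This makes charge additive over concatenation and
position-independent, which the tests assert. GRAVY is the plain mean of
Kyte–Doolittle values. Dispersions are sample standard deviations (n−1);
quantiles are nearest-rank.

Developability summaries map each read's V call to the published scaffold
classes (desirable / common-in-natural / neutral / poorly developable;
anything unlisted is `unclassified`), optionally after per-primer depth
normalisation in which every primer pool contributes equal total weight.

## Packaged reference data

The germline reference is **synthetic** and its file names say so: ~12
heavy V genes (one per published forward primer, whose first 18 nt realise
that primer's sequence), 6 heavy J, 6 kappa V, 5 kappa J, 4 lambda V and 4
lambda J genes, each with IMGT-style codon-aligned CDR bounds and conserved
anchors. Lambda carries four J genes (IGLJ1/2/3/7) rather than three
because the stated lambda mixing proportions address IGLJ2 and IGLJ3 as
separately callable segments. Reverse primers are not published, so
synthetic reverse records are packaged (flagged in the file name) purely to
make the pool combinatorics — 12 × 4 heavy PCRs, 12 × 2 scFv assembly
pools — enumerable from fixtures. CDR3 boundaries follow the IMGT
convention (anchors excluded), consistent with a median heavy CDR3 length
of 14 aa. Published table gene names are canonicalised (dash glyphs,
locus prefixes) by `normalize_gene_name()`.

## Design choices on open points

- **Uniform read weighting for usage recovery.** J-usage recovery checks
  sample one read per uniformly chosen clone. With power-law copy numbers,
  read-proportional sampling concentrates on ~10² effective clones, so the
  recovered share would fluctuate several percentage points regardless of
  read depth; uniform weighting makes the share binomial in the number of
  reads, which is the regime the checks assume. At production scale
  (~10^9 reads over ~10^7 clones) the two weightings converge.
- **Problem sizes.** The test suite and acceptance script run at desk
  scale by design: repertoires of 250–20,000 clones, 1,500–20,000 reads,
  accumulation grids of 4–8 points with 1–2 replicates. These sizes are
  chosen so distributional parameters (medians, usage shares, singleton
  fractions) are recoverable within stated tolerances while the whole
  suite stays fast; the headline multi-billion-read diversity figures of
  production libraries are not reproducible at this scale and are not
  asserted anywhere.

## Known limitations

The aligner is ungapped and will mis-handle genuine indels; there is no
D-gene calling, no lineage inference, no UMI consensus, and no
thermodynamic primer model. The packaged germline set is representative,
not authoritative — analyses of real data should substitute a current
reference release via `read_germline_reference()`.
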