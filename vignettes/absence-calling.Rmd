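---
title: "Calling gene absences in divergent lineages: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling gene absences in divergent lineages: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthotrace)
```

## The problem

Claiming that a gene is *absent* from a genome is much harder than
claiming it is present. In anaerobic protist lineages with extreme
sequence divergence and streamlined genomes, a standard similarity
search failing to find an ortholog is weak evidence: the ortholog may
be too diverged for the query model, or present in the genome but
missing from the predicted proteome because gene prediction failed.
`orthotrace` implements the full evidence cascade needed before an
absence call is defensible, and the comparative machinery to interpret
the resulting presence/absence patterns phylogenetically:

1. **Sensitive search** — position-specific log-odds profiles built
   from seed alignments, iteratively enriched with newly found
   divergent homologs until convergence.
2. **Tiered absence verification** — proteome search, then six-frame
   translation of the genome (rescuing unannotated genes), then a
   relaxed domain-level screen.
3. **Comparative synthesis** — presence/absence matrices, Dollo
   parsimony mapping of losses onto a rooted species tree, per-complex
   summaries, and completeness percentages against a reference
   ortholog set.
4. **Genome QC** — the credibility of an absence call rests on
   assembly completeness and correct ploidy handling, so the package
   computes k-mer completeness and an allele-balance ploidy verdict
   from base-count pileups.

Because real pipelines of this kind are validated against curated
genomes that cannot be shipped, the package's first-class citizen is a
synthetic genome/proteome evolution simulator that generates data with
known ground truth (which tips truly lost a family, which genes were
deliberately hidden from the proteome), so every stage is testable
end to end.

## Profile search

### Profile construction

A seed alignment is converted to a position-specific scoring matrix.
Column frequencies use Henikoff position-based sequence weights and
background-proportional pseudocounts,

$$ f'_j(a) = \frac{c_j(a) + \alpha\, b(a)}{n_{\mathrm{eff},j} + \alpha},
\qquad s_j(a) = \log_2 \frac{f'_j(a)}{b(a)} \ \text{(bits)}, $$

with `alpha = 1` by default and a uniform background
(`uniform_background()`, overridable with empirical frequencies).
Henikoff weighting matters here for a specific reason: an enriched
alignment is phylogenetically redundant (many near-identical seeds,
few divergent additions), and position-based weights automatically
give the divergent rows the influence that makes the next search round
more sensitive. Columns with more than 50% gaps are dropped
(majority-rule match-column assignment). With `alpha = 0` unobserved
residues score $-\infty$; the function warns and downstream code
treats those as very large negative finite scores.

### Local alignment

Scoring uses Smith–Waterman-style local alignment of a sequence
against the profile columns with affine gaps: a gap of length $g$
costs `gap_open + g * gap_extend`. Defaults are **3.5 / 0.3 bits**.
These are deliberately mild: profile columns carry roughly 4 bits at
consensus positions, and gap costs several times that would make null
alignments effectively gapless, concentrating the null score
distribution on a lattice that an extreme-value fit cannot describe
(see *Numerical choices*). Traceback tie-breaks are fixed (diagonal >
up > left; gap-open preferred over gap-extend), so alignments are
deterministic. Residues outside the 20-letter alphabet (`X` from
ambiguous codons) score zero against every column.

### E-value calibration

Significance is calibrated per profile on random decoys drawn i.i.d.
from the background (default 200 decoys, length = profile length).
The maximal local score of each decoy is collected and a Gumbel
(type-I extreme value) distribution is fitted — a maximum-likelihood
fit refined by minimizing the Cramér–von Mises distance between the
fitted and empirical CDFs. The refinement exists because the fitted
CDF *is* the object E-values are read from: for sharp profiles the
pure ML solution leaves a small systematic CDF offset that is visible
as non-uniform null p-values, while the minimum-distance refinement
tracks the empirical distribution closely (null p-values pass a
Kolmogorov–Smirnov uniformity test at $\alpha = 0.01$ in ~99% of
calibration seeds in our checks). E-values scale to the searched
database:

$$ E(S) = \frac{\text{db residues}}{\text{decoy length}}
   \exp\!\left(-\frac{S - \hat\mu}{\hat\lambda}\right). $$

Degenerate decoy scores (all equal, e.g. from an uninformative
profile) raise a calibration failure rather than returning a bogus
fit.

### Iterative taxa enrichment

`iterative_search()` loops: build profile → calibrate → score all
targets → include targets with $E \le$ `inclusion_E` (default
$10^{-5}$ per database; deliberately strict to prevent profile drift,
and overridable per family) → stack the included hits onto the profile
match columns via their alignment trace → rebuild. Iteration stops
when no new target id is added or after `max_iter` (default 10)
rounds; the included set never shrinks. Convergence is defined on
target identities, not scores, which makes the stopping rule robust to
small score fluctuations after recalibration.

Two gap-cost regimes are used on purpose. Scoring and significance use
the mild defaults above. The **realignment trace** used for stacking
an included hit is computed at stiffer costs (8 / 1): mild costs let
the traceback wander around divergent residues through cheap gaps, and
a residue placed in the wrong column contributes nothing to the
enriched profile — exactly the residues the enrichment exists to
capture. Stiff-trace stacking places them faithfully.

`simulate_bridge_family()` constructs the canonical validation case: a
mid-divergent homolog detectable from the seeds, and a far homolog
that shares residues with the mid homolog only where the mid homolog
diverged from the ancestor (plus a sparse, evenly spaced set of
ancestral residues). The far homolog is invisible to the seed-only
profile but strongly matched once the mid homolog is included, so it
can only be recovered at iteration two or later. Defaults (ancestor
length 250, mid divergence 0.4, kept-ancestral fraction 0.35) were
chosen so that the three E-value separations the construct must
realize each hold with orders-of-magnitude margins.

## The absence-verification cascade

`verify_absence()` runs three tiers and stops at the first hit:

| tier | database | threshold | call |
|------|----------|-----------|------|
| proteome | predicted proteins | `inclusion_E` ($10^{-5}$) | `present` |
| six-frame | stop-free translated genome segments | `inclusion_E` | `present_genome_only` |
| domain | proteome and segments, domain sub-profiles | `domain_E` ($10^{-3}$) | `present` / `present_genome_only` |

Only after all three tiers miss is a family called `absent`. The
six-frame tier is what rescues genes that exist in the genome but were
not annotated; the design of the relaxed domain tier follows the common
practice of accepting weaker, domain-level evidence before accepting
an absence. The tier-2/3 thresholds are explicit configuration — the
field's tools do not agree on a single value and we make the choice
visible rather than implicit. When no genome is available the call is
made on the proteome alone and flagged `genome_unchecked`.

Six-frame translation (`six_frame_translate()`) uses the standard
genetic code, splits segments at stop codons and at fully ambiguous
(`NNN`) codons, translates partially ambiguous codons to `X`, and
reports forward-strand 1-based inclusive coordinates such that
extracting the interval (reverse-complementing for negative frames)
and translating reproduces the peptide exactly. Internally all
coordinates are 0-based half-open; conversion happens only at the
interface.

Paralog counts are the number of distinct qualifying proteome
sequences (tier 1) or of non-overlapping qualifying genome intervals
(tier 2; greedy by descending bit score, intervals overlapping more
than 25% of the shorter are merged).

## Comparative synthesis

`build_matrix()` assembles the full (family × taxon) grid and refuses
duplicates or holes. For evolutionary reconstruction,
`present_genome_only` counts as present — the gene exists; its absence
from the proteome is an annotation artifact — but the annotation is
retained in all reports.

`dollo_reconstruct()` places the single origin of a family at the most
recent common ancestor of its present tips and infers losses on the
branches leading to the maximal subtrees below the origin that contain
no present tip. This is the minimum-loss single-gain labeling: tests
verify it against exhaustive enumeration of all single-gain labelings
for every rooted binary tree shape with up to six tips and every
presence pattern. Strict Dollo (no gains below the origin) matches the
single-origin assumption appropriate for ancient conserved machinery;
families suspected of repeated gains (e.g. via lateral transfer)
should be excluded from reconstruction — `reconstruct_all()` takes an
`exclude` argument for exactly this.

`complex_status()` reduces member families to a per-(taxon, complex)
status: `full` / `partial` / `absent`, a strict partition.
`busco_percentage()` is the completeness arithmetic used for
reference-set summaries: `round(100 * n_found / n_max)` with halves
away from zero — the rounding mode is pinned by worked examples
(217/245 → 89, 207/245 → 84) and tested.

## Genome QC

### Heterozygous sites and ploidy

A pileup site is *considered* at coverage ≥ 10 (`min_cov`), and
*heterozygous* when at least two distinct bases each have ≥ 2 reads
(`min_alt_reads`) — an explicit, auditable rule. `infer_ploidy()`
computes the heterozygous fraction among considered sites and the
minor-allele-fraction histogram (20 bins on $[0, 0.5]$, minor fraction
from the two most frequent bases).

The decision rule: **diploid** requires het fraction ≥
`het_frac_threshold` *and* a histogram mode inside `balance_window`
(default $[0.4, 0.5]$ — balanced alleles); **haploid** is called below
the threshold; everything else is `undetermined` (including too few
considered sites, default minimum 1,000).

Two numerical choices deserve justification. First,
`het_frac_threshold = 5e-3`: at 30× coverage and a 0.5% per-read error
rate, sequencing error alone produces a heterozygous-site fraction of
about $4 \times 10^{-3}$ under the two-read rule (two errors must hit
the same alternative base), so a workable threshold must sit above
that noise floor and below the $\sim 10^{-2}$ signal of a diploid with
1% heterozygosity. Second, the histogram mode is estimated on a 3-bin
moving average: error-driven sites pile into a narrow spike near
(min_alt_reads / coverage) ≈ 0.07, while true biallelic sites form a
broad folded-binomial peak near 0.5; with raw 20-bin counts the narrow
spike can outvote the broad peak, and mild smoothing restores the
intended comparison. The raw histogram is reported unchanged.

### K-mer completeness

`sample_kmer_sets()` produces canonical k-mers (lexicographic minimum
of a k-mer and its reverse complement) for an assembly and a
Poisson-coverage read k-mer count table; a `dropout` fraction of
genome positions is withheld from the *assembly* set, emulating
unassembled regions, so a dropout-$d$ simulation has known expected
completeness $100(1-d)$%. `kmer_completeness()` is the
reference-free completeness statistic: the fraction of *solid* read
k-mers (count ≥ `solid_min`, default 4 — a fixed error-filter
threshold rather than histogram-valley detection, which is adequate at
these scales) found in the assembly. Tests confirm 100% exactly at
zero dropout and ≈ 90% under 10% dropout.

## The simulator: what it does and does not emulate

`simulate_tree()` generates rooted binary trees with exponential
branch lengths and can scale one clade's branches by a constant factor
(default configuration: a quarter of the taxa at 2×), emulating a
fast-evolving lineage. `evolve_family()` evolves an ancestral protein
down the tree: per branch of length $t$ the family is lost with
probability $1 - e^{-\lambda_{loss} t}$ (irreversibly — losses are
sampled top-down and lost subtrees are skipped, enforcing Dollo), and
each site substitutes with probability $1 - e^{-\lambda_{sub} t}$,
the replacement drawn from the background restricted to the 19 other
residues so the realized substitution fraction matches the closed
form. `emit_genome_and_proteome()` reverse-translates present proteins
(standard code, uniform synonymous codon choice) onto random strands
of a synthetic contig with random intergenic spacers, and hides a
configurable fraction of genes from the proteome while recording them
in a registry — the ground truth for rescue testing.
`simulate_pileup()` and `sample_kmer_sets()` generate the QC inputs
with the statistical structure described above.

Deliberate simplifications, and what they mean for interpretation: the
substitution model has no exchangeability matrix (graded divergence is
all the search needs to be challenged on, but scores on real proteins
would benefit from empirical backgrounds); there are no indels, no
introns, no codon-usage bias, and no read-level sequence emission.
Passing tests therefore demonstrate the *machinery* — sensitivity
mechanics, tier logic, reconstruction correctness, calibration — on
data whose difficulty is controlled; they do not certify recall rates
on real divergent proteomes, where alignment quality, gene structure
and composition bias add failure modes the simulator does not model.

## Numerical choices collected

* Gap costs 3.5 / 0.3 bits (scoring), 8 / 1 (realignment trace); both
  deterministic tie-breaks.
* Pseudocount weight `alpha = 1`; background uniform unless supplied.
* Inclusion threshold $10^{-5}$ per database, domain tier $10^{-3}$,
  both per-family overridable.
* Calibration: ≥ 100 decoys enforced, 200 by default; Gumbel ML +
  Cramér–von Mises refinement; degenerate scores raise an error.
* Dollo: strict single gain; all-absent columns return a `no_origin`
  flag rather than an event.
* Het rule 10× / 2 reads; ploidy thresholds $5\times 10^{-3}$ and
  $[0.4, 0.5]$ with 3-bin-smoothed mode; solid k-mer threshold 4.
* Completeness rounding: half away from zero.
* All randomness flows from explicit integer seeds; every generator
  saves and restores the caller's RNG state.

## Problem sizes

The shipped analysis scripts and test suite run the full pipeline at
desk scale: 8 taxa × 12 families (ancestral length 120, substitution
rate 0.3, loss rate 0.15, 20% of genes hidden from proteomes), pileups
of 50,000 sites at 30× coverage, 10 kb genomes for k-mer statistics,
and 20-seed replicate sweeps for the stochastic recovery checks. These
sizes were chosen so that a complete validation run finishes in
minutes on a single core while leaving every statistical check
comfortably powered; all of them scale up through configuration
without code changes.

## Known limitations

* The profile model is a PSSM with affine gaps, not a full
  profile HMM: no insert/delete state emissions, no Plan7
  architecture. The sensitivity mechanism being exercised — position
  specificity plus iterative taxa enrichment — is the same, but score
  scales are not comparable to HMMER bit scores.
* Alignments grow only by stacking hits onto existing match columns;
  the package never re-infers a multiple alignment, so columns lost to
  the majority-gap rule early are never recovered.
* Dollo reconstruction is parsimony, not probabilistic gain/loss
  modeling; families with genuine multiple origins must be excluded
  explicitly.
* The ploidy rule distinguishes haploid from diploid; higher ploidies
  and aneuploidy are out of scope, as is per-chromosome analysis.
* `read_kmers` stands in for reads; there is no read simulation, no
  sequencing-error k-mers, and no quality-value estimation.
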