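---
title: "Calling and denoising CpG methylation patterns from deep amplicon bisulfite sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and denoising CpG methylation patterns from deep amplicon bisulfite sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Targeted bisulfite sequencing of long PCR amplicons at very high depth (10^5
read pairs per amplicon) makes it possible to observe the methylation state of
every CpG in a region *jointly, per molecule*. Each sequenced molecule yields
one binary vector over the amplicon's CpG index — a methylation pattern, or
epihaplotype — and the distribution of these patterns across a complex tissue
such as an insect brain reflects its mixture of cell types and epialleles. In
honey bee brain amplicons, most molecules carry one of a small number (roughly
4–12) of dominant patterns, with a long tail of rare patterns of uncertain
origin.

Two obstacles separate raw paired reads from that distribution. First, reads
must be turned into full-length, template-oriented molecule sequences:
selected by their nested PCR primer, aligned to the amplicon despite C→T
conversion, merged across the mate overlap, and filtered for quality. Second,
the observed pattern tally is contaminated: bisulfite non-conversion,
over-conversion and sequencing errors turn molecules of one pattern into reads
of another, so rare *observed* patterns are largely artefacts of abundant
*true* patterns. `epiamplicon` implements both steps and the downstream
condition comparisons.

## Read processing

**Primer selection.** A pair is kept when read 1 carries the amplicon's
forward nested primer and read 2 the reverse one: the read bases at 1-based
positions 4–33 must equal the primer's last 30 nt exactly. The three skipped
leading bases absorb the short non-template starts these libraries carry.
Matching is exact by design — with 10^5-scale depth, discarding imperfect
primer windows costs little and guarantees the amplicon assignment.

**Bisulfite-aware alignment.** Each mate (read 2 reverse-complemented) is
aligned to the *in-silico converted* template — the genomic top strand with
every non-CpG C replaced by T, CpG Cs retained. Scoring treats a read T
opposite a template C as a match (+2), because an unmethylated CpG is
legitimately sequenced as T; the converse (read C opposite template T) is a
mismatch (−3), as are all other disagreements. Gaps are affine: a gap of
length $k$ costs $5 + 2k$. The read is aligned globally with free end gaps on
the read row, so the template overhang around a partial read costs nothing.
Traceback is deterministic (diagonal preferred over up over left; rightmost
best end column), making every downstream table reproducible bit-for-bit. The
DP kernel is in C++; reads that match the template without mismatch at their
primer-implied offset take a shortcut, since the gap-free identity alignment
already attains the maximal possible score.

**Merging.** With template spans $[s_1, e_1)$ and $[s_2, e_2)$ overlapping by
$v$ columns, $\mathrm{round}(v L_1 / (L_1 + L_2))$ columns are trimmed from
the 3' end of read 1's span and the remainder from the 5' end of read 2's
span ($L_i$ = aligned column counts; round-half-up, so an odd remainder comes
off read 1). Aligner gaps are then removed and the parts concatenated. The
merged read records `aligned_len` (kept alignment columns) and `gap_fraction`
(gap columns over kept columns — the denominator is our choice, as only the
5% bound itself is prescribed). A pair whose second mate maps entirely 5' of
the first is rejected as *discordant*.

**Quality filter.** A merged read passes iff its gap-free length is ≥ 90% of
the template length and its gap fraction is ≤ 5%; length is checked first, so
`short` takes precedence over `gappy` when both fail. The tally of every
outcome class is exported and satisfies an exact conservation identity
(input = primer-unmatched + passed + short + gappy + discordant).

**Pattern calling.** Passed reads are re-aligned to the template — a second
pass that removes any positional drift indels introduced — and the base at
each expected CpG column is scored: C → 1, T → 0. A read showing any other
base, a gap, or not covering some CpG column is classed *ambiguous* as a
whole and excluded: the estimator below needs complete fixed-length patterns,
and partially scored reads would change its sample space. Ambiguous reads are
counted and reported, never silently dropped. Bases at declared SNP columns
are recorded verbatim alongside the pattern but never affect pattern
identity.

## The pattern mixture model

Let $t \in \{0,1\}^J$ index candidate true patterns with frequencies $\pi_t$,
and let an observed pattern $o$ arise from $t$ by independent per-site flips

$$P(o_j = 1 \mid t_j = 0) = f(1-m) + (1-f)\,m, \qquad
  P(o_j = 0 \mid t_j = 1) = g(1-m) + (1-g)\,m,$$

where $f$ is the bisulfite non-conversion rate, $g$ the over-conversion rate,
and $m$ the effective C↔T sequencing substitution rate at a CpG column.
Substitutions to other bases do not enter: they make the read ambiguous and
remove it before tabulation. The observed tally is then a multinomial mixture,
and `fit_pattern_mixture()` maximizes its likelihood by EM — initialized at
the empirical frequencies, stopped when the log-likelihood gain falls below
1e-8 (cap 10,000 iterations). The log-likelihood is concave in $\pi$, so the
EM fixed point is the global maximum; the implementation asserts monotonicity
of the likelihood at every iteration. The candidate support is restricted to
the *observed* patterns: at ultra-depth, a true pattern frequent enough to
matter is essentially never unobserved, and the restriction keeps the mixture
a few hundred components at most.

**Spurious-pattern elimination** is deliberately two-staged, because the two
stages fail differently:

1. *Frequency threshold* (`support_cut`, default `10/n_reads`): patterns whose
   estimated frequency falls below the threshold are removed, the rest
   renormalized and the EM re-run, iterated to a fixed point. This cheaply
   clears the long tail.
2. *Likelihood-ratio screen* (`lrt_cut`): each survivor is removed in turn and
   the model refit; the pattern is eliminated when twice the log-likelihood
   drop is below the threshold, least significant first, repeating until all
   survivors are significant. The default threshold is
   `qchisq(1 - 0.01/K, 1)` with `K` observed patterns — a familywise 1%
   screen. This stage exists because a fixed count cut cannot work at high
   depth: the single-flip error neighbours of a dominant pattern have
   expected tallies of dozens of reads, and ordinary Poisson excursions push
   their maximum-likelihood frequency past any small fixed cut. The ratio
   screen instead asks whether a pattern explains anything the error channel
   does not, which also protects genuinely rare true patterns whose reads
   cannot be explained as errors. With all error rates zero, every observed
   pattern is its own only explanation, the screen keeps everything, and the
   estimate equals the empirical distribution exactly.

Error rates are supplied by the user (or known from the simulator); the
package does not jointly estimate rates and frequencies — with a panel of a
few amplicons there is too little replication to separate them reliably, and
non-conversion is routinely measured by spike-ins or non-CpG cytosines.

**Reporting cutoffs.** The 1% and 5% minimum-frequency reporting levels are
applied *after* estimation, on estimated frequencies, without renormalizing —
the estimation stage owns denoising, the cutoff only selects what is drawn
and compared. The 5% set is nested in the 1% set by construction.

## Condition comparisons

Pattern sets are compared by bit-string equality only (recorded SNP bases are
annotation, not identity). `venn_counts()` gives exclusive region counts for
2–5 conditions; `pooled_comparison()` forms each group's set as the union of
its members' patterns passing the cutoff *within that member* — cutoff before
pooling, so a pattern prominent in one member is not diluted by the others —
and `cumulative_comparison()` sums the region counts over amplicons.
`per_cpg_levels()` and `overall_level()` reduce a distribution to combined
per-CpG methylation and its mean.

## The simulator, and what it does not emulate

`simulate_reads()` emulates the study conditions end-to-end: amplicons of
551/401/405 bp with 10/10/15 CpGs, five condition libraries, 2×300 read
geometry, a small number of dominant epiallele patterns per condition
(uniformly drawn distinct patterns with symmetric-Dirichlet frequencies,
sorted descending), bisulfite non-conversion/over-conversion, sequencing
substitutions and indels, and per-molecule truth tables. Default error rates
are `f = g = 0.005`, `m = 0.003`, indels `5e-4`, non-CpG conversion failure
`0.002` — plausible residual magnitudes after double bisulfite treatment on a
MiSeq, chosen once as the study condition since the source protocol prints no
rates. Qualities are constant (the pipeline applies no base-quality filter,
matching its length/gap-only quality contract), and output is byte-identical
given identical arguments.

Deliberately not modelled: PCR duplicates and chimeras, quality-score error
profiles, index hopping/demultiplexing, strand asymmetries, and any
relationship between the number of pooled individuals and the number of
epialleles (the mixture size `k` is exposed directly). Passing tests
therefore demonstrate correctness of the algorithms under the stated channel,
not robustness to artefacts the channel excludes — on real libraries, PCR
duplicates in particular would narrow the effective depth and correlate
errors in ways the estimator does not see.

## Numerical and design choices

- Coordinates are 0-based half-open internally; every exported table and
  config uses 1-based inclusive positions.
- Templates containing N are rejected at load time: a pattern position must
  be certain.
- `N` in reads never matches anything in alignment and yields an ambiguous
  call at a CpG column.
- Primer prefixes in simulated reads are 3 pad bases + the primer's last
  30 nt, so the exact-match window sits at read positions 4–33; extraction
  strips the 33-base window after matching.
- Tie-breaks: alignment traceback prefers diagonal, then up, then left, and
  the rightmost best end column; proportional truncation rounds half up with
  the odd column removed from read 1; pattern tables order by count
  descending then pattern string ascending.
- Degenerate inputs: empty FASTQ and empty call streams produce empty tables,
  not errors; an empty count table is a domain error for the estimator; a
  single observed pattern fits to a point mass.
- Problem sizes in the shipped validation: the zero-error identity runs the
  full 3 amplicons × 5 conditions × 10,000 pairs; estimator recovery runs 20
  replicates of n = 20,000 at the pattern level (the read-level channel is
  exercised by the zero-error identity and the read-level unit tests);
  alignment is cross-checked against a brute-force DP on 200 random short
  string pairs, and the estimator against a multi-start quasi-Newton
  optimizer on mixtures small enough for it to be trustworthy.

## Limitations

- Only the top (primer-selected) bisulfite strand is modelled; G/A conversion
  logic for the opposite strand is out of scope.
- Error rates are treated as known; misspecifying them biases the estimated
  frequencies, roughly linearly for small misspecification.
- The candidate support excludes never-observed patterns; a true pattern can
  only be recovered if at least one read shows it exactly.
- Non-CpG (CHH/CHG) contexts, fuzzy primer matching and base-quality-aware
  processing are intentionally absent.
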