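---
title: "circorf: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circorf: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the procedure
each stage implements, the assumptions behind it, the tunable parameters
with their defaults and rationale, what the synthetic-data generator does
and does not emulate, and the numerical choices that affect results in edge
cases. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The analysis model

The pipeline asks, for each backsplice event in a pan-cancer catalog:
*if this circle were translated, would the product be a genuinely new
protein?* It decomposes the question into independent, individually
testable stages:

1. **Selection.** Backsplice coordinates are 1-based inclusive (the catalog
   dialect does not state its convention; this choice is consistent with how
   such coordinate tables are usually printed, and BED output is converted
   to 0-based half-open). Records must be expressed in at least
   `min_samples` samples (default 40 — a recurrence filter against
   artifacts; synthetic runs scale this down via
   `min_samples_expressed`), must map to an annotated gene, and must not
   span more than one gene. "Read-through" exclusion is operationalized as
   *window overlaps ≥ 2 annotated gene extents* — a testable surrogate for
   a phrase the source recipe leaves informal.

2. **Circular splicing.** Each annotated transcript with an exon
   overlapping the window contributes one candidate isoform: exon segments
   are clipped to the window (clipped rather than dropped — this preserves
   junction-proximal sequence; the alternative is flagged as a sensitivity
   point, not a settled fact), concatenated in genomic order, and
   reverse-complemented for minus-strand genes. Isoforms shorter than
   `min_len_nt` (150) are dropped: shorter circles rarely host a 50-aa ORF
   and the filter bounds downstream cost.

3. **Circular ORF calling.** The spliced sequence is treated as a true
   circle: codons are read modulo its length, so ORFs freely cross the
   backsplice junction. `cycle_cap = 3` is not arbitrary: a circle of
   length L with L mod 3 ≠ 0 re-enters a new codon phase on each
   traversal and has visited all three phases after 3; if L mod 3 = 0 the
   frame repeats immediately. Hence any frame still stop-free after
   `cycle_cap` traversals is stop-free forever — a rolling-circle frame,
   reported with its product truncated at the cap and excluded from
   "longest ORF" selection (its product length is undefined). Internal
   ATGs are enumerated as separate starts, but only the longest ORF per
   circRNA is carried forward; ties break by smallest start offset, then
   smallest frame. Codons containing N never start an ORF, never count as
   stops, and translate only when unambiguous (e.g. GGN → G); an ambiguous
   codon ends the candidate without a stop, which rejects it — a
   conservative stance on dirty input.

4. **Terminus novelty.** Exact Smith–Waterman with affine gaps replaces a
   heuristic seeded search: at desk scale the exact optimum is affordable
   and removes a source of irreproducibility. Scoring is BLOSUM62 with gap
   open 11 / extend 1 and Karlin–Altschul constants λ = 0.267,
   K = 0.041 — the standard gapped protein-search defaults; the source
   recipe names only the search program version and the E ≤ 1e−10 gate,
   so these constants are this package's (documented, overridable)
   choice. The best cognate is the lowest-E hit over all isoforms of the
   gene (ties: higher score, then lexicographic id). Classification uses
   *span boundaries only*: substitutions inside the aligned span never
   create "novel" termini, because novelty is positional. `canonicalMet`
   requires the alignment to start at residue 1 of **both** sequences —
   starting at query residue 1 but inside the cognate is an internal Met,
   a different biological claim.

5. **Domain architecture.** The package consumes a precomputed domain
   table rather than running a profile-HMM search; "overlap" is defined on
   ordered domain identities (subsequence containment, repeats respected),
   not coordinate intervals, mirroring how architecture diagrams are read.
   With several cognate isoforms, `novelDomainStructure` requires
   disjointness from *every* isoform; otherwise the call is made against
   the isoform sharing the most distinct domains, with ties resolved by a
   fixed precedence (conserved > extra > lacking > differentOrder >
   lackingPlusExtra) then lexicographic id. The source recipe never says
   how a single class was chosen when isoforms disagreed; this
   maximal-overlap rule is this package's resolution and is flagged as
   such. Degenerate cases are defined, not special-cased: empty vs
   non-empty is `lackingDomain`, empty vs empty `conservedStructure`.

6. **Expression.** Counts → log2 RPM with pseudocount 1 (the recipe is
   silent on zeros); per-sample library sizes default to the per-sample sum
   of catalog reads because true library sizes are not part of the
   backsplice dialect (an external table can be supplied). Quantile
   normalization equalizes column distributions exactly; ties within a
   column receive the mean of the tied reference values. The sample filter
   retains totals *strictly greater* than the median (the comparator was
   unstated; strict-greater retains exactly half of an even number of
   distinct totals, and the all-equal case degenerates to "keep everything"
   with a warning). Row variability uses IQR > 0.5 with type-7 (linear
   interpolation) quartiles — stated because boundary rows depend on it.
   The DE test is a two-sided Wilcoxon rank-sum with the tie-corrected
   normal approximation and *no* continuity correction; the recipe never
   names its test, and a rank test is robust on quantile-normalized log
   counts. BH is applied over all tested rows first; the fold-change gate
   (|log2FC| ≥ 1) is applied after adjustment, since the order was
   unstated and gating first would invalidate the FDR bookkeeping.

7. **Overlap statistics.** The two-tailed Fisher test uses the
   point-probability method (sum all tables with point probability at most
   that of the observed one, with 1e−7 relative slack for float ties) —
   the common convention. Over-representation is one-sided
   ("greater") by default because enrichment is the question asked; the
   two-sided variant is a flag. Interval intersection is 0-based half-open
   internally, so touching intervals do not overlap; chromosome names
   tolerate a `chr` prefix on either side. Peptide matching counts exact
   containment in either direction (extension in database peptide, or
   database peptide in extension).

The IRES stage of the original analysis is out of scope by design: the
pipeline only carries a `prob_IRES` threshold (0.3) in its configuration as
a pass-through annotation; no IRES prediction is performed.

## The synthetic world

`make_reference()` works backwards from the answers. For each planted
scenario label it first designs the cognate protein P and the circORF
protein Q, then reverse-engineers a genome that reproduces exactly those
molecules through the real pipeline:

- Cognate bodies are drawn from the alphabet {A, L, G, S, T, Q, N, D} and
  novel extensions from {W, P, Y}. Every BLOSUM62 score between the two
  alphabets (and between extensions and M) is **strictly negative**, so an
  optimal local alignment can never extend into an extension: the aligned
  span boundaries — hence the recovered terminus classes — are forced, not
  merely likely. Noiseless recovery is therefore a correctness property,
  and the 100%-recovery acceptance test is meaningful.
- Codons are chosen from a fixed table whose entries never end in `A` or
  `AT`, so no ATG can arise across codon junctions; each designed circle
  carries exactly one ATG and hence exactly one ORF. The generator asserts
  this and fails loudly rather than emitting an ambiguous fixture.
- The designed ORF is split at a random codon boundary and laid out as
  `tail + filler + head` on the genome, with the start codon near the 3'
  end of the window — so every planted coding ORF genuinely crosses the
  backsplice junction. The filler contains no `A` at all and therefore no
  spurious starts. The circle is realized as a separate non-coding isoform
  (t2) of the gene whose cognate transcript (t1) lies outside the window.
- Extension peptides are drawn containment-free against every other
  extension and decoy database peptide (resampling until no string contains
  another), which makes peptide-database truth exact rather than
  probabilistic; their lengths are drawn around means of 24 aa (N) and
  17 aa (C), the magnitudes reported for real novel extensions.
- A rolling-circle gene plants a circle whose length is divisible by 3 with
  a single ATG and no in-frame stop. Four decoy records violate exactly one
  selection filter each (few samples, intergenic, too short after splicing,
  read-through), so the rejection paths are exercised by default. The
  intergenic decoy's symbol is deliberately absent from the GTF — the one
  sanctioned exception to the "every TSV symbol is annotated" invariant.
- Expression is log-normal on the log2 scale: baseline uniform on [2, 6]
  (moderate abundance), planted DE rows shifted by ±`de_effect`/2 per
  group so group means differ by exactly `de_effect` before noise, library
  sizes uniform on [0.5M, 2M]. Counts are derived by exponentiation and
  rounding; no read-level simulation is attempted. The generator
  deliberately avoids a parametric count likelihood (e.g.
  negative-binomial shot noise) so that the rank-based DE test is not
  being validated against its own generative assumptions.

What a green test does **not** establish: behaviour on real catalogs with
overlapping genes, heavily shared exons, many isoforms per gene,
sequencing-depth artifacts, or alignment ambiguity between paralogous
cognates — the toy world contains none of these. The generator's defaults
(12 records, 60 samples, effect 2, noise 0.5) describe a small but
fully-branching world, not a realistic corpus; corpus-scale headline counts
are out of reach by construction and are not asserted anywhere.

## Numerical and tie-breaking choices

- Smith–Waterman: the best cell is the first strict maximum in
  row-major scan order; traceback prefers diagonal, then subject-consuming
  gaps, then query-consuming gaps. This makes spans deterministic; on the
  designed fixtures the optimum is unique anyway.
- Gap cost convention: a gap of length k costs `open + k·extend`
  (first gap residue 12 under 11/1), matching the standard protein-search
  convention and the independent oracle used in the tests.
- `evalue()` is the literal closed form; it is monotone in score and linear
  in database length, both property-tested.
- BH adjustment is the step-up formula; adjusted values satisfy
  `p ≤ p_adj ≤ 1` and equal both the literal definition and
  `p.adjust(method = "BH")` on random vectors.
- Wilcoxon variance uses the tie correction
  `n1·n2/12·((N+1) − Σ(t³−t)/(N(N−1)))`; a zero variance (all values
  tied) returns p = 1.
- Quartiles are type 7 (linear interpolation). Sample-filter ties
  (all totals equal) retain everything with a warning rather than dropping
  an arbitrary half.
- The `cycles` field of an ORF is `ceiling(nt consumed / L)`: an ORF can
  cross the junction while consuming less than one full traversal.
- All writers are timestamp-free and locale-independent; two runs from one
  seed are byte-identical, which the acceptance suite checks with MD5
  digests.

## Known limitations

- One cognate protein per gene by default; the multi-isoform scenario flag
  exercises the best-hit and classify-vs-all logic but not deep isoform
  families.
- The E ≤ 1e−10 gate is applied to the best hit per circORF; whether the
  original analysis gated the best or any hit is unknowable from the
  recipe.
- Domain comparison ignores domain coordinates entirely; two architectures
  with identical id order but wildly different spacing are "conserved".
- The expression stage estimates library sizes from the circRNA catalog
  itself; if circRNA content co-varies with condition this biases RPM, and
  an external library-size table should be supplied.
- Rolling-circle products are detected and reported but never classified
  for novelty (their repeating primary structure has no stable terminus).
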