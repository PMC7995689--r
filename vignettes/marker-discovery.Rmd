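---
title: "Reference-free discovery and evaluation of short-amplicon microsatellite markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free discovery and evaluation of short-amplicon microsatellite markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strmarker)
```

## The problem

Censusing elusive, endangered mammals — the Sumatran rhinoceros
(*Dicerorhinus sumatrensis*) being the motivating case — often has to rely
on DNA recovered non-invasively from dung. Such DNA is scarce, fragmented
and contaminated, which constrains marker design in two ways: amplicons
must be short (fragments much beyond ~150 bp amplify poorly from degraded
template) and markers must be screened against plausible contaminant
genomes (human handlers; sympatric species such as the Asian tapir whose
dung can be confused with rhino dung in the field).

When no reference genome is available and tissue from only a couple of
individuals can be sequenced, polymorphic microsatellite (STR) loci can
still be found directly in unassembled shotgun reads: reads carrying the
same repeat locus are recognised by their shared flanking sequence, and a
locus whose reads show two or more distinct repeat-array lengths across
the sampled chromosomes (two diploid individuals = four chromosomes) is a
polymorphism candidate worth taking to the bench. `strmarker` implements
that discovery pipeline end to end, plus the panel statistics used to
judge the resulting markers: observed and expected heterozygosity,
F~IS~, the probability of identity for unrelated individuals and for full
siblings, cumulative panel power, and blood-versus-fecal genotype
concordance.

## Pipeline stages and their parameters

### Repeat scanning (`scan_reads`)

Perfect tandem arrays of primitive 2–4 bp units, at least `min_units = 4`
whole units long. Two conventions matter and are worth stating exactly:

* **Motif classes.** `(AC)n`, `(CA)n` and `(GT)n` describe one locus seen
  in different phases and strands. `canonical_motif()` maps a unit to the
  lexicographically smallest string over all cyclic rotations of the unit
  and of its reverse complement, so all of these hits share the class
  representative `"AC"`. Units that are repetitions of a shorter unit
  (`"ATAT"`, `"CCC"`) are invalid: the array is reported under its
  primitive unit instead.
* **Maximal spans.** A reported array is the *full* maximal run, including
  a trailing partial unit where a flanking base happens to continue the
  repeat (`…GGA|ACACACA|C…`). Truncating to whole units would be
  left-aligned and therefore asymmetric between strands — reads from the
  two strands of one locus would disagree about where the array ends by up
  to `len(unit) − 1` bases, which desynchronises the flank anchors used
  for clustering. With full spans, coordinates mirror exactly under
  reverse complement. `unit_count` still counts whole units, and it is the
  whole-unit count that the ≥6-repeats candidate filter uses.

The scan threshold is deliberately lenient (4 units); the stricter
6-unit rule is a *candidate* filter applied after allele calling, so that
borderline loci remain visible while clustering.

### Orientation and clustering (`orient_hits`, `cluster_hits`)

Reads arrive from both strands, so each hit is first flipped to a
canonical orientation. The flip decision compares the sequence read
outward from the right edge of the array in both candidate orientations
(as-read `right_flank` versus `revcomp(left_flank)`, over their common
length) and keeps the lexicographically smaller. Anchoring the comparison
at the array boundary is essential: a rule that compares whole
concatenated flanks changes its answer depending on where each read
happens to be truncated, and splits loci into two strand-clusters. Ties
(palindromic context) keep the as-read orientation.

Clustering then groups hits that share a canonical motif, agree exactly on
an `anchor_k = 12` bp flank k-mer immediately adjoining the array on at
least one side, and differ by at most `max_mismatch = 2` substitutions
over the full flank overlap (left flanks aligned at their array-adjacent
end, right flanks likewise). Merging is a transitive closure via
union–find, which makes the result independent of read input order and of
whether two individuals' hit lists are merged before or after clustering.
Hits with either flank shorter than `min_flank = 20` bp carry too little
context to place and are set aside; this also means a read whose array
touches the read end (allele length unknowable) never participates in
allele calling.

### Allele calling (`call_alleles`)

The allele carried by a read is its array span in bp. Alleles supported
by fewer than `min_support = 2` reads are dropped: with only ~4
chromosomes sampled, a single-read allele is more plausibly a sequencing
error than a real variant. A cluster is *polymorphic* with ≥2 surviving
alleles, *monomorphic* with exactly one, *ambiguous* with none. Allele
lengths are not forced to be motif-length multiples (a flank indel can
shift one allele by a non-multiple), but non-multiple spacing raises the
`nonmultiple_spacing` flag.

### Candidate filtering (`filter_loci`)

Polymorphic clusters are excluded, with *all* failing reasons reported,
when they show:

* `TOO_FEW_REPEATS` — longest allele below `min_unit_count = 6` whole
  units (short arrays are rarely polymorphic enough to be useful);
* `BROAD_RANGE` — allele span above `max_allele_range_bp = 20` (very
  broad spectra usually mean two paralogous loci collapsed into one
  cluster, and complicate short-amplicon design); "too broad" has no
  universal number, so the 20 bp default is a configurable quantification;
* `REPETITIVE` — a flank is low-complexity (DUST-like triplet score above
  1.5 in any 20 bp window) *or* its anchor k-mer recurs in more than
  `copy_number_cap = 2` clusters (a multi-copy signal that needs no
  repeat library);
* `CONTAMINANT_LIKE` — a flank matches a user-supplied contaminant FASTA
  (e.g. a human decoy set) at ≥0.90 ungapped identity over ≥30 bp, via
  deterministic seed-and-extend on both strands. With no contaminant set
  the check is skipped with a warning — never silently passed as checked.

Only the `flank_window = 60` bp adjacent to the array is screened: that is
the region a short-amplicon primer can occupy, and consensus further out
is both less reliable (fewer covering reads) and, in dense genomes, may
belong to a neighbouring locus.

### Primer design (`design_primers`)

An exhaustive search over the consensus flanks under explicit constraints:
per-primer length 18–22 nt with pair totals 36–44 nt, GC fraction
0.40–0.60, Tm 54–62 °C with |ΔTm| ≤ 3 °C, no homopolymer ≥5, a 3′ G/C
clamp with at most 3 G/C among the last five bases, primers never
overlapping the array, and the product for the *largest* known allele at
most `max_amplicon_bp = 150`. Ranking is deterministic: |ΔTm|, then
product size, then forward start. Tm defaults to the Wallace rule
(2(A+T) + 4(G+C)); a unified nearest-neighbour model (SantaLucia 1998
parameters, entropy salt correction at 50 mM Na⁺, 500 nM primer) is
available as `method = "nn"`. Reported marker size ranges add the 18 bp
M13 forward tail (`TGTAAAACGACGGCCAGT`) used for fluorescent genotyping;
the tail never participates in binding-site search, because only the
genomic primer hybridises.

### In-silico PCR (`find_binding_sites`, `amplify`, `classify_marker`)

Binding sites allow up to `max_mismatch = 2` substitutions (no indels)
but require the `three_prime_exact = 3` bases at the primer 3′ end to
match exactly — polymerase extension needs a matched 3′ terminus. Products
are enumerated for every facing pair of sites within
`max_product = 1000` bp (validation mode; design-time screening uses the
150 bp amplicon cap). Classification mirrors bench triage:
`multiple_products`, `monomorphic`, `broad_range`, `no_product`, or the
desired `single_product_polymorphic`.

## Panel statistics

For a locus with sample allele frequencies $p_i$ over $n$ typed diploids
(missing calls removed locus-wise):

* $H_O$ = fraction of typed individuals with two distinct alleles;
* $H_E = 1 - \sum_i p_i^2$, and unbiased
  $H_E^{u} = \frac{2n}{2n-1}\left(1 - \sum_i p_i^2\right)$ — the printed
  marker-table values reproduce only under the unbiased form, which is
  therefore the default;
* $P_{ID} = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2$, the probability that
  two unrelated Hardy–Weinberg individuals share the genotype;
* $P_{ID(sib)} = 0.25 + 0.5\sum_i p_i^2 + 0.5\left(\sum_i p_i^2\right)^2
  - 0.25\sum_i p_i^4$, the conservative full-sibling bound (always
  ≥ $P_{ID}$);
* $F_{IS}$ both as `simple` $1 - H_O/H_E^{u}$ and as the Weir–Cockerham
  (1984) single-population $f$ from variance components
  ($b_i = \frac{n}{n-1}(p_i(1-p_i) - h_i\frac{2n-1}{4n})$,
  $c_i = h_i/2$, $f = 1 - \sum c / \sum(b+c)$). The two differ for
  multi-allelic loci with few individuals; published tables of this kind
  match the variance-component form, so that is the default. F~IS~ at a
  monomorphic locus is undefined and reported as `NA`, never 0.

No small-sample correction is applied to $P_{ID}$ — the baseline
equations reproduce the published per-locus values. `panel_power()` sorts
loci by ascending per-locus probability (most informative first), takes
running products, and reports the smallest panel whose cumulative
probability drops below the threshold (default $10^{-4}$); products
across loci assume linkage equilibrium. Internal arithmetic is full
precision; display rounding is half-up to 2 decimals, matching the usual
table convention.

`genotype_concordance()` compares a reference table (e.g. blood) with a
test table (e.g. fecal) call by call: `match`, `allelic_dropout`
(reference heterozygote, test homozygous for one of its alleles),
`false_allele` (test carries an allele absent from the reference call,
which takes priority over dropout when both occur), `other_mismatch`.
The false-allele rate is estimated as $n_{false}/n$; the dropout rate
divides dropouts by reference-heterozygote pairs not already consumed by
a false allele.

## The synthetic truth sets

`simulate_genomes()` builds `2 × n_individuals` haplotypes (two diploids,
i.e. four chromosomes, by default) sharing unique random inter-locus
spacers, with one planted perfect array between consecutive spacers.
Polymorphic loci carry two allele lengths one to three units apart,
distributed so both alleles are present among the haplotypes. Spacer
boundary bases are constrained not to continue either adjacent repeat, so
the planted span is exactly what the scanner should report, and spacer
anchor 20-mers are resampled on collision so every planted locus has
clusterable, effectively unique flanks. `simulate_reads()` draws
per-haplotype Poisson read counts at the requested coverage, uniform
start positions, balanced strands, and independent substitution errors.
`degrade_genotypes()` emulates low-template genotyping: whole-call
missingness, allelic dropout of heterozygotes, and novel false-allele
labels, in that order, each at a configurable rate.

Default conditions are the study conditions this package targets: 2
individuals, 300 bp MiSeq-like reads, 30× per-haplotype coverage,
error-free by default (substitution-only when enabled, so allele-length
truth stays exact — no indel errors, a documented limitation). Desk-scale
problem sizes used by the test-suite and the acceptance script: 30
planted loci on ~4.7 kb haplotypes (~1,900 reads), 200 random sequences
for the scanner oracle, 10⁴ calls (500 individuals × 20 loci) for
error-rate recovery. At these sizes the whole suite runs in well under a
minute.

What passing these simulations does *not* show about real data: real
flanks are not uniformly random (repeat-dense neighbourhoods make the
REPETITIVE filter earn its keep far more often), real reads carry indels
and quality-dependent errors, PCR introduces stutter that the degradation
model only caricatures as dropout/false alleles, and real loci are not
ideally spaced. The pipeline's thresholds are therefore defaults to be
revisited per data set, not guarantees.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; `N` never matches and
  terminates arrays.
* Overlapping candidate arrays: longest wins, then smaller start, then
  shorter unit — deterministic and oracle-checkable.
* Consensus flanks are per-column majority votes aligned at the array
  boundary, ties resolved alphabetically.
* Cluster output is sorted by motif then consensus flanks, so cluster ids
  are stable across read orderings.
* All-missing loci, empty contaminant indexes, monomorphic F~IS~, and
  no-overlap concordance raise typed conditions rather than returning
  silent zeros.
* Every simulation function takes a mandatory seed; the CLI threads one
  seed through all stages.

## Known limitations

Penta-nucleotide and longer motifs, compound and interrupted repeats are
out of scope, as are indel-tolerant primer binding, thermodynamic
dimer/hairpin checks, diploid genotype calling from reads, and
linkage-disequilibrium testing. The contaminant screen is ungapped;
diverged contaminants with indels will score lower than a banded aligner
would report. The discovery stage assumes reads long enough to span an
array plus ≥20 bp of flank on both sides.
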