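---
title: "Methods: satellite DNA comparison and sex-linked marker screening"
author: "sexsatkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite DNA comparison and sex-linked marker screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Differentiating sex chromosomes accumulate repetitive DNA in their
non-recombining regions. Comparing the satellite DNA (satDNA) content
of males and females — and of related karyomorphs with different sex
chromosome systems — therefore gives a read-based window on sex
chromosome evolution without a genome assembly. `sexsatkit` implements
the computational stages of such a comparison: catalog curation and
cross-catalog homology, read-based abundance and divergence per family,
monomer haplotype networks with per-sex exclusivity, and a screen of
reduced-representation SNP genotypes for perfectly sex-linked markers
with an explicit expected-by-chance statistic. A synthetic-data module
generates all three input kinds with a planted ground truth, so the
whole pipeline is testable end to end.

# Catalog curation and comparison

## Pairwise identity between monomers

satDNA consensus monomers are circular in nature: two deposited records
of the same family may differ by an arbitrary rotation and by strand.
Identity between monomers `a` and `b` is computed by aligning the
shorter of the two, end to end, into the best window of the dimerized
longer one (`b·b`) and of its reverse complement, taking the better
strand. Dimerization exposes every rotational phase of `b` as a
contiguous substring, so a pure rotation scores exactly 100.

The alignment is *global in the pattern* (global–local). This is a
deliberate design choice: a purely local alignment maximizes its score
on the best-matching substring, and for short monomers that degenerates
— any two unrelated sequences share a short exact substring, which
would score 100% identity over a handful of columns and collapse the
relationship classification. Anchoring the whole shorter monomer makes
identity mean "fraction of the monomer that matches at its best phase
and strand".

Scoring is conventional short-tandem-repeat scoring: match +1, mismatch
−1, gap open −5, gap extend −1 (configurable via `sat_scoring()`).
Identity is `100 × matches / aligned columns`; gap columns count in the
denominator and `N` bases never count as matches.

Even with the anchored alignment, unrelated random monomers of ~30–50
bp reach 40–55% identity at their best phase/strand, so the >50%
superfamily threshold is intentionally permissive; this is visible in
the synthetic catalog comparison (stage 2 of the analysis) and is the
reason the family-sharing criterion is exposed as an option.

## Relationship classes and catalog overlap

Two records are classified, in decreasing order of stringency, as the
same variant (>95%), the same family (>80%), a superfamily (>50%), or
unrelated. Inequalities are strict: a pair at exactly 95.0 falls to
`same_family`. `compare_catalogs()` computes all cross-catalog pairs,
counts identical pairs (identity 100), and counts shared families over
the smaller catalog: a record is "shared" when it has at least one
cross-catalog partner above the `family_threshold`. Cross-karyomorph
homologs can sit below the 80% family threshold while still being
genuinely related, so the default sharing criterion is the superfamily
level (50%), with the stricter 80% available as the same parameter —
both are reported by the analysis scripts since the choice is a matter
of interpretation, not of algorithm.

## Naming

`name_catalog()` ranks records by decreasing genomic abundance (ties:
longer repeat unit first, then lexicographic consensus) and formats
names as `<prefix>Sat<zero-padded rank>-<repeat unit length>`, e.g.
`HmfSat01-28`; `parse_sat_name()` inverts the format.

# Read-based abundance and divergence

`map_reads()` aligns every read, on both strands, against a concatemer
of each catalog consensus — at least two copies (phase tolerance) and
enough copies to span a whole read, so a read consisting purely of
tandem copies aligns end to end. A read is assigned to the satDNA with
the best-scoring alignment, provided identity ≥ 80% and ≥ 28 aligned
bp (both configurable), and each read is counted at most once, so the
per-family aligned base counts never exceed the analyzed bases.

Genomic abundance is reported as the masked-base fraction
`aligned_bp / analyzed_bp` by default. A literal
mapped-reads-per-analyzed-nucleotide variant is available
(`mode = "reads_per_nt"`); the base-fraction form is the default
because it is comparable across families with different repeat-unit
lengths. Note that both definitions are *compositional*: a strongly
male-amplified family increases the male library's repetitive fraction
and thereby depresses the relative fraction of every other family, so
moderate inverse ratios in other families are expected side effects,
visible in the synthetic runs.

Per-read divergence uses the Kimura 2-parameter model. With transition
proportion $P$ and transversion proportion $Q$ over the ungapped
aligned columns,

$$K = -\tfrac12 \ln\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right],$$

undefined (saturated) when $1-2P-Q \le 0$ or $1-2Q \le 0$; saturated
reads are excluded from the per-family mean, which is weighted by
aligned bases. As $P,Q \to 0$, $K \to P+Q$.

`sex_ratio()` forms the male/female abundance ratio per family (with an
`Inf` sentinel when the family is absent in females) and flags
candidates at ≥1.5-fold in either direction — a deliberately
conservative default for probe-design shortlists, configurable.
`paired_catalog_test()` is the classical paired t-test on matched
repeat-class proportions of the two sexes at 95% confidence, with
explicit conventions for degenerate inputs (all-zero differences:
t = 0, p = 1; constant nonzero differences: t = ±∞, p = 0).

# Monomer haplotypes and the spanning tree

`extract_monomers()` aligns each read (both strands) to a consensus
concatemer long enough to cover it; complete monomer frames then fall
at multiples of the repeat-unit length in subject coordinates, so every
excised monomer is automatically in consensus phase. From each read
whose alignment reaches the identity floor (default 80%), the single
best-matching complete, gap-free monomer copy is excised (ties to the
leftmost); one monomer per read avoids double-counting tandem copies
within a read, and an `all_copies` mode exists for coverage-style
analyses. Reverse-complement reads yield the forward-phase monomer, so
extraction is strand-invariant.

A haplotype is an exact-sequence equivalence class of monomers.
Haplotypes observed once across all libraries (singletons) are
discarded as likely sequencing errors; exact matching (not clustering
at <100% identity) is used because a singleton *sequence* is precisely
what one error produces, and a clustering threshold would merge true
low-frequency variants. A `min_total` parameter generalizes the filter.

`build_mst()` builds the minimum spanning tree of the complete graph on
haplotypes with Hamming-distance weights (nucleotide mutational steps;
equal lengths are guaranteed by frame excision, and a Levenshtein mode
exists for unequal-length inputs). Equal-weight edges are broken
deterministically — prefer the edge joining the higher combined-count
node pair, then the lexicographically smallest endpoint sequences. This
is a simple documented rule rather than the goeBURST rule set of
PHYLOVIZ-style tools; tie-breaking can change tree *topology* but never
the total weight, which the tests pin to an exhaustive enumeration
oracle over all labelled spanning trees (Prüfer sequences) on ≤7-node
instances.

`group_stats()` maps libraries to groups (e.g. karyomorph × sex) and
reports the total haplotype count, the count exclusive to each group
(nonzero only there), the count present in more than one group, and the
top-k shared haplotypes; exclusives plus multi-group haplotypes always
partition the total.

# Sex-linked marker screen

Genotypes follow the collapsed DArT dialect: 0 homozygous reference, 1
homozygous alternate, 2 heterozygous, `-` missing. Under male
heterogamety (XY), a perfectly sex-linked SNP is heterozygous in every
male and homozygous in every female; `scan_xy()` returns such loci, and
`scan_zw()` the mirror image. By default only complete loci enter the
scan (`max_missing = 0`): "heterozygous in *all* males" is undefined
under missingness, so relaxation is explicit, and a locus is never
scanned on one sex only.

With $L$ null loci and per-individual heterozygosity $h$, the expected
number of chance XY patterns is

$$E = L \, h^{n_m} (1-h)^{n_f},$$

(mirrored for ZW), which at $h = 1/2$ reduces to $L\,2^{-(n_m+n_f)}$.
$h$ defaults to the observed heterozygosity of the matrix, with 0.5
available; $L$ counts only loci eligible for the scan. The geometric
dependence on sample size is the practical message: thousands of loci
genotyped on a handful of individuals per sex *will* contain perfect
patterns by chance, so an observed count is meaningful only against
$E$. The verdict rule makes this concrete: a system is called
XY- or ZW-suggestive only when the observed count exceeds $E$ *and* the
one-sided Poisson tail $P(X \ge \mathrm{obs})$ at mean $E$ is below
0.05; otherwise the screen is inconclusive. The Poisson margin is a
documented concrete rule standing in for the qualitative judgement such
screens usually apply.

# The synthetic-data generator

The generator is the package's study-condition definition, not a test
fixture. `simulate_sat_reads()` realizes each satDNA family as a set of
distinct monomer haplotypes around a (random or given) consensus —
shared variants at the family's mutation rate, plus per-library
exclusive haplotypes — assigns copy numbers split equally among
variants and scaled by the per-library sex-bias multipliers, builds a
head-to-tail array per family in which copies of one haplotype form
contiguous blocks (satDNA arrays are locally homogeneous, as concerted
evolution homogenizes neighboring copies; fully interleaved variants
would be both unrealistic and ill-posed for one-monomer-per-read
extraction), appends an i.i.d.-uniform background pool, and fragments
everything into fixed-length reads at uniform random positions and
strands, sampled in proportion to segment lengths as in
uniform-coverage sequencing. The truth ledger records every realized
haplotype and its per-library copy counts.

Default study conditions used by the analysis scripts and the
acceptance script: 150 bp reads, 1200 reads per library, two families
(repeat units 32 and 28 bp, three shared variants at 5% divergence, 120
copies), one family male-accumulated 3× with five male-exclusive
haplotypes, 20 kb background; genotype matrices of 1000 loci for 5
males and 5 females at 35% heterozygosity with four planted XY loci.
These sizes make every recovery property hold with large margins while
keeping a full run in seconds; they emulate a scaled-down version of
low-coverage WGS plus a DArT screen.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: no sequencing-error or quality model (the
singleton filter is therefore exercised by sampling noise, not by true
errors), no coverage or GC bias, no paired-end structure, no higher-
order repeat structure or array interruptions, and genotype loci are
independent (no linkage). Conclusions about real libraries still
require the usual caution about mapping reference bias and sampling
depth.

`simulate_genotypes()` plants perfect XY/ZW loci among i.i.d. null loci
(heterozygous with probability `het_prob`, otherwise 0 or 1 equally)
and applies missingness to null loci only, so planted loci are always
recoverable by a complete-locus scan — recovery failures would indicate
scan bugs, never simulation noise.

# Numerical choices and degenerate inputs

* Identity thresholds are strict inequalities; boundary values fall to
  the lower class.
* `kimura2p()` raises a saturation error rather than returning `NaN`;
  the internal per-read aggregation treats saturated reads as missing.
* `build_mst()` on one node returns zero edges; unequal-length input is
  an error unless edit-distance mode is requested.
* `filter_singletons()` of an empty or all-singleton input returns an
  empty, well-formed node table.
* Subsampling (`subsample`, `seed`) is without replacement and
  reproducible; requesting more reads than exist uses all reads with a
  warning.
* All pipeline randomness flows from the single `run_config()` seed;
  the run manifest hashes every output file, and the serialized config
  excludes the output path so identical runs in different directories
  produce identical manifests.
* Coordinates in all reports are 1-based inclusive.

# Known limitations

* The abundance definition is compositional (fractions of the analyzed
  bases); cross-library comparisons assume comparable library
  composition.
* Monomer excision requires one complete gap-free copy within the
  read; repeat units longer than the read length are rejected, and
  units longer than half the read length are warned about, since
  full-monomer capture is then not guaranteed.
* The MST is one minimum-weight tree among possibly many; only its
  total weight and the node statistics are invariant, not the topology.
* The chance-expectation statistic assumes independent loci and a
  common heterozygosity; linked or filtered SNP panels violate this in
  ways the screen cannot detect.
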