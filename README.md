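# sexsatkit

Satellite DNA (satDNA) catalog comparison, monomer haplotype networks,
and sex-linked SNP marker screening from low-coverage short-read data.

Differentiating sex chromosomes accumulate repeats in their
non-recombining regions. Given satDNA consensus catalogs, WGS read
libraries from males and females, and a reduced-representation SNP
genotype matrix, this package answers the questions such a comparison
turns on, assembly-free:

* **Which satDNA families do two catalogs share?** Phase- and
  strand-tolerant identity between monomers (the shorter monomer
  aligned end-to-end into the dimerized longer one, best strand), with
  the standard classification: same variant (>95%), same family
  (>80%), superfamily (>50%), else unrelated.
* **Which families are sex-biased?** Per-library genomic abundance
  (masked-base fraction of the analyzed nucleotides), male:female
  ratios with candidate flagging, and per-family divergence under the
  Kimura 2-parameter model,
  `K = -1/2 · ln[(1 − 2P − Q)·sqrt(1 − 2Q)]`, with transition/
  transversion proportions P and Q.
* **Are repeat variants confined to one sex?** One monomer per read is
  excised in consensus phase, singletons are discarded, and the
  haplotypes form a minimum spanning tree in nucleotide mutational
  steps with per-group exclusivity counts.
* **Are apparent sex-linked SNPs real?** Scans for loci heterozygous in
  all males and homozygous in all females (XY; mirrored for ZW),
  compared against the number expected by chance,
  `E = L · h^(n_het sex) · (1 − h)^(n_hom sex)`, with a one-sided
  Poisson margin before any system is called suggestive.

A synthetic-data generator produces read libraries, catalogs, and
genotype matrices with a planted ground truth (sex-biased families,
sex-exclusive haplotypes, sex-linked loci), so every stage is testable
without downloads.

## Worked example

The `analysis/` directory is a numbered workflow over the package
functions; each stage writes its tables under `results/`.

```sh
Rscript analysis/01_simulate.R     # synthetic libraries + genotypes
Rscript analysis/02_catalog.R      # catalog naming and comparison
Rscript analysis/03_abundance.R    # abundance, ratios, paired t
Rscript analysis/04_haplotypes.R   # monomers, MST, exclusivity
Rscript analysis/05_slm.R          # sex-linked marker screen
```

Stage 3 maps both simulated libraries against the catalog and prints
the male:female ratios (the planted male-accumulated family `ySat`
carries a 3× array bias plus five male-exclusive haplotypes):

```
karF_male: 710 of 1200 reads mapped to the catalog
karF_female: 295 of 1200 reads mapped to the catalog

Male:female abundance ratios:
  sat_name abundance_male abundance_female ratio candidate
2     ySat         0.5212            0.112 4.635      TRUE
1  autoSat         0.0691            0.133 0.519      TRUE

Top candidate for sex-chromosome accumulation: ySat (4.64-fold)
```

`ySat` tops the ranking at 4.6-fold; `autoSat`'s mild inverse ratio is
the compositional side effect of the male library being dominated by
`ySat` (abundances are fractions of the analyzed bases). Stage 4
recovers the haplotype structure exactly:

```
Haplotypes after singleton removal: 8 ( 0 monomers discarded )
MST: 7 edges, total weight 14 mutational steps
Total haplotypes: 8
Exclusive to KarF_F : 0
Exclusive to KarF_M : 5
Planted male-exclusive haplotypes: 5 | recovered: 5
```

and stage 5 shows the chance statistic doing its job — the four
planted XY loci are recovered, the fifth hit is the expected chance
false positive, and the excess over chance is what licenses the
verdict:

```
Screened 1000 complete loci, 5 males / 5 females, observed heterozygosity 0.350
  pattern observed expected_by_chance p_poisson
1      XY        5              0.608  0.000418
2      ZW        0              0.608  1.000000
Verdict: XY-suggestive
Planted XY loci recovered: 4 of 4
```

The same statistic explains why a large panel on few individuals is
uninformative: ~6100 loci on 3 males and 3 females expect ≈95 perfect
XY patterns by chance alone.

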