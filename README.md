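# mitotetrad

Quantitative analysis of **mitochondrial genome inheritance in fission-yeast
tetrads** from colony shotgun sequencing.

In *Schizosaccharomyces pombe*, parental mitochondria are tethered to
opposite cell poles during meiosis, so each parent is expected to pass its
mitochondrial genome to exactly two of the four spores (2:2 segregation,
strict uniparental inheritance). Sequencing colonies grown from dissected
spores makes this testable quantitatively: at every mitochondrial SNP that
distinguishes the two parents, the per-sample reference/alternate
observation counts (the freebayes `RO`/`AO` fields of a multi-sample VCF)
measure how much of the colony's mitochondrial DNA came from each parent.
`mitotetrad` implements the full analysis for crosses of genetically
distinct strains, where inheritance turns out to be less tidy than the
textbook picture: mixed (heteroplasmic) colonies, recombinant mitochondrial
genomes, and tetrads that violate 2:2.

## What it computes

For a multi-sample VCF (per-sample `GT`, `RO`, `AO`) plus a colony metadata
table (parental controls vs spores; cross, tetrad and spore index):

1. **Site/call filters** — biallelic SNPs only; site quality `QUAL >= 30`;
   SNPs within 3 bp of an indel removed; calls with depth `RO+AO < 3` or
   alternate support `AO < 3` masked; sites with more than half the
   samples uncalled dropped. Each rejected site gets exactly one primary
   reason.
2. **Marker derivation** — per cross, sites where the two parental
   controls are confidently (major-allele fraction ≥ 0.95) called for
   different alleles become oriented markers:
   `parent1_allele ∈ {reference, alternate}`.
3. **Heteroplasmy** — per call, the minor observation fraction
   `AO/(AO+RO)` for reference calls and `RO/(AO+RO)` for alternate calls;
   the headline statistic is the percentage of calls strictly above 5%.
4. **Parent-1 fraction profiles** — per spore colony and marker,
   `f = (reads of the parent-1 allele)/(RO+AO)`, ordered along the genome.
5. **Recombination** — a colony is recombinant when the overall
   minority parent still contributes > 10% of observations at ≥ 1 marker;
   crossover breakpoint intervals are the gaps between adjacent markers
   hard-assigned (cutoff 0.5) to different parents.
6. **Tetrad segregation** — mean fraction per spore → predominant parent;
   a tetrad deviates from 2:2 when ≥ 3 assigned spores share a parent.
7. **Transmission bias** — per cross, the fraction of colonies
   predominantly inheriting each parent, with an exact two-sided binomial
   test against 1/2.
8. **Self-mating exclusion** — tetrads whose spores carry nuclear marker
   alleles from only one parent are excluded.

A ground-truthed **simulator** (`simConfig()`, `simulateDataset()`,
`emitDataset()`) generates matching VCF + metadata under the tethered 2:2
model with leakage/mixing (Beta-distributed minor fractions), meiotic
crossovers, negative-binomial coverage, sequencing error, spore
inviability and self-mated tetrads, so the entire pipeline is testable
without any external data.

## Worked example

```r
library(mitotetrad)

cfg <- simConfig(n_tetrads = 4, seed = 42)   # 3 crosses x 4 tetrads
out <- emitDataset(cfg, tempfile("mtdemo"))  # VCF + metadata + truth

x <- readTetradVcf(out$vcf)
x <- addSampleMetadata(x, readSampleMetadata(out$metadata))
x
#> MitoTetradExperiment: 20 sites x 44 samples
#>   contigs: I (12), MT (8)
#>   samples: 4 parents, 40 spores (0 excluded)
#>   crosses: wildAxlabA, wildAxlabB, wildAxwildB

res <- analyzeTetrads(x)
res
#> TetradAnalysis
#>   markers: 14 (cross,site) pairs over 8 distinct sites
#>   heteroplasmy: 7.5% of 106 calls above threshold
#>   spores: 23 analyzed, 3 recombinant
#>   tetrads: 7, 0 deviating from 2:2
#>   wildAxlabA: 54% of 13 spores from parent1 (binomial p = 1)
#>   wildAxlabB: 57% of 7 spores from parent1 (binomial p = 1)
#>   wildAxwildB: 33% of 3 spores from parent1 (binomial p = 1)
```

Reading the output: the 8 distinct mitochondrial SNPs are oriented
per-cross into 14 (cross, site) markers; 7.5% of the 106 evaluable spore
calls had a minor observation fraction above 5% (heteroplasmic signal);
3 of 23 analyzed colonies carry > 10% of the minority parent at some
marker (recombination or strong mixing); 17 of the 40 sequenced spores
came from tetrads flagged as self-mated and were excluded before
summarization. Per-spore detail is in `res$spores`:

```r
head(res$spores[, c("sample_id", "mean_parent1_fraction",
                    "predominant_parent", "is_recombinant")])
#>           sample_id mean_parent1_fraction predominant_parent is_recombinant
#> 1 wildAxlabA_T01_S1          0.9742931593            parent1           TRUE
#> 2 wildAxlabA_T01_S2          0.9997751799            parent1          FALSE
#> 3 wildAxlabA_T01_S3          0.0024279170            parent2          FALSE
#> ...
```

`buildReport(res, "results")` writes `spores.tsv`, `tetrads.tsv`,
`crosses.tsv`, `heteroplasmy.tsv` and three figures (minor-fraction
histogram, per-colony fraction profiles along the genome, per-tetrad mean
fraction strips).

A thin command-line wrapper is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/mitotetrad.R", package="mitotetrad"))')
Rscript $CLI simulate -c config.yaml -o simdata
Rscript $CLI analyze --vcf simdata/sim.vcf --meta simdata/metadata.tsv -o results
Rscript $CLI report -i results
```

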