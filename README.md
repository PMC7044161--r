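# clonebench

Simulation and evaluation toolkit for benchmarking tumor clonal
deconvolution methods on multi-sample bulk sequencing data.

## The problem

Bulk sequencing of several samples from a patient's tumor(s) yields, per
single-nucleotide variant (SNV) and sample, mutant and total read counts.
Clonal deconvolution methods turn these into *clone genotypes* (which SNVs
each clone carries) and a *clone phylogeny* — a rooted tree whose root is
the germline and whose branches carry the somatic mutations acquired along
each lineage. Benchmarking such methods needs two things, both provided
here:

1. **Simulators** that produce read-count datasets from a known truth:
   - random clone phylogenies with "localized" sampling (each sample holds
     one tip clone plus all of its ancestors, so ancestral clones persist);
   - whole-haplotype copy-number gains, losses and LOH overlaid on a
     phylogeny, with copy-number-aware expected VAFs and depths;
   - a 3D lattice tumor-growth model (constant / step / linear cell-division
     rules) with sector sampling and clone calling;
   - an observation layer: total reads ~ Poisson(expected depth), mutant
     reads ~ Binomial(total, expected VAF).
2. **Metrics** that score an inference against the truth:
   - error rates of ordering *concurrent* / *sequential* / *parallel*
     mutation pairs (average of the missed-pair and false-pair proportions,
     flagged undefined when a category vanishes from the inference);
   - a multi-label tree vector (TreeVec) distance on root-to-MRCA depths of
     clone-label pairs, tolerant of duplicated tip labels;
   - rooted Robinson–Foulds distance after pruning to one best tip per true
     clone;
   - SNV assignment error per clone, ancestral-clone detection counts, and
     star/line degenerate-topology failure flags;
   - post-processing for methods that emit no clone frequencies:
     constrained regression of `V = ½ f M` (non-negative least squares with
     `Σf ≤ 1`), a shared-vs-unique VAF t-test that removes spurious
     ancestors, and a <2% rare-clone discard.

The core mixture identity is `V(s, v) = ½ Σ_c f(s, c) M(c, v)` for
copy-neutral heterozygous SNVs; under CNAs each clone instead contributes
`f(s, c) · mutant_copies / total_copies` (e.g. 2/3 after a gain of the
mutant haplotype) and expected depth is re-weighted by total copy number.

## Worked example

```r
library(clonebench)

ds <- generate_random_dataset(7, 4, seed = 11)   # 7 clones, 4 samples
ds
#> clone_dataset: 4 samples, 7 clones, 35 SNVs

v  <- expected_vaf_neutral(ds$composition, ds$genotypes)
rc <- sample_read_counts(v, 100, seed = 12)      # 100x Poisson/Binomial
rc$total[1:2, 1:4]
#>    s1 s2 s3  s4
#> T1 85 96 87 108
#> T2 93 98 93 115

# pretend a method recovered every clone except one ancestral clone
inferred <- ds$genotypes[colnames(ds$composition), ]
inferred <- inferred[setdiff(rownames(inferred), "C1"), ]
evaluate_inference(ds, inferred)
#> evaluation_report
#>   SNV assignment error: 0
#>   ordering error rates: concurrent=0, sequential=0, parallel=0
#>   TreeVec: 2.449  RF: NA
#>   ancestral clones detected: 2/3
#>   topology flag: ok
```

Reading the report: the surviving clones are genotype-perfect (SNV error 0)
and the mutational tree implied by them still orders every mutation pair
correctly, but the missing ancestral clone shifts six root-to-MRCA depths
(TreeVec = sqrt(6) ≈ 2.449), only 2 of 3 ancestral clones are detected, and
RF is undefined (`NA`) because with fewer inferred than true clones no
one-to-one tip pruning exists.

End-to-end bundles and file-based evaluation:

```r
run_pipeline(run_config("growth", seed = 1, out_dir = "out", model = "linear"))
evaluate_files("out", "my_method_genotypes.tsv", out = "report.json")
```

or from the command line (`inst/cli/clonebench`):

```sh
clonebench simulate --preset cna-overlay --seed 1 --out out/
clonebench evaluate --truth out/ --inferred inferred.tsv --out report.json
```

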