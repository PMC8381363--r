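# tissueatlas

Classify tissue-specific gene expression in a multi-tissue RNA-seq atlas,
and rank milk proteins by absolute abundance — the analysis core of a
tissue-based transcriptome/proteome map of the kind built for livestock
panels (heart, kidney, liver, lung, brain, spleen, …, breast) with a
paired milk proteome.

For each protein-coding gene with replicate-averaged FPKM
$v_1,\dots,v_n$ across $n$ tissues, the package assigns one of six
specificity categories (detection floor $d = 1$ FPKM, fold threshold
$f = 5$), applied in precedence order so the classes partition the genes:

| category | rule |
|---|---|
| not detected | $v_t < d$ in every tissue |
| tissue enriched | $v_{(1)} \ge d$ and $v_{(1)} \ge f\,v_{(2)}$ (fold $\ge 50$ ⇒ *highly* enriched) |
| group enriched | some set $G$ of 2–7 detected tissues with $\mathrm{mean}(G) \ge f \cdot \mathrm{mean}(G^c)$ |
| tissue enhanced | $v_{(1)} \ge d$ and $v_{(1)} \ge f \cdot \mathrm{mean}(v_{(2)},\dots,v_{(n)})$ |
| expressed in all | $v_t \ge d$ in every tissue |
| mixed | none of the above |

The group search is provably a top-$k$ prefix search (tested against
exhaustive subset enumeration). Around the classifier the package provides:
replicate-to-tissue aggregation and all tabular I/O; atlas summaries
(category shares, per-tissue enriched/elevated counts, detected-gene strata,
elevated transcript-mass fractions); Spearman-distance average-linkage
sample clustering with Newick export; the bipartite tissue/group enrichment
network (group nodes limited to ≤ 5 tissues and ≥ 3 genes, display size
√gene-count) with GraphML export; gffcompare-style novel-transcript
filtering (class code `u`, length > 200 nt, > 1 exon) and
annotation-evidence counting (bit score > 500, identity > 50 %,
E-value < 1e-20); iBAQ ranking (intensity / number of 6–30 aa fully tryptic
peptides from an in-silico digest with proline-suppressed K/R cleavage); and
cross-species milk-proteome overlap counting (E-value ≤ 1e-5,
identity ≥ 30 %). A seeded synthetic-data generator plants all six
categories with known truth so every stage is testable offline.

## Worked example

```r
library(tissueatlas)
cfg <- atlas_config()

classify_gene(c(breast = 310, brain = 6, liver = 5, lung = 4, heart = 3), cfg)
#> gene: tissue_enriched [breast, fold 51.67] (highly enriched)
```

The breast value is 51.67× the second-highest tissue: at least 5× every
other tissue (tissue enriched) and past the 50× bar for the highly enriched
flag — the expression pattern of a milk-protein gene such as lysozyme or
α-lactalbumin.

```r
sim <- generate_atlas(atlas_sim_spec(n_genes = 500, n_tissues = 16,
                                     replicates_per_tissue = 3, seed = 42))
profile <- aggregate_by_tissue(sim$matrix, sim$metadata)
res <- classify_all(profile, cfg)
res$summary
#> category summary over 500 genes
#>   not_detected          15  (3%)
#>   tissue_enriched       85  (17%)
#>   group_enriched        50  (10%)
#>   tissue_enhanced       98  (20%)
#>   expressed_in_all     212  (42%)
#>   mixed                 40  (8%)
mean(as.character(res$calls$category) == sim$truth$planted_category)
#> [1] 0.986

build_network(res$calls, cfg)
#> enrichment network: 16 tissue nodes, 2 group nodes, 4 edges
```

Counts are genes per category with their integer-percent shares; under the
default replicate noise (log-normal σ = 0.2) 98.6 % of planted categories
are recovered exactly, and the recovered shares track the planted mix
(42 % expressed in all, 16 % enriched, 10 % group, 21 % enhanced). With
`replicate_noise_sigma = 0` recovery is exact.

```r
hits <- data.frame(query_id = sprintf("p%03d", 1:285), species = "human",
                   pident = 60, evalue = 1e-10)
overlap_analysis(hits, c(human = 401), cfg)
#>   species n_total n_overlap fraction
#> 1   human     401       285       71
```

285 of 401 milk proteins with passing BLASTP hits against the human milk
proteome is an overlap of 71 %.

See `vignettes/tissueatlas-methods.Rmd` for the model, the generator's
assumptions and the numerical design choices.

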