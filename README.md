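# coopnet

Infer a transcription factor's cooperative partners and functionally
active target genes by integrating ChIP-seq peak evidence with short
time-course expression data, and assemble the resulting TF-centred
regulatory network.

The package is built around the AP-1 use case — a primary TF (e.g. JunD)
whose dimers read the TRE (`TGA[C/G]TCA`) or CRE (`TGACGTCA`) element —
but every stage is generic:

| Stage | Statistic |
|---|---|
| Peak annotation | posterior > 0.9 filter; nearest-TSS assignment within ±20 kb; promoter (±500 bp) binding indicators; library QC by log-count correlation clustering |
| Spaced-motif enrichment | best secondary-motif hit in 50 bp flanks of the oriented primary site, binned by (gap, quadrant); exact binomial upper tail `P[Binom(n, 1/n_bins) ≥ count]`, Bonferroni over bins × motifs |
| Cooperativity | pairs within both-bound vs. single-bound gene classes ranked by expression correlation; the count of both-bound pairs in the top 5% follows `Hypergeom(N, |P_both|, k)` (marginal of the multivariate hypergeometric) |
| Target ranking | Gaussian-process latent-force model `dx/dt = B + S f(t) − D x`, `f ~ GP(0, RBF(l))`, TF mRNA observed as the force; genes ranked by the marginal-likelihood ratio against the no-force null |
| Set enrichment | preranked GSEA (running-sum ES, matched-size random-set null, max-statistic FWER) |
| Differential expression | SAM `d = Δmean/(s + s0)` with Tusher's s0 and permutation FDR (exhaustive for the 4+4 design) |
| Over-representation | direction-separated hypergeometric test of target sets in DE genes |
| Network | partners passing both spacing and GSEA cuts; targets = union of retained sets |

A synthetic-data generator (`scenario_config()`, `make_peak_sequences()`,
`simulate_expression()`, `make_tss_and_binding()`) emulates the assumed
study design — a 0/2/4/8 h, 4-replicate, two-condition time course with a
20-fold attenuated TF in the second condition — with full truth tables, so
the whole pipeline is testable without external data.

## Worked example

```r
library(coopnet)

sc  <- demo_scenario(seed = 1)          # 400 genes, 120 targets, 300 peaks,
                                        # 5 planted partners + 3 decoys
res <- run_all(sc, out_dir = "demo_run", gsea_nperm = 500, verbose = FALSE)

res$network
#> <regulatory_network> 1 dimer(s), 5 partner TF(s), 110 distinct target gene(s), 163 edges

head(as.data.frame(res$gsea), 6)
#>   set_id size        es      nes p_nominal fwer
#> 1     P1   49 0.7512065 5.892517         0    0
#> 2     P2   43 0.7546088 5.619418         0    0
#> 3     P3   20 0.6631579 3.435907         0    0
#> 4     P4   24 0.6746454 3.825301         0    0
#> 5     P5   22 0.6260221 3.370709         0    0
#> 6     X1   17 0.7127937 3.412531         0    0
```

All five planted partner motifs (P1–P5) pass both the spacing and the
GSEA gates and enter the network; the decoys (X1–X3) form target sets of
bound genes too — hence enriched in the ranking — but carry no spacing
signal, so they are excluded.  The 110 recovered targets overlap the 120
planted ones with F1 ≈ 0.89.  `demo_run/` holds every intermediate table
(assignments, spacing, cooperativity screen, scores, GSEA, DE per time
point, over-representation), the network edge list and a stage-count
report; a rerun with the same seed is byte-identical.

Individual stages work standalone on files, e.g.:

```r
peaks <- filter_peaks(read_bed("peaks.bed"))            # posterior > 0.9
asn   <- assign_peaks(peaks, read_tss("tss.tsv"))       # ±20 kb nearest TSS
sp    <- spacing_enrichment(read_fasta("peaks.fasta"), ap1_pwms()$TRE,
                            read_pwm("transfac.dat", "transfac"))
```

and a thin CLI mirrors them
(`Rscript inst/cli/coopnet.R run-all --seed 1 --out demo_run`).

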