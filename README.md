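# rivst — spatial vs seasonal structure in river bacterioplankton communities

`rivst` is an R package for microbial ecologists analysing OTU count
surveys collected over a crossed season-by-site design along a river — for
example a transect running from an urban stretch through farmland into an
estuary, sampled across four seasons.  Its core is a variance-partitioning
test of whether *spatial* community turnover (e.g. the freshwater-to-
brackish salinity gradient) exceeds *seasonal* turnover, together with the
community-ecology toolkit that typically surrounds such an analysis:
Shannon/Chao1 diversity with rarefaction, Dice / Bray–Curtis / unweighted
UniFrac distances, PCoA, environmental PCA and UPGMA clustering, BIOENV
environmental subset selection, ANOSIM, and moving-window analysis of DGGE
fingerprints.  A seeded synthetic-community generator emulating the survey
design makes every stage testable without sequence data.

## The statistic at the core

For taxon *k* with abundance `X_ij(k)` in season *i* and spatial unit *j*
(*n = I·J* samples, taxa z-scored), two one-way ANOVA groupings are
contrasted through their residual sums of squares

    SSE_S(k) = Σ_ij (X_ij(k) − X̄_i(k))²        (seasonal grouping)
    SSE_L(k) = Σ_ij (X_ij(k) − X̄^(g(j))(k))²   (spatial grouping, group
                                                 means pooled over seasons)

and the cross-taxon difference `D = Σ_k {SSE_L(k) − SSE_S(k)}` is
standardized by its exact null moments (derived from a Dirichlet
decomposition of the standardized ANOVA components; see the methods
vignette) to give `T`, referred to N(0, 1).  A low `T` with a small
lower-tail p-value means spatial variation significantly exceeds seasonal
variation.  Asymptotic, Monte-Carlo and spatial-label permutation p-values
are provided.

## Worked example

```r
library(rivst)

sim <- simulateCommunity(syntheticConfig(nTaxa = 300, nSites = 3, seed = 1))
sim
#> RiverExperiment: 300 taxa x 12 samples
#>   seasons: 1, 2, 3, 4
#>   sites:   1, 2, 3
#>   spatial groups: riverine, estuarial
#>   env vars: temperature, salinity, TN, NO3_N, TP, DTP, TOC, chl_a, TSS
#>   tree: attached

spatioTemporalTest(sim)
#> Spatial-vs-seasonal SSE-difference test
#>   n = 12 samples, p = 284 taxa, method = asymptotic
#>   sum(SSE_L - SSE_S) = 170.8497  (null mean 568.0000, null sd 41.8054)
#>   T = -9.5000, one-sided (lower-tail) p-value = 1.05e-21
#>   spatial variation significantly exceeds seasonal variation (p < 0.05)
```

The generator planted a spatial effect twice the seasonal one, and the test
recovers it: the observed `D = 170.8` sits far below its null mean 568
(null mean is `2p` for this design; 16 of the 300 simulated taxa were
constant across samples and dropped by standardization, leaving p = 284),
so spatial variation dominates.  The same object feeds the rest of the
workflow:

```r
d <- communityDistance(sim, "unweighted_unifrac")   # uses the attached tree
anosimTest(d, as.character(sampleDesign(sim)$spatial_group), nPerm = 999, seed = 1)
#> ANOSIM: R = 0.3327, p = 0.0303 (exact enumeration, 495 labelings)

head(bioenvSearch(d, as.data.frame(envTable(sim)), maxSubsetSize = 2), 3)
#>        subset size         r
#> 1 salinity+TP    2 0.6552761
#> 2    TP+chl_a    2 0.5901472
#> 3      TP+DTP    2 0.5361236

head(alphaDiversity(sim, depth = min(colSums(otuCounts(sim))), seed = 1), 3)
#>   sample_id observed_taxa shannon chao1 log_base rarefaction_depth
#> 1     S1.T1           179   2.896 222.0    2.718              7588
#> 2     S2.T1           187   3.409 217.9    2.718              7588
#> 3     S3.T1           222   3.983 245.8    2.718              7588
```

Here ANOSIM on the riverine/estuarial grouping is significant (its exact
p over all 495 labelings of 12 samples), and BIOENV picks salinity-led
variable subsets as the best environmental correlates of community
structure — the pattern the generator builds in.

A command-line front end wraps the same functions
(`inst/exec/rivst.R`; subcommands `simulate`, `diversity`, `distance`,
`pcoa`, `cluster`, `sptest`, `bioenv`, `anosim`, `mwa`):

```sh
Rscript inst/exec/rivst.R simulate --seed 1 --ntaxa 300 --nsites 3 --out simdir
Rscript inst/exec/rivst.R sptest --table simdir/otu_table.tsv \
    --design simdir/design.tsv --partition riverine:1,2+estuarial:3 --out t.tsv
```

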