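# archbeta

Drivers of taxonomic and functional beta diversity in island
assemblages, at more than one spatial scale.

`archbeta` is an R package for community ecologists and biogeographers
who ask *why* assemblages differ among islands and grid cells: because
the environment differs (niche-based processes), because sites are far
apart (dispersal and drift), or because the sites' landmasses have
different histories of connection and isolation (e.g. land-bridge
islands separated by sea straits).  It implements the full workflow for
presence/absence data on a mixed grid-plus-island sampling design:

1. **Beta-diversity partitioning.**  For every site pair, with `a`
   shared species and `b`, `c` species unique to each site, the
   Jaccard-family decomposition

   - β_total = (b + c) / (a + b + c)
   - β_repl  = 2·min(b, c) / (a + b + c)   (replacement / turnover)
   - β_rich  = |b − c| / (a + b + c)        (richness difference)

   so that β_total = β_repl + β_rich exactly.  The functional variant
   replaces species counts with branch lengths of a trait dendrogram
   spanned by each community.
2. **Functional tree.**  Per-trait Gower distances are combined with
   weights optimized so every trait correlates equally with the
   combined distance (the gawdis approach); UPGMA turns the distance
   into an ultrametric dendrogram.
3. **Regionalization.**  UPGMA clustering of sites on β_repl, with a
   concordance score for candidate biogeographical borders (straits).
4. **Spatial predictors.**  Moran's eigenvector maps (MEMs) from four
   neighbor-graph constructions (Delaunay, Gabriel, relative
   neighborhood, minimum spanning tree), with Blanchet-style
   double-stopping forward selection and choice of the spatial
   weighting matrix by adjusted R².
5. **Variation partitioning.**  Distance-based RDA of each beta matrix
   on spatial (S), environmental (E) and historical (H) predictor sets;
   adjusted-R² inclusion–exclusion into seven unique/shared fractions
   plus residual; significance by permuting the rows of the community
   matrix and re-running the whole partition (p = (#{R²_perm ≥ R²_obs}
   + 1)/(nperm + 1)).
6. **Synthetic archipelago generator.**  A latitudinally elongated
   chain of grids and minor islands split by two straits into three
   regions (HKD / HSK / NNS), with scenarios that switch on exactly one
   generative process (`ENV_ONLY`, `SPACE_ONLY`, `HIST_ONLY`) or all of
   them (`MIXED`), so every stage of the pipeline can be validated
   against known ground truth.

Analyses run at two scales — the entire archipelago and the main
islands only (which removes the southern strait from the design) — so
scale-dependent drivers become visible.

## Worked example

```r
library(archbeta)

a  <- simulate_archipelago(scenario_config("MIXED", seed = 42))
bt <- beta_taxonomic(a$community)
print(bt)
#> taxonomic beta diversity over 60 sites
#>   beta_total = 0.84 +/- 0.17
#>   beta_repl = 0.57 +/- 0.26
#>   beta_rich = 0.28 +/- 0.20

ft <- functional_tree(a$traits[colnames(a$community), ])
#> weights: forearm_length=0.224, aspect_ratio=0.238,
#>          relative_wing_loading=0.266, wing_tip_shape=0.271

dend <- cluster_sites(bt$repl)
border_concordance(dend, a$sites, "tokara")
#> [1] 1

sw <- choose_swm(bt$total, a$sites, nperm = 199, seed = 42)
vp <- varpart_permutation(a$community,
                          function(m) beta_taxonomic(m)$total,
                          sw$mems, a$env, a$hist, nperm = 999, seed = 42)
print(vp)
#> Three-set variation partitioning (adjusted R2)
#>  fraction  adj_r2     p
#>   S|(E&H)  0.0063 0.241
#>   E|(S&H)  0.0112 0.219
#>   H|(S&E)  0.0121 0.170
#>     S&E|H  0.0058 0.130
#>     E&H|S -0.0016 0.597
#>     S&H|E  0.0630 0.001
#>     E&S&H  0.0701 0.001
#>   Total S  0.1453 0.001
#>   Total E  0.0856 0.001
#>   Total H  0.1437 0.001
#>  Residual  0.8330    NA
```

Read this as: in the mixed-process world the largest significant
fractions are the three-way overlap `E&S&H` and the space–history
overlap `S&H|E` — the replacement structure sits where environment,
space and history are collinear, exactly as the generator intended; the
clustering places the southern strait border perfectly (concordance 1).
`run_table1()` repeats this for all six responses (taxonomic and
functional × total/repl/rich) at both scales, and `run_pipeline()`
writes the whole artifact bundle (beta CSVs, Newick dendrograms,
cluster maps, MEM report, results table, manifest).  A thin CLI over
the same functions ships in `inst/cli/archbeta.R`.

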