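# spacerlink

Tools for resolving CRISPR-mediated interactions between invasive mobile
genetic elements (iMGEs — plasmids and bacteriophages) and their bacterial
hosts in time-resolved metagenomes.

Bacterial CRISPR arrays store spacers: short fragments cut from invading
elements and kept between near-identical repeats as an immunological memory.
The matching sequence on the element itself is the protospacer. In a dated
series of metagenomic assemblies these sequence links identify *which host
population interacts with which element, and when*: a spacer first detected
after its target element marks an acquisition (spacer integration) event,
and a spacer that outlives or predeceases its element marks loss or
secondary-contact dynamics. `spacerlink` implements the full analysis path:

* **Non-redundant CRISPR elements** — CD-HIT-style greedy identity
  clustering of spacers (90% identity, full length), flanking sequences
  (99% / 97.5% of both) and repeats (80% / 75% of the shorter sequence),
  plus the iterative repeat-parameter calibration ladder.
* **Host anchoring** — flanks matched to genome bins at 95% identity with
  length-dependent coverage (80% for flanks ≥ 100 nt, else 95%), confirmed
  by a same-bin repeat match at 75% / 80%, and spacers propagated from bins
  (MAGs) to representative genomes (rMAGs).
* **Protospacers** — seed-and-extend spacer search over both strands with
  the 95% identity / 95% coverage filter; protospacer-containing contigs
  (PSCCs) defined with repeat- and locus-contig exclusion.
* **Element classification** — consolidation of two plasmid and two phage
  predictor flags into `plasmid` / `phage` / `ambiguous` / `unclassified`,
  then element clustering at 80% / 50% with representative labels retained.
* **Abundance** — spacer counts-per-million with the inclusive 1 c.p.m.
  presence cutoff; length-weighted genome/element abundances; presence by
  detection in either metagenomic or metatranscriptomic data.
* **Events** — the six-category gain/loss classifier on first/last
  detections, integration and deletion lag statistics in weeks, and the
  gain-to-loss crossover timeline.
* **Networks** — global and per-date bipartite plasmid–host and phage–host
  networks with Barber modularity

  Q = (1/m) Σᵢⱼ (Aᵢⱼ − kᵢdⱼ/m) δ(gᵢ, gⱼ),

  NODF nestedness, node degree / betweenness / closeness, and one-mode host
  projections.
* **Community model** — family-level grouping, adjusted pairwise Pearson
  correlations, hierarchical clustering (cut height 4), a randomised
  linear-model search (uniform subsets of ≤ 15 groups ranked by adjusted
  R²), hypergeometric enrichment in the top models, global → reduced model
  selection, and predictor ablation.

A bundled synthetic-community generator (`simulate_community()`) plants all
of this with known ground truth — spacer→host assignments, spacer→element
links, event categories, lags and model coefficients — so the entire
pipeline is testable end to end without any external data.

## Worked example

```r
library(spacerlink)

cfg <- simulation_config(n_timepoints = 25, n_hosts = 6, n_families = 3,
                         n_imges = 68, n_spacers_per_host = 5, seed = 42)
community <- simulate_community(cfg)
result    <- run_pipeline(community, seed = 1)
print(result)
```

```
<pipeline_result>
  clusters: 40 spacers, 8 repeats, 8 flanks
  assignment: 40 spacer-rMAG rows
  protospacers: 44 hits on 26 PSCCs
  plasmid-host network: 6 hosts, 23 elements, 36 edges, Q = 0.500, NODF = 22.3
  phage-host network: 3 hosts, 3 elements, 4 edges, Q = 0.438, NODF = 33.3
  model: reduced adj R2 = 0.9977 (family_01|phage, family_01|plasmid, family_02|phage)
```

The 40 spacer clusters (each host locus carries 5 spacers over 8 loci)
were anchored to their rMAGs, 44 protospacer hits landed on 26 element
contigs, and the plasmid–host network has modularity Q = 0.50 — hosts and
their plasmids fall into clear interaction modules. The reduced linear
model explains the dominant family's abundance (adjusted R² ≈ 0.998) from
the three element groups the generator actually used to construct it.

```r
result$integration_lags
#>     group  n mean_weeks median_weeks sd_weeks
#> 1 overall 21   3.625850     3.142857 2.816669
#> 2 plasmid 19   3.706767     3.142857 2.956784
#> 3   phage  2   2.857143     2.857143 0.000000

recovery <- evaluate_recovery(result, community)
#> link recall 100%, event accuracy 100%
```

Integration lags (time from first element detection to first spacer
detection, in weeks) are reported overall and per element label; on this
noiseless community every planted link and event category is recovered.

A thin command-line wrapper ships in `inst/scripts/spacerlink.R`
(`simulate`, `validate`, `all` subcommands over fixture directories).

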