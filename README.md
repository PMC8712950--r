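# imacomplex

Protein complexes — groups of proteins that physically bind and act as one
molecular machine — show up in protein–protein interaction (PPI) networks
as clusters that are densely connected inside and sparsely connected to
everything else. `imacomplex` detects them in three stages, aimed at
systems-biology researchers who have an interaction network plus ordinary
attribute tables (expression time courses, GO-slim annotations,
subcellular localizations) and candidate clusterings to refine:

1. **Edge weighting.** Every interaction is scored with four evidence
   sources and their mean becomes the edge weight:

   - higher-order common neighbours
     `HCN(v,u) = |N(v) ∩ N(u)|² / (|N(v)| · |N(u)| · |N(v) ∪ N(u)|)`,
   - co-expression, the Pearson correlation rescaled to `[0,1]` via `(r+1)/2`,
   - GO-slim cosine similarity `|T_v ∩ T_u| / √(|T_v| · |T_u|)`,
   - co-localization `|SL(v) ∩ SL(u)|² / (|SL(v)| · |SL(u)|)`.

   Edges with no supporting evidence at all (all four components exactly
   zero) are removed as noise.

2. **Memetic optimization.** Candidate clusterings are evolved to maximize
   the summed cluster fitness

   `FF(C) = cohesiveness(C) + density(C) + AIEW(C) − ABEW(C) + AWM(C)`,

   where `cohesiveness = W_in/(W_in+W_out)`, `density = 2·W_in/(|V_C|·(|V_C|−1))`,
   `AIEW`/`ABEW` are the average inner/border edge weights and
   `AWM = AIEW/(AIEW+ABEW)`. The search combines binary-tournament parent
   selection, fitness-guided recombination, greedy per-cluster local
   optimization (strictly improving add/remove moves, capped at 20 passes,
   reverted if the whole individual does not improve) and roulette-wheel
   population update, with the best-ever individual recorded each
   generation.

3. **Evaluation.** Predictions are scored against a reference catalogue
   with the standard suite: precision/recall/F-measure at overlap score
   `OS(A,B) = |A∩B|²/(|A|·|B|) ≥ 0.2`, coverage rate, clustering-wise
   Sn/PPV/ACC, maximum matching ratio (exact maximum-weight one-to-one
   matching), Jaccard, their total score in `[0,5]`, hypergeometric
   enrichment and co-localization.

A planted-complex benchmark generator (`generate_benchmark()`) produces a
partition graph plus attribute tables correlated with the planted
complexes, so the whole pipeline is testable without any external
download.

## Worked example

Simulate a benchmark (8 planted complexes of 5–8 proteins), weight the
network, derive 24 noisy initial clusterings, run the search, and score
the result against the planted truth:

```r
library(imacomplex)

bench    <- generate_benchmark(synthetic_spec(rng_seed = 1))
weighted <- build_weighted_network(bench$network, bench$attributes)
inits    <- lapply(1:24, function(k)
  perturb_gold(bench$gold, 0.3, bench$network, rng_seed = 1000 + k))

res <- run_ima(weighted, inits, ima_config(rng_seed = 1))
res
#> ima_result: 8 complexes, best fitness 22.295 after 60 generations

evaluate_complexes(res$complexes, bench$gold)
#> eval_report: 8 detected (8 matched)
#>   F=1.0000 CR=1.0000 ACC=1.0000 MMR=1.0000 Jaccard=1.0000 total=5.0000
```

All eight planted complexes are recovered exactly from initial clusterings
in which ~30% of every membership was corrupted: every detected complex
matches a planted one (F-measure, coverage, accuracy, matching ratio and
Jaccard all 1, so the total score is the maximal 5).

Scoring a single cluster shows the five fitness components; on a 5-node
toy network (triangle `a,b,c` with weights 0.8/0.6/0.9, path `c–d–e` with
weights 0.2/0.5):

```r
net <- ppi_network(rbind(c("a","b"), c("a","c"), c("b","c"), c("c","d"), c("d","e")),
                   weights = c(0.8, 0.6, 0.9, 0.2, 0.5))
score_cluster(net, c("a", "b", "c"))
#> $cohesiveness 0.92   $density 0.767  $aiew 0.767
#> $abew 0.2            $awm 0.793      $ff 3.05
```

The cluster keeps 92% of its touching weight inside (`cohesiveness`), its
internal edges average weight 0.767, the single border edge weighs 0.2,
and the combined fitness is 3.05 of a maximal 4.

## Command-line use

A thin launcher over the same functions lives at `inst/cli/ima.R`:

```sh
Rscript inst/cli/ima.R simulate --outdir fixtures --seed 1
Rscript inst/cli/ima.R weight   --edges fixtures/edges.tsv --expr fixtures/expr.tsv \
    --go fixtures/go.tsv --loc fixtures/loc.tsv --out weighted.tsv
Rscript inst/cli/ima.R detect   --weighted weighted.tsv \
    --init fixtures/init1.txt --init fixtures/init2.txt --init fixtures/init3.txt \
    --out complexes.txt --seed 7
Rscript inst/cli/ima.R evaluate --detected complexes.txt --standard fixtures/gold.txt \
    --out report.tsv
```

`detect` also writes a per-generation fitness trace and a JSON manifest
(config echo, seed, input digests) sufficient to reproduce the run byte
for byte.

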