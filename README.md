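# netbench

Benchmarking and consensus construction for collections of molecular
interaction networks.

Dozens of human interactome resources — experimental screens, curated
pathway databases, functional-association compendia — differ widely in
coverage, bias, and usefulness. netbench makes such collections comparable:
it standardizes networks to canonical undirected edge lists over integer
gene identifiers, quantifies representation biases, benchmarks each network
by propagation-based gene-set recovery against degree-matched null models,
builds global and ranked consensus (composite) networks, evaluates
topological interaction prediction, scores externally detected communities,
and aggregates structure-model confidence scores. A synthetic-data module
generates every required input with controlled structure, so the full
pipeline runs without any download.

## The core statistic

For a gene set with $n$ members in a network, a fraction $\rho$ is seeded
and diffused by random walk with restart,

$$F = (1-\alpha)\,F_0\,(I - \alpha A_{norm})^{-1}, \qquad
A_{norm} = D^{-1/2} A D^{-1/2},$$

and the AUPRC for recovering the held-out members from the propagation
ranking is averaged over subsamples. Performance is the robust Z of that
mean AUPRC against the same quantity on degree-preserving rewired networks:

$$Z = \frac{\mathrm{AUPRC}_{obs} - \mathrm{median}(\mathrm{AUPRC}_{null})}
{1.4826 \cdot \mathrm{MAD}(\mathrm{AUPRC}_{null})}$$

with a relative performance gain, per-gene-set size adjustment (residuals
of $Z$ on $\log_{10}|E|$), and centralized ranks
($\mathrm{rank} - (m+1)/2$, summing to zero) for cross-network comparison.
$\rho$ and $\alpha$ default to fitted formulas in network size and gene-set
coverage ($\rho = 0.44 + 0.0093S - 0.0013C$, clamped to $[0.1, 0.8]$;
$\alpha = 0.59 + 0.24\bar\rho - 0.058S + 0.00036\bar{C}$, clamped to
$[0.2, 0.9]$).

Interaction prediction uses the L3 path-count score
($\sum_{U,V} a_{XU}a_{UV}a_{VY}/\sqrt{k_U k_V}$) and MPS (maximum
neighborhood-Jaccard similarity with preferential attachment as secondary
key), both evaluated by precision@k with $k$ equal to the evaluable
test-set size. Composites keep interactions supported by $\ge k$ of all
networks ($G_k$) or $\ge m$ of the top-$k$ ranked networks ($R^k_m$),
including the PCNet2.x construction presets.

## Worked example

```r
library(netbench)
library(dplyr)

# a synthetic interactome with a planted 25-gene module at 10x density
net <- generate_network(500, "powerlaw_configuration", 5000, seed = 7)
pl  <- plant_module(net, 25, 10, seed = 8)

sets <- bind_rows(
  generate_gene_sets(pl$net, mode = "planted"),
  generate_gene_sets(pl$net, n_sets = 2, size_range = c(25, 25),
                     mode = "degree_matched_random", seed = 9)
)

bm <- benchmark_recovery(list(synthetic = pl$net), sets,
                         rho = 0.3, alpha = 0.64,
                         n_samples = 10, n_null = 10, seed = 10,
                         min_present = 5, min_all_networks = 2)
tidy(bm) |> select(gene_set, mean_auprc, null_median, z, gain)
#> # A tibble: 3 × 5
#>   gene_set                mean_auprc null_median       z    gain
#> 1 planted_1                   0.881       0.0598 120.    13.7
#> 2 degree_matched_random_1     0.0567      0.0576  -0.181 -0.0156
#> 3 degree_matched_random_2     0.0565      0.0540   0.798  0.0447

cv <- cross_validate(pl$net, "l3", n_folds = 10, seed = 11)
attr(cv, "mean_p_at_k")
#> [1] 0.174
```

The planted module — genes that genuinely share dense wiring — scores a
robust Z around 120 against its degree-matched null, while degree-matched
random sets center on Z ≈ 0: the benchmark detects real modular signal,
not degree artifacts. L3 recovers ~17% of held-out edges within the top-k
on this small clustered graph, far above the ~2% candidate prevalence.

`autoplot()` methods visualize each result type (`recovery_benchmark`,
`cv_precision`, `density_matrix`), and a command-line front end over the
same functions ships at `inst/cli/bench.R`
(`Rscript bench.R synth|standardize|recover|composite|predict|assembly-score|afscore ...`).

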