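# ratemixr

Hybridization mixes more than ancestry: when two hybridizing species
evolve at different genomic substitution rates, gene flow blends their
molecular clocks. Genomic regions exchanged freely show similar numbers of
derived alleles in both lineages, while regions behind barriers to gene
flow keep accumulating substitutions at species-specific rates. The degree
of mixing is therefore itself a signal of reproductive isolation.

`ratemixr` is an R package for quantifying this *rate-mixing* process in a
two-population system from a handful of resequenced genomes. It provides:

* **Divergence scans** — sliding-window Hudson's F<sub>ST</sub>,
  D<sub>XY</sub> and nucleotide diversity (π) from unphased diploid
  genotypes, with segment averaging and weighted block-jackknife standard
  errors (1 Mb blocks).
* **Ancestry entropy** — two spectral-entropy metrics for unphased diploid
  local-ancestry signals: within-individual entropy S<sub>w</sub> (Shannon
  entropy of the folded power spectrum of the complex ancestry phasor
  z = √p₁ + i√p₂) and between-individual entropy S<sub>b</sub> (entropy of
  the eigen-spectrum of the cohort cross-correlation matrix), plus
  jackknifed correlations of entropy with π / D<sub>XY</sub> /
  F<sub>ST</sub>.
* **Site-pattern asymmetry** — the three-taxon D₃ = (nᴀʙʙ − nʙᴀʙ)/(nᴀʙʙ +
  nʙᴀʙ), the four-taxon ABBA-BABA D₄, and the observed rate ratio
  r = Σ f₁(1−f₂) / Σ (1−f₁)f₂ over outgroup-fixed sites, partitioned by
  background F<sub>ST</sub> thresholds or bins.
* **Coalescent theory** — the equilibrium isolation-with-migration model:
  F<sub>ST</sub> = 1/(1+4Nm), the six-state two-lineage generator, sojourn
  times S₁|₁ = (1+2Nm)/2m and S₂|₁ = N, the rate-mixing curve

      r = (1 + r₀ + Fst·(r₀−1)) / (1 + r₀ − Fst·(r₀−1)),   r₀ = μ₂/μ₁,

  closed-form recurrent-mutation biases of D₃ and D₄, and weighted
  least-squares estimation of r₀ from binned (F<sub>ST</sub>, r) data.
* **Seeded simulators** — the exact two-lineage chain, a multi-window
  landscape with heterogeneous gene flow, a 1-D stepping stone, a
  recurrent-mutation site-pattern generator, and the toy block-ancestry
  model, so every stage of the analysis is testable against theory.

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects
have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate a genomic landscape in which one species evolves 1.837× faster
than its sister and windows fall into four gene-flow classes
(Nm = 0.0625–4, equilibrium F<sub>ST</sub> 0.8–0.06), then recover the
true rate ratio from the binned r–F<sub>ST</sub> relation:

```r
library(ratemixr)

classes <- tibble::tibble(nm = c(0.0625, 0.25, 1, 4), n_windows = 100)
land <- simulate_im_landscape(classes, N = 50, mu1 = 0.2,
                              mu2 = 0.2 * 1.837, n_dip = 4, seed = 401)

pops  <- subset(land$samples, population %in% c("pop1", "pop2"))
scan  <- run_window_stats(land$genotypes, pops, width = 5e4, step = 1e4)
sites <- site_frequencies(land$genotypes,
                          list(p1 = paste0("p2_", 1:4),   # faster lineage first
                               p2 = paste0("p1_", 1:4),
                               o1 = "o1", o2 = "o2"))
dstat <- run_dstats(sites, scan$windows, n_bins = 10)
fit   <- run_rate_fit(dstat$r_by_bin, seed = 1)
fit
#> Equilibrium IM rate-ratio fit
#>   r0_hat = 1.8530 (bootstrap SE 0.0904), 10 bins, weighted RSS 33.7
```

The fitted r₀ = 1.85 recovers the simulated truth 1.837 within 0.9%; at
F<sub>ST</sub> → 1 the curve approaches r₀ (isolated regions keep their
species-specific clocks), at F<sub>ST</sub> → 0 it approaches 1 (rates
fully mixed). `autoplot(fit)` overlays the binned observations on the
fitted curve.

The closed-form pieces are available directly:

```r
im_sojourn(100, 0.01)       # s11 = 150, s21 = 100 (generations)
r_from_fst(0.5, r0 = 2)     # 1.4: half the rate divergence survives
d4_observed(-0.2, p1 = 0.1, p2 = 0.3)   # -0.1: spurious ABBA-BABA signal
```

and the entropy metrics work on any dosage table:

```r
sig <- ancestry_signal(c(rep(1, 32), rep(0.5, 16), rep(0, 16)))
within_entropy(sig)
#> Within-individual spectral entropy: Sw = 1.0666 nats (64 markers)
```

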