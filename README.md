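# aobr

Hydraulic characterisation, COD-removal bookkeeping and community-diversity
analysis for split-feeding anaerobic/oxic baffled reactors (A/OBR).

Baffled bioreactors treat high-strength wastewater in a chain of
compartments. Feeding all influent into the first compartment concentrates
the organic load (and any toxicity) there; *split feeding* divides the flow
among several compartments (e.g. 6:3:1 across compartments 1, 3 and 5) to
spread it. `aobr` is for process engineers and environmental
microbiologists who want to quantify what that does to the reactor: it
simulates tracer tests on a compartmental model, fits the standard
residence-time-distribution (RTD) descriptors, books COD removal per
compartment, and scores microbial diversity from DGGE gel lanes.

## The models

**Compartmental simulator.** Each compartment is an ideal stirred tank;
with feed fractions f₁…fₙ of total flow Q, the local flow is
Qᵢ = Q·Σ_{j≤i} fⱼ and the tracer balance is
Vᵢ dCᵢ/dt = Q_{i−1}C_{i−1} − QᵢCᵢ, integrated with a stiff-capable adaptive
scheme. The impulse enters with the feed (mass split by the feed ratios).

**RTD descriptors.** On dimensionless axes θ = t/HRT, C_θ = C/C₀:

- moments θₘ = ∫θC dθ / ∫C dθ and σ²_θ (trapezoidal, no smoothing);
- measured HRT = θₘ × nominal HRT;
- dead space V_d/V_T = 1 − centroid of the curve truncated at θ = 2;
- tanks-in-series N = 1/σ²_θ;
- dispersion number D/μL = σ²_θ/2 (small-dispersion), or the closed-vessel
  relation σ²_θ = 2d − 2d²(1 − e^(−1/d)) solved by bisection;
- mixing class: plug-flow below D/μL = 0.02, completely-mixed above 0.2,
  intermediate between.

**Diversity.** Shannon–Wiener H′ = −Σ Pᵢ ln Pᵢ over relative band
intensities Pᵢ = Iᵢ/ΣIⱼ per gel lane.

**Performance.** Per-compartment COD removal as the mass rate destroyed,
Qᵢ(C_in,i − C_out,i), relative to the total fed COD mass rate — the
convention under which compartment contributions telescope exactly to the
overall removal. Stage means ± sample SD and classical one-way ANOVA
(significance at P < 0.05) compare feeding strategies.

## Worked example

Simulate a tracer test on the 6:3:1 split-fed six-compartment reactor
(17.88 L, 0.37 L/h, nominal HRT 48.3 h), sampled every 6 h to three HRTs,
then summarise its hydraulics:

```r
library(aobr)
config <- read_run_config(system.file("extdata", "demo_config.yaml",
                                      package = "aobr"))
res <- run_pipeline(config, "aobr_out")
res$rtd
#> RTD summary
#>   mean theta        : 0.9957
#>   variance theta    : 0.2988
#>   measured HRT      : 48.12 h
#>   dead space        : 7.9 %
#>   dispersion number : 0.1494 (small-dispersion)
#>   tanks in series N : 3.35
#>   mixing pattern    : intermediate
```

The split-fed reactor behaves like ~3.4 ideal tanks in series with a
dispersion number of ~0.15 — intermediate between plug flow and complete
mixing — and under 8% hydraulic dead space. A single well-mixed tank run
through the same chain gives N ≈ 1, a completely-mixed label, and ~31%
apparent dead space, so the split feed markedly suppresses back-mixing and
channelling. The pipeline also writes the tracer curve, a COD-removal table
and per-lane diversity:

```r
res$cod_removal
#> COD removal summary (% of fed COD)
#>  compartment removal_pct cumulative_pct
#>            1       31.07          31.07
#>            2       11.62          42.69
#>            3       12.47          55.16
#>            4        7.37          62.53
#>            5       10.76          73.29
#>            6        1.99          75.28
#>   overall removal: 75.28 %
```

Each row is the percentage of the total fed COD destroyed in that
compartment; the cumulative column telescopes to the overall removal.

A thin command-line front end over the same functions ships at
`inst/scripts/aobr.R` (subcommands `simulate`, `rtd`, `diversity`,
`performance`, `demo`).

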