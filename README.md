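# fretnet

Kinetic Monte Carlo simulation of Förster resonance energy transfer (FRET)
in multichromophore light-harvesting assemblies — many donor chromophores
feeding a single acceptor — for photophysicists and modellers who want to
quantify how donor count, donor–donor distances and structural
heterogeneity shape the ensemble transfer efficiency.

## The model in one paragraph

An excitation starting on donor *i* of an *n*-donor assembly moves on a
linear kinetic network: intrinsic decay at rate *k*<sub>D</sub>,
donor→acceptor transfer at *k*<sub>D<sub>i</sub>A</sub>, and donor↔donor
hopping (homo-FRET) at *k*<sub>D<sub>i</sub>D<sub>j</sub></sub>, each
transfer rate given by the ideal-dipole Förster expression
*k* = (3/2) *k*<sub>D</sub> κ² Δ⁻⁶ with Δ the pair distance in units of
the isotropic Förster radius and κ² ∈ [0, 4] the orientation factor. The
per-donor efficiency Φ<sub>FRET</sub> — the probability the acceptor
eventually captures the excitation — is solved exactly as a linear
first-passage problem (no ODE integration on the hot path); the ensemble
efficiency η<sub>FRET</sub> averages Φ over Monte Carlo replicates that
draw distances (Gaussian, relative SD 0.2) and frozen orientation factors
per pair under four heterogeneity regimes, and
Δη<sub>FRET</sub> = η(DnA) − η(D1A) measures the multi-donor enhancement.
Donor geometries are platonic-solid catalogs (D2A…D20A), equidistant
pseudomodels, or six multiporphyrin dendrimers encoded as
distance-distribution models; a stretched-exponential module fits
transient-absorption donor decays
*I*(*t*) = *A* exp(−(*t*/τ<sub>DA</sub>)^β) + *I*<sub>long</sub> and
converts τ<sub>DA</sub> to the experimental efficiency
η = 1 − τ<sub>DA</sub>/τ<sub>D</sub> (τ<sub>D</sub> = 1300 ps).

## Worked example

```r
library(fretnet)

# 20 donors (dodecahedron vertices) with tightly packed donors,
# most-heterogeneous regime: Gaussian distances + static orientations
est <- estimate_eta(build_model("D20A"), mean_delta_da = 0.9,
                    mean_delta_dd = 0.1, case_spec("iv"),
                    n_replicates = 10000, seed = 1)
ref <- estimate_eta(build_model("D1A"), mean_delta_da = 0.9,
                    mean_delta_dd = 1, case_spec("iv"),
                    n_replicates = 10000, seed = 2)
est
#> <eta_estimate> D20A case (iv): eta_FRET = 0.7987 +- 0.00023 (10,000 replicates)
ref
#> <eta_estimate> D1A case (iv): eta_FRET = 0.4963 +- 0.0032 (10,000 replicates)
delta_eta(est, ref)$delta_eta
#> [1] 0.3024
```

At a mean normalized donor–acceptor distance of 0.9 a single pair
transfers ~50% of excitations, while the 20-donor antenna reaches ~80%: a
30-percentage-point enhancement produced purely by structural
heterogeneity plus donor–donor energy migration (in the homogeneous
dynamic limit, case "i", the enhancement is exactly zero).

```r
# modified theoretical prediction for the 2-donor dendrimer
theoretical_eta(build_dendrimer("MD2A"), d_da_mean = 1.65,
                n_replicates = 100000, seed = 1)
#> <eta_estimate> MD2A case (iv): eta_FRET = 0.7405 +- 0.00061 (1e+05 replicates)

# stretched-exponential analysis of a (noisy synthetic) decay trace
tr <- generate_trace(1, 338, 0.73, 0.1, noise_sd = 0.01, seed = 3)
fit_stretched_exponential(tr)
#> <stretched_fit> tau_DA = 341.2 ps, beta = 0.731, A = 0.995, I_long = 0.0995
#>   eta_FRET = 73.8% (tau_D = 1300 ps)
```

The MD2A prediction (74.1%) matches the efficiency derived from the
measured 338 ps time constant (74.0%), and the fit recovers the generating
parameters from a 1%-noise trace to ~1%.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fretnet.R", package = "fretnet"))')
Rscript $CLI models list
Rscript $CLI simulate --model D20A --case iv --delta-da 0.9 --delta-dd 0.1 \
        --replicates 10000 --seed 1 --out sim.csv
Rscript $CLI sweep --models D20A --cases iv --dd-grid 0.1 \
        --replicates 10000 --seed 1 --out sweep.csv
Rscript $CLI dendrimer --d-da 1.65 --replicates 100000 --seed 1 --out table.csv
Rscript $CLI ta-generate --tau 338 --beta 0.73 --i-long 0.1 --noise-sd 0.01 \
        --seed 1 --out trace.csv
Rscript $CLI ta-fit --trace trace.csv --out fit.json
```

Every result file embeds its fully resolved configuration and seed; the
same config + seed reproduces byte-identical output. Exit codes: 0 ok,
1 runtime failure, 2 invalid configuration.

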