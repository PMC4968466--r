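# beepath

Movement of pedestrians in open spaces with points of attraction — an event
fair, an exhibition park, a plaza — analysed and simulated as a
*stop-and-run* process. The package is aimed at movement ecologists and
computational social scientists who work with sparse GPS tracks (one fix
every ~15 s, errors of a few metres) and want to untangle *active*
(internally driven) from *reactive* (context-driven) contributions to
mobility.

## The model

A walker's position follows overdamped Langevin dynamics, discretized in
steps of Δt:

    v(t) = [r(t+Δt) − r(t)] / Δt = (F_R + F_A) / γ

* **Active force** `F_A = sqrt(2β/Δt) · ρ · û(θ)`: Rayleigh-distributed
  modulus (`p(ρ) = ρ exp(−ρ²/2)`) and a heading that turns by Von Mises
  increments with concentration κ/Δt. κ = 0 gives an isotropic random walk
  (RW); κ > 0 a correlated random walk (CRW).
* **Reactive force** `F_R = −∇V`, where the landscape potential is a sum of
  gravitational-like attraction wells, Keplerian `−V₀σ/d` outside a core of
  radius σ and harmonic inside, continuous at the seam. A walker entering an
  unvisited core is *trapped* (all other wells deactivate) until noise
  drives its escape — the two-dimensional Kramers problem, which makes
  in-well residence times exponential — and a well, once left, is
  permanently deactivated for that walker (visit memory).

Presets `RW`, `CRW`, `PRW` (potential-driven RW), `CPRW` and `DSW`
(destination-selection: wells skipped with probability `p_skip`) cover the
standard model ladder. Walkers live random lifetimes, are removed on
lifetime, on visiting every well, or on crossing the arena border, and are
respawned until a total simulated budget is covered.

Sampled tracks (and real GPS tracks read from CSV/GPX, projected to planar
metres) are decomposed into **stops** (maximal runs of fixes whose
successor lies within `R_stop` = 8 m) and **flights** (moving fixes grouped
by the rectangular corridor rule of width `R_flight`). The package fits the
two movement laws of this class of data,

    P(Δt_s > t) = ω exp(−t/τ₁) + (1−ω) exp(−t/τ₂)      (stop durations)
    P(Δr_f > r) = exp(−(r − R_stop)/λ),  r > R_stop     (flight lengths)

computes orientation and velocity statistics, decomposes the work done by
the two forces into active/reactive percentage shares, and rasterizes
population space use with a simplified dynamic Brownian bridge utilization
density (8 m cells, per-bridge sliding-window variance, 95%/99% isopleths).

## Worked example

Simulate a potential-driven population in the default 330 × 145 m arena
with 14 stands, segment it, and fit the movement laws:

```r
library(beepath)
land <- make_default_landscape()                 # 14 wells, sigma = 4 m
cfg  <- sim_config("PRW", total_budget = 60000)  # ~17 h of walkers
sc   <- run_scenario(cfg, land, seed = 42)
sc
#> <PRW scenario: 34 walker(s), 60997 s simulated, 4085 sampled fixes>
#>   terminations: border=4, lifetime=30

segs <- segment_tracks(sc$tracks)
fit_stop_mixture(stop_durations(segs))
#> Two-timescale exponential stop-duration mixture (mle)
#>   omega = 0.7172 (se 0.0655)
#>   tau1  = 682.48 s (se 87.21)
#>   tau2  = 42.12 s (se 12.97)
#>   chi2_red (binned CCDF, dof = bins - 3) = 0.000548;  n = 110

fit_flight_exponential(flight_lengths(segs), r_min = 8)
#> Shifted exponential flight-length fit
#>   lambda = 6.63 m (se 0.64), support starts at r_min = 8 m

work_decomposition(sc)$pct_reactive
#> 9.7
ud <- population_ud(sc$tracks, land$arena)       # cell 8 m, error 4.071 m
ud_mass_near_wells(ud, land)                     # within 2*sigma of a stand
#> 0.85
```

The two fitted stop timescales separate the dwell behaviour: τ₂ ≈ 42 s are
brief reorientation pauses produced by the sampling of diffusive motion,
while τ₁ ≈ 682 s is the Kramers escape time from the attraction wells —
trapped visits at the stands. The utilization density concentrates 85% of
its mass within two core radii of a stand, against ~16% for a pure RW at
the same settings; `report()` renders the standard four panels (UD map,
polar orientation, the two CCDFs with their fits) plus a JSON summary, and
`inst/cli/beepath.R` exposes the whole pipeline (`simulate`, `segment`,
`fit`, `ud`, `report`, ...) from a shell.

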