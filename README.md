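# cavijet

Shock-induced cavitation bubble collapse and polymer damage, at desk scale.

When a pressure wave hits a cavitation bubble, the bubble collapses
asymmetrically and fires a narrow supersonic liquid jet — a *water hammer* —
along the propagation direction. In the brain's extracellular matrix this
mechanism is a candidate for tearing the hyaluronan (HA) filaments that
scaffold the perineuronal nets around neurons. `cavijet` packages the two
levels of that story:

* **An exact analytic damage metric.** The jet's total kinetic energy
  scales as `E_k ∝ D³ p_p` for a bubble of diameter `D` collapsed by a
  post-shock pressure `p_p`; spread over the frontal patch `(D + 2d)²`
  facing a filament a gap `d` away, the energy per frontal area is

  ```
  E_k / (D + 2d)²  =  D³ / (D + 2d)² · p_p      [N/m]
  ```

  with rupture predicted above ~40 N/m. The package evaluates this law in
  SI units, generates the nine-case reference grid (D = 5, 8, 10 nm crossed
  with p_p = 2.65, 7.97, 16.2 GPa at d = 1 nm), classifies cells against
  the threshold, and computes the Young–Laplace pressure `2γ/r` that makes
  nanobubbles intrinsically unstable.

* **A particle-based shock tube.** A 2D Lennard-Jones fluid (reduced
  units), a carved bubble void, and a breakable bead-spring filament; shock
  generation by the momentum-mirror method (uniform piston velocity toward
  a reflective wall, NVE propagation), a cell-list velocity-Verlet engine
  with irreversible bond rupture, and the post-processing used to
  characterise the mechanism: cubic-bin continuum fields, maximum-local-
  velocity jet series, shock-front tracking, axial velocity profiles with
  cross-replicate error bars, and fragment/break-site damage reports.

## Worked example: the analytic damage grid

```r
library(cavijet)
classify_damage(generate_table1(d_nm = 1), threshold = 40)
```

```
Water-hammer kinetic energy per frontal area (N/m), d = 1 nm
              D=5 nm D=8 nm D=10 nm
v_s=3.60 km/s   6.76   13.6    18.4
v_s=5.35 km/s  20.30   40.8    55.3
v_s=7.20 km/s  41.30   82.9   113.0
Cells exceeding 40 N/m (predicted rupture): 5
              D=5 nm D=8 nm D=10 nm
v_s=3.60 km/s  FALSE  FALSE   FALSE
v_s=5.35 km/s  FALSE   TRUE    TRUE
v_s=7.20 km/s   TRUE   TRUE    TRUE
```

Each cell is the kinetic energy the collapse jet delivers per metre of
frontal width; five of the nine simulated bubble scenarios exceed the
40 N/m rupture threshold — larger bubbles and faster shocks break the
filament, the smallest/slowest cases only bend it.

## Worked example: one desk-scale collapse run

```r
cfg <- load_config(list(seed = 1))
rec <- run_scenario(cfg, D = 14, v_p = 3.0, replicate = 1)
rec$summary[, c("v_s", "peak_jet_speed", "broken", "fragment_count", "break_sites")]
```

```
       v_s peak_jet_speed broken fragment_count break_sites
1 15.55868       7.857981   TRUE              3 0.591,0.773
```

The front crosses the pre-bubble window at `v_s ≈ 15.6` (reduced units;
supersonic relative to the piston velocity 3.0), the collapse jet peaks at
about 2.6× the piston speed, and the chain ruptures at two interior sites
into three fragments. The full experiment — bubble diameters {0, 8, 11, 14}
× piston velocities {1.5, 2.25, 3.0} × 3 replicates differing in chain
rotation and velocity seed — runs in a few minutes:

```r
summary <- run_grid(cfg, outdir = "runs")     # resumable, one row per run
aggregate(cbind(peak_jet_speed, broken) ~ D + v_p, summary, mean)
```

No-bubble runs never rupture; the rupture region occupies the large-D /
fast-piston corner of the grid; jet strength grows with bubble diameter at
every piston speed — the qualitative damage map of the scaling law,
reproduced by the particle mechanism.

A thin CLI over the same functions lives at `inst/cli/cavijet.R`
(`scaling-table1`, `run`, `grid`, `analyze` subcommands).

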