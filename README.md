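# gradnav

Enhanced exploration of low-dimensional potential energy surfaces **without
bias potentials**. `gradnav` restarts short, fully unbiased Langevin dynamics
segments from points displaced along the negative gradient of the
*observation density* — the kernel density estimate of everywhere the
simulation has already been. The walker is repeatedly nudged away from
well-sampled regions, escaping deep metastable wells orders of magnitude
faster than plain dynamics, while every individual segment retains the
original, unbiased physics and can be replayed bit-for-bit.

## The method in one paragraph

Simulation proceeds in segments. After a long *outer* segment (500 frames by
default) the accumulated observations define a 2-D Gaussian KDE and a
boundary around the explored region. A short *inner* probe segment (50
frames) is then launched from a restart point displaced from the last frame
by `rate = γ(β + v/k)` along `-∇ρ/‖∇ρ‖`, the direction of steepest decrease
of observation density. If the probe's centroid settles back inside the
boundary (γ = 1) the walker has not escaped: the stride counter `v` is
incremented (`v ← γ(v + 1)`), so successive probes are pushed progressively
farther. If the centroid lands outside everything observed so far *and*
beyond the probe's own launch point (γ = 0), a new well has been found: `v`
resets and a fresh outer segment starts from the escaped probe's last frame.
Because restarts only choose initial conditions — never alter forces — each
segment is an exact, unbiased trajectory, and thermodynamic quantities can
be reconstructed from the frames by Boltzmann inversion.

## What's in the package

| Area | Functions |
|---|---|
| Model surfaces | `muller_surface()`, `modified_muller_surface()`, `potential_surface()`, `gaussian_term()`, `pes_evaluate()`, `pes_gradient()`, `find_minima()`, `assign_basins()` |
| Langevin dynamics | `ld_params()`, `ld_simulate()`, `ld_step()`, `noise_stream()` (compiled BAOAB integrator with counter-based, replayable noise) |
| The navigator | `gradnav_config()`, `gradnav_run()`, `estimate_density()`, `density_gradient()`, `observation_boundary()`, `next_start()`, `replay_gradnav_segment()` |
| Metrics | `dwef()` (deepest-well escape frame), `wells_identified()`, `ssir()`, `run_ssir_experiment()` |
| Reconstruction | `cross_section()`, `reconstruct_profile()`, `boltzmann_invert()` |
| Trajectory banks | `synthesize_bank()`, `bank_from_trajectories()`, `bank_engine()`, `propose_restart()`, `replay_segment()` — drive the navigator over pre-computed collective-variable trajectories instead of live dynamics |
| CLI | `inst/cli/gradnav.R` with subcommands `simulate`, `run`, `dwef`, `ssir`, `reconstruct`, `minima`, `synth-bank`, `replay` |

## Worked example

Escape the deepest well of the Müller potential — a well so deep that plain
Langevin dynamics at the same temperature stays trapped for its entire run:

```r
library(gradnav)

surface <- muller_surface()
wells   <- find_minima(surface)
wells
#> <gn_wellset: 3 minima of 'muller'>
#>        x      y   energy
#>  -0.5549 1.4450 -147.132
#>   0.5727 0.0367  -96.757
#>  -0.0631 0.4698  -79.470

cfg <- gradnav_config(preset = "muller")
cfg
#> <gn_config (muller): beta=0.75 k=100 outer=500 inner=50 budget=10000 boundary=bbox scope=run>

run <- gradnav_run(surface, cfg, wells$minima[1, ], seed = 1)
run
#> <gn_result: 10000 frames in 173 segments (2 escapes), engine=langevin, seed=1>

dwef(run$trajectory, surface, wells)
#> <gn_escape: escaped seed basin 1 at frame 1050 (persistence 50)>

# plain Langevin dynamics with the same physics and budget, for contrast
plain <- ld_simulate(surface, ld_params(), wells$minima[1, ], 10000, seed = 1)
dwef(plain, surface, wells)
#> <gn_escape: not escaped from basin 1 within 10000 frames>

wells_identified(run$trajectory, surface, wells)    # GradNav finds all three
#> [1] 3
wells_identified(plain, surface, wells)             # plain LD finds one
#> [1] 1
```

Every segment of the run is plain, unbiased dynamics and replays exactly:

```r
seg <- replay_gradnav_segment(langevin_engine(surface), run, 2)
identical(unname(seg$points), unname(segment_frames(run, 2)))
#> [1] TRUE
```

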