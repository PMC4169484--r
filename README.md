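# fibresim

Stochastic simulation of plant-fibre length attrition during mixed
enzymatic hydrolysis of lignocellulosic biomass, for researchers studying
liquefaction and particle-size reduction of insoluble feedstocks.

During high-dry-matter hydrolysis with free-fall mixing, impacts break
fibres into shorter pieces — but measured length distributions *stagnate*
partway through the process. `fibresim` implements a minimal mechanical
explanation. A fibre of length *L* is a simply supported beam; as a
transverse impact force *P* sweeps along it, the largest attainable
bending moment at relative position *r = x/L* is the parabolic envelope

    M_max(r) = P · L · r · (1 − r),   max M = P·L/4 at r = 1/2.

The wall fails where the moment reaches the failure moment *M_u*. The
only mechanical parameter is the length-valued ratio *M_u/P* (µm): the
**probable failure region** (PFR) is the central fraction

    e(L) = sqrt(1 − 4·(M_u/P)/L)      (0 if 4·M_u/P ≥ L)

of the fibre. Fibres shorter than `4·M_u/P` can never break — the origin
of stagnation — and under uniformly random impacts a breakable fibre
breaks with probability exactly `e(L)`, creating two fragments no shorter
than `M_u/P`. A step-wise simulator lowers *M_u/P* geometrically
(default 400 µm, ×0.75 per step, floor 40 µm) to emulate enzymatic
weakening; a random-segmentation null model (every fibre split every
step) provides the contrast that fails to stagnate.

## Worked example

```r
library(fibresim)

pop <- synthetic_population(10000, seed = 1)   # razor-cut 3-7 mm + fines
pop
#> Fibre population 'synthetic': 10000 fibres, total length 4.142e+04 mm
#>   length (um): min 39, median 4.51e+03, max 7e+03

bin_length_weighted(pop)
#> Length distribution (length-weighted, 10000 fibres):
#>   [0, 0.25) mm [0.25, 0.5) mm    [0.5, 3) mm      [3, 7] mm
#>          0.002          0.005          0.024          0.969

traj <- run_attrition(pop, config = sim_config(seed = 1))
traj
#> mechanical trajectory: 10000 fibres initially, 71 steps (stopped by min_active)
#>   final: 93 active, 274202 retired

series <- trajectory_series(traj)
detect_stagnation(series, tol = 0.01, patience = 2)
#> [1] 14

series$distributions[[n_steps(traj) + 1]]
#> Length distribution (length-weighted, 274295 fibres):
#>   [0, 0.25) mm [0.25, 0.5) mm    [0.5, 3) mm      [3, 7] mm
#>          0.643          0.186          0.172          0.000
```

Reading the output: the run starts from 10,000 synthetic fibres with 97 %
of the length in the 3–7 mm class. Breakage plus the weakening schedule
shorten the population until fewer than 100 fibres remain breakable
(71 steps here). The binned series stops changing (total-variation
distance < 0.01 for two consecutive steps) from step 14 on — stagnation —
and the terminal distribution still holds 17 % of the length in the
0.5–3 mm class: the population froze because its fibres dropped below the
breakable-length threshold `4·M_u/P`, not because everything was ground
into the shortest class. Running `run_random_segmentation()` on the same
population instead drives the shortest-class share monotonically toward 1
and never stagnates over a comparable window.

A thin command-line interface over these functions (subcommands `synth`,
`simulate`, `nullsim`, `bin`, `compare`, `calibrate`) is installed at
`system.file("cli", "fibresim.R", package = "fibresim")`.

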