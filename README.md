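# nfkbtherm

Temperature control of NF-kB oscillations, as a simulation and analysis
toolbox.

Under TNF-alpha stimulation the transcription factor NF-kB shuttles
periodically between cytoplasm and nucleus (period ~1.5 h at 37 degC),
and the oscillation period falls as temperature rises. `nfkbtherm` is
for systems biologists who want to simulate and quantify that
temperature dependence: it implements the five-variable
NF-kB / IkB / IKK negative-feedback model with every kinetic rate scaled
by temperature, and the downstream analyses that turn trajectories into
biology -- spectral periods, the oscillation onset (Hopf bifurcation),
downstream gene output and its temperature crossover, entrainment by
oscillating temperature, multistability, and the transition to chaos.

## The model

Five concentrations (uM): nuclear NF-kB $N_n$, IkB mRNA $I_m$,
cytoplasmic IkB $I$, and active/inactive IKK ($IKK_a$, $IKK_i$; the
neutral form is $IKK_n = IKK_{tot} - IKK_a - IKK_i$, so the pool is
conserved exactly):

$$\dot N_n = k_{Nin}(N_{tot}-N_n)\tfrac{K_I}{K_I+I}
 - k_{Iin} I \tfrac{N_n}{K_N+N_n}, \quad
\dot I_m = k_t N_n^2 - \gamma_m I_m,$$

$$\dot I = k_{tl} I_m - \alpha\, IKK_a (N_{tot}-N_n)\tfrac{I}{K_I+I},$$

$$\dot{IKK_a} = k_a\,\mathrm{TNF}\, IKK_n - k_i IKK_a,\quad
\dot{IKK_i} = k_i IKK_a - k_p IKK_i \tfrac{k_{A20}}{k_{A20}+A20\cdot \mathrm{TNF}}.$$

Temperature enters through linearised rate laws around 310.15 K:
reaction-limited (Arrhenius) rates scale as $k_0(1 + S\,\Delta T/T_{ref})$
(scale factor $S$ = 20 for the impactful rates $k_{Iin}, k_i, k_p$, 1 for
$k_{tl}, \gamma_m, k_a$) and diffusion-limited rates
($k_{Nin}, k_t, \alpha$) as $k_0(1 + \Delta T/T_{ref})$. Binding
constants and pool sizes are temperature independent.

The package also generates synthetic single-cell nuclear/cytoplasmic
intensity-ratio traces (10-min sampling, protocol-specific initial
peaks, noise and drift) and implements the smoothing / detrending /
power-spectral period-extraction pipeline used on such traces, so the
whole analysis chain is testable end to end.

## Worked example

```r
library(nfkbtherm)

# simulate at 37 degC, constant TNF = 0.5, and extract the period
traj <- simulate_nfkb(forcing = forcing_protocol(tnf_base = 0.5, temp_base = 37),
                      t_end = 10000, transient_cut = 2000)
dominant_period(traj)
#> [1] 108.2191
oscillation_amplitude(traj)
#> [1] 0.2756984

# period against temperature, three TNF levels
sw <- sweep_period_temperature(temperatures = seq(32, 39.5, 0.5),
                               tnf_levels = c(0.2, 0.5, 1.0))
glance(fit_period_slope(sw, tnf = 0.5))$slope_min_per_C
#> [1] -6.971934
autoplot(sw)

# entrainment: 1 degC temperature oscillation at the natural frequency
rotation_number(A_T = 1, f_tmp = 0.01)$W
#> [1] 1

# chaos onset for 40-min temperature forcing
chaos_transition_amplitude(f_tmp = 1/40, seed = 1)$transition_amplitude
#> [1] 2.15625
```

The simulated period at 37 degC (108 min) sits inside the experimentally
reported flow-cohort band (100.8 +/- 10.9 min), and at 32 degC the model
gives 140 min against the reported 160.4 +/- 32.4. A 1 degC temperature
oscillation at 0.01/min phase-locks the oscillator 1:1 (rotation number
exactly 1), and twin-trajectory divergence flags chaos above ~2.2 degC
of forcing amplitude at period 40 min -- within the temperature
variation cells tolerate.

Synthetic traces and their analysis:

```r
co <- generate_cohort(12, "single", temperature = 37, seed = 5)
cohort_period_stats(co)
#> # A tibble: 1 x 4
#>   mean_period_min sd_period_min     n n_excluded
#>             <dbl>         <dbl> <int>      <int>
#> 1            109.        0.0166    12          0
```

The cohort mean matches the generator's ground truth within half a
percent; the tiny spread reflects that the generator does not emulate
cell-to-cell period heterogeneity (see the vignette's limitations).

```r
```

A thin command-line front end over the same functions lives at
`inst/cli/nfkbtherm-cli.R` (subcommands `simulate`, `sweep-temperature`,
`hopf`, `genes`, `staircase`, `plateau`, `multistab`, `chaos`, `synth`,
`analyze`), writing CSV outputs plus a JSON manifest per run.

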