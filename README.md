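# exofatigue

Can a back exosuit increase how much a worker lifts *and* reduce their risk
of a low back disorder at the same time? `exofatigue` answers that question
quantitatively. It implements a fatigue-failure model of cumulative low back
damage with an exo-assistance offset, estimates the lumbar extension moment a
passive elastic exosuit delivers, analyses single-case (AB/ABA) lifting
endurance studies, and maps the breakeven frontier where doing more lifting
cancels the exo's protective effect.

It is aimed at occupational biomechanists, ergonomists and exoskeleton
researchers evaluating back-assist devices for material-handling work.

## The model

Overexertion injuries are treated as mechanical fatigue: each lift consumes a
fraction `1 / N_f` of the tissue's fatigue life, where the number of cycles to
failure follows an S-N (load vs. cycles-to-failure) relationship in the peak
lumbar moment `M`:

```
log10(N_f) = a − b · M
D = n · 1 / N_f(M − M_exo)
```

- `M = m · g · d` — peak load moment: object weight times the maximum
  horizontal object-to-hip distance (Nm),
- `M_exo` — the exo's lumbar extension moment at peak loading (Nm),
  subtracted directly from the load moment,
- `n` — lifting repetitions; cumulative damage `D` is linear in repetitions
  but **exponential** in peak load.

That asymmetry is the core result: a 30 Nm exo cuts per-lift damage by ~68%,
so repetitions must rise far more than proportionally (79% for 15.3 Nm of
assistance, 399% for 42.3 Nm) before the exo's benefit is cancelled — whereas
a few percent more object *weight* can cancel it outright.

The exo moment itself is estimated from elastic-band mechanics: band stretch
→ band force (manufacturer force-displacement curve) → peak extension moment
(force × moment arm about L5/S1), corrected for band hysteresis and
moment/loading timing mismatch, minus the flexion moment of the trunk-worn
device mass.

## Worked example

A nominal task — a 22.7 kg (50 lb) object lifted 1000 times at a 70 cm
object-to-hip distance — with and without a 30 Nm exo:

```r
library(exofatigue)

nominal <- lift_task(mass = 22.7, distance = 0.70, repetitions = 1000)
cumulative_damage(nominal, exo_moment = 30)
#>   load_moment exo_moment effective_moment per_lift_damage cumulative_damage
#> 1        156.         30             126.        0.000133             0.133

productivity_scenarios()
#>   scenario             description cumulative_damage damage_change_pct
#> 1        A    nominal task, no exo             0.415              0.00
#> 2        B      same task with exo             0.133            -68.02
#> 3        C   exo + 20% repetitions             0.159            -61.63
#> 4        D exo + 20% object weight             0.434              4.57
```

The exo alone reduces cumulative damage by 68% (B). Increasing productivity
20% via repetitions keeps a 62% reduction (C); taking the same 20% via
heavier objects erases the benefit entirely (D).

Breakeven analysis — how much more lifting cancels a given assistance level:

```r
breakeven_rep_increase(c(15.3, 42.3))
#> [1]  78.9 399.1   # percent more repetitions
breakeven_weight_increase(15.3, nominal_mass = 45, distance = 0.6)
#> [1] 5.78          # percent more weight (~3 kg) — far less forgiving
```

And a synthetic ABA withdrawal case series with a known ground-truth
endurance effect, analysed end to end:

```r
sets <- simulate_case_series(generator_config(n_participants = 4, seed = 42))
summarize_series(analyze_case_series(sets))
#>   n n_increase n_decrease range_low range_high mean n_reversal_confirmed
#> 1 4          4          0      36.8       71.4 58.8                    4
```

All four simulated participants lifted more with the exo and reverted when it
was removed (`n_reversal_confirmed = 4`), the fingerprint of a genuine
intervention effect in a withdrawal design.

A thin command-line front end (`inst/scripts/exofatigue.R`) exposes `synth`,
`case-series`, `sweep`, `breakeven` and `scenarios` subcommands over the same
functions, writing tidy CSVs.

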