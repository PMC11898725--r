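# napacool

Postharvest cold-storage modelling for Chinese cabbage (*Brassica rapa*
ssp. *pekinensis*), for food-process engineers and postharvest researchers
who need the produce-side thermal chain without a CFD licence: size
classification of heads, respiration heat, transient conduction in the
porous head, surface-coefficient calibration, and a zonal comparison of
cold-room loading strategies. All inputs the chain needs (morphology
tables, sealed-chamber CO₂ traces, cooling curves, environment logs) can be
generated synthetically with the statistical structure of the underlying
measurements, so the whole pipeline runs and is tested without sensor data.

## The models

- **Classification.** K-means (Lloyd, k-means++, best of restarts) on
  z-standardized length circumference, width circumference and weight,
  minimising $\sum_{i=1}^{K}\sum_{x \in S_i} \lVert x - \mu_i \rVert^2$;
  the cluster count is selected by mean silhouette
  $s = (b-a)/\max(a,b)$ with the SSE elbow as a diagnostic.
- **Respiration.** Molar rate from sealed-chamber traces by the ideal gas
  law, $R_{CO_2} = P V \dot{x} / (M R_u \bar{T})$; heat by the power law
  $Q(T) = \frac{10.7 f}{3600}(9T/5+32)^g$ W/kg
  ($f = 6.0803\times10^{-4}$, $g = 2.6183$); volumetric source
  $\dot q = Q\,m/V_{basket}$.
- **Conduction.** Volume-averaged porous-sphere energy equation under
  local thermal equilibrium,
  $C(T)\,\partial_t T = r^{-2}\partial_r(r^2 k_{eff}\partial_r T) + \dot q(T)$,
  with symmetry at the centre and Robin exchange
  $-k_{eff}\partial_r T = h(T_s - T_\infty)$ at $r = R$;
  backward-Euler finite volumes in C++, verified against the analytic
  eigenfunction series ($1 - \lambda\cot\lambda = Bi$) and the steady
  generation profile $T_\infty + \dot qR/3h + \dot q(R^2-r^2)/6k_{eff}$.
- **Calibration.** $h$ by RMSE grid scan of the forward model against
  observed cooling curves (grid 150–400 W/m²K, step 10).
- **Loading strategies.** Lumped blocks
  $mC_p \dot{T_b} = h_{eff}A(T_{zone}-T_b) + Q(T_b)m$ with per-block
  $h_{eff} = h_{ref}\cdot\mathrm{fraction}^{0.8}$, comparing fully packed,
  50:50 batch, and batch-with-repositioned-coolers layouts on gradient
  (4.25 °C) and equilibrium (4.1 °C ± 0.05) times.

## Worked example

```r
library(napacool)

rec <- gen_morphology(54, seed = 1)          # 162 synthetic heads
select_k(rec, 2:5, seed = 1)$silhouette
#>   k silhouette
#> 1 2  0.6165315
#> 2 3  0.7172740      <- k = 3 wins
#> 3 4  0.6054788
#> 4 5  0.4695111
kmeans_fit(rec, 3, seed = 1)
#> K-means cluster model: k = 3  SSE = 31.8197
#> Cluster sizes (by class): 54 / 54 / 54
#> Class mean weights (g): 1505.53, 2134.38, 2830.13
```

The three recovered mean weights sit within a few grams of the generating
class means (1503.20, 2132.48, 2826.37 g). The thermal side:

```r
tr <- gen_sealed_trace(2, T_chamber = 5, noise_sd = 5, seed = 12)
estimate_respiration_rate(tr)        # ~2.32e-4 mol CO2 / kg h
respiration_heat(5)                  # 0.0302 W/kg at 5 degC

fld <- solve_transient(class_sphere(2), thermal_properties(2),
                       boundary_conditions(h = 270, T_inf = 4.1, T0 = 20),
                       heat_source_respiration(density = 675.70),
                       t_end = 20 * 3600)
tail(as.data.frame(fld), 1)          # volume average ~6.3 degC at 20 h:
                                     # metabolic heat holds the head above
                                     # the 4.1 degC air

compare_scenarios(c("repositioned_batch", "batch_50_50", "fully_packed"))
#>               layout gradient_time_h equilibrium_time_h
#> 1 repositioned_batch           0.666               6.05
#> 2        batch_50_50           0.709               6.45
#> 3       fully_packed           4.413               7.95
```

Staged loading with repositioned coolers equilibrates first, fully packed
last — the ordering that motivates batch filling (desk-scale clock times;
room-scale times depend on the room's aerodynamics).

The numbered scripts under `analysis/` run these stages end to end and
write their tables to `results/`.

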