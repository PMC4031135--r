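# cryoiif

Coupled modelling of osmotic cell dehydration and nucleation-limited
intracellular ice formation (IIF) during freezing, for cryobiologists
working on cryopreservation and cryotherapy protocol design.

When cells are cooled without cryoprotectants, extracellular ice
concentrates the medium and cells dehydrate through their membrane while
the supercooled cytoplasm may nucleate ice. `cryoiif` implements:

* the Mazur-type water-transport ODE for cell volume along a linear
  cooling ramp,

  dV/dT = (L_p A R T)/(B v_w) · [ln x_w − (ΔH_f/R)(1/T_R − 1/T)],
  with Arrhenius membrane permeability
  L_p = L_pg exp[−(E_Lp/R)(1/T − 1/T_R)];

* Toner-type heterogeneous nucleation rates for surface-catalyzed (SCN)
  and volume-catalyzed (VCN) nucleation,

  I(T) = Ω₀ (η₀/η(T)) exp[−κ₀ (T_f/T_f0)⁴ / ((T_f − T)² T³)],

  including a **critical-volume gate**: the rate is set to zero once the
  cell dehydrates below a mechanism-specific volume V_f. Gating lets
  predicted probability-of-ice-formation (PIF) curves plateau below 1, as
  observed in populations whose maximum PIF is well under 100%, where the
  ungated model is pushed towards certainty at deep subzero temperatures;

* PIF curves PIF(T) = 1 − exp[−(1/B)∫ I·S dT′] (S = membrane area for
  SCN, cell volume for VCN) and their independent-competition total;

* stochastic single-cell IIF event simulation (inhomogeneous-hazard
  inverse-CDF sampling with competing-risk mechanism attribution) and
  empirical-PIF tallies;

* two-stage pooled nonlinear least-squares estimation: membrane
  parameters (L_pg, E_Lp, V_b) from multi-rate normalized-volume tables,
  then nucleation parameters (Ω₀, κ₀, V_f per mechanism) from PIF tables
  with the stage-1 trajectories frozen — with seeded screened-multistart
  bounded Levenberg–Marquardt under the hood.

See the methods vignette (`vignettes/iif-modelling.Rmd`) for the model,
its assumptions, and every numerical and design choice.

## Worked example

Simulate dehydration and PIF for a HeLa-like cell (radius 7.51 um,
L_pg = 0.1166 um min⁻¹ atm⁻¹, E_Lp = 11.9236 kcal mol⁻¹) cooled at
60 °C/min to −50 °C:

```r
library(cryoiif)

V0   <- 4/3 * pi * 7.51^3                       # 1774.2 um^3
cell <- cell_params(V0 = V0, Vb = 0.25 * V0,
                    Lpg = 0.1166, ELp = 11.9236)

# membrane permeability collapse that rate-limits dehydration at depth
water_permeability(233.15, cell) / water_permeability(272.65, cell)
#> [1] 0.02403155     # L_p at -40 C is 2.4% of its value at -0.5 C

traj <- integrate_water_transport(cooling_protocol(B = 60), cell)
traj
#> Dehydration trajectory: B = 60 K/min, -0.50 -> -50.00 degC, 991 points
#>   terminal normalized volume 0.2936

scn <- nucleation_params("SCN", Omega0 = 5e8,  kappa0 = 4.3e9, Vf = 0.45 * V0)
vcn <- nucleation_params("VCN", Omega0 = 5e15, kappa0 = 5e10,  Vf = 0.36 * V0)
pif_curve(traj, scn, vcn)
#> PIF curve: 991 points, -0.50 -> -50.00 degC; terminal PIF 0.4574 (SCN 0.4279, VCN 0.0516)
```

The cell shrinks to 29% of its isotonic volume by −50 °C; total PIF rises
to 0.457 and then plateaus — SCN hazard stops when the cell passes
0.45 V0 (near −24 °C), VCN when it passes 0.36 V0 (near −32 °C) — so the
model predicts that ~54% of this population never freezes internally, no
matter how deep the cooling goes.

The full synthetic loop — generate observation tables from known ground
truth, then re-estimate everything two-stage:

```r
gt  <- ground_truth(seed = 42)
rec <- recover_parameters(gt, seed = 1)
rec
#> Two-stage parameter recovery
#>   Lpg: true 0.1166, fitted 0.1168 (rel err 0.17%)
#>   ELp: true 11.9236, fitted 11.9412 (rel err 0.15%)
#>   Vf_SCN/V0: true 0.450, fitted 0.451 (abs err 0.001)
#>   Vf_VCN/V0: true 0.360, fitted 0.340 (abs err 0.020)
```

A thin command-line interface (`exec/cryoiif`) exposes the same pipeline
over CSV tables: `simulate-volume`, `predict-pif`, `fit-volume`,
`fit-pif`, `make-fixtures` and `recover`, each taking a YAML config (see
`inst/extdata/default_config.yaml`).

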