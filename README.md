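# epimech

Biomechanics of the growing epiphysis: does the secondary ossification
center (SOC) — the bony nucleus that forms inside the cartilaginous bone end
of mammals — mechanically shield the fragile hypertrophic chondrocytes of
the growth plate? `epimech` packages the quantitative tools needed to study
that question:

* a **parametric plane-strain finite-element model** of the epiphysis
  (semicircular cartilage head on a trapezoidal shaft, five labeled
  subdomains) with swappable stiff regions — a semi-elliptical SOC, or
  ossified protrusion fingers as found in stem tetrapods and archosaurs —
  solved with total-Lagrangian Saint Venant–Kirchhoff kinematics
  (E = ½(FᵀF − I), S = λ tr(E) I + 2μ E) under a quadratic 45° sector
  pressure that follows the deforming surface;
* **stress post-processing** into second Piola–Kirchhoff tensors and the
  three scalar measures used to read such models: hydrostatic stress
  σ\_h = tr(S)/3, lowest principal stress s₃, and octahedral shear stress
  τ\_oct = √(2J₂/3), with growth-plate-band zone summaries;
* **ex-vivo mechanical-test analysis**: contact-referenced deformation,
  stiffness of the initial linear portion, oval-area stress and
  height-normalised strain, 0.2 % offset yield strength, and
  pressure-matched load computation (F = p · π d₁d₂/4);
* **Hertzian indentation fitting** for AFM and nanoindenter force–distance
  curves, F = (4/3)·E/(1−ν²)·√R·δ^{3/2}, with joint contact-point/modulus
  estimation and per-cell/per-animal aggregation;
* **allometric scaling**: with stylopod diameter D = k·BM^a, growth-plate
  pressure scales as BM^{1−2a} — the calculations behind the observation
  that a thousandfold body-mass increase raises growth-plate pressure only
  4.3–6.6-fold;
* **synthetic-data generators** with embedded ground truth for all of the
  above, so the full pipeline is testable without instrument recordings.

## Worked example

Allometry and indentation, straight from the console:

```r
library(epimech)

law <- allometric_law("combined")          # D = 1.26 BM^0.364
stylopod_diameter(70, law)
#> [1] 5.915429
round(pressure_fold(1000, 0.3944), 1)      # insectivores/rodents exponent
#> [1] 4.3
round(pressure_fold(1000, 0.364), 1)       # combined-tetrapod exponent
#> [1] 6.5

# five synthetic AFM curves from 10 kPa tissue, 2 % force noise, then refit
curves <- gen_force_curves(E_true = 10, z0 = 0.3, noise_sd = 0.02,
                           n = 5, seed = 42)
fits <- lapply(curves, fit_hertz)
fits[[1]]
#> hertz_fit: E = 9.96 kPa (nu = 0.5), z0 = 0.299 um, rms 0.348 nN
aggregate_fits(fits)
#>       mean         sd n
#> 1 9.957073 0.08820152 5
```

A thousandfold heavier animal thus sees only a ~4–7× higher growth-plate
pressure (not 1000×), and the Hertz fit recovers the generator's 10 kPa
modulus to within noise.

A synthetic mechanical test (true stiffness 30 N/mm, yield stress 0.4 MPa,
1 % position noise):

```r
dims <- epiphysis_dims(height = 2, top_d1 = 4, top_d2 = 3,
                       side_d1 = 3.5, side_d2 = 2.5)
rec <- gen_load_deformation(stiffness_true = 30, yield_stress_true = 0.4,
                            dims = dims, noise_sd = 0.01, seed = 7)
mech_summary(rec, dims, "vertical")
#>   stiffness_N_mm fit_start fit_end    fit_r2 yield_MPa yield_strain
#> 1       31.02296         1     377 0.9575461 0.4068305   0.06520789
load_for_pressure(0.023, dims)   # pressure-matched load, N
#> [1] 0.2167699
```

A finite-element comparison (physiological 0.3 MPa vertical load, coarse
mesh for illustration):

```r
cfg <- list(variants = c("with_soc", "no_soc"),
            mesh = list(target_edge_length = 2),
            load_cases = list(list(sector_center_angle = 90,
                                   peak_pressure = 0.3)),
            out_dir = tempfile())
bundle <- run_simulation(cfg, quiet = TRUE)
subset(bundle$summary, measure == "tau_oct",
       select = c(variant, peak, mean, deflection_mm))
#>    variant        peak        mean deflection_mm
#> 3 with_soc 0.009262570 0.006734505     0.1469535
#> 6   no_soc 0.009441163 0.006022662     0.4052773
```

The band octahedral-shear summary and the apex deflection per variant: the
with-SOC model deflects roughly a third as much as the SOC-free one. Meshes, displacement and stress fields go to legacy ASCII VTK
files in `out_dir` for viewing in ParaView.

A thin command-line wrapper with subcommands `simulate`, `mech-test`,
`fit-hertz`, `allometry` and `make-fixtures` ships in `inst/cli/epimech`.

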