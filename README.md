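# ecmonitor

Automated analysis of bacteria colonizing confined, non-fluidic
microsystems with embedded gold microelectrodes — for microbiologists and
bio-electrochemists who monitor growth simultaneously through a microscope
and a potentiostat.

When *E. coli* grow along a 60-µm microchannel and reach the
electrode-enabled active area, the expanding cell mass forms a conductive,
electrochemically active bridge between the microelectrodes. `ecmonitor`
detects and characterizes that *colonization event* from three data
streams:

* **time-lapse micrographs** — channel border detection (Hough transform),
  rectification, percentile texture segmentation, and growth-phase
  extraction (lag / exponential / stationary, the ~30% border offset, the
  65-min per-segment colonization);
* **cyclic voltammetry (CV)** — per-sweep current variance, min–max
  normalization, and single-changepoint detection by the two-segment
  log-variance cost
  `J(k) = (k−1)·log var(V₁…V_{k−1}) + (n−k+1)·log var(V_k…V_n)`,
  plus redox-peak identification (primary peaks from the per-potential
  variance, secondary peaks from variance-derivative ratios, 1-D
  clustering) and peak change ratios
  `R = mean(x_k…x_n) / mean(x₁…x_{k−1})`;
* **impedance spectroscopy (EIS)** — |Z| and phase variance changepoints,
  and complex nonlinear least-squares fitting of the simplified equivalent
  circuit `Z(ω) = R_elec + [jωC_belec + (R_b + 1/(Q_i(jω)^n_i))⁻¹]⁻¹`
  (series resistance, interface capacitance, bacterial charge-transfer
  resistance, constant phase element).

A rule-based monitor combines the three channels into a
colonization / control / damage-after-colonization / early-damage call.
Since no raw data of this kind are deposited anywhere, the package also
ships seeded synthetic generators for all three streams with ground truth
attached — every analysis stage is tested as a recovery problem against
them. The methods vignette (`vignettes/methods.Rmd`) documents the models,
defaults and limitations.

## Worked example

```r
library(ecmonitor)

# a colonized experiment: CV + EIS sessions and an image stack
cv <- generate_cv_session(cv_scenario(seed = 42), total_duration_s = 35 * 3600)
vp <- cv_variance_series(cv)
sprintf("event detected at %.1f h", vp$changepoint$time_s / 3600)
#> "event detected at 8.5 h"        (injected at 8.0 h)

groups <- split_by_changepoint(cv, vp$changepoint$time_s)
ratios <- peak_change_ratio(groups$before, groups$after)
#> anodic ratio 8.11 at +140.0 mV; cathodic ratio 5.93 at -200.0 mV

eis <- generate_eis_session(eis_scenario(seed = 43))
vs <- eis_variance_series(eis)
vs$impedance$changepoint$change_ratio
#> 0.156                            (the post/pre normalized-variance ratio)

fit <- fit_circuit(epoch_mean_spectrum(eis, vs$impedance$changepoint$time_s,
                                       before = TRUE))
#> before-event fit: R_elec 15.97 kOhm, C_belec 0.919 nF, R_b 5.72 MOhm

classify_event(vp, vs$impedance, vs$phase)$label
#> "colonization"

curve <- analyze_stack(generate_image_stack(imaging_scenario(seed = 44)))$curve
#> image offset 30.0%, colonization completed in 67 min
```

The numbers mean: the CV current variance steps one measurement interval
after the injected event; the anodic/cathodic peak currents grow ~8× and
~6× at the expected peak potentials (grid-limited); the impedance variance
drops to ~0.16 of its pre-event level; the fitted before-event circuit
reproduces the open, bacteria-free interface (megaohm charge-transfer
resistance, sub-nanofarad interface capacitance); and the image pipeline
reads the border offset and the front-traversal time off the micrographs.

A thin command-line wrapper is installed under `inst/cli/ecmonitor`
(subcommands `simulate`, `analyze-images`, `analyze-cv`, `analyze-eis`,
`fit-circuit`, `classify`, `report`); `ecmonitor_cli()` is the same entry
point from R.

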