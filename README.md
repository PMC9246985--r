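# cestnet

Autonomous analysis of amide-proton **anti-phase CEST** NMR profiles in R.

Proteins often exchange between a visible ground conformation and sparsely
populated excited states. Chemical exchange saturation transfer (CEST)
detects those invisible states: a weak B1 field is stepped across offsets,
and saturation transferred through exchange carves "dips" into the
normalized intensity profile I/I0 at the chemical shifts of the exchanging
species. Amide-proton CEST is recorded on the *anti-phase* state 2HzNz (to
suppress 1H-1H cross-relaxation in perdeuterated samples), so every state
imprints a doublet split by the one-bond scalar coupling 1J_HN of about
-93 Hz instead of a single dip — profiles are broad, overlapped, and hard
to read by eye.

cestnet re-implements an autonomous two-network analysis of such profiles,
validated end to end on synthetic data:

- **Spin-dynamics simulator** (`simulate_ap_profile()`,
  `simulate_ip_profile()`): Liouvillian evolution of two-site and forked
  three-site exchange (E1 ⇌ G ⇌ E2) including the INEPT element, with the
  real-eigenvalue dephasing propagator `V_re exp(-T_ex D_re) V_re^-1`
  (eigenvalues kept when |Im λ| ≤ 1e-3 s^-1), which reproduces
  B1-inhomogeneity averaging without explicit distributions. Compiled
  (RcppArmadillo) and reference R paths agree to machine precision.
- **Fixed-size packing** (`pack_profile()`): dip transform
  `max(I/I0) - I/I0`, real FFT to the `floor(N/2)+1` non-redundant complex
  coefficients, zero-fill to 65 complex points, two 130-vectors (values +
  time axis) as network input; inverse real FFT upsamples to 128 offsets.
- **Transformation network** (`build_dnn_tr()`, `train_dnn_tr()`,
  `transform_profile()`): dilated gated convolutions with residual
  connections that *virtually decouple* anti-phase profiles into in-phase
  profiles sampled at 128 offsets.
- **Shift network** (`build_dnn_cs()`, `train_dnn_cs()`,
  `predict_shifts()`): densely connected 1-D conv features with a
  windowed soft-argmax locator head, emitting the 3 × 2 output — three
  normalized shifts f_ω and three sigmoidal confidences c, all in (0,1).
  Shifts map affinely into the offset window;
  uncertainties follow `σ_pred = k (1/c_pred - 1)` with
  `k = span × sqrt(L_freq)` calibrated after training. The loss is the
  heteroscedastic `L_freq = Σ (f_pred - f_true)² / σ_pred²` plus
  `L_uncer = 1e-4 Σ 1_i sqrt(σ_pred,i)`.
- **Pipeline and validation** (`analyze_profile()`, `least_squares_fit()`,
  `evaluate_calibration()`, `consistency_analysis()`): one-shot analysis,
  a Levenberg-Marquardt fitting back-end over the same forward model, and
  evaluators for uncertainty calibration (error-vs-confidence histograms,
  68.3/95.4/99.7% envelopes, coverage at c_pred ≥ 0.4) and full-vs-half
  data or two-B1 consistency.

All networks train on the fly from the built-in synthetic-data generator
(`sample_scenario()`, `generate_tr_examples()`), which draws the study
conditions: five static fields from 14.1 to 23.5 T, B1 of 15-50 Hz, 50-128
points over a 3.4 ppm window, T_ex = 0.4 s, τ_M of 3-20 ns, kex of
10-300 s^-1, excited populations of 1-15%, three-site topology with
probability 25%, and Gaussian noise of 0.01 of each profile's maximum
(0.001-0.04 for the shift-network regime).

## Worked example

```r
library(cestnet)

# a ground state at 8.0 ppm exchanging with a 6% excited state at 8.9 ppm
sc  <- exchange_scenario(populations = c(0.94, 0.06, 0), kex = c(150, 0),
                         shifts = c(8.0, 8.9, 0), tau_m = 8, j_hn = -93)
cfg <- acquisition_config(b0 = 18.8, b1 = 30, offset_min = 6.6,
                          offset_span = 3.4, n_offsets = 90, tex = 0.4)
ap  <- simulate_ap_profile(sc, cfg)    # anti-phase doublet dips
autoplot(ap)

# classical route: least-squares fit of the forward model
fit <- least_squares_fit(ap, sc)
tidy(fit)
#> # A tibble: 5 x 3
#>   term     estimate std_error
#>   <chr>       <dbl>     <dbl>
#> 1 shift_G      8            0
#> 2 shift_E1     8.9          0
#> 3 kex_GE1    150            0
#> 4 p_E1         0.06         0
#> 5 dr2_E1       0            0
```

On this noiseless profile, started at the true parameters, the fitter
confirms the exact solution (shifts 8.0 and 8.9 ppm, zero residual) — the
forward model is self-consistent; with noisy data and perturbed starts it
recovers shifts to ~1e-3 ppm with covariance-based uncertainties.
With trained networks (see `train_dnn_tr()` / `train_dnn_cs()`, or the
`inst/cli/cestnet.R` command line), `analyze_profile(ap, tr, cs)` returns
the same information in one shot, with per-state confidences and
calibrated σ in ppm, and `evaluate_calibration()` quantifies how often the
true shift falls within ±σ_pred.

The closed-form calibration constant at the conditions above:

```r
calibrate_k(3.4, 7.3e-5)
#> [1] 0.02904961   # ppm; prints as 0.029 at two significant figures
```

## Command line

```sh
Rscript inst/cli/cestnet.R simulate --config scenario.cfg --phase ap --out ap.txt
Rscript inst/cli/cestnet.R train-tr --n 12000 --epochs 30 --seed 1 --out tr.rds
Rscript inst/cli/cestnet.R train-cs --tr tr.rds --n 12000 --seed 2 --out cs.rds
Rscript inst/cli/cestnet.R analyze --tr tr.rds --cs cs.rds --in 'profiles/*.txt' --out results.csv
```

Profile files are plain text (`offset_ppm intensity`, `# key: value`
headers for B0/B1/T_ex metadata; Hz offsets supported with a units flag).

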