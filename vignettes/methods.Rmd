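---
title: "Models and methods behind cestnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cestnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cestnet simulates amide-proton anti-phase CEST (chemical exchange
saturation transfer) NMR profiles for slowly exchanging protein
conformations and analyses them autonomously with a pair of trained
networks: a transformation network that virtually decouples anti-phase
profiles into in-phase profiles, and a shift network that reads off the
chemical shifts of the exchanging states together with calibrated
uncertainties. A least-squares fitter over the same forward model provides
the classical analysis route, and calibration/consistency evaluators
quantify how trustworthy the network output is. This vignette records the
models, the conventions, and the design decisions a maintainer would want
to know.

## The spin model

Each residue is modelled as an amide ^1^H coupled to its ^15^N
(^1^J~HN~ of −91 to −95 Hz) in a molecule whose backbone exchanges between
a ground state G and up to two sparsely populated states in the forked
topology E~1~ ⇌ G ⇌ E~2~. Per branch, the exchange rate is
`kex = k_forward + k_backward` with detailed balance
`k_G→Ei · p_G = k_Ei→G · p_Ei`; with that convention the stationary
distribution of the rate matrix equals the input populations and the
two-site case reduces to the familiar `k_G→E = kex · p_E`.

During the CEST element the magnetization evolves under a real Liouvillian
`L` with `M(t) = exp(−L t) M(0)`. For the anti-phase experiment the basis
holds `{Hx, Hy, Hz}` in each of the two ^15^N longitudinal manifolds
(α/β) for every exchange state (a 6·n~states~-dimensional space). The α
manifold precesses at `Ω + πJ`, the β manifold at `Ω − πJ`; interchange of
the manifolds proceeds at the ^15^N longitudinal relaxation rate `R1_N`
(spin flips of the coupled nitrogen), and chemical exchange couples
corresponding operators across states. The in-phase (J = 0) system drops
the manifold structure (3·n~states~ dimensions). The ^15^N spin is treated
as a classical two-level bath for the proton — no nitrogen coherences are
needed for CW saturation of longitudinal proton order, which keeps the
matrices small and the per-offset eigendecompositions cheap.

Relaxation rates are computed from the rotational correlation time τ~M~
under rigid isotropic tumbling: spectral density
`J(ω) = (2/5) τ / (1 + (ωτ)²)`, ^1^H–^15^N dipolar coupling with
r~HN~ = 1.02 Å for the proton, and dipolar plus ^15^N CSA (−164 ppm) for
the nitrogen. Remote protons are neglected — the samples this experiment
targets are perdeuterated, which is also why the magnetization is kept
anti-phase during the exchange period in the first place. A
microsecond-exchange contribution `R_ex` adds to the R~2~ of *every*
state (implemented as an additive R~2~ term only), and the excited states
carry additional R~2~ offsets `dR2_Ei`. These standard expressions are the
package's own documented choice of relaxation model.

### The dephasing propagator

Experimental CEST profiles are smooth because the B~1~ field is
inhomogeneous: coherent nutation dephases across the sample. Instead of
averaging the full propagator over a B~1~ distribution, the simulator
projects the Liouvillian onto its real-eigenvalue subspace: after
`L V = V D`, the propagator is `V_re exp(−t D_re) V_re^{-1}`, keeping only
eigenvalues with `|Im λ| ≤ 10⁻³` s⁻¹. Oscillatory components are thereby
removed entirely, which is exactly what ensemble dephasing does to them.
The test suite verifies this equivalence: profiles computed with the
projector agree with brute-force Gaussian B~1~ averaging (10% fractional
width, 21-point quadrature, full complex matrix exponentials) to well
under 1% RMS over random two-site systems. The projector is also a
semigroup on its subspace (`P(t₁)P(t₂) = P(t₁+t₂)`), which the suite
asserts to 10⁻⁸.

Degenerate Liouvillians (for instance exactly coincident shifts of two
states) are a measure-zero input set; the simulator perturbs the offset by
10⁻⁶ ppm and warns rather than failing.

### The anti-phase experiment and its doublet convention

The INEPT element (delay `1/(4|J|)` — simultaneous 180°(H,N) — delay
`1/(4|J|)`) converts in-phase transverse magnetization into the anti-phase
state, represented as `Hz^α = +1, Hz^β = −1` per state, weighted by the
populations. In the default `inept = "explicit"` mode the element is
evolved under the full Liouvillian (with B~1~ = 0), so relaxation and
exchange attenuate the prepared state by the appropriate per-state factor;
`inept = "ideal"` skips the losses. The chemical shift is refocused by the
midpoint 180° pulse, so the carrier position during the element is
immaterial beyond second-order relaxation effects.

The detected signal is the ground-state anti-phase difference
`⟨Hz^α⟩ − ⟨Hz^β⟩` at the end of T~ex~, normalized by the same quantity
propagated with B~1~ = 0 (the analogue of the far-off-resonance reference
experiment). A consequence worth stating explicitly, because descriptions
of anti-phase CEST can suggest otherwise: with this preparation and
detection the propagation is a contraction, so `I/I₀` stays within
[0, 1] and each exchanging state imprints a doublet of two *same-signed*
dips separated by |J~HN~|. At the weak-B~1~ limit the two minima sit at
±J/2 around the state's shift (the suite asserts the separation against a
peak-picking oracle); at the 15–50 Hz fields used for training the two
components broaden and partially merge, which is precisely what makes
these profiles hard to read by eye and motivates the learned decoupling.
With J = 0 and an ideal INEPT the α/β manifolds are degenerate and the
anti-phase difference obeys the in-phase equation, so the simulator
delegates to the in-phase code path and the two outputs are identical by
construction.

ppm↔Hz conversions use the proton Larmor frequency implied by B~0~ through
the physical gyromagnetic ratio (42.577 MHz/T, so 18.8 T ≈ 800 MHz).

## Fixed-size packing of profiles

Profiles enter the networks through a deterministic chain:
`max(I/I₀) − I/I₀` (the dip transform, which makes a CEST profile look
like a 1D spectrum), a real Fourier transform keeping the
`⌊N/2⌋ + 1` non-redundant complex coefficients, zero-filling to exactly
65 complex points (the size forced by the 128-offset maximum), and packing
into two length-130 real vectors — real parts in slots 1–65, imaginary
parts in slots 66–130, plus the matching time axis `t_k = k / SW` (SW the
offset span in Hz), which is how the network learns the field-dependent
Hz↔ppm relation. The inverse real FT of the 65 points yields exactly 128
offsets spanning the original window; because of the zero-fill this is the
band-limited (sinc) interpolation of the input, exact for 128-point
profiles and checked against an independently evaluated trigonometric
interpolant in the tests. Naive sinc interpolation alone is *not*
sufficient to upsample coarsely sampled profiles with narrow dips — its
error reaches tens of percent there, which is the quantitative reason the
transformation network exists.

## The synthetic-data generator

The generator draws the study conditions used for training and
evaluation: B~0~ from {14.1, 16.4, 18.8, 21.1, 23.5} T, B~1~ uniform on
15–50 Hz, 50–128 sampled points over a 3.4 ppm window, T~ex~ = 0.4 s,
inter-scan delay 0.5 s, τ~M~ uniform on 3–20 ns, ^1^J~HN~ uniform on −95
to −91 Hz, `R_ex = |N(1, 2)|` s⁻¹, `dR2_Ei ~ N(0, 2)` s⁻¹, shifts uniform
over the sweep width, `kex` uniform on 10–300 s⁻¹, excited populations
uniform on 0.01–0.15, and a forked three-site topology with probability
25%. Gaussian noise with σ = 0.01 of each profile's maximum is added to
transformation-network inputs (uniform 0.001–0.04 for the shift-network
regime); targets are always noise-free. The offset window is anchored at
6.6 ppm by default — an arbitrary choice of origin in the amide region
that cancels out of every result through the affine shift mapping.

Slot semantics are fixed: slot 1 is the ground state and slots 2–3 the
excited states ordered by population, descending — evaluating ground-state
accuracy separately requires a fixed ordering, and the generator rather
than the loss enforces it. The normalized shift target of an absent state
is parked at 0.5; its value is immaterial because the trained uncertainty
of that slot grows without bound, driving its accuracy term to zero.

What the generator does *not* emulate: B~0~ drift, temperature
instability, baseline artifacts, ^1^H–^1^H cross-relaxation (perdeuterated
samples), or correlated noise. Tests passing on these synthetic
conditions therefore demonstrate correctness of the method under the
stated spin model, not robustness to every experimental artifact.

## The two networks

No deep-learning framework is available to R in this package's dependency
footprint, so cestnet ships a compact network engine of exactly the layer
types needed — dense layers, dilated 1-D convolutions with gated
(tanh × sigmoid) activations and residual connections, densely connected
convolution blocks, average pooling — with an Adam optimizer,
global-norm gradient clipping and hand-derived backpropagation that the
test suite verifies against finite differences to ~10⁻⁹ relative error.

**Transformation network.** The input contract is always the two packed
130-vectors. Two bodies are implemented. The *time-domain* body reshapes
the input to 65 time points × 3 channels (scaled real part, imaginary
part, scaled time) and applies residual gated dilated convolutions — in
the time domain the decoupling operation is approximately a per-point
division by the coupling modulation, so a per-point stack with modest
receptive field fits the task — followed by a dense mixing layer and
either a 65-complex head decoded by an exact inverse real FT or a direct
128-point head (the two descriptions of the output are equivalent up to
that fixed transform; both are provided). The *spectral* body — the
default — first applies the deterministic band-limited inverse FT to get
the naive (still doublet-coupled) 128-point interpolation, then runs a
fully convolutional stack of residual gated dilated convolutions
(dilations 1, 2, 4, 8, 16) that deconvolves the doublet in place; its
channels carry the naive profile, the scalar-coupling splitting expressed
in grid steps (which encodes B₀, since the window is fixed in ppm) and
the grid position (window-edge effects). At the reduced scale this
package targets, the spectral body is markedly more accurate (profile R²
0.99 versus 0.95) with roughly a tenth of the parameters, because
deconvolution is local in the offset domain and the fully convolutional
form shares it across positions; no recurrent module is used at this
scale. Training minimizes the MSE to the clean in-phase dip profile; the
reduced-scale default (roughly 10⁴ examples, a few tens of epochs at
batch 256) is sized so the full suite trains in minutes on one CPU while
reaching R² well above 0.9 on held-out clean two-site profiles.

The learning-rate schedule `lr = 4 × 10⁻⁴ × loss^{3/4}` (clipped to
[10⁻⁶, lr]) is implemented as an option; at reduced scale the loss is far
from its large-scale regime and the schedule collapses the rate
prematurely, so the default is a constant rate with a manual step decay.

**Shift network.** Input: the 128-point decoupled dip profile. Body:
densely connected 1-D convolution blocks (each convolution sees the
concatenation of all previous feature maps) at full resolution, with
dilations 1/2/4 so the receptive field spans neighbouring dips. Head: a
locator that emits the 3 × 2 output — three normalized shifts `f_ω` and
three confidences `c`, all in (0, 1). Each slot's shift is read out as a
windowed soft argmax of a per-slot score map: softmax weights over the
grid, with the expectation restricted to a window around the weight
profile's peak (a plain soft argmax is biased by residual weight mass on
*other* dips — a few percent of mass one ppm away shifts the expectation
by several grid steps). Slots are read out sequentially with learnable
explaining-away couplings: a later slot's score map receives the earlier
slots' weight profiles, which is what makes "the next dip, not the one
already claimed" expressible with convolutional features. Confidences are
sigmoidal, computed from pooled features plus two per-slot regressors:
the log concentration of the slot's weight profile (sharply localized ⇒
confident) and the log distance to the nearest other slot (two slots on
the same dip ⇒ ambiguous assignment). A plain dense readout of the
conv features — the obvious literal rendering of a DenseNet classifier
head — was tried first and underfits position regression badly at this
training scale (median ground-state error ~0.07 ppm, versus ~0.01 ppm
for the locator and ~0.013 ppm for naive peak picking of the same
input); the locator head is the package's design choice, with the
shifts still confined to (0, 1) and the confidences still sigmoidal.
Shifts map affinely onto the offset window
(`δ = offset_min + span · f_ω`), and confidences map to uncertainties
through `σ = k (1/c − 1)`, a bijection from (0, 1) onto (0, ∞).

The loss is the sum of an accuracy term, `L_freq = Σᵢ (f_pred,i −
f_true,i)² / σᵢ²` with k = 1 (a χ²-like heteroscedastic term: the network
may only claim high confidence where it is accurate), and
`L_uncer = 10⁻⁴ Σᵢ 1ᵢ √σᵢ`, which pushes confidences up for states that
are actually present (indicator {1,1,0} for two-state input) and leaves
absent-state uncertainties free. Confidences are clamped to
[10⁻⁶, 1 − 10⁻⁶] before the σ conversion. Two training-schedule devices
make the loss workable at reduced scale without changing it. First, a
warm-up phase freezes σ at 1 (plain squared error on the shifts, no
gradient to the confidences): the `1/σ²` weighting otherwise slows shift
localization badly. Second, the locator's readout window starts global
(plain soft argmax, so the score maps develop contrast rather than
collapsing into a degenerate argmax-of-noise regime) and is narrowed for
the final `refine_epochs`; at the switch the confidence biases are
recentered so each slot's median σ equals the RMS of its current
residuals — a bias-scaling initialization in the spirit of post-hoc
confidence calibration, after which the loss continues to train
everything jointly. After training, k is computed
once from the final mean per-profile `L_freq` as
`k = span · √L_freq` — this rescales `L_freq` to unit expectation so that
σ reports the expected error in ppm. Whether per-epoch recalibration was
ever used historically is unknowable from the description this follows;
recalibrating once at the end is the simpler, documented choice.
Slot-to-state assignment is the generator's fixed ordering; no
permutation matching is performed, since the loss is written slot-wise.

The shift network trains on profiles that have passed through the
transformation network (with anti-phase input noise uniform on
0.001–0.04), so its confidences internalize the transformation error; a
bypass mode that feeds clean simulated in-phase profiles exists for unit
tests only and is labelled as such.

## Calibration and its validity domain

`evaluate_calibration()` simulates fresh scenarios, runs the stacked
analysis and bins `δ_pred − δ_true` against `c_pred` (0.05 × 0.005 ppm
bins), with empirical 68.3/95.4/99.7% envelopes per confidence bin and
the `σ = k (1/c − 1)` overlay. The headline number is the fraction of
predictions with `c_pred ≥ 0.4` whose error lies within ±σ_pred; for an
ideally calibrated model that fraction sits near 68%, and the suite
asserts a [0.5, 0.85] band at reduced scale. This is the one property of
the full-scale method that the reduced-scale models do not reproduce,
and the reason is structural rather than a matter of tuning: the global
rescaling `k = span √L_freq` ties the σ scale to the slot-summed mean of
`e²/σ²`, which at reduced scale is dominated by a heavy tail of
assignment ambiguities (overlapping ground/excited dips). Any per-slot σ
assignment then leaves the *confident* subset overcovered — the measured
within-±σ fraction is around 0.95, i.e. σ_pred is conservative (too
large) for high-confidence predictions — unless the per-profile
confidence features track the conditional error tightly, which is
precisely what ~10⁷ training profiles buy the full-scale network and a
minutes-scale CPU model does not attain. The uncertainties err on the
safe side, never the optimistic side. Below `c_pred = 0.4` the mapped σ
is not a reliable error estimate; such predictions are flagged
(`pass_c04 = FALSE`) but never dropped from raw output.

## Least-squares back-end

`least_squares_fit()` wraps Levenberg–Marquardt (minpack.lm) around the
simulator: floated parameters default to shifts, branch `kex`, excited
populations and excited-state R₂ offsets, with the relaxation baseline
fixed from τ~M~ — which parameters a practitioner floats varies, and this
set mirrors common practice for CEST fits. Multiple profiles (for example
two B~1~ fields) are fitted jointly with shared parameters. Uncertainties
come from the covariance at the optimum (`2 s² H⁻¹`); on noiseless
synthetic data the fit recovers shifts to < 10⁻³ ppm from a true-parameter
start, and the suite checks the covariance σ against replicate scatter.
Network predictions make good starting values for this fitter — that, not
replacement of least squares, is the intended division of labour; note the
networks predict only shifts, while kinetic parameters (`kex`,
populations) come from the fitter alone.

## Numerical choices and problem sizes

- Eigendecompositions use LAPACK through base R (reference path) and
  Armadillo (compiled path); the two simulate identically to ~10⁻¹⁵ and
  the suite asserts it.
- The packed size (65 complex), the 128-offset output and the 3 × 2 shift
  head are architecture constants, not tunables.
- Input featurization scales (coefficients ÷ 32, time × 50) bring network
  inputs to order one; they are part of the trained model, and no test
  depends on their values.
- Reduced-scale training in the test suite uses roughly 10⁴ transformation
  examples and 10⁴ shift examples with the tiny default configurations;
  evaluation sets are a few hundred to a few thousand profiles. These
  sizes are the package's chosen operating point for routine validation:
  large enough that recovery and calibration are meaningful, small enough
  to run on a single CPU in minutes.
- Training is fully reproducible from the RNG seed (data order, weight
  initialization and noise share R's generator); inference is
  deterministic.

## Known limitations

- The networks shipped here are reduced-scale: they demonstrate the
  method end-to-end and meet the recovery/calibration properties above,
  but their absolute accuracy is far from what the same architecture
  reaches with ~10⁷ training profiles and GPU-scale capacity. Parameter
  counts of the full-scale architectures are not reproduced.
- Exchange outside the trained ranges (kex beyond 300 s⁻¹, populations
  above 15%, offset spans far from 3.4 ppm) is extrapolation; the
  pipeline warns on span mismatch but cannot detect every violation.
- A maximum of three states is built into the output head; more states
  require retraining with a different head, and only the forked three-site
  topology is generated.
- No pulse-level effects beyond the INEPT element and CW CEST saturation
  are modelled; methyl-proton variants and ¹⁵N/¹³C in-phase CEST are out
  of scope (the architecture would transfer, the trained weights would
  not).
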