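---
title: "Piecewise-helical modelling of backbone traces: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piecewise-helical modelling of backbone traces: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixfit)
```

## The model and its assumptions

`helixfit` describes a backbone trace (protein Cα or nucleic-acid P
atoms) as a chain of *genuine helical curves*, one fitted to every
sliding window of four consecutive guide atoms. The working assumption is
local, not global: within any four-residue stretch the backbone is close
to some helix. Four atoms is the minimum that determines a helix
non-degenerately (three are always co-circular), and the shortest window
reacts fastest to conformational change — a kink shows up in exactly the
windows that straddle it.

A curve is parameterised by phase $\tau$:

$$\mathbf{x}(\tau) = \mathbf{c}_0 + R \cdot
  \big(r\sin\tau,\; r\cos\tau,\; (p/t)\,\tau\big)^{\mathsf T}$$

* $r$ — radius (Å), $r > 0$;
* $p$ — **rise per residue** (Å). This package never stores rise per
  turn; where a "pitch" is wanted it is $p \cdot 2\pi/|t|$. Keeping the
  per-residue convention makes $p$ directly comparable across helices of
  different twist and makes the chord identity below clean;
* $t$ — signed turn angle per residue (radians), $0 < |t| \le \pi$,
  positive for right-handed;
* $R$, $\mathbf{c}_0$ — a proper rotation and a center, placing the curve
  in the lab frame. The helix axis is $R\,\hat{\mathbf z}$.

Consecutive guide atoms are one turn angle apart in phase, giving the
chord identity $d^2 = p^2 + 4r^2\sin^2(t/2)$ that links the observable
inter-atom distance $d$ to the parameters.

## Fitting a window

**Closed-form seed.** With difference vectors
$\Delta_1 = \mathbf v_1 - \mathbf v_2$, $\Delta_2 = \mathbf v_2 -
\mathbf v_3$ of the centered window,
$\cos|t| = \Delta_1\!\cdot\!\Delta_2 / (|\Delta_1||\Delta_2|)$, the axis
is $\pm\,\Delta_1\times\Delta_2$, $p$ is the projection of one residue
step onto the axis, $r$ follows from the chord identity, and the sign of
$t$ is the sign of the virtual dihedral of the four atoms. On exact
helical input the seed is already exact.

**Grid refinement.** Real windows are noisy, so the seed is refined by an
exhaustive search on a $51\times 51$ grid over $(r, p)$ spanning
$\pm0.25$ Å around the seed in steps of $0.01$ Å ($t$ is re-derived from
the mean inter-atom distance at each candidate via the chord identity).
For each candidate, four ideal atoms at phases $0, t, 2t, 3t$ are
superposed onto the observed atoms (Kabsch SVD with reflection
correction, so the returned rotation is always proper), and the candidate
is ranked by $\Delta$, the RMS of the observed atoms' closest-point
distances to the candidate curve. Ties break to the first candidate in
$(r, p)$ order, which makes the search fully deterministic. The defaults
($\pm0.25$ Å, step $0.01$ Å) bracket the spread observed across noisy
helical windows at $\sigma \le 0.2$ Å while keeping one window fit around
0.2 s; both half-widths and the step are user-settable via
`fit_config()`, and halving the step can only lower $\Delta$ (verified in
the test suite).

**Closest-point queries.** Distance from a point to a helix has no closed
form; the solver samples the phase window uniformly (512 samples per
turn) and polishes the best bracket by golden-section search to a phase
tolerance of $10^{-9}$. An independent brute-force scan
($10^6$ samples) serves as the test oracle; the two agree to better than
$10^{-6}$ Å on random curve/query pairs.

**Degeneracies.** Collinear or duplicate atoms, and windows whose seed
turn angle falls below an angular floor of $0.05$ rad (where the axis
direction from $\Delta_1 \times \Delta_2$ becomes numerically unstable),
are rejected; `helixfit()` records them as gaps rather than inventing a
curve, and the model builder simply averages fewer contributors across a
gap.

## Scoring

Each window is compared with reference moments
$(\mu_r, \sigma_r, \mu_p, \sigma_p, \mu_t, \sigma_t, \sigma_\Delta)$
through the **product**

$$h = \frac{(r-\mu_r)^2}{2\sigma_r^2}\cdot
      \frac{(p-\mu_p)^2}{2\sigma_p^2}\cdot
      \frac{(t-\mu_t)^2}{2\sigma_t^2}\cdot
      \frac{\Delta^2}{2\sigma_\Delta^2}.$$

A product of standardized squared deviations is unusual — a sum would be
the Mahalanobis-style default, and the choice is genuinely ambiguous in
informal descriptions of such scores ("combines the deviations of the
four quantities"). This package implements the product deliberately and
documents the consequence: $h = 0$ whenever *any single* parameter
matches its reference mean, so $h$ is a conjunctive measure — a window
scores badly only if *every* aspect deviates. The fixed points used by
the tests pin the convention down: $h$ at any matched mean is exactly 0,
and the all-at-1σ case is $(1/2)^4 = 0.0625$. Bins for visualization:
green $\le 20$ < celeste $\le 50$ < yellow $\le 100$ < magenta $\le 200$
< red.

The shipped default constants are *not* hand-picked: they are the sample
moments of the 50-trace synthetic calibration corpus
(`calibration_corpus_specs()`: canonical α-helix, 12 atoms,
$\sigma = 0.05$ Å, seeds 1–50), regenerated bit-identically by
`scripts/make_default_params.R`. Users with a domain corpus should
recalibrate with `calibrate_score_params()`, which requires at least 30
fits and refuses zero-spread corpora.

## Averaging into a model curve

The model between atoms $i$ and $i+1$ averages the corresponding arcs of
the (up to three) window curves covering that gap; contributor counts
follow $1, 2, 3, \dots, 3, 2, 1$ along the chain. Each contributor is
sampled at `m` phases between its own closest-point phases for the two
atoms, so averaging happens between corresponding points, and the shared
endpoint of adjacent segments is unified afterwards to make the curve
exactly C0. On exact helical input all contributors coincide, so the
model reproduces the generating curve (to $10^{-6}$ Å in the acceptance
checks, in practice $\sim 10^{-10}$).

Two metrics quantify the payoff against the classic alternative (a cubic
Catmull–Rom spline through the same atoms, provided as
`hermite_baseline()` for comparison only):

* `choppiness()` — RMS successive difference of discrete (Menger)
  curvature along the samples. Helical pieces have locally constant
  curvature; across the calibration corpus the model's choppiness is
  3–6× lower than the spline's on every member.
* `detachment()` — per-atom distance to the model polyline, flagged
  against the ribbon half-thickness. The spline interpolates the atoms by
  construction; the model stays within noise scale of them.

## Center polyline and the `max_delta` filter

Each good window contributes one axis point (the axis foot of its middle
atoms); chaining them gives the center polyline, with bend angles at
interior vertices. For an ideal helix the polyline is straight
($\le 10^{-4}$ rad). For a kinked helix the bend should localize at the
junction — but windows that *straddle* the junction are fitting four
atoms that lie on no single helix; their $\Delta$ jumps an order of
magnitude and their fitted centers are meaningless, producing spurious
$\sim 90°$ bends if kept. `center_polyline(fit, max_delta = 0.08)`
therefore filters contributing windows by fit quality before chaining.
The default is `Inf` (no filtering; honest raw output), and 0.08 Å is the
recommended cutoff for kink analysis: on noisy-but-genuine helical
windows ($\sigma = 0.05$ Å) $\Delta$ stays well below 0.08 Å, while
junction-straddling windows sit far above it, so the cutoff separates
"bad fit of a good helix" from "good fit of a non-helix". With it, a 30°
kinked fixture yields a single dominant bend of 34.8°, within the 5°
acceptance band.

## Ribbons

`build_ribbon()` sweeps a rectangular cross-section (width 2.0 Å,
thickness 0.5 Å by default — thin enough that the detachment flag at
thickness/2 is meaningful) along the model samples. The in-plane
direction points from the sample toward the local window axis,
orthogonalized against the tangent and sign-continued to avoid flips;
vertices are duplicated per side strip so faces carry flat normals; per
vertex colors come from the score bins. Output is ASCII PLY or OBJ (with
`v x y z r g b` color extension), both bit-stable.

## Synthetic generators: scope and limits

`generate_fixture()` produces traces that are pure functions of a
`fixture_spec()` (kind, size, parameters, seed) with the global RNG state
saved and restored. Kinds: ideal and noisy helices of either handedness
with seeded random rigid placement, a kinked helix (one helix whose
continuation past the junction atom is rigidly rotated by the kink angle
— both arms genuine helices, phase continuous through the junction), an
ideal B-DNA strand (r = 9.4 Å, rise = 3.4 Å, twist = 36°/residue, the
classic fiber-diffraction values), and two non-helical controls
(collinear, random coil). The generators deliberately cover *local*
geometry only — no sequence effects, no correlated noise, no
super-helical curvature — so conclusions drawn from them are about the
fitting machinery, not about force fields or real ensembles. Real
structures enter through `read_guide_traces()` (PDB via `bio3d`; model 1,
highest-occupancy altlocs, chains split at gaps > 4.5 Å Cα / 8.5 Å P).

## Problem sizes

The shipped study sizes are this package's own choices, made to keep
every check desk-scale: 100 random parameter draws for exact recovery,
1000 curve/query pairs against a $10^6$-sample oracle, a noise ladder
$\sigma \in \{0.02, 0.05, 0.1, 0.2\}$ Å with 20 seeds per level, and a
50-trace calibration corpus. They are large enough that the observed
margins (e.g. recovery error $\sim 10^{-13}$ against a $10^{-6}$
criterion) leave no realistic room for a qualitative reversal at larger
sizes, and small enough to rerun in minutes.

## Open-question decisions

* **Rise convention**: per residue, not per turn (see above).
* **Score combination**: product, not sum, with the $0$ / $0.0625$ fixed
  points as the defining contract.
* **Turn angle during grid search**: re-derived from the mean of the
  three observed inter-atom distances at each grid candidate rather than
  searched as a third dimension — it is pinned by the chord identity once
  $(r, p)$ are fixed, and the 2-D search keeps runtime quadratic.
* **DNA stride**: stride-3 decimation of the P-trace (~108°/residue for
  B-form) is offered as a mode rather than hard-wired, since the full
  trace (~36°/residue) is equally valid at its own scale.
* **Hermite baseline exported**: the comparison spline is part of the
  public API so that the smoothness claims are reproducible by users, not
  just by the test suite.

## Limitations

* Four-atom windows cannot see curvature of the helix *axis* within a
  window; super-helical coiling appears only through the polyline.
* The score is conjunctive by design; a window wrong in a single
  parameter but perfect otherwise scores 0. Use the per-parameter columns
  of the residue table when a disjunctive view is needed.
* The closest-point solver assumes the query's relevant phase lies within
  one turn of the sampled window; pathological queries near the axis of a
  tight helix resolve to any of many near-equidistant phases (the
  distance is still correct).
* Chains are modelled independently; no inter-chain or inter-arm
  reasoning (e.g. coiled-coil pairing) is attempted.
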