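---
title: "Methods: stereocilia height reconstruction and bundle morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereocilia height reconstruction and bundle morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereostair)
```

## The measurement problem

Cochlear hair cells carry a staircase of stereocilia rows of precisely
graded heights: a tallest, non-transducing first row, and shorter
second and third rows whose tips bear the mechano-electrical
transduction (MET) channels, plus supernumerary (rank 4--5 and
unranked) projections that are pruned during development. Scanning
electron micrographs show only *projections* of these structures: a
stereocilium of height $h$ inclined at insertion tilt $\alpha$ to the
apical-surface normal, viewed at an "angle of view" $\tau$ (the
difference between the stage tilt of the image and the stage tilt at
which stereocilia are parallel to the beam), appears with projected
length

$$ p = h\,\lvert\sin\tau\rvert . $$

`stereostair` implements this forward model and its three inverse
procedures, a morphometric layer (staircase steps, relative heights,
tip-diameter profiles, wedge-tip heights, tip-link classification,
supernumerary counts), a group-comparison layer, and a synthetic
three-dimensional bundle generator whose forward-rendered measurements
make every inverse computation testable by round trip.

## Forward model and conventions

All geometry lives in the vertical plane spanned by the bundle's
mechanosensitivity axis $x$ and the surface normal $z$. The
stereocilium axis is $u = (\sin\alpha, 0, \cos\alpha)$; the beam at
angle of view $\tau$ is $b = (\sin(\alpha+\tau), 0, \cos(\alpha+\tau))$.
Row-$i$ bases sit at $x = -(i-1)d$, where $d$ is the inter-row base
distance, a per-bundle input (assumed centre-to-centre). Projecting
onto the image plane, the in-image stereocilia axis has norm
$\lvert\sin\tau\rvert$, giving the full-length law above, and the
separation between a row-1 tip (height $h_1$) and a row-$i$ tip
(height $h_i$) along the projected axis is

$$ s_i = (h_1 - h_i)\sin\tau - (i-1)\,d\cos(\alpha+\tau). $$

Three conventions are worth stating because the underlying geometry
fixes none of them:

* **Signed step projections.** $s_i$ is stored *signed* (positive when
  the row-1 tip projects beyond the shorter tip). A magnitude
  convention makes the inverse ambiguous at small $\tau$, where the
  $d$-dependent term can dominate and both sign candidates reproduce
  the same magnitude. With the signed convention the inverse
  $h_i = h_1 - \bigl(s_i + (i-1)d\cos(\alpha+\tau)\bigr)/\sin\tau$ is
  exact at every usable $\tau$; the test suite verifies this round
  trip down to $\tau = 5^\circ$.
* **One stage frame.** Stage tilt 0 looks along the surface normal, so
  the stage tilt at which stereocilia are parallel to the beam equals
  the insertion tilt $\alpha$. The parallel-angle determination
  therefore also provides the bundle's $\alpha$, which the step
  inversion needs. Medial ("front") views have $\tau > 0$, lateral
  ("back") views $\tau < 0$.
* **Angles in degrees** at every interface, converted internally,
  matching how tilt series are reported.

## Inverse procedures

1. **Two-view solving** (`solve_height_two_view`): two projections of
   the same stereocilium at tilts separated by $\tau$ satisfy
   $p_1 = h\sin\alpha$, $p_2 = h\sin(\alpha+\tau)$, solved exactly via
   $\cot\alpha = (p_2/p_1 - \cos\tau)/\sin\tau$, $h = p_1/\sin\alpha$.
   A closed form is used rather than iteration for determinism. The
   degenerate $p_1 = 0$ case returns $\alpha = 0$; $p_1 = p_2 = 0$ is
   an error (no length information).
2. **Reference-angle solving** (`solve_height_known_parallel`): once
   the parallel angle is known, $h = p/\lvert\sin\tau\rvert$ per
   single image. This is the lighter workhorse route; the two routes
   agree exactly on noise-free data, and the test suite asserts this
   equality to $10^{-6}\,\mu m$.
3. **Front-view step inversion** (`solve_row_height_front_view`):
   rows 2--3 from a medial step projection given $h_1$, $d$, $\alpha$
   and $\tau$, using the signed closed form above.

The parallel angle itself is estimated by `find_parallel_angle`, a
least-squares fit of $h\lvert\sin(\theta-\theta_0)\rvert$ to a tilt
series with $h$ profiled out and $\theta_0$ optimised on a
$0.25^\circ$ grid refined by golden-section search (tolerance well
under the $0.1^\circ$ target). The fit is preferred to the sampled
minimum because tilt grids are coarse (5--10° steps). A strictly
monotone series means the minimum was not bracketed and is refused
rather than extrapolated.

**Degenerate inputs.** Views with $\lvert\tau\rvert < 1^\circ$ are
rejected wherever a division by $\sin\tau$ occurs: the error
amplification of the inverse scales as $1/\sin\tau$. Perpendicular
views ($\lvert\tau\rvert = 90^\circ$, $p = h$ exactly) are allowed. A
step inversion implying $h \le 0$ marks the stereocilium unresolved in
`reconstruct_bundle` (and errors in the scalar solver), never a
clamped height.

`reconstruct_bundle` orchestrates these per measurement table: row-1
heights by the reference-angle route when a view's parallel angle is
recorded (averaging across views), else by two-view solving; rows 2--3
by step inversion against the stereocilium's recorded row-1 partner
(falling back on the bundle's row-1 mean); each height records the
solver that produced it, and stereocilia with insufficient views are
returned unresolved rather than dropped.

## Morphometric layer

* **Steps** are tip-apex to tip-apex differences $h_1 - h_i$; heights
  trace each stereocilium to its highest point and deliberately ignore
  tip-shape changes. `step_from_projection` computes the same quantity
  straight from a step projection, the route that needs fewer
  calculations and is preferred for small staircase changes.
* **Relative heights** are $100\,h/h_1$ with the bundle's row-1 mean
  as reference (pooling per-stereocilium values across cells requires
  a per-bundle reference).
* **Tip profiles** use a one-parameter power law
  $\mathrm{diam}(s) = D\min\{1, (s/L)^\gamma\}$ ($s$ = distance from
  the apex, $D$ = shaft diameter). This family is a package choice:
  the source observations are qualitative (rounded / wedge / pointed
  tips), and one parameter spans all three regimes
  ($\gamma \approx 0.5$ blunt, $\approx 1$ conical,
  $> 1$ pointed) while keeping every tip statistic closed-form
  testable. Default measurement positions are 0.025, 0.05, 0.1,
  0.2 µm from the apex plus a mid-shaft sentinel; the positions are
  configurable since only "several positions near the tip" is
  specified by the measurement tradition this emulates.
* **Wedge-tip height** is the axial extent of the taper: the smallest
  $s$ with $\mathrm{diam}(s) \ge 0.95\,D$, i.e. $L\cdot 0.95^{1/\gamma}$.
  The 0.95 threshold is a package default (no quantitative wedge
  boundary exists in the measurement tradition). Note that under this
  family the wedge height *increases* with $\gamma$ toward $L$: a
  pointier tip tapers over a longer axial extent before meeting the
  shaft.
* **Tip links**: a link is a tip link iff it originates at the *top
  cap* of the shorter stereocilium's tip, runs toward a taller row
  along the mechanosensitivity axis, and obliquely upward; links from
  elsewhere on the tip hemisphere or from the shaft never qualify.
  Percentages are computed per cell and summarised as mean ± SE
  across cells.
* **Supernumerary counts**: stereocilia of rank ≥ 4 or unranked.

## Statistics

Per-stereocilium measures (heights, steps, diameters) are summarised
as mean ± SD and compared with two-sided Welch $t$ tests; per-cell
percentages as mean ± SE with two-sided Student $t$ tests — the
conventions of the morphometric literature this package serves. Stars:
\*\*\*\* $p<10^{-4}$, \*\*\* $p<10^{-3}$, \*\* $p<0.01$, \* $p<0.05$,
n.s. otherwise. Two deliberate limitations: **no multiple-testing
correction** (stars are per panel, uncorrected), and **no
mixed-effects modelling of cell-level clustering** — stereocilia are
pooled across cells, so p-values on per-stereocilium measures treat
stereocilia as independent. Both mirror standard practice in this
literature and should be kept in mind when interpreting output. The
$t$ machinery delegates to `stats::t.test`; an independent
textbook-formula oracle in the test suite pins both tests to
$10^{-10}$ and checks the empirical Welch type-I error
(10,000 null simulations at $n = 20$ with unequal variances) against
the nominal 0.05 level.

## What the synthetic generator emulates — and what it does not

`generate_bundle` draws per-row heights from independent normals
truncated at $>0$, a Poisson number of supernumerary stereocilia, and
Bernoulli tip links on rows 2--3; all outputs are pure functions of
(spec, seed). The default OHC geometry — row means 2.4 / 1.4 / 0.7 µm,
SDs 0.15 / 0.12 / 0.08 µm, $\alpha = 10^\circ$, $d = 0.4$ µm — is an
internal fixture chosen as a realistic mid-cochlear staircase at the
ages studied; no published per-stereocilium table exists to calibrate
against, so **recovery is always scored against generated ground
truth, never against these defaults**. The supernumerary means (10.9
per OHC, 25.1 per IHC) are the one place observed control values are
used directly.

The treatment model composes a single-site dose-response
`blocked_fraction(dose, ic50) = dose/(dose + ic50)` (Hill
coefficient fixed at 1 — only two calibration points per drug exist,
~75% block at 100 µM amiloride and ~90% at 30 µM benzamil, from which
the default IC50s 100/3 µM and 10/3 µM are back-solved) with a
two-component shortening mixture applied to rows 2--3 and
supernumeraries, never row 1: with probability
$p_{\text{retract}} f$ a deep retraction losing a uniform 50--90% of
height, otherwise a graded normal loss (mean 0.4 µm at full effect,
truncated at ≥ 0), plus an additive increase of the tip exponent
$\gamma$ (tip pointing) and binomial thinning of the supernumerary set.
Amiloride's larger height variability is modelled by a 1.8× inflation
of the shortening SD; smaller IHC effects by an overall
`effect_scale`; shorter incubations by `duration_scale`. Row-1
invariance is exact (bit-identical rows), and tip-link presence is
unchanged by treatment — both deliberate model commitments matching
the negative findings the analysis must be able to reproduce.

Measurement noise is multiplicative Gaussian on projections (default
CV 5%, a realistic manual-measurement error) and additive on
diameters; noise seeds are separated from generation seeds so the same
ground truth can be re-measured.

The generator deliberately omits: pixel-level image formation and
registration, tip-link tension mechanics, Ca²⁺ or actin-turnover
dynamics, kinetics of shortening/regrowth (recovery is modelled only
as a `duration_scale` moved back toward 0), within-bundle height
correlations, and row-dependent insertion tilts. Passing tests
therefore demonstrate correctness of the *computational* pipeline
under the stated statistical structure, not fidelity of that structure
to any particular tissue.

## Validation scale and numerical choices

The shipped test suite validates: exact ($\le 10^{-6}$ µm) noise-free
round trips over 1,000 randomly parameterised stereocilia
($h \in [0.3, 3]$ µm, $\alpha \in [0, 30]^\circ$,
$\tau \in [5, 85]^\circ$) and full bundles through both row-1 routes;
mean absolute relative height error < 5% with < 2% bias under 5%
projection noise (1,000 stereocilia, fixed seed); the headline
staircase pattern (row 1 n.s., rows 2--3 $p < 10^{-4}$) on 100 seeded
control-vs-benzamil cohorts of ~100 stereocilia per row per group; and
the dose-response anchors exactly. These problem sizes were chosen so
the full suite completes in a few minutes on a single core while
keeping Monte-Carlo standard errors well inside the asserted margins.
One caution for re-runners: the row-1 contrast of the cohort check is
an exact null, so its per-seed "n.s." probability is inherently
$\approx 0.95$ and the 95-of-100 criterion sits at the edge of its own
sampling noise.

Numerical details collected in one place: angles converted
degree→radian only at trig call sites; truncated normals by rejection
(safe because all default means sit far from the truncation point);
treated heights floored at 0.02 µm (a fully resorbed actin core is not
modelled); CSV serialisation fixes 6 decimal places on µm/degree
columns so write→read round trips are exact at the recorded precision;
all stochastic stages require explicit integer seeds and the pipeline
manifest records them, making re-runs byte-identical.
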