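---
title: "Deformation-based shape analysis of the mid-sagittal corpus callosum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformation-based shape analysis of the mid-sagittal corpus callosum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmorph)
```

## The problem

Group studies of corpus-callosum (CC) morphometry usually compare the
area of the mid-sagittal CC cross-section, possibly split into genu
(gCC), body (bCC) and splenium (sCC). Area is a global summary: a
disease process that thins one small portion of the boundary can leave
the total area almost unchanged. `ccmorph` implements a *localized*
alternative: every subject's CC boundary curve is registered to a cohort
template by a large-deformation diffeomorphic metric mapping (LDDMM) for
curves, and the Jacobian determinant of the resulting transport is read
off at every template point. This "deformation marker"
$J_k = \det D\varphi(x_k)$ measures the relative area change of an
infinitesimal neighborhood of template point $k$: $J_k > 1$ is local
expansion of the target relative to the template, $J_k < 1$ local
inward deformation. Pointwise covariate-adjusted permutation tests on
the markers then localize group differences along the boundary.

## Pipeline

1. **Extraction.** The mid-sagittal slice of a labeled segmentation
   volume is the central sagittal slice (1-based index
   $\lceil n/2 \rceil$; slice 91 of the 181-slice 1 mm MNI grid). The
   union of the three sub-region labels is traced with Moore-neighbor
   boundary following (8-connected foreground, Jacob's stopping
   criterion), starting at the lower-left boundary pixel and proceeding
   clockwise in a y-up coordinate frame. Each curve point carries the
   sub-region label of its pixel; labels are consolidated by a cyclic
   5-point majority vote so each sub-region forms one contiguous arc.
   Two area dialects coexist deliberately: pixel-count areas (exact
   mm^2 on the 1 mm grid, used for all area statistics and for template
   selection) and the shoelace area of the pixel-center polygon (used
   for internal consistency checks; for a $w \times h$ block it is
   $(w-1)(h-1)$ rather than $wh$).

2. **Template.** The template is the cohort curve whose pixel-count
   area is closest to the cohort mean (ties broken by smallest subject
   id), resampled to $K = 200$ points. Resampling iterates equal
   arc-length placement to its fixed point, so the operation is
   idempotent and the template points are uniformly spaced along the
   template itself.

3. **Registration.** Each target curve is resampled to $K$ points and
   rigidly aligned to the template (rotation + translation only, by ICP
   from a centroid/principal-axis initialization; scale is deliberately
   not removed so that size differences remain in the markers). LDDMM
   then minimizes
   $$E(\alpha) = \sum_t \Delta t \sum_{ij} \alpha_i(t)^\top \alpha_j(t)\,
   e^{-\|x_i(t)-x_j(t)\|^2/\sigma_V^2}
   + \lambda\,\|[\varphi_1(\text{template})] - [\text{target}]\|_{W}^2,$$
   with momenta $\alpha$ supported at the template points, explicit
   Euler flow over `n_timesteps` steps, and a currents data term: a
   curve is represented by segment midpoints $c_i$ and tangents
   $\tau_i$, with
   $\langle [a],[b] \rangle = \sum_{ij} \tau_i^\top \tau_j'\,
   e^{-\|c_i - c_j'\|^2/\sigma_W^2}$. Currents compare curves without
   point correspondence and are orientation-aware. Optimization is
   plain gradient descent with Armijo backtracking (energy is
   non-increasing across accepted steps by construction). The ambient
   $2 \times 2$ Jacobian is integrated alongside the flow,
   $\dot D = (\nabla v_t)(\varphi_t(x))\, D$, with the same Euler
   scheme; the markers are its determinants at $t = 1$.

4. **Statistics.** At each template point the marker is modeled as
   $J_k = \beta_{k,0} + \beta_{k,1}\gamma + \sum_c \alpha_c X_c +
   \varepsilon_k$, with $\gamma = 1$ for patients and age, gender and
   total intracranial volume (TIV) as nuisance covariates (age and TIV
   only within a single-gender scope). Significance comes from
   Freedman–Lane permutation: the reduced model (without $\gamma$) is
   fitted, its residual rows are permuted and added back to the reduced
   fit, and the full model is refitted on each reconstructed response.
   Family-wise error across the $K$ points is controlled by the
   single-step Westfall–Young max-$|t|$ distribution; its exceedance
   probability at the observed max-$|t|$ doubles as the omnibus shape
   p-value, so the omnibus p equals the smallest corrected pointwise p
   by construction. Raw p-values use the add-one estimator
   $(1+b)/(1+m)$, which cannot return zero. When $n!$ does not exceed
   the requested permutation count the scheme switches to exhaustive
   enumeration and p-values become exact proportions. The reported
   effect is $-\beta_{k,1}$, so positive values mean inward deformation
   in the patient group. Cohen's d is computed on the raw (unadjusted)
   markers or areas with the $(n-1)$-weighted pooled SD, reported
   alongside the adjusted-model p-values. The gender-by-group
   interaction is tested with the same machinery (reduced model = main
   effects + covariates); per-gender post-hoc comparisons are always
   computed and the interaction gate (p at or below 0.05 by default) is
   recorded with them. Area analyses run the identical model per
   structure (CC, gCC, bCC, sCC) with no correction across the four
   structures, which are reported individually.

## The synthetic cohort

No clinical images ship with the package; a generator produces
everything the pipeline consumes.

The base shape is a parametric arched band (a C opening downward):
the region between two radial profiles $R_m \pm h(\theta)$ over
$\theta \in [-0.25, \pi + 0.25]$, with $R_m = 26$ mm, $h(\theta)$
around 3.2 mm with Gaussian thickenings at the anterior (genu) and
posterior (splenium) ends. This reproduces realistic magnitudes — about
717 mm^2 total area and 7.2 mm mean thickness at scale 1 on a 1 mm
grid — and the topology that matters for the method (a closed boundary
with three contiguous sub-arcs), but it is *not* an anatomical atlas:
sub-regions are assigned by angular thirds of the arc because no
atlas-based definition is available to a self-contained package, and
the split is documented as configurable rather than anatomically
authoritative.

Each subject is derived from the base outline by, in order:

* global scaling by $(\text{TIV}/\overline{\text{TIV}})^{1/3}$ — the
  cube root makes a volume covariate act on a 2D slice dimensionally
  consistently;
* a random smooth stationary velocity field (12 Gaussian bumps, width
  `warp_smoothness_mm` = 8 mm, amplitudes
  $\mathcal N(0, \text{warp\_amplitude\_mm}^2)$ with 0.6 mm default),
  integrated by 16 small compositional steps; each step map must be
  orientation-preserving on a probe grid, otherwise generation aborts
  with advice to lower the amplitude;
* for patients, an inward displacement along the outline normal over a
  configured arc-fraction support, windowed by a cosine-tapered (Tukey)
  window with 0.25 taper per side. The plateau makes the injected area
  deficit approximately $0.75 \times \text{amplitude} \times
  \text{support length}$, so localization and first-order area oracles
  know exactly what was injected. The default support is the outer
  (superior) genu arc; the default amplitude is 0.8 mm in female
  patients with `effect_gender_ratio = 0` (no effect in male patients);
* a small rigid jitter (1 degree / 0.5 mm SDs).

Covariates: age uniform on 12–43 years; TIV normal with gender-specific
means (F 1.50e6, M 1.35e6 mm^3, SD 1e5). The female mean is set higher
so that, through the TIV–scale coupling, female CC areas exceed male CC
areas — the direction reported for callosal areas in the literature this
package's design follows; the generator makes no claim about actual TIV
physiology. Per-subject RNG streams are keyed by (seed, subject id), so
cohorts are reproducible and order-independent, and regenerating with
the effect disabled yields exchangeable groups.

What the generator does **not** emulate: MRI intensities and artifacts,
segmentation errors, anatomically realistic sub-region boundaries, 3D
geometry, or realistic covariate–shape confounding beyond the TIV–size
coupling. Passing tests therefore demonstrate that the pipeline
recovers what it is pointed at under controlled conditions — they do not
certify performance on clinical segmentations.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `sigma_V` | bbox diagonal / 8 | mm | smoothness scale of admissible deformations |
| `sigma_W` | `sigma_V` / 2 | mm | scale at which curves are compared |
| `lambda_match` | $K / M_0$ | – | matching weight; $M_0$ is the initial mismatch |
| `n_timesteps` | 10 | – | Euler steps of the flow (and of the Jacobian transport) |
| `max_iters`, `rel_tol` | 500, 1e-6 | – | gradient-descent budget and stopping threshold |
| `K` | 200 | points | template discretization |
| `n_perm` | 10000 | – | Monte-Carlo permutations |
| `alpha` | 0.05 | – | FWER level and interaction gate |

Notes on choices that were genuinely open:

* **$\lambda$ normalization.** With zero initial momenta the
  regularization term starts at exactly 0, so "balance the two terms at
  iteration 0" cannot be applied literally; normalizing the initial
  mismatch to the number of curve points ($\lambda = K/M_0$) makes the
  two terms comparable once the optimizer has moved. Stronger matching
  (larger multiples of $K/M_0$, together with a smoother kernel such as
  diagonal/4) approaches the perfect-match limit, in which a uniform
  scaling by $s$ is recovered as markers near $s^2$. Within a cohort,
  one *study-wide* $\lambda$ is resolved from the median initial
  mismatch across subjects: normalizing per subject would couple each
  subject's matching/deformation trade-off — and hence their marker
  noise — to their own distance from the template (mostly head size),
  which measurably distorts the exchangeability the permutation tests
  rely on. Even with the shared weight, the null distribution of the
  omnibus p retains a mild conservatism in its extreme lower tail
  (under the generator's null the family-wise error at nominal 0.05
  measures near 0.03), which is the safe direction for inference.
* **Kernel width vs. band thickness.** With $\sigma_V$ (about 8.7 mm)
  larger than the band thickness (about 7 mm), the velocity field
  couples the two facing boundary sides: pressing the outer genu
  boundary inward also contracts the inner genu boundary. This is real
  mechanics of the model, not an artifact — significance maps of a
  genu-localized effect cover both boundary sides of the genu.
* **Ambient vs. tangential Jacobian.** The marker is the determinant of
  the full 2x2 ambient Jacobian, matching the "relative area change
  over an infinitesimal region" interpretation; a tangential derivative
  along the curve would measure arc stretch instead.
* **Equivariance in floating point.** Energy, flow and Jacobian
  transport are exactly rotation-equivariant (verified to 1e-9 at
  fixed momenta). End-to-end registrations of rotated problems agree
  only to a few percent: line-search accept/reject decisions flip under
  rounding noise and the optimizer settles on slightly different points
  of a nearly flat valley. The default `sigma_V` is also tied to the
  axis-aligned bounding box, so a pinned kernel width is required for
  strict rotation comparisons.
* **Permutation scheme.** Freedman–Lane was chosen as the standard
  covariate-respecting scheme; single-step max-$|t|$ Westfall–Young as
  the permutation-native FWER control whose omnibus p has the
  min-corrected-p identity. A tie guard (1e-8 relative) makes the
  identity permutation count as an exceedance despite floating-point
  route differences between the observed and permuted statistics.
* **Degenerate inputs.** Boundary tracing requires at least 4 boundary
  pixels (a single pixel is rejected as implausibly small); multiple
  foreground components are reduced to the largest with a warning;
  self-intersecting polygons are rejected by `curve_area`; a
  non-positive marker aborts registration with advice to refine the
  flow discretization; rank-deficient designs name their collinear
  columns; empty gender-by-group cells abort the interaction test.

## Problem sizes used in the shipped tests

The package's own validation uses deliberately scaled-down studies: the
FWER calibration runs 200 replicate null cohorts of 12 subjects at
$K = 50$ and 500 permutations; the effect-recovery study uses the full
25-subjects-per-cell design over 20 replicates at $K = 50$; the
area-consistency check registers a 40-subject cohort at $K = 100$; the
acceptance script analyses a 48-subject cohort at $K = 100$ with 2000
permutations. These sizes keep the whole suite reproducible on a single
CPU while leaving every statistical property test at its nominal
operating point.

## Known limitations

* The generator's sub-region split (angular thirds) is a stand-in for
  atlas-defined boundaries; absolute sub-region areas are therefore not
  comparable to atlas-based studies, although their statistical
  behavior is.
* Boundary curves are pixel-center polygons; no sub-pixel contouring is
  attempted, and curve (shoelace) areas are systematically below
  pixel-count areas by roughly half a perimeter.
* The rigid prestep uses ICP, which can in principle settle into a
  local minimum for heavily rotated inputs; the principal-axis
  initialization with both orientations makes this unlikely for
  CC-like shapes.
* Thickness is defined as twice the Euclidean distance transform
  sampled on a Zhang–Suen skeleton; other thickness estimators
  (medial-axis pruning, orthogonal profiles) would give slightly
  different absolute values.
* Markers from under-converged registrations shrink toward 1; cohort
  analyses at reduced iteration budgets remain valid group comparisons
  (the attenuation is shared by both groups) but absolute marker values
  should be read with the convergence diagnostics in hand.
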