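---
title: "Positioning volumetric body models with hard-constrained Laplacian deformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positioning volumetric body models with hard-constrained Laplacian deformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbmpose)
```

## The problem

Finite-element human body models (HBMs) ship in one reference posture.
Using them for injury analysis in a different posture — seated to standing,
a bent knee, a raised arm — requires moving every node of a volumetric mesh
with hundreds of thousands of elements while keeping the mesh usable for
simulation: no inverted ("negative volume") elements, no severe stretching,
and no interpenetration of anatomically adjacent but topologically
unconnected components such as organs, bones and skin.

`hbmpose` implements a simulation-free positioning pipeline in three
stages:

1. **Pre-processing** — posed skin and skeleton surfaces define hard
   positional constraints; thin-plate-spline (TPS) interpolation predicts
   targets for *extra constrained nodes* on component interfaces near
   joints.
2. **Hard-constrained Laplacian deformation** — free (interior) node
   positions are recovered by preserving differential coordinates through
   a sparse symmetric positive-definite linear solve.
3. **Post-processing** — distorted elements are detected by their scaled
   Jacobian and repaired by mapping original-mesh spatial relationships
   onto the positioned mesh, again with TPS.

## The deformation model

The mesh is a graph: two nodes are neighbours when they share an element
(solid, shell or beam — all element classes contribute adjacency). Edge
weights decay with the cube of the rest-pose distance,

$$w_{ij} = \frac{1}{d_{ij}^3 + \epsilon},$$

so close-packed regions are stiffly coupled while long edges contribute
little. $\epsilon$ (default $10^{-8}$ in cubed mesh-length units) guards
the division for coincident nodes; coincident pairs are additionally
reported as a modelling smell. The graph Laplacian is $L = D - A$ with
weighted degrees on the diagonal, and the differential coordinate of node
$i$ is

$$\delta_i = \sum_{j \in N(i)} w_{ij}\,(v_i - v_j), \qquad \delta = L V.$$

A common variant divides each $\delta_i$ by the degree $\deg_i$. That is a
positive rescaling of each equation of the square constrained system and
cannot change its solution, so the package works with the unnormalised
convention, which keeps $L$ symmetric and lets plain conjugate gradients
apply; the equivalence is asserted as a test property rather than assumed.

Partitioning nodes into free (F) and constrained (C) sets and fixing
$v_j = c_j$ for $j \in C$ turns $\delta = LV$ into

$$L_{FF}\, v_{\mathrm{free}} = \delta_{\mathrm{free}} - L_{FC}\, c_{\mathrm{fixed}},$$

with $\delta$ always computed from the *original* coordinates. $L_{FF}$ is
symmetric positive definite as soon as every connected component of the
graph contains at least one constrained node; components without one are
rejected up front as "unconstrained islands", with the offending part
labels in the error.

### Solver

Each coordinate axis is solved independently by Jacobi-preconditioned
conjugate gradients (relative residual tolerance $10^{-10}$ by default,
iteration cap $10\,n_{\mathrm{free}}$), warm-started from the original
free-node positions. On non-convergence the package falls back to a sparse
Cholesky factorisation and says so. Two numerical details matter:

* **Frame centring.** The mean constraint displacement is removed before
  the solve and added back afterwards. A pure translation of all targets
  is therefore reproduced to machine precision rather than to solver
  tolerance — and general solves are better conditioned because the
  right-hand side is not dominated by a large common offset.
* **Warm starting** makes identity-like solves (targets at or near the
  rest pose) converge in zero or a handful of iterations.

Scaling equivariance deliberately does *not* hold: the weights are
functions of rest-pose distances, so uniformly scaling the targets is a
genuinely different problem. This is a property of the method, asserted in
the tests as an inequality.

## Extra constrained nodes

Surface constraints alone under-determine regions near large joint
rotations: differential coordinates are not rotation-invariant, so interior
structure near a 90° hinge lags the rotation, and disconnected components
(an organ tethered only loosely to its surroundings) can end up inside a
bone or outside the skin. The remedy is a set of *extra constrained nodes*
on or near component interfaces, whose targets are predicted before the
solve:

1. collect the already-constrained nodes (skin + skeleton surfaces);
2. for each candidate, find its $k$ nearest constrained nodes in the
   original coordinates (exact brute-force neighbour search — fixture
   scales make a tree structure unnecessary);
3. fit a local TPS from those neighbours' original to target positions and
   evaluate it at the candidate.

The TPS uses the $\phi(r) = r^2 \log r$ kernel with a full first-order
polynomial part and the standard orthogonality side conditions, so every
fitted map reproduces affine transforms exactly and interpolates its
control points exactly at zero ridge. A singular system (coplanar
controls) is retried once with a small ridge on the whole block system,
with a warning.

**Choosing k.** The default, $k = 30$, keeps fits local and is right for
candidates whose neighbourhood moves approximately rigidly. Near a joint,
however, the candidate sits *between* two rigid bodies, and a useful local
map must see constraint nodes of **both**; with small $k$ the neighbour
sets of adjacent candidates flip abruptly from one bone to the other and
the predicted targets fold. For the bundled bend experiment the organ
predictions use $k = 400$, large enough that every organ node's
neighbourhood spans both bone ends across the 40 mm joint gap. The rule of
thumb: $k$ must cover the constraint nodes within a radius comparable to
the candidate's distance to *both* adjacent rigid structures.

Candidate selection itself remains a reviewed, persistable choice (the
generator records ground-truth interface IDs; `select_interface_candidates()`
accelerates manual selection on real models, and ID lists can be stored
for reuse).

## Quality metrics and repair

Element quality uses two dimensionless metrics:

* **Scaled Jacobian $J$** — at each corner, the determinant of the
  normalised emanating edge vectors; the element value is the corner
  minimum. A unit cube scores 1, an inverted element below 0, and for
  hexahedra $J \in [-1, 1]$. Tetrahedra are normalised by $\sqrt{2}/2$ and
  triangles by $\sqrt{3}/2$ so the regular shapes score 1. The convention
  is the pre-processor-style corner Jacobian; conventions differ across
  tools, so absolute counts are comparable only within one convention.
* **Aspect ratio AR** — longest over shortest element edge. Structurally
  collapsed edges (repeated connectivity entries in degenerate records)
  are not edges; a geometrically zero edge between distinct nodes yields
  `Inf`.

The three standard counts — $J < 0.3$, $J < 0$ and $\mathrm{AR} > 10$ —
summarise distortion before and after each stage.

**Repair** extracts elements with $J$ below threshold, clusters them by
shared nodes, and classifies nodes: members of distorted elements are
*defective* (moved), remaining nodes of the clusters' neighbouring
elements are *reference* (kept). Per cluster, a TPS fitted from the
reference nodes' original to positioned coordinates is evaluated at each
defective node's original position — transplanting the baseline mesh's
local spatial relationships into the deformed state. Three design choices
are the package's own:

* Hard constraints are immovable: a constrained node in a distorted
  element is reclassified as reference. Boundary fidelity defines the
  posture and wins over element quality.
* Clusters with fewer than 5 reference nodes grow their neighbourhood by
  up to three element rings before being declared unrepairable.
* Repair iterates (`repair_until_stable()`), re-measuring quality each
  pass and stopping as soon as the distorted count fails to strictly
  decrease; a worsening pass is discarded, so the reported per-pass counts
  are non-increasing and the returned mesh is the best seen.

## The synthetic limb fixture

Licensed body models cannot ship with the package, so `generate_limb()`
builds the smallest structure that exercises every failure mode the
pipeline addresses: two segments along $z$ with a hinge; each segment has
a tubular hexahedral bone (marrow radius 5, outer radius 10 mm), a shared
flesh annulus out to 20 mm, and a quadrilateral skin shell closed with
end caps; a slender organ tube (radius 4, length 28 mm) floats in the
joint cavity, tethered to the lower bone-end ring by a few beam elements —
anatomically adjacent, topologically disconnected, exactly the situation
that needs extra constraints. Posing uses a programmatic armature with
linear blend skinning (LBS): bones bind rigidly to their segment, soft
tissue blends across a transition band by a smoothstep profile.

The geometry defaults were fixed by three design constraints, worked out
before the acceptance checks were written:

* **Joint gap 40 mm** — flat-ended rigid bones at a hinge angle
  $\theta$ collide at the inner corner unless the gap exceeds
  $2 r_{\mathrm{bone}} \tan(\theta/2)$ (20 mm at 90°); colliding
  constraints crush the intervening flesh into unrepairable inversions.
  The generous margin stands in for the rounded condyles of real joints.
* **Blend band 70 mm** — the LBS inner-side skin folds over itself unless
  the band exceeds $\approx 1.5\, r_{\mathrm{flesh}}\, \theta$ (47 mm at
  90°, the 1.5 factor being the peak slope of the smoothstep); a folded
  *target* surface makes inverted shells that no interior repair can fix.
  Conversely the band should stay near the gap so that blended skin does
  not slide over rigidly posed bone. 70 mm balances the two.
* **Slender organ** — following the local constraint field across the
  joint bends the organ by the full hinge angle over its own length; its
  tube radius must stay well under the resulting bend radius
  ($\approx$ half its length at 90°) or its own predicted targets invert
  it.

At the defaults the fixture has ≈ 23 k nodes and ≈ 20 k elements, and the
pristine mesh scores $J \ge 0.5$ everywhere with no stretched elements.
Deterministic jitter (2 % of the element height, seeded) breaks exact
symmetry in the flesh interior.

**What the fixture does not emulate:** anatomical geometry, contact
mechanics, material behaviour, multi-joint kinematic chains, and the
sliding of skin over bone. Passing the bundled experiments shows the
pipeline's mechanisms work at realistic severity (a 90° single-hinge bend
with disconnected anatomy); it does not certify results on any particular
licensed model.

## Penetration checking

`count_penetrations()` classifies points against a closed surface by ray
parity (Möller–Trumbore ray–triangle intersection; quads are split into
two triangles), voting over three fixed axis-skew ray directions so an
edge-grazing ray cannot silently flip a result. Both "outside the skin"
and "inside the wrong part" semantics are supported. The bend experiment
counts organ nodes outside the skin, inside the skeleton, or inside the
flesh solid; the dominant failure without extra constraints is the third —
the unconstrained cavity wall sweeps across the statically tethered organ.

## Worked example

```{r example, eval = FALSE}
limb <- generate_limb(limb_spec())
ps <- pose_limb_surfaces(limb, angle = 90)

res <- run_position(limb$mesh, ps$posed_surfaces,
                    extra_ids = limb$interface_ids$organ,
                    k = 400, max_passes = 8)
res$repair_passes
res$quality_after
```

On the default fixture this reports roughly 70–80 elements below
$J = 0.3$ (of ≈ 20 k) after the solve, a ≥ 75 % reduction after iterated
repair, and zero negative-volume elements — while the same bend *without*
extra constraints leaves over a hundred organ nodes inside the flesh.

## Numerical choices and limitations

* CG tolerance $10^{-10}$ (relative); identity recovery is then accurate
  to $\sim 10^{-14}$ of the bounding box, far below the $10^{-8}$
  contract.
* TPS ridge defaults to 0 (exact interpolation); the automatic singular
  retry uses $10^{-10} \times$ (mean pairwise distance)$^2$.
* Repair cluster fits cap the reference pool at 1500 nodes
  (deterministically thinned) because dense TPS systems scale cubically.
* Problem sizes in the test-suite experiments: the default fixture
  (≈ 23 k nodes) for end-to-end checks, ≤ 216-node blocks for dense-oracle
  comparisons, and a coarse ≈ 1.3 k-node limb for module-level tests.
* Weights are uniform inverse-cubic; anisotropic or cotangent weighting,
  soft (penalty) constraints and multigrid solvers are out of scope.
* Repair relocates nodes only — it never remeshes, and it cannot fix an
  element whose nodes are all hard-constrained; such clusters are
  reported as skipped.
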