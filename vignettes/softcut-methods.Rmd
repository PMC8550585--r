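---
title: "Methods: meshless cutting simulation over a fixed-width table store"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meshless cutting simulation over a fixed-width table store}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softcut)
```

## The problem

Real-time simulators for surgical training must deform virtual soft tissue
and let the user cut it, at interactive rates.  Accelerator (GPU-style)
implementations want rigid, fixed-layout memory, while cutting wants to
edit the element--node graph every frame.  `softcut` implements the
simulation side of this trade-off in full, and *models* the device side:
every graph-shaped array lives in a fixed-row-width table whose batched
dirty tracking quantifies exactly how many bytes a mirrored copy on a
device would have to receive after each update.  The package's headline
statistic is the per-update transfer reduction achieved by batch-wise
flushing versus whole-array copies.

## Discretization and dynamics

The object is discretized Element-Free-Galerkin style: a cloud of nodes
plus *cubic integration elements* (quadrature cells with a center and a
volume $h^3$).  Each element carries a neighbor set of at least
`k_min = 8` nodes.  Shape functions are moving least squares (MLS) with a
linear basis $p(x) = (1, x, y, z)$ and the $C^2$ cubic B-spline weight of
normalized distance $q = \lVert x - x_i \rVert / r_i$:

$$\phi_i(x) = p(x)^\top A(x)^{-1} w_i(x)\, p(x_i), \qquad
  A(x) = \sum_j w_j(x)\, p(x_j) p(x_j)^\top .$$

Gradients use the full total-derivative formula (differentiating both $A$
and $w$).  These choices make three properties *exact* up to roundoff, and
the test suite asserts them after generation and after every cut: partition
of unity $\sum_i \phi_i = 1$, gradient consistency $\sum_i \nabla\phi_i =
0$, and linear reproduction $\sum_i \phi_i x_i = x$.

Shape functions are evaluated at rest positions only (total-Lagrangian,
small-strain).  Per element, strain is
$\varepsilon = \mathrm{sym}(\sum_i \nabla\phi_i \otimes p_i)$, stress is
linear-elastic $\sigma = \lambda\,\mathrm{tr}(\varepsilon) I +
2\mu\varepsilon$, and nodal forces accumulate as $f_i \mathrel{-}= V\,
\sigma \nabla\phi_i$.  The stiffness matrix is never assembled: this
element loop *is* the operator $K p$, implemented as a compiled kernel,
and the implicit system is solved matrix-free.

Time stepping solves, per frame,

$$(M - \Delta t^2 K)\,\Delta \dot u = \Delta t\,(f^{elastic}_0 + f^{ext}_0),
  \qquad u = u_0 + \Delta t\,(\dot u_0 + \Delta\dot u),$$

with $M$ the lumped (diagonal) mass $m_i = \sum_I \rho V_I \phi_i^I$, by
unpreconditioned conjugate gradient.  Each CG iteration reduces to the two
scalars $r^\top r$ and $p^\top A p$ -- the only values a device
implementation would ship back to decide convergence.  Dirichlet
constraints are handled by symmetric projection (zeroing fixed components
of operator input and output), which preserves operator symmetry.

**A note on dissipation.**  The update above omits the
$\Delta t^2 K \dot u_0$ cross term of full backward Euler.  Analyzed per
vibration mode, its one-step map has determinant exactly 1 and trace in
$(0, 2)$, i.e. unit-modulus eigenvalues for *every* time step: the scheme
is unconditionally stable (bounded for arbitrary $\Delta t$, which the
stability-probe test verifies at $100\times$ the explicit limit) but only
*marginally* so.  Energy strictly decays from zero-velocity states (modal
factor $1/(1 + \Delta t^2 \omega^2)$) and total momentum is conserved when
nothing is fixed; both are tested.  A state with nonzero velocity can
transiently gain elastic energy.  No Rayleigh damping is added, since the
update equation contains none.

## The fixed-width table store

Four large per-frame arrays form the mutable state of the graph: the
element connectivity rows, the shape values, the shape gradients, and the
surface vertex--node weights.  Each is a `FixedWidthTable`: a single
allocation of `n_rows x max_row_width` item slots plus a row-length
vector.  Rows may shrink or grow up to the fixed capacity without touching
any other row; no operation ever reallocates (a contract the tests assert
over random edit scripts).  A row longer than `max_row_width` raises an
overflow error naming the row -- the store's one hard limitation.

Rows are grouped into contiguous *batches* (default 64 rows; the dirty
granularity is the batch, not the row, mirroring the idea of coalescing
many small transfers into few larger ones).  `flushTable()` emits a
transfer plan covering exactly the dirty batches -- payload plus that
batch's slice of the row-length vector, so one flush unit is
self-contained -- and a `TransferLedger` accumulates per-frame
`bytes_batched` versus `bytes_full` per table.  The reported reduction is
$1 - \sum \text{batched} / \sum \text{full}$ over the frames with any
edit.  A host-side mirror (`makeMirror()` / `applyFlush()`) realizes the
copy contract in memory; a property test checks that a mirror receiving
only flushed batches always equals the source.  Actual accelerator
execution and wall-clock timings are out of scope by design: the byte
accounting is hardware-independent, the timings are not.

Batches are per-table rather than global, and the row-length slice ships
with its batch; both choices were genuinely open and are fixed here for
self-containedness of a flush unit.

## Cutting

The tool is a polyline; between consecutive frames each segment sweeps a
quad, split into two triangles (degenerate sweeps dropped).  A link --
element center to node, or surface vertex to node, both at *rest*
coordinates, consistent with rest-configuration shape functions -- is
severed iff it intersects a new sweep triangle.  The intersection test is
an orientation-sign formulation with ties counted as hits (conservative
severing); an axis-aligned bounding-box prefilter prunes candidates but
never decides.

After severing, an element with fewer than `k_min` neighbors or a
neighbor set failing the coplanarity test is refilled with its nearest
*visible* nodes -- visible meaning the connecting segment crosses no
triangle of the accumulated cut surface, so nothing ever reconnects across
a cut.  The coplanarity criterion is the smallest eigenvalue of the
centered covariance of the neighbor positions exceeding
$(0.05\,h)^2$; it guards the invertibility of the MLS moment matrix, and a
moment matrix whose condition number exceeds `1e12` raises an error rather
than silently regularizing.  Vertex mappings lose severed nodes and are
renormalized; a vertex whose weight sum collapses below $10^{-9}$ is
remapped from scratch to its nearest visible element's node set (rebuild
only on degeneracy -- renormalization is the cheap common path).  Lumped
masses of affected nodes are refreshed after each cut frame so $M$ stays
consistent with the shape tables.  Because MLS values can be mildly
negative (especially for stretched post-cut neighbor sets), mass lumping
clips negative values and renormalizes per element: each element always
distributes exactly $\rho V$, so nodal masses stay non-negative and total
mass is conserved through any cutting sequence.  A node disconnected
entirely receives a floor mass of $10^{-12}\times$ the mean so the system
stays definite.
Surface re-triangulation along the cut faces is deliberately not
performed; cutting the render mesh is reduced to severing and reweighting
the embedding.

## The synthetic scene

Every experiment runs on a generated torus, the package's only test
object: nodes on a regular grid of spacing $h$ inside
$(\sqrt{x^2+y^2}-R)^2 + z^2 \le r^2$, elements on the dual grid (offset
$h/2$ -- the simplest consistent placement of cubic integration cells),
a closed parametric triangle surface, nodes with $x < -(R - r/2)$ fixed so
the torus hangs under gravity, and a two-point blade translating across
the tube cross-section, entering and leaving outside the solid.  The
blade's sweep plane is offset from $y = 0$ by $r/17$: the grid and the
surface seam both lie exactly on $y = 0$, and a tie-inclusive intersection
rule would classify on-plane nodes as invisible from *both* sides -- a
degenerate tangency the offset removes.

Default parameters (all overridable via `defaultRunConfig()` /
YAML config):

| parameter | default | units | rationale |
|---|---|---|---|
| $R$, $r$ | 1, 0.3 | length | reference torus |
| $h$ | 0.07 | length | $\approx$ 5k elements at the reference scale |
| `n_u`, `n_v` | 100, 50 | -- | 10k surface triangles |
| $E$, $\nu$, $\rho$ | 10 kPa, 0.45, 1000 kg/m$^3$ | | soft-tissue-like, nearly incompressible |
| $\Delta t$ | 1/60 | s | frame-coupled physics at 60 FPS |
| frames | 200, blade active 41--100 | -- | one cut pass amid free sagging |
| `k_min`, `max_row_width` | 8, 16 | -- | at-least-8 neighbor rule; 2x headroom |
| `batch_size` | 64 | rows | transfer/locality compromise |
| CG `tol`, `max_iter` | $10^{-6}$, $10 n$ | -- | config-exposed; neither is prescribed by the method |

Support radius of node $i$ is $1.1\times$ the distance to its 8th-nearest
element center at rest, precomputed once.  When a legitimately selected
neighbor (boundary elements, post-cut replacements) lies beyond that
nominal radius, the per-pair effective radius is expanded to
$\max(r_i, d/0.95)$ so its weight stays positive; MLS consistency is
unaffected, since the exactness properties hold for any positive weights.

What the generator does *not* emulate: organ-shaped geometry,
heterogeneous materials, contact and self-collision, haptic input, and
measurement noise -- there is none, the pipeline is deterministic.
Passing tests therefore demonstrate correctness of the discrete machinery
and the transfer accounting under a clean, localized cut; they do not
certify behavior on irregular anatomy, multiple simultaneous cuts, or
real device latencies.

## Numerical choices

* MLS basis is evaluated unshifted; at the demo's coordinate-to-spacing
  ratio the moment-matrix condition numbers sit around $10^3$--$10^5$
  (up to a few $10^6$ for stretched boundary neighbor sets), still six
  orders of magnitude below the $10^{12}$ rejection threshold.
* The weight at $q = 0$ has $w'(0) = 0$, so the gradient of the
  normalized distance is safely defined as zero at coincident points.
* Tie-breaking in neighbor selection is by distance then node index, so
  generation is fully deterministic; the table zero-fills unused slots so
  serialized snapshots are reproducible byte-for-byte.
* The coplanar (segment-in-plane) branch of the intersection test falls
  back to a bounding-box overlap -- conservative, and measure-zero under
  the offset sweep plane.
* An optional `precision = "single"` switch rounds the state through
  IEEE float32 each step, exposing reduced-precision drift for study; no
  claim is attached to it.

## Problem sizes used by the checks

The transfer-reduction experiment runs at the reference scale (about
5,000 elements, 10,000 surface triangles, 200 frames).  Oracle
equivalences (dense-assembled stiffness, direct linear solves, all-pairs
cut detection) run on models of 27--550 nodes, where dense references are
exact and cheap; the instrumented cutting run re-derives the severed set
of every frame with an independent parametric intersection oracle.  The
stability probe takes 200 steps at $100\times$ the explicit limit
$2/\omega_{\max}$, with $\omega_{\max}$ and the static sag from dense
eigen/solve oracles on the small torus.

## Reproducing the headline number

```r
demo <- runCuttingDemo(defaultRunConfig())
demo$reduction_edit_frames   # percent reduction over frames with edits
demo$report$per_table        # per-table breakdown
```

`scripts/acceptance.R` wraps exactly this and writes the result as JSON.

## Known limitations

* Linear (non-corotational) elasticity: large rotations produce the usual
  small-strain artifacts; the demo's soft material sags deeply on purpose.
* An element may never reference more than `max_row_width` nodes; the
  cutter raises a structured overflow error when a cut corners an element
  into an unsatisfiable neighbor set (forcible in adversarial geometry,
  not observed in the torus runs).
* Severed-off nodes keep integrating ballistically (floor mass, zero
  stiffness); they are inert debris, not removed.
* No crack-face triangle generation, element subdivision, contact, or
  preconditioning; these are listed future work, not partial features.
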