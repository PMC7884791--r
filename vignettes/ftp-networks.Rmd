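---
title: "Constructing binary recurrent networks from transition graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing binary recurrent networks from transition graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftpnet)
```

## The model and its assumptions

`ftpnet` works with the linear-threshold neuron: a recurrent population of
`N_rec` binary units driven by `N_in = 2` one-hot input units,

$$
\mathbf{u}(t) = \mathbf{y}(t)\,\mathbf{W}^{in} + \mathbf{z}(t-1)\,\mathbf{W}^{rec},
\qquad
\mathbf{z}(t) = H(\mathbf{u}(t) - \boldsymbol{\theta}),
$$

with a strict threshold (`u > θ` fires). Everything the package does rests
on one observation: if the firing states the network should visit and the
activations they should evoke are both known, the weights are not a search
problem but the solution of the linear system $\mathbf{CW} = \mathbf{U}$,
where each row of $\mathbf{C}$ is a concatenation $[\mathbf{y}_s\,
\mathbf{z}_m]$ of an input code and a source firing state, and the matching
row of $\mathbf{U}$ is the activation vector of the destination state. The
transition graph of the task dictates which $(m, s) \to m'$ triples appear.

Two facts shape the construction. First,
$[\mathbf{y}_2\,\mathbf{z}_m] = [\mathbf{y}_1\,\mathbf{z}_m] -
[\mathbf{y}_1\,\mathbf{z}_P] + [\mathbf{y}_2\,\mathbf{z}_P]$ for any state
$P$, so $\mathrm{rank}(\mathbf{C}) = M + 1$ no matter how many of the $2M$
rows are stacked. Second, by Rouché–Capelli the system is consistent only
if the rows of $\mathbf{U}$ satisfy the same combinations, which collapses
to a single structural requirement: *the difference between the
activations evoked by the two stimuli from a common source state is one
constant vector* $\Delta$ *per network.* Activation rows are therefore not
free; they are generated in $\Delta$-linked pairs (more generally chains),
and one free row per chain is all the randomness the system admits. The
minimum-Frobenius-norm solution $\mathbf{W} = \mathbf{C}^{+}\mathbf{U}$ is
taken as *the* network, on the argument that biological synapses are
resource-bounded; all other solutions differ by elements of
$\ker(\mathbf{C})$ and form the isofunction space.

The package treats the sequence-memory task (the "s-task") as its primary
object: with stimuli presented i.i.d. with equal probability, the network
must encode the last $\tau$ stimuli in its current firing state, which
requires $M = 2^\tau$ states arranged as a binary de Bruijn shift
register. State $m$ encodes the history as the bits of $m - 1$, most
recent stimulus in the least-significant bit, so the two members of each
pair $(2k-1, 2k)$ share all history except the latest stimulus — exactly
the $\Delta$-pairing the consistency argument needs, and the reason this
indexing produces the banded transition matrix.

## Construction choices

**Activation grid.** Thresholds are drawn from $\{1/2, 3/2, 5/2\}$ and
base activations are $\theta_i + r + 1/2$ with integer $r$; the $+1/2$
keeps every activation half a unit away from its threshold so that no
numerical tie can flip a firing state. We draw $|r|$ uniformly from
$\{1,\dots,5\}$ and set the sign positive with probability equal to the
target firing rate: this excludes $r = 0$ (whose firing status would be
asymmetric: $0 + 1/2$ fires) and makes the firing-rate target exact in
expectation. The firing-rate target is applied to the thresholded firing
matrix $\mathbf{Z}$, not to the full coefficient matrix, because the input
columns of $\mathbf{C}$ are fixed by the task.

**Input codes.** $\mathbf{y}_1 = (1,0)$, $\mathbf{y}_2 = (0,1)$. Any two
distinct codes work; one-hot keeps `N_in = 2` and makes the rank argument
transparent.

**Expansion and placement.** Each $\Delta$-chain receives one free base
row; its position within the chain is chosen uniformly at random and the
remaining rows are derived by adding or subtracting $\Delta$. The random
placement balances the activation distributions of the two stimuli.
Derived rows are computed by sequential addition so that on the
half-integer grid the pair identity `row(2k) − row(2k−1) = Δ` holds to the
last bit. The genetic algorithm evaluates fitness with deterministic
placement ("first position") instead, so that fitness is a pure function
of the individual and elite fitness can never decrease; the stochastic
placement is used only when a network is finally built.

**Correlation factor.** Scaling $\Delta$ by $f_{cc} \ge 1$ *before*
expansion makes the two stimuli drive increasingly different activations,
which manifests as pairwise correlation in the simulated rasters; the pair
identity then holds with the scaled vector. Large $f_{cc}$ pushes derived
rows far from threshold, so more thresholded rows collide and the
validity-triggered restart rate rises — at $f_{cc} = 5$ a handful of
restarts per network is normal, which is why `construct_network()` exposes
`max_restarts`.

**Validity and restarts.** A candidate system is accepted only if all `Z`
rows are distinct, $\mathrm{rank}(\mathbf{C}) = M+1$ and
$\mathrm{rank}([\mathbf{C}\,\mathbf{U}]) = M+1$ (rank from singular values
above $10^{-10}$ of the largest; residual bound $10^{-8}$). Failures
restart the whole draw — they are a property of the random base, not of
the algorithm. Restarts are common only for $\tau < 5$ with $f_{cc} > 1$.

## Random transition graphs and the bicoloured fraction

The null models ("F networks") follow graphs whose destinations are
random, subject to the same consistency algebra. The first $M$ edge slots
use every $\Delta$-pair once as a destination pair, guaranteeing in-degree
at least one everywhere; the remaining $M/2$ slots draw pairs uniformly
with replacement; sources are attached through a random permutation.
Rewiring a quadruple of consecutive states $(i, i+1, i+2, i+3)$ into the
chain $i \to i+1 \to i+3$ (the destination-pair series $(1,2),(2,4)$)
makes state $i+1$ reachable under both stimuli — *bicoloured* — at the
cost of displacing state $i+2$ from the pairing altogether: no remaining
row differs from it by $\Delta$, so it could never again be a
destination. The package therefore re-pairs the displaced states of
consecutive rewired quadruples with each other, which restores
reachability without creating further bicoloured states, keeping the
count at exactly `round(f_bc * M / 4)`, one per rewired quadruple.

This repair is not optional cosmetics. Viewing the used destination pairs
as an edge cover of the $\Delta$-chains, a bicoloured state is precisely a
doubly-covered node, and the number of doubly-covered nodes in any edge
cover equals $2 \times (\text{number of distinct pairs used}) - M$ — an
even number whenever $M$ is even. An odd bicoloured count is therefore
mathematically incompatible with every state receiving an edge, and
`build_random_graph()` rejects it with an explanation rather than
silently miscounting. All fractions used in practice
($f_{bc} \in \{0, 0.25, 0.5, 0.75, 1\}$ at $M = 128$, and the test
configurations) give even counts. Two forbidden patterns are scanned for
and redrawn: a state mapping to one destination under both stimuli
(consistent only with $\Delta = 0$) and two paired states mapping
crosswise onto themselves.

## Structural constraints in the null space

Any change $\Delta\mathbf{W} = \ker(\mathbf{C})\,\mathcal{M}$ preserves
every coded transition. Constraints are imposed by alternating between the
constraint set and this affine solution space: at each iteration neurons
are typed excitatory or inhibitory by the sign of their summed outgoing
recurrent weights (rows of $\mathbf{W}^{rec}$ — the presynaptic
convention; typing columns, the postsynaptic reading, was tested and
stalls immediately), relabelled at the $|\eta|$ closest to zero to meet a
requested Ex:In ratio; the desired change $\Delta\mathbf{W}_d$ negates
self-connections, sign-violating entries, and the below-percentile
magnitudes for sparsity (nearest-rank percentile over the entries not
already zeroed by the other two components, so the sparsity target acts
on top of them); the projection
$\ker(\mathbf{C})\,\ker(\mathbf{C})^{\top}\Delta\mathbf{W}_d$ is applied;
and the loss $\mathcal{L} = \langle|\Delta\mathbf{W}_d|\rangle$ is
tracked. Input rows are exempt from typing by default (`dale_inputs`
flips this).

**Stopping.** Success requires two things at once: $\mathcal{L} \le e_1$
(default $10^{-3}$) *and*, after clipping every violating entry to exactly
zero, a clipping error $e_{clip} = \langle|\mathbf{CW}_{sc} -
\mathbf{U}|\rangle \le 10^{-3}$. These two cannot be separated: the loss
averages the violations over all weight entries while the clip error
re-accumulates them column-wise through $\mathbf{C}$, so at the first
crossing of $e_1$ the clip error is reliably an order of magnitude larger.
Feasible cases converge geometrically (the active sets freeze and the
iteration becomes an alternating projection between two affine sets), so
the descent simply continues below $e_1$ until the clipped weights also
reproduce $\mathbf{U}$; infeasible cases flatten out and are caught by the
relative-improvement test $(\mathcal{L}(k-1) - \mathcal{L}(k)) /
\mathcal{L}(k) < e_2$ (default $10^{-4}$). A clip error below the bound
can never flip a firing state, because every activation sits at least
$1/2$ from its threshold; success therefore implies bit-identical rasters,
which the tests verify rather than assume.

Not every minimum-norm network admits a given constraint set — that is a
finding, not a failure mode. `build_constrained_network()` counts the
fresh networks consumed until the first success; at $\tau = 3$ with 64
neurons and the full set (no self-connections, 4:1, 40% sparsity) one to
a handful of attempts suffice, and feasibility rises steeply with neuron
count. The configuration $\tau = 4$ with `f_r = 3` (48 neurons) succeeds
only rarely (about 1 in 100 draws here); it sits below the screening
minimum of $4 \cdot 2^\tau$ neurons that the efficiency analyses
use, and results quoted for it should be read as selected successes.

## Statistics and their conventions

* **Pairwise correlation** is the Spearman coefficient per neuron pair
  across time steps (average ranks; on binary trains it coincides with the
  product-moment coefficient, which the tests cross-check). The default
  return is the signed mean with constant-train pairs counted as zero —
  the contract used by the genetic algorithm's state statistics. The
  *published-value* convention is the mean of absolute coefficients over
  pairs where the coefficient is defined (`absolute = TRUE,
  drop_constant = TRUE`): it is the only reading that simultaneously
  reproduces the correlation plateau at $f_{cc} \ge 5$ and makes the
  shuffled-raster floor equal the analytic null
  $\sqrt{2/(\pi(n-1))}$ for the mean absolute coefficient of independent
  trains of length $n$. Noise correlation conditions on the stimulus and
  averages the two per-stimulus means with equal weight.
* **ISI shuffling** permutes, per neuron, the gaps between consecutive
  spikes including the gap before the first spike, and keeps trailing
  silence fixed — one consistent reading of an under-specified control;
  spike counts are conserved exactly, and single-spike trains are
  invariant under this convention.
* **Reciprocity** is the Spearman correlation between mirrored ordered
  pairs of the min–max-normalised absolute recurrent weights, restricted
  to pairs whose both members exceed a zero tolerance ($10^{-12}$) so that
  clipping-induced structural zeros drop out. Rank correlation is
  invariant to the normalisation itself; it is kept for interpretability
  of the tolerance.
* **KS-to-normal** compares the weights with a freshly drawn normal sample
  of matched mean, variance and size; zero-variance input returns 1 by
  convention, flagged with a warning.

## What the generator emulates — and what it does not

The synthetic world is the stated one: two equiprobable stimuli, one per
time step; thresholds on the half-integer grid; activation magnitudes
$|r| \le 5$; defaults `f_r = 1`, `target_fr = 0.5`, `f_cc = 1`,
simulation length $10 \cdot 2^\tau$ post burn-in with burn-in $\tau$ and
the initial state drawn from the coded set. A green test establishes that
the construction, constraint and measurement machinery behave as derived
on this world. It does not establish anything about continuous-valued or
spiking neurons, more than two stimuli, non-uniform stimulus statistics,
trained (rather than solved) networks, or biological data; those are
outside the model class by design.

## Numerical choices, degenerate inputs, limitations

Rank tolerance $10^{-10}$ (relative to the leading singular value),
residual tolerance $10^{-8}$, PGD iteration cap 2000, restart cap 50
(raise it for $f_{cc} \gg 1$ at small $\tau$), rejection-sampling cap 1000
per random graph. Serialization writes 17 significant digits so that the
$\mathbf{CW} = \mathbf{U}$ residual survives a round trip. Degenerate
cases are first-class: duplicate thresholded states, rank defects,
residual failures, trivial null spaces, infeasible Ex:In ratios, odd
bicoloured counts and degenerate weight matrices each raise a typed
condition or flagged value rather than propagating silently.

Known limitations: networks with fewer neurons than states are not
supported (the full-rank base requires $N_{rec} \ge M/2 + 1$, and
reliable behaviour requires $N_{rec} \ge M$); the genetic algorithm is
mutation-only (no crossover) and its mean-fitness stopping rule can be
slow for extreme joint targets; graph drawing, readout training and the
gradient-descent baseline are out of scope.
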