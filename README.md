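# agentnet

Interaction inference for agent-based systems with **variable-wise graph
attention**, in pure R (plus a few small C++ kernels).

## The problem

Collective behavior — flocking, clustering, pattern formation — emerges from
pairwise interactions whose form and range are usually unknown.  Given only
observed trajectories of $n$ interchangeable agents with states
$\mathbf{s}_i^t$, the package learns the one-step transition rule

$$\Delta\mathbf{s}_i^{t+1} \;=\; f\!\Big(h_{\mathrm{self}}(\mathbf{s}_i^t),\;
\textstyle\sum_{j\neq i} w^q_{ij}\, \mathbf{v}_j(\mathbf{s}_j^t)\Big),$$

and, at the same time, the **per-state-variable interaction strength**
$w^q_{ij} \ge 0$ — how strongly agent $j$ drives variable $q$ of agent $i$.
The estimator is a graph attention network with *neural attention*: for each
output variable $q$, a private MLP maps the encoded pair (key$_i$, query$_j$,
globals) to a coefficient squashed by a sigmoid,

$$\alpha^q_{ij} = \sigma\big(\mathrm{Att}_q(k_i, q_j, \mathbf{u})\big) \in (0,1),$$

with **no softmax across neighbors**, so $\alpha^q_{ij}$ is an absolute
interaction strength.  Each variable's attention feeds only that variable's
decoder, which is what makes the weights physically interpretable — and the
package verifies the recovered $\alpha$ against exactly known ground truth.

Three classic systems ship as simulators with known interaction structure:

| system | states | true interaction |
|---|---|---|
| cellular automaton (14×14, bounded) | `x, y, c` | Moore-neighborhood indicator (r ≤ √2) |
| vision-cone flocking model | `x, y, vx, vy` | disc sector: r < 1 m, bearing within a 120° cone |
| active Ornstein–Uhlenbeck particles | `x, y, vx, vy` + global `R` | soft-core force `3 r² e^(−r³/R³)/R³`, hidden propulsion |

## Worked example

Simulate the particle system into its clustered steady state and read the
lattice spacing off the pair-distance distribution:

```r
library(agentnet)

hp <- desk_study("aoup_pattern", seed = 1, R = 2)
hp$spacing / 2        # lattice spacing in units of the interaction length R
#> [1] 1.42156
hp$confident
#> [1] TRUE
```

The clustered phase of this soft-core system is a hexagonal (cluster)
crystal with spacing ≈ 1.4 R; the estimator finds the first peak of the
radial pair-distance profile past the multi-occupancy peak at the origin.

Train the attention model on one-step flocking transitions and recover the
vision cone nobody told it about:

```r
vm <- desk_study("vicsek", seed = 1)   # ~8 min on one CPU
round(c(radius = vm$radius, width = vm$angular_width, auc = vm$auc), 3)
#>  radius   width     auc
#>   0.947 105.818   0.997
```

The simulator's agents interact within radius 1 m and a 120° vision cone;
`sector_recovery()` reads both back from the heading-aligned attention map
(the attention-vs-membership AUC of 0.997 says the learned weights separate
true neighbors from non-neighbors almost perfectly).

Inspect any frame directly:

```r
st <- vicsek_state(30, seed = 7)
f <- an_forward(vm$model, as.matrix(as.data.frame(st)))
dim(f$attention)      # target x source x output variable
#> [1] 30 30  2
f$mu[1, ]             # predicted mean displacement of agent 1
f$s2[1, ]             # and its per-variable predictive variances
```

## Command line

A thin CLI over the package functions ships in `inst/cli/agentnet.R`:

```sh
Rscript inst/cli/agentnet.R simulate vicsek --n-samples 200 --seed 1 --out traj.csv
Rscript inst/cli/agentnet.R train vicsek --data traj.csv --seed 1 --out model.ckpt
Rscript inst/cli/agentnet.R analyze sector --ckpt model.ckpt --data traj.csv --out analysis/
```
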