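---
title: "The networking-under-infection model: mechanics, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The networking-under-infection model: mechanics, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nidmsim)
```

## The model

`nidmsim` simulates a round-based social networking game played on a
60-node network under an SIR-style epidemic. Each round has four stages:

1. every node (*ego*) is offered 12 other nodes (*alters*) and decides to
   maintain or dissolve existing ties and to propose new ones;
2. recipients of proposals accept or decline (creation needs mutual
   consent; dissolution is unilateral);
3. point rewards are computed;
4. the disease spreads along the current ties and infection clocks advance.

The game ends when no infectious node remains, or after 20 rounds.

### Rewards

A node $i$ with $t_i$ ties, a proportion $x_i$ of closed triads among its
neighbor pairs, and disease state $s_i$ earns per round

$$U_i = \Big[b_1 t_i + b_2\Big(1 - 2\,\frac{|x_i - \alpha|}{\max(\alpha, 1-\alpha)}\Big)\Big]
        - \big[c_1 t_i + c_2 t_i^2\big] - [\sigma]\,,$$

scaled into points by a factor of 41.88. Under the defaults
($b_1 = 1$, $c_1 = 0.2$, $c_2 = 0.067$, $b_2 = 0.5$, $\sigma = 0.34$) six
ties are optimal and worth 100 points, the triad term pays up to 21 points
at the preferred proportion $\alpha$ (0 in the low-clustering setting,
0.67 in the high-clustering setting), and every infected round costs 14
points. The relation term is floored at zero (`clamp_relation_reward`), so
hoarding ties never yields negative relation points; the triad term is
*not* floored — the zero floor is a rule about relation rewards only, and
a flag records the choice. Two scaling factors circulate in descriptions
of this design (41.55 and 41.88); only 41.88 is consistent with the worked
products $2.388 \times 41.88 \approx 100$, $0.5 \times 41.88 \approx 21$
and $0.34 \times 41.88 \approx 14$, so 41.88 is the default and 41.55
remains settable.

### Risk perception

Agents decide myopically: each offered tie change is evaluated by the
one-round utility difference it would produce ([`tie_delta()`]), holding
everything else at the round-start network. In these decision utilities
the objective severity $\sigma$ is replaced by the perceived cost

$$\sigma^{r_i}\, \pi_i^{\,2 - r_i}, \qquad
  \pi_i = 1 - (1-\gamma)^{t_{i_I}},$$

where $r_i \in (0,2)$ is the node's risk-aversion score (1 = neutral) and
$t_{i_I}$ its count of infectious neighbors. Perception only shapes
decisions; realized stage-3 rewards always charge the objective $\sigma$.
Susceptible egos bear the perceived cost, infected egos carry the constant
$\sigma$ (irrelevant when comparing tie changes), recovered egos bear
nothing. Three behavioural extensions are switchable: a weight on the
perceived cost (`ext_risk_weight`), a probability of deciding
reward-seekingly (`ext_p_reward_seeking`, with the complement drawing
uniformly between the two actions when the alter is not infected), and
extending the perceived penalty to infected and recovered egos
(`ext_penalty_all_egos`). With an infected alter the randomized deviation
never applies: observed behaviour shows infected alters are treated
deliberately, and the extension is meant to inject noise only into
disease-irrelevant decisions.

An exact-zero delta resolves to the status quo (maintain / not propose /
decline): inertia is the only neutral convention. Decisions are evaluated
independently per opportunity — the model is explicitly myopic, and no
joint optimization over the $2^{12}$ action subsets is attempted. Stage-2
acceptances are evaluated against the round-start network as well, since
egos cannot observe mid-round changes.

### Epidemic timing

Stage 4 orders its three sub-steps as: transmission draw from the current
infectious set, clock decrement (with recovery at zero), then activation
of the new infections with clock $\tau$. Consequently a node infected at
the end of round $k$ is in state I — penalized and infectious — during
rounds $k+1$ to $k+\tau$, and recovered from round $k+\tau+1$; the index
case, infected before round 1, is infectious in rounds 1 to $\tau$. This
is the only ordering that makes "infected for exactly $\tau$ rounds" hold
simultaneously for the index case and for nodes infected mid-game.

## Opportunity selection

Twelve offers per ego per round (`round(phi * n)`). Each slot draws a tier
— neighbors, neighbors-of-neighbors, others — with probabilities
$(\psi, \xi, 1-\psi-\xi) = (0.5, 0.3, 0.2)$, so the mixture is per-slot
stochastic rather than quota-based (matching "on average 50/30/20"). A
tier out of unoffered candidates falls through in the cyclic order
neighbor → second neighbor → other, preserving the priority of closer
nodes. Within a tier, with probability $\omega$ the not-yet-offered node
with the most similar risk score is taken (ties to the lowest id),
otherwise a uniform draw; $\omega$ is 0 under random mixing and 0.8 under
assortative mixing, which is the mechanism that sustains assortativity as
the network rewires.

## Baseline networks

Both baselines have 60 nodes, 178 edges — the only edge count whose mean
degree $2 \cdot 178 / 60 = 5.933$ prints as the designed 5.93 — and are
connected, with mean local clustering 0.06 (LO) versus 0.62 (HI).

The generator is constructive rather than search-based. For LO, 18
triangles are chained so that each of 27 corner nodes sits in exactly two
edge-disjoint triangles (local proportion $2/15$; the mean over 60 nodes
is then exactly $27 \times 2/15 / 60 = 0.06$), and the rest of the graph
is filled triangle-free at degree 6, except four degree-5 nodes required
by the edge count. For HI, nine 6-cliques are wired by one external tie
per member (local proportion $10/15 = 2/3$), four members of one clique
stay internal (degree 5, proportion 1), and six connector nodes with
triangle-free neighborhoods tie into six distinct cliques each; the mean
is $(50 \cdot 2/3 + 4)/60 = 0.622$, printing as 0.62.

These designs are *pairwise-stable* under the no-disease utility: no node
profits from dissolving any tie, and no pair of nodes both profit from
creating one. That is the sense in which starting positions are optimal —
a purely unilateral notion is unattainable at these targets, because a
degree-5 node always wants a sixth tie; what blocks it is consent (every
potential partner would lose) or triangle formation (in LO the four
degree-5 nodes share a hub, so any tie among them would close a triad and
cost more than the sixth tie gains under $\alpha = 0$). The knife-edge
arithmetic is tight but strict: at $\alpha = 0$ a degree-6 node in one
triangle would profit from dissolving the triangle tie
($+1/15 > 0.063$), so LO concentrates triangles on nodes carrying two of
them, where dissolving one forfeits only $1/30$ of triad value. A
degree-preserving swap search towards the clustering target is retained
as a fallback, but the constructive start hits the tolerances directly.
Seeds permute node labels and randomize the fill, so different seeds give
different edge sets with identical structural properties. Closeness is a
secondary objective (its normalization,
$1 - (\bar d - 1)/(n - 1)$, is itself a modeling choice made because it
reproduces the designed values at plausible mean distances); the LO
construction lands at about 0.975 and HI near 0.96.

## Participant assignment

Scores are sorted ascending and mapped to a fixed node ordering. The
ordering is the Fiedler-vector (spectral) ordering of the graph
Laplacian, sharpened by greedy position swaps that minimize the summed
squared rank distance over edges — in HI this lines cliques up as
contiguous rank blocks, in LO it is the best available one-dimensional
locality. Assortative mixing assigns ranks in order; random mixing
spreads them along the same ordering with a fixed golden-ratio
(low-discrepancy) scrambling. A strictly alternating low/high pattern was
rejected: it systematically pairs lows with highs across edges and drives
the edgewise correlation *negative*, whereas random mixing should leave
it near zero. The package checks assignments with
[`edgewise_risk_correlation()`]; with heterogeneous scores the assortative
map exceeds $+0.4$ and the random map stays within $\pm 0.15$ — artifact
acceptance bands, not empirical claims.

Simulated scores are drawn from a normal with mean 1.27 and SD 0.45
truncated to $(0, 2)$, matching the empirical staircase-score
distribution rescaled to the model range. Truncation pulls the realized
mean to about 1.223 and the SD to about 0.40 — the nominal 1.27/0.45
describe the untruncated parent.

## The staircase task

Five binary choices between a 50:50 gamble for 300 points and a
guaranteed amount: 160 first, then bisection with halving steps (80, 40,
20, 10) — gambles raise, safe choices lower the next offer, giving 80 or
240 in round two. Only the first two amounts are pinned by the design;
the halving schedule is the standard bisection consistent with 32
terminal positions. The five choices map bijectively to positions 1
(always safe) through 32 (always gamble), and the score inverts the
position linearly onto $[0, 2]$. Under this linear map risk-neutrality
(1.0) does not coincide with an integer position — position 16 scores
about 1.03 — a wrinkle of the published description that is noted, not
resolved. The simulated responder thresholds on a power-utility certainty
equivalent ($u(x) = x^{2-r}$, so $r = 1$ values the gamble at 150 points)
and yields scores weakly monotone in the true $r$.

## Orchestration and data

A batch plays 48 sessions of two games: the first game's clustering
alternates per session (LO, HI, HI, LO, ...) and mixing alternates every
second session (RA, RA, AS, AS, ...), giving 24 games per condition.
Scores are drawn once per session and reused in both games. Every random
draw descends from the master seed, so batches reproduce exactly.

Outputs mirror the three data categories of such experiments: network
data (one row per directed edge occurrence per round-start snapshot, plus
empty-partner rows for isolates), decision data (stage, opportunity type,
action, perceived delta) and participant data (node ids per game, score,
implied staircase position). Analysis helpers compute final epidemic size
$(|I| + |R|)/n$ at game end, decision-proportion tables by ego/alter
disease state (empty cells are undefined, not zero), counterfactual
rewardingness (the realized stage-3 reward against the same round with
the single tie toggled), and a rank-sum test with tie-corrected normal
approximation for comparing final-size samples.

## Numerical choices and degenerate inputs

* Nodes with degree below 2 have triad proportion 0 (no possible triads),
  so the triad term evaluates at $x = 0$ for them.
* Edgewise correlation symmetrizes each undirected edge into both ordered
  pairs; zero variance on a margin returns `NA` with a warning.
* The index case minimizes the L1 sum of absolute z-scores of degree,
  local clustering and risk score; zero-variance quantities contribute
  nothing, ties break to the lowest id.
* Reciprocal simultaneous proposals auto-create the tie: mutual consent
  is already established and no cleaner stage-2 rule exists.
* Displayed points are rounded for logs; all internal arithmetic is
  unrounded. Node ids are 1-based throughout, following R convention.

## Problem sizes used in the test suite

The shipped tests exercise full-size objects where the design demands it
(60-node baselines, 96-game batches, $10^4$-draw Monte-Carlo checks of
the transmission and offer mixtures) and scale Monte-Carlo replication to
what stabilizes each statistic: 50 games with the three risk-aversion
levels 0.5/1.0/1.5 mixed twenty agents each for the avoidance-monotonicity
check, and a dozen paired games for the similarity-weight comparison.
These sizes are the package's own choices for statistical resolution.

The monotonicity check deliberately mixes the levels *within* games. One
functional subtlety of the perceived cost motivates this: for $r < 1$ the
exponent on the probability, $\pi^{2-r}$, is convex, so the marginal
perceived saving of shedding one of *several* infectious neighbors is
larger at $r = 0.5$ than at $r = 1$ (e.g.
$\sigma^{r}(\pi_2^{2-r} - \pi_1^{2-r})$ is 0.051 versus 0.043 at
$\gamma = 0.15$), while shedding the *only* infectious neighbor is
cleanly monotone in $r$. Homogeneous populations additionally shape their
own epidemics, confounding the comparison; holding the epidemic
environment fixed across levels isolates the behavioural gradient, which
is then monotone.

## What the generator does and does not emulate

Synthetic games reproduce the *mechanics* of the experiment: reward
structure, offer mixture, consent protocol, epidemic process, schedule.
They do not reproduce human behaviour — real participants avoided
susceptible alters with infected neighbors, neglected clustering, and
made only about two-thirds of decisions reward-seekingly. Passing tests
therefore validate the simulator and the model's internal logic, not
behavioural predictions about people; the behavioural extensions exist
precisely so such deviations can be modeled, and the decision logs are
exported regression-ready rather than fitted here (multilevel model
fitting is out of scope).

## Known limitations

* Networks are fixed at the 60-node design; other sizes would need new
  structural targets.
* The baseline construction is specific to the degree-5.93/clustering
  targets; arbitrary target pairs fall back to the swap search, which is
  slower and approximate.
* Agents have no memory, learning or anticipation; stage-2 decisions
  cannot react to stage-1 outcomes of the same round.
* Decision timers, unresponsive participants and payment conversion are
  not modeled.
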