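---
title: "Simulating metabolic pathway evolution with fluxsel: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating metabolic pathway evolution with fluxsel: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxsel)
```

# The problem

Enzymes do not evolve in isolation: a mutation that degrades one catalytic
step changes the steady-state concentrations and fluxes of the whole
pathway, and therefore the selective value of every other enzyme's
parameters. `fluxsel` simulates this coupling directly.  A kinetic
metabolic model — species, reactions, explicit rate laws — supplies the
genotype-to-phenotype map: the phenotype is the vector of steady-state
reaction fluxes, computed by solving the model's ODE system, and fitness
is a saturating function of the fluxes a user places under selection.
Evolution proceeds as a forward-time mutation-selection-drift process in
discrete generations along a rooted phylogeny, so that the output is a set
of simulated parameter histories for every lineage of a species tree.

The mutation-selection regime represents the population by a single
parameter state: each mutation either fixes population-wide or is lost
before the next one arises.  This sidesteps an explicit Wright-Fisher
population and makes effective population sizes of $10^6$ or more
tractable, at the cost of excluding standing variation, heterozygosity and
soft sweeps, which are out of scope here.

# Fitness from steady-state flux

For every selected reaction the current flux $J$ is *proportionalized* by
the reference flux $J_0$ recorded at the start of the simulation (before
any mutation) and a user multiplier $m$:

$$x = \frac{J}{J_0\, m}.$$

The raw fitness kernel is a logistic in $x$,

$$L(x) = \frac{1}{1 + e^{10(0.5 - x)}},$$

whose upper branch encodes a diminishing marginal return: a cell cannot
survive with zero flux, while production beyond the starting level buys
almost nothing.  The kernel is rescaled so that a score of 0 corresponds
to zero flux and a score of 1 to the starting flux,

$$\mathrm{score} = \frac{L(x) - L(0)}{L(x_0) - L(0)}, \qquad x_0 = 1/m,$$

floored at zero.  With $m = 1$ the population starts at score 1 just
below the saturating shoulder (stabilizing selection, the wild type is
fit); $m > 1$ re-anchors score 1 on the rising limb of the logistic, so
that flux increases carry a real selective advantage (positive-selection
mode).  Population fitness is the weighted geometric mean
$\prod_i \mathrm{score}_i^{w_i}$ over the selected reactions; a single
zero-flux target annihilates it, as it should.  Reference fluxes may be
negative (the proportionalization is signed); a reference flux of exactly
zero is rejected at configuration time because the ratio is undefined.

# Mutation, Haldane coupling, and fixation

**Proposal process.**  Each mutable parameter receives a
$\mathrm{Poisson}(\lambda)$ number of proposals per generation with
$\lambda = 0.003$.  Effects are multiplicative,
$\theta \mapsto \theta(1+\delta)$, with
$\delta \sim \mathcal N(\mu, \sigma)$, $\mu = -1\%$ for every role except
binding constants, where $\mu = +1\%$ because poorer binding corresponds
to a *larger* Michaelis constant.  The standard deviation is not dictated
by the underlying theory; the default $\sigma = 0.01$ keeps most effects
within a few percent, on the same scale as $|\mu|$, and is configurable.
Draws with $1+\delta \le 0$ are redrawn (kinetic parameters are
physically positive).

**Expression versus function.**  A typical enzyme gene exposes on the
order of 250 amino-acid sites to functional change and a comparable
number of expression-affecting sites, so models that parameterize enzyme
concentration $[E]$ should see expression and functional proposals in a
1:1 ratio.  This is implemented per reaction: the reaction's
$[E]$-parameter gets proposal rate $\lambda k$, where $k$ is the count of
that reaction's mutable functional parameters.  Reaction-local parameters
belong to their reaction; a global parameter is attributed to the first
reaction whose rate law references it, a deterministic choice that only
matters for models sharing kinetic constants across reactions.

**Haldane's relationship.**  In a reversible reaction the equilibrium
constant, maximal velocities and Michaelis constants are not free to vary
independently:

$$K_{eq} = \frac{V_f}{V_r}\,\frac{\prod K_{m,P}}{\prod K_{m,S}}.$$

Groups are built for every reaction carrying a forward and a reverse
maximal velocity (or catalytic constant), an equilibrium constant, and
Michaelis constants that can be paired — which requires equal numbers of
substrates and products.  Sides are assigned by name (a substrate or
product species id embedded in the constant's name, or a `KmS`/`KmP`
prefix), falling back to declaration order; reactions that cannot be
paired are skipped and their constants mutate unconstrained.  After any
mutation to a member binding constant the reverse velocity is recomputed
from the identity, holding $V_f$ and $K_{eq}$ fixed.  Two design choices
extend this: mutations to $V_f$ also trigger the $V_r$ update (otherwise
the identity would drift), and both the dependent $V_r$ and all
equilibrium constants are excluded from direct mutation — $K_{eq}$ is a
thermodynamic property of the reaction, not of the enzyme, and $V_r$ is
determined by the constraint.  With these rules the group identity holds
to a relative residual below $10^{-9}$ after every event of a run, which
the test suite verifies over $10^4$ generations.

**Fixation.**  All proposals arising in one generation are applied
jointly, the steady state is re-solved once, and the joint event is
accepted or rejected as a unit with Kimura's diffusion probability

$$P_{fix} = \frac{1 - e^{-2cN_e s p}}{1 - e^{-2cN_e s}},$$

where $s$ is the new/old fitness ratio minus one, $c$ the ploidy, $N_e$
the effective population size, and the initial frequency $p$ is set to
$0.5$ rather than $1/(cN_e)$, which accelerates the neutral walk and
gives neutral mutations a 50% chance of fixing.  The formula is evaluated
in guarded branches: $|2cN_e s| < 10^{-12}$ returns $p$ exactly, and
strongly deleterious arguments use the asymptotic form
$e^{2cN_e s(1-p)}$, so no overflow can occur at realistic $N_e$.  A
proposal set after which the solver fails to converge — or which drives a
selected flux to zero — scores fitness 0; such lethal events are logged
with their nominal probability but cannot fix, since a population at
fitness zero is extinct rather than fixed.  (At biologically meaningful
population sizes the formula assigns them a probability that underflows
to zero anyway.)  On rejection every parameter, including Haldane
partners, reverts bit-identically.

# The steady-state solver

The phenotype computation must succeed thousands of times per run, warm
and cold.  `solveSteadyState` proceeds in three stages: if the starting
point already satisfies the residual tolerance it is returned; otherwise
Newton iteration with a finite-difference Jacobian (step
$10^{-7}\max(|C|,1)$, damped, constrained to non-negative concentrations)
is attempted directly, which almost always succeeds when warm-started
from the pre-mutation steady state; failing that, the system is
integrated with a stiff solver (`deSolve::lsoda`) in geometrically
growing time chunks — clipping negative concentrations to zero — until
the residual $\max_i |dC_i/dt|$ falls below tolerance or a time cap is
reached, and then Newton-polished.  The defaults (absolute tolerance
$10^{-9}$, time cap $10^6$ time units) are ordinary simulation-engine
settings and are exposed in the configuration.  Non-convergence
(divergence, oscillation, unbounded accumulation) is an in-band result,
not an exception; the evolution layer translates it into fitness 0.  The
solver contains no randomized restarts, so identical inputs give
bit-identical results — a property the end-to-end determinism test leans
on.  Boundary species (network inputs and sinks) are held at their
initial concentrations and excluded from both the ODE state and, by
default, from mutation.

# Equilibration and its stopping rule

An imported kinetic model reaches steady state, but it is not at
*evolutionary* equilibrium: under the mutational scheme most parameters
drift systematically until mutation, selection and the Haldane coupling
balance.  Branching a non-equilibrated root would confound this relaxation
with lineage-specific change, so the root population is first burned in.
Stability is detected on non-overlapping windows of 100 consecutive
fixation events: within each window the least-squares slope of the series
(normalized by the window mean, making the verdict invariant to the scale
of the series) and the coefficient of variation are computed, for fitness
and for every reaction flux.  Equilibrium is declared when fitness and at
least 80% of the flux series are flat — $|$slope$| \le 10^{-5}$,
CV $\le 0.01$ by default — over five consecutive windows.  The thresholds
themselves are configuration, not theory; the defaults were chosen so
that the bundled fixtures equilibrate in desk-scale runs, and real models
may need different ones.  Once the criterion is met at generation $g$,
the run continues for another $g$ generations (total $2g$) before
branching, as a safety margin against criteria met by chance.  A hard cap
(default $10^6$ generations) bounds the phase; hitting it is reported,
not fatal.  The equilibrated root — parameter values, reference fluxes,
fitness, proposal counters and RNG state — round-trips losslessly through
a plain-text snapshot, so one equilibration can seed any number of trees
that share the same starting population parameters, or be resumed and
equilibrated further.

# From branch lengths to generations

Branch lengths arrive in millions of years or substitutions per site, and
must be converted to generation counts.  The calibration rests on the
two-percent rule — diverging vertebrate lineages accumulate roughly 1%
sequence difference per lineage per million years — combined with the
per-gene site counts above.  During equilibration the simulator counts
proposals per reaction separately for the enzyme-concentration and the
functional category; the calibration picks the smallest generation at
which the across-reaction average reaches 7 in *both* categories (the
wording "to both" is ambiguous between "both" and "their average"; this
implementation requires both, i.e. the later of the two crossings, the
more conservative reading).  That generation count becomes $G$, the
number of generations per million years, equivalently per 1% divergence.
A branch of length $\ell$ Myr is simulated for
$\mathrm{round}(\ell\,G)$ generations (half-up rounding; a branch that
rounds to zero is simulated for zero generations, which is what
zero-length branches in published trees mean); substitutions per site are
first multiplied by 100 to convert to percent divergence.

Trees must be rooted — an unrooted trifurcation at the root is rejected
with instructions rather than silently re-rooted, since rooting is a
judgment the user should make with dedicated tools.  Polytomies below the
root are accepted behind an explicit flag, each child inheriting
independently.  Simulation recurses depth-first; both children of a node
start from bit-identical copies of its final state, each branch runs with
its own effective population size (uniform, or addressed per branch by
the child node's label, with unlabeled internal nodes auto-labelled
`node<k>`), and no re-equilibration is attempted after a population-size
change — the population simply is out of equilibrium for a while, as real
populations are.  Every branch draws from an RNG stream seeded
deterministically from the run seed and the branch's path from the root,
so sibling branches are statistically independent, the whole run is
reproducible from one integer, and any single branch can be replayed in
isolation.

# Outputs

The canonical outputs are TSVs at full double precision: a mutation log
with one row per proposal (fixed and unfixed, with selection coefficient,
fixation probability and Haldane partner updates), per-branch and
per-lineage trajectories of fitness and all fluxes at every fixation, and
percent-change matrices — rows are lineages or branches, columns are all
model values (fitness, fluxes, steady-state concentrations, parameters),
cells are the percent change from the equilibrated root to the end of the
lineage.  Cells whose reference value is zero are undefined and serialize
as `NA` rather than a silent zero.  Each matrix is also emitted normalized
column-wise by the maximum absolute value, mapping every column into
$[-1, 1]$ with signs preserved.  When several branching replicates are run
from the same root, raw percent changes are averaged cell-wise first and
the average is then normalized (averaging normalized values would weight
replicates by their own extremes).  A manifest with md5 checksums closes
the file set; file names and number formatting are deterministic, so a
repeated run with the same seed is byte-identical.

# The fixtures and what they do and do not show

The package generates its own test models, chosen so that the solver has
closed-form oracles:

* `makeLinearChain(n, v0, Vmax, Km)` — a constant source feeding $n$
  irreversible Michaelis-Menten steps, steady state
  $S_i^* = K_{m,i} v_0/(V_{max,i} - v_0)$, all fluxes $v_0$; with
  $V_{max} \le v_0$ it becomes the deliberate divergence fixture.  Because
  its flux is pinned by the source, every mutation is selectively neutral
  — useful for testing the neutral fixation rate in isolation.
* `makeReversibleChain(n, ...)` — reversible uni-uni steps with $V_r$
  derived from the Haldane identity at construction and names that
  classify without overrides; exercises the coupled-update machinery.
* `makeBranchedFixture()` — one input splitting into two outputs, so
  multi-target selection has real trade-offs; the optional disconnected
  side reaction provides a strictly neutral mutation class, giving the
  fixation-probability histogram its point mass at 0.5.

These fixtures are deliberately small (one to five free metabolites).
They validate the algebra, the solver, the stochastic machinery and the
plumbing; they do not emulate the stiffness, conservation cycles,
allosteric regulation or parameter counts of curated genome-scale kinetic
models, and passing on them says nothing about the biological realism of
any particular published model.  Equilibration tests and the acceptance
script run the fixtures with smaller stability windows (10 fixations, 2
consecutive) and looser flatness thresholds than the defaults, and a few
thousand generations rather than $10^5$–$10^6$; these are the problem
sizes at which the fixtures' behaviour is already unambiguous.

# Numerical and design notes

* Rate laws are restricted to an arithmetic expression tree
  ($+, -, \times, \div$, powers, `exp`); this is a superset of the
  Michaelis-Menten-style laws the method was designed around, and the SBML
  reader rejects anything outside it (events, rules, delays) explicitly
  rather than approximating.
* Compartments are collapsed to volume 1 (concentrations equal amounts);
  function definitions in SBML are inlined at parse time.
* Same-generation proposals are applied jointly with a single
  steady-state recalculation per generation.  Joint evaluation keeps the
  event log unambiguous (one selection coefficient per generation);
  per-proposal sequential evaluation would interleave solver calls and
  make the fixation bookkeeping order-dependent.
* The per-branch seed is a polynomial hash of the run seed and the branch
  path, reduced modulo a prime below $2^{31}$; collisions between the
  handful of branches of a tree are astronomically unlikely, and the
  scheme needs no global stream bookkeeping.
* Windows are indexed by fixation events, not generations, and do not
  overlap; "five consecutive windows" therefore has a single meaning.
* The equilibration doubling rule measures $g$ from the start of the
  current equilibration call, so importing a root and equilibrating
  further doubles only the additional span.

# Known limitations

The network architecture is fixed: no gene duplication, no temporal
regulation, no lineage-specific optima.  There is no explicit population,
hence no heterozygosity or standing variation, and kinetics are
deterministic ODEs — no stochastic (Gillespie) formulation, no lin-log or
power-law approximations.  Exact numerical agreement with any external
simulation engine's steady-state settings is not claimed; the solver is
validated against closed forms instead.
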