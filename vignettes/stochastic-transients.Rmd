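---
title: "Decomposing stochastic population dynamics into asymptotic and transient components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing stochastic population dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochtrans)
```

## The model

A stage-classified population is projected by a non-negative square
matrix of vital rates, $\mathbf{x}(t+1) = \mathbf{A}(t)\,\mathbf{x}(t)$.
In a constant environment the long-run growth rate is the dominant
eigenvalue $\lambda_{max}$ of $\mathbf{A}$ and the population converges
to the stable stage structure $\mathbf{w}$, its dominant right
eigenvector. In a variable environment neither condition holds: the
matrix changes from year to year and the stage structure is perpetually
displaced from the (moving) stable structure. Each time step then
factorizes exactly into an asymptotic and a transient part,

$$\lambda_{obs}(t) \;=\; \frac{\lVert \mathbf{A}(t)\mathbf{x}(t)\rVert_1}
   {\lVert \mathbf{x}(t)\rVert_1}
 \;=\; \lambda_{max}(t)\cdot reactivity(t), \qquad
 reactivity(t) = \left\lVert \frac{\mathbf{A}(t)}{\lambda_{max}(t)}
   \frac{\mathbf{x}(t)}{\lVert \mathbf{x}(t)\rVert_1}\right\rVert_1 ,$$

additively on the log scale:
$\log\lambda_{obs} = \log\lambda_{max} + \log reactivity$. Reactivity
above one is transient amplification (*boom*), below one attenuation
(*bust*); at $\mathbf{x} \propto \mathbf{w}$ it is exactly one.

Net growth hides antagonism: a step in which strong asymptotic growth
is cancelled by strong attenuation looks identical to a step in which
nothing happens. The *absolute dynamic*
$\log\lambda_{abs} = |\log\lambda_{max}| + |\log reactivity|$
distinguishes them, and $|\log reactivity| / \log\lambda_{abs}$ is the
per-step share of the absolute dynamic owed to transients. We use the
natural logarithm throughout, the standard convention for demographic
growth rates. The absolute dynamic is built from $\log\lambda_{max}$
and $\log reactivity$ only — it is the magnitude-wise counterpart of
the additive decomposition above, which is what makes the triangle
inequality $\log\lambda_{abs} \ge |\log\lambda_{obs}|$ hold with
equality exactly when the two components agree in sign.

## Eigen-analysis conventions

`dominant_eigenvalue()` returns, among the modulus-maximal eigenvalues,
the one with the largest real part: for a non-negative matrix this is
the Perron root even when a periodic (imprimitive) pattern places
complex eigenvalues on the same circle. Imprimitive-but-irreducible
matrices are accepted without complaint — the pipeline only needs
$\lambda_{max}$ and $\mathbf{w}$, both well defined there, and stage
patterns without self-loops do occur in published matrices. We chose
not to emit a warning on every such call: the ergodicity diagnosis is
available explicitly through `is_ergodic()` (irreducibility via strong
connectivity of the nonzero pattern, primitivity via Wielandt's bound
$B^{s^2-2s+2} > 0$), and a per-call warning would fire thousands of
times inside a simulation while telling the user nothing new.
A dominant eigenvalue is treated as real when
$|\mathrm{Im}| \le 10^{-8}(1+|\mathrm{Re}|)$, which absorbs
floating-point dust without masking genuine complex dominance.
Matrices whose dominant eigenspace is not one-dimensional (e.g. the
identity pattern) raise an ergodicity error from `stable_structure()`;
during database simulation such populations are skipped with a logged
reason rather than guessed at.

## Simulation protocol

Each replicate starts from equal abundance in every stage,
$\mathbf{x}(0) = (1/s,\dots,1/s)$, and is projected through a burn-in
of 500 steps (default), drawing the annual matrix i.i.d. uniformly —
with replacement, no environmental autocorrelation — from the
population's matrix set. A fresh matrix is drawn for the measured step
after burn-in; drawing fresh (rather than reusing the last burn-in
matrix) is the reading consistent with an environment drawn anew each
interval. One decomposition is recorded per replicate, 1000 replicates
per population by default, so each population contributes 1000 measures
of each metric.

The stage vector is renormalized to unit one-norm every step. All four
metrics depend on $\mathbf{x}$ only through
$\mathbf{x}/\lVert\mathbf{x}\rVert_1$, so renormalization provably
changes nothing (the test suite verifies this against raw iteration
over short horizons) while preventing overflow across 500 multiplicative
steps. Replicates whose projected abundance hits exactly zero are
excluded and counted; with the strictly positive matrices the generator
produces this never occurs.

Reproducibility: each population is simulated under its own RNG stream
whose seed is a deterministic hash of the population id mixed with the
global seed. Results are therefore bit-identical across runs *and*
independent of the order (or parallel schedule) in which populations
are processed.

## Partitioning

Per population, the share of variance in $\log\lambda_{obs}$ explained
by each component is the squared Pearson correlation (sample
normalization) of the 1000 replicate values of $\log\lambda_{obs}$ with
$\log\lambda_{max}$ and with $\log reactivity$ respectively. The two
$R^2$ need not sum to one because the components covary. The transient
share of the absolute dynamic is the mean over replicates of
$|\log reactivity| / \log\lambda_{abs}$; replicates with
$\log\lambda_{abs} = 0$ carry no information about the split (0/0) and
are excluded with a logged count rather than assigned an arbitrary
value. A population in which a component has exactly zero variance
(e.g. a single-matrix population, where reactivity is identically one
after burn-in) has no defined partition and raises a classed error
naming the degenerate component.

## The synthetic database generator

No public matrix collection ships with this package; instead the
generator builds databases with the same statistical silhouette as the
large published compilations of plant projection matrices: about 100
species contributing one to a few populations each (200–280 populations
in total), 3+ annual matrices per population, stage counts between 2
and 15 with mean near 5.3, growth-form labels dominated by herbaceous
perennials, and asymptotic growth rates tightly distributed around 1.

Each population gets a Lefkovitch-type skeleton — stasis on the
diagonal, progression on the subdiagonal, weak retrogression above,
fecundities in the top row of the upper stages — with archetype
weightings per growth form (trees and palms: high stasis, low fecundity
variance; herbs: the reverse). Annual matrices apply multiplicative
year-to-year noise: lognormal and mean-preserving on fecundities,
Gaussian on the logit scale for survival rates so that survival stays in
$(0,1)$; a final safeguard rescales any survival column that would
exceed total survival of 1. Fecundities are then rescaled by a common
factor so the dominant eigenvalue of the element-wise *mean* of the
annual matrices hits its target exactly (root-finding to $10^{-6}$ on
the log scale); targets are drawn per population as
$N(0, 0.05^2)$, keeping growth rates near stationarity as observed for
plants. The baseline temporal CV defaults to 0.3, a typical magnitude
for year-to-year variation in plant vital rates; species carry a
lognormal random intercept on their CV (SD 0.3 on the log scale) so
that the species random effect in the comparative models is real rather
than cosmetic. An optional `dimension_effect` couples matrix dimension
to the realized CV for effect-injection experiments.

What the generator does *not* emulate: observed covariance between
vital rates within a year, density dependence, demographic
stochasticity, taxonomic or phylogenetic structure, and the messiness
of real matrix collections (seed banks, clonality, varying stage
definitions). Passing tests on synthetic databases therefore
demonstrates correctness of the pipeline's arithmetic and statistics
under known conditions — not that any particular empirical effect size
will recur in real data.

### The recovery family

Testing whether the comparative model recovers a known dimension effect
requires a generator in which the *injected truth is analytic*. The
realistic generator cannot provide that: the mapping from vital-rate
noise to the transient share is emergent. The package therefore
includes a second, deliberately stylized family
(`generate_recovery_database`) built from rank-one matrices
$\mathbf{A} = (\lambda / \mathbf{v}'\mathbf{u})\,\mathbf{u}\mathbf{v}'$.
Rank-one projection collapses any stage vector onto the matrix's own
profile $\mathbf{u}$ in a single step, so the stage structure at the
measured step is exactly the profile of the previously drawn matrix.
With two profiles and two asymptotic rates $e^{\pm a}$ per population,
$|\log reactivity|$ takes exactly two values — zero when the
environment repeats a profile (probability 1/2), a dimension-tuned
constant $b$ on a switch — and the expected transient share is exactly
$\tfrac12 \cdot b/(a+b)$. Choosing $b$ per population makes the
expected share follow $\mathrm{logit}^{-1}(\beta_0 + \beta_{dim}\,s +
u_{species})$ with a slope $\beta_{dim}$ that is known *a priori*, not
calibrated by simulation. The construction caps the attainable share at
one half (a repeated environment contributes no transient), so the
defaults keep every population's injected share below 0.475 and species
intercepts are truncated at two standard deviations.

## Comparative models

Proportion responses are logit-transformed after clamping to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$ — smaller
than any resolution attainable from 1000 replicates, so the clamp only
guards exact 0/1. The contribution models regress the transformed
response on growth form and matrix dimension with a species random
intercept. Growth forms are coded as one intercept per form (no
reference level), which makes per-form predictions and their intervals
directly comparable; the dimension slope is shared. A fixed effect is
*important* exactly when its 95% interval excludes zero — no p-value
threshold substitutes for this rule.

Inference backend: restricted maximum likelihood via `lme4`, with
Satterthwaite-degree-of-freedom t intervals from `lmerTest`. The
scientific content of the analysis rests on interval semantics and the
interval-excludes-zero rule, not on a particular sampler, and an ML
mixed model with t intervals delivers those semantics at a fraction of
the cost of MCMC; the boom test reports the two-sided Satterthwaite
p-value as its tail probability, the frequentist analogue of a
posterior sign probability. Degenerate designs fall back gracefully:
with a single population per species the random intercept is
unidentified and the model collapses to ordinary least squares (the
test suite pins this to the `lm` oracle); a response with literally
zero residual variance, which breaks the mixed-model covariance
computation, takes the same fallback. The association tests additionally
report a likelihood-ratio statistic from ML refits against the no-slope
null.

## Numerical and design choices

* **Problem sizes.** Unit tests run on databases of 6–25 species with
  reduced replicate counts; the recovery experiment uses 20 syntheses
  of 30 species × 2 populations at 200 replicates; the acceptance
  script runs the full ~200-population study at 1000 replicates. These
  sizes give stable Monte-Carlo behaviour while keeping a full check
  run in minutes on a single core.
* **Eigen tie-breaks.** Modulus ties resolved by maximal real part
  (Perron root); dominant-eigenspace multiplicity checked within
  $10^{-9}$ relative tolerance.
* **Feasibility.** A growth-rate target below the survival-only
  dominant eigenvalue cannot be reached by scaling fecundity and raises
  a classed infeasibility error; the database generator retries a fresh
  skeleton a few times before giving up.
* **Exchange format.** Matrix collections travel as long-format CSV
  (one row per entry, 1-based indices, 17 significant digits) so that
  write–read round-trips are exact and external collections can be
  converted in from any source; the native serializations of public
  databases are intentionally not parsed here.

## Limitations

The pipeline measures one step after burn-in, per the protocol it
implements; it says nothing about multi-step transient envelopes,
maximal amplification bounds, or inertia. Environmental sequences are
i.i.d. — no autocorrelation, no observed-sequence ordering. The
comparative models assume Gaussian residuals on the logit scale and a
single variance component for species; phylogenetic covariance
structures are out of scope. Empirical claims about real plant
populations require a real matrix database supplied through the CSV
exchange format.
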