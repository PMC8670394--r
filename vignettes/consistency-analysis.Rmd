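---
title: "Ontology-guided consistency analysis of acid-base state dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-guided consistency analysis of acid-base state dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abstate)
```

## The problem

Intensive-care and surgical teams monitor a patient's acid-base state (ABS)
through a panel of 21 blood-gas and electrolyte parameters — pH, oxygen and
carbon dioxide partial pressures, bicarbonates, base excess, the major ions,
glucose, lactate and derived quantities (`abs_parameter_table()`).  The
organism regulates these parameters as one system: what carries clinical
information is not any single value but the *consistency* of the whole
parameter system and how that consistency shifts across the peri-operative
time course.  Analyzing such data requires a chain of non-trivial choices —
how to impute values missing not at random, which multivariate statistic
captures system consistency, how to detect structural change over time —
that clinicians without data-mining training resort to trial and error for.

`abstate` implements both halves of a knowledge-driven answer:

1. **A knowledge-base engine and packaged DM knowledge.**  Data-mining
   expertise is stored as a typed entity/axiom graph (concepts, properties,
   subsumption hierarchies, existential restrictions, instances).  A domain
   ontology is merged into the DM core, the task-relevant sub-ontology is
   extracted, and conjunctive description-logic queries select the
   algorithm for each step of a CRISP-DM style workflow.
2. **The selected analysis methods.**  K-nearest-neighbour imputation with
   Euclidean distance; the criteria function (CF), a Mahalanobis-type
   quadratic form measuring a patient's departure from a reference
   correlation structure, with exact branch-and-bound feature-subset
   search; the Kupershtokh–Mirkin–Trofimov (KMT) partition functional that
   decomposes the parameter system into functional subsystems; and
   Mann–Whitney comparisons between groups and time points.

A synthetic cohort generator reproduces the statistical structure of the
study setting (391 cardiac-surgery patients in three groups, six time
points) so that every stage is testable end to end without clinical data.

## The knowledge model

A knowledge base is a five-tuple: concepts $C$, properties $R$, a concept
hierarchy $H^C$ (`subClassOf`), a property hierarchy $H^R$
(`subPropertyOf`), and instance assertions $I$.  Axioms additionally
include existential restrictions $C_1 \sqsubseteq \exists P.C_2$, which are
the load-bearing links: `KNN_Imputation_ED suitableFor some
Missing_not_Random`, `CF employedBy some ConsistencyModelling`,
`MissingValueProcessing hasInput some DataWithMissingValue`, and so on.

Queries are conjunctions of named classes and existential atoms
(`Algorithm and suitableFor some SmallSizeDataset`).  A named class $X$
answers the atom $\exists P.C$ when some restriction
$X' \sqsubseteq \exists P'.C'$ exists with $X \sqsubseteq X'$,
$P' \sqsubseteq P$ and $C' \sqsubseteq C$ in the reflexive–transitive
closure; individuals answer through their class and property assertions.
This deliberately covers only the constructs the workflow queries need —
conjunction and existential restriction over named fillers; there is no
negation, cardinality, or tableau reasoning.

Merging rewrites both axiom sets into one namespace; entities sharing a
local name unify (that is how `ConsistencyAnalysis` in the medical ontology
connects to the algorithms the DM core links to it), and a shared name with
two different kinds is an error rather than a silent repair.  Byte-identical
duplicate axioms are stored once; nothing else is deduplicated.

Extraction walks from the task entity along subclass/subproperty edges
upward and restriction edges in both directions to a fixed point, keeping
instance assertions of kept classes, then retains exactly the axioms whose
full signature survives.  On the packaged content this keeps the
descriptive algorithms, the imputation branch and the stage scaffolding
while dropping classification and clustering knowledge that is not on any
restriction path from `ConsistencyAnalysis` — and the workflow built on the
extracted sub-ontology is identical to the one built on the full merge,
which the test suite asserts.

## Workflow construction

`build_workflow()` runs the stepwise query procedure: stages of the task,
processes of each stage, the processes the current data profile makes
*required* (all `hasInput` characteristics satisfied under subsumption; a
process with no input restriction is an organizational step), and the
suitable algorithm per process (every `suitableFor` condition of the
candidate matched by a profile characteristic or the task itself).  All
co-optimal algorithms are reported in lexicographic order — the
consistency-analysis task legitimately selects two data-processing
algorithms.  After each selected preprocessing step the profile is updated
from the process's output restrictions (inputs consumed, data-characteristic
outputs added, characteristics that merely qualified a consumed one lapse
with it), which is the query–execute–estimate cycle: once imputation has
produced `DataWithoutMissingValue`, rebuilding yields a workflow without an
imputation process.

Two rules had to be made concrete where the knowledge model is silent:

* **MNAR detection.**  Nothing in a dataset announces that its missingness
  is not at random.  `profile_data()` uses a logistic screen: the
  missingness indicator of each entry is regressed on the absolute
  standardized value of the same parameter at the adjacent observed time
  point; association at $p < 0.05$ flags `Missing_not_Random`, otherwise
  `Missing_Random`.  The screen has power because consecutive measurements
  of one patient are correlated; it is overridable by passing an explicit
  characteristic vector.
* **Objective conversion.**  The mapping from a clinical objective to a DM
  objective is a knowledge-base lookup (a data property on the task),
  not an inference.

## The criteria function

For a parameter subset $A_m$ of size $m$, a standardized patient vector
$X_m$ and the correlation matrix $S_m$ of a reference group,

$$C(A_m) = X_m^{\top} S_m^{-1} X_m .$$

When the patient is drawn from the reference distribution,
$E\,C(A_m) \approx m$; departures of the mean CF above $m$ measure loss of
consistency with the reference structure.  Two referencing schemes are
provided:

* `reference = "baseline"` (default): each group's first time point supplies
  the standardization and $S_m$, so the CF trajectory measures departure
  from the group's baseline state.  This is the scheme under which group
  and time-point contrasts are meaningful.
* `reference = "cell"`: every group × time-point cell is self-referenced.
  Then the mean CF is pinned near $m$ in *every* cell by construction —
  useful as a calibration check, useless for contrasts; the package
  defaults to the baseline scheme for exactly that reason.

The quadratic form is monotone under subset nesting ($A \subset B$ implies
$C(A) \le C(B)$ for every patient, by the positive-definite Schur
complement), which gives the branch-and-bound subset search an exact upper
bound: the mean CF of a partial selection plus all remaining candidates
bounds every completion, so pruned branches provably contain no optimum.
The search is exact for the sizes used here (a sweep over $m$ with $n=21$);
the test suite verifies it against exhaustive enumeration.  Which $m$ the
original analysis used is not recoverable, so the package reports the full
$m$-versus-objective profile rather than one preferred size.

## The KMT partition functional

The parameter set $R$ is decomposed into disjoint classes $R_s$
("functional subsystems") by locally maximizing

$$F(a, R) = \sum_s \sum_{i<j \in R_s} (a_{ij} - a),$$

where $a_{ij}$ is the link indicator between parameters $i$ and $j$ and $a$
is the link-importance threshold.  Each unordered pair is counted once, so
the all-singleton partition is the natural zero baseline, and for a fixed
partition $F$ is linear in $a$ with slope $-$(number of within-class
pairs).  Links default to $|r|$ (Pearson): the functional treats a link as
an importance magnitude, and negative physiological couplings are still
couplings; a signed mode exists for users who disagree.

Optimization is greedy agglomeration from singletons followed by
single-element relocation to a 1-move local maximum, taken over 20 seeded
restarts; the returned partition always carries a 1-move optimality
certificate, and on seven-parameter instances the search matches exhaustive
enumeration over all 877 partitions in well over 95% of cases.  Exact
global optimization is out of reach in general — the objective is of the
NP-hard correlation-clustering family — so the certificate plus restart
agreement is the honest guarantee.

`scan_threshold()` reports the three indicators (functional value,
threshold, class count) along a grid.  The *selected threshold* is the
point where the optimal partition first becomes non-trivial — the level at
which the system decomposes, which tracks the strength of cross-subsystem
links.  The full scan table is always returned, so no convention hides
information.  An earlier candidate rule — maximize $F$ penalized by the
class count — degenerates: the single-class partition at $a=0$ always
wins, freezing the threshold dynamics at zero, and was rejected.

`functional_dynamics()` computes the indicator triple per group and time
point and defines each group's *critical period* as the consecutive
time-point interval with the largest absolute change in $F$ (and,
separately, in the selected threshold).  One stabilizing convention
matters here.  The functional evaluated right at the decomposition
boundary is dominated by the coarsest two-class partition and is
numerically fragile: its value jumps by the within-pair count times one
grid step whenever the boundary moves by a single point, which is sampling
noise, not physiology.  The reported $F$ and class count are therefore
evaluated at a *fixed reference threshold* (`f_reference = 0.3` by
default, midway between typical cross-subsystem and within-subsystem link
levels), identical across every group and time point, so that the $F$
dynamics measure changes in link strength against a stable yardstick while
the selected threshold separately reports where the decomposition boundary
moved.

## Mann–Whitney comparisons

`mann_whitney()` uses the pair-count convention
$U = \#\{x_i > y_j\} + \tfrac12\#\{x_i = y_j\}$, computed from midranks.
For $n_1 + n_2 \le 20$ the p-value is exact by full enumeration of all
$\binom{n_1+n_2}{n_1}$ labelings — valid under ties, which is why the
enumeration is done directly rather than delegated to `stats::wilcox.test`
(the reference implementation refuses exactness under ties; it serves as a
cross-check on tie-free samples in the tests).  Larger samples use the
normal approximation with tie-corrected variance and no continuity
correction.  `comparison_suite()` runs the study-style contrasts: each pair
of groups on per-patient CF averaged over time, and the baseline point
against each later point within each group and overall.  Per-patient CF is
the only statistically coherent unit for these tests; group-mean replicates
would manufacture precision.  No multiplicity correction is applied by
default, matching the descriptive reporting style the analysis mirrors;
Holm correction is a flag away.

## The synthetic cohort

`cohort_config()` encodes the study conditions: 391 patients in three
near-equal groups (131/130/130; the exact split is not recorded anywhere,
so near-equal thirds is the default), six time points, the 21 ABS
parameters in four planted correlation blocks (sizes 6+5+5+5, within-block
correlation 0.7, cross-block 0.1).  Per group and time point, values are
multivariate normal with the scheduled block-correlation matrix and mean
shift; a patient's consecutive time points are tied by a latent AR(1)
process ($\phi = 0.5$) that preserves unit marginal variance — without that
persistence no adjacent-time screen could ever detect MNAR, and real
repeated measurements are strongly autocorrelated.  The MNAR mask makes an
entry's missingness log-odds increase with its absolute standardized value
(coefficient 1 per SD around a 10% base rate).

The schedule is the package's one-time statement of the study conditions it
emulates, chosen so the generator realizes the qualitative structure the
analyses are meant to detect and then left alone:

* a time profile that is nearly flat across points 1–5 and jumps at
  point 6, so the largest structural shift of groups 1 and 2 falls in the
  5→6 interval;
* group 2 perturbed much more strongly than group 1: mean shifts of 2.5 vs
  1.0 SD at the final point, a within-block correlation drop of 0.36 vs
  0.13, and a cross-block rise of 0.16 vs 0.03 (capped so the block
  structure never inverts), making group 2 the unstable group in both KMT
  indicators;
* group 3 near-constant (amplitudes an order of magnitude smaller), so its
  variations are smallest.

What the generator does *not* emulate: physiological ranges and units of
the parameters (everything is on the standardized scale), non-Gaussian
tails unless `tails_df` is set, informative dropout of whole patients, and
measurement error structure.  Passing tests therefore demonstrate that the
pipeline detects the planted structure under its own assumptions — block
correlations, Gaussian margins, logistic MNAR — not that it would detect
arbitrary clinical signals.

## Numerical choices

* Correlation matrices get an escalating ridge $S + \lambda I$ (from
  $10^{-6}$) only when the condition number exceeds $10^{10}$; constant
  columns are an error naming the column, never silently dropped.
* KNN imputation standardizes columns, measures Euclidean distance on the
  jointly observed coordinates rescaled by $\sqrt{p/\#\text{shared}}$,
  breaks distance ties by row index, and imputes within one time point
  only, so post-operative dynamics never leak backwards.  $k = 5$ by
  default; the selection knowledge names the algorithm but not $k$, so the
  value is an implementer's default, exposed in the API.
* Partition search restarts default to 20, all seeded; every reported
  partition passes the 1-move certificate.
* The threshold grid for the KMT scan defaults to steps of 0.0125 on
  $[0, 0.6]$, shared across cells so thresholds are comparable over time;
  the fine step keeps quantization of the decomposition boundary well
  below its sampling noise.
* All randomness flows from explicit integer seeds; generator and pipeline
  restore the caller's RNG state.

## Problem sizes in the tests

The test suite exercises the oracles at sizes where exhaustive truth is
computable: subset search against all $\binom{10}{4}$ subsets, partition
search against all $B_7 = 877$ partitions, query answering against
brute-force satisfaction on KBs of up to ~20 entities, Mann–Whitney against
all $\binom{10}{5}$ labelings, and planted-partition recovery at the full
cohort size ($n = 391$, 20 seeds).  Null calibration of the exact test uses
800 replicates at $n_1 = n_2 = 8$.  These sizes are chosen so the complete
suite runs in minutes on one core while each claim is still checked against
an independent computation.

## Known limitations

The DL fragment is intentionally small; ontologies relying on negation,
universal restrictions or cardinality will not round-trip.  The KMT
optimizer certifies local, not global, optimality beyond enumeration
sizes.  The MNAR screen detects value-dependent missingness through
temporal persistence and will miss mechanisms driven by unmeasured
covariates.  CF contrasts inherit the usual caveat of baseline-referenced
designs: a drifting baseline inflates every later CF.  And the synthetic
cohort is a structural emulation, not a clinical simulacrum — conclusions
about real ABS data require the real data.
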