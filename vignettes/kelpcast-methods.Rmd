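---
title: "Methods: niche modelling with dispersal-latency range reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: niche modelling with dispersal-latency range reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Annual kelps such as *Saccorhiza polyschides* have a two-phase life cycle:
macroscopic sporophytes recruit each spring, release spores in late summer,
and die; microscopic gametophytes overwinter and can arrest development
("latency") through unfavourable years. At a warm range edge, whether a
stretch of coast holds kelp in a given year therefore depends on three
things at once: whether the *seasonal extremes* of that year (and the
preceding winter) were tolerable, whether the cell held a population
recently enough for dormant stages to re-found it, and whether a nearby
population could re-colonize it by spore dispersal. `kelpcast` implements
this chain as a testable pipeline: seasonal extreme-event predictors from
daily fields, a constrained niche model, and a dispersal-latency occupancy
automaton whose two parameters are estimated by grid search.

Because the real inputs (satellite SST, reanalysis waves and winds,
decades of survey compilations) are far beyond desk scale, the package
ships a first-class synthetic world with known ground truth. Every claim a
test makes is a claim about that stated world.

# Seasonal predictors

Seasons follow the species' phenology: spring (MAMJ), winter (ONDJF) and
previous summer (JAS). Winter of predictor-year *t* spans October–December
of *t − 1* plus January–February of *t*: spores settle in autumn and the
vulnerable gametophyte stage overwinters into the recruitment spring. The
month sets are configurable (`season_definition()`); ONDJF is the default
winter.

The default predictors are extreme-event statistics, not means:

| predictor | statistic | why it matters |
|---|---|---|
| `sst_winter_run18` | longest run of winter days with SST > 18 °C | fertilization of female gametophytes fails above ~18 °C |
| `sst_spring_run18` | longest run of spring days with SST > 18 °C | warm, nutrient-poor spring water halts recruitment |
| `sst_winter_max` | winter maximum SST | acute thermal limit of overwintering stages |
| `cui_spring_runfav` | longest run of spring days with CUI > 16 m³/s | persistent upwelling supplies nutrients for recruitment |
| `swh_winter_max` | winter maximum significant wave height | storm disturbance |
| `swh_spring_run3` | longest run of spring days with waves > 3 m | sustained disturbance during recruitment |

"Above" is strict (>) throughout, and "consecutive days" is read as the
longest maximal run (not the total count of qualifying days) — the natural
reading for a cumulative physiological stress, flagged here because the
distinction is rarely stated in print.

The coastal upwelling index is the Bakun convention: wind stress
$\tau = \rho_{air} C_d |W| \vec W$, Ekman transport per unit coastline
$\vec Q = (\tau_y / (\rho_{sw} f),\; -\tau_x / (\rho_{sw} f))$ with
$f = 2\Omega \sin(\mathrm{lat})$, projected on the local offshore normal
and reported per 100 m of coastline. Constants (`cui_params()`):
$\rho_{air} = 1.22$ kg/m³, $C_d = 1.4\times10^{-3}$,
$\rho_{sw} = 1025$ kg/m³, $\Omega = 7.2921\times10^{-5}$ rad/s. These are
the standard Bakun values; they make the conventional 16 m³/s
favourability threshold dimensionally meaningful. Latitudes within 1° of
the equator are rejected (Coriolis singularity).

# Niche model

Training absences are *pseudo-absences from outside the ecological
space*, not survey absences (a cell may be empty for dispersal reasons
alone). Predictors are z-scored over all cells; presence cells define a
Mahalanobis centroid; suitability is the upper chi-square tail of
$D^2$ with df = number of predictors (the canonical transform for
normalized data — the choice of transform is a design decision, as is
normalizing over all cells rather than presences only). Cells with
suitability ≤ 0.2 (presence cells excluded) are stratified by K-means with
k = number of presences, and one cell is drawn per cluster, so pseudo-
absences always match presences in number. Empty clusters are topped up
from the largest clusters to preserve the count.

The learner is Bernoulli gradient boosting with per-feature monotone
constraints: negative for SST- and SWH-derived predictors, positive for
CUI-derived ones. No pre-installed R backend offers monotone boosting, so
the package carries a small Rcpp engine (xgboost-style: constrained splits
must order child values; node bounds clamp every leaf beneath them). The
canonical tuning grid — trees 100–10000 step 50, learning rates
{0.01, 0.005, 0.001}, tree complexity 1 to the subset size, bag fraction
0.5 — is selected by 10-fold cross-validation on holdout deviance, with
tree counts evaluated as checkpoints of a single boosting run per
(rate, depth, fold). Rates or tree counts off the canonical grid are
rejected unless explicitly overridden. Tests use reduced grids purely for
runtime; the defaults are the canonical grid.

One model is fitted per predictor subset in which all pairs have Spearman
|R| < 0.8. Transferability is scored by temporal cross-validation: fit on
one survey year, score on the other, both directions. The score is the
Minimum Predicted Area (MPA): the fraction of test cells predicted
suitable at the *largest* threshold that keeps test sensitivity ≥ 0.9
(ties in the threshold search break toward the larger cutoff, i.e. the
smaller area, since MPA is minimized). The ensemble is the subsets within
the lowest decile of the mean-MPA range — "most transferable" is not a
sharp rule in the source methods, so the decile is a configurable design
choice — refit on the pooled years and averaged per cell-year.

Per-predictor contributions are exposed under two operationalizations,
because the source wording conflates them: `"reduction"` (default)
averages the MPA drop over paired subsets (M vs M ∪ {p});
`"one_minus_mpa"` transforms the mean MPA of subsets containing p as
1 − MPA. Both are rescaled to sum to 100.

# The occupancy automaton

Ensemble probabilities are binarized at the MPA threshold (suitable iff
probability ≥ threshold). Occupancy then evolves from the earliest
suitability map: a suitable cell *i* is occupied at year *t* iff

1. **latency** — *i* was occupied in some year of {t−1, …, t−L}, or
2. **rescue** — some other cell occupied at t−1 lies within D km of *i*
   along the coast (inclusive comparison, shortest path along the coastal
   chain).

Two readings of the latency wording exist; the window reading above is the
default because the literal "exactly t − L" reading would forbid plain
year-to-year persistence at L > 1, which is biologically incoherent. The
literal reading remains available (`latency_window = FALSE`). L = 1 is
simple persistence; the "no dispersal, no latency" baseline is the
no-dispersal mode (D = 0, L = 1), with an L = 0 variant exposed for the
stricter reading of "no latency". Rescue looks only at t−1 — dormant
stages travel in time, spores in space, and spores are produced by extant
populations.

(D, L) are estimated by exhaustive search, D ∈ 1–500 km step 1 ×
L ∈ 1–5 yr step 1 (2500 candidates), scoring each reconstruction against
all records pooled over space and time with the True Skill Statistic
(TSS = sensitivity + specificity − 1) and reporting the margin over the
baseline. Pooling (rather than averaging per-year TSS) is the default
because records are sparse within years. Ties break toward highest TSS,
then smallest L, then smallest D — parsimony. The automaton core is C++;
an independent brute-force oracle that literally re-evaluates both
conditions over all cell pairs and lag years backs it in the tests, and
the suite checks the nesting invariants (occupancy ⊆ suitability;
monotone growth in D and L; no-dispersal ⊆ explicit ⊆ unlimited).

# The synthetic world

`default_world()` states the conditions once:

* a 150-cell chain at 5 km spacing (~750 km, 0.05° cells, 25 km² each),
  laid roughly south–north so "equatorward" is well defined; a chain
  realizes shortest-path coastal distances exactly;
* SST = latitudinal mean (17 °C at 40°, −0.6 °C per degree poleward)
  + a 3.5 °C seasonal sinusoid peaking in late August
  + a 0.25 °C/decade warming trend (applied per calendar year, so trend
  examples are exact) + AR(1) anomalies (φ = 0.8; coast-wide sd 0.4 °C,
  per-cell sd 0.15 °C) + additive heat-wave pulses in the calendar years
  of the region's documented events (1988–90, 1996–98, 2003–04, 2006–07),
  hitting the southern half of the coast;
* a southern upwelling zone with year-round equatorward alongshore wind
  (7 m/s) and 2.5 °C surface cooling — the cooling is what makes the zone
  a refugium under a winter-limited niche, mirroring how real upwelling
  cells buffer warming;
* the true niche: suitable iff the winter >18 °C run stays below 25 days
  and winter maximum SST stays below 23 °C (the gametophyte survival
  ceiling); truth occupancy = the automaton at D* = 5 km, L* = 2 yr;
* surveys: perfect-detection reads of the truth with visits drawn with
  replacement (duplicates collapse to unique gridded cell-years, presences
  taking precedence on conflict — a stated guess, since detection is
  perfect here conflicts cannot actually arise);
* calendar: 365-day years. No leap days means constant season lengths and
  exactly periodic degenerate climates, at the cost of a ~0.07 % drift
  from the real calendar, irrelevant to any quantity computed here.

Every noise component is drawn before episode pulses are added, so
toggling one component changes nothing else — the additivity the test
suite relies on. What the world does *not* emulate: 2-D ocean structure,
tides, wave spectra, imperfect detection, abundance. A green test
establishes that the algorithms recover what this world hides, not that
the real ocean behaves like the world.

# What the numbers mean, and limits

With records read from the *true* occupancy, the grid search recovers
(D* = 5, L* = 2) in ≥ 80 % of seeded replicates (ties resolved by
parsimony occasionally return L = 1 when the records never witness a
2-year bridge). In the full pipeline the search runs on *modelled*
suitability, and niche-model error is partly absorbed into (D, L) — runs
of `run_pipeline()` typically return larger D than the truth. That is a
property of the method, not a bug: the source study's estimate is likewise
conditional on its niche model.

The acceptance contract is property-based (automaton-oracle equivalence,
nesting invariants, parameter recovery, metric identities, the worked
upwelling example, the 2500-candidate grid); the source study's headline
accuracy numbers depend on its proprietary-scale inputs and are treated as
qualitative references only. `scripts/acceptance.R` runs the seeded
end-to-end pipeline and writes an (empty) target object, since no numeric
targets are defined at desk scale.
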