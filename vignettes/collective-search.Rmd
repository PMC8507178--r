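---
title: "Scoring, metrics and simulation of collective chemical-space search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, metrics and simulation of collective chemical-space search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In a goal-directed design experiment, participants (or simulated agents)
repeatedly draw and modify molecular structures while a single scalar score
tells them how close each saved structure is to a hidden target molecule.
Experiments run in two modes that differ in one setting only: in
*individual* mode every participant can reopen only their own saved
molecules; in *collective* mode everyone can reopen anyone's. The package
provides everything needed to score such experiments, to analyse their
event logs, to compare them with published automatic de novo designers, and
to generate synthetic logs with the same structure.

# The molecular score

The in-app score of a molecule $m$ against target $t$ is the count-vector
Tanimoto similarity of their ECFC4 fingerprints folded into 1024 buckets,

$$ S(m, t) = \frac{\sum_k \min(c_k(m),\, c_k(t))}{\sum_k \max(c_k(m),\, c_k(t))}, $$

linearly normalised to the 0--1000 range with half-away-from-zero rounding,
so a similarity of 0.7216 displays as 722. The dot-product count
generalisation $a\cdot b/(|a|^2+|b|^2-a\cdot b)$ is available as
`tanimoto_count(..., variant = "dot")`; which of the two the original
scoring stack used for count vectors is not documented, so the choice is a
recorded configuration value (`score_config()`) embedded in every report.
The min/max form is the default because it is the common count-vector
reading of Tanimoto similarity.

## The fingerprint engine

`count_fingerprint()` enumerates circular atom environments of radius 0, 1
and 2 (diameter 4) around every heavy atom. Initial atom identifiers hash
the invariant (atomic number, heavy degree, total hydrogen count, formal
charge, ring membership); each round rehashes the sorted (bond label,
neighbour identifier) pairs. Bond labels are the kekulé orders 1/2/3 plus a
dedicated aromatic label, so symmetry-equivalent aromatic environments
collapse to a single identifier. Environments whose bond set was already
covered by an earlier environment describe the same substructure and are
dropped; surviving identifiers fold into 1024 buckets by modulus, and
counts accumulate per bucket.

Two facts shape the validation strategy:

* the *total count* (environments surviving deduplication) is independent
  of any hashing choice, and reproduces the published reference totals for
  all five benchmark drugs (45/71/85/87/86);
* the *cardinality* (nonzero buckets) depends on how a toolkit's
  identifiers collide when folded into 1024 buckets. The engine reproduces
  the published cardinalities of the three lowest complexity levels
  (33/41/51) exactly; for the two highest it computes 55 and 57 against
  published 53 and 54, which are collision artefacts of the original
  toolkit's hash (the structural class counts are 55 and 58). Deviations
  are never silently accepted: `profile_fidelity()` reports every feature
  of every reference drug as matched or mismatched, per molecule.

Identifiers come from a polynomial rolling hash modulo the Mersenne prime
$2^{31}-1$, evaluated exactly in double precision via 16-bit split
multiplication; the multiplier is fixed so that the engine passes the
published fidelity anchors above.

## Chemistry model

Molecules are parsed by OpenBabel into kekulised connection tables; a
syntax validator runs first because lenient readers silently repair inputs
such as `C(`, which must instead surface as invalid records. A structure is
a valid molecule when it parses as a single connected fragment over the
organic element set with all valences satisfiable (standard valences, with
hypervalent sulfur and phosphorus allowed).

Ring perception takes the smallest set of smallest rings (shortest cycle
through every non-bridge bond, added shortest-first until the cyclomatic
count is covered). A ring is aromatic when every atom can contribute a
p orbital and the ring's pi-electron count satisfies the 4n+2 rule; the
contribution table (endocyclic double bond 1 per atom, exocyclic double
bond to N/O/S 0, exocyclic double bond into a fused ring 1, lone-pair
heteroatom 2, exocyclic double bond to a non-ring carbon or a saturated
ring carbon disqualifies the ring) reproduces the published aromatic versus
aliphatic ring classification of all five reference drugs, including the
non-aromatic central thiopyran ring of thiothixene. The model is applied
per SSSR ring; macrocyclic or envelope aromaticity is out of scope and
recorded as such.

Murcko scaffolds strip terminal atoms to rings plus linkers, then restore
atoms multiple-bonded directly to the framework. Acyclic molecules map to a
reserved empty-scaffold sentinel (`""`) that counts as one scaffold class in
ratio computations - the least surprising convention for a quantity whose
published values all come from ring-rich logs. Molecule uniqueness is the
full 27-character standard InChIKey throughout.

# Experiment logs and metrics

A log is an ordered table of molecule-creation events (creator, timestamp,
SMILES, parent pointer, score). Ordering is total: timestamp, then event id
lexicographically, so all metrics are permutation-deterministic. Dangling
parent pointers are downgraded to scratch starts with a warning; invalid
SMILES stay in the log (they count as scoring calls) but are excluded from
every structure-based metric, with the excluded count reported.

*Design sessions.* An event opens a new session when it starts from scratch,
when its parent was created by someone else, or when its parent is not the
most recent molecule its own creator had saved at that moment; otherwise it
continues its parent's session. This is the operational reading of
"starting from scratch or from a certain molecule already in the system";
the rule lives in one place (`assign_sessions()`) so alternative readings
can be swapped in and compared.

*Metrics.* `metrics_report()` assembles: maximum score; unique molecules
(InChIKey classes); scoring calls (all events, duplicates included); time
played (per participant, summing inter-event gaps, omitting gaps strictly
longer than 60 s - both the threshold and the strictness are configuration
values); scaffold/molecule ratio (unique scaffolds over unique molecules,
the orientation that matches the published values below 1; the inverse is a
flag away); leader changes (a strict running-maximum scan in which an event
that beats the best score under a new creator counts one change; the first
event seeds the leader without counting); the forefront creator set
(creators of all strict improvements); and, for experiments whose target
was found, the evolution steps (distinct sessions along the provenance
path) and collaboration degree (path creators as a percentage of engaged
participants - engaged, not invited, because the published degrees are
quoted out of participants who created at least one event). Target
detection uses InChIKey equality rather than score 1000, because folded
fingerprints can in principle saturate the score on a non-target molecule.

# Benchmarks

Goal-directed benchmark scoring follows the published suite: rediscovery
benchmarks score the single best raw similarity; similarity benchmarks pass
raw similarity through the thresholded modifier
$\min(s, t)/t$ (threshold 0.75) and average the top-1, top-10 and top-100
means; the final score is the top-1 score (rediscovery) or the mean of the
three per-k means (similarity). Streams are deduplicated by InChIKey before
ranking so a redrawn molecule cannot occupy several top-k slots, and the
target itself is scored like any molecule. A stream shorter than the
largest k is an error by default (a permissive mode computes over what is
available, with a warning). The published baseline scores of the automatic
designers are embedded as quoted constants cell by cell
(`guacamol_baselines()`, `scoring_call_baselines()`); `comparison_table()`
flags computed versus published columns so the two provenances can never be
confused. The in-app score and the benchmark score share one fingerprint
engine here; the original study notes its app score differed from its
benchmark scoring in unspecified ways, so this single-engine simplification
is deliberate and documented.

# The simulator

The simulator's purpose is structural realism - provenance chains,
sessions, leader dynamics, duplicate draws, idle pauses - not cognitive
fidelity; no claim is made that agents model human moves. Agents act in
round-robin. Each move restarts from scratch with probability 0.05 (single
carbon seed, null parent) or selects a parent from the visible pool
(own molecules in individual mode, all in collective mode) with probability
proportional to $\exp(\beta\, s/1000)$, then applies one random
valence-valid edit (atom addition or removal, bond-order change, ring
closure or opening, element substitution over C/N/O/S/F/Cl, size capped at
60 heavy atoms; invalid edits are resampled up to a bounded retry budget).

Parameters were fixed once by pilot calibration before the analyses:
greediness $\beta = 20$ and one edit per move let a four-agent collective
run rediscover an eight-heavy-atom target within a few hundred to a couple
of thousand events on most seeds, while smaller $\beta$ or multi-edit moves
stall on plateaus; seven agents (the reported mean engagement of the human
experiments) is the default crowd size. Inter-event gaps mix short
in-session pauses (5-45 s, probability 0.9) with longer idle gaps
(90-600 s), so the one-minute idle filter is genuinely exercised. One
master seed spawns one L'Ecuyer-CMRG substream per agent: a run is
bit-identical given (config, seed), and adding an agent leaves the others'
private draws untouched.

What simulated logs do *not* emulate: human skill and its variance between
participants, chemistry-aware editing (agents propose valence-valid but
chemically naive structures), motivation dynamics, and wall-clock
synchronisation between participants. Passing metric tests on simulated
logs therefore validates the metric definitions and their implementations,
not any claim about human behaviour.

The packaged fixture log is the complementary ground truth: 27 hand-written
events by three participants, with duplicates, cross-creator branches,
session re-openings and a found target, whose every metric was derived by
hand at authoring time and shipped as an expectations file.

# Numerical and scale choices

Tests and the acceptance script run at desk scale: metric/oracle
equivalence uses one hundred simulated logs of 30-60 events; the
mode-comparison property pools twenty seeds of 600-event four-agent runs
and asserts only the direction of the mean (collective at least as high),
never per-seed outcomes. The t-SNE map uses an exact $O(n^2)$
implementation with fixed-seed initialisation, perplexity bisection and
early exaggeration, written for the package because no t-SNE
implementation is available in the supported R stack; layouts are
seed-reproducible but, as always with t-SNE, only qualitatively
interpretable.

# Known limitations

* Folded fingerprint cardinalities are only portable across toolkits up to
  hash collisions; totals and class counts are the portable anchors, and
  the per-molecule fidelity report is the honest interface to the
  remainder.
* The aromaticity model covers single SSSR rings; exotic fused or charged
  aromatic systems may classify differently than perception models that
  consider ring envelopes.
* Benchmark scores of human-scale logs depend on deduplication mode; the
  default scores unique molecules, and an all-events mode exists for
  sensitivity checks.
* The study's deposited raw human logs are not redistributable with this
  package; the human-data reproduction path (`parse_log()` with a column
  mapping onto the native schema, then `metrics_report()`) is implemented
  and tested on synthetic data, and activates when those files are placed
  under `inst/extdata/human/`.
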