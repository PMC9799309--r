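---
title: "Assessing methionine oxidation liability from the solvent environment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing methionine oxidation liability from the solvent environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metox)
```

## The problem and the model

Methionine oxidation to the sulfoxide is one of the most common chemical
degradation routes of therapeutic antibodies. The classical predictor of
a residue's susceptibility is solvent exposure of the side chain,
measured as solvent-accessible surface area (SASA): surface methionines
oxidize faster than buried ones. But exposure alone under-predicts a
specific, pharmacologically important class — methionines that are
partially buried (often at the end of the CDR-H3 loop) yet still
oxidize. The mechanistic picture behind this package is that the
rate-limiting charge separation in the oxidation reaction is stabilised
by a hydrogen-bond network around the sulfur; that network can be
supplied by bulk water, by the few transient waters that reach a
partially buried sulfur, or by the hydroxyl groups of neighbouring
serine, threonine and tyrosine side chains.

The package therefore computes four per-methionine descriptors:

* **sSASA** — Shrake–Rupley SASA of the side chain (CB, CG, SD, CE) in
  the static structure, with all solvent stripped;
* **dSASA** — the same quantity averaged with equal weights over the
  frames of a conformational ensemble;
* **WCN** — the two-shell water coordination number: the mean number of
  water molecules whose oxygen lies within 6 Å of the side-chain sulfur;
* **#OH** — the mean number of Ser OG / Thr OG1 / Tyr OH oxygens within
  the same shell.

and applies the decision rules

* sSASA/dSASA rule: oxidation prone iff relative SASA > 15 %;
* WCN rule: oxidation prone iff at least 6 waters in the shell;
* WCN-OH rule: oxidation prone iff `WCN > 6` (condition 1) **or**
  `WCN > 0.1 ∧ #OH > 1.5` (condition 2).

Condition 2 encodes the hydroxyl-mediated mechanism: the sulfur must be
reachable by at least the occasional water (`WCN > 0.1`), and more than
one hydroxyl group must sit in the shell.

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `shell_radius` | 6.0 | Å | coordination shell around the sulfur |
| `probe_radius` | 1.4 | Å | water probe for SASA |
| `sphere_points` | 960 | — | Shrake–Rupley test points per atom |
| `radii_set` | Bondi-style | Å | per-element vdW radii |
| `max_sasa_reference["MET"]` | 224.4 | Å² | relative-SASA normalisation |
| `sasa_rel_cut` | 15 | % | SASA rule threshold |
| `wcn_cut` | 6 | waters | WCN rule / WCN-OH condition 1 |
| `wcn_floor`, `oh_cut` | 0.1, 1.5 | — | WCN-OH condition 2 |

All are configurable via `descriptor_params()` and `ox_thresholds()`;
the thresholds are part of the method's definition, not fitted by this
package, so changing them changes the method.

Two definitional choices deserve emphasis. First, counting is
heavy-atom based: a water is its oxygen, a hydroxyl is its oxygen. This
makes every count independent of whether the input carries hydrogens,
at the cost of ignoring hydroxyl orientation. Second, SASA is computed
with all solvent stripped (a protein-surface property), whereas the
coordination counts are computed with solvent present (they count the
solvent). Relative SASA divides the side-chain area by a whole-residue
maximum-allowed area; since a side chain alone cannot reach the
whole-residue maximum, relative values well below 100 % are expected
even for fully extended, fully exposed methionines, and the 15 % cut is
calibrated on that same convention.

## Numerical choices

* **Shell membership** uses the closed ball (distance ≤ radius). The
  boundary is measure-zero in real data, but a deterministic convention
  keeps fixtures and regression tests exact. With a periodic box,
  distances follow the minimum-image convention for orthorhombic cells;
  a box smaller than twice the shell radius triggers a warning (the
  shell then wraps onto itself) but counting proceeds, since the
  minimum-image distance remains well defined.
* **Quadrature**: SASA test points come from a deterministic
  golden-spiral construction. At 960 points/atom the side-chain SASA of
  the test fixtures is converged to well under 2 % against a 4000-point
  reference, and an isolated sphere reproduces its closed-form area
  within 1 %.
* **Comparison operators**: the plain WCN rule is worded "at least 6"
  where it is introduced, but its restatement as condition 1 of WCN-OH
  says "greater than 6". The package does not resolve this silently:
  `classify_wcn()` defaults to `>=`, condition 1 of
  `classify_wcn_oh()` to `>`, and both operators are configurable
  (`wcn_op`, `wcn_oh_op`). At the defaults the two disagree only at WCN
  exactly 6, which cannot occur for a time average over a generic
  ensemble and never occurs in the packaged tables.
* **Altloc resolution** keeps the highest-occupancy conformer, ties
  broken alphabetically; selenomethionine (MSE) is treated as MET with
  SE in the sulfur role, switchable off.
* **Degenerate inputs**: structures with no methionines yield an empty
  descriptor table (a valid result with a distinct pipeline status);
  a MET residue lacking its sulfur is skipped with a warning;
  undefined sensitivity/specificity ratios are reported as `NA` with an
  explicit flag, never as 0.

## Evaluation protocol

Observed oxidation data come in two resolutions, and the confusion
matrix is built accordingly:

* **Residue-resolved** (forced-oxidation studies with peptide mapping):
  a methionine is an observed event iff its measured oxidation level is
  ≥ 5 % (inclusive); labels are compared cell-wise.
* **Event counts** (per-molecule totals without residue identity):
  predicted and observed events are matched count-wise within each
  molecule, `TP = min(observed, predicted)`, the remainder falling to
  FN/FP and the rest of the methionines to TN. This is the only
  matching consistent with residue-anonymous counts, and on the
  packaged 14-antibody benchmark it yields TP=8, FN=1, FP=0, TN=37 —
  exactly one of 46 events misassigned under the WCN-OH rule.

Bootstrap errors resample the evaluation units with replacement
(50 replicates by default, fixed seed, session RNG untouched) and
report the standard deviation of per-replicate sensitivity and
specificity; replicates with an undefined ratio are dropped and
counted. Both natural units are supported: per-methionine outcomes
(event-count data are first expanded through
`expand_event_outcomes()`) and per-molecule tuples. On the 14-antibody
benchmark the bootstrap mean sensitivity is ≈ 0.88–0.89 under either
unit, with a replicate standard deviation of ≈ 0.10–0.13 — the
dispersion a resampling of 9 positive events supports; substantially
smaller quoted errors cannot be reproduced by unit resampling of these
data under any unit choice we implemented.

For residue-resolved datasets with measured oxidation levels,
`semiquant_metrics()` adds ordinary-least-squares R², Pearson and
Spearman coefficients of the continuous descriptor against the
oxidation level, supporting ranking-style use of the descriptors.

## What the synthetic fixtures emulate — and what they do not

`probe_spec()`/`build_probe()` generate a single idealized methionine
with waters and Ser/Thr/Tyr hydroxyl oxygens placed at controlled
sulfur distances: "in" atoms within `[2.8 Å, shell − 0.05 Å]`, "out"
atoms beyond `shell + 0.05 Å`, so the closed-ball convention can never
flip a fixture's truth; a 2.4 Å minimum interatomic distance keeps the
SASA geometry sane. `build_ensemble()` moves designated waters across
the shell boundary on a per-frame schedule, so the exact per-frame
counts and their time averages are known by construction.
`probe_spec(cage_radius =)` adds a quasi-uniform carbon shell that
buries the side chain; the cage is a geometric occluder with no
packing realism (it is exempt from the 2.4 Å rule, which is harmless
because waters are counted by sulfur distance and stripped before
SASA).

These fixtures validate the *computational* contract — counting,
minimum-image arithmetic, quadrature, frame averaging, file round-trips
— exactly. They do not emulate real solvation physics: no water
structure, no force field, no conformational sampling. Passing fixture
tests therefore certifies that descriptors are computed correctly from
coordinates, not that a 5 ns simulation of a given antibody will
reproduce published descriptor values; those depend on the simulation
engine and protocol that produced the frames.

Problem sizes used in the shipped test-and-validation suite — probes of
up to ~25 placed atoms, ensembles of up to 100 frames, 100-case
randomized property batteries, 50-replicate bootstraps — were chosen as
the smallest sizes at which every property is exercised with margin.

## Design decisions taken where the method description is open

* **Which waters count**: a water "molecule" is in the shell iff its
  oxygen is — not any atom. Oxygen-based counting is
  hydrogen-representation independent and avoids double counting;
  the alternative is reachable by filtering the structure differently
  before analysis.
* **Relative-SASA reference**: the theoretical maximum-allowed-area
  table (MET 224.4 Å²) rather than an empirical one; the reference is
  configurable, and both absolute and relative values are always
  emitted so no hidden conversion is baked into the outputs.
* **Crystallographic waters**: whether input HETATM waters of an X-ray
  structure should contribute to WCN is dataset-dependent; the pipeline
  exposes `strip_input_waters` and leaves them in by default.
* **Frames are equally weighted** with no burn-in discard: the package
  consumes production ensembles and takes them as given.
* **Bootstrap unit**: per-methionine outcomes for residue-resolved
  data; for event-count data both the per-molecule tuple and the
  expanded per-methionine outcome set are supported, and the packaged
  benchmark is reported with the expanded 46-outcome unit.

## Known limitations

* The package consumes structures and ensembles; it does not generate
  them (no homology modelling, loop modelling, protonation or MD), and
  prediction quality on real antibodies is bounded by the quality of
  those inputs.
* Absolute SASA values depend on the vdW radii set and quadrature;
  published per-residue SASA tables computed with other engines agree
  only approximately, which is why classification thresholds operate on
  relative values and the test battery checks algorithmic properties
  rather than third-party absolute numbers.
* The threshold rules are calibrated for antibody variable regions with
  explicit-water ensembles of a few nanoseconds; applying them to
  static structures (where `WCN` collapses to a crystallographic-water
  count) is supported but weaker, as the worked crystal-structure
  example shows for condition-2 positives.
* Only orthorhombic periodic boxes are supported; triclinic cells are
  rejected with an error.

## A complete miniature analysis

```{r example}
be <- build_ensemble(
  probe_spec(n_waters_in = 1, n_ser_in = 2, in_range = c(2.8, 4.0),
             cage_radius = 5.0, n_cage = 60, seed = 7),
  schedule = c(1, 0, 1, 0))
desc <- met_descriptors(be$ensemble, molecule_id = "buried_met")
desc
predict(desc)
```

A methionine with zero SASA and half a water on average is flagged by
no exposure-based rule, but two shell hydroxyls trip condition 2 of
WCN-OH — the partially buried liability class the combined descriptor
exists to catch.

```{r benchmark}
cm <- confusion_from_event_counts(cst_event_units("wcn_oh"))
cm
bootstrap_errors(expand_event_outcomes(cst_event_units("wcn_oh")),
                 n_reps = 50, seed = 20221229)
```
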