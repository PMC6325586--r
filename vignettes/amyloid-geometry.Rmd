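---
title: "Geometric screening for amyloid-like parallel beta-sheets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric screening for amyloid-like parallel beta-sheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyloidscreen)
```

## The problem and the model

Amyloid fibrils are insoluble aggregates built from many distinct
polypeptide chains stacked into near-parallel beta-sheets — the cross-beta
architecture, with inter-strand spacing near 4.8 Å set by backbone
hydrogen bonding.  Because amyloids are insoluble, most deposited amyloid
structures come from solid-state NMR, and their annotation is uneven;
`amyloidscreen` therefore classifies structures from coordinates alone,
using nothing but the C-alpha trace.

For an ordered pair of chains (A, B), both accepted as beta-sheet chains,
the screen computes the distance profile d(i) = min_j ‖CA_i(A) − CA_j(B)‖
and applies three rules:

* **(a) parallelism** — there is a maximal contiguous fragment F of A with
  every d(i) in [`d_min`, `d_max`] = [2, 15] Å and σ(d over F) ≤
  `sigma_max` = 1.5 Å.  A fragment running parallel to the partner chain
  at constant spacing has a near-constant profile, so a small σ is the
  parallelism signature while tolerating singular outliers better than a
  max-minus-min criterion would.
* **(b) low curvature** — the pseudo-bond angles at consecutive C-alpha
  triples of F, averaged over F, lie in [`theta_min`, `theta_max`] =
  [110°, 180°].  Extended strands average ≈ 127°, alpha-helices ≈ 90°, so
  this removes locally parallel helix bundles that pass rule (a).
* **(c) relative length** — `len(F) ≥ len(A) / 7`, with `len(A)` the
  number of residues of the full deposited chain that have a C-alpha
  (unresolved residues do not count, and the divisor is applied to the
  chain, not to a break segment).

A structure is amyloid-like iff some ordered pair yields a fragment
surviving all three rules.  Structures with fewer than two protein chains
are negative by construction: the defining property of an aggregate is
many *distinct*, approximately parallel chains, which deliberately
excludes single-chain partial amyloids and beta-barrels whose strands are
self-parallel within one chain.

```{r worked}
fib <- make_cross_beta(fibril_spec(n_chains = 2, n_residues = 14))
screen_structure(fib)
```

## Design choices in genuinely open territory

**How chains are "identified as beta-sheets".**  The triage predicate is
the one part of the procedure with no canonical definition, so every
hypothesis is switchable in `sheet_call_config()`:

* `annotation` uses deposited `SHEET`/`_struct_sheet_range` ranges;
* `geometric` is a C-alpha-only call in the spirit of P-SEA: a residue is
  extended when its pseudo-bond angle is in [100°, 155°] and its
  pseudo-dihedral is outside the helical band (|τ| ≥ 90°); terminal
  residues inherit the nearest interior flag so short amyloid peptides
  (often 6–12 residues) are not penalized at their ends;
* `annotation_then_geometric` (default) trusts annotation when present —
  many solid-state NMR amyloid entries carry none, and then the geometric
  call takes over;
* `none` disables triage so rules (a)–(c) carry the full burden.

A chain qualifies when ≥ 25 % of its residues are extended
(`min_extended_fraction`); the threshold is deliberately permissive
because rule (c) already demands a long parallel fragment — triage should
cheapen the pair search, not pre-empt the rules.

**Standard deviation.**  σ is computed in population form (divide by n),
the plain reading of σ and stable for the shortest admissible windows
(n = 3); a `sd_type = "sample"` switch exists for sensitivity analysis.
Windows are accumulated with Welford's algorithm, so the boundary case
σ = 1.5 exactly is decided without catastrophic cancellation.

**Closed intervals.**  "Between 2 and 15 Å" and "between 110° and 180°"
are treated as closed: a profile sitting exactly at a bound passes.  The
suite probes σ = 1.5, d = 2 and d = 15 exactly.

**Maximality.**  "Maximal fragment" is read as inclusion-maximal: no
strict superwindow also satisfies rule (a).  Because σ is not monotone
under extension, maximal windows can overlap; all are kept.  The search
scans each window start once, keeping the longest qualifying end per
start; a candidate is maximal iff its end exceeds every earlier start's
longest end.  Equivalence with full O(n³) enumeration is asserted over
1000 random profiles (n ≤ 50) in the test suite.

**Ordered pairs.**  The distance profile is asymmetric (it is computed
from A's residues), so both (A, B) and (B, A) are evaluated and either
suffices.  The same residue range found against two targets yields two
fragment records — deduplication would hide diagnostic information.

**Chain breaks.**  Chains are split where consecutive C-alphas are more
than `max_gap` = 4.5 Å apart (trans C-alpha step ≈ 3.8 Å), and windows are
confined to one segment so that no fragment averages geometry across
unresolved density.  Rule (c) still divides by the full chain length.

**File reading.**  Only the first model of multi-model NMR files is used
(amyloid depositions stack near-identical models); for alternate
locations the highest-occupancy conformer wins, ties resolving to file
order; `HETATM` and non-standard residues are excluded unless
allowlisted; the deposited asymmetric unit is screened as-is, with no
biological-assembly expansion.

## What the synthetic generators emulate

The generator module provides structures with known ground truth so the
full pipeline is testable without downloads:

* `make_cross_beta()` — planar zig-zag strands (3.8 Å C-alpha step,
  3.4 Å axial advance, vertex angle ≈ 127°) stacked 4.8 Å apart, with
  optional per-step twist and isotropic Gaussian noise.  Noise-free
  stacks with ≥ 2 chains are always positive, and sit far from every rule
  boundary by construction.
* `make_helix_bundle()` — ideal alpha-helical traces (2.3 Å radius,
  1.5 Å rise, 100°/residue) in a row 10 Å apart.  Adjacent helices run
  parallel at near-constant separation, so rule-(a) windows exist, but
  every interior pseudo-bond angle is ≈ 90°: the fixture isolates rule
  (b).
* `make_barrel()` — one chain threading straight strands on a cylinder
  (adjacent strands 4.8 Å apart by default): self-parallel geometry that
  must be excluded by the distinct-chain requirement alone, which
  `split_chains = TRUE` demonstrates by converting the same geometry into
  a positive once the strands become separate chains.

These are idealized C-alpha skeletons: no side chains, hydrogen bonds,
register twist disorder, or crystallographic noise.  Passing on them
shows the rules and their boundary behaviour are implemented exactly; it
does not by itself validate recall on deposited structures, which is what
the network tier of the acceptance suite (real PDB accessions) measures
when a connection is available.

Study-condition sizes used throughout the tests and the acceptance
script: 2–5 chains of 14–28 residues, 20-residue helices, 8-strand
barrels, 20 noise replicates at noise_sd = 6 Å, and 1000 random profiles
of length ≤ 50 for the window-search cross-check.

## Numerical and degenerate-input behaviour

* Cosines are clamped to [−1, 1] before `acos`; zero-length rays raise an
  error in `pseudo_bond_angle()` itself, while the chain-level sheet call
  maps degenerate vertices (collinear traces have no defined torsion) to
  NA and treats them as not-extended.
* Windows shorter than 3 residues are never emitted: rule (b)'s mean
  needs at least one interior vertex.  For chains shorter than 21
  residues rule (c)'s demand falls below this floor, so the effective
  minimum is 3.
* Distance profiles use the exact pairwise minimum (no cutoff
  heuristics); all screening quantities are rigid-body invariant, which
  the suite asserts to 1e-6 under random rotations.
* PDB coordinates are written at the format's fixed-width 3-decimal
  precision, so round trips agree to 1e-3 Å.

## Known limitations

* The verdict is a boolean membership call, not an amyloidogenicity
  score or ranking.
* Any one qualifying pair suffices; no consistency across multiple
  neighbour chains (as in a real fibril lattice) is demanded.
* No biological-assembly expansion: a fibril deposited as a single
  asymmetric chain with symmetry operators would be missed.
* The geometric sheet call is a triage heuristic, not a secondary
  structure assignment; it has no hydrogen-bond information.
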