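---
title: "Designing trans-cleaving hammerhead ribozymes with hammerhead"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing trans-cleaving hammerhead ribozymes with hammerhead}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hammerhead)
```

## The design problem

A trans-cleaving hammerhead ribozyme (hhRz) is a small catalytic RNA built
from three largely independent parts: two substrate-binding arms (helices I
and III) that hybridize to the target transcript on either side of an NUH
cleavage triplet (N any base, U uridine, H any base but G), and a constant
catalytic core containing the conserved CUGAUGA and GAAA boxes around the
stem II hairpin. Cleavage occurs immediately 3' of the H. Because the arms
are dictated by the target sequence, designing a ribozyme amounts to
choosing *where* to cut and *how long* to make each arm — a combinatorial
space in which most candidates are poor: their arms melt at the wrong
temperature, the ribozyme folds onto itself and buries its own core, the
target site is sequestered in local secondary structure, or the arms anneal
elsewhere in the transcriptome.

`hammerhead` automates this search. For every NUH site of the requested
triplet types it enumerates all arm-length combinations in a user range
(roughly `(arm-length range)^2 x (number of cut-sites)` candidates),
assembles each ribozyme as

```
5'- revcomp(target 3' of cut) + core + revcomp(target 5' of the U) -3'
```

and scores the survivors on four axes before ranking them by successive
Pareto fronts.

### Where the arms end: the NUH geometry

The catalytically active fold leaves both the U and the H of the triplet
unpaired: helix III ends at the N, helix I begins immediately 3' of the
cleavage position. This convention is pinned by the package's fixture set
(`yz_fixture_set()`): four experimentally validated anti-PABPN1 ribozymes
whose printed sequences all decompose into `arm1 + CUGAUGAGUCGCUGAAAUGCGACGAAAC
+ arm3`, and whose reverse-complement-derived target contexts only produce
valid NUH triplets under this geometry (they yield AUC/AUC/AUC/CUC sites).
The H base itself cannot be recovered from the arms, so the fixture
contexts set it to C and are documented as synthetic.

### The catalytic core

The minimal-model core is the 28-nt constant shared by the validated
designs: `CUGAUGA + GUCGC + UGAAAU + GCGAC + GAAAC`, i.e. the CUGAUGA box,
a 5-bp stem II closed by a 6-nt loop, and the GAAAC box. The extended
(wishbone) model's additional stem II nucleotides vary between published
scaffolds; `core_template("extended")` therefore defaults to a conservative
one-extra-pair stem II and is intended to be overridden
(`core_template(stem2 =, loop2 =)`) with the scaffold of the user's choice.
The template records the designed stem II pairs and the positions that must
remain unpaired, which downstream scoring consumes.

## The quality measures

### Annealing temperature (filter)

Arm/target duplex melting temperatures use the RNA/RNA nearest-neighbor
stacking model (Watson-Crick parameter set of Xia et al. 1998, shipped as a
plain-text table in `inst/extdata/` and swappable via `nn_table(path)`):

    Tm(K) = 1000 * dH / (dS + R * ln(CT / 4)) + 16.6 * log10([Na+]eff)

with duplex initiation and terminal A-U terms, oligomer concentration `CT`
(default 500 nM), and Mg2+ folded into the effective monovalent
concentration as `120 * sqrt(mg_mM)` mM. Arms shorter than 2 nt, for which
the stacking model is undefined, get a `-Inf` sentinel and can never pass.
Candidates are kept when each arm's Tm lies within **-5 to +60 degrees C of
the environment temperature**; because one strong arm can compensate for a
weak one, a candidate with one arm outside the window is rescued when the
*mean* of the two arm Tms still falls inside it (`tm_filter(strict = TRUE)`
disables the rescue). The compensation rule is the package's reading of a
qualitative statement; the window itself is fixed.

Note that with this parameter set short arms melt well below physiological
temperature: a 4-nt duplex has Tm around -10 degrees C, so arms of 3-5 nt
only survive the filter in cold in-vitro conditions or via the rescue rule.
This is physically faithful; worked examples below therefore use GC-rich
arms and/or low environment temperatures when they want every enumerated
candidate to survive.

### Ribozyme structure (Q_f)

Each candidate is folded into an ensemble of (by default) 10 secondary
structures with probability weights. Per structure, the score `Q_s` sums
the melting temperatures — in Kelvin, so that negative Celsius values
cannot cancel — of every continuous double-stranded stretch other than the
designed stem II, which is meant to be there. A stretch may bridge at most
one 1x1 internal mismatch ("up to one mismatch per continuous stretch");
larger loops split stretches. Stretch Tm is the nearest-neighbor Tm of the
stretch's paired bases; an isolated pair carries no stacking information
and contributes 0. A penalty of **50** (same Kelvin-sum scale) is added
whenever the catalytic core is not intact, i.e. when any conserved core
position is paired or stem II is not fully formed — a fully unpaired
structure is penalized too. The ensemble score is the weighted sum
`Q_f = sum(f_s * Q_s)`; lower is better and 0 means "arms always open,
core always formed".

### Target accessibility

The target is folded **once per run** (folding a transcript is by far the
most expensive step) and its ensemble shared by all candidates. Two terms
are computed:

* **Cut-site inaccessibility** (per candidate): the ensemble-weighted
  Kelvin-sum of stretch melting temperatures, exactly as for `Q_f`, but
  over target stretches intersecting the candidate's actual arm-binding
  window (arm 3 segment + the unpaired U and H + arm 1 segment). Reported
  as *accessibility 1*.
* **Disruption energy** (per cut-site): the free-energy cost (kcal/mol) to
  melt local target structure across a fixed window of
  `arm_max + 3 + arm_max` nt — 23 nt at the default `arm_max = 10` —
  centred on the triplet and clipped at the ends. Per structure, the
  stabilizing free energies (`dG = dH - T*dS` from the same
  nearest-neighbor table) of all base-pair stacks with at least one partner
  inside the window are summed and sign-flipped, floored at 0, then
  ensemble-weighted. Stacks straddling the window boundary count in full:
  melting the window necessarily breaks them. Reported as
  *accessibility 2*.

Both are approximate *relative* scores, not absolute folding energetics.

### Off-target specificity (in vivo)

For in vivo designs each cut-site's query — the target window covering both
arms' maximal binding sites (23 nt at defaults) — is searched against a
local reference transcriptome with ungapped approximate matching
(Biostrings `matchPattern`, no indels: ribozyme arms anneal contiguously).
Each hit is weighted by its matched-pair fraction, so the intended site
scores exactly 1; hits below `min_weight = 0.75` are discarded (the
configurable stand-in for a remote search's sensitivity threshold).
Predicted records (accessions starting XM/XR) are reported but excluded
from the score. In `cleavage_only` mode a hit counts only when the aligned
U position is U and the aligned H position is not G; `annealing_and_
cleavage` counts every annealing-competent hit and therefore never scores
lower. Transcripts are directional, so only the sense strand is searched.
In vitro runs skip the stage and report `NA`.

## Normalization and ranking

Structure and both accessibility measures are min-max normalized over the
surviving candidate set, `M_norm = (M - M_min) / (M_max - M_min)`, and
adjusted `M_adj = 1 - M_norm` so 1 is always best; when all candidates
share a value the measure carries no information and everyone gets
`M_adj = 1`. Arm Tms and specificity are reported raw — users judge them
directly.

Ranking is successive non-dominated sorting over the *raw* minimized
objectives {`Q_f`, inaccessibility, disruption energy} plus specificity for
in vivo runs: front 1 is the non-dominated set, and so on. Candidates with
identical objective vectors share a rank; Tm is excluded from dominance
(it has already been filtered, and its normalization would be arbitrary).
Report ordering within a rank is a deterministic position/arm-length sort
that does not affect ranks. The implementation is quadratic per front,
which is comfortable up to a few thousand candidates — full-transcript runs
at that scale are dominated by folding anyway.

## The mock folding backend, and what tests do (not) show

Ensemble folding is a pluggable contract. The shipped backends:

* `mock_backend()` — a deterministic maximum-base-pairing (Nussinov) folder
  in C++ (Watson-Crick + GU, minimum loop 3). Suboptimal ensemble members
  are produced by forbidding pairs of the optimum in a seed-determined
  order and re-folding, de-duplicated, with weights Boltzmann-like in the
  pair count and normalized to 1. Sequences with no pairable structure
  correctly return a single open structure of weight 1. Named fixture
  ensembles override the algorithmic fold, letting tests pin structures
  exactly.
* `vienna_backend()` — an adapter over ViennaRNA's `RNAsubopt`
  (energy-sorted suboptimal structures, Boltzmann-factor weights), used
  when a thermodynamically realistic ensemble is wanted. It is
  deterministic because no stochastic backtracking is used.

The mock backend makes every stage exercisable offline and
bit-reproducibly, which is what the test suite leans on. It emulates the
*shape* of an ensemble provider — multiple weighted, valid, diverse
structures — but maximum pairing is not a thermodynamic model: its
structures over-pair relative to real RNA, and its weights are not
partition-function probabilities. Green tests therefore certify the scoring
arithmetic, the contracts and the determinism of the pipeline, not the
biological quality of any particular mock-scored design. For real designs
use the ViennaRNA backend.

Similarly, `make_transcript()` generates uniform (optionally GC-biased)
random backgrounds with exactly the planted cut-sites and no accidental
ones — real transcripts have codon structure, repeats and strong
composition biases that the generator does not emulate.

## Numerical and scale choices

* Coordinates are 0-based half-open throughout the public site/window
  fields (`index`, `cut_pos`, window start/end); 1-based indices appear
  only inside pair tables, matching dot-bracket positions.
* Kelvin/Celsius conversions use 273.15 exactly; stretch Tms are floored
  at 0 K.
* Degenerate inputs: empty candidate sets yield a header-only report with
  a warning (the CLI exits non-zero); empty transcriptomes score 0 with a
  warning; sub-2-nt arms get the `-Inf` sentinel.
* Test and example problem sizes were chosen so the whole suite runs in
  well under a minute: targets of 40-400 nt for scored stages, a single
  3000-nt enumeration-only example, mock ensembles of 10 structures, and
  Pareto fuzzing at up to 100 candidates x 5 objectives against a
  quadratic oracle.
* The end-to-end fixture (two identical GC-rich GUC contexts, arms 5-6,
  4 degrees C in vitro) is constructed so that no candidate is lost to the
  Tm filter, making the stage counts of a run fully predictable from the
  enumeration formula.

## Known limitations

* No dangling-end, coaxial-stacking or loop-sequence thermodynamics; the
  nearest-neighbor table covers Watson-Crick stacks only, and stretches
  containing GU pairs are scored through the top strand's perfect
  complement as an approximation.
* Off-target search is ungapped and k-mer exact-scan based; it will not
  find bulged annealing modes, and it searches only the provided
  transcriptome, not a genome.
* The extended-model core default is a placeholder scaffold: supply your
  own stem II/loop for serious extended-ribozyme work.
* Pseudoknots are outside the folding contract.

## A worked run

```{r worked}
tgt <- make_transcript(120, planted = data.frame(triplet = "GUC",
                                                 position = c(40, 80)),
                       seed = 7, margin = 12, gc_bias = 0.7)
report <- run_design(tgt,
                     design_params(arm_min = 6, arm_max = 8),
                     design_env(temperature = 20),
                     mock_backend(), seed = 1)
report$table[, c("cutsite", "position", "arm1_len", "arm3_len",
                 "tm_arm1", "tm_arm3", "ribozyme_shape",
                 "accessibility1", "accessibility2", "rank")]
```

Rank-1 rows are the Pareto-optimal designs: improving any one of their
quality measures would worsen another. The full table (including raw
scores and the assembled sequences) serializes with `write_report()`, and
`emit_t7_template()` produces transcription templates for in vitro work.
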