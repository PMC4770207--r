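# hammerhead

Automated design of trans-cleaving hammerhead ribozymes in R.

Hammerhead ribozymes (hhRz) are small catalytic RNAs that bind a target
transcript through two hybridizing arms and cleave it immediately 3' of an
NUH triplet (N = any base, U = uridine, H = A/C/U). They are a general
tool for sequence-specific RNA knockdown — in vitro, in bacteria, or in
mammalian cells — but hand-designing one means juggling several competing
considerations at once: arm annealing strength, the ribozyme's own folding,
the accessibility of the target site, and off-target annealing elsewhere in
the transcriptome. This package is for molecular biologists and RNA
engineers who want that search automated and ranked, and for method
developers who want each scoring stage as a separately testable function.

## The procedure

Given a target RNA and design parameters, `run_design()`:

1. **Enumerates** every NUH site of the requested triplet types and every
   arm-length combination in `[arm_min, arm_max]` — about
   `(arm-length range)^2 x (number of cut-sites)` candidates — and
   assembles each ribozyme as
   `revcomp(target 3' of cut) + catalytic core + revcomp(target 5' of the U)`
   around the conserved core `CUGAUGA...GAAAC` (stem II included).
2. **Filters on annealing temperature**: per-arm nearest-neighbor RNA/RNA
   Tm (Xia et al. 1998 stacking parameters, salt-corrected with Mg2+ as an
   effective monovalent contribution), keeping candidates whose arm Tms lie
   within −5 to +60 °C of the environment temperature (one strong arm can
   compensate a weak one).
3. **Scores ribozyme structure** over a 10-structure weighted ensemble:
   `Q_f = Σ f_s · Q_s`, where `Q_s` sums the Kelvin melting temperatures of
   extraneous double-stranded stretches (≤ 1 mismatch per stretch, designed
   stem II excluded) plus a 50-degree penalty whenever the catalytic core
   is not intact.
4. **Scores target accessibility**: cut-site inaccessibility (same
   Kelvin-sum over target structure intersecting the arm-binding window;
   per candidate) and disruption energy ΔG_disruption (free-energy cost to
   melt structure across a fixed 23-nt window; per cut-site), both
   ensemble-weighted with the target folded once per run.
5. **Assesses specificity** (in vivo runs): ungapped matched-pair-weighted
   search of the 23-nt site query against a local reference transcriptome;
   a perfect, unique match scores 1, XM/XR predicted records are reported
   but not counted.
6. **Normalizes and ranks**: min-max normalization with
   `M_adjusted = 1 − M_normalized` (1 = best), then successive
   Pareto-front ranking over the minimized objectives — rank 1 is the
   non-dominated set.

Folding is a pluggable contract: a deterministic C++ maximum-pairing mock
backend (offline, bit-reproducible; used by the tests) or a ViennaRNA
`RNAsubopt` adapter for thermodynamically realistic ensembles. See the
methods vignette (`vignettes/design-methods.Rmd`) for the model details and
design choices.

## Worked example

```r
library(hammerhead)

# a 120-nt synthetic transcript with two planted GUC sites in GC-rich context
tgt <- make_transcript(120,
                       planted = data.frame(triplet = "GUC",
                                            position = c(40, 80)),
                       seed = 7, margin = 12, gc_bias = 0.7)

report <- run_design(tgt,
                     design_params(arm_min = 6, arm_max = 8),
                     design_env(temperature = 20),   # cool in vitro run
                     mock_backend(), seed = 1)
#> [cut_sites] 2 candidates
#> [enumerated] 18 candidates
#> [tm_filtered] 13 candidates
#> ...
head(report$table[, c("cutsite", "position", "arm1_len", "arm3_len",
                      "tm_arm1", "tm_arm3", "ribozyme_shape",
                      "accessibility1", "accessibility2", "rank")])
#>   cutsite position arm1_len arm3_len tm_arm1 tm_arm3 ribozyme_shape
#> 1       0       40        6        8   4.103   28.77         1.0000
#> 2       0       40        7        8  11.069   28.77         0.8787
#> 3       1       80        6        6  16.454   24.33         0.9992
#> 4       1       80        6        7  16.454   34.98         0.9992
#> 5       0       40        8        8  24.507   28.77         0.7521
#> 6       1       80        7        6  28.754   24.33         0.9992
#>   accessibility1 accessibility2 rank
#> 1        1.00000              1    1
#> 2        1.00000              1    2
#> 3        0.58816              0    2
#> 4        0.58816              0    2
#> 5        1.00000              1    3
#> 6        0.51654              0    3
```

18 candidates were enumerated (2 sites × 3² arm combinations); 13 cleared
the annealing window. Each row is one candidate: `tm_arm1`/`tm_arm3` are
the arm annealing temperatures in °C (reported raw), `ribozyme_shape` is
the adjusted structure score and `accessibility1`/`accessibility2` the
adjusted cut-site inaccessibility and disruption-energy scores (all 0 =
worst, 1 = best among the surviving set), and `rank` is the Pareto front:
the single rank-1 row here is open-armed, targets the more accessible site
and cannot be improved on any measure without losing on another.
`write_report()` serializes the full table as TSV with a `#` metadata
header; `emit_t7_template()` returns sense/antisense T7 transcription
templates for in vitro synthesis.

A thin CLI wrapper ships in `inst/scripts/ribodesign`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "ribodesign", package = "hammerhead"))')" \
  --target target.fa --arm-min 6 --arm-max 8 --temp 20 --seed 1 --out out/
```

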