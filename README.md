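# silacTurnover

Protein turnover analysis for in vivo pulsed-SILAC proteomics of slowly
renewing, collagen-rich tissues (cartilage, bone, skin, plasma).

## The problem

Feeding an animal a heavy-lysine (^13C6-Lys) diet for a few weeks labels
every protein synthesised during the pulse. Mass spectrometry then reports,
per protein group and replicate, a heavy/light ratio H/L and per-channel
iBAQ intensities. From these, the fraction of each protein pool made during
the pulse is

    % incorporation = 100 · (H/L) / (H/L + 1)

and the underlying kinetics are one-compartment first-order turnover with
growth dilution: after a pulse of `t` days with precursor enrichment `p`,

    f(t) = p · (1 − exp(−(k + g)·t))

where `k` is the turnover rate constant and `g` the tissue growth rate
(per day). A pulse-chase contrast (label, then wash out on light diet)
separates **fast-turnover** proteins (>80% incorporation during the pulse,
<20% retained after the chase) from **stable** ones (retention ratio
r = %B/%A ≥ 0.8), with everything else **intermediate**. Comparing young
and older adults after identical pulses quantifies how new protein
incorporation declines with age.

The hard part is missingness: channel intensities below the detection limit
drop out, so fully labelled proteins lose their light channel and fully
turned-over proteins their heavy channel — missing *not* at random. The
package implements three censoring-aware imputation schemes (column-extreme
from iBAQ evidence, K-nearest-neighbour completion, and seeded
uniform-near-extreme rescue), an unpaired Student's t / Benjamini–Hochberg
differential pipeline, matrisome category reporting, and a synthetic-data
generator with known ground truth so every stage is testable.

## Who it is for

Proteomics analysts working with MaxQuant `proteinGroups` output from
pulsed metabolic-labelling designs, and method developers who need a
simulated pulsed-SILAC dataset with controllable kinetics, noise and
MNAR censoring.

## Worked example

```r
library(silacTurnover)

# Simulate the four-group design: A = pulse during growth, B = pulse + chase,
# C = young-adult pulse, D = older-adult pulse; 2-fold reduced turnover in
# 20% of proteins in group D.
sim <- generate_dataset(
  synthetic_config(n_proteins = 300, effect = list(fraction = 0.2, size = 2)),
  seed = 42)
sim$tables$A
#> quant_table: 300 protein groups x 4 samples
#>   groups: A (synthetic)
#>   missing H/L cells: 425 / 1200
#>   flagged rows (reverse/contaminant/site-only): 0

# Pulse-chase turnover classes
prof  <- retention_profile(summarize_group(sim$tables$A, "A"),
                           summarize_group(sim$tables$B, "B"))
calls <- classify_turnover(prof$percent_A, prof$percent_B)
class_summary(calls)
#>          class  n total  percent display
#> 1         fast 41   169 24.26036      24
#> 2       stable 31   169 18.34320      18
#> 3 intermediate 97   169 57.39645      57

# Young vs older differential incorporation
dt <- differential_table(sim$tables$C, sim$tables$D, seed = 42)
attr(dt, "counts")
#> increased decreased     total
#>         1        32       254
head(dt[order(dt$q_value),
        c("protein_id", "mean_C", "mean_D", "fc", "q_value", "recovered_by")], 3)
#>          protein_id   mean_C   mean_D        fc      q_value recovered_by
#> SYN00244   SYN00244 98.25486 19.67752 -4.993254 2.464666e-08 ibaq_extreme
#> SYN00074   SYN00074 92.31122 73.88141 -1.249451 8.353807e-05         none
#> SYN00064   SYN00064 95.30852 84.16135 -1.132450 1.722344e-04         none
```

Of 300 simulated proteins, 169 are quantifiable (status `OK`) in both the
pulse and the chase group; 24% classify as fast turnover, 18% as stable.
In the age comparison, 33 of 254 testable proteins are significant
(q < 0.05, |FC| > 1.5), 32 of them with *decreased* incorporation in the
older group — the direction the simulated effect imposes. Note the top
hit's `recovered_by` flag: its group C ratios were all missing and were
rescued from iBAQ evidence by the uniform-near-extreme scheme, so its fold
change is driven by the imputation bounds; the flag exists so such
proteins can be inspected or excluded downstream.

Real MaxQuant tables enter through
`read_protein_groups(path, sample_spec(...))`, and the whole analysis runs
as one deterministic, manifest-writing step via `run_pipeline()` /
`read_pipeline_config()` (or the thin CLI in `inst/cli/silac-turnover.R`).

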