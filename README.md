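# pamscreen

Quantitative analysis of **base-editing survival screens of randomized PAM
libraries**.

Cytosine base editors (a deaminase fused to dCas9) only edit where dCas9
can bind, and binding requires a protospacer-adjacent motif (PAM). A
sensitive way to map which PAMs support editing is a bacterial survival
screen: a counterselectable `upp` gene carries an engineered TGG codon
downstream of a randomized 4-base PAM slot (256-member library). Editing
converts TGG into a stop codon (TAG/TGA/TAA), truncating Upp, so edited
cells survive 5-fluorouracil while unedited cells die. Rounds of induction
and 5-FU selection enrich lineages whose PAM supports editing — including
weakly active, non-canonical PAMs that unselected assays miss — and deep
sequencing of the PAM+codon amplicon before and after screening turns
colony survival into per-PAM numbers.

pamscreen is aimed at people designing or analysing such screens. It
provides, as one tested pipeline:

* **Selection simulator** — per-round dynamics of (PAM, edited) lineages:
  induction with probability π\_p + μ, relative fitness *s* < 1 for
  unedited cells under 5-FU, and a multinomial colony bottleneck. For two
  lineages starting unedited, one round multiplies their odds by
  (π + (1 − π)s)/s.
* **Synthetic read generator** — ground-truthed Phred+33 FASTQ for any
  library composition, with per-base substitutions, N calls, adapter
  tails and both-strand emission.
* **Read classifier** — cleaning (adapter/poly-N/quality/length), anchor
  matching on both strands with bounded mismatches and a unique-best-hit
  rule, per-PAM codon-state tallies with full QC accounting.
* **Statistics** — per-PAM editing efficiency
  (n\_TGA + n\_TAG + n\_TAA)/n\_total; enrichment factor
  EF(p) = [edited-read share of p in the enriched library] /
  [read share of p in the initial library]; strict functional (> 1%) and
  enriched (EF > 1) calls; stop-codon mutation patterns; library
  uniformity; replicate merging.
* **Reporting** — max-normalized 16×16 efficiency heatmaps,
  information-content sequence logos, enrichment-weighted PAM wheels, all
  backed by TSV tables.

## Worked example

Simulate the classic spiked-mixture control — a functional-PAM strain
mixed 1:15 into an invalid-PAM majority — for two rounds of screening:

```r
library(pamscreen)

params <- screen_params(edit_prob = c(GGGG = 0.1, TTTT = 0),
                        background_escape = 0, unedited_survival = 0.02,
                        rounds = 2, mode = "deterministic")
init <- init_population(make_mixture_weights(c(1, 15), "GGGG", "TTTT"))
traj <- run_screen(init, params)
subset(traj$summary, pam == "GGGG")
#>  round  pam proportion edited_fraction
#>      0 GGGG  0.0625000       0.0000000
#>      1 GGGG  0.2822967       0.8474576
#>      2 GGGG  0.9445082       0.9968274
```

The functional lineage rises from 6.25% to 94.5% of the population — the
odds multiply by (0.1 + 0.9·0.02)/0.02 ≈ 5.9 each round — and by round 2
nearly every surviving cell of it is edited.

A full in-silico screen of the 256-member library (40 active PAMs,
stochastic bottleneck, 50,000 reads per library, then classification and
scoring) is one call:

```r
cfg <- run_config(outdir = "demo", seed = 1, n_reads = 50000,
                  error_model = error_model(substitution_rate = 0,
                                            n_rate = 0, adapter_rate = 0))
out <- run_pipeline(cfg)   # simulate -> process -> stats -> report
st <- out$stats
sum(st$functional)
#> [1] 40
head(st[order(-st$efficiency),
        c("pam", "efficiency", "enrichment_factor", "functional")], 3)
#>   pam efficiency enrichment_factor functional
#>  AATA      1.000              5.03       TRUE
#>  ACCG      0.999              8.62       TRUE
#>  AATT      0.999              7.13       TRUE
```

The strict 1%-efficiency call recovers exactly the 40 truly active PAMs;
`demo/` now contains the FASTQ, tallies, statistics table, heatmap, logo
and PAM-wheel figures, and a checksummed manifest. The same stages run
from a shell via the thin wrapper in `inst/scripts/pamscreen.R`
(`--config run.yaml` or `--demo`).

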