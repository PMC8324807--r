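---
title: "Quantifying PAM compatibility from base-editing survival screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PAM compatibility from base-editing survival screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamscreen)
```

## The experimental system pamscreen models

Cytosine base editors (a deaminase fused to catalytically dead Cas9) convert
C·G pairs to T·A within a window fixed by where the dCas9 binds, and binding
requires a protospacer-adjacent motif (PAM) next to the target. A sensitive
way to measure which PAMs support editing is a survival screen in
*E. coli*: a counterselectable gene (`upp`, which converts 5-fluorouracil
into a toxic metabolite) is engineered to carry a TGG tryptophan codon at
its sixth position, placed downstream of a randomized 4-base PAM slot
(256-member library). When the editor can engage a library member's PAM,
deamination of the TGG codon's guanines — cytosines on the antisense strand
— produces one of the stop codons TAG, TGA or TAA, truncating the protein.
Edited cells survive 5-FU; unedited cells are counterselected. Rounds of
induction plus 5-FU selection therefore enrich lineages whose PAM supports
editing, and deep sequencing of the PAM-plus-codon amplicon before and
after screening quantifies every PAM's activity, including weak
non-canonical ones that unselected assays miss.

pamscreen implements the quantitative side of this design end to end:

1. a **population simulator** for editing + counterselection dynamics
   (`screen_params()`, `run_screen()`),
2. a **synthetic read generator** with exact per-read ground truth
   (`generate_library_reads()`, `couple_to_reads()`),
3. a **read classifier** that cleans FASTQ, locates the construct by anchor
   matching on both strands, and tallies per-PAM codon states
   (`process_fastq()`),
4. **statistics** — per-PAM editing efficiency, enrichment factors,
   functional/enriched calls, mutation patterns, library uniformity,
   replicate merging (`pam_stats()` and friends), and
5. **reporting** — max-normalized heatmaps, information-content sequence
   logos, and PAM wheels (`write_reports()`).

## The amplicon model

The sequenced unit is a 152-bp amplicon. `amplicon_template()` fixes its
layout with 0-based half-open coordinates: a constant 5' anchor (default
20 nt), the randomized PAM slot (default width 4), then a constant segment
whose open reading frame carries the target TGG at a fixed offset (the
sixth codon, offset 15 from the ORF start). The default template's anchor
bases are synthetic: every statistic in the package depends only on the
coordinate layout, so any real construct can be described in a small YAML
file (`write_template_yaml()`) and dropped in.

Codon states are closed under the editing chemistry: from TGG, C·G→T·A
conversion on the antisense strand can only reach TAG, TGA and TAA (the
stop codons), so `classify_codon()` maps those four 3-mers to their states
and everything else — including `N`-containing codons — to `OTHER`. `OTHER`
reads stay in efficiency denominators but are never counted as edits.

A strand convention is needed because the sequencer does not know which
strand carries the protospacer. PAMs are reported so the canonical motif
reads "NGG"; the template flag `pam_report_strand` records whether that
requires reverse-complementing the sequenced slot (default `as_template`).

## The selection model

One screening round is modeled as three steps applied to the abundance of
each (PAM, edited-status) lineage:

* **induction** — unedited cells of PAM $p$ become edited with probability
  $\pi_p + \mu$, where $\pi_p$ is the per-round editing probability and
  $\mu$ a spontaneous-escape rate;
* **selection/growth** — edited lineages keep relative fitness 1; unedited
  lineages are multiplied by $s < 1$, a single per-round factor absorbing
  both 5-FU killing and growth differences;
* **renormalization**, followed in stochastic mode by a multinomial
  bottleneck of $N$ colonies (binomial draws are used for induction in that
  mode).

For two lineages starting fully unedited, one round multiplies their odds
by $(\pi + (1-\pi)s)/s$ — the closed form the test suite checks the
simulator against, round for round. Any $\pi_p > 0$ therefore grows without
bound relative to a $\pi = 0$ lineage as rounds accumulate, which is the
screen's sensitivity argument: even weak PAMs become detectable after
enough rounds.

Defaults, with units and rationale:

| parameter | default | meaning |
|---|---|---|
| `edit_prob` | 0.1 /round | canonical-PAM induction probability; about one cell in ten survives counterselection after one induction with the canonical PAM |
| `unedited_survival` (s) | 0.02 /round | relative fitness of unedited cells under 5-FU; a free parameter, since growth curves do not pin a rate constant |
| `background_escape` (μ) | 1e-6 /round | spontaneous inactivation of the counterselectable gene; prevents degenerate zero-survivor states |
| `bottleneck_size` (N) | 1e5 colonies | colonies harvested between rounds |
| `rounds` | 2 | screening rounds before sequencing |

The simulator makes no attempt to fit $(\pi, s)$ to reproduce any
particular measured colony-count trajectory: distinct mixing experiments
imply distinct per-round odds multipliers, so only the qualitative,
monotone enrichment behaviour is asserted, plus the exact closed-form
algebra above.

## The read generator and what it does (not) emulate

`generate_library_reads()` draws each read's PAM from the library weights,
sets it edited with the lineage's editing fraction, splits edits across
TGA/TAA/TAG with a configurable triplet (default 0.5/0.3/0.2 — the
observed ordering for this codon, TGA most frequent and TAG least, with
invented magnitudes), builds the exact amplicon, and then corrupts it:
uniform per-base substitutions, `N` calls, an optional 3' adapter tail, and
reverse-complement emission with probability 0.5 so both-strand anchoring
is always exercised. Error model defaults: substitution 1e-3/base, `N`
5e-4/base, Phred 37 for clean and 11 for corrupted bases. Output is
Phred+33 FASTQ plus a ground-truth table of realized (PAM, state) counts;
identical inputs and seed give byte-identical FASTQ.

What it deliberately does not emulate: PCR amplification bias, indel
sequencing errors, instrument-specific quality profiles, and paired-end
read structure (the amplicon is short enough that merged single reads are
the natural unit). Tests passing on this generator therefore validate the
classification and statistics machinery, not robustness to artifacts
outside this model — real libraries additionally carry position-dependent
error and coverage biases this generator leaves out.

## Read classification

Cleaning applies, in order: 3' adapter trimming (cut where a ≥10-base
adapter prefix matches with ≤1 mismatch), an `N`-fraction filter (>0.1
rejects), a mean-quality filter (Phred < 20 rejects), and a minimum-length
filter (the template span through the codon). The thresholds are
conventional rather than derived and all sit in `cleaning_params()`.

The locator then scans each read and its reverse complement for the
template's two constant segments — the 5' anchor and the constant stretch
between PAM slot and codon — allowing at most `max_anchor_mm`
substitutions each (default 2) and no indels (substitution-only matching
keeps the locator exact and checkable against an exhaustive Hamming-scan
reference, and amplicon indel rates are negligible at this scale). Among
candidate placements the unique one with fewest total mismatches wins;
ties are rejected as `ambiguous` and a PAM containing `N` as
`ambiguous_pam` — a PAM is never guessed or imputed. Every input read is
accounted for: `reads_in = kept + rejections`, per reason, in the tally's
QC block.

## Statistics

For PAM $p$ with classified read counts $n_\cdot$:

* **editing efficiency**: $(n_{TGA} + n_{TAG} + n_{TAA}) / n_{total}$,
  undefined (never 0) when $n_{total} = 0$;
* **enrichment factor**: the proportion of reads of $p$ that underwent
  editing in the enriched library, divided by the proportion of all reads
  of $p$ in the initial library; undefined when the initial proportion
  is 0. The numerator counts only edited reads (the definition's literal
  reading); `numerator = "all"` provides the all-reads variant for
  sensitivity analysis, and the choice is recorded in the report metadata.
  Whether real denominators should be all reads or only anchor-classified
  reads is not knowable from the assay description; classified reads are
  used and recorded.
* **calls**: functional ⇔ efficiency > 1% and enriched ⇔ EF > 1, both
  strict inequalities, so boundary values never call;
* **fold enrichment** of a spiked strain: final/initial proportion,
  reported rounded half-away-from-zero (9.26 → "9-fold", 55.2 → "55-fold");
* **library uniformity**: a 256-category library has no meaningful
  normality test, so "evenly represented" is operationalized as a
  chi-square goodness of fit against the flat 1/256 expectation plus the
  coefficient of variation of per-PAM frequencies;
* **replicates** are kept side by side, averaged arithmetically, and
  called in consensus only when every replicate calls — the conservative
  choice when no pooling rule is canonical.

## Reporting conventions

* Heatmap: 16×16, rows = PAM bases 1–2, columns = bases 3–4, both in
  A,C,G,T lexicographic order; values divided by the maximum efficiency so
  the hottest cell is exactly 1; missing PAMs are 0 with a mask flag.
* Sequence logo: position frequencies $f(b,i)$ (enrichment-factor-weighted
  by default, uniform on request), information content
  $IC_i = 2 + \sum_b f \log_2 f$ bits, letter heights $f \cdot IC_i$. The
  16-member NGGN set yields exactly (0, 2, 2, 0) bits.
* PAM wheel: a prefix-tree sunburst; ring $r$ holds length-$r$ prefixes,
  position 1 innermost; a node's arc is proportional to the summed
  enrichment factor of its member PAMs, children partition their parent's
  arc, and every ring's spans sum to $2\pi$. The wheel conveys positional
  dependencies (e.g. "when base 1 is T, base 2 is usually G") that
  column-independent logos cannot.

All figures are derived from TSV tables written next to them, so every
plot is reproducible from text artifacts alone.

## Numerical and design choices

* Coordinates are 0-based half-open internally, converted only at report
  boundaries.
* All randomness flows from one integer seed; the generator and simulator
  restore the caller's RNG state.
* Stochastic induction uses binomial draws and bottlenecks multinomial
  draws; the deterministic mode propagates expectations, and the two agree
  in the mean (checked at 3 standard errors over 200 seeds).
* Degenerate inputs are flagged, not silently coerced: zero-read PAMs give
  `NA` efficiency, PAMs absent from the initial library give `NA`
  enrichment, all-zero logo weights and empty wheels are errors.
* Problem sizes used by the shipped checks — 2×10^5 reads for round-trip
  and end-to-end runs, 10^4 reads for the locator-versus-reference
  comparison, 200 seeds for stochastic/deterministic agreement — were
  chosen as the smallest scales at which the binomial tolerances are
  informative.

## Limitations

* The default template is a synthetic construct with the documented
  layout, not any particular laboratory sequence; supply a real template
  for real data.
* Exact recovery of an active PAM set by the strict 1% call is a property
  of noise-free reads: under realistic sequencing error, lineages depleted
  by selection yield so few reads that a single error-induced TGG→TGA/TAG
  read can exceed 1%, and with a spontaneous-escape rate μ > 0 an escape
  cell occasionally rides the bottleneck into an inactive lineage. Real
  analyses should lean on replicate consensus (as `merge_replicates()`
  does) rather than single-library exactness.
* Selection is a single multiplicative fitness per round; continuous-time
  growth, plating efficiency, induction kinetics and plasmid copy-number
  effects are out of scope.
* The classifier is substitution-only; reads whose anchors carry indels
  are rejected rather than rescued.
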