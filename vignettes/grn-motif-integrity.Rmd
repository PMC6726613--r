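---
title: "Integrity scoring of TF–gene–miRNA regulatory motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrity scoring of TF–gene–miRNA regulatory motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnmotifs)
```

## The model

A regulatory motif here is a trio — one transcription factor (TF), one
target gene, one miRNA — connected by some subset of the four admissible
directed edges: TF→gene (`TG`), TF→miRNA (`TM`), miRNA→TF (`MT`) and
miRNA→gene (`MG`). Reciprocal TF ⇌ miRNA regulation is a feedback (FB)
pair; every unreciprocated edge is feed-forward (FF). Four motif classes
partition the classifiable trios:

| class | pattern | reading |
|---|---|---|
| closed loop, reciprocal (CL1) | `TG, TM, MT, MG` | TF ⇌ miRNA, both converge on the gene |
| closed loop, unidirectional (CL2) | `TG, MG` + exactly one of `TM`/`MT` | one-way TF–miRNA link closes the loop |
| common gene (G) | `TG, MG`, no TF–miRNA edge | independent regulators share a target |
| common TF (TFC) | `TG, TM`, no `MG` | one TF drives both gene and miRNA |
| common miRNA (MIR) | `MT, MG`, no `TG` | one miRNA suppresses both TF and gene |

Per condition (control plus the three disease courses RRMS, PPMS, SPMS),
each motif receives the integrity score

$$N = (r_{tf}e_{tf})(r_{mir}e_{mir}) + (r_{mir}e_{mir})(r_{gene}e_{gene})
      + (r_{gene}e_{gene})(r_{tf}e_{tf})$$

where $e$ are strictly positive per-condition expression summaries and
the regulatory weights $r_{tf}=1$, $r_{gene}=0.75$, $r_{mir}=0.5$ encode
the components' regulatory hierarchy: the TF initiates transcription of
both partners, the gene participates broadly in downstream processes, and
the miRNA acts as a post-transcriptional suppressor. The regulatory fold
change of a motif for a disease contrast is
$\mathrm{RFC} = N_{\text{disease}} / N_{\text{control}}$, called UP when
RFC > 1 and DOWN when RFC < 1.

Two structural facts drive everything downstream. $N$ is a degree-2 form
in the expressions, so scaling all three components by $c$ scales $N$ by
$c^2$; consequently RFC is invariant to common rescaling of the whole
matrix and a joint fold-$f$ perturbation of a motif yields
$\mathrm{RFC} = f^2$. And the class precedence CL1 > CL2 > G > TFC > MIR
makes classification a *partition*: each trio counts exactly once, so the
per-class census sums to the total.

## Assumptions

- Expression is intensity-like and strictly positive after normalization;
  $N$ and RFC are undefined otherwise, and the code enforces this.
- Gene and miRNA profiles come from the *same individuals*; matrices are
  joined on shared sample ids.
- Co-expression confirmation uses **control samples only** — edges should
  reflect the baseline regulatory wiring, not disease-induced
  correlation.
- A motif's per-condition expression is the arithmetic mean over that
  condition's samples (median available). The upstream material does not
  prescribe an aggregation; the mean is the natural first moment for
  intensity data and keeps RFC interpretable.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `z_cut` | 2.33 | Z-score | one-sided 1% tail for TFBS matches; inclusive boundary |
| `mem_cut` | 0.05 | probability | MEM co-expression significance; inclusive |
| `cometa_cut` | 4 | score | CoMeTa co-expression support; inclusive |
| `p_cut` (Pearson) | 0.05 | probability | two-sided t-transform p at n − 2 df |
| `require_sign` | off | flag | optionally demand r < 0 for miRNA edges, r > 0 otherwise |
| `r_tf, r_gene, r_mir` | 1, 0.75, 0.5 | weights | regulatory hierarchy (see above) |
| `k_up, k_down` | 10, 10 | motifs | top-list size per type, direction and contrast |
| `min_hits` | 1 | abstracts | minimum corpus mentions for a mined symbol |

All printed cut-offs are **inclusive** (an edge at Z = 2.33 exactly
passes). Edges carrying *no* evidence field are dropped — evidence
filtering exists to enrich true positives, and an evidence-free edge
cannot be vouched for. On duplicate edges the strongest value per field
is kept (largest |Z|, smallest p, largest score).

## Design choices where the design was open

- **"Significantly co-expressed"** is read as two-sided p ≤ 0.05 with no
  |r| floor and no sign constraint; repression-aware sign filtering is
  behind `require_sign` because the directionality convention for
  miRNA–target correlation is not settled upstream.
- **CL2 admits either TF–miRNA edge direction.** The unidirectional
  closed loop is described only loosely upstream; both readings preserve
  the partition, and the reciprocal case is unambiguous (CL1), so the
  inclusive reading costs nothing.
- **Classification precedence** CL1 > CL2 > G > TFC > MIR is what makes
  per-class counts sum to the total — the published count arithmetic
  implies a partition without stating the disambiguation rule.
- **Ranking metric** is RFC extremity: descending among UP, ascending
  among DOWN, with exact RFC = 1 excluded and ties broken
  lexicographically by motif id so outputs are reproducible.
- **Text mining** is whole-token dictionary matching (split on anything
  that is not alphanumeric or a hyphen, case-insensitive, alias-aware).
  This avoids substring artifacts ("CAT" inside "LOCATION") while keeping
  hyphenated miRNA names intact; genes and TFs are mined, miRNAs are not.
- **miRNA pathway annotation** goes through the miRNA's target genes
  (union of the targets' pathways); direct miRNA pathway membership is
  rare in GMT resources.
- **No multiple-testing correction** by default in the
  over-representation test, mirroring the raw p < 0.05 convention of the
  original enrichment tooling; Benjamini–Hochberg is behind `adjust =
  "BH"`.
- **qPCR group comparison** uses the classical equal-variance Student's t
  (the stated test), Welch behind a flag; group-level relative expression
  for scoring is the arithmetic mean of per-sample $2^{-\Delta Ct}$
  values, and sub-group (per-course) means feed the per-contrast scores.

## Numerical choices

- Pearson p-values use the exact Student-t transform
  $t = |r|\sqrt{(n-2)/(1-r^2)}$ with clamping of $r$ into $[-1, 1]$;
  zero-variance profiles have undefined $r$ and are dropped with a
  warning rather than silently scored.
- Quantile normalization delegates to limma's rank-average
  implementation; `log2_shift` computes $\log_2(x+1)$ then shifts the
  minimum just above zero, because downstream scores require strict
  positivity.
- The degenerate two-group comparison (zero variance in both groups,
  equal means) returns t = 0, p = 1 by convention; unequal constant
  groups are an error rather than a fabricated p.
- RFC exactly 1 is excluded from both direction lists (the direction enum
  has no "unchanged" member upstream).

## What the synthetic generator emulates — and what it does not

`generate_network()` plants the configured number of motifs of each class
on dedicated node trios (background edges are drawn only among the
remaining nodes, so planted classes cannot be upgraded or demoted) with
evidence guaranteed to pass the default cut-offs; a configurable fraction
of background edges carries failing evidence. `generate_expression()`
draws log-normal baselines, gives the three components of each planted
motif a shared per-sample latent log-factor (SD 0.4) so planted edges
survive Pearson confirmation, applies cell-wise multiplicative noise
(`noise_sd`, natural-log scale, default 0.1), and multiplies all three
components of a perturbed motif by the requested fold in the requested
condition — the cleanest construction exercising the $c^2$ law. Default
cohort shape is 14 controls and 7/6/6 RRMS/PPMS/SPMS with paired sample
ids across the gene and miRNA matrices; the qPCR generator defaults to
30/14/13/12, reference Ct near 20 (GAPDH) or 18 (U6), and planted shifts
in cycles (−1 cycle doubles relative expression in expectation). All
generators are seed-deterministic.

Not emulated: probe-level microarray artifacts, batch effects,
platform-specific preprocessing, realistic correlation *between* motifs,
negative miRNA–target correlation (the latent factor is shared with
positive sign), or the long-tailed degree distributions of real
interactomes. A green recovery test therefore establishes that the
pipeline's arithmetic and selection logic are correct under the stated
noise model — not that the method would recover the same motifs from real
arrays, whose evidence columns and co-expression structure come from
external databases this package deliberately treats as inputs.

## Known limitations

- The four-class taxonomy is restricted to one TF, one gene, one miRNA;
  larger motifs and two-miRNA/two-TF cycles are out of scope.
- RFC carries no significance estimate; ranking is purely by extremity,
  matching the upstream procedure.
- The enrichment stand-in is structure-compatible with the original
  proprietary tool, not value-compatible: pathway *lists* depend entirely
  on the GMT supplied by the user.
- Published headline counts (e.g. millions of enumerated motifs) depend
  on external interaction databases and full-size arrays; at desk scale
  the package reproduces the procedure's structural guarantees (partition
  arithmetic, 4 records per motif, 240 selections, 75% concordance
  arithmetic), which is exactly what the test suite asserts.
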