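---
title: "Homolog-based virtual transcript quantification: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homolog-based virtual transcript quantification: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtquant)
```

## The model

When no reference genome exists, reads from all datasets under comparison
are pooled and assembled de novo into contigs. Assembly fragments
transcripts unpredictably, and the fragments carry no stable identity, so
per-contig expression values cannot be compared across datasets quantified
against different assemblies. `vtquant` restores a shared unit of
quantification through homology: every annotatable contig is assigned its
best protein-database hit, and all contigs sharing a best-hit subject are
clustered into one *virtual transcript* (VT) identified by that subject
accession. The VT — not the contig — is the quantified unit, and because the
clustering derives from the pooled assembly, it is identical for every
dataset.

The assumptions this rests on:

1. **Fragments of one transcript share a best hit.** True when the homolog
   is well conserved along its length; violated for chimeric contigs or
   proteins with strong local domain similarity to other family members, in
   which case fragments scatter across VTs or two genes merge into one VT.
2. **One subject ≈ one gene.** Paralogs that best-hit the same subject are
   collapsed; recent duplicates are not resolved. This is deliberate: the
   method targets between-dataset comparison, not isoform or paralog
   resolution.
3. **Read counts at contig granularity suffice.** Reads are counted per
   contig (primary alignments only, each mate counting one) and summed over
   VT members; no positional information is used.

## The three measures

With member contigs $i = 1..k_x$ of VT $x$, lengths $l_{x,i}$ and mapped
read counts $n_{x,i}$ in one dataset:

$$\mathrm{RC}_j = n_j \qquad
\mathrm{eRPKM}_x = \frac{10^9 \sum_i n_{x,i}}
   {\sum_i l_{x,i} \cdot \sum_t \sum_i n_{t,i}} \qquad
\mathrm{eTPM}_x = \frac{10^6\, r_x}{\sum_t r_t},\;
   r_x = \frac{\sum_i n_{x,i}}{\sum_i l_{x,i}}$$

RC is depth-dependent and kept because it is what count-based downstream
tools consume. eRPKM and eTPM are invariant under global depth scaling
(`counts -> c*counts`) and under re-fragmentation of a VT's members that
preserves total length and reads — the two invariances that make values
comparable across datasets. eTPM additionally sums to $10^6$ per dataset.

A subtle point we kept exactly as the formulas read: the read total in
eRPKM's denominator runs over **virtual-transcript members only**. Reads on
orphan contigs (no hit) or short contigs (below cutoff) do not enter it. A
`denominator = "all-mapped"` option uses the profile's full mapped total
instead; it is off by default. Consequently
$\mathrm{eTPM}_x = 10^6\,\mathrm{eRPKM}_x / \sum_t \mathrm{eRPKM}_t$ holds
identically, which the test suite asserts at $10^{-9}$ relative tolerance.

Per-contig RPKM (for assembly-wide expression overviews) uses the profile's
*total* mapped reads as denominator — the conventional definition — since a
per-contig view predates clustering; this choice is documented rather than
derivable from the VT formulas.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| `min_length` | 200 bp | annotation cutoff; a shorter contig encodes at most `floor(200/3) = 66` aa even UTR-free, too little for reliable homology. Strictly "longer than": a 200 bp contig is excluded. |
| `max_evalue` | `Inf` | no e-value ceiling by default; best hit is chosen by bit score (max), then e-value (min), then subject id (lexicographic) so results are order-independent. |
| `include_orphans` | `FALSE` | orphans stay out of the reference; enabling it makes each orphan a singleton VT named `orphan:<contig>` and changes *every* eRPKM/eTPM value because m and the denominators change. |
| `denominator` | `vt-only` | see above. |
| `level_mode` | `min` | GO level = minimum edge distance to the namespace root over is_a/part_of; the common level-picker convention. `max` (longest path) is available. |

The length filter is applied **before** hit selection, so a 150 bp contig
with a strong hit is still excluded at defaults: the cutoff restricts what
is annotatable, not what happens to align.

## GO summaries

Each VT inherits the GO terms of its best-hit subject. Annotation sets are
closed under the ancestor relation (is_a and part_of only; regulates-type
edges are ignored), then summarized per term at a chosen level: number of
VTs carrying the term and cumulative RC/eRPKM/eTPM per dataset. Cumulative
semantics mean an ancestor's row always dominates each descendant's row — a
monotonicity the tests verify edge by edge. A VT annotated to two sibling
terms contributes fully to both rows, so level sums are *not* a partition of
the dataset total; the VT count is annotation-based and therefore identical
across datasets sharing the reference.

## What the synthetic generator emulates — and what it does not

`simulate_world()` builds a ground truth of homolog subjects with known
lengths and abundances, fragments each into contiguous contigs (a 250 bp
floor per fragment, so sub-cutoff contigs arise only from the explicit
`short_fraction` truncation), strips hits from an `orphan_fraction` of
contigs, and emits a random single-rooted is_a ontology. Abundance is an
integer per-base read rate (1–20) per transcript and condition — the
simplest model in which expected counts are exactly proportional to
rate × length.

Two noise modes:

* **exact** — counts are `rate * length * f` with a single integer factor
  `f` rounding the requested depth; because rounding happens in `f`, not per
  contig, counts remain exactly proportional to abundance and the pipeline
  must recover the analytic
  $\mathrm{eTPM}_x = 10^6\, \mathrm{rate}_x / \sum_t \mathrm{rate}_t$ to
  $10^{-9}$ — a sharp end-to-end correctness check, not a statistical one.
* **poisson** — independent Poisson draws around depth-scaled means;
  recovery error should shrink like $1/\sqrt{\mathrm{depth}}$, which the
  acceptance suite checks across depths $10^3, 10^4, 10^5$.

What the generator does **not** emulate: read-level errors and insert-size
effects, misassembly and chimerism, homology-score realism (hit tables are
constructed to contain the true subject plus lower-scored decoys), and
multi-mapping ambiguity. A green test therefore establishes algorithmic
correctness on well-posed inputs, not robustness to assembly or alignment
artifacts.

Defaults (20 transcripts, ~2 fragments each, lengths 300–3000 bp, 10%
orphans, 10% short, 20 GO terms) keep a full-pipeline fixture around 40
contigs — large enough to exercise every code path, small enough that the
whole suite runs in well under a minute.

## Numerical choices and degenerate inputs

* Double precision throughout; values are rounded (6 significant digits)
  only at TSV serialization, so file round-trips agree to ~$10^{-5}$ while
  in-memory invariants hold to $10^{-12}$.
* A dataset with zero reads on the reference is a hard error (both
  normalizations are undefined), including the edge case where reads land
  only on orphan contigs. A zero-read *VT* within a live dataset is fine:
  it reports 0 and stays in the table, since m is a property of the shared
  reference.
* Ties in best-hit selection, row orders, and member orders are all resolved
  lexicographically, making every output byte-deterministic under input
  permutation.
* Empty FASTA, duplicate contig ids, malformed hit rows (wrong column
  count, unparsable numerics) and cyclic ontologies fail hard with the
  offending id or line number; unknown association terms are dropped with a
  warning.

## Open design points we resolved

* **Whether reads are counted against contigs or concatenated VT
  sequences:** per contig, then summed — consistent with the per-contig
  counts in the eRPKM formula, and it keeps SAM/TSV inputs equivalent.
* **One hit table per run:** clustering merges hit spaces only within one
  database's accession namespace; to use two databases, run twice and
  compare.
* **VT counting in GO views:** a VT counts once per term (not once per
  level), so sibling multi-membership is visible rather than hidden.
* **Config file format:** plain `key = value` lines rather than YAML/TOML;
  explicit command-line flags always win.

## Known limitations

Chimeric contigs can bridge two genes into one VT; conserved domains can
attract fragments of different genes to one subject; expression of genes
with no detectable homolog is invisible unless `include_orphans` is set; no
effective-length or fragment-length correction is applied (lengths are raw
contig lengths); and no differential-expression testing is performed — the
output tables are the intended input to dedicated DE tools.
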