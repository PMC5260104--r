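# vtquant

Comparable RNA-seq quantification for organisms **without a reference
genome**, via a homolog-based *virtual transcript* reference.

## The problem

For a non-model organism there is no annotated transcriptome to map reads
against. The usual workaround — de novo assembly per dataset — produces a
different, fragmented contig set for every sample, so RPKM/TPM computed per
dataset are not comparable: the same transcript may be represented by one
contig here and three partial contigs there. `vtquant` implements a
pooled-reference strategy: contigs assembled from *all* datasets together are
searched against a protein database, contigs sharing the same best homology
hit are clustered into one **virtual transcript** (VT), and every dataset is
quantified against that single shared reference.

## The statistics

For virtual transcript *x* with member contigs *i = 1..k_x*, contig lengths
*l_{x,i}* and per-dataset mapped read counts *n_{x,i}*:

- **RC** (read count, per contig *j*): `RC_j = n_j`
- **eRPKM** (estimated RPKM, per VT):

  `eRPKM_x = 1e9 * Σ_i n_{x,i} / ( Σ_i l_{x,i} * Σ_t Σ_i n_{t,i} )`

  where the read total in the denominator runs over members of virtual
  transcripts only (orphan and short contigs excluded).
- **eTPM** (estimated TPM, per VT): with rate `r_x = Σ_i n_{x,i} / Σ_i l_{x,i}`,

  `eTPM_x = 1e6 * r_x / Σ_t r_t`

  so every dataset's eTPM column sums to 10^6.

Contigs of 200 bp or less are excluded from annotation (they can encode at
most 66 amino acids even with no UTR, so their hits are unreliable); contigs
longer than the cutoff but without a homology hit are *orphans*, reported per
contig but outside the virtual reference by default.

## Worked example

Three contigs, two of which (c1: 1000 bp, c2: 500 bp) share best hit P001
while c3 (2000 bp) hits P002; two datasets differing only 10x in depth:

```r
library(vtquant)
contigs <- contig_set(c("c1", "c2", "c3"), c(1000L, 500L, 2000L))
hits <- data.frame(query_id = c("c1", "c2", "c3"),
                   subject_id = c("P001", "P001", "P002"),
                   percent_identity = 90, alignment_length = 300L,
                   mismatches = 10L, gap_opens = 0L, q_start = 1L,
                   q_end = 300L, s_start = 1L, s_end = 300L,
                   e_value = 1e-50, bit_score = 200)
eligible <- filter_annotatable(contigs, 200)
vref <- build_virtual_transcripts(select_best_hit(hits, eligible),
                                  eligible, contigs)
d1 <- mapping_profile("liver", c(c1 = 100,  c2 = 50,  c3 = 300))
d2 <- mapping_profile("gut",   c(c1 = 1000, c2 = 500, c3 = 3000))
compare_datasets(vref, list(d1, d2), contigs)
```

prints

```
  vtranscript_id subject_id n_contigs total_length rc.liver erpkm.liver
1           P001       P001         2         1500      150    222222.2
2           P002       P002         1         2000      300    333333.3
  etpm.liver rc.gut erpkm.gut etpm.gut
1      4e+05   1500  222222.2    4e+05
2      6e+05   3000  333333.3    6e+05
```

Read: P001's two fragments act as one 1500 bp transcript with 150 reads
(rate 0.1 reads/bp), P002 as 2000 bp with 300 reads (rate 0.15), giving
eTPM 400,000 vs 600,000. The `gut` dataset has 10x the depth: its RC column
is 10x larger but eRPKM/eTPM are identical — depth differences cancel,
expression comparisons don't.

## Command line

```sh
inst/cli/vtquant simulate --out-dir demo --seed 7          # synthetic world
inst/cli/vtquant build-ref demo/contigs.fasta demo/hits.tsv --out ref.tsv
inst/cli/vtquant quantify ref.tsv demo/counts_cond1.tsv demo/counts_cond2.tsv --out quant.tsv
inst/cli/vtquant go-summarize quant.tsv ref.tsv demo/ontology.obo demo/associations.tsv --level 2 --out go.tsv
```

`go-summarize` rolls each VT's GO annotation up to all ancestors (is_a,
part_of) and reports, per term at the chosen level, the number of VTs and
the cumulative RC/eRPKM/eTPM per dataset.

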