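# nmdkit

Discovery and prioritisation of alternative-splicing events coupled to
nonsense-mediated decay (AS-NMD), for transcriptomics workflows built on
custom (assembled) transcriptomes.

## The problem

A large fraction of mammalian genes produce, besides their productive mRNA,
isoforms that the nonsense-mediated decay (NMD) pathway destroys. The
splicing choices that route transcripts into or away from NMD — poison
cassette exons, protective cassette exons, alternative donor/acceptor usage
and intron retention — act as post-transcriptional switches for gene
expression, prominently during neuronal differentiation. Finding these
events in RNA-seq-derived transcriptomes, deciding which of them actually
move gene expression, and quantifying how much repression they can deliver,
requires a chain of steps that `nmdkit` implements end to end:

1. **Gene assignment** (`drop_reference_matches()`, `assign_genes()`):
   novel transcripts whose intron chains exactly duplicate a reference
   transcript are removed; the remainder are allocated to the same-strand
   reference gene with maximal shared exonic bases.
2. **ORF building** (`build_cds()`): annotated reference start codons are
   projected onto each novel isoform; translation proceeds in silico to the
   first in-frame stop.
3. **NMD prediction** (`predict_nmd()`, `annotate_nmd()`): the 50-nt rule —
   a transcript is NMD-sensitive when its stop codon lies more than 50
   spliced nucleotides upstream of the last exon–exon junction (strict
   inequality, distance measured from the base after the stop codon to the
   first base of the final exon). Biotype labels in the input are ignored.
4. **Event calculus** (`diff_splice_chains()`, `build_event_catalog()`):
   isoform pairs are diffed into cassette exons (CE), alternative donors
   (AD), alternative acceptors (AA) and retained introns (RI); each event is
   labelled NMD-stimulating (NS) or NMD-repressing (NR) according to which
   side of the event co-occurs with the NMD-sensitive verdict.
5. **Prioritisation** (`shortlist_responsive()`, `test_gene_corr()`,
   `kendall_trend()`, `fisher_enrichment()`,
   `shortlist_regulator_dependent()`): events responding to NMD inhibition
   (ΔPSI > 0.1, probability > 0.9, plus high/low-inclusion retention rules)
   are tested for correlation between their NMD-protective splicing pattern
   and gene expression, using the variance-stabilising transform
   `VST_PSI = 2·arcsin(√PSI)/π` and Pearson's r on `VST` (NR) or `1 − VST`
   (NS); monotonic expression trends use Kendall's τ (|τ| > 0.75,
   p < 0.05) and group comparisons a one-sided Fisher test with BH FDR.
6. **Conservation** (`flank_intervals()`, `mean_conservation()`): per-base
   conservation (e.g. PhastCons) averaged over event-type-specific intronic
   windows — 100 nt either side of a CE, first/last 100 nt of an RI, 200 nt
   of intron past an AD donor or before an AA acceptor.
7. **Downregulation model** (`simulate_downregulation()`,
   `model_preset()`): the ODE `dR/dt = r_t·r_n·v_sr − k_dr·R` with
   `k_dr = ln2/t_half`, where `r_t` (transcriptional) and `r_n` (AS-NMD)
   are piecewise-constant repression factors, simulating the four
   coordination scenarios between NMD-dependent and NMD-independent
   repression.

A deterministic fixture generator (`fixture_plan()`,
`make_toy_annotation()`, `simulate_quantification()`, `make_toy_track()`)
builds toy genomes with planted NS/NR events of all four types, planted
ΔPSI responses and planted splicing–expression correlations, so the entire
workflow is testable without any downloads.

## Worked example

```r
library(nmdkit)

plan <- fixture_plan(seed = 7, n_genes = 6)      # one planted event per gene
fix  <- make_toy_annotation(plan)

ann      <- annotate_nmd(fix$annotation, fix$genome)
catalog  <- build_event_catalog(ann$annotation, ann$verdicts)
catalog[, c("event_id", "event_type", "nmd_effect", "n_supporting_pairs")]
#>              event_id event_type nmd_effect n_supporting_pairs
#> 1 CE:chr1:4916-5005:+         CE         NS                  1
#> 2 CE:chr2:4995-5085:-         CE         NR                  1
#> 3 AD:chr3:4811-4870:+         AD         NS                  1
#> 4 AA:chr4:4891-4950:-         AA         NS                  1
#> 5 RI:chr5:4811-5110:+         RI         NS                  1
```

Five genes carry a planted event (the sixth is single-isoform): a poison
cassette exon (NS — inclusion triggers decay), a protective cassette exon
(NR — skipping triggers decay), and NS variants of donor extension,
acceptor extension and intron retention; all five are recovered with the
correct label. The per-transcript verdicts show why, e.g. the chr1
inclusion isoform's premature stop sits 207 spliced nt upstream of its
last junction (> 50 → NMD-sensitive), while the skipping isoform's stop is
in the last exon (distance −63 → insensitive).

Downstream, with quantification tables:

```r
quant <- simulate_quantification(fix$truth, plan)
shortlist_responsive(quant$dpsi, catalog)    # ΔPSI/probability filters
test_gene_corr(psi_series, expr_series, "NS")  # protective-orientation r
simulate_downregulation(model_preset("coincident"), seq(0, 336, 1))
```

The `"coincident"` preset starts at the pre-repression steady state
`R* = 1·0.78·1.76/k_dr ≈ 14.0` molecules/cell and relaxes to
`0.39·0.12·1.76/k_dr ≈ 0.84` after the day-2–4 onset of both repression
mechanisms — a final level 6% of the initial one.

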