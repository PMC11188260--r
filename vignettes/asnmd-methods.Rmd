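---
title: "Methods: AS-NMD event discovery, prioritisation and the downregulation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AS-NMD event discovery, prioritisation and the downregulation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdkit)
```

This vignette documents the models, conventions and design choices behind
`nmdkit`, in the spirit of a methods section: what is computed, under which
assumptions, and where the genuinely open choices were made.

## Coordinates and the transcript data model

All intervals are stored 1-based closed in `GenomicRanges` containers, the
native convention of both the GTF format and the Bioconductor interval
stack. Keeping the ecosystem's convention means GTF import/export involves
no coordinate shifts and every interval operation (overlap, setdiff,
reduce) runs on `IRanges` rather than hand-written arithmetic. Transcript
("spliced") offsets are 1-based and counted 5'→3' in transcription
direction, so on the minus strand the highest genomic coordinate of the
5'-most exon is offset 1. Strand is mandatory for every transcript: donor
and acceptor sites, reading frames and junction distances are meaningless
without it, so `"*"`-stranded transcripts are rejected at construction
rather than silently mishandled. Overlapping exons within one transcript
(which assemblers occasionally emit) are merged with a warning. Attribute
columns are carried verbatim; only `gene_id`/`transcript_id` (and
optionally biotype, for reporting) are interpreted.

## Gene assignment

Novel transcripts duplicating the reference are recognised by *intron-chain
identity*: the ordered list of intron coordinates on the same strand, which
deliberately ignores terminal exon ends (assembled transcripts routinely
differ from the reference only in their termini). Single-exon transcripts
have no intron chain; they are removed only on exact exon equality — the
conservative analogue. Remaining transcripts are assigned to the same-strand
reference gene sharing the most exonic bases (span overlap would
misattribute transcripts inside long introns of other genes; antisense
overlap never assigns). Ties — rare, but possible for overlapping paralogs —
break lexicographically on `gene_id`, making assignment invariant to input
order. Intergenic transcripts found a fresh gene whose identifier is derived
from the locus (`chrom:start-end:strand`), so reruns agree without global
state.

## ORF building and the 50-nt rule

`build_cds()` projects *annotated* start codons of the same gene onto the
novel isoform: the three genomic bases of a reference start must be exonic
and read consecutively in the target's spliced coordinates (one piece or
across a shared junction). Among projectable starts the 5'-most is taken,
and translation proceeds codon-by-codon to the first stop. There is
deliberately no de-novo longest-ORF fallback: fabricated ORFs on
unannotated 5' structure would inflate false NMD calls; isoforms where no
start projects are flagged (`no-start`) rather than guessed at, and an
in-frame stop that never arrives before the transcript end is flagged
(`stop-not-found`). Annotated reference CDSs are taken at face value;
selenocysteine readthrough and non-ATG initiation are out of scope. Stored
CDSs exclude the stop codon (the GTF convention), so the stop occupies the
three bases after the CDS end.

`predict_nmd()` implements the exon-junction-complex displacement logic as
the 50-nt rule: a transcript with ≥ 2 exons is NMD-sensitive iff the
number of spliced nucleotides strictly between the stop codon and the
first base of the final exon exceeds the threshold (default 50 nt, strict
`>`). The literature quotes 50–55 nt; the default follows the stricter
end, and the threshold is a parameter. The measurement anchor is a
genuinely open convention — from the end of the stop codon (default) or
from its start (`stop_anchor = "start"`, which adds the two remaining stop
bases). Both are exposed; all headline numbers use the default. The
workflow never reads input biotype labels: verdicts derive from
coordinates and sequence alone, which is what lets it recover
decay-biotype transcripts blindly and annotate novel isoforms no biotype
curation has seen.

## Event calculus

Two same-gene isoforms are diffed into events defined in transcription
direction: CE (internal exon of one chain absent from the other, both
flanking junctions shared), AD (shared acceptor, alternative donor, next
junction shared), AA (shared donor, alternative acceptor, previous junction
shared) and RI (an intron of one isoform spanned exactly by a single exon
of the other). On the minus strand the donor is the *genomically left* edge
of an exon and the acceptor the right edge; the implementation works on
genomic edges and maps the labels by strand. Differences at transcript
termini (alternative TSS/TES) are not splicing events and are excluded;
any other unexplained exonic difference is reported as `complex` and
skipped rather than force-fitted — mutually exclusive exons, notably, stay
out of the catalog.

NMD attribution uses only isoform pairs that differ by exactly one
recognised event, so a verdict flip is never attributed to an event that
co-varies with another. Across all informative pairs (discordant NMD
verdicts, both isoforms with a CDS): inclusion-side decay in every pair
gives NS, skipping-side decay gives NR, and conflicting evidence across
isoform backgrounds is labelled `ambiguous` — an explicit category, kept in
the catalog but excluded from NS/NR-specific statistics, since silently
picking a side would misdirect downstream prioritisation. Events
deduplicate by (type, coordinates, strand) and genes lacking discordant
isoforms contribute nothing.

## Prioritisation statistics

PSI is a fraction in [0, 1] everywhere internally (tables declaring
`psi_percent` are divided by 100 on input). Responsiveness to an NMD-block
contrast (e.g. cycloheximide vs vehicle) uses ΔPSI > 0.1 with posterior
probability > 0.9 for NS events, ΔPSI < −0.1 for NR, plus the
inclusion-level retention rule for events with no room to move: NS with
mean PSI > 0.9 and NR with mean PSI < 0.1 across conditions. A stringent
preset (|ΔPSI| > 0.25, probability > 0.95) is available; all cutoffs are
arguments.

Correlation with gene expression stabilises PSI variance with
$\mathrm{VST}_{PSI} = 2\arcsin(\sqrt{PSI})/\pi$ — the arcsine-square-root
transform rescaled by $2/\pi$ so that 0, 0.5 and 1 are fixed points. The
NMD-*protective* orientation is correlated with transformed expression:
$\mathrm{VST}$ for NR events (inclusion protects) and
$1-\mathrm{VST}$ for NS events (skipping protects), so a positive r always
means "protective splicing tracks expression". p-values are two-sided from
the t distribution (`stats::cor.test`); BH FDR is computed within
event-type strata (NS-CE, NR-CE, other) because these groups are reported
separately — a global option exists. Events with r > 0, p < 0.05 and
FDR < 0.1 are flagged *facilitating*. A minimum of 3 matched timepoints is
required and results with n < 5 carry a low-power flag; zero-variance
series are reported as degenerate and non-significant instead of
propagating NaN.

Monotonic expression trends use Kendall's τ-b against time (ties handled;
exact null for small tie-free series, normal approximation otherwise;
two-sided, since sidedness is not dictated by the classification use), with
"downregulated" meaning τ < −0.75 at p < 0.05 and "upregulated" the
mirror. Enrichment of trend membership between gene groups uses the
one-sided (greater) Fisher exact test; a 2×2 table with an empty margin
carries no evidence and is reported as p = 1 with an undefined odds ratio.

Regulator dependence (the PTBP1-style screen) requires (a) a significant
knockdown response (|ΔPSI| > 0.1, probability > 0.9), annotated from the
highest-priority significant contrast — single knockdown before
double knockdown, embryonic stem cells before neural progenitors; (b) a
time-course correlation between the event's PSI and the regulator's
expression at p < 0.05; and (c) opposite signs of that correlation and the
knockdown ΔPSI (a repressor's loss should move splicing against its
expression trend).

## Conservation windows

Conservation of the *intronic context* is what distinguishes functional
events, so windows avoid the event's own exonic sequence: 100 nt of intron
on each side of a CE; the first and last 100 nt of an RI; 200 nt of intron
immediately downstream (transcription direction) of an AD's donor; 200 nt
immediately upstream of an AA's acceptor. For AD/AA the window anchors on
the *distal* (event-defining) splice site — the proximal site is shared
between isoforms and its flank is ordinary intron; this anchoring is an
explicit assumption of this implementation. Windows truncate at
neighbouring exon boundaries (and at the retained intron's own extent) with
a flag. Track bases without data are *excluded* from the mean and counted:
PhastCons gaps mark unalignable sequence, and imputing zeros would drag
scores down for reasons unrelated to conservation. A `missing_as_zero`
mode exists for parity experiments. bigWig input is supported via
`rtracklayer`; the plain-text bedGraph dialect keeps fixtures text-only.

## The downregulation ODE

Productive-mRNA abundance follows

$$\frac{dR}{dt} = r_t(t)\, r_n(t)\, v_{sr} - k_{dr} R, \qquad
k_{dr} = \frac{\ln 2}{t_{1/2}},$$

with synthesis rate $v_{sr}$ (molecules·cell⁻¹·h⁻¹), half-life $t_{1/2}$
(h), a transcriptional repression factor $r_t$ and an AS-NMD repression
factor $r_n$ (the fraction of transcriptional output spliced into the
productive, NMD-escaping isoform), both piecewise-constant in $[0,1]$.
NMD-sensitive isoforms are assumed far less stable than productive mRNA
and carry no compartment of their own. $r_n$ derives from inclusion under
NMD blockade, $r_n = 1 - \mathrm{PSI}_{CHX}/100$; $r_t$ from late/early
expression ratios in cells where the AS-NMD switch has been genetically
disabled. Steady state is $R^* = r_t r_n v_{sr}/k_{dr}$.

Defaults ship as presets: `genomewide` uses published transcriptome-wide
medians ($v_{sr} = 1.76$, $t_{1/2} = 7.08$ h) and `gene-averaged` the
three experimentally dissected genes ($v_{sr} = 2.63$, $t_{1/2} = 5.11$ h);
both repress $r_t: 1 \to 0.39$ and $r_n: 0.78 \to 0.12$. The four
coordination scenarios place the onsets inside the 48–96 h window with the
±1-day stagger seen experimentally: AS-NMD alone (60 h, no transcriptional
step), AS-NMD preceding (48/72 h), coinciding (60/60 h) or following
(72/48 h) transcription. The exact breakpoints are not published; these
are this package's defaults and every one is overridable.

Integration is adaptive Runge–Kutta (`deSolve`, `ode45`) performed
segment-wise between schedule breakpoints, so discontinuities never fall
inside an integrator step; with tolerances of 1e−10 the solution matches
the piecewise closed form
$R(t) = R^*_i + (R(t_i) - R^*_i)e^{-k_{dr}(t-t_i)}$ to well under 1e−6
relative error (the closed form is kept *outside* the package, as the test
oracle). `R(0)` defaults to the initial steady state; time is hours
internally, with the CLI accepting days.

```{r ode-demo}
p <- model_preset("coincident")
tr <- simulate_downregulation(p, seq(0, 336, by = 4))
c(initial = tr$R[1], final = tr$R[nrow(tr)],
  final_ss = steady_state(p$v_sr, 0.39, 0.12, p$k_dr))
```

The dichotomy point of a mutant-vs-wild-type time course — the stage
preceding the first exceedance of a threshold (default: pooled median of
the normalised mutant values) by the clone-averaged series — is the
empirical anchor for the AS-NMD onset used above.

## The fixture generator: what it emulates and what it does not

`make_toy_annotation()` builds one gene per 10-kb toy chromosome
(alternating strands): a four-exon productive isoform with an annotated
CDS and, per plan, a variant isoform planting one of NS-CE, NR-CE, NS-AD,
NS-AA, NS-RI. Exonic sequence is drawn from the T-free alphabet
`{A, C, G}` — no stop codon can occur in any reading frame — and ATG/TAA
codons are planted explicitly, so the frame consequences of every splicing
variant are controlled exactly: every planted premature stop sits ≥ 30 nt
inside its segment and > 50 nt (with ≥ 100 nt margin in practice) of
spliced sequence upstream of the last junction, and the NR-CE design plants
a skip-frame stop that the inclusion frame reads through harmlessly.
Intron margins of ≥ 100 nt around planted segments leave room for untruncated
conservation windows. Everything is a pure function of the plan's seed:
reruns are byte-identical.

`simulate_quantification()` emulates Whippet-style outputs at the level
the prioritisation statistics consume: PSI trajectories (rising for NS,
falling for NR) with noise applied on the VST scale and back-transformed
(keeping values in [0, 1]); a ΔPSI table whose `probability` column is a
stand-in for Whippet's posterior, not a re-derivation of it; and an
expression matrix whose correlation with each event's protective pattern
equals the planted ρ *exactly in-sample* — the drawn noise vector is
orthogonalised against the signal before mixing. The raw
`y = ρx + ε` construction was rejected because the Pearson estimator is
biased low at n = 5, which would conflate an estimator property with a
defect of the correlation module; a generator's job is planting known
structure. Consequently, recovery tests check the machinery (transforms,
orientation, matching), not sampling variability.

What passing these tests does *not* show about real data: no read-level
noise or coverage effects, no splicing-motif realism, no Whippet posterior
calibration, no multi-event transcripts or overlapping genes, and PSI
noise that is homoscedastic on the VST scale by construction. The
generator validates the logic of the pipeline, not the error model of any
particular quantifier.

## Numerical and edge-case conventions

* `vst_psi` rejects inputs outside [0, 1]; its inverse is exact on the
  closed interval.
* Correlation on constant series: degenerate, r = NA, non-significant,
  with a reason string.
* Kendall on all-tied series: τ = 0, p = 1, trend "flat".
* Fisher on empty margins: p = 1, odds ratio NA.
* Intron shorter than a requested flank window: truncated and flagged,
  never silently shortened.
* Duplicate ΔPSI rows deduplicate by (event, contrast); shortlists are
  sorted by event id, making output order input-order invariant.
* The ODE rejects negative schedule values and `k_dr = 0` steady-state
  queries.

## Problem sizes

The shipped tests run the full pipeline on plans of 2–12 genes, the
NMD-oracle comparison on ~1000 transcripts (550 genes), correlation
recovery on 1000 replicates per planted ρ, the Fisher oracle on every 2×2
table with N ≤ 30 (46 376 tables), Kendall enumeration up to n = 8, and
100 random piecewise schedules for the integrator; `scripts/acceptance.R`
uses 150 genes and the same replicate counts. These sizes were chosen to
exercise every code path and strand/type combination exhaustively at the
scale of the planted designs.
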