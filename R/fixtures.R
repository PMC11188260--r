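## Deterministic toy-genome generator: genes with planted AS-NMD structure
## (poison cassette exons, frame-protective exons, alternative donor/acceptor
## extensions and retained introns carrying premature termination codons),
## plus quantification tables with planted statistical structure.
##
## Construction trick: exonic sequence is drawn from the T-free alphabet
## {A,C,G}, which cannot contain a stop codon in any reading frame; start and
## stop codons are then planted explicitly, so the reading-frame consequences
## of every splicing variant are fully controlled. Every planted premature
## stop sits at least 10 nt from the nearest exon boundary and > 50 nt of
## spliced sequence upstream of the last junction, with generous margins.

## local plus-strand gene layout (1-based, gene-local coordinates)
.FIX <- list(
  e_len = c(150L, 120L, 150L, 200L),
  i_len = c(300L, 300L, 300L),
  pad = 4240L)

.fix_layout <- function() {
  e <- .FIX$e_len; i <- .FIX$i_len
  starts <- cumsum(c(1L, head(as.integer(rbind(e, c(i, 0L))), -1)))
  exon_start <- starts[c(1, 3, 5, 7)]
  exon_end <- exon_start + e - 1L
  list(exon_start = exon_start, exon_end = exon_end,
       gene_len = exon_end[4])
}

#' Plan for a synthetic AS-NMD fixture
#'
#' @param seed integer; fully determines every generated byte.
#' @param n_genes number of genes (one per toy chromosome; strands
#'   alternate + / -).
#' @param event_types per-gene planted event labels, recycled over genes;
#'   subset of `NS-CE`, `NR-CE`, `NS-AD`, `NS-AA`, `NS-RI`, `none`.
#' @param timepoints quantification timepoints (days).
#' @param rho planted Pearson correlation between the NMD-protective
#'   splicing pattern and transformed gene expression.
#' @param noise_sd PSI noise s.d. on the variance-stabilised scale.
#' @param dpsi,prob planted responsive-event delta-PSI magnitude and
#'   confidence.
#' @export
fixture_plan <- function(seed = 1, n_genes = 6,
                         event_types = c("NS-CE", "NR-CE", "NS-AD", "NS-AA",
                                         "NS-RI", "none"),
                         timepoints = c(0, 3, 6, 12, 24),
                         rho = 0.6, noise_sd = 0.05,
                         dpsi = 0.3, prob = 0.99) {
  stopifnot(all(event_types %in% c("NS-CE", "NR-CE", "NS-AD", "NS-AA",
                                   "NS-RI", "none")))
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 event_types = rep(event_types,
                                   length.out = max(n_genes, 0)),
                 timepoints = timepoints, rho = rho, noise_sd = noise_sd,
                 dpsi = dpsi, prob = prob),
            class = "fixture_plan")
}

.rand_seq <- function(n, alphabet = c("A", "C", "G", "T"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

.plant <- function(seq, pos, what) {
  stopifnot(pos >= 1, pos + nchar(what) - 1 <= nchar(seq))
  paste0(substr(seq, 1, pos - 1), what, substr(seq, pos + nchar(what),
                                               nchar(seq)))
}

## design one gene in local plus-strand coordinates
.design_gene <- function(type) {
  lay <- .fix_layout()
  es <- lay$exon_start; ee <- lay$exon_end
  L <- lay$gene_len
  notx <- c("A", "C", "G")
  seq <- .rand_seq(L)                 # introns: full alphabet
  for (k in 1:4)                      # exonic backbone: T-free
    seq <- .plant(seq, es[k], .rand_seq(ee[k] - es[k] + 1, notx))
  ## translation start in exon 1, local offset 61 (40+ nt 5' UTR)
  seq <- .plant(seq, 61, "ATG")
  seq <- .plant(seq, 64, "C")         # guard against TGA across the junction
  t1 <- cbind(es, ee)
  ev <- NULL; t2 <- NULL
  ce_len <- if (identical(type, "NR-CE")) 91L else 90L
  if (type %in% c("NS-CE", "NR-CE")) {
    xs <- ee[2] + 106L                # >= 100 nt intron left on both sides
    xe <- xs + ce_len - 1L
    seq <- .plant(seq, xs, .rand_seq(ce_len, notx))
    t2 <- rbind(t1[1:2, ], c(xs, xe), t1[3:4, ])
    ev <- list(type = "CE", start = xs, end = xe)
  } else if (type == "NS-AD") {
    xs <- ee[2] + 1L; xe <- ee[2] + 60L
    seq <- .plant(seq, xs, .rand_seq(60, notx))
    t2 <- rbind(c(es[1], ee[1]), c(es[2], xe), t1[3:4, ])
    ev <- list(type = "AD", start = xs, end = xe)
  } else if (type == "NS-AA") {
    xs <- es[3] - 60L; xe <- es[3] - 1L
    seq <- .plant(seq, xs, .rand_seq(60, notx))
    t2 <- rbind(t1[1:2, ], c(xs, ee[3]), t1[4, , drop = FALSE])
    ev <- list(type = "AA", start = xs, end = xe)
  } else if (type == "NS-RI") {
    xs <- ee[2] + 1L; xe <- es[3] - 1L
    seq <- .plant(seq, xs, .rand_seq(xe - xs + 1, notx))
    t2 <- rbind(c(es[1], ee[1]), c(es[2], ee[3]), t1[4, , drop = FALSE])
    ev <- list(type = "RI", start = xs, end = xe)
  }
  ## stop codons. Planted "PTC" sites sit at spliced offset 301-303 of the
  ## variant isoform (in frame with the offset-61 start; >= 30 nt into the
  ## variant segment), far upstream of the last junction.
  if (type == "NR-CE") {
    seq <- .plant(seq, es[3] + 12L, "TAA")   # PTC read in the skip frame
    seq <- .plant(seq, es[4] + 89L, "TAA")   # inclusion-frame normal stop
    cds_spliced_end <- 282L                  # t1 CDS ends before its PTC
  } else {
    seq <- .plant(seq, es[4] + 60L, "TAA")   # normal stop in the last exon
    cds_spliced_end <- 480L
    if (!is.null(ev)) seq <- .plant(seq, ev$start + 30L, "TAA")
  }
  nmd_effect <- if (is.null(ev)) NA_character_ else
    if (identical(type, "NR-CE")) "NR" else "NS"
  list(seq = seq, t1 = t1, t2 = t2, ev = ev, nmd_effect = nmd_effect,
       cds_spliced_end = cds_spliced_end, gene_len = L)
}

## map a spliced interval onto local genomic intervals of an exon matrix
.spliced_to_local <- function(exons, from, to) {
  w <- exons[, 2] - exons[, 1] + 1L
  cum <- cumsum(w); first <- c(1L, head(cum, -1) + 1L)
  keep <- which(cum >= from & first <= to)
  cbind(pmax(from, first[keep]) - first[keep] + exons[keep, 1],
        pmin(to, cum[keep]) - first[keep] + exons[keep, 1])
}

#' Generate a toy genome + annotation with planted AS-NMD events
#'
#' Each gene gets its own 10-kb chromosome (alternating strands) carrying a
#' four-exon productive isoform `t1` (annotated CDS) and, per the planned
#' event type, a variant isoform `t2` whose inclusion segment either carries
#' a premature stop > 50 nt of spliced sequence upstream of the last
#' junction (NS types) or protects the reading frame that the skipping
#' isoform breaks (NR-CE). Ground truth records every planted event with
#' its expected catalog label.
#'
#' @param plan [fixture_plan()]
#' @return list: `genome` (named `DNAStringSet`), `annotation`
#'   ([annotation_set()]), `truth` (data.frame: gene_id, planted type,
#'   event_id, event_type, chrom, start, end, strand, nmd_effect,
#'   inclusion_tx, skipping_tx).
#' @export
make_toy_annotation <- function(plan) {
  stopifnot(inherits(plan, "fixture_plan"))
  set.seed(plan$seed)
  pad <- .FIX$pad
  chroms <- list(); exons <- list(); cds <- list(); meta <- list()
  truth <- list()
  for (gi in seq_len(plan$n_genes)) {
    type <- plan$event_types[gi]
    strand <- if (gi %% 2 == 1) "+" else "-"
    gene_id <- sprintf("GENE%03d", gi)
    chrom <- sprintf("chr%d", gi)
    d <- .design_gene(type)
    gene_seq <- d$seq
    flip <- function(iv)            # local interval -> chromosome interval
      if (strand == "+") iv + pad else pad + d$gene_len - rev(iv) + 1L
    if (strand == "-")
      gene_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gene_seq)))
    chroms[[chrom]] <- paste0(.rand_seq(pad), gene_seq, .rand_seq(pad))
    to_gr <- function(m) {
      iv <- t(apply(m, 1, flip))
      GenomicRanges::GRanges(chrom,
                             IRanges::IRanges(pmin(iv[, 1], iv[, 2]),
                                              pmax(iv[, 1], iv[, 2])),
                             strand)
    }
    t1_id <- paste0(gene_id, ".t1")
    exons[[t1_id]] <- to_gr(d$t1)
    cds_local <- .spliced_to_local(d$t1, 61L, d$cds_spliced_end)
    cds[[t1_id]] <- sort(to_gr(cds_local))
    meta[[t1_id]] <- data.frame(transcript_id = t1_id, gene_id = gene_id,
                                transcript_biotype = "protein_coding",
                                stringsAsFactors = FALSE)
    if (!is.null(d$t2)) {
      t2_id <- paste0(gene_id, ".t2")
      exons[[t2_id]] <- to_gr(d$t2)
      meta[[t2_id]] <- data.frame(transcript_id = t2_id, gene_id = gene_id,
                                  transcript_biotype = "protein_coding",
                                  stringsAsFactors = FALSE)
      evi <- flip(c(d$ev$start, d$ev$end))
      evs <- min(evi); eve <- max(evi)
      truth[[length(truth) + 1]] <- data.frame(
        gene_id = gene_id, planted = type,
        event_id = paste0(d$ev$type, ":", chrom, ":", evs, "-", eve, ":",
                          strand),
        event_type = d$ev$type, chrom = chrom, start = evs, end = eve,
        strand = strand, nmd_effect = d$nmd_effect,
        inclusion_tx = t2_id, skipping_tx = t1_id,
        stringsAsFactors = FALSE)
    }
  }
  genome <- Biostrings::DNAStringSet(unlist(chroms))
  aset <- annotation_set(GenomicRanges::GRangesList(exons),
                         cds = GenomicRanges::GRangesList(cds),
                         transcripts = do.call(rbind, unname(meta)),
                         provenance = list(source = "synthetic fixture",
                                           seed = plan$seed))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(0), planted = character(0),
               event_id = character(0), event_type = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), nmd_effect = character(0),
               inclusion_tx = character(0), skipping_tx = character(0),
               stringsAsFactors = FALSE)
  list(genome = genome, annotation = aset, truth = truth)
}

## sample-correlation-exact planting: returns y with cor(x, y) == rho by
## projecting the drawn noise into the orthogonal complement of x
.plant_correlation <- function(x, rho, location = 9, scale = 1.5) {
  n <- length(x)
  xs <- as.numeric(scale(x))
  repeat {
    e <- stats::rnorm(n)
    ep <- stats::residuals(stats::lm(e ~ xs))
    if (stats::sd(ep) > 1e-8) break
  }
  es <- as.numeric(scale(ep))
  y <- rho * xs + sqrt(1 - rho^2) * es
  location + scale * y
}

#' Simulate quantification tables over planted events
#'
#' Produces Whippet-style outputs for the planted truth: a PSI table (DMSO
#' condition, per timepoint), a delta-PSI contrast table (CHX-DMSO) with a
#' probability column, and a variance-stabilised expression matrix whose
#' series correlate with each event's NMD-protective splicing pattern at
#' exactly the planted Pearson rho (noise is drawn randomly, then
#' orthogonalised against the signal in-sample, so the sample correlation
#' equals rho in every replicate). PSI noise is applied on the
#' variance-stabilised scale and back-transformed. The probability column is
#' a stand-in for Whippet's posterior, simulated near 1 for responsive
#' events.
#'
#' @param truth truth table from [make_toy_annotation()].
#' @param plan [fixture_plan()] supplying timepoints, rho, noise and
#'   delta-PSI magnitude.
#' @param roles optional named character vector (event_id ->
#'   `"responsive"` / `"null"` / `"extreme-inclusion"`); defaults to all
#'   responsive. `extreme-inclusion` plants near-constitutive inclusion
#'   (NS, mean PSI > 0.9) or near-complete skipping (NR, mean PSI < 0.1)
#'   with a negligible delta-PSI.
#' @param seed RNG seed; defaults to `plan$seed + 1`.
#' @return list: `psi` (long data.frame), `dpsi` (one row per event),
#'   `expr` (matrix gene x timepoint), `roles`.
#' @export
simulate_quantification <- function(truth, plan, roles = NULL, seed = NULL) {
  set.seed(if (is.null(seed)) plan$seed + 1L else seed)
  tp <- plan$timepoints
  n <- length(tp)
  if (is.null(roles))
    roles <- stats::setNames(rep("responsive", nrow(truth)), truth$event_id)
  psi_rows <- list(); dpsi_rows <- list()
  expr <- matrix(NA_real_, nrow = nrow(truth), ncol = n,
                 dimnames = list(truth$gene_id, paste0("d", tp)))
  for (i in seq_len(nrow(truth))) {
    eid <- truth$event_id[i]
    role <- roles[[eid]]
    ns <- truth$nmd_effect[i] == "NS"
    base <- switch(role,
      "responsive" = if (ns) seq(0.1, 0.7, length.out = n)
                     else seq(0.7, 0.1, length.out = n),
      "null" = rep(0.5, n),
      "extreme-inclusion" = if (ns) rep(0.95, n) else rep(0.05, n))
    v <- vst_psi(base) + stats::rnorm(n, 0, plan$noise_sd)
    psi <- vst_psi_inverse(pmin(1, pmax(0, v)))
    psi_rows[[i]] <- data.frame(event_id = eid,
                                sample_id = paste0("DMSO_d", tp),
                                condition = "DMSO", timepoint = tp,
                                psi = psi, stringsAsFactors = FALSE)
    protective <- if (ns) 1 - vst_psi(psi) else vst_psi(psi)
    expr[i, ] <- .plant_correlation(protective, plan$rho)
    d <- switch(role,
      "responsive" = (if (ns) 1 else -1) * plan$dpsi +
        stats::rnorm(1, 0, 0.01),
      "null" = stats::runif(1, -0.04, 0.04),
      "extreme-inclusion" = (if (ns) 1 else -1) * 0.02)
    p <- switch(role,
      "responsive" = min(1, plan$prob + stats::runif(1, 0, 1 - plan$prob)),
      "null" = stats::runif(1, 0.2, 0.8),
      "extreme-inclusion" = stats::runif(1, 0.2, 0.8))
    dpsi_rows[[i]] <- data.frame(event_id = eid, contrast = "CHX-DMSO",
                                 dpsi = d, probability = p,
                                 psi_mean = mean(pmin(1, pmax(0, psi + d / 2))),
                                 stringsAsFactors = FALSE)
  }
  list(psi = do.call(rbind, psi_rows), dpsi = do.call(rbind, dpsi_rows),
       expr = expr, roles = roles)
}

#' Toy per-base conservation track
#'
#' Background score 0.1 across each chromosome, planted score 0.9 over the
#' intronic flank windows of designated events, optional uncovered gaps.
#'
#' @param fix output of [make_toy_annotation()].
#' @param conserved event_ids receiving high-conservation flanks (default:
#'   all planted events).
#' @param gaps optional `GRanges` punched out of the track (uncovered).
#' @param padding flank padding (nt).
#' @return `GRanges` with a `score` column (bedGraph-style).
#' @export
make_toy_track <- function(fix, conserved = fix$truth$event_id, gaps = NULL,
                           padding = 100) {
  chrom_len <- stats::setNames(Biostrings::width(fix$genome),
                               names(fix$genome))
  bg <- GenomicRanges::GRanges(names(chrom_len),
                               IRanges::IRanges(1, unname(chrom_len)), "*")
  pieces <- lapply(which(fix$truth$event_id %in% conserved), function(i) {
    ev <- fix$truth[i, ]
    ev$up_intron_start <- NA_integer_; ev$down_intron_end <- NA_integer_
    granges_nometa(flank_intervals(ev, padding = padding))
  })
  hi <- if (length(pieces))
    suppressWarnings(do.call(c, pieces)) else GenomicRanges::GRanges()
  hi <- GenomicRanges::reduce(hi, ignore.strand = TRUE)
  lo <- BiocGenerics::setdiff(bg, hi, ignore.strand = TRUE)
  if (!is.null(gaps)) {
    lo <- BiocGenerics::setdiff(lo, gaps, ignore.strand = TRUE)
    hi <- BiocGenerics::setdiff(hi, gaps, ignore.strand = TRUE)
  }
  sort(c(`score<-`(lo, value = 0.1), `score<-`(hi, value = 0.9)))
}

#' Write a complete fixture bundle to disk
#'
#' genome.fa, annotation.gtf, truth.tsv, psi.tsv, dpsi.tsv, expr.tsv and
#' cons.bedGraph under `dir`. All plain text; byte-identical across reruns
#' of the same plan.
#'
#' @param plan [fixture_plan()]
#' @param dir output directory (created).
#' @return invisibly, the list from [make_toy_annotation()].
#' @export
write_fixtures <- function(plan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fix <- make_toy_annotation(plan)
  quant <- simulate_quantification(fix$truth, plan)
  Biostrings::writeXStringSet(fix$genome, file.path(dir, "genome.fa"))
  export_annotation(fix$annotation, file.path(dir, "annotation.gtf"))
  utils::write.table(fix$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(quant$psi, file.path(dir, "psi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(quant$dpsi, file.path(dir, "dpsi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = rownames(quant$expr), quant$expr),
                     file.path(dir, "expr.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rtracklayer::export(make_toy_track(fix), file.path(dir, "cons.bedGraph"),
                      format = "bedGraph")
  invisible(fix)
}
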