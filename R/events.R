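## Diffing isoform exon chains into CE / AD / AA / RI events and labelling
## each event's effect on NMD sensitivity.
##
## Donor/acceptor are defined in transcription direction: a plus-strand exon
## has its acceptor (3' splice site) at its genomic start and its donor
## (5' splice site) at its genomic end; on the minus strand the edges swap.

#' Diff two isoforms' exon chains into splicing events
#'
#' Detects, between two same-gene, same-strand isoforms:
#' \describe{
#'   \item{CE}{an internal exon of one chain absent from the other, with both
#'     flanking splice junctions shared.}
#'   \item{AD / AA}{a pair of exons sharing the acceptor but differing at the
#'     donor (AD), or sharing the donor and differing at the acceptor (AA),
#'     with the junction beyond the alternative site shared.}
#'   \item{RI}{an intron of one isoform fully contained in a single exon of
#'     the other whose boundaries match the flanking exons.}
#' }
#' Exonic differences not matching these patterns are reported as one
#' `complex` row per contiguous residual region and are skipped downstream.
#'
#' @param aset [annotation_set()]
#' @param tx_a,tx_b transcript ids on the same gene and strand.
#' @return data.frame: event_id, event_type (CE/AD/AA/RI/complex), chrom,
#'   start, end (1-based, the included interval), strand, inclusion_tx,
#'   skipping_tx, up/down adjacent-intron bounds (genomic left/right;
#'   NA where not applicable).
#' @export
diff_splice_chains <- function(aset, tx_a, tx_b) {
  sa <- tx_strand(aset, tx_a); sb <- tx_strand(aset, tx_b)
  if (sa != sb) stop("transcripts on different strands")
  ga <- tx_gene(aset, tx_a); gb <- tx_gene(aset, tx_b)
  if (!is.na(ga) && !is.na(gb) && ga != gb)
    stop("transcripts belong to different genes")
  A <- tx_exons(aset, tx_a); B <- tx_exons(aset, tx_b)
  chrom <- as.character(GenomicRanges::seqnames(A))[1]
  ev <- rbind(.find_ce(A, B, tx_a, tx_b), .find_ce(B, A, tx_b, tx_a),
              .find_ri(A, B, tx_a, tx_b), .find_ri(B, A, tx_b, tx_a),
              .find_alt_site(A, B, tx_a, tx_b, sa))
  if (is.null(ev))
    ev <- data.frame(event_type = character(0), start = integer(0),
                     end = integer(0), inclusion_tx = character(0),
                     skipping_tx = character(0),
                     up_intron_start = integer(0), up_intron_end = integer(0),
                     down_intron_start = integer(0),
                     down_intron_end = integer(0), stringsAsFactors = FALSE)
  ev <- unique(ev)
  ## residual exonic differences not explained by recognised events
  diffbases <- c(BiocGenerics::setdiff(granges_nometa(A), granges_nometa(B)),
                 BiocGenerics::setdiff(granges_nometa(B), granges_nometa(A)))
  if (nrow(ev)) {
    expl <- GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(ev$start, ev$end), sa)
    resid <- BiocGenerics::setdiff(diffbases, expl, ignore.strand = TRUE)
  } else resid <- diffbases
  ## transcript-end differences (alternative TSS/TES) are not events
  span_a <- range(c(GenomicRanges::start(A), GenomicRanges::end(A)))
  span_b <- range(c(GenomicRanges::start(B), GenomicRanges::end(B)))
  inner <- c(max(span_a[1], span_b[1]), min(span_a[2], span_b[2]))
  resid <- resid[GenomicRanges::start(resid) >= inner[1] &
                 GenomicRanges::end(resid) <= inner[2]]
  if (length(resid)) {
    resid <- GenomicRanges::reduce(resid, ignore.strand = TRUE)
    ev <- rbind(ev, data.frame(
      event_type = "complex", start = GenomicRanges::start(resid),
      end = GenomicRanges::end(resid), inclusion_tx = NA_character_,
      skipping_tx = NA_character_, up_intron_start = NA_integer_,
      up_intron_end = NA_integer_, down_intron_start = NA_integer_,
      down_intron_end = NA_integer_, stringsAsFactors = FALSE))
  }
  if (!nrow(ev)) {
    ev$event_id <- character(0); ev$chrom <- character(0)
    ev$strand <- character(0)
    return(ev[c("event_id", "event_type", "chrom", "start", "end", "strand",
                "inclusion_tx", "skipping_tx", "up_intron_start",
                "up_intron_end", "down_intron_start", "down_intron_end")])
  }
  ev$chrom <- chrom
  ev$strand <- sa
  ev$event_id <- paste0(ev$event_type, ":", chrom, ":", ev$start, "-",
                        ev$end, ":", sa)
  ev[order(ev$start, ev$event_type),
     c("event_id", "event_type", "chrom", "start", "end", "strand",
       "inclusion_tx", "skipping_tx", "up_intron_start", "up_intron_end",
       "down_intron_start", "down_intron_end")]
}

## cassette exons of A absent from B (A = inclusion isoform)
.find_ce <- function(A, B, tx_a, tx_b) {
  if (length(A) < 3) return(NULL)
  out <- NULL
  sA <- GenomicRanges::start(A); eA <- GenomicRanges::end(A)
  sB <- GenomicRanges::start(B); eB <- GenomicRanges::end(B)
  for (i in 2:(length(A) - 1)) {
    if (any(sB <= eA[i] & eB >= sA[i])) next       # overlaps a B exon
    j <- which(eB == eA[i - 1])                    # shared donor junction
    if (length(j) != 1 || j == length(B)) next
    if (sB[j + 1] != sA[i + 1]) next               # shared acceptor junction
    out <- rbind(out, data.frame(
      event_type = "CE", start = sA[i], end = eA[i],
      inclusion_tx = tx_a, skipping_tx = tx_b,
      up_intron_start = eA[i - 1] + 1L, up_intron_end = sA[i] - 1L,
      down_intron_start = eA[i] + 1L, down_intron_end = sA[i + 1] - 1L,
      stringsAsFactors = FALSE))
  }
  out
}

## introns of B retained inside a single exon of A (A = retaining isoform)
.find_ri <- function(A, B, tx_a, tx_b) {
  if (length(B) < 2) return(NULL)
  out <- NULL
  sA <- GenomicRanges::start(A); eA <- GenomicRanges::end(A)
  sB <- GenomicRanges::start(B); eB <- GenomicRanges::end(B)
  for (j in seq_len(length(B) - 1)) {
    i <- which(sA == sB[j] & eA == eB[j + 1])      # exon spanning both + intron
    if (length(i) != 1) next
    out <- rbind(out, data.frame(
      event_type = "RI", start = eB[j] + 1L, end = sB[j + 1] - 1L,
      inclusion_tx = tx_a, skipping_tx = tx_b,
      up_intron_start = NA_integer_, up_intron_end = NA_integer_,
      down_intron_start = NA_integer_, down_intron_end = NA_integer_,
      stringsAsFactors = FALSE))
  }
  out
}

## alternative donor/acceptor pairs between A and B
.find_alt_site <- function(A, B, tx_a, tx_b, strand) {
  out <- NULL
  sA <- GenomicRanges::start(A); eA <- GenomicRanges::end(A)
  sB <- GenomicRanges::start(B); eB <- GenomicRanges::end(B)
  for (i in seq_along(A)) for (j in seq_along(B)) {
    if (sA[i] > eB[j] || sB[j] > eA[i]) next       # no overlap
    if (sA[i] == sB[j] && eA[i] != eB[j]) {
      ## shared genomic-start edge, alternative genomic-end edge; needs a
      ## shared junction at the next genomic exon on both chains
      if (i == length(A) || j == length(B)) next
      if (sA[i + 1] != sB[j + 1]) next
      type <- if (strand == "+") "AD" else "AA"
      longer_a <- eA[i] > eB[j]
      out <- rbind(out, data.frame(
        event_type = type, start = min(eA[i], eB[j]) + 1L,
        end = max(eA[i], eB[j]),
        inclusion_tx = if (longer_a) tx_a else tx_b,
        skipping_tx = if (longer_a) tx_b else tx_a,
        up_intron_start = NA_integer_, up_intron_end = NA_integer_,
        down_intron_start = max(eA[i], eB[j]) + 1L,
        down_intron_end = sA[i + 1] - 1L, stringsAsFactors = FALSE))
    } else if (eA[i] == eB[j] && sA[i] != sB[j]) {
      if (i == 1 || j == 1) next
      if (eA[i - 1] != eB[j - 1]) next
      type <- if (strand == "+") "AA" else "AD"
      longer_a <- sA[i] < sB[j]
      out <- rbind(out, data.frame(
        event_type = type, start = min(sA[i], sB[j]),
        end = max(sA[i], sB[j]) - 1L,
        inclusion_tx = if (longer_a) tx_a else tx_b,
        skipping_tx = if (longer_a) tx_b else tx_a,
        up_intron_start = eA[i - 1] + 1L,
        up_intron_end = min(sA[i], sB[j]) - 1L,
        down_intron_start = NA_integer_, down_intron_end = NA_integer_,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Label one event's effect on NMD from a pair of discordant isoforms
#'
#' Over all supporting isoform pairs of an event: inclusion co-occurring
#' with NMD sensitivity and skipping with insensitivity in every informative
#' pair makes the event NMD-stimulating (`NS`); the reverse, NMD-repressing
#' (`NR`); mixed evidence, `ambiguous`; no informative pair, `none`.
#'
#' @param pair_rows data.frame rows for one event (from
#'   [diff_splice_chains()]) with `inclusion_tx`/`skipping_tx`.
#' @param verdicts verdict table from [annotate_nmd()].
#' @return character scalar: NS / NR / ambiguous / none.
#' @export
classify_event_nmd <- function(pair_rows, verdicts) {
  v <- function(tx) {
    k <- match(tx, verdicts$transcript_id)
    if (is.na(k) || !verdicts$has_cds[k]) NA else verdicts$is_nmd[k]
  }
  labels <- character(0)
  for (r in seq_len(nrow(pair_rows))) {
    vi <- v(pair_rows$inclusion_tx[r]); vs <- v(pair_rows$skipping_tx[r])
    if (is.na(vi) || is.na(vs) || vi == vs) next
    labels <- c(labels, if (vi) "NS" else "NR")
  }
  if (!length(labels)) return("none")
  u <- unique(labels)
  if (length(u) == 1) u else "ambiguous"
}

#' Build the non-redundant AS-NMD event catalog of an annotation set
#'
#' Diffs every same-gene isoform pair, keeps pairs differing by exactly one
#' recognised event (so NMD attribution is never confounded by co-varying
#' events), labels each event NS/NR/ambiguous via [classify_event_nmd()],
#' and deduplicates by (type, coordinates, strand). Genes without at least
#' one NMD-sensitive and one insensitive isoform contribute nothing.
#'
#' @param aset [annotation_set()]
#' @param verdicts verdict table from [annotate_nmd()].
#' @param keep_ambiguous keep events with conflicting NS/NR evidence
#'   (labelled `ambiguous`); default TRUE.
#' @return data.frame: event_id, gene_id, event_type, chrom, start, end,
#'   strand, nmd_effect, n_supporting_pairs, adjacent-intron bounds.
#' @export
build_event_catalog <- function(aset, verdicts, keep_ambiguous = TRUE) {
  genes <- split(aset$transcripts$transcript_id, aset$transcripts$gene_id)
  rows <- list()
  for (g in sort(names(genes))) {
    txs <- sort(genes[[g]])
    vg <- verdicts[verdicts$transcript_id %in% txs & verdicts$has_cds, ]
    if (!any(vg$is_nmd) || !any(!vg$is_nmd)) next
    if (length(txs) < 2) next
    for (i in seq_len(length(txs) - 1)) for (j in (i + 1):length(txs)) {
      ev <- diff_splice_chains(aset, txs[i], txs[j])
      ev <- ev[ev$event_type != "complex", , drop = FALSE]
      if (nrow(ev) != 1) next                     # unconfounded pairs only
      ev$gene_id <- g
      rows[[length(rows) + 1]] <- ev
    }
  }
  if (!length(rows))
    return(data.frame(event_id = character(0), gene_id = character(0),
                      event_type = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), nmd_effect = character(0),
                      n_supporting_pairs = integer(0),
                      stringsAsFactors = FALSE))
  all_rows <- do.call(rbind, rows)
  out <- lapply(split(all_rows, all_rows$event_id), function(d) {
    eff <- classify_event_nmd(d, verdicts)
    n_inf <- sum(vapply(seq_len(nrow(d)), function(r) {
      k1 <- match(d$inclusion_tx[r], verdicts$transcript_id)
      k2 <- match(d$skipping_tx[r], verdicts$transcript_id)
      !is.na(k1) && !is.na(k2) && verdicts$has_cds[k1] &&
        verdicts$has_cds[k2] && verdicts$is_nmd[k1] != verdicts$is_nmd[k2]
    }, logical(1)))
    cbind(d[1, c("event_id", "gene_id", "event_type", "chrom", "start",
                 "end", "strand", "up_intron_start", "up_intron_end",
                 "down_intron_start", "down_intron_end")],
          data.frame(nmd_effect = eff, n_supporting_pairs = n_inf,
                     stringsAsFactors = FALSE))
  })
  cat <- do.call(rbind, out)
  keep <- cat$nmd_effect %in% c("NS", "NR", if (keep_ambiguous) "ambiguous")
  cat <- cat[keep, , drop = FALSE]
  cat <- cat[order(cat$chrom, cat$start, cat$event_type), ]
  rownames(cat) <- NULL
  cat[c("event_id", "gene_id", "event_type", "chrom", "start", "end",
        "strand", "nmd_effect", "n_supporting_pairs", "up_intron_start",
        "up_intron_end", "down_intron_start", "down_intron_end")]
}
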