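## Allocation of assembled (novel) transcripts to reference genes, and removal
## of novel entries whose intron chains duplicate a reference transcript.

#' Intron-chain identity key
#'
#' String key identifying a transcript's ordered intron chain
#' (chrom/strand/intron coordinates). Terminal exon boundaries do not enter
#' the key, so transcripts differing only at their ends compare equal.
#' Single-exon transcripts instead get an exon-identity key, marked as such.
#'
#' @param aset [annotation_set()]
#' @param transcript_id transcript id.
#' @export
intron_chain_key <- function(aset, transcript_id) {
  ex <- tx_exons(aset, transcript_id)
  chrom <- as.character(GenomicRanges::seqnames(ex))[1]
  str <- as.character(GenomicRanges::strand(ex))[1]
  if (length(ex) == 1)
    return(paste0("monoexon|", chrom, ":", GenomicRanges::start(ex), "-",
                  GenomicRanges::end(ex), ":", str))
  introns <- exon_gaps(ex)
  paste0("chain|", chrom, ":", str, "|",
         paste(GenomicRanges::start(introns), GenomicRanges::end(introns),
               sep = "-", collapse = ","))
}

#' Drop novel transcripts duplicating reference intron chains
#'
#' A multi-exon novel transcript is removed iff some same-strand reference
#' transcript has the exact same ordered intron chain (the gffcompare "="
#' class code); terminal exon ends may differ. Single-exon novel transcripts
#' are removed only on exact exon equality with a reference single-exon
#' transcript, the conservative analogue of chain identity.
#'
#' @param novel,ref [annotation_set()]s.
#' @return list with `annotation` (filtered novel set) and `removed`
#'   (data.frame: transcript_id, matched reference transcript).
#' @export
drop_reference_matches <- function(novel, ref) {
  ref_keys <- vapply(names(ref$exons), function(tx) intron_chain_key(ref, tx),
                     character(1))
  nov_keys <- vapply(names(novel$exons), function(tx)
    intron_chain_key(novel, tx), character(1))
  hit <- match(nov_keys, ref_keys)
  drop <- !is.na(hit)
  removed <- data.frame(transcript_id = names(novel$exons)[drop],
                        matched_reference = names(ref$exons)[hit[drop]],
                        stringsAsFactors = FALSE)
  keep <- names(novel$exons)[!drop]
  list(annotation = subset_annotation(novel, keep), removed = removed)
}

#' Subset an annotation set to selected transcripts
#' @param aset [annotation_set()]
#' @param transcript_ids ids to keep.
#' @export
subset_annotation <- function(aset, transcript_ids) {
  stopifnot(all(transcript_ids %in% names(aset$exons)))
  annotation_set(
    aset$exons[transcript_ids],
    cds = aset$cds[intersect(names(aset$cds), transcript_ids)],
    transcripts = aset$transcripts[
      aset$transcripts$transcript_id %in% transcript_ids, , drop = FALSE],
    provenance = aset$provenance)
}

#' Allocate novel transcripts to reference genes
#'
#' Each novel transcript is assigned to the same-strand reference gene with
#' maximal shared exonic base overlap; ties break lexicographically on
#' gene_id so assignment is input-order invariant. Transcripts overlapping no
#' reference exons get a fresh, deterministic novel gene id derived from
#' their locus.
#'
#' @param novel,ref [annotation_set()]s (novel ideally pre-filtered with
#'   [drop_reference_matches()]).
#' @return data.frame with one row per novel transcript: `transcript_id`,
#'   `assigned_gene_id`, `overlap_bases`, `status`
#'   (`assigned` / `novel-gene`).
#' @export
assign_genes <- function(novel, ref) {
  ## flatten reference exons with gene labels
  ref_tab <- ref$transcripts
  ref_ex <- lapply(names(ref$exons), function(tx) {
    g <- granges_nometa(ref$exons[[tx]])
    g$gene_id <- ref_tab$gene_id[match(tx, ref_tab$transcript_id)]
    g
  })
  ref_ex <- if (length(ref_ex)) do.call(c, ref_ex) else GenomicRanges::GRanges()
  recs <- lapply(names(novel$exons), function(tx) {
    ex <- novel$exons[[tx]]
    if (length(ref_ex)) {
      hits <- GenomicRanges::findOverlaps(ex, ref_ex, ignore.strand = FALSE)
      if (length(hits)) {
        genes <- unique(ref_ex$gene_id[S4Vectors::subjectHits(hits)])
        ## shared exonic bases per candidate gene, on reduced exon sets so
        ## overlapping reference exons are not double counted
        exact <- vapply(genes, function(g) {
          gex <- GenomicRanges::reduce(ref_ex[ref_ex$gene_id == g])
          sum(GenomicRanges::width(BiocGenerics::intersect(
            granges_nometa(ex), granges_nometa(gex))))
        }, numeric(1))
        best <- sort(genes[exact == max(exact)])[1]
        return(data.frame(transcript_id = tx, assigned_gene_id = best,
                          overlap_bases = unname(max(exact)),
                          status = "assigned", stringsAsFactors = FALSE))
      }
    }
    data.frame(transcript_id = tx,
               assigned_gene_id = novel_gene_id(ex),
               overlap_bases = 0, status = "novel-gene",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

## deterministic id from the transcript locus, stable across reruns
novel_gene_id <- function(ex) {
  paste0("NOVELG:", as.character(GenomicRanges::seqnames(ex))[1], ":",
         min(GenomicRanges::start(ex)), "-", max(GenomicRanges::end(ex)), ":",
         as.character(GenomicRanges::strand(ex))[1])
}

#' Merge a novel annotation into a reference using gene assignments
#'
#' Rewrites the novel transcripts' `gene_id`s per [assign_genes()] and
#' concatenates reference and novel sets.
#'
#' @param novel,ref [annotation_set()]s.
#' @param assignments output of [assign_genes()] (recomputed when NULL).
#' @export
merge_annotations <- function(novel, ref, assignments = NULL) {
  if (is.null(assignments)) assignments <- assign_genes(novel, ref)
  ntab <- novel$transcripts
  ntab$gene_id <- assignments$assigned_gene_id[
    match(ntab$transcript_id, assignments$transcript_id)]
  ntab$novelty <- "novel"
  rtab <- ref$transcripts
  rtab$novelty <- "reference"
  allcols <- union(names(rtab), names(ntab))
  for (col in setdiff(allcols, names(rtab))) rtab[[col]] <- NA
  for (col in setdiff(allcols, names(ntab))) ntab[[col]] <- NA
  annotation_set(
    c(ref$exons, novel$exons),
    cds = c(ref$cds, novel$cds),
    transcripts = rbind(rtab[allcols], ntab[allcols]),
    provenance = list(source = "merged"))
}
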