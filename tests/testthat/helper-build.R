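## Hand-built annotation sets used across tests. Coordinates given 1-based
## closed (GTF style), exons as rbind(c(start, end), ...) matrices.

make_set <- function(txs, gene_ids = NULL) {
  exons <- list(); cds <- list(); meta <- list()
  for (id in names(txs)) {
    t <- txs[[id]]
    exons[[id]] <- GenomicRanges::GRanges(
      t$chrom, IRanges::IRanges(t$exons[, 1], t$exons[, 2]), t$strand)
    if (!is.null(t$cds))
      cds[[id]] <- GenomicRanges::GRanges(
        t$chrom, IRanges::IRanges(t$cds[, 1], t$cds[, 2]), t$strand)
    meta[[id]] <- data.frame(
      transcript_id = id,
      gene_id = if (is.null(t$gene)) "G1" else t$gene,
      stringsAsFactors = FALSE)
  }
  annotation_set(GenomicRanges::GRangesList(exons),
                 cds = if (length(cds)) GenomicRanges::GRangesList(cds)
                       else NULL,
                 transcripts = do.call(rbind, unname(meta)))
}

## random DNA of length n as a character string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

## genome with one chromosome from a character string
one_chrom <- function(seq, name = "chr1")
  Biostrings::DNAStringSet(stats::setNames(seq, name))
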