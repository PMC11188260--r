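#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList strand seqnames start end width
#'   reduce findOverlaps pintersect mcols mcols<-
#' @importFrom IRanges IRanges ranges
#' @importFrom S4Vectors queryHits subjectHits Rle DataFrame
NULL

#' Transcript annotation container
#'
#' An `annotation_set` bundles a transcriptome: per-transcript exon chains,
#' optional CDS chains, and a transcript-level metadata table. Coordinates are
#' 1-based closed genomic intervals (the GTF and GenomicRanges convention);
#' exons of a transcript are stored sorted by genomic start and are pairwise
#' disjoint. Strand is mandatory for every transcript because donor/acceptor
#' semantics and ORF logic are strand-aware.
#'
#' @param exons `GRangesList` named by transcript id; each element one
#'   transcript's exons (any order; they are sorted and validated).
#' @param cds `GRangesList` named by transcript id (subset of `names(exons)`);
#'   may be missing or empty.
#' @param transcripts data.frame with at least `transcript_id` and `gene_id`
#'   columns; one row per transcript. Extra columns (e.g. biotype) are kept
#'   verbatim.
#' @param provenance free-form list recording where the data came from.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(exons, cds = NULL, transcripts = NULL,
                           provenance = list()) {
  stopifnot(methods::is(exons, "GRangesList"))
  if (length(exons) && (is.null(names(exons)) || anyDuplicated(names(exons))))
    stop("exons must be a GRangesList uniquely named by transcript_id")
  exons <- GRangesList(lapply(exons, .tidy_exons), compress = TRUE)
  if (is.null(cds)) cds <- GRangesList()
  if (length(cds)) {
    if (!all(names(cds) %in% names(exons)))
      stop("cds names must be a subset of exon names")
    cds <- GRangesList(lapply(cds, function(gr) sort(gr)), compress = TRUE)
  }
  if (is.null(transcripts)) {
    ids <- if (is.null(names(exons))) character(0) else names(exons)
    transcripts <- data.frame(transcript_id = ids,
                              gene_id = rep(NA_character_, length(ids)),
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(c("transcript_id", "gene_id") %in% names(transcripts)))
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicated transcript_id in metadata table")
  if (!setequal(transcripts$transcript_id, names(exons)))
    stop("metadata table and exon list disagree on transcript ids")
  transcripts <- transcripts[match(names(exons), transcripts$transcript_id), ,
                             drop = FALSE]
  rownames(transcripts) <- NULL
  ## strand is required (donor/acceptor semantics); "*" is rejected
  str <- vapply(seq_along(exons), function(i)
    as.character(strand(exons[[i]])[1]), character(1))
  if (any(str == "*"))
    stop("transcripts with undefined strand ('*'): ",
         paste(names(exons)[str == "*"], collapse = ", "))
  structure(list(exons = exons, cds = cds, transcripts = transcripts,
                 provenance = provenance),
            class = "annotation_set")
}

.tidy_exons <- function(gr) {
  gr <- sort(gr, ignore.strand = TRUE)
  if (length(gr) > 1 && any(start(gr)[-1] <= end(gr)[-length(gr)])) {
    warning("overlapping/adjacent exons within one transcript merged")
    gr <- reduce(gr)
  }
  if (length(unique(as.character(seqnames(gr)))) != 1)
    stop("exons of one transcript on multiple chromosomes")
  if (length(unique(as.character(strand(gr)))) != 1)
    stop("exons of one transcript on multiple strands")
  gr
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$exons), "transcripts,",
      length(unique(x$transcripts$gene_id)), "genes;",
      sum(lengths(x$cds) > 0), "with CDS\n")
  invisible(x)
}

#' Number of transcripts in an annotation set
#' @param x annotation_set
#' @export
n_transcripts <- function(x) length(x$exons)

#' Exons / CDS of one transcript
#'
#' @param aset annotation_set
#' @param transcript_id single transcript id
#' @return `GRanges` of exons (sorted by genomic start), or CDS intervals
#'   (`tx_cds`; zero-length `GRanges` when the transcript has no CDS).
#' @export
tx_exons <- function(aset, transcript_id) {
  if (!transcript_id %in% names(aset$exons))
    stop("unknown transcript: ", transcript_id)
  aset$exons[[transcript_id]]
}

#' @rdname tx_exons
#' @export
tx_cds <- function(aset, transcript_id) {
  if (transcript_id %in% names(aset$cds)) aset$cds[[transcript_id]]
  else GRanges()
}

#' Strand and gene of a transcript
#' @inheritParams tx_exons
#' @export
tx_strand <- function(aset, transcript_id)
  as.character(strand(tx_exons(aset, transcript_id))[1])

#' @rdname tx_strand
#' @export
tx_gene <- function(aset, transcript_id)
  aset$transcripts$gene_id[match(transcript_id,
                                 aset$transcripts$transcript_id)]

#' Introns of a transcript
#'
#' Gaps between consecutive exons; empty for single-exon transcripts.
#'
#' @inheritParams tx_exons
#' @return `GRanges` of introns sorted by genomic start.
#' @export
get_introns <- function(aset, transcript_id) {
  ex <- tx_exons(aset, transcript_id)
  exon_gaps(ex)
}

## gaps between sorted exons, as a GRanges on the same chrom/strand
exon_gaps <- function(ex) {
  if (length(ex) < 2)
    return(GRanges(seqnames = character(0), ranges = IRanges(),
                   strand = character(0)))
  GRanges(seqnames = as.character(seqnames(ex))[1],
          ranges = IRanges(start = end(ex)[-length(ex)] + 1L,
                           end = start(ex)[-1] - 1L),
          strand = as.character(strand(ex))[1])
}

#' Spliced (mRNA) length of a transcript
#' @inheritParams tx_exons
#' @export
spliced_length <- function(aset, transcript_id)
  sum(width(tx_exons(aset, transcript_id)))

#' Map genomic positions to spliced transcript offsets
#'
#' Offsets are 1-based and count spliced nucleotides from the transcript 5'
#' end in transcription direction: on the minus strand the highest genomic
#' coordinate of the 5'-most exon maps to offset 1.
#'
#' @inheritParams tx_exons
#' @param gpos vector of genomic base positions (1-based); every position must
#'   be exonic in the transcript.
#' @return integer vector of transcript offsets.
#' @export
genomic_to_transcript <- function(aset, transcript_id, gpos) {
  ex <- tx_exons(aset, transcript_id)
  minus <- as.character(strand(ex))[1] == "-"
  cum <- cumsum(width(ex))
  off <- vapply(gpos, function(g) {
    i <- which(g >= start(ex) & g <= end(ex))
    if (length(i) != 1)
      stop("position ", g, " is not exonic in ", transcript_id)
    before <- if (i > 1) cum[i - 1] else 0L
    as.integer(before + (g - start(ex)[i]) + 1L)
  }, integer(1))
  if (minus) sum(width(ex)) - off + 1L else off
}

#' Map spliced transcript offsets back to genomic positions
#'
#' Inverse of [genomic_to_transcript()].
#'
#' @inheritParams tx_exons
#' @param offset vector of 1-based transcript offsets in
#'   `[1, spliced_length]`.
#' @export
transcript_to_genomic <- function(aset, transcript_id, offset) {
  ex <- tx_exons(aset, transcript_id)
  total <- sum(width(ex))
  if (any(offset < 1 | offset > total))
    stop("offset outside [1, ", total, "] for ", transcript_id)
  minus <- as.character(strand(ex))[1] == "-"
  plus_off <- if (minus) total - offset + 1L else offset
  cum <- cumsum(width(ex))
  vapply(plus_off, function(o) {
    i <- which.max(cum >= o)
    before <- if (i > 1) cum[i - 1] else 0L
    as.integer(start(ex)[i] + (o - before) - 1L)
  }, integer(1))
}

#' Genomic footprint of a spliced sub-interval
#'
#' Projects the transcript-coordinate interval `[from, to]` (1-based, in
#' transcription direction) onto the genome, returning one `GRanges` piece per
#' exon it touches.
#'
#' @inheritParams tx_exons
#' @param from,to transcript offsets, `from <= to`.
#' @export
spliced_interval_to_genomic <- function(aset, transcript_id, from, to) {
  stopifnot(from <= to)
  ex <- tx_exons(aset, transcript_id)
  minus <- as.character(strand(ex))[1] == "-"
  total <- sum(width(ex))
  ## convert to plus-orientation spliced coordinates
  pr <- if (minus) c(total - to + 1L, total - from + 1L) else c(from, to)
  cum <- cumsum(width(ex))
  first <- c(1L, cum[-length(cum)] + 1L)
  keep <- which(cum >= pr[1] & first <= pr[2])
  pieces <- lapply(keep, function(i) {
    s <- max(pr[1], first[i]) - first[i] + start(ex)[i]
    e <- min(pr[2], cum[i]) - first[i] + start(ex)[i]
    c(s, e)
  })
  GRanges(seqnames = as.character(seqnames(ex))[1],
          ranges = IRanges(start = vapply(pieces, `[`, numeric(1), 1),
                           end = vapply(pieces, `[`, numeric(1), 2)),
          strand = as.character(strand(ex))[1])
}

#' Spliced transcript sequence
#'
#' @inheritParams tx_exons
#' @param genome named `DNAStringSet` (names = chromosomes) or any object
#'   `Biostrings::getSeq` accepts.
#' @return `DNAString` of the mature mRNA (reverse-complemented on minus
#'   strand).
#' @export
spliced_seq <- function(aset, transcript_id, genome) {
  ex <- tx_exons(aset, transcript_id)
  chrom <- as.character(seqnames(ex))[1]
  if (methods::is(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) stop("chromosome absent from genome: ", chrom)
    pieces <- Biostrings::DNAStringSet(lapply(seq_along(ex), function(i)
      Biostrings::subseq(genome[[chrom]], start(ex)[i], end(ex)[i])))
  } else {
    pieces <- Biostrings::getSeq(genome, `strand<-`(ex, "+"))
  }
  s <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  if (as.character(strand(ex))[1] == "-") Biostrings::reverseComplement(s) else s
}

#' Read a GTF annotation
#'
#' Parses a GENCODE-dialect GTF via `rtracklayer` into an [annotation_set()].
#' Exon and CDS features must carry `gene_id` and `transcript_id` attributes;
#' transcripts with undefined strand are rejected. Exon rows listed in any
#' order are sorted; overlapping exons within one transcript are merged with
#' a warning.
#'
#' @param path GTF file.
#' @param keep_attributes extra attribute columns to retain on the transcript
#'   table when present (e.g. `"transcript_biotype"`). `gene_name` is always
#'   kept when present.
#' @return [annotation_set()]
#' @export
read_annotation <- function(path,
                            keep_attributes = c("gene_name",
                                                "transcript_biotype",
                                                "gene_biotype")) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (!length(gr)) stop("no exon/CDS features in ", path)
  bad <- which(is.na(gr$transcript_id) | is.na(gr$gene_id))
  if (length(bad))
    stop("feature #", bad[1], " (", as.character(seqnames(gr))[bad[1]], ":",
         start(gr)[bad[1]], "-", end(gr)[bad[1]],
         ") lacks transcript_id/gene_id")
  is_exon <- gr$type == "exon"
  exons <- split(gr[is_exon], gr$transcript_id[is_exon])
  exons <- GRangesList(lapply(exons, function(g) {
    mcols(g) <- NULL
    g
  }), compress = TRUE)
  cdsgr <- gr[!is_exon]
  cds <- if (length(cdsgr)) {
    sp <- split(cdsgr, cdsgr$transcript_id)
    GRangesList(lapply(sp, function(g) { mcols(g) <- NULL; sort(g) }),
                compress = TRUE)
  } else GRangesList()
  meta_src <- as.data.frame(mcols(gr[is_exon]))
  keep <- intersect(unique(c("gene_id", keep_attributes)), names(meta_src))
  idx <- match(names(exons), gr$transcript_id[is_exon])
  transcripts <- cbind(data.frame(transcript_id = names(exons),
                                  stringsAsFactors = FALSE),
                       meta_src[idx, keep, drop = FALSE])
  rownames(transcripts) <- NULL
  annotation_set(exons, cds = cds, transcripts = transcripts,
                 provenance = list(source = path, dialect = "gtf"))
}

#' Write an annotation set as GTF
#'
#' Emits transcript, exon and CDS rows; a read/write/read round trip
#' preserves exon chains, CDS intervals and the retained attributes.
#'
#' @param aset [annotation_set()]
#' @param path output file.
#' @export
export_annotation <- function(aset, path) {
  rows <- list()
  for (tx in names(aset$exons)) {
    ex <- aset$exons[[tx]]
    meta <- aset$transcripts[match(tx, aset$transcripts$transcript_id), ,
                             drop = FALSE]
    cds <- tx_cds(aset, tx)
    gr <- c(granges_nometa(ex), granges_nometa(cds))
    ## GTF frame column: phase of each CDS piece in transcription order
    phase <- rep(NA_integer_, length(gr))
    if (length(cds)) {
      w <- width(cds)
      ord <- if (as.character(strand(cds))[1] == "-") rev(seq_along(w)) else
        seq_along(w)
      before <- cumsum(c(0L, w[ord]))[seq_along(w)]
      ph <- (3L - before %% 3L) %% 3L
      phase[length(ex) + ord] <- ph
    }
    df <- DataFrame(type = c(rep("exon", length(ex)),
                             rep("CDS", length(cds))),
                    phase = phase,
                    transcript_id = tx,
                    gene_id = meta$gene_id)
    for (col in setdiff(names(meta), c("transcript_id", "gene_id")))
      df[[col]] <- meta[[col]]
    mcols(gr) <- df
    rows[[tx]] <- gr
  }
  out <- if (length(rows)) do.call(c, unname(rows)) else
    GRanges(type = character(0))
  rtracklayer::export(out, path, format = "gtf")
  invisible(path)
}

granges_nometa <- function(gr) {
  mcols(gr) <- NULL
  gr
}

#' Write an event catalog as TSV
#'
#' One row per non-redundant event, mirroring the exported exon-table format:
#' event id, gene, type, 1-based coordinates, NMD-effect label and support.
#'
#' @param catalog data.frame as returned by [build_event_catalog()].
#' @param path output TSV.
#' @export
export_event_table <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a PSI / delta-PSI / expression TSV
#'
#' Thin readers for Whippet-style quantification tables. PSI values are
#' fractions in \[0, 1\]; a `psi_percent` column, if present instead of `psi`,
#' is divided by 100.
#'
#' @param path TSV file.
#' @export
read_psi_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"psi" %in% names(df) && "psi_percent" %in% names(df)) {
    df$psi <- df$psi_percent / 100
    df$psi_percent <- NULL
  }
  if (any(df$psi < 0 | df$psi > 1, na.rm = TRUE))
    stop("psi values outside [0,1]")
  df
}
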