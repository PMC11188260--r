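## Event-type-specific intronic flank windows and per-base conservation
## averaging over them.

#' Intronic flank windows of an AS event
#'
#' Derives the windows over which intronic conservation is scored:
#' \describe{
#'   \item{CE}{`padding` nt of intron on each side of the exon.}
#'   \item{RI}{first and last `padding` nt of the retained intron.}
#'   \item{AD}{`2*padding` nt of intron immediately downstream (in
#'     transcription direction) of the distal donor.}
#'   \item{AA}{`2*padding` nt of intron immediately upstream of the distal
#'     acceptor.}
#' }
#' Windows are truncated at the neighbouring exon boundaries (the adjacent
#' intron bounds recorded in the event catalog) and at the retained intron's
#' own extent; truncation is flagged. Windows never overlap the event's
#' exonic sequence for CE/AD/AA.
#'
#' @param event one catalog row (list/data.frame with event_type, chrom,
#'   start, end, strand and the adjacent-intron bound columns; missing
#'   bounds mean "no truncation known").
#' @param padding nt, default 100.
#' @return `GRanges` of windows with a logical `truncated` metadata column.
#' @export
flank_intervals <- function(event, padding = 100) {
  type <- event$event_type
  chrom <- event$chrom; s <- event$start; e <- event$end
  str <- event$strand
  lo_bound <- event$up_intron_start
  hi_bound <- event$down_intron_end
  win <- function(ws, we) {
    tr <- FALSE
    if (!is.null(lo_bound) && !is.na(lo_bound) && ws < lo_bound) {
      ws <- lo_bound; tr <- TRUE
    }
    if (!is.null(hi_bound) && !is.na(hi_bound) && we > hi_bound) {
      we <- hi_bound; tr <- TRUE
    }
    if (ws < 1) { ws <- 1; tr <- TRUE }
    if (we < ws) stop("flank window collapsed for event at ",
                      chrom, ":", s, "-", e)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(ws, we), str,
                           truncated = tr)
  }
  if (type == "CE") {
    return(c(win(s - padding, s - 1), win(e + 1, e + padding)))
  }
  if (type == "RI") {
    w <- e - s + 1
    first <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(s, min(e, s + padding - 1)), str,
      truncated = w < padding)
    last <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(max(s, e - padding + 1), e), str,
      truncated = w < padding)
    return(c(first, last))
  }
  if (type == "AD") {
    ## distal donor: extension far edge; window downstream in transcription
    if (str == "+") return(win(e + 1, e + 2 * padding))
    return(win(s - 2 * padding, s - 1))
  }
  if (type == "AA") {
    ## distal acceptor: extension far edge; window upstream in transcription
    if (str == "+") return(win(s - 2 * padding, s - 1))
    return(win(e + 1, e + 2 * padding))
  }
  stop("unsupported event type: ", type)
}

#' Read a per-base conservation track
#'
#' bedGraph (plain-text, for fixtures) or bigWig via `rtracklayer`.
#'
#' @param path track file; format inferred from the extension.
#' @return `GRanges` with a numeric `score` column.
#' @export
read_track <- function(path) {
  fmt <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) "bigWig"
  else "bedGraph"
  rtracklayer::import(path, format = fmt)
}

#' Mean conservation over a set of intervals
#'
#' Arithmetic mean of per-base track values over the bases the track covers;
#' uncovered bases are excluded from the mean (PhastCons gaps mark
#' unalignable sequence) and counted, unless `missing_as_zero = TRUE`, which
#' instead imputes them as 0.
#'
#' @param intervals `GRanges` (e.g. from [flank_intervals()]).
#' @param track `GRanges` with `score` (from [read_track()]).
#' @param missing_as_zero impute uncovered bases as 0 (default FALSE).
#' @return list: mean_score (NA with a reason when nothing is covered),
#'   covered_bases, missing_bases, total_bases.
#' @export
mean_conservation <- function(intervals, track, missing_as_zero = FALSE) {
  intervals <- GenomicRanges::reduce(intervals, ignore.strand = TRUE)
  total <- sum(GenomicRanges::width(intervals))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(intervals, track, ignore.strand = TRUE))
  if (!length(hits)) {
    if (missing_as_zero && total > 0)
      return(list(mean_score = 0, covered_bases = 0L,
                  missing_bases = total, total_bases = total))
    return(list(mean_score = NA_real_, covered_bases = 0L,
                missing_bases = total, total_bases = total,
                reason = "no covered bases"))
  }
  qs <- intervals[S4Vectors::queryHits(hits)]
  ts <- track[S4Vectors::subjectHits(hits)]
  w <- pmin(GenomicRanges::end(qs), GenomicRanges::end(ts)) -
    pmax(GenomicRanges::start(qs), GenomicRanges::start(ts)) + 1L
  sc <- ts$score
  covered <- sum(w)
  denom <- if (missing_as_zero) total else covered
  list(mean_score = sum(sc * w) / denom,
       covered_bases = covered,
       missing_bases = total - covered,
       total_bases = total)
}

#' Conservation scores for an event catalog
#'
#' @param catalog event catalog ([build_event_catalog()]).
#' @param track `GRanges` with score, or a path readable by [read_track()].
#' @param padding flank padding in nt (default 100).
#' @param missing_as_zero see [mean_conservation()].
#' @return catalog with mean_score, covered_bases, missing_bases and
#'   truncated columns appended.
#' @export
score_catalog_conservation <- function(catalog, track, padding = 100,
                                       missing_as_zero = FALSE) {
  if (is.character(track)) track <- read_track(track)
  res <- lapply(seq_len(nrow(catalog)), function(i) {
    ev <- catalog[i, ]
    fl <- flank_intervals(ev, padding = padding)
    sc <- mean_conservation(fl, track, missing_as_zero = missing_as_zero)
    data.frame(mean_score = sc$mean_score, covered_bases = sc$covered_bases,
               missing_bases = sc$missing_bases,
               truncated = any(fl$truncated))
  })
  cbind(catalog, do.call(rbind, res))
}
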