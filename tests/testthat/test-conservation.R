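ce_event <- function(start = 501, end = 600, strand = "+",
                     up = NA_integer_, down = NA_integer_)
  data.frame(event_type = "CE", chrom = "chr1", start = start, end = end,
             strand = strand, up_intron_start = up, down_intron_end = down,
             stringsAsFactors = FALSE)

test_that("flank windows follow the event-type rules", {
  fl <- flank_intervals(ce_event(), padding = 100)
  expect_equal(GenomicRanges::start(fl), c(401, 601))
  expect_equal(GenomicRanges::end(fl), c(500, 700))
  expect_false(any(fl$truncated))
  ## windows never overlap the exon
  expect_true(all(GenomicRanges::end(fl) < 501 |
                  GenomicRanges::start(fl) > 600))

  ri <- data.frame(event_type = "RI", chrom = "chr1", start = 1001,
                   end = 2000, strand = "+", up_intron_start = NA,
                   down_intron_end = NA)
  fr <- flank_intervals(ri, padding = 100)
  expect_equal(GenomicRanges::start(fr), c(1001, 1901))
  expect_equal(GenomicRanges::end(fr), c(1100, 2000))

  ad_plus <- data.frame(event_type = "AD", chrom = "chr1", start = 601,
                        end = 660, strand = "+", up_intron_start = NA,
                        down_intron_end = NA)
  fa <- flank_intervals(ad_plus, padding = 100)
  expect_equal(c(GenomicRanges::start(fa), GenomicRanges::end(fa)),
               c(661, 860))
  ## minus-strand AD: downstream in transcription = genomically left
  ad_minus <- ad_plus; ad_minus$strand <- "-"
  fm <- flank_intervals(ad_minus, padding = 100)
  expect_equal(c(GenomicRanges::start(fm), GenomicRanges::end(fm)),
               c(401, 600))
  aa_plus <- ad_plus; aa_plus$event_type <- "AA"
  fp <- flank_intervals(aa_plus, padding = 100)
  expect_equal(c(GenomicRanges::start(fp), GenomicRanges::end(fp)),
               c(401, 600))
})

test_that("windows are truncated at neighbouring exon boundaries and flagged", {
  fl <- flank_intervals(ce_event(up = 461, down = 640), padding = 100)
  expect_equal(GenomicRanges::start(fl), c(461, 601))
  expect_equal(GenomicRanges::end(fl), c(500, 640))
  expect_true(all(fl$truncated))
  ## short retained intron
  ri <- data.frame(event_type = "RI", chrom = "chr1", start = 1001,
                   end = 1060, strand = "+", up_intron_start = NA,
                   down_intron_end = NA)
  fr <- flank_intervals(ri, padding = 100)
  expect_true(all(fr$truncated))
  expect_true(all(GenomicRanges::start(fr) >= 1001 &
                  GenomicRanges::end(fr) <= 1060))
})

test_that("strand reversal mirrors the flank windows of planted fixtures", {
  fix <- make_toy_annotation(fixture_plan(seed = 3, n_genes = 4,
                                          event_types = c("NS-AD", "NS-AD",
                                                          "NS-AA", "NS-AA")))
  tr <- fix$truth
  stopifnot(tr$strand[1] == "+", tr$strand[2] == "-")
  for (type in c("AD", "AA")) {
    pair <- tr[tr$event_type == type, ]
    f_plus <- flank_intervals(transform(pair[1, ], up_intron_start = NA,
                                        down_intron_end = NA))
    f_minus <- flank_intervals(transform(pair[2, ], up_intron_start = NA,
                                         down_intron_end = NA))
    ## identical local geometry: window offsets mirror around the event
    d_plus <- GenomicRanges::start(f_plus) - pair$end[1]
    d_minus <- pair$start[2] - GenomicRanges::end(f_minus)
    expect_equal(abs(d_plus), abs(d_minus))
  }
})

test_that("mean conservation averages covered bases and counts the gaps", {
  uni <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000), "*",
                                score = 0.5)
  res <- mean_conservation(flank_intervals(ce_event()), uni)
  expect_equal(res$mean_score, 0.5)
  expect_equal(res$covered_bases, 200)
  expect_equal(res$missing_bases, 0)

  half <- c(GenomicRanges::GRanges("chr1", IRanges::IRanges(401, 500), "*",
                                   score = 1),
            GenomicRanges::GRanges("chr1", IRanges::IRanges(601, 700), "*",
                                   score = 0))
  expect_equal(mean_conservation(flank_intervals(ce_event()),
                                 half)$mean_score, 0.5)

  ## sparse track: agree with the per-base loop oracle; gaps counted
  set.seed(14)
  pieces <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(410, 470, 630, 690),
                             end = c(430, 520, 660, 699)), "*")
  pieces$score <- round(runif(4), 3)
  win <- flank_intervals(ce_event())
  got <- mean_conservation(win, pieces)
  expect_equal(got$mean_score, oracle_mean_conservation(win, pieces))
  expect_equal(got$covered_bases + got$missing_bases, 200)
  ## missing-as-zero mode shrinks the mean by the coverage fraction
  z <- mean_conservation(win, pieces, missing_as_zero = TRUE)
  expect_equal(z$mean_score,
               got$mean_score * got$covered_bases / got$total_bases)
})

test_that("zero coverage is reported as undefined with a reason", {
  track <- GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 10), "*",
                                  score = 1)
  res <- mean_conservation(flank_intervals(ce_event()), track)
  expect_true(is.na(res$mean_score))
  expect_equal(res$reason, "no covered bases")
})

test_that("bedGraph round trip feeds the scorer", {
  fix <- make_toy_annotation(fixture_plan(seed = 6, n_genes = 2,
                                          event_types = c("NS-CE", "NR-CE")))
  track <- make_toy_track(fix)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  rtracklayer::export(track, path, format = "bedGraph")
  back <- read_track(path)
  ann <- annotate_nmd(fix$annotation, fix$genome)
  cat1 <- build_event_catalog(ann$annotation, ann$verdicts)
  scored <- score_catalog_conservation(cat1, back)
  expect_equal(scored$mean_score, rep(0.9, nrow(scored)))
  ## an event without planted conservation scores at background level
  t2 <- make_toy_track(fix, conserved = fix$truth$event_id[1])
  scored2 <- score_catalog_conservation(cat1, t2)
  other <- scored2$event_id != fix$truth$event_id[1]
  expect_equal(scored2$mean_score[other], rep(0.1, sum(other)))
})
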