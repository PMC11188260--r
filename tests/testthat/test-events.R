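test_that("cassette exons are detected with both flanking junctions shared", {
  aset <- make_set(list(
    A = list(chrom = "chr1", strand = "+",
             exons = rbind(c(1, 100), c(501, 600), c(801, 900))),
    B = list(chrom = "chr1", strand = "+",
             exons = rbind(c(1, 100), c(801, 900)))))
  ev <- diff_splice_chains(aset, "A", "B")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_type, "CE")
  expect_equal(c(ev$start, ev$end), c(501, 600))
  expect_equal(ev$inclusion_tx, "A")
  ## symmetric call swaps inclusion sides only
  ev2 <- diff_splice_chains(aset, "B", "A")
  expect_equal(ev2$event_id, ev$event_id)
  expect_equal(ev2$inclusion_tx, "A")
})

test_that("alternative donors and acceptors follow transcription-direction semantics", {
  plusAD <- make_set(list(
    A = list(chrom = "chr1", strand = "+",
             exons = rbind(c(1, 120), c(201, 300))),
    B = list(chrom = "chr1", strand = "+",
             exons = rbind(c(1, 100), c(201, 300)))))
  ev <- diff_splice_chains(plusAD, "A", "B")
  expect_equal(ev$event_type, "AD")
  expect_equal(c(ev$start, ev$end), c(101, 120))
  expect_equal(ev$inclusion_tx, "A")

  plusAA <- make_set(list(
    A = list(chrom = "chr1", strand = "+",
             exons = rbind(c(1, 100), c(181, 300))),
    B = list(chrom = "chr1", strand = "+",
             exons = rbind(c(1, 100), c(201, 300)))))
  ev <- diff_splice_chains(plusAA, "A", "B")
  expect_equal(ev$event_type, "AA")
  expect_equal(c(ev$start, ev$end), c(181, 200))
  expect_equal(ev$inclusion_tx, "A")

  ## minus strand: donor sits at the genomic-left exon edge, so a shared
  ## genomic-right junction with differing genomic-left edges is an AD
  minusAD <- make_set(list(
    A = list(chrom = "chr1", strand = "-",
             exons = rbind(c(1, 100), c(181, 300), c(401, 500))),
    B = list(chrom = "chr1", strand = "-",
             exons = rbind(c(1, 100), c(201, 300), c(401, 500)))))
  ev <- diff_splice_chains(minusAD, "A", "B")
  expect_equal(ev$event_type, "AD")
  expect_equal(c(ev$start, ev$end), c(181, 200))
  expect_equal(ev$inclusion_tx, "A")

  ## minus strand: shared donor (intron genomic-right end), different
  ## acceptors (genomic-left intron ends) is an AA
  minusAA <- make_set(list(
    A = list(chrom = "chr1", strand = "-",
             exons = rbind(c(1, 100), c(301, 400))),
    B = list(chrom = "chr1", strand = "-",
             exons = rbind(c(1, 120), c(301, 400)))))
  ev <- diff_splice_chains(minusAA, "A", "B")
  expect_equal(ev$event_type, "AA")
  expect_equal(c(ev$start, ev$end), c(101, 120))
  expect_equal(ev$inclusion_tx, "B")
})

test_that("retained introns require the retaining exon to match both flanking exons", {
  aset <- make_set(list(
    A = list(chrom = "chr1", strand = "+", exons = rbind(c(1, 300))),
    B = list(chrom = "chr1", strand = "+",
             exons = rbind(c(1, 100), c(201, 300))),
    C = list(chrom = "chr1", strand = "+",
             exons = rbind(c(1, 100), c(201, 350)))))
  ev <- diff_splice_chains(aset, "A", "B")
  expect_equal(ev$event_type, "RI")
  expect_equal(c(ev$start, ev$end), c(101, 200))
  expect_equal(ev$inclusion_tx, "A")
  ## C's terminal exon end differs from A's: not a clean retention
  ev2 <- diff_splice_chains(aset, "A", "C")
  expect_false("RI" %in% ev2$event_type)
})

test_that("unmatched internal differences come back as complex, not mislabelled events", {
  ## mutually exclusive exons
  aset <- make_set(list(
    A = list(chrom = "chr1", strand = "+",
             exons = rbind(c(1, 100), c(301, 400), c(801, 900))),
    B = list(chrom = "chr1", strand = "+",
             exons = rbind(c(1, 100), c(501, 600), c(801, 900)))))
  ev <- diff_splice_chains(aset, "A", "B")
  expect_true(all(ev$event_type == "complex"))
})

test_that("different strands are a usage error", {
  aset <- make_set(list(
    A = list(chrom = "chr1", strand = "+", exons = rbind(c(1, 100))),
    B = list(chrom = "chr1", strand = "-", exons = rbind(c(1, 100)),
             gene = "G1")))
  expect_error(diff_splice_chains(aset, "A", "B"), "strand")
})

verdict_table <- function(...) {
  v <- list(...)
  data.frame(transcript_id = names(v), has_cds = TRUE,
             is_nmd = unlist(v), stringsAsFactors = FALSE)
}

test_that("event NMD labels follow the inclusion/verdict co-occurrence rule", {
  rows <- data.frame(inclusion_tx = "A", skipping_tx = "B",
                     stringsAsFactors = FALSE)
  expect_equal(classify_event_nmd(rows, verdict_table(A = TRUE, B = FALSE)),
               "NS")
  expect_equal(classify_event_nmd(rows, verdict_table(A = FALSE, B = TRUE)),
               "NR")
  expect_equal(classify_event_nmd(rows, verdict_table(A = TRUE, B = TRUE)),
               "none")
  rows2 <- data.frame(inclusion_tx = c("A", "C"), skipping_tx = c("B", "D"),
                      stringsAsFactors = FALSE)
  expect_equal(classify_event_nmd(rows2, verdict_table(A = TRUE, B = FALSE,
                                                       C = FALSE, D = TRUE)),
               "ambiguous")
})

test_that("the catalog is non-redundant, labelled from fixtures, and order-invariant", {
  plan <- fixture_plan(seed = 11, n_genes = 12)
  fix <- make_toy_annotation(plan)
  ann <- annotate_nmd(fix$annotation, fix$genome)
  cat1 <- build_event_catalog(ann$annotation, ann$verdicts)
  expect_equal(anyDuplicated(cat1$event_id), 0)
  expect_setequal(cat1$event_id, fix$truth$event_id)
  expect_equal(cat1$nmd_effect[match(fix$truth$event_id, cat1$event_id)],
               fix$truth$nmd_effect)
  ## reversing transcript order leaves the catalog unchanged
  rev_ids <- rev(names(ann$annotation$exons))
  aset_rev <- subset_annotation(ann$annotation, rev_ids)
  cat2 <- build_event_catalog(aset_rev, ann$verdicts)
  expect_equal(cat1$event_id, cat2$event_id)
  expect_equal(cat1$nmd_effect, cat2$nmd_effect)
})

test_that("genes whose isoforms are all productive contribute no events", {
  aset <- make_set(list(
    A = list(chrom = "chr1", strand = "+",
             exons = rbind(c(1, 100), c(501, 600), c(801, 900)),
             cds = rbind(c(1, 100), c(501, 540))),
    B = list(chrom = "chr1", strand = "+",
             exons = rbind(c(1, 100), c(801, 900)),
             cds = rbind(c(1, 100), c(801, 840)))))
  verdicts <- data.frame(transcript_id = c("A", "B"), has_cds = TRUE,
                         is_nmd = FALSE, stringsAsFactors = FALSE)
  expect_equal(nrow(build_event_catalog(aset, verdicts)), 0)
})
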