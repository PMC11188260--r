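## geometry helper: plus-strand two-exon transcript whose stop codon ends
## exactly `d` spliced nt upstream of the last junction (CDS excludes stop;
## stop occupies spliced offsets 61..63, exon 1 length 63 + d)
two_exon_with_distance <- function(d) {
  L1 <- 63 + d
  make_set(list(T1 = list(
    chrom = "chr1", strand = "+",
    exons = rbind(c(1, L1), c(L1 + 101, L1 + 200)),
    cds = rbind(c(1, 60)))))
}

test_that("the 50-nt rule is strict and needs >= 2 exons", {
  expect_false(predict_nmd(two_exon_with_distance(49), "T1")$is_nmd)
  expect_false(predict_nmd(two_exon_with_distance(50), "T1")$is_nmd)
  expect_true(predict_nmd(two_exon_with_distance(51), "T1")$is_nmd)
  expect_equal(predict_nmd(two_exon_with_distance(51), "T1")$
                 dist_stop_to_last_junction, 51)
  ## stop inside the last exon: negative distance, never NMD
  last <- make_set(list(T1 = list(
    chrom = "chr1", strand = "+",
    exons = rbind(c(1, 100), c(201, 400)),
    cds = rbind(c(1, 100), c(201, 297)))))
  v <- predict_nmd(last, "T1")
  expect_true(v$dist_stop_to_last_junction < 0)
  expect_false(v$is_nmd)
  ## single-exon transcript
  mono <- make_set(list(T1 = list(chrom = "chr1", strand = "+",
                                  exons = rbind(c(1, 400)),
                                  cds = rbind(c(1, 60)))))
  expect_false(predict_nmd(mono, "T1")$is_nmd)
  ## missing CDS
  nocds <- make_set(list(T1 = list(chrom = "chr1", strand = "+",
                                   exons = rbind(c(1, 100), c(201, 300)))))
  expect_false(predict_nmd(nocds, "T1")$has_cds)
})

test_that("raising the threshold never converts a negative call to positive", {
  aset <- two_exon_with_distance(120)
  calls <- vapply(c(0, 50, 100, 119, 120, 200),
                  function(th) predict_nmd(aset, "T1", threshold = th)$is_nmd,
                  logical(1))
  expect_equal(calls, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(all(diff(as.integer(calls)) <= 0))  # monotone non-increasing
})

test_that("stop-anchor choice shifts the distance by the two remaining stop bases", {
  aset <- two_exon_with_distance(49)
  expect_equal(predict_nmd(aset, "T1", stop_anchor = "start")$
                 dist_stop_to_last_junction, 51)
  expect_true(predict_nmd(aset, "T1", stop_anchor = "start")$is_nmd)
})

test_that("appending exons 3' of the stop codon can only create, not destroy, NMD calls", {
  base <- make_set(list(T1 = list(
    chrom = "chr1", strand = "+",
    exons = rbind(c(1, 100), c(201, 400)),
    cds = rbind(c(1, 100), c(201, 230)))))
  extended <- make_set(list(T1 = list(
    chrom = "chr1", strand = "+",
    exons = rbind(c(1, 100), c(201, 400), c(501, 700)),
    cds = rbind(c(1, 100), c(201, 230)))))
  expect_false(predict_nmd(base, "T1")$is_nmd)
  expect_true(predict_nmd(extended, "T1")$is_nmd)
})

## hand-built locus for CDS projection: reference R1 with annotated CDS,
## novel isoforms sharing (or not) its start codon. T-free exonic sequence
## with explicitly planted ATG / TAA codons.
projection_locus <- function() {
  set.seed(42)
  chars <- strsplit(rand_dna(400), "")[[1]]
  no_t <- function(a, b) {
    n <- b - a + 1
    chars[a:b] <<- sample(c("A", "C", "G"), n, TRUE)
  }
  no_t(1, 61)                       # exon 1 [1,61], ATG at 11
  chars[11:13] <- c("A", "T", "G"); chars[14] <- "C"
  no_t(100, 129)                    # cassette [100,129], TAA at 103
  chars[103:105] <- c("T", "A", "A")
  no_t(162, 261)                    # exon 2 [162,261], TAA at 192
  chars[192:194] <- c("T", "A", "A")
  genome <- one_chrom(paste(chars, collapse = ""))
  aset <- make_set(list(
    R1 = list(chrom = "chr1", strand = "+",
              exons = rbind(c(1, 61), c(162, 261)),
              cds = rbind(c(11, 61), c(162, 191))),
    N_same = list(chrom = "chr1", strand = "+",      # longer terminal exon
                  exons = rbind(c(1, 61), c(162, 300))),
    N_ce = list(chrom = "chr1", strand = "+",        # in-frame stop cassette
                exons = rbind(c(1, 61), c(100, 129), c(162, 261))),
    N_nostart = list(chrom = "chr1", strand = "+",   # excludes the ref ATG
                     exons = rbind(c(162, 261))),
    N_nostop = list(chrom = "chr1", strand = "+",    # T-free to the end
                    exons = rbind(c(1, 61)))))
  list(aset = aset, genome = genome)
}

test_that("reference start codons project onto novel isoforms and translation finds the stop", {
  loc <- projection_locus()
  same <- build_cds(loc$aset, "N_same", loc$genome)
  expect_equal(same$status, "built")
  ## same stop as the reference: CDS ends at genomic 191
  expect_equal(max(GenomicRanges::end(same$cds)), 191)
  expect_equal(min(GenomicRanges::start(same$cds)), 11)

  ce <- build_cds(loc$aset, "N_ce", loc$genome)
  expect_equal(ce$status, "built")
  ## truncated inside the cassette exon by its in-frame TAA
  expect_equal(max(GenomicRanges::end(ce$cds)), 102)

  expect_equal(build_cds(loc$aset, "N_nostart", loc$genome)$status,
               "no-start")
  expect_equal(build_cds(loc$aset, "N_nostop", loc$genome)$status,
               "stop-not-found")
})

test_that("annotate_nmd matches the codon-walking oracle on seeded fixtures", {
  plan <- fixture_plan(seed = 301, n_genes = 12)
  fix <- make_toy_annotation(plan)
  ann <- annotate_nmd(fix$annotation, fix$genome)
  for (tx in names(ann$annotation$exons)) {
    o <- oracle_nmd(ann$annotation, tx, fix$genome)
    k <- match(tx, ann$verdicts$transcript_id)
    expect_equal(ann$verdicts$is_nmd[k], o$is_nmd, info = tx)
    expect_equal(ann$verdicts$has_cds[k], o$has_cds, info = tx)
  }
  ## determinism
  ann2 <- annotate_nmd(fix$annotation, fix$genome)
  expect_identical(ann$verdicts, ann2$verdicts)
})

test_that("poison-exon fixtures give discordant verdicts for inclusion and skipping isoforms", {
  fix <- make_toy_annotation(fixture_plan(seed = 5, n_genes = 2,
                                          event_types = c("NS-CE", "NR-CE")))
  ann <- annotate_nmd(fix$annotation, fix$genome)
  v <- function(tx) ann$verdicts$is_nmd[match(tx, ann$verdicts$transcript_id)]
  expect_true(v("GENE001.t2"))    # NS: inclusion isoform degraded
  expect_false(v("GENE001.t1"))
  expect_false(v("GENE002.t2"))   # NR: inclusion isoform protected
  expect_true(v("GENE002.t1"))
})

test_that("an annotation without any CDS yields only has_cds = FALSE verdicts", {
  aset <- make_set(list(T1 = list(chrom = "chr1", strand = "+",
                                  exons = rbind(c(1, 100), c(201, 300)))))
  ann <- annotate_nmd(aset, genome = NULL)
  expect_false(any(ann$verdicts$has_cds))
  expect_false(any(ann$verdicts$is_nmd))
})
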