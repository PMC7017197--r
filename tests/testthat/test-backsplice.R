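.seg <- function(rid, idx, chrom, s, e, strand = "+", sample = "S1") {
  data.frame(read_id = rid, segment_index = idx, chrom = chrom,
             start = s, end = e, strand = strand, sample_id = sample,
             stringsAsFactors = FALSE)
}

test_that("reverse-order segments define a junction; forward order does not", {
  rev2 <- rbind(.seg("r1", 1, "chr1", 800, 820), .seg("r1", 2, "chr1", 500, 530),
                .seg("r2", 1, "chr1", 790, 815), .seg("r2", 2, "chr1", 500, 540))
  j <- detectJunctions(rev2, minSupport = 2)
  expect_length(j, 0)  # two reads but two distinct candidate coordinates
  rev2b <- rbind(.seg("r1", 1, "chr1", 800, 820), .seg("r1", 2, "chr1", 500, 530),
                 .seg("r2", 1, "chr1", 800, 820), .seg("r2", 2, "chr1", 500, 530))
  j <- detectJunctions(rev2b, minSupport = 2)
  expect_length(j, 1)
  # 0-based [500, 820) -> 1-based 501..820
  expect_equal(GenomicRanges::start(j), 501)
  expect_equal(GenomicRanges::end(j), 820)
  fwd <- rbind(.seg("f1", 1, "chr1", 500, 530), .seg("f1", 2, "chr1", 800, 820),
               .seg("f2", 1, "chr1", 500, 530), .seg("f2", 2, "chr1", 800, 820))
  expect_length(detectJunctions(fwd), 0)
})

test_that("single-read junctions, cross-chromosome and cross-strand pairs are excluded", {
  one <- rbind(.seg("r1", 1, "chr1", 800, 820), .seg("r1", 2, "chr1", 500, 530))
  expect_length(detectJunctions(one, minSupport = 2), 0)
  expect_length(detectJunctions(one, minSupport = 1), 1)
  xc <- rbind(.seg("r1", 1, "chr1", 800, 820),
              .seg("r1", 2, "chr2", 500, 530),
              .seg("r2", 1, "chr1", 800, 820),
              .seg("r2", 2, "chr2", 500, 530))
  expect_length(detectJunctions(xc, minSupport = 1), 0)
  xs <- rbind(.seg("r1", 1, "chr1", 800, 820),
              .seg("r1", 2, "chr1", 500, 530, strand = "-"),
              .seg("r2", 1, "chr1", 800, 820),
              .seg("r2", 2, "chr1", 500, 530, strand = "-"))
  xs$strand <- c("+", "-", "+", "-")
  expect_length(detectJunctions(xs, minSupport = 1), 0)
})

test_that("reads with more than two segments are skipped with a warning", {
  three <- rbind(.seg("r1", 1, "chr1", 800, 820),
                 .seg("r1", 2, "chr1", 600, 630),
                 .seg("r1", 3, "chr1", 500, 530))
  expect_warning(j <- detectJunctions(three, minSupport = 1), "r1")
  expect_length(j, 0)
  bad <- .seg("r1", 1, "chr1", 500, 400)
  expect_error(detectJunctions(bad), "malformed")
})

test_that("detection equals the exhaustive double-loop reference", {
  for (rep in 1:30) {
    tab <- randomSegmentTable(nReads = sample(20:120, 1), seed = 400 + rep)
    got <- juncKeys(detectJunctions(tab, minSupport = 2))
    want <- oracleDetectJunctions(tab, minSupport = 2)
    expect_identical(got, want)
  }
})

test_that("junction boundaries snap to exon ends within tolerance only", {
  gm <- makeGenome(1, c(3, 3), seed = 2)
  ex <- exonRanges(gm)
  ex <- ex[order(GenomicRanges::start(ex))]
  es <- GenomicRanges::start(ex)[1]; ee <- GenomicRanges::end(ex)[2]
  strand1 <- as.character(GenomicRanges::strand(ex))[1]
  mk <- function(s, e) GenomicRanges::GRanges("chr1",
    IRanges::IRanges(s, e), strand1,
    circ_id = "c", total_support = 2L)
  off <- snapToExons(mk(es + 1, ee - 1), gm, tolerance = 2)
  expect_true(S4Vectors::mcols(off)$snapped)
  expect_equal(GenomicRanges::start(off), es)
  expect_equal(GenomicRanges::end(off), ee)
  exact <- snapToExons(mk(es, ee), gm, tolerance = 2)
  expect_true(S4Vectors::mcols(exact)$snapped)
  expect_equal(GenomicRanges::start(exact), es)
  far <- snapToExons(mk(es + 10, ee - 10), gm, tolerance = 2)
  expect_false(S4Vectors::mcols(far)$snapped)
  expect_equal(GenomicRanges::start(far), es + 10)  # unchanged
})

test_that("origins classify as exonic, intronic or intergenic", {
  gm <- makeGenome(2, c(6, 6), seed = 9)
  tx <- transcriptTable(gm)
  ex <- exonRanges(gm)
  sub <- ex[S4Vectors::mcols(ex)$transcript_id == tx$transcript_id[1]]
  sub <- sub[order(GenomicRanges::start(sub))]
  strand1 <- as.character(GenomicRanges::strand(sub))[1]
  chrom <- as.character(GenomicRanges::seqnames(sub))[1]
  mk <- function(s, e) GenomicRanges::GRanges(chrom,
    IRanges::IRanges(s, e), strand1, circ_id = "c")
  # exons 2..4 (genomic order) of a 6-exon transcript
  span <- mk(GenomicRanges::start(sub)[2], GenomicRanges::end(sub)[4])
  got <- classifyOrigin(span, gm)
  expect_equal(S4Vectors::mcols(got)$origin, "coding-exon")
  expect_equal(S4Vectors::mcols(got)$n_exons, 3L)
  expect_equal(S4Vectors::mcols(got)$host_gene, tx$gene_id[1])
  # ordinals count from the transcript 5' end
  ords <- as.integer(strsplit(S4Vectors::mcols(got)$exon_indices, ",")[[1]])
  if (strand1 == "+") expect_equal(ords, 2:4) else expect_equal(ords, 3:5)
  # inside intron 1
  intr <- mk(GenomicRanges::end(sub)[1] + 5, GenomicRanges::start(sub)[2] - 5)
  expect_equal(S4Vectors::mcols(classifyOrigin(intr, gm))$origin, "intronic")
  # before any gene
  away <- GenomicRanges::GRanges(chrom, IRanges::IRanges(5, 50), strand1,
                                 circ_id = "c")
  expect_equal(S4Vectors::mcols(classifyOrigin(away, gm))$origin,
               "intergenic")
})

test_that("RPM follows its definition and is duplication invariant", {
  expect_equal(unname(quantifyRpm(c(S1 = 5), c(S1 = 2e6))[1, 1]), 2.5)
  expect_equal(unname(quantifyRpm(c(S1 = 0), c(S1 = 1e6))[1, 1]), 0)
  expect_equal(unname(quantifyRpm(c(S1 = 1000), c(S1 = 1000))[1, 1]), 1e6)
  expect_error(quantifyRpm(c(S1 = 5), c(S1 = 0)), "S1")
  set.seed(77)
  m <- matrix(rpois(30, 10), 10, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  tot <- c(a = 1e5, b = 2e5, c = 3e5)
  expect_equal(quantifyRpm(2 * m, 2 * tot), quantifyRpm(m, tot))
})

test_that("the minimum-evidence filter honors the two-read rule", {
  m <- rbind(allOnes = c(1, 1, 1), oneGood = c(0, 2, 0), zero = c(0, 0, 0))
  colnames(m) <- c("s1", "s2", "s3")
  kept <- filterMinEvidence(m)
  expect_identical(rownames(kept), "oneGood")
  empty <- m[0, , drop = FALSE]
  expect_identical(filterMinEvidence(empty), empty)
})

test_that("per-gene summaries average RPM and drop intergenic junctions", {
  gr <- GenomicRanges::GRanges(rep("chr1", 3),
                               IRanges::IRanges(c(1, 100, 200) * 10,
                                                c(5, 105, 205) * 10))
  S4Vectors::mcols(gr)$host_gene <- c("g1", "g1", NA)
  rpm <- matrix(c(1, 3, 99), ncol = 1)
  out <- perGeneSummary(gr, rpm)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_circ, 2)
  expect_equal(out$mean_rpm, 2)
})

test_that("noise-free fixtures are recovered perfectly", {
  gm <- makeGenome(12, c(3, 5), seed = 41, exonLength = c(100, 200))
  tx <- transcriptTable(gm)
  ex <- exonRanges(gm)
  plan <- do.call(rbind, lapply(1:10, function(i) {
    sub <- ex[S4Vectors::mcols(ex)$transcript_id == tx$transcript_id[i]]
    sub <- sub[order(GenomicRanges::start(sub))]
    data.frame(circ_id = sprintf("p%02d", i),
               chrom = as.character(GenomicRanges::seqnames(sub))[1],
               start = GenomicRanges::start(sub)[1],
               end = GenomicRanges::end(sub)[2],
               strand = as.character(GenomicRanges::strand(sub))[1],
               S1 = 2L + i %% 3, S2 = 3L, stringsAsFactors = FALSE)
  }))
  sim <- simulateBackspliceReads(gm, plan, c("S1", "S2"),
                                 linearDepth = 100, readLength = 80,
                                 seed = 6)
  j <- detectJunctions(sim$segments, minSupport = 2)
  expect_length(j, 10)
  got <- paste(as.character(GenomicRanges::seqnames(j)),
               GenomicRanges::start(j), GenomicRanges::end(j))
  want <- paste(plan$chrom, plan$start, plan$end)
  expect_setequal(got, want)
})
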