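test_that("index entries are 36-nt doubled-sequence substrings", {
  set.seed(110)
  circles <- stats::setNames(vapply(1:8, function(i)
    randomCircle(sample(60:200, 1), seed = 110 + i), character(1)),
    sprintf("c%02d", 1:8))
  idx <- buildJunctionIndex(circles, flank = 18)
  entries <- as.character(indexEntries(idx))
  expect_true(all(nchar(entries) == 36))
  for (cid in names(entries)) {
    s <- circles[[cid]]; L <- nchar(s)
    dbl <- strrep(s, 2)
    expect_identical(entries[[cid]], substr(dbl, L - 18 + 1, L + 18))
  }
  # identical junction 36-mers deduplicate with a cross-reference
  twin <- c(circles, stats::setNames(circles[1], "twin"))
  idx2 <- buildJunctionIndex(twin)
  expect_false("twin" %in% names(indexEntries(idx2)))
  expect_equal(unname(idx2@duplicates["twin"]), names(circles)[1])
  # short circles wrap and are flagged
  idx3 <- buildJunctionIndex(c(tiny = randomCircle(20, 5)))
  expect_equal(idx3@short, "tiny")
  expect_equal(unname(nchar(as.character(indexEntries(idx3)))), 36)
})

test_that("footprints filter to the 25-40 nt window inclusively", {
  reads <- c(a = strrep("A", 24), b = strrep("C", 25), c = strrep("G", 40),
             d = strrep("T", 41))
  kept <- filterReads(reads)
  expect_setequal(names(kept), c("b", "c"))
  expect_equal(attr(kept, "n_dropped"), 2)
  empty <- filterReads(character(0))
  expect_length(empty, 0)
})

test_that("junction-crossing reads map and linear-body reads do not", {
  circles <- stats::setNames(vapply(1:4, function(i)
    randomCircle(150 + 10 * i, seed = 130 + i), character(1)),
    sprintf("c%02d", 1:4))
  idx <- buildJunctionIndex(circles)
  sim <- simulateRpfReads(circles, nReads = 40, junctionFraction = 0.4,
                          seed = 14)
  hits <- mapToIndex(sim$reads, idx)
  jnc <- sim$truth[sim$truth$crosses_junction, ]
  expect_setequal(hits$read_id, jnc$read_id)   # all crossing, none linear
  # every hit names the true source circle
  expect_identical(
    stats::setNames(hits$junction_id, hits$read_id)[jnc$read_id],
    stats::setNames(jnc$circ_id, jnc$read_id))
  expect_true(all(hits$mismatches == 0))
  expect_true(all(pmin(hits$left_anchor, hits$right_anchor) >= 6))
})

test_that("mapping tolerates mismatches up to the limit and respects anchors", {
  circ <- c(c1 = randomCircle(200, seed = 17))
  idx <- buildJunctionIndex(circ)
  dbl <- strrep(circ[[1]], 2)
  read <- substr(dbl, 200 - 15 + 1, 200 - 15 + 30)  # 15/15 split
  hit <- mapToIndex(c(r1 = read), idx)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$left_anchor, 15)
  expect_equal(hit$offset, 18 - 15)
  mut <- read
  substr(mut, 5, 5) <- if (substr(read, 5, 5) == "A") "C" else "A"
  expect_equal(nrow(mapToIndex(c(r1 = mut), idx, maxMismatch = 1)), 1)
  expect_equal(nrow(mapToIndex(c(r1 = mut), idx, maxMismatch = 0)), 0)
  # a read crossing by only 3 nt fails the 6-nt anchor rule
  shallow <- substr(dbl, 200 - 27 + 1, 200 - 27 + 30)  # 27/3 split
  expect_equal(nrow(mapToIndex(c(r1 = shallow), idx)), 0)
  # exclusion list removes reads before mapping
  expect_equal(nrow(mapToIndex(c(r1 = read), idx, exclude = "r1")), 0)
})

test_that("the matcher equals the brute-force Hamming oracle", {
  circles <- stats::setNames(vapply(1:3, function(i)
    randomCircle(120, seed = 150 + i), character(1)), c("x", "y", "z"))
  idx <- buildJunctionIndex(circles)
  sim <- simulateRpfReads(circles, nReads = 30, junctionFraction = 0.5,
                          seed = 19)
  # inject mismatches into a third of the reads
  reads <- sim$reads
  set.seed(20)
  for (k in sample(seq_along(reads), 10)) {
    pos <- sample(nchar(reads[k]), 1)
    substr(reads[k], pos, pos) <-
      sample(setdiff(c("A", "C", "G", "T"),
                     substr(reads[k], pos, pos)), 1)
  }
  got <- mapToIndex(reads, idx, maxMismatch = 1, minAnchor = 6)
  want <- oracleMapReads(reads, circles, flank = 18, maxMismatch = 1,
                         minAnchor = 6)
  expect_setequal(got$read_id, names(want))
  for (rid in names(want))
    expect_equal(got$junction_id[got$read_id == rid], want[[rid]])
})

test_that("region labels follow maximal overlap with the stated priority", {
  gm <- makeGenome(3, c(3, 4), seed = 23)
  cds <- cdsRanges(gm)
  one <- cds[1]
  inside <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(one)),
    IRanges::IRanges(GenomicRanges::start(one) + 2,
                     GenomicRanges::end(one) - 2),
    circ_id = "a")
  expect_equal(annotateRegions(inside, gm)$label, "cds")
  away <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2, 40),
                                 circ_id = "b")
  expect_equal(annotateRegions(away, gm)$label, "other")
  # hand-built model: 60 nt of 5'UTR vs 40 nt of CDS -> 5utr
  u5 <- utr5Ranges(gm)[1]
  tid <- S4Vectors::mcols(u5)$transcript_id[1]
  cdsTx <- cds[S4Vectors::mcols(cds)$transcript_id == tid]
  strand1 <- as.character(GenomicRanges::strand(u5))
  if (strand1 == "+") {
    lo <- max(GenomicRanges::start(u5),
              GenomicRanges::end(u5) - 59)
    hi <- min(GenomicRanges::start(cdsTx)[1] + 39,
              GenomicRanges::end(cdsTx)[1])
    span <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(u5)),
      IRanges::IRanges(lo, hi), circ_id = "c")
    res <- annotateRegions(span, gm)
    if (res$utr5[1] > res$cds[1]) expect_equal(res$label, "5utr")
  }
  succeed()
})

test_that("composition comparison is the Pearson chi-square", {
  same <- compareComposition(c(cds = 10, utr5 = 5), c(cds = 10, utr5 = 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  sep <- compareComposition(c(a = 10, b = 0), c(a = 0, b = 10))
  expect_equal(sep$statistic, 20)
  expect_equal(sep$df, 1)
  expect_equal(sep$p, stats::pchisq(20, 1, lower.tail = FALSE))
  expect_error(compareComposition(c(a = 5), c(a = 3)), "2 labels")
  expect_warning(compareComposition(c(a = 5, b = 0, c = 3),
                                    c(a = 2, b = 0, c = 4)), "zero-margin")
})

test_that("planted wrap-spanning ORFs are recovered with exact peptides", {
  planted <- plantOrfCircle(300, orfStart = 250, nCodons = 61, seed = 29)
  orfs <- rollingOrfs(planted$sequence)
  hit <- orfs[orfs$start == 250, ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$crosses_junction)
  expect_equal(hit$aa_length, 61)
  expect_identical(hit$peptide, planted$peptide)
  expect_equal(nrow(rollingOrfs(strrep("CCA", 40))), 0)  # no ATG anywhere
  expect_error(rollingOrfs("ATGNNN"), "non-ACGT")
})

test_that("stopless frames are flagged iff the circle length is divisible by 3", {
  # L = 99 (0 mod 3): one frame of safe codons, ATG start, no stop anywhere
  set.seed(33)
  safe <- c("GCT", "GCC", "GGA", "TGC", "GAC", "TTC", "CAC", "ATC",
            "AAA", "CTG", "AAC", "CCG")
  body <- paste(sample(safe, 32, replace = TRUE), collapse = "")
  circ <- paste0("ATG", body)   # 99 nt, frame 0 never stops
  orfs <- rollingOrfs(circ, minAa = 20)
  stopless <- orfs[orfs$stopless, ]
  expect_gte(nrow(stopless), 1)
  expect_true(any(stopless$start == 0))
  expect_equal(stopless$aa_length[stopless$start == 0], 33)  # one full turn
  # L = 100: the same construction cannot be stopless
  circ2 <- paste0(circ, "A")
  orfs2 <- suppressWarnings(rollingOrfs(circ2, minAa = 5))
  expect_false(any(orfs2$stopless))
})

test_that("the ORF caller equals a brute-force translated scan", {
  for (rep in 1:40) {
    L <- sample(60:240, 1)
    circ <- randomCircle(L, seed = 1700 + rep)
    got <- suppressWarnings(rollingOrfs(circ, minAa = 5))
    want <- oracleRollingOrfs(circ, minAa = 5)
    expect_setequal(got$start, want$start)
    for (st in want$start)
      expect_identical(got$peptide[got$start == st],
                       want$peptide[want$start == st])
  }
})

test_that("coding calls require a long junction-crossing ORF", {
  orfs <- list(
    good = data.frame(start = 0, aa_length = 100, crosses_junction = TRUE),
    short = data.frame(start = 0, aa_length = 10, crosses_junction = TRUE),
    linear = data.frame(start = 0, aa_length = 50,
                        crosses_junction = FALSE),
    none = data.frame(start = integer(), aa_length = integer(),
                      crosses_junction = logical()))
  calls <- callCoding(orfs, minAa = 20)
  expect_identical(unname(calls), c(TRUE, FALSE, FALSE, FALSE))
  relaxed <- callCoding(orfs, minAa = 20, requireJunction = FALSE)
  expect_true(relaxed[["linear"]])
})

test_that("group abundance comparison is the exact rank test on RPM rates", {
  tot <- rep(1e6, 6)
  g <- factor(rep(c("rest", "depol"), each = 3), c("rest", "depol"))
  same <- suppressWarnings(compareGroupAbundance(rep(5, 6), tot, g))
  expect_equal(same$difference, 0)
  expect_equal(same$p, 1)
  r <- compareGroupAbundance(c(1, 2, 3, 10, 20, 30), tot, g)
  expect_equal(r$p, 0.1)   # U = 0, exact two-sided 3v3
  expect_gt(r$difference, 0)
  expect_warning(
    one <- compareGroupAbundance(c(1, 10), c(1e6, 1e6),
                                 factor(c("a", "b"))), "one sample")
  expect_equal(one$p, 1)
  expect_error(compareGroupAbundance(1:3, rep(1e6, 3),
                                     factor(rep("a", 3))), "two groups")
})
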