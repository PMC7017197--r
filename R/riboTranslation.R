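#' Build a back-splice junction index for footprint mapping
#'
#' Each circle contributes one entry: the last `flank` nt of the circle
#' followed by its first `flank` nt (transcript orientation), i.e. the
#' `2 * flank`-nt window of the doubled sequence centered on the wrap
#' point. With the default flank of 18 every entry is 36 nt. Circles
#' shorter than `2 * flank` wrap cyclically and are flagged; entries
#' identical in sequence are deduplicated with a cross-reference.
#'
#' @param circles Named character vector (or DNAStringSet) of circle
#'   sequences in transcript orientation (minus-strand circles must already
#'   be reverse-complemented, as [circSequence()] does).
#' @param flank Nucleotides kept on each side of the wrap point.
#' @return A [JunctionIndex-class].
#' @export
buildJunctionIndex <- function(circles, flank = 18L) {
  circles <- stats::setNames(.asDnaChar(as.character(circles)),
                             names(circles))
  if (is.null(names(circles)) || anyNA(names(circles)))
    stop("circles must be named")
  if (any(!nzchar(circles)))
    stop("missing sequence for circ: ",
         paste(names(circles)[!nzchar(circles)], collapse = ", "))
  L <- nchar(circles)
  short <- names(circles)[L < 2L * flank]
  entries <- vapply(circles, function(s) {
    .cyclicSubstr(s, nchar(s) - flank, 2L * flank)
  }, character(1))
  dupIdx <- duplicated(entries)
  dups <- character(0)
  if (any(dupIdx)) {
    first <- names(entries)[match(entries[dupIdx], entries)]
    dups <- stats::setNames(first, names(entries)[dupIdx])
  }
  keep <- !dupIdx
  methods::new("JunctionIndex",
    entries = DNAStringSet(entries[keep]),
    circles = DNAStringSet(circles[keep]),
    flank = as.integer(flank), duplicates = dups, short = short)
}

#' Length-filter ribosome-protected fragments
#'
#' Retains reads between `minLen` and `maxLen` nt inclusive, the canonical
#' footprint window.
#'
#' @param reads Named character vector (or DNAStringSet).
#' @param minLen,maxLen Inclusive length bounds, defaults 25 and 40.
#' @return The retained reads, with attribute `n_dropped`.
#' @export
filterReads <- function(reads, minLen = 25L, maxLen = 40L) {
  reads <- stats::setNames(as.character(reads), names(reads))
  keep <- nchar(reads) >= minLen & nchar(reads) <= maxLen
  out <- reads[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Map footprint reads to the back-splice junction index
#'
#' A read hits a junction when it aligns, with Hamming distance at most
#' `maxMismatch`, to the junction entry extended with circle sequence on
#' both sides, crossing the wrap point with at least `minAnchor` nt on each
#' side. Reads longer than the 36-nt entry overhang into the circle body;
#' the extension absorbs that. The best placement per read is kept (fewest
#' mismatches, then largest left anchor, then lexicographic junction id).
#' Reads in an optional exclusion list (e.g. footprints that aligned to
#' the linear genome, or contaminant small RNAs) are dropped first.
#'
#' @param reads Named character vector of footprint sequences.
#' @param index A [JunctionIndex-class].
#' @param maxMismatch Maximum Hamming distance, default 2.
#' @param minAnchor Minimum nt on each side of the wrap, default 6.
#' @param exclude Character vector of read ids to skip.
#' @return data.frame with `read_id`, `junction_id`, `offset` (0-based
#'   start on the flank-extended junction sequence; 0 = first base of the
#'   entry, negative = starts upstream of it), `mismatches`,
#'   `left_anchor`, `right_anchor`.
#' @export
mapToIndex <- function(reads, index, maxMismatch = 2L, minAnchor = 6L,
                       exclude = character()) {
  reads <- stats::setNames(.asDnaChar(as.character(reads)), names(reads))
  reads <- reads[!names(reads) %in% exclude]
  flank <- indexFlank(index)
  circ <- as.character(indexCircles(index))
  rows <- list()
  for (rid in names(reads)) {
    rd <- reads[[rid]]
    len <- nchar(rd)
    best <- NULL
    for (jid in names(circ)) {
      s <- circ[[jid]]; Lc <- nchar(s)
      if (len > Lc) next
      # left anchors a: read occupies circle positions [Lc - a, Lc - a + len)
      for (a in seq(minAnchor, len - minAnchor)) {
        ref <- .cyclicSubstr(s, Lc - a, len)
        mm <- .hamming(rd, ref)
        if (mm <= maxMismatch) {
          cand <- list(read_id = rid, junction_id = jid,
                       offset = flank - a, mismatches = as.integer(mm),
                       left_anchor = as.integer(a),
                       right_anchor = as.integer(len - a))
          replace <- is.null(best) || mm < best$mismatches ||
            (mm == best$mismatches && a > best$left_anchor)
          if (replace) best <- cand
        }
      }
    }
    if (!is.null(best)) rows[[length(rows) + 1L]] <- best
  }
  if (!length(rows))
    return(data.frame(read_id = character(), junction_id = character(),
                      offset = integer(), mismatches = integer(),
                      left_anchor = integer(), right_anchor = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Annotate junctions by the genomic feature they overlap most
#'
#' Intersects each junction's genomic span with the 5'UTR, CDS and 3'UTR
#' intervals of the annotation and labels it with the feature class of
#' maximal overlap (ties broken 5utr > cds > 3utr); `other` when nothing
#' overlaps.
#'
#' @param junctions A [GenomicRanges::GRanges] of junction spans.
#' @param gm A [GeneModel-class].
#' @return data.frame with `junction_id`, `label`, `utr5`, `cds`, `utr3`
#'   overlap widths.
#' @export
annotateRegions <- function(junctions, gm) {
  ids <- if (!is.null(mcols(junctions)$circ_id)) mcols(junctions)$circ_id
    else as.character(seq_along(junctions))
  feat <- list(utr5 = utr5Ranges(gm), cds = cdsRanges(gm),
               utr3 = utr3Ranges(gm))
  labelOf <- c(utr5 = "5utr", cds = "cds", utr3 = "3utr")
  ovl <- vapply(feat, function(f) {
    if (!length(f)) return(rep(0L, length(junctions)))
    red <- GenomicRanges::reduce(granges(f), ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(junctions, red, ignore.strand = TRUE)
    w <- integer(length(junctions))
    if (length(hits)) {
      pi <- IRanges::pintersect(
        granges(junctions)[S4Vectors::queryHits(hits)],
        red[S4Vectors::subjectHits(hits)], ignore.strand = TRUE)
      agg <- tapply(width(pi), S4Vectors::queryHits(hits), sum)
      w[as.integer(names(agg))] <- as.integer(agg)
    }
    w
  }, integer(length(junctions)))
  ovl <- matrix(ovl, nrow = length(junctions),
                dimnames = list(NULL, names(feat)))
  label <- apply(ovl, 1, function(x) {
    if (all(x == 0)) return("other")
    unname(labelOf[names(feat)[which(x == max(x))][1]])  # order = priority
  })
  data.frame(junction_id = ids, label = label, utr5 = ovl[, "utr5"],
             cds = ovl[, "cds"], utr3 = ovl[, "utr3"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Chi-square comparison of region compositions
#'
#' Pearson chi-square (no continuity correction) on the label-by-set
#' contingency table of two composition vectors, e.g. translated vs
#' non-translated circRNAs per region label.
#'
#' @param countsA,countsB Named integer vectors of per-label counts.
#' @return list with `statistic`, `df`, `p`, `expected`.
#' @export
compareComposition <- function(countsA, countsB) {
  labels <- union(names(countsA), names(countsB))
  if (length(labels) < 2) stop("need at least 2 labels")
  a <- stats::setNames(rep(0, length(labels)), labels)
  b <- a
  a[names(countsA)] <- countsA; b[names(countsB)] <- countsB
  tab <- cbind(A = a, B = b)
  zero <- rowSums(tab) == 0
  if (any(zero)) {
    warning("dropping zero-margin label(s): ",
            paste(labels[zero], collapse = ", "))
    tab <- tab[!zero, , drop = FALSE]
  }
  if (nrow(tab) < 2) stop("fewer than 2 informative labels")
  if (any(colSums(tab) == 0)) stop("a set has zero total")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Rolling-circle ORF prediction on a circular sequence
#'
#' The circle is concatenated `nRepeats` times (default 4) and the three
#' forward frames are scanned for ATG-initiated ORFs whose start lies in
#' the first copy. An ORF crossing a multiple of the circle length is
#' junction-crossing. When a frame returns to its own phase without ever
#' meeting a stop (possible only when the circle length is divisible by 3)
#' the ORF is flagged `stopless` and its peptide truncated at one full
#' turn (L/3 codons). An ORF running off the concatenation end without a
#' stop is reported truncated, with a warning.
#'
#' @param circle Circle sequence (DNA, ACGT only).
#' @param nRepeats Number of concatenated copies, default 4.
#' @param minAa Minimum peptide length reported, default 20.
#' @param hostPhase Optional phase (0--2): the position within a host
#'   codon of circle coordinate 0. Enables the `frame_vs_host` call.
#' @return data.frame with `start` (0-based, first copy), `aa_length`,
#'   `crosses_junction`, `stopless`, `truncated`, `frame_vs_host`,
#'   `peptide`.
#' @export
rollingOrfs <- function(circle, nRepeats = 4L, minAa = 20L,
                        hostPhase = NA_integer_) {
  circle <- .asDnaChar(circle)
  if (grepl("[^ACGT]", circle)) stop("circle contains non-ACGT symbols")
  L <- nchar(circle)
  if (L < 3) stop("circle must be at least 3 nt")
  concat <- strrep(circle, nRepeats)
  total <- nchar(concat)
  starts <- gregexpr("ATG", concat, fixed = TRUE)[[1]]
  starts <- as.integer(starts[starts > 0]) - 1L      # 0-based
  starts <- starts[starts < L]
  rows <- list()
  for (st in starts) {
    nCodons <- (total - st) %/% 3L
    if (nCodons < 1) next
    sub <- substr(concat, st + 1L, st + 3L * nCodons)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub)))
    stopAt <- regexpr("*", aa, fixed = TRUE)[1]
    stopless <- FALSE; truncated <- FALSE
    if (stopAt == -1) {
      if (L %% 3L == 0L) {
        stopless <- TRUE
        aaLen <- L %/% 3L
        pep <- substr(aa, 1L, aaLen)
      } else {
        truncated <- TRUE
        warning("ORF at ", st, " abuts the concatenation end; ",
                "peptide may be truncated")
        aaLen <- nCodons
        pep <- aa
      }
    } else {
      aaLen <- stopAt - 1L
      pep <- substr(aa, 1L, aaLen)
    }
    if (aaLen < minAa) next
    spanEnd <- if (stopless) st + L else st + 3L * (aaLen + 1L)
    crosses <- spanEnd > L
    fvh <- if (is.na(hostPhase)) "na"
      else if ((st - hostPhase) %% 3L == 0L) "in-frame" else "out-of-frame"
    rows[[length(rows) + 1L]] <- data.frame(
      start = st, aa_length = aaLen, crosses_junction = crosses,
      stopless = stopless, truncated = truncated, frame_vs_host = fvh,
      peptide = pep, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(start = integer(), aa_length = integer(),
                      crosses_junction = logical(), stopless = logical(),
                      truncated = logical(), frame_vs_host = character(),
                      peptide = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Coding calls from rolling-circle ORFs
#'
#' A circRNA is called coding when it carries at least one ORF of
#' `minAa` amino acids or more that crosses the back-splice junction (the
#' junction requirement can be dropped). This is an ORF-length heuristic,
#' not a trained coding-potential model; calls are comparative, not
#' absolute.
#'
#' @param orfsByCirc Named list of data.frames from [rollingOrfs()].
#' @param minAa Minimum peptide length, default 20.
#' @param requireJunction Require the ORF to cross the junction.
#' @return Named logical vector, one call per circle.
#' @export
callCoding <- function(orfsByCirc, minAa = 20L, requireJunction = TRUE) {
  vapply(orfsByCirc, function(orfs) {
    if (!nrow(orfs)) return(FALSE)
    ok <- orfs$aa_length >= minAa
    if (requireJunction) ok <- ok & orfs$crosses_junction
    any(ok)
  }, logical(1))
}

#' Compare normalized junction-read abundance between groups
#'
#' Per-sample junction reads are normalized to reads-per-million mapped and
#' the two groups compared with a two-sided Mann-Whitney rank test (exact
#' for small samples, the [stats::wilcox.test()] default).
#'
#' @param junctionReads Named numeric vector: junction-spanning reads per
#'   sample.
#' @param totalMapped Named numeric vector: mapped reads per sample.
#' @param groups Factor of two levels aligned with `junctionReads`.
#' @return list with `rates`, `medianA`, `medianB`, `difference`
#'   (B minus A, per million), `p`.
#' @export
compareGroupAbundance <- function(junctionReads, totalMapped, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2 || any(table(groups) < 1))
    stop("need two groups with >= 1 sample each")
  rates <- 1e6 * junctionReads / totalMapped
  gA <- groups == levels(groups)[1]
  rA <- rates[gA]; rB <- rates[!gA]
  if (length(rA) == 1 && length(rB) == 1) {
    warning("one sample per group: no rank test possible, p = 1")
    return(list(rates = rates, medianA = rA, medianB = rB,
                difference = rB - rA, p = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(rB, rA,
                                            alternative = "two.sided"))
  p <- wt$p.value
  if (is.nan(p)) p <- 1   # fully tied rates carry no evidence
  list(rates = rates, medianA = stats::median(rA),
       medianB = stats::median(rB),
       difference = stats::median(rB) - stats::median(rA), p = p)
}
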