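#' Simulate split-segment alignment evidence for back-splice junctions
#'
#' Emits the per-read segment-alignment records that a chimeric aligner
#' would produce. Each planted back-splice read appears as two segments in
#' reversed genomic order: the read's 5' part maps just upstream of the
#' junction's donor end and its 3' part at the acceptor start. Linear reads
#' are emitted as single segments (or, optionally, forward-order splices)
#' and contribute to the per-sample mapped totals only.
#'
#' @param gm A [GeneModel-class] (used to validate junction flanks).
#' @param circPlan data.frame with columns `circ_id`, `chrom`, `start`,
#'   `end` (1-based inclusive exon-boundary junction coordinates), `strand`,
#'   plus one integer column per sample holding planted junction-read
#'   counts.
#' @param sampleIds Character vector naming the count columns of `circPlan`.
#' @param linearDepth Linear (non-junction) reads per sample.
#' @param readLength Read length in nt.
#' @param mismatchRate Per-base probability of recording a mismatch flag
#'   (kept 0 for noise-free fixtures; coordinates are never perturbed).
#' @param seed Integer seed.
#' @return list with `segments` (data.frame: read_id, sample_id,
#'   segment_index, chrom, start, end, strand; 0-based half-open) and
#'   `totalMapped` (named integer vector per sample).
#' @export
simulateBackspliceReads <- function(gm, circPlan, sampleIds,
                                    linearDepth = 200L, readLength = 100L,
                                    mismatchRate = 0, seed = 1L) {
  stopifnot(all(sampleIds %in% colnames(circPlan)))
  half <- ceiling(readLength / 2)
  w <- circPlan$end - circPlan$start + 1L
  tooShort <- w < readLength
  if (any(tooShort))
    stop("junction flanks too short for read length: ",
         paste(circPlan$circ_id[tooShort], collapse = ", "))

  .withSeed(seed, {
    rows <- list(); k <- 0L
    totals <- stats::setNames(integer(length(sampleIds)), sampleIds)
    readNo <- 0L
    for (s in sampleIds) {
      for (i in seq_len(nrow(circPlan))) {
        nReads <- circPlan[[s]][i]
        if (nReads == 0) next
        for (r in seq_len(nReads)) {
          readNo <- readNo + 1L
          rid <- sprintf("%s_bsj_%06d", s, readNo)
          aLen <- .sampleRange(20L, readLength - 20L)
          bLen <- readLength - aLen
          # 5' part of the read: last aLen nt of the circle (donor side)
          donorEnd0 <- circPlan$end[i]                  # half-open end
          seg1 <- c(donorEnd0 - aLen, donorEnd0)
          # 3' part: first bLen nt (acceptor side)
          accStart0 <- circPlan$start[i] - 1L
          seg2 <- c(accStart0, accStart0 + bLen)
          k <- k + 1L
          rows[[k]] <- data.frame(
            read_id = rid, sample_id = s, segment_index = c(1L, 2L),
            chrom = circPlan$chrom[i],
            start = c(seg1[1], seg2[1]), end = c(seg1[2], seg2[2]),
            strand = circPlan$strand[i], stringsAsFactors = FALSE)
        }
        totals[s] <- totals[s] + nReads
      }
      # linear reads: single-segment records within random exons
      ex <- exonRanges(gm)
      ok <- which(width(ex) >= readLength)
      if (linearDepth > 0 && length(ok)) {
        pick <- ok[sample.int(length(ok), linearDepth, replace = TRUE)]
        off <- vapply(pick, function(j) {
          sample.int(width(ex)[j] - readLength + 1L, 1L) - 1L
        }, integer(1))
        readNo2 <- readNo + seq_len(linearDepth)
        k <- k + 1L
        rows[[k]] <- data.frame(
          read_id = sprintf("%s_lin_%06d", s, readNo2),
          sample_id = s, segment_index = 1L,
          chrom = as.character(seqnames(ex))[pick],
          start = start(ex)[pick] - 1L + off,
          end = start(ex)[pick] - 1L + off + readLength,
          strand = as.character(strand(ex))[pick],
          stringsAsFactors = FALSE)
        totals[s] <- totals[s] + linearDepth
      }
    }
    segments <- if (k) do.call(rbind, rows) else
      data.frame(read_id = character(), sample_id = character(),
                 segment_index = integer(), chrom = character(),
                 start = integer(), end = integer(), strand = character(),
                 stringsAsFactors = FALSE)
    rownames(segments) <- NULL
    list(segments = segments, totalMapped = totals)
  })
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Counts follow NB with variance `m + dispersion * m^2` (Poisson when
#' `dispersion` is 0). Group-B means are scaled by `2^log2fc` per feature.
#'
#' @param featureIds Character vector of feature ids.
#' @param nA,nB Samples per group (>= 1).
#' @param mean Baseline mean count (> 0).
#' @param dispersion NB dispersion (>= 0; 0 = Poisson).
#' @param de Named numeric vector of log2 fold changes (B over A); features
#'   absent from `de` are null.
#' @param unassigned Extra per-sample mapped-read mass added to library
#'   sizes (reads mapped but not assigned to any feature).
#' @param seed Integer seed.
#' @return list with `counts` (matrix features x samples), `groups`
#'   (factor), `libSizes` (column sums plus `unassigned`).
#' @export
simulateCounts <- function(featureIds, nA, nB, mean = 100, dispersion = 0.1,
                           de = numeric(), unassigned = 0L, seed = 1L) {
  if (nA < 1 || nB < 1) stop("nA and nB must be >= 1")
  if (mean <= 0) stop("mean must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  lfc <- stats::setNames(numeric(length(featureIds)), featureIds)
  if (length(de)) {
    unknown <- setdiff(names(de), featureIds)
    if (length(unknown))
      stop("de effects for unknown features: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    lfc[names(de)] <- de
  }
  .withSeed(seed, {
    nf <- length(featureIds)
    draw <- function(mu, n) {
      m <- matrix(0, nf, n)
      for (j in seq_len(n)) {
        m[, j] <- if (dispersion == 0) stats::rpois(nf, mu)
        else stats::rnbinom(nf, mu = mu, size = 1 / dispersion)
      }
      m
    }
    A <- draw(rep(mean, nf), nA)
    B <- draw(mean * 2^lfc, nB)
    counts <- cbind(A, B)
    dimnames(counts) <- list(featureIds,
                             c(sprintf("A%d", seq_len(nA)),
                               sprintf("B%d", seq_len(nB))))
    groups <- factor(rep(c("A", "B"), c(nA, nB)), levels = c("A", "B"))
    libSizes <- colSums(counts) + unassigned
    list(counts = counts, groups = groups, libSizes = libSizes,
         log2fc = lfc)
  })
}

# site string written on the target (DNA, 5'->3') for a seed + site type;
# `position` is the 0-based start of the core (miRNA positions 2-7) match
.siteString <- function(seed7, type) {
  seed7 <- .asDnaChar(seed7)
  if (nchar(seed7) != 7) stop("seed must be 7 nt (miRNA positions 2-8)")
  core6 <- .revcompChar(substr(seed7, 1L, 6L))       # pairs positions 2-7
  m8 <- .revcompChar(substr(seed7, 7L, 7L))          # pairs position 8
  switch(type,
    "8mer"     = paste0(m8, core6, "A"),
    "7mer-m8"  = paste0(m8, core6),
    "7mer-A1"  = paste0(core6, "A"),
    "6mer"     = core6,
    stop("unknown site type: ", type))
}

# 0-based start of the written site string relative to the core position
.siteOffset <- function(type) {
  if (type %in% c("8mer", "7mer-m8")) -1L else 0L
}

#' Plant canonical miRNA seed-match sites into target sequences
#'
#' Writes, at each planned position, the exact reverse-complement match for
#' the requested canonical site type (8mer, 7mer-m8, 7mer-A1, 6mer).
#' `position` is the 0-based start of the core seed match (pairing miRNA
#' positions 2-7) on the target; 8mer and 7mer-m8 sites extend one nt
#' upstream of it.
#'
#' @param targets Named character vector or [Biostrings::DNAStringSet].
#' @param mirnas Named character vector of mature miRNA sequences (RNA or
#'   DNA alphabet).
#' @param sitePlan data.frame with columns `mirna_id`, `target_id`,
#'   `site_type`, `position`.
#' @return list with `targets` (edited, same class as input coerced to
#'   character) and `planted` (the realized site table with the written
#'   span).
#' @export
plantMirnaSites <- function(targets, mirnas, sitePlan) {
  targets <- stats::setNames(.asDnaChar(as.character(targets)),
                             names(targets))
  if (!nrow(sitePlan))
    return(list(targets = targets, planted = sitePlan))
  spans <- lapply(seq_len(nrow(sitePlan)), function(i) {
    type <- sitePlan$site_type[i]
    mir <- mirnas[[sitePlan$mirna_id[i]]]
    s <- .siteString(substr(.asDnaChar(mir), 2L, 8L), type)
    st <- sitePlan$position[i] + .siteOffset(type)
    if (st < 0) stop("site extends before target start (row ", i, ")")
    c(start = st, end = st + nchar(s))          # 0-based half-open
  })
  # overlap check within each target
  byTarget <- split(seq_len(nrow(sitePlan)), sitePlan$target_id)
  for (tid in names(byTarget)) {
    ii <- byTarget[[tid]]
    if (length(ii) < 2) next
    sp <- do.call(rbind, spans[ii])
    ord <- order(sp[, "start"])
    sp <- sp[ord, , drop = FALSE]
    clash <- which(sp[-1, "start"] < sp[-nrow(sp), "end"])
    if (length(clash))
      stop("overlapping planted sites on ", tid, " at positions ",
           paste(sp[clash, "start"], collapse = ", "))
  }
  for (i in seq_len(nrow(sitePlan))) {
    tid <- sitePlan$target_id[i]
    type <- sitePlan$site_type[i]
    mir <- mirnas[[sitePlan$mirna_id[i]]]
    s <- .siteString(substr(.asDnaChar(mir), 2L, 8L), type)
    st <- spans[[i]]["start"]
    if (st + nchar(s) > nchar(targets[[tid]]))
      stop("site extends past end of ", tid)
    substr(targets[[tid]], st + 1L, st + nchar(s)) <- s
  }
  planted <- sitePlan
  planted$span_start <- vapply(spans, `[`, numeric(1), "start")
  planted$span_end <- vapply(spans, `[`, numeric(1), "end")
  list(targets = targets, planted = planted)
}

#' Simulate ribosome-protected fragments from circular templates
#'
#' Junction reads are substrings of the circularized sequence crossing the
#' wrap point with at least `minAnchor` nt on each side; the remaining
#' reads lie entirely within the linear body. The number of junction reads
#' is exactly `round(junctionFraction * nReads)` per circle.
#'
#' @param circles Named character vector (or DNAStringSet) of circle
#'   sequences.
#' @param nReads Reads per circle.
#' @param junctionFraction Fraction of reads crossing the wrap point.
#' @param readLength Integer range, default 25--40 nt.
#' @param minAnchor Minimum nt on each side of the wrap for junction reads.
#' @param seed Integer seed.
#' @return list with `reads` (named character vector; names encode
#'   `<circ>_jnc_<i>` or `<circ>_body_<i>`) and `truth` (data.frame:
#'   read_id, circ_id, crosses_junction, start0 on the circle).
#' @export
simulateRpfReads <- function(circles, nReads = 100L, junctionFraction = 0.3,
                             readLength = c(25L, 40L), minAnchor = 6L,
                             seed = 1L) {
  circles <- stats::setNames(.asDnaChar(as.character(circles)),
                             names(circles))
  L <- nchar(circles)
  if (any(L < max(readLength)))
    stop("circle(s) shorter than maximum read length: ",
         paste(names(circles)[L < max(readLength)], collapse = ", "))
  .withSeed(seed, {
    out <- list(); truth <- list()
    for (cid in names(circles)) {
      s <- circles[[cid]]; Lc <- nchar(s)
      nJ <- round(junctionFraction * nReads)
      nB <- nReads - nJ
      reads <- character(0); rows <- list()
      if (nJ > 0) for (i in seq_len(nJ)) {
        len <- .sampleRange(readLength[1], readLength[2])
        a <- .sampleRange(minAnchor, len - minAnchor)  # left anchor
        st <- Lc - a                                    # 0-based on circle
        reads[sprintf("%s_jnc_%04d", cid, i)] <- .cyclicSubstr(s, st, len)
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = sprintf("%s_jnc_%04d", cid, i), circ_id = cid,
          crosses_junction = TRUE, start0 = st, stringsAsFactors = FALSE)
      }
      if (nB > 0) for (i in seq_len(nB)) {
        len <- .sampleRange(readLength[1], readLength[2])
        st <- sample.int(Lc - len + 1L, 1L) - 1L
        reads[sprintf("%s_body_%04d", cid, i)] <- substr(s, st + 1L, st + len)
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = sprintf("%s_body_%04d", cid, i), circ_id = cid,
          crosses_junction = FALSE, start0 = st, stringsAsFactors = FALSE)
      }
      out[[cid]] <- reads
      truth[[cid]] <- do.call(rbind, rows)
    }
    list(reads = unlist(unname(out)),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}

#' Construct a circle sequence with a planted rolling-circle ORF
#'
#' Builds a circular sequence of length `circLen` carrying a single ATG-
#' initiated ORF of `nCodons` codons whose stop codon is reached only after
#' wrapping past the back-splice point, with no other in-frame ATG upstream
#' of the planted start. Used to test junction-crossing ORF recovery with
#' exact peptides.
#'
#' @param circLen Circle length in nt (>= 3 * nCodons is not required; the
#'   ORF wraps).
#' @param orfStart 0-based start of the ATG on the circle.
#' @param nCodons Codons before the stop.
#' @param seed Integer seed.
#' @return list with `sequence`, `orfStart`, `peptide` (expected amino-acid
#'   string).
#' @export
plantOrfCircle <- function(circLen, orfStart, nCodons, seed = 1L) {
  if ((orfStart + 3 * (nCodons + 1)) <= circLen)
    stop("ORF does not wrap; extend nCodons or shift orfStart")
  if (3 * (nCodons + 1) > circLen)
    stop("ORF (incl. stop) cannot exceed the circle length")
  .withSeed(seed, {
    # codons free of ATG/stop so the planted ORF is unique and uninterrupted
    safe <- c("GCT", "GCC", "GGA", "GGC", "TGC", "GAC", "GAA", "TTC",
              "CAC", "ATC", "AAA", "CTG", "AAC", "CCG", "CAG", "CGT",
              "AGC", "ACC", "GTT", "TGG", "TAC")
    body <- c("ATG", sample(safe, nCodons - 1L, replace = TRUE))
    orfNt <- paste(body, collapse = "")
    stopCodon <- "TAA"
    seqChars <- rep(NA_character_, circLen)
    # lay ORF + stop cyclically from orfStart
    lay <- function(str, from) {
      for (i in seq_len(nchar(str))) {
        pos <- (from + i - 1L) %% circLen
        seqChars[pos + 1L] <<- substr(str, i, i)
      }
    }
    lay(orfNt, orfStart)
    lay(stopCodon, orfStart + nchar(orfNt))
    # fill remaining positions with A/C (no G/T runs that could form ATG/stop
    # unexpectedly is not guaranteed in other frames; the planted frame is)
    free <- which(is.na(seqChars))
    seqChars[free] <- sample(c("A", "C"), length(free), replace = TRUE)
    sq <- paste(seqChars, collapse = "")
    pep <- as.character(Biostrings::translate(Biostrings::DNAString(orfNt)))
    list(sequence = sq, orfStart = orfStart, peptide = pep)
  })
}
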