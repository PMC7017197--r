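#' Detect back-spliced junctions from split-segment alignments
#'
#' A read supports a candidate back-splice junction when its two aligned
#' segments share a chromosome and strand and occur in reversed genomic
#' order: the segment occurring first in the read maps genomically
#' downstream of (at or beyond the end of) the second. The candidate
#' junction runs from the leftmost coordinate of the upstream segment to
#' the rightmost coordinate of the downstream segment. Candidates sharing
#' (chrom, start, end, strand) are merged and only junctions supported by
#' at least `minSupport` reads in total are reported -- the "more than one
#' read" confidence rule.
#'
#' @param segments data.frame with columns `read_id`, `segment_index`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand`, and optionally
#'   `sample_id` (defaults to a single sample `"S1"`).
#' @param minSupport Minimum total junction reads, default 2.
#' @return A [GenomicRanges::GRanges] (1-based) with metadata columns
#'   `circ_id`, `support_<sample>` count columns, and `total_support`.
#' @export
detectJunctions <- function(segments, minSupport = 2L) {
  req <- c("read_id", "segment_index", "chrom", "start", "end", "strand")
  miss <- setdiff(req, colnames(segments))
  if (length(miss))
    stop("segment table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(segments)) {
    bad <- which(!is.finite(segments$start) | !is.finite(segments$end) |
                 segments$end <= segments$start)
    if (length(bad))
      stop("malformed segment row(s) at line ",
           paste(utils::head(bad, 3), collapse = ", "))
  }
  if (is.null(segments$sample_id)) segments$sample_id <- "S1"
  sampleIds <- sort(unique(segments$sample_id))

  cand <- list()
  byRead <- split(seq_len(nrow(segments)), segments$read_id)
  for (rid in names(byRead)) {
    sub <- segments[byRead[[rid]], , drop = FALSE]
    if (nrow(sub) == 1L) next                      # linear single segment
    if (nrow(sub) > 2L) {
      warning("read ", rid, " has >2 segments; skipped")
      next
    }
    sub <- sub[order(sub$segment_index), , drop = FALSE]
    s1 <- sub[1, ]; s2 <- sub[2, ]
    if (s1$chrom != s2$chrom || s1$strand != s2$strand) next
    if (s1$start < s2$end) next                    # forward/overlapping
    cand[[length(cand) + 1L]] <- data.frame(
      chrom = s1$chrom, start = s2$start, end = s1$end,
      strand = s1$strand, sample_id = s1$sample_id,
      stringsAsFactors = FALSE)
  }
  empty <- GenomicRanges::GRanges()
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  key <- paste(cand$chrom, cand$start, cand$end, cand$strand, sep = "|")
  tab <- split(cand, key)
  keys <- sort(names(tab))
  rows <- lapply(keys, function(kk) {
    sub <- tab[[kk]]
    supp <- vapply(sampleIds, function(s) sum(sub$sample_id == s), integer(1))
    c(list(chrom = sub$chrom[1], start = sub$start[1], end = sub$end[1],
           strand = sub$strand[1]), as.list(supp))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  total <- rowSums(df[, sampleIds, drop = FALSE])
  keep <- total >= minSupport
  df <- df[keep, , drop = FALSE]; total <- total[keep]
  if (!nrow(df)) return(empty)
  gr <- GenomicRanges::GRanges(df$chrom,
                               .zeroToOne(df$start, df$end),
                               strand = df$strand)
  mcols(gr)$circ_id <- sprintf("circ_%s_%d_%d_%s", df$chrom, df$start,
                               df$end, df$strand)
  for (s in sampleIds) mcols(gr)[[paste0("support_", s)]] <- df[[s]]
  mcols(gr)$total_support <- as.integer(total)
  gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
}

#' Snap junction coordinates to annotated exon boundaries
#'
#' If an annotated exon start lies within `tolerance` nt of the junction
#' start and an exon end within `tolerance` nt of the junction end, on the
#' same gene and strand, coordinates are replaced by those exon boundaries.
#' When several transcripts match, the transcript covering the junction
#' with the most exons wins, then lexicographic transcript id.
#'
#' @param junctions [GenomicRanges::GRanges] from [detectJunctions()].
#' @param gm A [GeneModel-class].
#' @param tolerance Max boundary offset in nt, default 2.
#' @return The input with coordinates adjusted and metadata columns
#'   `snapped` (logical) and `snap_transcript` (id or NA).
#' @export
snapToExons <- function(junctions, gm, tolerance = 2L) {
  ex <- exonRanges(gm)
  snapped <- logical(length(junctions))
  snapTx <- rep(NA_character_, length(junctions))
  newStart <- start(junctions); newEnd <- end(junctions)
  for (i in seq_along(junctions)) {
    chrom <- as.character(seqnames(junctions))[i]
    str <- as.character(strand(junctions))[i]
    onCh <- ex[as.character(seqnames(ex)) == chrom &
               as.character(strand(ex)) == str]
    if (!length(onCh)) next
    sHit <- abs(start(onCh) - start(junctions)[i]) <= tolerance
    eHit <- abs(end(onCh) - end(junctions)[i]) <= tolerance
    txS <- unique(mcols(onCh)$transcript_id[sHit])
    txE <- unique(mcols(onCh)$transcript_id[eHit])
    txBoth <- intersect(txS, txE)
    if (!length(txBoth)) next
    nEx <- vapply(txBoth, function(tid) {
      sub <- onCh[mcols(onCh)$transcript_id == tid]
      sum(start(sub) >= start(junctions)[i] - tolerance &
          end(sub) <= end(junctions)[i] + tolerance)
    }, integer(1))
    pick <- txBoth[order(-nEx, txBoth)][1]
    sub <- onCh[mcols(onCh)$transcript_id == pick]
    bs <- start(sub)[which.min(abs(start(sub) - start(junctions)[i]))]
    be <- end(sub)[which.min(abs(end(sub) - end(junctions)[i]))]
    newStart[i] <- bs; newEnd[i] <- be
    snapped[i] <- TRUE; snapTx[i] <- pick
  }
  out <- junctions
  IRanges::ranges(out) <- IRanges::IRanges(newStart, newEnd)
  mcols(out)$snapped <- snapped
  mcols(out)$snap_transcript <- snapTx
  out
}

#' Classify the genomic origin of back-splice junctions
#'
#' A junction is exonic when both ends coincide with exon boundaries of one
#' transcript; the exonic label is refined to `coding-exon`, `5utr` or
#' `3utr` by the regions the included exons overlap, with priority
#' coding-exon > 5utr > 3utr. A junction fully inside one intron is
#' `intronic`; anything else is `intergenic`. Exon ordinals count from the
#' transcript 5' end (so minus-strand genes count from the right).
#'
#' @param junctions Snapped [GenomicRanges::GRanges] (see [snapToExons()]).
#' @param gm A [GeneModel-class].
#' @return The input with metadata columns `host_gene`, `host_transcript`,
#'   `origin`, `n_exons`, `exon_indices` (comma-separated ordinals).
#' @export
classifyOrigin <- function(junctions, gm) {
  ex <- exonRanges(gm)
  n <- length(junctions)
  host <- rep(NA_character_, n); htx <- rep(NA_character_, n)
  origin <- rep("intergenic", n)
  nEx <- integer(n); exIdx <- rep("", n)
  for (i in seq_len(n)) {
    chrom <- as.character(seqnames(junctions))[i]
    str <- as.character(strand(junctions))[i]
    js <- start(junctions)[i]; je <- end(junctions)[i]
    onCh <- ex[as.character(seqnames(ex)) == chrom &
               as.character(strand(ex)) == str]
    txS <- unique(mcols(onCh)$transcript_id[start(onCh) == js])
    txE <- unique(mcols(onCh)$transcript_id[end(onCh) == je])
    txBoth <- sort(intersect(txS, txE))
    if (length(txBoth)) {
      cov <- vapply(txBoth, function(tid) {
        sub <- onCh[mcols(onCh)$transcript_id == tid]
        sum(start(sub) >= js & end(sub) <= je)
      }, integer(1))
      pick <- txBoth[order(-cov, txBoth)][1]
      sub <- onCh[mcols(onCh)$transcript_id == pick]
      inc <- sub[start(sub) >= js & end(sub) <= je]
      ords <- sort(mcols(inc)$exon_number)
      host[i] <- mcols(sub)$gene_id[1]; htx[i] <- pick
      nEx[i] <- length(inc)
      exIdx[i] <- paste(ords, collapse = ",")
      span <- GenomicRanges::GRanges(chrom, IRanges::IRanges(js, je), str)
      ovl <- function(feat) {
        feat <- feat[as.character(seqnames(feat)) == chrom]
        if (!length(feat)) return(0L)
        sum(width(GenomicRanges::intersect(
          granges(span), GenomicRanges::reduce(granges(feat)),
          ignore.strand = TRUE)))
      }
      cdsTx <- cdsRanges(gm)
      cdsTx <- cdsTx[mcols(cdsTx)$transcript_id == pick]
      u5 <- utr5Ranges(gm); u3 <- utr3Ranges(gm)
      u5 <- u5[mcols(u5)$transcript_id == pick]
      u3 <- u3[mcols(u3)$transcript_id == pick]
      origin[i] <- if (ovl(cdsTx) > 0) "coding-exon"
        else if (ovl(u5) > 0) "5utr"
        else if (ovl(u3) > 0) "3utr"
        else "coding-exon"
      next
    }
    # intronic: fully inside one intron of some transcript
    intronHit <- FALSE
    for (tid in unique(mcols(onCh)$transcript_id)) {
      sub <- onCh[mcols(onCh)$transcript_id == tid]
      sub <- sub[order(start(sub))]
      if (length(sub) < 2) next
      iS <- end(sub)[-length(sub)] + 1L
      iE <- start(sub)[-1] - 1L
      if (any(js >= iS & je <= iE)) {
        intronHit <- TRUE
        host[i] <- mcols(sub)$gene_id[1]; htx[i] <- tid
        break
      }
    }
    if (intronHit) origin[i] <- "intronic"
  }
  out <- junctions
  mcols(out)$host_gene <- host
  mcols(out)$host_transcript <- htx
  mcols(out)$origin <- origin
  mcols(out)$n_exons <- ifelse(origin %in% c("coding-exon", "5utr", "3utr"),
                               nEx, 0L)
  mcols(out)$exon_indices <- exIdx
  out
}

#' Reads-per-million normalization of junction support
#'
#' `rpm[s] = 1e6 * support[s] / totalMapped[s]` -- back-splice junction
#' reads per million mapped reads, the standard circRNA abundance unit.
#'
#' @param support Matrix (junctions x samples) or vector of junction-read
#'   counts.
#' @param totalMapped Named numeric vector of per-sample mapped totals
#'   (> 0).
#' @return Numeric matrix (or vector) of RPM values.
#' @export
quantifyRpm <- function(support, totalMapped) {
  if (is.null(dim(support))) support <- matrix(support, nrow = 1,
    dimnames = list(NULL, names(support)))
  bad <- totalMapped <= 0
  if (any(bad))
    stop("zero total mapped reads for sample(s): ",
         paste(names(totalMapped)[bad], collapse = ", "))
  if (!is.null(colnames(support)))
    totalMapped <- totalMapped[colnames(support)]
  sweep(support, 2, totalMapped, "/") * 1e6
}

#' Minimum-evidence filter for junction count matrices
#'
#' Keeps a junction iff its count reaches `minReads` in at least
#' `minSamples` samples -- removing junctions with fewer than two
#' back-spliced reads in every sample under the defaults.
#'
#' @param counts Integer matrix, junctions x samples.
#' @param minReads Count threshold per sample, default 2.
#' @param minSamples Number of samples that must reach it, default 1.
#' @return The filtered matrix (possibly 0 rows).
#' @export
filterMinEvidence <- function(counts, minReads = 2L, minSamples = 1L) {
  if (!nrow(counts)) return(counts)
  keep <- rowSums(counts >= minReads) >= minSamples
  counts[keep, , drop = FALSE]
}

#' Per-gene circRNA summary
#'
#' One row per host gene with the number of circRNAs and their mean RPM
#' (averaged over circRNAs and samples). Junctions without a host gene
#' (intergenic) are excluded.
#'
#' @param junctions Annotated [GenomicRanges::GRanges] from
#'   [classifyOrigin()].
#' @param rpm Numeric matrix of RPM values, rows aligned with `junctions`.
#' @return data.frame with `gene_id`, `n_circ`, `mean_rpm`.
#' @export
perGeneSummary <- function(junctions, rpm) {
  host <- mcols(junctions)$host_gene
  keep <- !is.na(host)
  if (!any(keep))
    return(data.frame(gene_id = character(), n_circ = integer(),
                      mean_rpm = numeric(), stringsAsFactors = FALSE))
  rpm <- rpm[keep, , drop = FALSE]
  host <- host[keep]
  genes <- sort(unique(host))
  data.frame(
    gene_id = genes,
    n_circ = vapply(genes, function(g) sum(host == g), integer(1)),
    mean_rpm = vapply(genes, function(g)
      mean(rpm[host == g, , drop = FALSE]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
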