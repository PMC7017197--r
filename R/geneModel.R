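#' Generate a toy genome with multi-exon gene models
#'
#' Builds random chromosome sequences carrying spliced, stranded gene models
#' with explicit exon structure and a CDS flanked by 5' and 3' UTRs. The
#' output stands in for a reference genome plus GTF annotation so that every
#' downstream stage (junction detection, origin classification, sequence
#' extraction, ORF scanning) can be exercised with known coordinates.
#'
#' @param nGenes Number of genes (one transcript each), >= 1.
#' @param exonsPerGene Integer range (length-2) of exons per gene.
#' @param seed Integer seed; identical seeds reproduce identical models.
#' @param exonLength Integer range of exon lengths in nt (min >= 30).
#' @param intronLength Integer range of intron lengths in nt.
#' @param genesPerChrom Genes placed per chromosome.
#' @return A [GeneModel-class] object.
#' @examples
#' gm <- makeGenome(3, c(3, 5), seed = 1)
#' transcriptTable(gm)
#' @export
makeGenome <- function(nGenes, exonsPerGene = c(2L, 10L), seed = 1L,
                       exonLength = c(80L, 300L),
                       intronLength = c(60L, 300L),
                       genesPerChrom = 5L) {
  if (nGenes < 1) stop("nGenes must be >= 1")
  exonsPerGene <- as.integer(range(exonsPerGene))
  if (exonsPerGene[1] < 1) stop("exonsPerGene must be >= 1")
  if (min(exonLength) < 30) stop("exon lengths must be >= 30 nt")
  if (min(intronLength) < 1) stop("intron lengths must be >= 1 nt")

  .withSeed(seed, {
    gap <- 500L
    chromOf <- ceiling(seq_len(nGenes) / genesPerChrom)
    chromNames <- paste0("chr", seq_len(max(chromOf)))
    cursor <- stats::setNames(rep(gap, length(chromNames)), chromNames)

    exAll <- list(); cdsAll <- list(); txRows <- list()
    for (i in seq_len(nGenes)) {
      gid <- sprintf("gene%03d", i)
      tid <- sprintf("tx%03d", i)
      chrom <- chromNames[chromOf[i]]
      nEx <- .sampleRange(exonsPerGene[1], exonsPerGene[2])
      exw <- .sampleRange(exonLength[1], exonLength[2], nEx)
      inw <- if (nEx > 1)
        .sampleRange(intronLength[1], intronLength[2], nEx - 1L)
        else integer()
      strand <- sample(c("+", "-"), 1L)
      start1 <- cursor[[chrom]] + 1L
      starts <- start1 + cumsum(c(0L, exw[-nEx] + inw))
      ends <- starts + exw - 1L
      cursor[[chrom]] <- ends[nEx] + gap

      ex <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                                   strand = strand)
      ordinal <- if (strand == "+") seq_len(nEx) else rev(seq_len(nEx))
      mcols(ex)$gene_id <- gid
      mcols(ex)$transcript_id <- tid
      mcols(ex)$exon_number <- ordinal

      # CDS: trim a UTR of >= 10 nt off each transcript end, inside the
      # terminal exons
      u5 <- .sampleRange(10L, exw[1] - 20L)
      u3 <- .sampleRange(10L, exw[nEx] - 20L)
      cdsStart <- starts[1] + u5
      cdsEnd <- ends[nEx] - u3
      cdsParts <- IRanges::restrict(IRanges::IRanges(starts, ends),
                                    cdsStart, cdsEnd)
      cdsParts <- cdsParts[IRanges::width(cdsParts) > 0]
      cd <- GenomicRanges::GRanges(chrom, cdsParts, strand = strand)
      mcols(cd)$gene_id <- gid
      mcols(cd)$transcript_id <- tid

      exAll[[i]] <- ex; cdsAll[[i]] <- cd
      txRows[[i]] <- data.frame(transcript_id = tid, gene_id = gid,
                                chrom = chrom, strand = strand,
                                n_exons = nEx, stringsAsFactors = FALSE)
    }
    # combining ranges across chromosomes merges their seqlevels
    exons <- suppressWarnings(do.call(c, exAll))
    cds <- suppressWarnings(do.call(c, cdsAll))
    txs <- do.call(rbind, txRows)

    chromLen <- vapply(chromNames, function(ch) {
      onCh <- exons[as.character(seqnames(exons)) == ch]
      max(end(onCh)) + gap
    }, numeric(1))
    genome <- DNAStringSet(vapply(chromLen, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1)))
    names(genome) <- chromNames

    utrs <- .deriveUtrs(exons, cds)
    methods::new("GeneModel", genome = genome, exons = exons, cds = cds,
                 utr5 = utrs$utr5, utr3 = utrs$utr3, transcripts = txs)
  })
}

# exonic regions outside the CDS span, split into 5' and 3' by strand
.deriveUtrs <- function(exons, cds) {
  emptyGr <- GenomicRanges::GRanges()
  u5 <- list(); u3 <- list()
  txIds <- unique(mcols(exons)$transcript_id)
  for (tid in txIds) {
    ex <- exons[mcols(exons)$transcript_id == tid]
    cd <- cds[mcols(cds)$transcript_id == tid]
    if (!length(cd)) next
    strand1 <- as.character(strand(ex))[1]
    cdsLo <- min(start(cd)); cdsHi <- max(end(cd))
    parts <- GenomicRanges::setdiff(
      granges(ex),
      GenomicRanges::GRanges(seqnames(ex)[1],
                             IRanges::IRanges(cdsLo, cdsHi), strand1))
    if (!length(parts)) next
    left <- parts[end(parts) < cdsLo]
    right <- parts[start(parts) > cdsHi]
    five <- if (strand1 == "+") left else right
    three <- if (strand1 == "+") right else left
    if (length(five)) { mcols(five)$transcript_id <- tid; u5[[tid]] <- five }
    if (length(three)) { mcols(three)$transcript_id <- tid; u3[[tid]] <- three }
  }
  list(
    utr5 = if (length(u5)) suppressWarnings(do.call(c, unname(u5)))
      else emptyGr,
    utr3 = if (length(u3)) suppressWarnings(do.call(c, unname(u3)))
      else emptyGr
  )
}

#' Write a gene model to FASTA + GTF
#'
#' Deterministic writers: the same [GeneModel-class] always produces
#' byte-identical files. Coordinates in the GTF are 1-based inclusive.
#'
#' @param gm A [GeneModel-class].
#' @param fasta,gtf Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
writeGenome <- function(gm, fasta, gtf) {
  Biostrings::writeXStringSet(genomeSeq(gm), fasta)
  feats <- list()
  addType <- function(gr, type) {
    if (!length(gr)) return(NULL)
    mcols(gr)$type <- type
    gr
  }
  ex <- exonRanges(gm)
  cd <- cdsRanges(gm)
  u5 <- utr5Ranges(gm); u3 <- utr3Ranges(gm)
  fill <- function(gr) {
    for (col in c("gene_id", "transcript_id"))
      if (is.null(mcols(gr)[[col]])) mcols(gr)[[col]] <- NA_character_
    gr
  }
  all <- c(addType(ex, "exon"), addType(cd, "CDS"),
           addType(fill(u5), "five_prime_utr"), addType(fill(u3), "three_prime_utr"))
  mcols(all)$source <- "circActivity"
  ord <- order(as.character(seqnames(all)), start(all),
               mcols(all)$transcript_id, mcols(all)$type)
  rtracklayer::export(all[ord], gtf, format = "gtf")
  invisible(c(fasta, gtf))
}

#' Read a GTF annotation into a gene model
#'
#' Imports exon and CDS features, converts to internal ranges, sorts exons,
#' assigns 5'-to-3' exon ordinals when absent, and derives 5'/3' UTRs from
#' the CDS when UTR features are not present in the file.
#'
#' @param path GTF path (1-based inclusive coordinates, per the standard).
#' @param genome Optional [Biostrings::DNAStringSet] (or FASTA path) of the
#'   matching genome; without it sequence-dependent operations are
#'   unavailable but interval operations work.
#' @return A [GeneModel-class].
#' @export
readGtf <- function(path, genome = NULL) {
  # coordinate sanity scan with line numbers before parsing proper
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  lineNo <- which(body)
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 8)
      stop("GTF parse error at line ", lineNo[k], ": fewer than 8 fields")
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e) || e < s)
      stop("GTF parse error at line ", lineNo[k], ": end < start")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  cd <- gr[gr$type == "CDS"]
  if (!length(ex)) stop("GTF contains no exon features")
  ord <- order(mcols(ex)$transcript_id, start(ex))
  ex <- ex[ord]
  if (is.null(mcols(ex)$exon_number) || anyNA(mcols(ex)$exon_number)) {
    num <- unlist(lapply(split(seq_along(ex), mcols(ex)$transcript_id),
                         function(ii) {
      n <- length(ii)
      if (as.character(strand(ex))[ii[1]] == "-") rev(seq_len(n)) else seq_len(n)
    }), use.names = FALSE)
    ordBack <- unlist(split(seq_along(ex), mcols(ex)$transcript_id),
                      use.names = FALSE)
    mcols(ex)$exon_number[ordBack] <- num
  } else {
    mcols(ex)$exon_number <- as.integer(mcols(ex)$exon_number)
  }
  keep <- c("gene_id", "transcript_id", "exon_number")
  mcols(ex) <- mcols(ex)[, keep]
  if (length(cd))
    mcols(cd) <- mcols(cd)[, c("gene_id", "transcript_id")]
  else
    cd <- GenomicRanges::GRanges()

  txIds <- unique(mcols(ex)$transcript_id)
  txs <- do.call(rbind, lapply(txIds, function(tid) {
    sub <- ex[mcols(ex)$transcript_id == tid]
    data.frame(transcript_id = tid,
               gene_id = mcols(sub)$gene_id[1],
               chrom = as.character(seqnames(sub))[1],
               strand = as.character(strand(sub))[1],
               n_exons = length(sub), stringsAsFactors = FALSE)
  }))
  utr5 <- gr[gr$type %in% c("five_prime_utr", "5UTR")]
  utr3 <- gr[gr$type %in% c("three_prime_utr", "3UTR")]
  if (!length(utr5) && !length(utr3) && length(cd)) {
    utrs <- .deriveUtrs(ex, cd)
    utr5 <- utrs$utr5; utr3 <- utrs$utr3
  } else {
    if (length(utr5)) mcols(utr5) <- mcols(utr5)[, "transcript_id", drop = FALSE]
    if (length(utr3)) mcols(utr3) <- mcols(utr3)[, "transcript_id", drop = FALSE]
  }
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (is.null(genome)) genome <- Biostrings::DNAStringSet()
  methods::new("GeneModel", genome = genome, exons = ex, cds = granges(cd,
               use.mcols = TRUE), utr5 = granges(utr5, use.mcols = TRUE),
               utr3 = granges(utr3, use.mcols = TRUE), transcripts = txs)
}

#' Concatenated exonic sequence of a circRNA
#'
#' Returns the sequence of a circle whose back-splice junction spans
#' `[start, end]` (1-based inclusive, genomic): the exons of the host
#' transcript falling inside the span are concatenated and, for
#' minus-strand transcripts, reverse-complemented so the result reads in
#' transcript orientation. When no transcript matches the span boundaries,
#' the plain genomic span (strand-adjusted) is returned.
#'
#' @param gm A [GeneModel-class] with genome sequences.
#' @param chrom,start,end,strand Junction coordinates (1-based inclusive).
#' @param transcriptId Optional transcript to use; defaults to the boundary
#'   match used by [classifyOrigin()].
#' @return A character scalar (DNA).
#' @export
circSequence <- function(gm, chrom, start, end, strand,
                         transcriptId = NULL) {
  if (!length(genomeSeq(gm))) stop("GeneModel carries no genome sequence")
  ex <- exonRanges(gm)
  pick <- NULL
  if (is.null(transcriptId)) {
    hit <- ex[as.character(seqnames(ex)) == chrom &
              as.character(strand(ex)) == strand]
    cand <- unique(mcols(hit)$transcript_id[start(hit) == start])
    cand2 <- unique(mcols(hit)$transcript_id[end(hit) == end])
    both <- intersect(cand, cand2)
    if (length(both)) pick <- sort(both)[1]
  } else pick <- transcriptId
  chromSeq <- genomeSeq(gm)[[chrom]]
  if (is.null(pick)) {
    s <- as.character(Biostrings::subseq(chromSeq, start, end))
    if (strand == "-") s <- .revcompChar(s)
    return(s)
  }
  sub <- ex[mcols(ex)$transcript_id == pick &
            start(ex) >= start & end(ex) <= end]
  sub <- sub[order(start(sub))]
  parts <- vapply(seq_along(sub), function(i) {
    as.character(Biostrings::subseq(chromSeq, start(sub)[i], end(sub)[i]))
  }, character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-") s <- .revcompChar(s)
  s
}
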