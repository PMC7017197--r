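#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom BiocGenerics start end strand width
#' @importFrom GenomicRanges GRanges GRangesList seqnames granges
#' @importFrom IRanges ranges ranges<-
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet DNAString
NULL

#' Gene models for a toy or real genome
#'
#' Container for a genome and its transcript annotation: exon and CDS
#' intervals per transcript plus the 5'/3' UTR intervals derived from them.
#' All ranges are 1-based inclusive [GRanges] on the genome in `genome`.
#'
#' @slot genome A [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot exons A [GenomicRanges::GRanges] of exons with metadata columns
#'   `gene_id`, `transcript_id`, `exon_number` (ordinal from the transcript
#'   5' end, so minus-strand transcripts count from the right).
#' @slot cds A [GenomicRanges::GRanges] of CDS intervals with
#'   `transcript_id`; may be empty for non-coding annotation.
#' @slot utr5,utr3 [GenomicRanges::GRanges] of untranslated regions derived
#'   from exons minus CDS, strand-aware.
#' @slot transcripts A `data.frame` with one row per transcript:
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `n_exons`.
#' @export
setClass("GeneModel",
  representation(
    genome = "DNAStringSet",
    exons = "GRanges",
    cds = "GRanges",
    utr5 = "GRanges",
    utr3 = "GRanges",
    transcripts = "data.frame"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  need <- c("gene_id", "transcript_id", "exon_number")
  if (!all(need %in% colnames(mcols(object@exons))))
    msg <- c(msg, "exons must carry gene_id, transcript_id, exon_number")
  if (length(object@exons) && length(object@genome)) {
    bad <- !as.character(seqnames(object@exons)) %in% names(object@genome)
    if (any(bad))
      msg <- c(msg, "exon seqnames absent from genome")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneModel Chromosome sequences.
#' @param x A `GeneModel`.
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @export
setMethod("genomeSeq", "GeneModel", function(x) x@genome)

#' @describeIn GeneModel Exon ranges.
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @export
setMethod("exonRanges", "GeneModel", function(x) x@exons)

#' @describeIn GeneModel CDS ranges.
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))
#' @export
setMethod("cdsRanges", "GeneModel", function(x) x@cds)

#' @describeIn GeneModel 5' UTR ranges.
#' @export
setGeneric("utr5Ranges", function(x) standardGeneric("utr5Ranges"))
#' @export
setMethod("utr5Ranges", "GeneModel", function(x) x@utr5)

#' @describeIn GeneModel 3' UTR ranges.
#' @export
setGeneric("utr3Ranges", function(x) standardGeneric("utr3Ranges"))
#' @export
setMethod("utr3Ranges", "GeneModel", function(x) x@utr3)

#' @describeIn GeneModel Transcript table.
#' @export
setGeneric("transcriptTable", function(x) standardGeneric("transcriptTable"))
#' @export
setMethod("transcriptTable", "GeneModel", function(x) x@transcripts)

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel with", length(object@genome), "sequence(s),",
      nrow(object@transcripts), "transcript(s),",
      length(object@exons), "exon(s)\n")
})

#' Tripartite circRNA-miRNA-mRNA network
#'
#' An undirected simple graph over three node kinds in which the only legal
#' edges are circRNA--miRNA and miRNA--mRNA, and every miRNA--mRNA edge
#' joins nodes of opposite differential-expression direction (the
#' competing-endogenous-RNA constraint). circRNA--miRNA edges carry no
#' direction constraint: a sponge need not change the steady-state level of
#' the miRNA it sequesters.
#'
#' @slot graph An [igraph::igraph] with vertex attributes `kind`
#'   (`"circ"`, `"mir"`, `"mrna"`) and `direction` (`"up"`, `"down"`).
#' @export
setClass("TripartiteNetwork", representation(graph = "ANY"))

setValidity("TripartiteNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must be an igraph object")
  if (igraph::vcount(g) == 0) return(TRUE)
  msg <- character()
  kind <- igraph::V(g)$kind
  dir <- igraph::V(g)$direction
  if (is.null(kind) || !all(kind %in% c("circ", "mir", "mrna")))
    msg <- c(msg, "vertex attribute 'kind' must be circ/mir/mrna")
  if (is.null(dir) || !all(dir %in% c("up", "down")))
    msg <- c(msg, "vertex attribute 'direction' must be up/down")
  if (igraph::ecount(g) > 0 && length(msg) == 0) {
    ends <- igraph::as_edgelist(g, names = FALSE)
    k1 <- kind[ends[, 1]]; k2 <- kind[ends[, 2]]
    pair <- paste(pmin(k1, k2), pmax(k1, k2))
    if (!all(pair %in% c("circ mir", "mir mrna")))
      msg <- c(msg, "edges must be circ-mir or mir-mrna")
    mm <- pair == "mir mrna"
    if (any(mm & dir[ends[, 1]] == dir[ends[, 2]]))
      msg <- c(msg, "mir-mrna edges must join opposite-direction nodes")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TripartiteNetwork The underlying igraph object.
#' @param x A `TripartiteNetwork`.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))
#' @export
setMethod("asIgraph", "TripartiteNetwork", function(x) x@graph)

#' @describeIn TripartiteNetwork Named vector of node kinds.
#' @export
setGeneric("nodeKind", function(x) standardGeneric("nodeKind"))
#' @export
setMethod("nodeKind", "TripartiteNetwork", function(x) {
  g <- x@graph
  stats::setNames(igraph::V(g)$kind, igraph::V(g)$name)
})

#' @describeIn TripartiteNetwork Named vector of node DE directions.
#' @export
setGeneric("nodeDirection", function(x) standardGeneric("nodeDirection"))
#' @export
setMethod("nodeDirection", "TripartiteNetwork", function(x) {
  g <- x@graph
  stats::setNames(igraph::V(g)$direction, igraph::V(g)$name)
})

#' @describeIn TripartiteNetwork Edge list as a two-column data.frame.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @export
setMethod("edgeTable", "TripartiteNetwork", function(x) {
  el <- igraph::as_edgelist(x@graph)
  data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
})

setMethod("show", "TripartiteNetwork", function(object) {
  g <- object@graph
  kind <- igraph::V(g)$kind
  cat("TripartiteNetwork:", sum(kind == "circ"), "circRNA,",
      sum(kind == "mir"), "miRNA,", sum(kind == "mrna"), "mRNA nodes;",
      igraph::ecount(g), "edges\n")
})

#' Back-splice junction index for ribosome-footprint mapping
#'
#' For each circRNA the index stores the `2 * flank`-nt sequence read across
#' the back-splice junction in transcript orientation: the last `flank` nt
#' of the circle followed by its first `flank` nt. Circles shorter than
#' `2 * flank` wrap cyclically and are flagged. Identical junction k-mers
#' are deduplicated; `duplicates` maps each dropped circ id to the retained
#' entry carrying the same sequence.
#'
#' @slot entries A [Biostrings::DNAStringSet] of junction sequences, one per
#'   retained circRNA, all of width `2 * flank`.
#' @slot circles A [Biostrings::DNAStringSet] of the full circle sequences
#'   backing each entry (used to extend alignments beyond the entry).
#' @slot flank Integer scalar, nt retained on each side of the wrap point.
#' @slot duplicates Named character vector: dropped id -> retained id.
#' @slot short Character vector of circle ids shorter than `2 * flank`.
#' @export
setClass("JunctionIndex",
  representation(
    entries = "DNAStringSet",
    circles = "DNAStringSet",
    flank = "integer",
    duplicates = "character",
    short = "character"
  )
)

setValidity("JunctionIndex", function(object) {
  msg <- character()
  if (length(object@flank) != 1L || object@flank < 1L)
    msg <- c(msg, "flank must be a positive scalar")
  if (length(object@entries) &&
      !all(width(object@entries) == 2L * object@flank))
    msg <- c(msg, "all entries must have width 2*flank")
  if (!identical(names(object@entries), names(object@circles)))
    msg <- c(msg, "entries and circles must share names")
  if (length(msg)) msg else TRUE
})

#' @describeIn JunctionIndex Junction sequences.
#' @param x A `JunctionIndex`.
#' @export
setGeneric("indexEntries", function(x) standardGeneric("indexEntries"))
#' @export
setMethod("indexEntries", "JunctionIndex", function(x) x@entries)

#' @describeIn JunctionIndex The flank width in nt.
#' @export
setGeneric("indexFlank", function(x) standardGeneric("indexFlank"))
#' @export
setMethod("indexFlank", "JunctionIndex", function(x) x@flank)

#' @describeIn JunctionIndex Full circle sequences backing the entries.
#' @export
setGeneric("indexCircles", function(x) standardGeneric("indexCircles"))
#' @export
setMethod("indexCircles", "JunctionIndex", function(x) x@circles)

setMethod("show", "JunctionIndex", function(object) {
  cat("JunctionIndex:", length(object@entries), "entries of",
      2L * object@flank, "nt;", length(object@duplicates),
      "duplicate junction(s),", length(object@short), "short circle(s)\n")
})
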