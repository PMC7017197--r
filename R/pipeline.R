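#' Read a split-segment alignment table
#'
#' Tab-delimited with columns `read_id`, `segment_index`, `chrom`,
#' `start`, `end`, `strand` (0-based half-open) and optionally
#' `sample_id`. Malformed rows are reported with their line number.
#'
#' @param path TSV path.
#' @return data.frame suitable for [detectJunctions()].
#' @export
readSegmentTable <- function(path) {
  df <- .readTsv(path)
  req <- c("read_id", "segment_index", "chrom", "start", "end", "strand")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("segment table lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
               df$end <= df$start | !df$strand %in% c("+", "-"))
  if (length(bad))
    stop("malformed segment row at line ", bad[1] + 1L)  # +1 for header
  df
}

#' Write junctions as BED6
#'
#' Coordinates convert to BED's 0-based half-open convention; the name
#' field carries the circ id and the score the total read support.
#'
#' @param junctions [GenomicRanges::GRanges] from [detectJunctions()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeJunctionBed <- function(junctions, path) {
  df <- data.frame(
    chrom = as.character(seqnames(junctions)),
    start = start(junctions) - 1L,
    end = end(junctions),
    name = mcols(junctions)$circ_id,
    score = mcols(junctions)$total_support,
    strand = as.character(strand(junctions)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate a complete synthetic study with planted ground truth
#'
#' Emulates the data of a depolarization experiment at desk scale: a toy
#' genome with spliced gene models; back-splice read evidence for planted
#' circRNAs over 3 + 3 replicates with negative-binomial support counts
#' and planted fold changes; miRNA and mRNA count matrices over 4 + 4
#' replicates; mature miRNA sequences with canonical seed sites planted
#' into circRNA and mRNA sequences so that a known set of circRNAs becomes
#' network hubs; and ribosome footprints crossing the circle wrap points.
#' Every planted feature is returned in machine-readable `truth`.
#'
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @param nGenes Genes in the toy genome.
#' @param nCirc Planted circRNAs.
#' @param nMir miRNAs.
#' @param nMrnaDe Differentially expressed mRNA targets.
#' @param nHubPlanted Circles wired as high-connectivity hubs.
#' @param circMean,circDisp NB parameters of junction-read support.
#' @param linearDepth Linear reads per sample (mapped-total padding).
#' @param readLength Back-splice read length.
#' @return list with the inputs each stage consumes plus `truth`.
#' @export
simulateStudy <- function(seed = 1L, nGenes = 40L, nCirc = 20L,
                          nMir = 10L, nMrnaDe = 40L, nHubPlanted = 3L,
                          circMean = 20, circDisp = 0.05,
                          linearDepth = 1000L, readLength = 100L) {
  gm <- makeGenome(nGenes, c(3L, 6L), seed = seed,
                   exonLength = c(120L, 300L))
  txs <- transcriptTable(gm)
  ex <- exonRanges(gm)

  .withSeed(seed + 101L, {
    # safe against R's scalar-sample expansion
    resample <- function(x) x[sample.int(length(x), 1L)]
    # --- circRNA plan: whole-exon spans wide enough for the read length
    circGenes <- sample(txs$transcript_id, nCirc)
    plan <- do.call(rbind, lapply(seq_along(circGenes), function(i) {
      tid <- circGenes[i]
      sub <- ex[mcols(ex)$transcript_id == tid]
      sub <- sub[order(start(sub))]
      n <- length(sub)
      i0 <- resample(seq_len(n - 1L))
      j0 <- resample(seq(i0 + 1L, n))
      data.frame(circ_id = sprintf("circ%02d", i),
                 transcript_id = tid,
                 gene_id = txs$gene_id[txs$transcript_id == tid],
                 chrom = as.character(seqnames(sub))[1],
                 start = start(sub)[i0], end = end(sub)[j0],
                 strand = as.character(strand(sub))[1],
                 stringsAsFactors = FALSE)
    }))
    ok <- (plan$end - plan$start + 1L) >= readLength
    plan <- plan[ok, , drop = FALSE]

    # planted circRNA fold changes: first half up, next quarter down
    nC <- nrow(plan)
    circLfc <- stats::setNames(numeric(nC), plan$circ_id)
    up <- seq_len(ceiling(nC / 2))
    down <- seq(max(up) + 1L, max(up) + floor(nC / 4))
    circLfc[up] <- 2; circLfc[down] <- -2

    circCounts <- simulateCounts(plan$circ_id, 3L, 3L, mean = circMean,
                                 dispersion = circDisp, de = circLfc,
                                 seed = seed + 202L)
    sampleIds <- colnames(circCounts$counts)
    planCounts <- cbind(plan, as.data.frame(circCounts$counts))

    sim <- simulateBackspliceReads(gm, planCounts, sampleIds,
                                   linearDepth = linearDepth,
                                   readLength = readLength,
                                   seed = seed + 303L)

    # --- miRNA: sequences and counts (4 + 4), half up / half down
    mirIds <- sprintf("mir%02d", seq_len(nMir))
    mirSeq <- stats::setNames(vapply(seq_len(nMir), function(i) {
      paste(sample(c("A", "C", "G", "U"), 22L, replace = TRUE),
            collapse = "")
    }, character(1)), mirIds)
    mirLfc <- stats::setNames(rep(c(2, -2), length.out = nMir), mirIds)
    mirCounts <- simulateCounts(mirIds, 4L, 4L, mean = 200,
                                dispersion = 0.05, de = mirLfc,
                                seed = seed + 404L)

    # --- mRNA: DE genes distinct from circ hosts where possible
    mrnaPool <- setdiff(txs$gene_id, plan$gene_id)
    if (length(mrnaPool) < nMrnaDe)
      mrnaPool <- txs$gene_id
    mrnaIds <- sort(sample(mrnaPool, min(nMrnaDe, length(mrnaPool))))
    mrnaLfc <- stats::setNames(rep(c(-2, 2), length.out = length(mrnaIds)),
                               mrnaIds)
    mrnaCounts <- simulateCounts(mrnaIds, 4L, 4L, mean = 300,
                                 dispersion = 0.05, de = mrnaLfc,
                                 seed = seed + 505L)

    # --- sequences: circle exonic sequences and mRNA transcript sequences
    circSeqs <- stats::setNames(vapply(seq_len(nC), function(i) {
      circSequence(gm, plan$chrom[i], plan$start[i], plan$end[i],
                   plan$strand[i], transcriptId = plan$transcript_id[i])
    }, character(1)), plan$circ_id)
    mrnaSeqs <- stats::setNames(vapply(mrnaIds, function(g) {
      tid <- txs$transcript_id[txs$gene_id == g][1]
      sub <- ex[mcols(ex)$transcript_id == tid]
      rng <- range(start(sub))
      circSequence(gm, as.character(seqnames(sub))[1], min(start(sub)),
                   max(end(sub)), as.character(strand(sub))[1],
                   transcriptId = tid)
    }, character(1)), mrnaIds)

    # --- planted interaction wiring: hubs bind many miRNAs
    hubIds <- plan$circ_id[seq_len(min(nHubPlanted, nC))]
    sitePlanCirc <- list(); sitePlanMrna <- list()
    mirPerHub <- min(6L, nMir)
    usedPos <- function(n, k) seq(10L, by = 40L, length.out = k)
    for (h in seq_along(hubIds)) {
      mirsH <- mirIds[((seq_len(mirPerHub) + h - 2L) %% nMir) + 1L]
      pos <- usedPos(nchar(circSeqs[[hubIds[h]]]), mirPerHub)
      sitePlanCirc[[h]] <- data.frame(
        mirna_id = mirsH, target_id = hubIds[h], site_type = "8mer",
        position = pos, stringsAsFactors = FALSE)
    }
    others <- setdiff(plan$circ_id, hubIds)
    for (k in seq_along(others)) {
      mid <- mirIds[(k - 1L) %% nMir + 1L]
      sitePlanCirc[[length(sitePlanCirc) + 1L]] <- data.frame(
        mirna_id = mid, target_id = others[k], site_type = "8mer",
        position = 10L, stringsAsFactors = FALSE)
    }
    # each miRNA targets mRNAs of opposite planted direction
    mrnaPerMir <- 4L
    slot <- 0L
    for (m in seq_len(nMir)) {
      wantDir <- if (mirLfc[m] > 0) -1 else 1
      cands <- mrnaIds[sign(mrnaLfc[mrnaIds]) == wantDir]
      if (!length(cands)) next
      pickG <- cands[((slot + seq_len(mrnaPerMir) - 1L) %% length(cands)) + 1L]
      slot <- slot + mrnaPerMir
      for (g in unique(pickG)) {
        sitePlanMrna[[length(sitePlanMrna) + 1L]] <- data.frame(
          mirna_id = mirIds[m], target_id = g, site_type = "8mer",
          position = 10L + 40L * (m %% 5L), stringsAsFactors = FALSE)
      }
    }
    planCircSites <- do.call(rbind, sitePlanCirc)
    planMrnaSites <- do.call(rbind, sitePlanMrna)
    circEdit <- plantMirnaSites(circSeqs, mirSeq, planCircSites)
    mrnaEdit <- plantMirnaSites(mrnaSeqs, mirSeq, planMrnaSites)

    # --- ribosome footprints from a subset of circles
    riboCircs <- circEdit$targets[seq_len(min(6L, nC))]
    rpf <- simulateRpfReads(riboCircs, nReads = 60L,
                            junctionFraction = 0.3, seed = seed + 606L)
    # per-sample junction-read totals: more in depolarized (group B)
    riboSamples <- c(sprintf("rest%d", 1:3), sprintf("depol%d", 1:3))
    riboGroups <- factor(rep(c("rest", "depol"), each = 3),
                         levels = c("rest", "depol"))
    riboJuncReads <- stats::setNames(
      c(stats::rpois(3, 40), stats::rpois(3, 120)), riboSamples)
    riboTotals <- stats::setNames(rep(2e6, 6), riboSamples)

    list(
      geneModel = gm,
      segments = sim$segments, totalMapped = sim$totalMapped,
      circPlan = planCounts, circCounts = circCounts,
      mirSeq = mirSeq, mirCounts = mirCounts,
      mrnaCounts = mrnaCounts,
      circSeqs = circEdit$targets, mrnaSeqs = mrnaEdit$targets,
      riboReads = rpf$reads,
      riboJuncReads = riboJuncReads, riboTotals = riboTotals,
      riboGroups = riboGroups,
      truth = list(
        seed = seed,
        circ_junctions = plan,
        circ_log2fc = circLfc, mir_log2fc = mirLfc,
        mrna_log2fc = mrnaLfc,
        planted_circ_sites = circEdit$planted,
        planted_mrna_sites = mrnaEdit$planted,
        hub_ids = hubIds,
        rpf_truth = rpf$truth))
  })
}

#' Run the full analysis chain on a synthetic study
#'
#' Orchestrates detection, filtering, annotation, RPM quantification, the
#' three differential analyses, target prediction, network assembly,
#' consensus hub selection and the ribosome-footprint stage, writing every
#' stage's table plus a `manifest.json` (parameters and md5 of each
#' output) to `outDir`. Identical seeds produce byte-identical outputs and
#' manifests.
#'
#' @param outDir Output directory (created if missing).
#' @param seed Master seed.
#' @param epcReplicates Percolation replicates for the EPC centrality
#'   (reduced from the analysis default to keep the end-to-end run fast;
#'   see the methods vignette).
#' @param ... Passed to [simulateStudy()].
#' @return Invisibly, a list with all stage results and the truth bundle.
#' @export
runAll <- function(outDir, seed = 1L, epcReplicates = 200L, ...) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  study <- simulateStudy(seed = seed, ...)

  # detection -> filter -> snap -> classify -> RPM
  junc <- detectJunctions(study$segments, minSupport = 2L)
  sampleIds <- names(study$totalMapped)
  supp <- as.matrix(mcols(junc)[, paste0("support_", sampleIds)])
  colnames(supp) <- sampleIds
  rownames(supp) <- mcols(junc)$circ_id
  supp <- filterMinEvidence(supp, 2L, 1L)
  junc <- junc[mcols(junc)$circ_id %in% rownames(supp)]
  junc <- snapToExons(junc, study$geneModel)
  junc <- classifyOrigin(junc, study$geneModel)
  rpm <- quantifyRpm(supp, study$totalMapped)

  # differential expression, three classes
  # circRNA counts are normalized by total mapped reads (the RPM
  # denominator), not by junction-count column sums
  circLib <- study$totalMapped[colnames(study$circCounts$counts)]
  deC <- classifyDE(testTwoGroup(study$circCounts$counts,
                                 study$circCounts$groups,
                                 libSizes = circLib),
                    alpha = 0.05, fcMin = 2, useFdr = FALSE)
  deMi <- classifyDE(testTwoGroup(study$mirCounts$counts,
                                  study$mirCounts$groups),
                     alpha = 0.05, fcMin = 1.5, useFdr = TRUE)
  deMr <- classifyDE(testTwoGroup(study$mrnaCounts$counts,
                                  study$mrnaCounts$groups),
                     alpha = 0.05, fcMin = 2, useFdr = TRUE)

  # target prediction and network
  intCirc <- predictInteractions(study$mirSeq, study$circSeqs,
                                 circular = TRUE)
  intMrna <- predictInteractions(study$mirSeq, study$mrnaSeqs)
  cm <- buildCircMirPairs(deC, deMi, intCirc)
  mm <- buildMirMrnaPairs(deMi, deMr, intMrna)
  dirs <- c(stats::setNames(deC$direction, deC$feature_id),
            stats::setNames(deMi$direction, deMi$feature_id),
            stats::setNames(deMr$direction, deMr$feature_id))
  dirs <- dirs[dirs %in% c("up", "down")]
  net <- mergeNetwork(cm, mm, dirs)
  rankings <- lapply(centralityMethods(), function(m)
    centrality(net, m, epcReplicates = epcReplicates, seed = seed + 707L))
  hubs <- selectHubs(rankings, net, kTop = 20L, nHubs = 15L)
  subnet <- hubSubnetwork(net, hubs$node)

  # ribosome stage
  idx <- buildJunctionIndex(study$circSeqs, flank = 18L)
  rpfKept <- filterReads(study$riboReads)
  hits <- mapToIndex(rpfKept, idx)
  regions <- annotateRegions(junc, study$geneModel)
  orfs <- lapply(study$circSeqs, rollingOrfs)
  coding <- callCoding(orfs)
  abund <- compareGroupAbundance(study$riboJuncReads, study$riboTotals,
                                 study$riboGroups)

  # outputs + manifest
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(outDir, name)
    .writeTsv(df, p)
    paths[[name]] <<- p
  }
  writeJunctionBed(junc, file.path(outDir, "junctions.bed"))
  paths[["junctions.bed"]] <- file.path(outDir, "junctions.bed")
  juncDf <- as.data.frame(junc)
  put(juncDf, "junction_annotation.tsv")
  put(data.frame(circ_id = rownames(rpm), rpm, check.names = FALSE),
      "rpm.tsv")
  put(deC, "de_circ.tsv"); put(deMi, "de_mirna.tsv")
  put(deMr, "de_mrna.tsv")
  put(intCirc, "interactions_circ.tsv")
  put(intMrna, "interactions_mrna.tsv")
  put(edgeTable(net), "network_edges.tsv")
  put(hubs, "hubs.tsv")
  put(edgeTable(subnet), "hub_subnetwork_edges.tsv")
  put(hits, "rpf_hits.tsv")
  put(regions, "region_annotation.tsv")
  orfTab <- do.call(rbind, lapply(names(orfs), function(cid) {
    o <- orfs[[cid]]
    if (!nrow(o)) return(NULL)
    cbind(circ_id = cid, o)
  }))
  if (is.null(orfTab))
    orfTab <- data.frame(circ_id = character())
  put(orfTab, "orfs.tsv")
  put(data.frame(circ_id = names(coding), coding = coding), "coding.tsv")

  manifest <- list(
    seed = seed,
    parameters = list(min_support = 2, min_reads = 2, min_samples = 1,
                      snap_tolerance = 2, de_alpha = 0.05,
                      fc_circ = 2, fc_mirna = 1.5, fc_mrna = 2,
                      score_cutoff = -0.2, k_top = 20, n_hubs = 15,
                      epc_replicates = epcReplicates, flank = 18,
                      rpf_len = c(25, 40), max_mismatch = 2,
                      min_anchor = 6, n_repeats = 4, min_aa = 20),
    outputs = as.list(unname(Map(function(nm, p)
      list(file = nm, md5 = unname(tools::md5sum(p))),
      names(paths), paths))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(study = study, junctions = junc, support = supp,
                 rpm = rpm, de = list(circ = deC, mirna = deMi,
                                      mrna = deMr),
                 interactions = list(circ = intCirc, mrna = intMrna),
                 network = net, rankings = rankings, hubs = hubs,
                 subnetwork = subnet, index = idx, rpfHits = hits,
                 regions = regions, orfs = orfs, coding = coding,
                 abundance = abund))
}

#' Correlate circular and linear expression per gene
#'
#' Per-gene mean circular RPM against linear TPM (or, in `"change"` mode,
#' the log2 fold changes of the two between groups), filtered for
#' well-expressed genes (circular RPM and linear TPM above their
#' thresholds), associated by Spearman rank correlation.
#'
#' @param circRpm Matrix of circRNA RPM values (circles x samples).
#' @param circGenes Host gene per circRNA row.
#' @param mrnaTpm Matrix of TPM-like values with gene ids as rownames.
#' @param circMin,tpmMin Expression filters, defaults 0.2 and 0.2.
#' @param mode `"level"` correlates mean levels; `"change"` correlates
#'   between-group log2 fold changes (requires `circGroups`/`mrnaGroups`).
#' @param circGroups,mrnaGroups Two-level factors for `"change"` mode.
#' @return list with `rho`, `p`, `n` from [spearmanAssoc()].
#' @export
correlateCircLinear <- function(circRpm, circGenes, mrnaTpm,
                                circMin = 0.2, tpmMin = 0.2,
                                mode = c("level", "change"),
                                circGroups = NULL, mrnaGroups = NULL) {
  mode <- match.arg(mode)
  genes <- intersect(unique(circGenes[!is.na(circGenes)]),
                     rownames(mrnaTpm))
  circLevel <- vapply(genes, function(g)
    mean(circRpm[circGenes == g & !is.na(circGenes), , drop = FALSE]),
    numeric(1))
  tpmLevel <- rowMeans(mrnaTpm[genes, , drop = FALSE])
  keep <- circLevel > circMin & tpmLevel > tpmMin
  genes <- genes[keep]
  if (length(genes) < 3)
    stop("fewer than 3 genes pass the expression filters")
  if (mode == "level") {
    res <- spearmanAssoc(circLevel[keep], tpmLevel[keep])
  } else {
    if (is.null(circGroups) || is.null(mrnaGroups))
      stop("change mode needs circGroups and mrnaGroups")
    fcOf <- function(mat, rowsPick, groups) {
      g <- factor(groups)
      mA <- rowMeans(mat[rowsPick, g == levels(g)[1], drop = FALSE])
      mB <- rowMeans(mat[rowsPick, g == levels(g)[2], drop = FALSE])
      log2(mB + 0.5) - log2(mA + 0.5)
    }
    circFc <- vapply(genes, function(gn) {
      rows <- which(circGenes == gn)
      mean(fcOf(circRpm, rows, circGroups))
    }, numeric(1))
    mrnaFc <- fcOf(mrnaTpm, genes, mrnaGroups)
    res <- spearmanAssoc(circFc, mrnaFc)
  }
  list(rho = res$rho, p = res$p, n = length(genes))
}
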