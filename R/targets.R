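#' Seed region of a mature miRNA
#'
#' Returns the 7-mer at miRNA positions 2--8 (1-based from the 5' end),
#' the region whose Watson-Crick complement on a target defines canonical
#' site types.
#'
#' @param mirna Character scalar, mature miRNA sequence (RNA or DNA
#'   alphabet), length >= 8.
#' @return The 7-nt seed, in the input alphabet.
#' @examples
#' seedOf("UGAGGUAGUAGGUUGUAUAGUU")  # "GAGGUAG"
#' @export
seedOf <- function(mirna) {
  mirna <- toupper(as.character(mirna))
  if (nchar(mirna) < 8) stop("miRNA must be at least 8 nt")
  substr(mirna, 2L, 8L)
}

#' Find canonical miRNA seed-match sites on a target sequence
#'
#' Scans the target (DNA alphabet, 5'->3') for the reverse complement of
#' the seed. At each match locus only the strongest applicable type is
#' reported: an exact match to positions 2--8 plus an A opposite position 1
#' is an `8mer`; with only the position-8 match it is `7mer-m8`; with only
#' the A it is `7mer-A1`; a bare match to positions 2--7 is a `6mer`.
#' Reported positions are the 0-based start of the core match (pairing
#' miRNA positions 2--7) on the scanned sequence.
#'
#' @param mirna Mature miRNA sequence (RNA or DNA).
#' @param target Target sequence (DNA; U is tolerated and mapped to T).
#' @param circular If TRUE the target is treated as circular: the scan runs
#'   over the sequence extended by its first 7 nt, positions are reported
#'   modulo the true length, and sites spanning the wrap are flagged.
#' @return data.frame with `site_type`, `position`, `spans_junction`.
#' @export
findSites <- function(mirna, target, circular = FALSE) {
  target <- .asDnaChar(target)
  L <- nchar(target)
  scan <- if (circular) paste0(target, substr(target, 1L, 7L)) else target
  seed7 <- .asDnaChar(seedOf(mirna))
  core6 <- .revcompChar(substr(seed7, 1L, 6L))
  m8nt <- .revcompChar(substr(seed7, 7L, 7L))
  empty <- data.frame(site_type = character(), position = integer(),
                      spans_junction = logical(), stringsAsFactors = FALSE)
  hits <- gregexpr(core6, scan, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(empty)
  # 0-based cyclic character access in circular mode; "" off either end
  # in linear mode
  charAt <- function(i) {
    if (circular) i <- i %% L
    if (i < 0 || i >= L) return("")
    substr(target, i + 1L, i + 1L)
  }
  rows <- lapply(as.integer(hits), function(p1) {
    p <- p1 - 1L                                    # 0-based core start
    if (circular && p >= L) return(NULL)            # dedupe wrapped copy
    m8 <- charAt(p - 1L) == m8nt
    hasA <- charAt(p + 6L) == "A"
    type <- if (m8 && hasA) "8mer" else if (m8) "7mer-m8"
      else if (hasA) "7mer-A1" else "6mer"
    spanStart <- p + .siteOffset(type)
    spanEnd <- spanStart + switch(type, "8mer" = 8L, "7mer-m8" = 7L,
                                  "7mer-A1" = 7L, "6mer" = 6L)
    data.frame(site_type = type, position = p,
               spans_junction = circular && (spanEnd > L || spanStart < 0),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$position), , drop = FALSE]
}

#' Score a seed-match site with the base + AU-context surrogate
#'
#' A simplified stand-in for context-style site efficacy: each site type
#' carries a base score (more negative = stronger) and a penalty
#' proportional to the GC content of the site's local context:
#' `score = base(type) + auWeight * (1 - AU fraction)`, where the AU
#' fraction is measured over the `windowSize` nt surrounding the site
#' (half on each side, excluding the site span itself, clipped at the
#' sequence ends; a site with no flanking context takes no penalty).
#'
#' @param siteType One of `8mer`, `7mer-m8`, `7mer-A1`, `6mer`.
#' @param position 0-based core start of the site on the target.
#' @param target Target sequence (DNA).
#' @param baseScores Named numeric vector of per-type base scores.
#' @param auWeight Weight of the (1 - AU) context penalty.
#' @param windowSize Context window width in nt.
#' @return Numeric score.
#' @export
scoreSite <- function(siteType, position, target,
                      baseScores = c("8mer" = -0.31, "7mer-m8" = -0.16,
                                     "7mer-A1" = -0.10, "6mer" = -0.03),
                      auWeight = 0.10, windowSize = 30L) {
  target <- .asDnaChar(target)
  L <- nchar(target)
  spanStart <- position + .siteOffset(siteType)
  spanLen <- switch(siteType, "8mer" = 8L, "7mer-m8" = 7L,
                    "7mer-A1" = 7L, "6mer" = 6L)
  half <- windowSize %/% 2L
  upFrom <- max(0L, spanStart - half)
  up <- if (spanStart > 0) substr(target, upFrom + 1L, spanStart) else ""
  spanEnd <- spanStart + spanLen
  down <- if (spanEnd < L)
    substr(target, spanEnd + 1L, min(L, spanEnd + half)) else ""
  win <- paste0(up, down)
  auFrac <- if (nchar(win)) mean(strsplit(win, "")[[1]] %in% c("A", "T"))
    else 1
  unname(baseScores[siteType] + auWeight * (1 - auFrac))
}

#' Predict miRNA-target interactions under a score cutoff
#'
#' For every (miRNA, target) pair, finds canonical seed sites, scores them,
#' retains sites with score strictly below `cutoff`, and reports one row
#' per pair with at least one retained site. `bestScore` is the minimum
#' (strongest) retained site score.
#'
#' @param mirnas Named character vector (or DNAStringSet/RNAStringSet) of
#'   mature miRNA sequences.
#' @param targets Named character vector (or DNAStringSet) of target
#'   sequences.
#' @param cutoff Score threshold, default -0.2; only sites with
#'   `score < cutoff` are retained.
#' @param circular Treat targets as circular (see [findSites()]).
#' @param baseScores,auWeight Passed to [scoreSite()].
#' @return data.frame with `mirna_id`, `target_id`, `best_score`,
#'   `n_sites`.
#' @export
predictInteractions <- function(mirnas, targets, cutoff = -0.2,
                                circular = FALSE,
                                baseScores = c("8mer" = -0.31,
                                               "7mer-m8" = -0.16,
                                               "7mer-A1" = -0.10,
                                               "6mer" = -0.03),
                                auWeight = 0.10) {
  mirnas <- stats::setNames(toupper(as.character(mirnas)), names(mirnas))
  targets <- stats::setNames(.asDnaChar(as.character(targets)),
                             names(targets))
  rows <- list()
  for (mid in names(mirnas)) {
    for (tid in names(targets)) {
      sites <- findSites(mirnas[[mid]], targets[[tid]], circular = circular)
      if (!nrow(sites)) next
      scanSeq <- if (circular)
        paste0(targets[[tid]], substr(targets[[tid]], 1L, 7L))
        else targets[[tid]]
      sc <- vapply(seq_len(nrow(sites)), function(i) {
        scoreSite(sites$site_type[i], sites$position[i], scanSeq,
                  baseScores = baseScores, auWeight = auWeight)
      }, numeric(1))
      keep <- sc < cutoff
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mid, target_id = tid, best_score = min(sc[keep]),
        n_sites = sum(keep), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mirna_id = character(), target_id = character(),
                      best_score = numeric(), n_sites = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
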