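# Independent reference implementations used as oracles. These are written
# as literal, naive enumerations so they share no code path with the
# package functions they check.

# --- back-splice detection: exhaustive double loop over reads ------------
oracleDetectJunctions <- function(segments, minSupport = 2) {
  found <- list()
  for (rid in unique(segments$read_id)) {
    rows <- segments[segments$read_id == rid, ]
    if (nrow(rows) != 2) next
    rows <- rows[order(rows$segment_index), ]
    a <- rows[1, ]; b <- rows[2, ]
    if (a$chrom != b$chrom) next
    if (a$strand != b$strand) next
    if (!(a$start >= b$end)) next          # first-in-read must be downstream
    key <- paste(a$chrom, b$start, a$end, a$strand)
    found[[key]] <- c(found[[key]], rid)
  }
  keys <- names(found)[vapply(found, length, 1L) >= minSupport]
  if (!length(keys)) return(character(0))
  sort(keys)
}

# package junctions -> same key format
juncKeys <- function(gr) {
  if (!length(gr)) return(character(0))
  sort(paste(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
             as.character(GenomicRanges::strand(gr))))
}

# random segment table: mixture of back-splice, forward-splice, single,
# cross-chromosome and opposite-strand reads
randomSegmentTable <- function(nReads, seed) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nReads)) {
    kind <- sample(c("bsj", "fwd", "single", "xchrom", "xstrand"), 1,
                   prob = c(0.4, 0.2, 0.2, 0.1, 0.1))
    chrom <- sample(c("chr1", "chr2"), 1)
    strand <- sample(c("+", "-"), 1)
    # few distinct junction positions so that support accumulates
    js <- sample(c(100L, 300L, 500L), 1)
    je <- js + sample(c(200L, 400L), 1)
    w1 <- sample(20:60, 1); w2 <- sample(20:60, 1)
    rid <- sprintf("r%04d", i)
    if (kind == "single") {
      rows[[i]] <- data.frame(read_id = rid, segment_index = 1L,
        chrom = chrom, start = js, end = js + w1, strand = strand)
      next
    }
    seg1 <- c(je - w1, je); seg2 <- c(js, js + w2)
    if (kind == "fwd") { tmp <- seg1; seg1 <- seg2; seg2 <- tmp }
    ch2 <- if (kind == "xchrom") setdiff(c("chr1", "chr2"), chrom) else chrom
    st2 <- if (kind == "xstrand") setdiff(c("+", "-"), strand) else strand
    rows[[i]] <- data.frame(read_id = rid, segment_index = c(1L, 2L),
      chrom = c(chrom, ch2), start = c(seg1[1], seg2[1]),
      end = c(seg1[2], seg2[2]), strand = c(strand, st2))
  }
  do.call(rbind, rows)
}

# --- seed sites: brute force over every substring ------------------------
oracleFindSites <- function(mirna, target) {
  toDna <- function(x) gsub("U", "T", toupper(x), fixed = TRUE)
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  mir <- toDna(mirna)
  target <- toDna(target)
  seed27 <- substr(mir, 2, 7)
  seed8 <- substr(mir, 8, 8)
  core <- rc(seed27)
  m8 <- rc(seed8)
  L <- nchar(target)
  out <- NULL
  for (p0 in 0:(L - 6)) {
    if (substr(target, p0 + 1, p0 + 6) != core) next
    hasM8 <- p0 >= 1 && substr(target, p0, p0) == m8
    hasA <- p0 + 6 < L && substr(target, p0 + 7, p0 + 7) == "A"
    type <- if (hasM8 && hasA) "8mer" else if (hasM8) "7mer-m8"
      else if (hasA) "7mer-A1" else "6mer"
    out <- rbind(out, data.frame(site_type = type, position = p0,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    data.frame(site_type = character(), position = integer(),
               stringsAsFactors = FALSE)
  else out
}

# --- graph oracles: hand-rolled BFS, no igraph ---------------------------
# graphs are adjacency matrices (0/1, symmetric, zero diagonal)
randomAdjacency <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p) { A[i, j] <- 1L; A[j, i] <- 1L }
  A
}

adjacencyToIgraph <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- sprintf("n%02d", seq_len(nrow(A)))
  g
}

bfsDist <- function(A, s) {
  n <- nrow(A); d <- rep(Inf, n); d[s] <- 0; q <- s
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (w in which(A[v, ] == 1)) if (is.infinite(d[w])) {
      d[w] <- d[v] + 1; q <- c(q, w)
    }
  }
  d
}

# all shortest s->t paths by backward DFS over a BFS distance field
allShortestPaths <- function(A, s, t) {
  d <- bfsDist(A, s)
  if (is.infinite(d[t])) return(list())
  paths <- list()
  walk <- function(v, acc) {
    if (v == s) { paths[[length(paths) + 1]] <<- rev(c(acc, s)); return() }
    for (u in which(A[v, ] == 1)) if (d[u] == d[v] - 1) walk(u, c(acc, v))
  }
  walk(t, integer(0))
  paths
}

oracleCentralities <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  d <- do.call(rbind, lapply(seq_len(n), function(s) bfsDist(A, s)))
  clo <- vapply(seq_len(n), function(v) {
    dv <- d[v, -v]; sum(1 / dv[is.finite(dv)])
  }, 0)
  ecc <- vapply(seq_len(n), function(v) {
    dv <- d[v, ]; dv <- dv[is.finite(dv)]
    m <- max(dv)
    if (m == 0) 1 else 1 / m
  }, 0)
  btw <- numeric(n); str <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- allShortestPaths(A, s, t)
    if (!length(ps)) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(ps, function(pp) v %in% pp, TRUE))
      btw[v] <- btw[v] + through / length(ps)
      str[v] <- str[v] + through
    }
  }
  # radiality within components
  rad <- numeric(n)
  comp <- rep(NA_integer_, n); cc <- 0
  for (v in seq_len(n)) if (is.na(comp[v])) {
    cc <- cc + 1
    comp[is.finite(d[v, ])] <- cc
  }
  for (k in unique(comp)) {
    vs <- which(comp == k)
    if (length(vs) == 1) { rad[vs] <- 0; next }
    diam <- max(d[vs, vs])
    for (v in vs) rad[v] <- sum(diam + 1 - d[v, setdiff(vs, v)]) /
      (length(vs) - 1)
  }
  list(Degree = deg, Closeness = clo, Eccentricity = ecc,
       Betweenness = btw, Stress = str, Radiality = rad)
}

# MCC by exhaustive subset enumeration (maximal cliques)
oracleMcc <- function(A) {
  n <- nrow(A)
  isClique <- function(S) {
    if (length(S) < 2) return(TRUE)
    all(A[S, S][upper.tri(matrix(0, length(S), length(S)))] == 1)
  }
  out <- numeric(n)
  for (mask in seq_len(2^n) - 1L) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!length(S) || !isClique(S)) next
    maximal <- TRUE
    for (v in setdiff(seq_len(n), S))
      if (all(A[v, S] == 1)) { maximal <- FALSE; break }
    if (!maximal) next
    out[S] <- out[S] + factorial(length(S) - 1)
  }
  out
}

# --- ribo: brute-force Hamming scan of reads against extended entries ----
oracleMapReads <- function(reads, circles, flank, maxMismatch, minAnchor) {
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  hits <- list()
  for (rid in names(reads)) {
    rd <- reads[[rid]]; len <- nchar(rd)
    best <- NULL
    for (cid in names(circles)) {
      s <- circles[[cid]]; L <- nchar(s)
      if (len > L) next
      dbl <- paste0(s, s)
      for (a in minAnchor:(len - minAnchor)) {
        ref <- substr(dbl, L - a + 1, L - a + len)
        mm <- ham(rd, ref)
        if (mm <= maxMismatch &&
            (is.null(best) || mm < best$mm ||
             (mm == best$mm && a > best$a)))
          best <- list(id = cid, mm = mm, a = a)
      }
    }
    if (!is.null(best)) hits[[rid]] <- best$id
  }
  hits
}

# --- ORFs: brute 3-frame translated scan of the concatenation ------------
oracleRollingOrfs <- function(circle, nRepeats = 4, minAa = 20) {
  codonTable <- Biostrings::GENETIC_CODE
  concat <- strrep(circle, nRepeats)
  total <- nchar(concat)
  L <- nchar(circle)
  out <- NULL
  for (st in 0:(L - 1)) {
    if (substr(concat, st + 1, st + 3) != "ATG") next
    pep <- ""
    pos <- st
    stopped <- FALSE
    while (pos + 3 <= total) {
      cod <- substr(concat, pos + 1, pos + 3)
      aa <- codonTable[[cod]]
      if (aa == "*") { stopped <- TRUE; break }
      pep <- paste0(pep, aa)
      pos <- pos + 3
    }
    if (!stopped && L %% 3 == 0) pep <- substr(pep, 1, L / 3)
    if (nchar(pep) < minAa) next
    out <- rbind(out, data.frame(start = st, peptide = pep,
                                 stopped = stopped,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    data.frame(start = integer(), peptide = character(),
               stopped = logical(), stringsAsFactors = FALSE)
  else out
}

randomCircle <- function(L, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# small tripartite fixture with explicit directions
randomDeTables <- function(seed, nCirc = 4, nMir = 3, nMrna = 6) {
  set.seed(seed)
  mk <- function(prefix, n) data.frame(
    feature_id = sprintf("%s%02d", prefix, seq_len(n)),
    direction = sample(c("up", "down"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  list(circ = mk("c", nCirc), mir = mk("m", nMir), mrna = mk("g", nMrna))
}
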