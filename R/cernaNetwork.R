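#' Build circRNA-miRNA edges
#'
#' An edge is created for every predicted interaction whose circRNA and
#' miRNA are both differentially expressed. No direction constraint is
#' applied: a circRNA sponge is assumed not to alter the steady-state level
#' of the miRNAs it sequesters, so co-directional pairs are kept.
#'
#' @param deCirc,deMir data.frames with `feature_id` and `direction`
#'   columns (only `up`/`down` rows are used).
#' @param interactions data.frame with `mirna_id`, `target_id` (circ ids).
#' @return data.frame with `circ_id`, `mirna_id`.
#' @export
buildCircMirPairs <- function(deCirc, deMir, interactions) {
  circIds <- deCirc$feature_id[deCirc$direction %in% c("up", "down")]
  mirIds <- deMir$feature_id[deMir$direction %in% c("up", "down")]
  keep <- interactions$target_id %in% circIds &
    interactions$mirna_id %in% mirIds
  out <- data.frame(circ_id = interactions$target_id[keep],
                    mirna_id = interactions$mirna_id[keep],
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Build miRNA-mRNA edges under the inverse-direction rule
#'
#' An edge requires a predicted interaction between a DE miRNA and a DE
#' mRNA whose directions are opposite: repression by a miRNA should leave
#' an inverse footprint on its target's abundance.
#'
#' @param deMir,deMrna data.frames with `feature_id` and `direction`.
#' @param interactions data.frame with `mirna_id`, `target_id` (mRNA ids).
#' @return data.frame with `mirna_id`, `mrna_id`.
#' @export
buildMirMrnaPairs <- function(deMir, deMrna, interactions) {
  dirOf <- function(de) {
    de <- de[de$direction %in% c("up", "down"), ]
    stats::setNames(de$direction, de$feature_id)
  }
  mdir <- dirOf(deMir); gdir <- dirOf(deMrna)
  keep <- interactions$mirna_id %in% names(mdir) &
    interactions$target_id %in% names(gdir)
  sub <- interactions[keep, , drop = FALSE]
  opp <- mdir[sub$mirna_id] != gdir[sub$target_id]
  out <- data.frame(mirna_id = sub$mirna_id[opp],
                    mrna_id = sub$target_id[opp],
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Merge edge lists into the tripartite ceRNA network
#'
#' Union of the circRNA-miRNA and miRNA-mRNA edge lists. miRNAs with edges
#' on only one side are retained with their one-sided edges (set
#' `linkersOnly = TRUE` to keep only miRNAs linking both sides); nodes with
#' no edges are dropped.
#'
#' @param circMir data.frame from [buildCircMirPairs()].
#' @param mirMrna data.frame from [buildMirMrnaPairs()].
#' @param directions Named character vector (`up`/`down`) covering every
#'   node id appearing in the edge lists.
#' @param linkersOnly Drop miRNAs present on only one side.
#' @return A [TripartiteNetwork-class].
#' @export
mergeNetwork <- function(circMir, mirMrna, directions,
                         linkersOnly = FALSE) {
  if (linkersOnly) {
    common <- intersect(circMir$mirna_id, mirMrna$mirna_id)
    circMir <- circMir[circMir$mirna_id %in% common, , drop = FALSE]
    mirMrna <- mirMrna[mirMrna$mirna_id %in% common, , drop = FALSE]
  }
  circs <- unique(circMir$circ_id)
  mirs <- unique(c(circMir$mirna_id, mirMrna$mirna_id))
  mrnas <- unique(mirMrna$mrna_id)
  nodes <- c(sort(circs), sort(mirs), sort(mrnas))
  kind <- c(rep("circ", length(circs)), rep("mir", length(mirs)),
            rep("mrna", length(mrnas)))
  miss <- setdiff(nodes, names(directions))
  if (length(miss))
    stop("missing direction for node(s): ",
         paste(utils::head(miss, 3), collapse = ", "))
  el <- rbind(
    if (nrow(circMir)) cbind(circMir$circ_id, circMir$mirna_id),
    if (nrow(mirMrna)) cbind(mirMrna$mirna_id, mirMrna$mrna_id))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes, kind = kind,
                            direction = unname(directions[nodes]))
  if (!is.null(el) && nrow(el))
    g <- igraph::add_edges(g, t(el))
  g <- igraph::simplify(g)
  methods::new("TripartiteNetwork", graph = g)
}

#' The eleven topological centrality methods
#'
#' @return Character vector of method names accepted by [centrality()].
#' @export
centralityMethods <- function() {
  c("Degree", "MNC", "DMNC", "MCC", "Closeness", "Betweenness", "Stress",
    "Radiality", "Eccentricity", "BottleNeck", "EPC")
}

# BFS from s over adjacency list: distances and shortest-path counts
.bfsCounts <- function(adj, s, n) {
  dist <- rep(Inf, n); sigma <- numeric(n)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

.stressScores <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  bfs <- lapply(seq_len(n), function(s) .bfsCounts(adj, s, n))
  d <- do.call(rbind, lapply(bfs, `[[`, "dist"))
  sig <- do.call(rbind, lapply(bfs, `[[`, "sigma"))
  stress <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      if (s == v) next
      for (t in (s + 1):n) {
        if (t == v || t == s) next
        if (is.finite(d[s, t]) && d[s, v] + d[v, t] == d[s, t])
          stress[v] <- stress[v] + sig[s, v] * sig[v, t]
      }
    }
  }
  stress
}

.radialityScores <- function(g) {
  n <- igraph::vcount(g)
  d <- igraph::distances(g)
  comp <- igraph::components(g)$membership
  out <- numeric(n)
  for (cc in unique(comp)) {
    vs <- which(comp == cc)
    if (length(vs) == 1) { out[vs] <- 0; next }
    dc <- d[vs, vs, drop = FALSE]
    diam <- max(dc)
    nC <- length(vs)
    out[vs] <- vapply(seq_len(nC), function(i)
      sum((diam + 1 - dc[i, -i])) / (nC - 1), numeric(1))
  }
  out
}

.mncSub <- function(g, v) {
  nb <- as.integer(igraph::neighbors(g, v))
  if (!length(nb)) return(NULL)
  sub <- igraph::induced_subgraph(g, nb)
  comp <- igraph::components(sub)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie on size: take the component with the most edges, then first
    ne <- vapply(best, function(b) {
      igraph::ecount(igraph::induced_subgraph(sub,
        which(comp$membership == b)))
    }, numeric(1))
    best <- best[order(-ne)][1]
  }
  igraph::induced_subgraph(sub, which(comp$membership == best))
}

.mncScores <- function(g) {
  vapply(seq_len(igraph::vcount(g)), function(v) {
    sub <- .mncSub(g, v)
    if (is.null(sub)) 0 else igraph::vcount(sub)
  }, numeric(1))
}

.dmncScores <- function(g, eps = 1.7) {
  vapply(seq_len(igraph::vcount(g)), function(v) {
    sub <- .mncSub(g, v)
    if (is.null(sub) || igraph::vcount(sub) < 2) return(0)
    igraph::ecount(sub) / igraph::vcount(sub)^eps
  }, numeric(1))
}

.mccScores <- function(g) {
  n <- igraph::vcount(g)
  out <- numeric(n)
  cliques <- igraph::max_cliques(g)
  for (cl in cliques) {
    contrib <- factorial(length(cl) - 1)
    out[as.integer(cl)] <- out[as.integer(cl)] + contrib
  }
  out
}

# deterministic BFS shortest-path tree rooted at s: parent = neighbor at
# distance d-1 with smallest vertex index
.bottleneckScores <- function(g, threshold = 4) {
  n <- igraph::vcount(g)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  d <- igraph::distances(g)
  score <- numeric(n)
  for (s in seq_len(n)) {
    inTree <- which(is.finite(d[s, ]))
    nTree <- length(inTree)
    if (nTree == 1) next
    parent <- rep(NA_integer_, n)
    for (v in inTree) {
      if (v == s) next
      cand <- adj[[v]][d[s, adj[[v]]] == d[s, v] - 1]
      parent[v] <- min(cand)
    }
    # subtree sizes: count descendants (node itself included)
    sizes <- rep(1L, n); sizes[setdiff(seq_len(n), inTree)] <- 0L
    ord <- inTree[order(-d[s, inTree])]
    for (v in ord) {
      if (v == s || is.na(parent[v])) next
      sizes[parent[v]] <- sizes[parent[v]] + sizes[v]
    }
    score <- score + as.numeric(sizes > nTree / threshold)
  }
  score
}

.epcScores <- function(g, replicates = 1000L, retention = 0.5) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  acc <- numeric(n)
  for (r in seq_len(replicates)) {
    keep <- which(stats::runif(m) < retention)
    sub <- igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
    comp <- igraph::components(sub)
    acc <- acc + comp$csize[comp$membership]
  }
  acc / replicates
}

#' Rank network nodes by a topological centrality method
#'
#' Implements the eleven local and global centrality measures used for hub
#' discovery on undirected simple graphs. Distance-based scores are
#' computed within connected components; Closeness is harmonic
#' (`sum of 1/d`), so disconnected pairs contribute zero rather than
#' infinity. Ranks are 1 = best, ties broken by node id.
#'
#' @param network A [TripartiteNetwork-class] or igraph object.
#' @param method One of [centralityMethods()].
#' @param epcReplicates,epcRetention Edge-percolation parameters for EPC
#'   (mean size of the percolated component containing each node over
#'   seeded random edge-retention replicates).
#' @param bottleneckThreshold A node scores a point for a shortest-path
#'   tree when its subtree holds more than `1/bottleneckThreshold` of the
#'   tree's nodes.
#' @param dmncEps Exponent of the DMNC denominator `|V|^eps`.
#' @param seed Seed for the EPC percolation replicates.
#' @return list with `method`, `scores` (named), `ranks` (named, 1 = best).
#' @export
centrality <- function(network, method,
                       epcReplicates = 1000L, epcRetention = 0.5,
                       bottleneckThreshold = 4, dmncEps = 1.7,
                       seed = 1L) {
  g <- if (methods::is(network, "TripartiteNetwork")) asIgraph(network)
    else network
  if (!igraph::is_igraph(g)) stop("network must be TripartiteNetwork/igraph")
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  methodsOk <- centralityMethods()
  if (!method %in% methodsOk)
    stop("unknown centrality method: ", method)
  nm <- igraph::V(g)$name
  scores <- switch(method,
    Degree = igraph::degree(g),
    Closeness = igraph::harmonic_centrality(g, normalized = FALSE),
    Betweenness = igraph::betweenness(g, directed = FALSE),
    Stress = .stressScores(g),
    Radiality = .radialityScores(g),
    Eccentricity = {
      ecc <- igraph::eccentricity(g)
      ifelse(ecc == 0, 1, 1 / ecc)
    },
    MNC = .mncScores(g),
    DMNC = .dmncScores(g, eps = dmncEps),
    MCC = .mccScores(g),
    BottleNeck = .bottleneckScores(g, threshold = bottleneckThreshold),
    EPC = .withSeed(seed,
      .epcScores(g, replicates = epcReplicates, retention = epcRetention))
  )
  scores <- stats::setNames(as.numeric(scores), nm)
  list(method = method, scores = scores, ranks = .rankByScore(scores))
}

#' Consensus hub selection across all centrality methods
#'
#' For each node of the restricted kind, counts the methods in whose top-k
#' it appears, then selects the `nHubs` nodes with the highest counts.
#' Ties are broken by mean rank across methods, then lexicographic id.
#'
#' @param rankings List of results from [centrality()], one per method.
#' @param network The [TripartiteNetwork-class] the rankings were computed
#'   on (provides node kinds).
#' @param kTop Top-k membership threshold per method, default 20.
#' @param nHubs Number of hubs to select, default 15.
#' @param restrictKind Node kind eligible for selection, default `"circ"`.
#' @return data.frame with `node`, `n_top`, `mean_rank`, ordered by the
#'   selection criterion; at most `nHubs` rows (fewer, with a warning, when
#'   not enough eligible nodes exist).
#' @export
selectHubs <- function(rankings, network, kTop = 20L, nHubs = 15L,
                       restrictKind = "circ") {
  kind <- nodeKind(network)
  eligible <- names(kind)[kind == restrictKind]
  if (!length(eligible)) {
    warning("no eligible nodes of kind ", restrictKind)
    return(data.frame(node = character(), n_top = integer(),
                      mean_rank = numeric(), stringsAsFactors = FALSE))
  }
  nTop <- stats::setNames(integer(length(eligible)), eligible)
  rankSum <- stats::setNames(numeric(length(eligible)), eligible)
  for (rk in rankings) {
    top <- names(rk$ranks)[rk$ranks <= kTop]
    hit <- names(nTop) %in% top
    nTop[hit] <- nTop[hit] + 1L
    rankSum <- rankSum + rk$ranks[eligible]
  }
  meanRank <- rankSum / length(rankings)
  ord <- order(-nTop, meanRank, eligible)
  out <- data.frame(node = eligible[ord], n_top = unname(nTop[ord]),
                    mean_rank = unname(meanRank[ord]),
                    stringsAsFactors = FALSE)
  if (nrow(out) < nHubs)
    warning("only ", nrow(out), " eligible nodes for ", nHubs, " hubs")
  utils::head(out, nHubs)
}

#' Hub-induced subnetwork
#'
#' The subgraph induced by the hub circRNAs, every miRNA adjacent to a
#' hub, and every mRNA adjacent to one of those miRNAs.
#'
#' @param network A [TripartiteNetwork-class].
#' @param hubs Character vector of hub circRNA ids.
#' @return A [TripartiteNetwork-class].
#' @export
hubSubnetwork <- function(network, hubs) {
  g <- asIgraph(network)
  kind <- nodeKind(network)
  badKind <- hubs[kind[hubs] != "circ"]
  if (anyNA(kind[hubs]) || length(badKind))
    stop("hubs must be circRNA nodes of the network")
  if (!length(hubs)) {
    sub <- igraph::induced_subgraph(g, integer(0))
    return(methods::new("TripartiteNetwork", graph = sub))
  }
  neighborsOf <- function(ids) {
    unique(unlist(lapply(igraph::adjacent_vertices(g, ids),
                         igraph::as_ids)))
  }
  mirs <- neighborsOf(hubs)
  mirs <- mirs[kind[mirs] == "mir"]
  mrnas <- character(0)
  if (length(mirs)) {
    mrnas <- neighborsOf(mirs)
    mrnas <- mrnas[kind[mrnas] == "mrna"]
  }
  keep <- c(hubs, mirs, mrnas)
  sub <- igraph::induced_subgraph(g, keep)
  methods::new("TripartiteNetwork", graph = sub)
}

#' Write a tripartite network (with optional per-method scores) to GraphML
#'
#' @param network A [TripartiteNetwork-class].
#' @param path Output path.
#' @param rankings Optional list of [centrality()] results; each method
#'   adds `score_<method>` and `rank_<method>` vertex attributes.
#' @return Invisibly, the path.
#' @export
writeGraphml <- function(network, path, rankings = NULL) {
  g <- asIgraph(network)
  if (!is.null(rankings)) {
    for (rk in rankings) {
      igraph::vertex_attr(g, paste0("score_", rk$method)) <-
        unname(rk$scores[igraph::V(g)$name])
      igraph::vertex_attr(g, paste0("rank_", rk$method)) <-
        unname(rk$ranks[igraph::V(g)$name])
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
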