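.de <- function(ids, dirs) data.frame(feature_id = ids, direction = dirs,
                                      stringsAsFactors = FALSE)
.int <- function(mir, tgt) data.frame(mirna_id = mir, target_id = tgt,
                                      stringsAsFactors = FALSE)

test_that("circRNA-miRNA pairing ignores direction but requires DE and a site", {
  deC <- .de(c("c1", "c2"), c("up", "up"))
  deM <- .de(c("m1", "m2"), c("up", "down"))
  ints <- .int(c("m1", "m1", "m2"), c("c1", "c3", "c2"))
  got <- buildCircMirPairs(deC, deM, ints)
  # same-direction pair kept; non-DE c3 dropped
  expect_setequal(paste(got$circ_id, got$mirna_id), c("c1 m1", "c2 m2"))
  # no predicted site -> no edge
  expect_equal(nrow(buildCircMirPairs(deC, deM, .int(character(), character()))), 0)
})

test_that("miRNA-mRNA pairing enforces the inverse-direction rule", {
  deM <- .de(c("m1", "m2"), c("up", "down"))
  deG <- .de(c("g1", "g2", "g3"), c("down", "up", "up"))
  ints <- .int(c("m1", "m1", "m2", "m2"), c("g1", "g2", "g2", "g3"))
  got <- buildMirMrnaPairs(deM, deG, ints)
  expect_setequal(paste(got$mirna_id, got$mrna_id),
                  c("m1 g1", "m2 g2", "m2 g3"))
})

test_that("merged networks keep one-sided miRNAs and drop isolated nodes", {
  dirs <- c(c1 = "up", m1 = "down", m2 = "up", g1 = "up")
  net <- mergeNetwork(data.frame(circ_id = c("c1", "c1"),
                                 mirna_id = c("m1", "m2")),
                      data.frame(mirna_id = "m1", mrna_id = "g1"),
                      dirs)
  g <- asIgraph(net)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)
  expect_equal(unname(igraph::degree(g)["m2"]), 1)  # one-sided, retained
  only <- mergeNetwork(data.frame(circ_id = c("c1", "c1"),
                                  mirna_id = c("m1", "m2")),
                       data.frame(mirna_id = "m1", mrna_id = "g1"),
                       dirs, linkersOnly = TRUE)
  expect_false("m2" %in% names(nodeKind(only)))
  empty <- mergeNetwork(data.frame(circ_id = character(),
                                   mirna_id = character()),
                        data.frame(mirna_id = character(),
                                   mrna_id = character()), dirs)
  expect_equal(igraph::vcount(asIgraph(empty)), 0)
})

test_that("the class validity enforces tripartite structure and direction rules", {
  g <- igraph::make_graph(~ a - b)
  igraph::V(g)$kind <- c("mir", "mrna")
  igraph::V(g)$direction <- c("up", "up")
  expect_error(methods::new("TripartiteNetwork", graph = g),
               "opposite-direction")
  igraph::V(g)$direction <- c("up", "down")
  expect_s4_class(methods::new("TripartiteNetwork", graph = g),
                  "TripartiteNetwork")
  g2 <- igraph::make_graph(~ a - b)
  igraph::V(g2)$kind <- c("circ", "mrna")
  igraph::V(g2)$direction <- c("up", "down")
  expect_error(methods::new("TripartiteNetwork", graph = g2),
               "circ-mir or mir-mrna")
})

test_that("centrality scores reproduce hand-enumerated examples", {
  star <- adjacencyToIgraph(rbind(
    c(0, 1, 1, 1, 1), c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0),
    c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0)))
  expect_equal(unname(centrality(star, "Degree")$scores[1]), 4)
  expect_equal(unname(centrality(star, "Betweenness")$scores[1]), 6)
  path4 <- adjacencyToIgraph(rbind(
    c(0, 1, 0, 0), c(1, 0, 1, 0), c(0, 1, 0, 1), c(0, 0, 1, 0)))
  expect_equal(unname(centrality(path4, "Betweenness")$scores[2]), 2)
  expect_equal(unname(centrality(path4, "Stress")$scores[2]), 2)
  tri <- adjacencyToIgraph(rbind(
    c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)))
  expect_equal(unname(centrality(tri, "MCC")$scores), rep(2, 3))
  # a triangle with a pendant: MNC of the pendant's neighbor
  g4 <- adjacencyToIgraph(rbind(
    c(0, 1, 1, 1), c(1, 0, 1, 0), c(1, 1, 0, 0), c(1, 0, 0, 0)))
  mnc <- centrality(g4, "MNC")$scores
  expect_equal(unname(mnc[1]), 2)  # neighbors {2,3,4}: largest comp {2,3}
  dmnc <- centrality(g4, "DMNC")$scores
  expect_equal(unname(dmnc[1]), 1 / 2^1.7)
  one <- adjacencyToIgraph(matrix(0, 1, 1))
  for (m in centralityMethods()) {
    r <- centrality(one, m, epcReplicates = 10)
    expect_true(is.finite(r$scores[1]))
    expect_equal(unname(r$ranks[1]), 1)
  }
})

test_that("distance centralities match the hand-rolled BFS oracle", {
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    A <- randomAdjacency(n, p = 0.4, seed = 900 + rep)
    g <- adjacencyToIgraph(A)
    want <- oracleCentralities(A)
    for (m in names(want)) {
      got <- unname(centrality(g, m)$scores)
      expect_equal(got, unname(want[[m]]), tolerance = 1e-9,
                   label = paste(m, "rep", rep))
    }
    mccGot <- unname(centrality(g, "MCC")$scores)
    expect_equal(mccGot, oracleMcc(A), label = paste("MCC rep", rep))
  }
})

test_that("the BottleNeck score favors articulation hubs deterministically", {
  # two 3-stars joined by a bridge: the bridge endpoints dominate
  A <- matrix(0L, 8, 8)
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(5, 6), c(5, 7), c(5, 8),
                 c(1, 5))
  for (k in seq_len(nrow(edges))) {
    A[edges[k, 1], edges[k, 2]] <- 1L; A[edges[k, 2], edges[k, 1]] <- 1L
  }
  g <- adjacencyToIgraph(A)
  bn <- centrality(g, "BottleNeck")$scores
  expect_true(all(bn[c(1, 5)] > max(bn[c(2, 3, 4, 6, 7, 8)])))
  expect_identical(centrality(g, "BottleNeck")$scores, bn)  # deterministic
})

test_that("EPC percolation estimates converge across replicate draws", {
  A <- randomAdjacency(10, p = 0.35, seed = 1234)
  g <- adjacencyToIgraph(A)
  e1 <- centrality(g, "EPC", epcReplicates = 3000, seed = 1)$scores
  e2 <- centrality(g, "EPC", epcReplicates = 3000, seed = 2)$scores
  expect_lt(max(abs(e1 - e2) / pmax(e1, 1e-9)), 0.02)
})

test_that("hub selection counts top-k membership with the stated tie-breaks", {
  dirs <- c(h1 = "up", c2 = "up", c3 = "down",
            m1 = "down", m2 = "up", m3 = "down", m4 = "up",
            g1 = "up", g2 = "down")
  cm <- data.frame(
    circ_id = c("h1", "h1", "h1", "h1", "c2", "c3"),
    mirna_id = c("m1", "m2", "m3", "m4", "m1", "m2"))
  mm <- data.frame(mirna_id = c("m1", "m3"), mrna_id = c("g1", "g1"))
  net <- mergeNetwork(cm, mm, dirs)
  rankings <- lapply(setdiff(centralityMethods(), "EPC"), function(m)
    centrality(net, m))
  rankings <- c(rankings, list(centrality(net, "EPC",
                                          epcReplicates = 200, seed = 4)))
  hubs <- selectHubs(rankings, net, kTop = 3, nHubs = 2)
  expect_equal(hubs$node[1], "h1")  # dominant degree-4 node wins every method
  expect_warning(selectHubs(rankings, net, kTop = 3, nHubs = 5), "eligible")
  expect_false(any(startsWith(hubs$node, "m")))
})

test_that("hub subnetworks follow the two-hop induced construction", {
  dirs <- c(h = "up", m1 = "up", m2 = "down",
            g1 = "down", g2 = "down", g3 = "up", g4 = "up", g5 = "up",
            g6 = "down")
  cm <- data.frame(circ_id = c("h", "h"), mirna_id = c("m1", "m2"))
  mm <- data.frame(mirna_id = rep(c("m1", "m2"), each = 3),
                   mrna_id = c("g1", "g2", "g6", "g3", "g4", "g5"))
  net <- mergeNetwork(cm, mm, dirs)
  sub <- hubSubnetwork(net, "h")
  g <- asIgraph(sub)
  expect_equal(igraph::vcount(g), 1 + 2 + 6)
  expect_equal(igraph::ecount(g), 2 + 6)
  none <- hubSubnetwork(net, character(0))
  expect_equal(igraph::vcount(asIgraph(none)), 0)
  expect_error(hubSubnetwork(net, "m1"), "circRNA")
})

test_that("merge and split round-trip preserves both edge lists", {
  for (rep in 1:10) {
    de <- randomDeTables(seed = 700 + rep)
    set.seed(800 + rep)
    cm <- unique(data.frame(
      circ_id = sample(de$circ$feature_id, 6, replace = TRUE),
      mirna_id = sample(de$mir$feature_id, 6, replace = TRUE)))
    mm <- unique(data.frame(
      mirna_id = sample(de$mir$feature_id, 6, replace = TRUE),
      mrna_id = sample(de$mrna$feature_id, 6, replace = TRUE)))
    dirs <- c(stats::setNames(de$circ$direction, de$circ$feature_id),
              stats::setNames(de$mir$direction, de$mir$feature_id),
              stats::setNames(de$mrna$direction, de$mrna$feature_id))
    # mir-mrna edges must respect the inverse rule to build a valid network
    mm <- mm[dirs[mm$mirna_id] != dirs[mm$mrna_id], , drop = FALSE]
    net <- mergeNetwork(cm, mm, dirs)
    et <- edgeTable(net)
    kind <- nodeKind(net)
    gotCm <- et[kind[et$from] == "circ" | kind[et$to] == "circ", ]
    gotMm <- et[kind[et$from] == "mrna" | kind[et$to] == "mrna", ]
    normalize <- function(a, b) sort(paste(pmin(a, b), pmax(a, b)))
    expect_identical(normalize(gotCm$from, gotCm$to),
                     normalize(cm$circ_id, cm$mirna_id))
    expect_identical(normalize(gotMm$from, gotMm$to),
                     normalize(mm$mirna_id, mm$mrna_id))
  }
})
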