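test_that("identical rows give a complete graph with unit weights", {
  X <- matrix(1, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  g <- build_graph(X, max_edges = 2)
  expect_equal(igraph::ecount(g), 3)
  expect_true(all(igraph::E(g)$weight == 1))
})

test_that("per-node degree cap bounds the edge count", {
  set.seed(9)
  X <- matrix(rnorm(30), 3, 10, dimnames = list(paste0("c", 1:3), NULL))
  g <- build_graph(X, max_edges = 1)
  expect_lte(igraph::ecount(g), 3)
  X10 <- matrix(rnorm(100), 10, 10, dimnames = list(paste0("c", 1:10), NULL))
  g10 <- build_graph(X10, max_edges = 3)
  # union of directed 3-NN selections: each vertex has >= 3 neighbours
  expect_true(all(igraph::degree(g10) >= 3))
  expect_lte(igraph::ecount(g10), 30)
})

test_that("retained neighbours equal a brute-force all-pairs sort", {
  set.seed(17)
  X <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(paste0("c", 1:10), NULL))
  k <- 4
  g <- build_graph(X, max_edges = k)
  D <- as.matrix(dist(X))
  want <- list()
  for (i in 1:10) {
    nn <- order(D[i, -i])[1:k]
    nbr <- paste0("c", (1:10)[-i][nn])
    for (j in nbr) {
      want[[length(want) + 1L]] <- sort(c(paste0("c", i), j))
    }
  }
  want <- unique(want)
  got <- apply(igraph::as_edgelist(g), 1, function(e) sort(e), simplify = FALSE)
  expect_setequal(lapply(got, paste, collapse = "|"),
                  lapply(want, paste, collapse = "|"))
  # weights are 1 - d/d_max in (0, 1]
  w <- igraph::E(g)$weight
  expect_true(all(w > 0 & w <= 1))
})

test_that("disconnected cliques form separate communities", {
  edges <- rbind(t(combn(1:5, 2)), t(combn(6:10, 2)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$name <- paste0("c", 1:10)
  igraph::E(g)$weight <- 1
  memb <- infomap_communities(g, seed = 1)
  expect_length(unique(memb), 2L)
  expect_length(unique(memb[paste0("c", 1:5)]), 1L)
  expect_length(unique(memb[paste0("c", 6:10)]), 1L)
  # a single node is a singleton community
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g1)$name <- "solo"
  expect_equal(unname(infomap_communities(g1, 1)), 1L)
})

test_that("two dense clusters joined by a weak edge match the max-modularity split", {
  # brute-force best-modularity bipartition over all partitions of 6 nodes
  w <- matrix(0, 6, 6)
  for (p in combn(1:3, 2, simplify = FALSE)) w[p[1], p[2]] <- 1
  for (p in combn(4:6, 2, simplify = FALSE)) w[p[1], p[2]] <- 1
  w[3, 4] <- 0.05
  w <- w + t(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$name <- paste0("c", 1:6)
  # enumerate all set partitions of 6 elements, score Newman modularity
  parts <- function(v) {
    if (length(v) == 0) return(list(list()))
    out <- list()
    for (p in parts(v[-1])) {
      for (i in seq_along(p)) {
        q <- p; q[[i]] <- c(q[[i]], v[1]); out[[length(out) + 1]] <- q
      }
      out[[length(out) + 1]] <- c(p, list(v[1]))
    }
    out
  }
  mod <- function(groups) {
    m2 <- sum(w)
    s <- 0
    deg <- rowSums(w)
    for (grp in groups) {
      for (i in grp) for (j in grp) {
        s <- s + w[i, j] - deg[i] * deg[j] / m2
      }
    }
    s / m2
  }
  all_parts <- parts(1:6)
  best <- all_parts[[which.max(vapply(all_parts, mod, numeric(1)))]]
  best_sets <- lapply(best, sort)
  expect_setequal(lapply(best_sets, paste, collapse = ","),
                  list("1,2,3", "4,5,6"))
  memb <- infomap_communities(g, seed = 3)
  expect_length(unique(memb), 2L)
  expect_length(unique(memb[paste0("c", 1:3)]), 1L)
})

test_that("reclustering splits only multi-copy bins and partitions the input", {
  panel <- default_marker_panel()
  set.seed(31)
  # two synthetic genomes, each with a full single-copy panel, merged into
  # one bin with separated embeddings
  ids_a <- paste0("a", 1:10); ids_b <- paste0("b", 1:10)
  hits <- c(
    setNames(split(panel, rep(1:10, length.out = 107)), ids_a),
    setNames(split(panel, rep(1:10, length.out = 107)), ids_b)
  )
  ann <- marker_annotation(hits, panel)
  emb <- rbind(matrix(rnorm(10 * 5, 0, 0.1), 10),
               matrix(rnorm(10 * 5, 5, 0.1), 10))
  rownames(emb) <- c(ids_a, ids_b)
  lens <- setNames(rep(1000, 20), c(ids_a, ids_b))
  subs <- recluster_bin(c(ids_a, ids_b), ann, emb, lens, seed = 1)
  expect_length(subs, 2L)
  expect_setequal(unlist(subs), c(ids_a, ids_b))
  expect_true(setequal(subs[[1]], ids_a) || setequal(subs[[1]], ids_b))
  # single-copy bin is returned unchanged
  one <- recluster_bin(ids_a, ann, emb, lens, seed = 1)
  expect_identical(one, list(ids_a))
  # marker-free bin is returned unchanged
  none <- recluster_bin(c("x", "y"), ann,
                        rbind(x = rnorm(5), y = rnorm(5)),
                        c(x = 10, y = 10), seed = 1)
  expect_identical(none, list(c("x", "y")))
})

test_that("k is clamped when marker multiplicity exceeds the bin size", {
  panel <- default_marker_panel()
  hits <- list(z1 = rep(panel[1], 5), z2 = panel[2])
  ann <- marker_annotation(hits, panel)
  emb <- rbind(z1 = rnorm(4), z2 = rnorm(4))
  expect_warning(
    subs <- recluster_bin(c("z1", "z2"), ann, emb, c(z1 = 5, z2 = 5), seed = 2),
    "clamping"
  )
  expect_setequal(unlist(subs), c("z1", "z2"))
})
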