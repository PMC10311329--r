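# Short-read clustering: sparse similarity graph over [embedding, abundance]
# rows -> Infomap community detection -> marker-guided weighted k-means
# reclustering of bins whose mean single-copy marker multiplicity exceeds 1.

#' Build the sparse contig similarity graph
#'
#' Euclidean distances are computed on the row-wise concatenation of the
#' embedding and the transformed abundance features. Per node only the
#' `max_edges` nearest neighbours are kept; the union of these directed
#' selections forms an undirected graph with edge weight
#' `1 - d / d_max` (`d_max` = largest retained distance globally), clipped
#' into `(0, 1]`.
#'
#' @param embeddings Numeric matrix (rownames = contig ids).
#' @param abundances Transformed abundance matrix aligned to `embeddings`
#'   rows (or NULL to use embeddings only).
#' @param max_edges Per-node neighbour cap (default 200).
#' @return An [igraph::graph] with vertex name attributes and edge weights.
#' @export
build_graph <- function(embeddings, abundances = NULL, max_edges = 200L) {
  X <- as.matrix(embeddings)
  if (!is.null(abundances)) {
    ab <- as.matrix(abundances)
    stopifnot(nrow(ab) == nrow(X))
    X <- cbind(X, ab)
  }
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  n <- nrow(X)
  if (n < 2L) {
    return(igraph::make_empty_graph(n, directed = FALSE) |>
             igraph::set_vertex_attr("name", value = ids))
  }
  D <- as.matrix(dist(X))
  k <- min(max_edges, n - 1L)
  ei <- integer(0); ej <- integer(0); ed <- numeric(0)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i])[seq_len(k)]
    nbr <- seq_len(n)[-i][ord]
    ei <- c(ei, rep.int(i, k)); ej <- c(ej, nbr); ed <- c(ed, D[i, nbr])
  }
  # symmetrize: keep each unordered pair once
  a <- pmin(ei, ej); b <- pmax(ei, ej)
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]; b <- b[keep]; d <- ed[keep]
  d_max <- max(d)
  w <- if (d_max > 0) pmax(1 - d / d_max, .Machine$double.eps) else rep(1, length(d))
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::V(g)$name <- ids
  igraph::E(g)$weight <- w
  g
}

#' Infomap community detection on the contig graph
#'
#' @param graph Graph from [build_graph()].
#' @param seed RNG seed (Infomap is stochastic).
#' @return Named integer vector: contig id -> community id.
#' @export
infomap_communities <- function(graph, seed = 0L) {
  if (igraph::vcount(graph) == 0L) return(setNames(integer(0), character(0)))
  memb <- with_seed(seed, {
    if (igraph::ecount(graph) == 0L) {
      seq_len(igraph::vcount(graph))
    } else {
      as.integer(igraph::membership(
        igraph::cluster_infomap(graph, e.weights = igraph::E(graph)$weight)
      ))
    }
  })
  setNames(memb, igraph::V(graph)$name)
}

# Lloyd iterations of k-means with per-observation weights (contig lengths),
# deterministic given the initial centers. stats::kmeans has no observation
# weights, hence this small dedicated implementation.
weighted_kmeans <- function(X, centers, w, max_iter = 100L) {
  k <- nrow(centers)
  n <- nrow(X)
  assign_pts <- function(centers) {
    d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
    max.col(-d2, ties.method = "first")
  }
  cl <- assign_pts(centers)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      sel <- cl == j
      if (!any(sel)) {
        # reseed an empty cluster at the point farthest from its center
        far <- which.max(rowSums((X - centers[cl, , drop = FALSE])^2))
        centers[j, ] <- X[far, ]
        cl[far] <- j
        next
      }
      centers[j, ] <- colSums(X[sel, , drop = FALSE] * w[sel]) / sum(w[sel])
    }
    new_cl <- assign_pts(centers)
    if (all(new_cl == cl)) break
    cl <- new_cl
  }
  cl
}

#' Recluster a preliminary bin guided by marker multiplicity
#'
#' If the bin's mean single-copy marker copy number (`G / N_distinct`)
#' exceeds 1, the bin likely aggregates several genomes and is split by
#' weighted k-means on the embeddings, with contig lengths as observation
#' weights, `k` = the highest multiplicity of any single marker, and centers
#' initialized at the contigs carrying that marker. Otherwise the bin is
#' returned unchanged.
#'
#' @param bin_contigs Character vector of contig ids.
#' @param annotation A `marker_annotation`.
#' @param embeddings Embedding matrix (rownames = contig ids).
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @param seed RNG seed (used only to top up missing initial centers).
#' @return List of character vectors (the sub-bins; length 1 when no split).
#' @export
recluster_bin <- function(bin_contigs, annotation, embeddings, contig_lengths,
                          seed = 0L) {
  hits <- unlist(annotation$hits[intersect(bin_contigs, names(annotation$hits))],
                 use.names = FALSE)
  if (length(hits) == 0L) return(list(bin_contigs))
  tab <- table(hits)
  if (length(hits) / length(tab) <= 1) return(list(bin_contigs))
  k <- max(tab)
  if (k > length(bin_contigs)) {
    warning("marker multiplicity ", k, " exceeds bin size ",
            length(bin_contigs), "; clamping k")
    k <- length(bin_contigs)
  }
  if (k < 2L) return(list(bin_contigs))
  X <- embeddings[bin_contigs, , drop = FALSE]
  top_marker <- names(tab)[which.max(tab)]
  carriers <- names(Filter(function(h) top_marker %in% h,
                           annotation$hits[intersect(bin_contigs,
                                                     names(annotation$hits))]))
  carriers <- intersect(bin_contigs, carriers)
  init_ids <- head(carriers, k)
  if (length(init_ids) < k) {
    # a marker hit twice on one contig: top up with seeded random contigs
    extra <- with_seed(seed, sample(setdiff(bin_contigs, init_ids),
                                    k - length(init_ids)))
    init_ids <- c(init_ids, extra)
  }
  cl <- weighted_kmeans(X, X[init_ids, , drop = FALSE],
                        w = contig_lengths[bin_contigs])
  unname(split(bin_contigs, cl))
}

#' Short-read clustering of embedded contigs
#'
#' Graph construction, Infomap preliminary bins, then one round of
#' marker-guided reclustering of each preliminary bin.
#'
#' @param embeddings Embedding matrix (rownames = contig ids).
#' @param abundances Transformed abundance matrix for graph building.
#' @param annotation A `marker_annotation` or NULL (skips reclustering).
#' @param contig_lengths Named vector of contig lengths.
#' @param max_edges Per-node neighbour cap.
#' @param seed RNG seed.
#' @return Named character vector contig id -> bin id.
#' @export
cluster_short <- function(embeddings, abundances, annotation, contig_lengths,
                          max_edges = 200L, seed = 0L) {
  g <- build_graph(embeddings, abundances, max_edges)
  memb <- infomap_communities(g, seed)
  bins <- split(names(memb), memb)
  out_bins <- list()
  for (bin in bins) {
    subs <- if (is.null(annotation)) {
      list(bin)
    } else {
      recluster_bin(bin, annotation, embeddings, contig_lengths, seed)
    }
    out_bins <- c(out_bins, subs)
  }
  assignment <- rep(sprintf("bin_%04d", seq_along(out_bins)),
                    lengths(out_bins))
  setNames(assignment, unlist(out_bins, use.names = FALSE))
}
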