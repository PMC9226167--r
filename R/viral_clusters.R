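#' Hypergeometric shared-PC similarity between contig pairs
#'
#' For each pair of contigs that share at least one protein cluster, computes
#' the probability of observing at least the shared number of PCs by chance
#' given the two PC-set sizes and the PC universe size, Bonferroni-scales it
#' by the number of pairs, and takes `-log10`:
#' `sim = -log10(P_hyper(shared >= observed) * n * (n - 1) / 2)`.
#' Pairs with `sim >= threshold` (default 1) become network edges.
#'
#' @param pc_membership A data frame with columns `contig_id`, `pc_id`.
#' @param universe Total number of PCs in the universe; must be at least the
#'   number of distinct PCs observed.
#' @param threshold Minimum similarity for an edge.
#' @return A tibble `contig_a`, `contig_b`, `shared`, `similarity` with one
#'   row per unordered pair passing the threshold.
#' @export
vc_similarity_edges <- function(pc_membership, universe, threshold = 1) {
  vp_assert_fields(pc_membership, c("contig_id", "pc_id"),
                   "`pc_membership`")
  n_pc <- dplyr::n_distinct(pc_membership$pc_id)
  vp_assert(universe >= n_pc,
            "`universe` is smaller than the number of observed PCs")
  sets <- split(unique(pc_membership)$pc_id, unique(pc_membership)$contig_id)
  ids <- names(sets)
  n <- length(ids)
  if (n < 2) {
    return(tibble(contig_a = character(0), contig_b = character(0),
                  shared = integer(0), similarity = numeric(0)))
  }
  n_pairs <- n * (n - 1) / 2
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      if (shared == 0) next
      sim <- hypergeom_similarity(shared, length(sets[[i]]),
                                  length(sets[[j]]), universe, n_pairs)
      if (sim >= threshold) {
        out[[length(out) + 1L]] <- tibble(
          contig_a = ids[i], contig_b = ids[j],
          shared = shared, similarity = sim
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(contig_a = character(0), contig_b = character(0),
                  shared = integer(0), similarity = numeric(0)))
  }
  bind_rows(out)
}

# upper tail P(X >= shared) for X ~ Hypergeom(universe, size_a, size_b)
hypergeom_similarity <- function(shared, size_a, size_b, universe, n_pairs) {
  p_tail <- phyper(shared - 1, size_a, universe - size_a, size_b,
                   lower.tail = FALSE)
  val <- p_tail * n_pairs
  if (val <= 0) return(Inf)
  -log10(val)
}

#' Markov clustering (MCL) of a weighted undirected graph
#'
#' Deterministic MCL on a column-stochastic transition matrix with self
#' loops: alternate expansion (matrix squaring) and inflation (elementwise
#' power followed by column renormalisation), pruning negligible entries,
#' until the matrix changes by less than `eps` or `max_iter` iterations.
#' Clusters are the connected components of the converged matrix's support.
#'
#' @param adjacency Symmetric non-negative weight matrix with dimnames.
#' @param inflation Inflation exponent (default 1.5).
#' @param eps Convergence tolerance on the max absolute change.
#' @param max_iter Maximum number of iterations.
#' @return Integer cluster membership vector named by node.
#' @export
markov_cluster <- function(adjacency, inflation = 1.5, eps = 1e-6,
                           max_iter = 200) {
  vp_assert(is.matrix(adjacency) && nrow(adjacency) == ncol(adjacency),
            "`adjacency` must be a square matrix")
  vp_assert(!is.null(rownames(adjacency)), "`adjacency` needs dimnames")
  n <- nrow(adjacency)
  m <- adjacency
  # self loops at each node's maximum incident weight keep two-node
  # cliques together under expansion/inflation
  diag(m) <- pmax(diag(m), apply(adjacency, 1, max), 1)
  m <- sweep(m, 2, colSums(m), "/")
  for (iter in seq_len(max_iter)) {
    m2 <- m %*% m                       # expansion
    m2 <- m2^inflation                  # inflation
    m2[m2 < 1e-12] <- 0                 # prune
    cs <- colSums(m2)
    cs[cs == 0] <- 1
    m2 <- sweep(m2, 2, cs, "/")
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < eps) break
  }
  support <- (m > 1e-5) | (t(m) > 1e-5)
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

#' Group phage contigs into viral clusters by shared protein-cluster content
#'
#' Builds the hypergeometric shared-PC similarity network
#' ([vc_similarity_edges()]) over all contigs in `contig_ids`, then applies
#' Markov clustering ([markov_cluster()]) to the edge weights. Contigs with
#' no significant edges become singleton VCs, so the output is a partition of
#' the input contigs. VC ids are deterministic, numbered along the sorted
#' lexicographically-smallest member of each cluster.
#'
#' @param pc_membership A data frame `contig_id`, `pc_id` (a contig may have
#'   zero rows here and still be clustered, as a singleton).
#' @param universe Total number of PCs in the universe.
#' @param contig_ids All phage contig ids to partition; defaults to those in
#'   `pc_membership`.
#' @param threshold Minimum similarity for an edge (default 1).
#' @param inflation,eps,max_iter Markov clustering controls.
#' @return A tibble `contig_id`, `vc_id`, `singleton`.
#' @export
build_viral_clusters <- function(pc_membership, universe,
                                 contig_ids = NULL, threshold = 1,
                                 inflation = 1.5, eps = 1e-6,
                                 max_iter = 200) {
  contig_ids <- sort(unique(contig_ids %||% pc_membership$contig_id))
  edges <- vc_similarity_edges(pc_membership, universe,
                               threshold = threshold)
  membership <- setNames(rep(NA_integer_, length(contig_ids)), contig_ids)
  if (nrow(edges) > 0) {
    nodes <- sort(unique(c(edges$contig_a, edges$contig_b)))
    adj <- matrix(0, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    for (r in seq_len(nrow(edges))) {
      adj[edges$contig_a[r], edges$contig_b[r]] <- edges$similarity[r]
      adj[edges$contig_b[r], edges$contig_a[r]] <- edges$similarity[r]
    }
    cl <- markov_cluster(adj, inflation = inflation, eps = eps,
                         max_iter = max_iter)
    membership[names(cl)] <- cl
  }
  # singletons (no edges) get fresh cluster numbers
  n_clusters <- if (all(is.na(membership))) 0L else
    max(membership, na.rm = TRUE)
  lone <- is.na(membership)
  membership[lone] <- n_clusters + seq_len(sum(lone))

  smallest <- tapply(names(membership), membership, min)
  vc_index <- match(smallest[as.character(membership)], sort(smallest))
  res <- tibble(
    contig_id = names(membership),
    vc_id = sprintf("VC_%04d", vc_index)
  )
  res |>
    group_by(vc_id) |>
    mutate(singleton = dplyr::n() == 1) |>
    ungroup() |>
    arrange(contig_id)
}

#' Percent of total protein clusters shared between two contigs
#'
#' `100 * |PCs(a) intersect PCs(b)| / |PCs(a) union PCs(b)|`. Symmetric;
#' the self-fraction is 100. When divergence splits a core gene into several
#' PCs, related genomes can share a small fraction of PCs even though they
#' share all core genes.
#'
#' @param a,b Contig ids.
#' @param pc_membership A data frame `contig_id`, `pc_id`.
#' @return Shared-PC percentage.
#' @export
shared_pc_fraction <- function(a, b, pc_membership) {
  sets <- split(pc_membership$pc_id, pc_membership$contig_id)
  for (id in c(a, b)) {
    vp_assert(id %in% names(sets) && length(sets[[id]]) > 0,
              sprintf("contig '%s' has no protein clusters", id))
  }
  pa <- unique(sets[[a]])
  pb <- unique(sets[[b]])
  100 * length(intersect(pa, pb)) / length(union(pa, pb))
}

#' Pairwise shared-PC fraction matrix
#'
#' @param pc_membership A data frame `contig_id`, `pc_id`.
#' @param contig_ids Contigs to include (default: all in `pc_membership`).
#' @return A symmetric matrix of shared-PC percentages with 100 on the
#'   diagonal.
#' @export
shared_pc_matrix <- function(pc_membership, contig_ids = NULL) {
  contig_ids <- sort(unique(contig_ids %||% pc_membership$contig_id))
  n <- length(contig_ids)
  m <- matrix(100, n, n, dimnames = list(contig_ids, contig_ids))
  if (n < 2) return(m)
  sets <- lapply(
    split(pc_membership$pc_id, pc_membership$contig_id)[contig_ids],
    unique
  )
  sizes <- lengths(sets)
  vp_assert(all(sizes > 0) && !anyNA(names(sets)),
            "every contig in `contig_ids` needs at least one PC")
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      f <- 100 * inter / (sizes[i] + sizes[j] - inter)
      m[i, j] <- f
      m[j, i] <- f
    }
  }
  m
}
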