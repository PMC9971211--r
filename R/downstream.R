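#' @title Functional enrichment and network hub analysis of DMG lists
#' @description Gene lists produced by either pipeline are characterized in
#'   two ways: (i) annotation-term fold enrichment against a gene
#'   population with a hypergeometric upper-tail test, keeping terms above a
#'   fold threshold (fourfold or tenfold are typical working values); and
#'   (ii) detection of the "core hub" of an interaction network — after
#'   dropping nodes with fewer than 2 edges, six per-node centrality metrics
#'   are computed, z-standardized, and k-means-clustered (k = 3, up to 500
#'   Lloyd iterations, Euclidean distance); the core hub is the cluster with
#'   the highest centrality, operationalized as the largest mean
#'   standardized degree + betweenness.
#' @name downstream
NULL

#' Term fold-enrichment analysis
#'
#' For each term with `K` annotated genes among the `N` population genes and
#' `k` hits among the `n` study genes: `fold = (k/n) / (K/N)` and the
#' p-value is the hypergeometric upper tail `P(X >= k)`. Results are
#' BH-adjusted and filtered to `fold > min_fold` and adjusted p `< alpha`,
#' sorted by fold descending. Unannotated population genes count in `N`
#' only; terms with no population annotation are skipped.
#'
#' @param study_genes character vector (must be a subset of `population`).
#' @param annotation data.frame with columns `gene_id`, `term_id` and
#'   optionally `term_name`.
#' @param population character vector of all testable genes.
#' @param min_fold fold threshold (default 4, exclusive).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return data.table: `term_id`, `term_name`, `k`, `n`, `K`, `N`, `fold`,
#'   `p_value`, `p_adjusted`.
#' @export
enrich_terms <- function(study_genes, annotation, population,
                         min_fold = 4, alpha = 0.05) {
  study <- unique(study_genes); popn <- unique(population)
  if (length(study) == 0) stop("empty study gene set")
  if (!all(study %in% popn))
    stop("study genes must be a subset of the population")
  ann <- as.data.table(annotation)
  stopifnot(all(c("gene_id", "term_id") %in% names(ann)))
  if (!"term_name" %in% names(ann)) ann[, term_name := term_id]
  ann <- unique(ann[gene_id %in% popn, .(gene_id, term_id, term_name)])
  n <- length(study); N <- length(popn)
  res <- ann[, .(term_name = term_name[1], K = .N,
                 k = sum(gene_id %in% study)), by = term_id]
  res <- res[K > 0]
  if (nrow(res) == 0)
    return(data.table(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), fold = numeric(), p_value = numeric(),
                      p_adjusted = numeric()))
  res[, `:=`(n = n, N = N)]
  res[, fold := (k / n) / (K / N)]
  # upper tail P(X >= k) with X ~ Hypergeom(K, N-K, n)
  res[, p_value := phyper(k - 1, K, N - K, n, lower.tail = FALSE)]
  res[, p_adjusted := adjust_pvalues(p_value)]
  out <- res[fold > min_fold & p_adjusted < alpha]
  setorder(out, -fold)
  out[, .(term_id, term_name, k, n, K, N, fold, p_value, p_adjusted)]
}

#' Read an interaction edge list
#'
#' Tab-separated `node_a`, `node_b` and optional `score` columns
#' (STRING-export-like). Self-loops are dropped and the graph is simplified
#' to an undirected simple graph.
#'
#' @param path edge list TSV.
#' @return An `igraph` undirected graph.
#' @export
read_edge_list <- function(path) {
  ed <- fread(path, sep = "\t", header = TRUE)
  stopifnot(ncol(ed) >= 2)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Drop low-degree nodes
#'
#' Single pass: removes the nodes whose degree in the input graph is below
#' `min_edges`. Removal is not iterated by default — nodes whose degree
#' drops below the threshold only because a neighbor was removed stay —
#' matching the usual network-viewer semantics; set `cascade = TRUE` for
#' iterated removal.
#'
#' @param graph an undirected `igraph` graph.
#' @param min_edges minimum degree (default 2).
#' @param cascade iterate removal to a fixed point (default FALSE).
#' @return The pruned graph.
#' @export
prune_low_degree <- function(graph, min_edges = 2L, cascade = FALSE) {
  g <- igraph::simplify(graph)
  repeat {
    drop <- igraph::V(g)[igraph::degree(g) < min_edges]
    if (length(drop) == 0) break
    g <- igraph::delete_vertices(g, drop)
    if (!cascade) break
  }
  g
}

#' Per-node centrality profiles
#'
#' Computes the six metrics used for hub clustering. Distance-based metrics
#' are computed within each connected component: closeness is
#' `(n_comp - 1) / sum(d)`, average shortest path length `sum(d)/(n_comp-1)`,
#' eccentricity the maximum distance in the component. Betweenness is the
#' unnormalized count of shortest paths through the node (each unordered
#' pair counted once, endpoints excluded); the local clustering coefficient
#' is `triangles / (deg * (deg - 1) / 2)`, 0 for degree < 2. Isolated nodes
#' get closeness 0, average path length 0, eccentricity 0.
#'
#' @param graph an undirected `igraph` graph.
#' @return data.table: `node_id`, `betweenness`, `closeness`,
#'   `avg_shortest_path_length`, `clustering_coefficient`, `degree`,
#'   `eccentricity`.
#' @export
centrality_profile <- function(graph) {
  g <- igraph::simplify(graph)
  nv <- igraph::vcount(g)
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(nv))
  if (nv == 0)
    return(data.table(node_id = character(), betweenness = numeric(),
                      closeness = numeric(),
                      avg_shortest_path_length = numeric(),
                      clustering_coefficient = numeric(), degree = numeric(),
                      eccentricity = numeric()))
  d <- igraph::distances(g)
  comp <- igraph::components(g)$membership
  clo <- asp <- ecc <- numeric(nv)
  for (i in seq_len(nv)) {
    others <- which(comp == comp[i])
    others <- setdiff(others, i)
    if (length(others) == 0) { clo[i] <- 0; asp[i] <- 0; ecc[i] <- 0; next }
    dsum <- sum(d[i, others])
    clo[i] <- length(others) / dsum
    asp[i] <- dsum / length(others)
    ecc[i] <- max(d[i, others])
  }
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  data.table(node_id = ids,
             betweenness = igraph::betweenness(g, directed = FALSE),
             closeness = clo, avg_shortest_path_length = asp,
             clustering_coefficient = cc,
             degree = as.numeric(igraph::degree(g)),
             eccentricity = ecc)
}

#' K-means core-hub clustering of centrality profiles
#'
#' Z-standardizes the six metrics (a metric with zero spread contributes a
#' constant 0 column), runs Lloyd's k-means with Euclidean distance from a
#' seeded initialization (k distinct random nodes as starting centers,
#' capped at `iterations`), and designates the cluster with the highest
#' mean standardized degree + betweenness as the core hub.
#'
#' @param profiles [centrality_profile()] output.
#' @param k number of clusters (default 3).
#' @param iterations Lloyd iteration cap (default 500).
#' @param seed integer seed for the initialization.
#' @return list of class `hub_clustering`: `assignment` (data.table
#'   `node_id`, `cluster`), `core_cluster_id`, `core_nodes`, `centers`,
#'   `k`, `iterations`, `seed`.
#' @export
kmeans_hub_cluster <- function(profiles, k = 3L, iterations = 500L,
                               seed = 1L) {
  profiles <- as.data.table(profiles)
  metrics <- c("betweenness", "closeness", "avg_shortest_path_length",
               "clustering_coefficient", "degree", "eccentricity")
  stopifnot(all(metrics %in% names(profiles)))
  nv <- nrow(profiles)
  if (k > nv) stop("k exceeds the number of nodes")
  z <- scale(as.matrix(profiles[, metrics, with = FALSE]))
  z[, attr(z, "scaled:scale") == 0] <- 0   # constant metrics
  z[!is.finite(z)] <- 0
  if (nrow(unique(as.data.table(z))) < k) {
    warning("fewer distinct centrality profiles than k; clusters collapse")
    k <- max(1L, nrow(unique(as.data.table(z))))
  }
  set.seed(seed)
  distinct <- which(!duplicated(as.data.table(z)))
  centers0 <- z[distinct[sample.int(length(distinct), k)], , drop = FALSE]
  km <- suppressWarnings(
    kmeans(z, centers = centers0, iter.max = iterations,
           algorithm = "Lloyd"))
  score <- vapply(seq_len(k), function(cl) {
    idx <- km$cluster == cl
    if (!any(idx)) return(-Inf)
    mean(z[idx, "degree"]) + mean(z[idx, "betweenness"])
  }, numeric(1))
  core <- which.max(score)
  structure(list(
    assignment = data.table(node_id = profiles$node_id,
                            cluster = unname(km$cluster)),
    core_cluster_id = core,
    core_nodes = profiles$node_id[km$cluster == core],
    centers = km$centers, k = k, iterations = iterations, seed = seed,
    tot_withinss = km$tot.withinss),
    class = "hub_clustering")
}
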