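test_that("fold enrichment follows the (k/n)/(K/N) definition", {
  # 5 of 50 study genes vs 10 of 1000 population genes -> fold 10
  ann <- data.frame(
    gene_id = c(sprintf("s%02d", 1:5), sprintf("p%03d", 1:5)),
    term_id = "T1")
  pop <- c(sprintf("s%02d", 1:50), sprintf("p%03d", 1:950))
  res <- enrich_terms(sprintf("s%02d", 1:50), ann, pop, min_fold = 1,
                      alpha = 1)
  expect_equal(res$fold, 10)
  expect_equal(as.numeric(res[, c(k, n, K, N)]), c(5, 50, 10, 1000))
  expect_equal(res$p_value, hyper_tail_bruteforce(5, 10, 1000, 50),
               tolerance = 1e-12)
})

test_that("the fold threshold is exclusive and study=population gives fold 1", {
  pop <- sprintf("g%02d", 1:40)
  ann <- data.frame(gene_id = pop[1:10], term_id = "T1")
  res <- enrich_terms(pop, ann, pop, min_fold = 0.5, alpha = 2)
  expect_equal(res$fold, 1)     # no enrichment possible; p = 1 exactly
  expect_equal(res$p_value, 1)
  expect_equal(nrow(enrich_terms(pop, ann, pop, min_fold = 4, alpha = 2)), 0)
  expect_error(enrich_terms(character(), ann, pop), "empty study")
  expect_error(enrich_terms(c("zzz"), ann, pop), "subset")
})

test_that("enrichment p-values match direct hypergeometric summation", {
  set.seed(15)
  for (i in 1:30) {
    N <- sample(5:30, 1)
    pop <- sprintf("g%d", 1:N)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    ann <- data.frame(gene_id = pop[1:K], term_id = "T")
    study <- sample(pop, n)
    res <- enrich_terms(study, ann, pop, min_fold = 0, alpha = 1.0)
    if (nrow(res) == 0) next     # k = 0 or filtered
    expect_equal(res$p_value,
                 hyper_tail_bruteforce(res$k, K, N, n), tolerance = 1e-10)
  }
})

test_that("low-degree pruning is a single pass by default", {
  # triangle + pendant: pendant removed, triangle intact
  g <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("c", "a"), c("a", "d")),
    directed = FALSE)
  pg <- prune_low_degree(g)
  expect_setequal(igraph::V(pg)$name, c("a", "b", "c"))
  # path A-B-C: endpoints removed, B kept with degree 0 (single pass)
  path <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("B", "C")),
                                      directed = FALSE)
  pp <- prune_low_degree(path)
  expect_equal(igraph::V(pp)$name, "B")
  expect_equal(igraph::degree(pp, "B"), c(B = 0))
  # cascade iterates to a fixed point
  pc <- prune_low_degree(path, cascade = TRUE)
  expect_equal(igraph::vcount(pc), 0)
  expect_equal(igraph::vcount(prune_low_degree(igraph::make_empty_graph())),
               0)
})

test_that("star and path centralities match hand enumeration", {
  star <- igraph::graph_from_edgelist(
    rbind(c("hub", "l1"), c("hub", "l2"), c("hub", "l3")), directed = FALSE)
  prof <- centrality_profile(star)
  hub <- prof[node_id == "hub"]
  expect_equal(hub$betweenness, 3)       # the 3 leaf pairs
  expect_equal(hub$eccentricity, 1)
  expect_equal(prof[node_id == "l1"]$eccentricity, 2)
  tri <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("c", "a")), directed = FALSE)
  tp <- centrality_profile(tri)
  expect_equal(tp$clustering_coefficient, rep(1, 3))
  expect_equal(tp$betweenness, rep(0, 3))
  path <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("B", "C")),
                                      directed = FALSE)
  pp <- centrality_profile(path)
  expect_equal(pp[node_id == "B"]$closeness, 1.0)       # 2/(1+1)
  expect_equal(pp[node_id == "A"]$closeness, 2 / 3)     # 2/(1+2)
  expect_equal(pp[node_id == "A"]$avg_shortest_path_length, 1.5)
})

test_that("all six centralities match brute-force APSP on random graphs", {
  # 60 random graphs here; the acceptance suite runs 200
  set.seed(16)
  for (i in 1:60) {
    n <- sample(2:8, 1)
    adj <- random_adj(n, p = runif(1, 0.2, 0.8))
    prof <- centrality_profile(graph_from_adj(adj))
    oracle <- centralities_bruteforce(adj)
    prof <- prof[match(as.character(1:n), node_id)]
    for (m in names(oracle))
      expect_equal(prof[[m]], oracle[[m]], tolerance = 1e-9,
                   label = paste(m, "graph", i))
  }
})

test_that("k-means recovers three well-separated centrality clouds", {
  set.seed(17)
  mk_cloud <- function(center, n) {
    m <- matrix(rnorm(n * 6, sd = 0.05), n, 6)
    sweep(m, 2, center, `+`)
  }
  pts <- rbind(mk_cloud(rep(0, 6), 10), mk_cloud(rep(5, 6), 10),
               mk_cloud(c(10, 0, 10, 0, 10, 0), 10))
  prof <- data.table::data.table(
    node_id = sprintf("n%02d", 1:30),
    betweenness = pts[, 1], closeness = pts[, 2],
    avg_shortest_path_length = pts[, 3],
    clustering_coefficient = pts[, 4], degree = pts[, 5],
    eccentricity = pts[, 6])
  hc <- kmeans_hub_cluster(prof, k = 3, seed = 99)
  truth <- rep(1:3, each = 10)
  # partition identity up to label permutation
  tab <- table(truth, hc$assignment$cluster)
  expect_equal(unname(sort(apply(tab, 1, max))), c(10, 10, 10))
  # core = highest mean standardized degree + betweenness -> cloud 3
  expect_setequal(hc$core_nodes, sprintf("n%02d", 21:30))
  # determinism given the seed
  hc2 <- kmeans_hub_cluster(prof, k = 3, seed = 99)
  expect_identical(hc$assignment, hc2$assignment)
})

test_that("degenerate clustering inputs are handled", {
  prof <- data.table::data.table(
    node_id = c("a", "b"), betweenness = 1, closeness = 1,
    avg_shortest_path_length = 1, clustering_coefficient = 1, degree = 1,
    eccentricity = 1)
  expect_error(kmeans_hub_cluster(prof, k = 3), "exceeds")
  expect_warning(hc <- kmeans_hub_cluster(prof, k = 2, seed = 1),
                 "collapse")
  expect_equal(hc$k, 1)
  # k = 1: everything is the core cluster
  prof2 <- data.table::data.table(
    node_id = c("a", "b", "c"), betweenness = c(1, 2, 3), closeness = 1,
    avg_shortest_path_length = 1, clustering_coefficient = 0,
    degree = c(3, 2, 1), eccentricity = 1)
  h1 <- kmeans_hub_cluster(prof2, k = 1, seed = 1)
  expect_setequal(h1$core_nodes, c("a", "b", "c"))
})

test_that("edge lists load as simple undirected graphs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_a\tnode_b\tscore", "A\tB\t0.9", "B\tA\t0.8",
               "A\tA\t0.5", "B\tC\t0.7"), f)
  g <- read_edge_list(f)
  expect_equal(igraph::ecount(g), 2)      # dedup + self-loop dropped
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
})
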