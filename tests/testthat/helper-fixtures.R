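# Small in-code fixtures shared across test files.

make_sites <- function(chrom = "Chr1", pos, strand = "+", context = "CG",
                       n_meth, n_unmeth) {
  n <- length(pos)
  data.frame(chrom = rep_len(chrom, n), pos = pos,
             strand = rep_len(strand, n), context = rep_len(context, n),
             n_meth = n_meth, n_unmeth = n_unmeth)
}

# three control replicates sharing five CG sites, with mild count variation
tiny_controls <- function() {
  lapply(1:3, function(i)
    methylome_sample(
      make_sites(pos = c(100, 200, 300, 400, 500),
                 n_meth = c(5, 0, 10, 3, 7) + i,
                 n_unmeth = c(5, 10, 0, 7, 3)),
      sprintf("ctl_%d", i), "control"))
}

write_tiny_gff3 <- function(path, genes) {
  lines <- c("##gff-version 3",
             sprintf("%s\tsrc\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$type, genes$start, genes$end,
                     genes$strand, genes$id))
  writeLines(lines, path)
  path
}

# adjacency matrix -> igraph with node names V1..Vn
graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

random_adj <- function(n, p = 0.4) {
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- as.integer(runif(sum(up)) < p)
  adj + t(adj)
}
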