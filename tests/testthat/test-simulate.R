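# a small genome used throughout: keeps unit tests fast
small_genome <- function() genome_spec(chrom_lengths = c(Chr1 = 60000L),
                                       n_genes = 20L, n_sites = 2500L)

test_that("identical seeds give byte-identical experiments", {
  e1 <- simulate_experiment(small_genome(), sim_design(seed = 21))
  e2 <- simulate_experiment(small_genome(), sim_design(seed = 21))
  expect_identical(e1$truth$gene_truth, e2$truth$gene_truth)
  for (nm in names(e1$samples))
    expect_identical(e1$samples[[nm]]$sites, e2$samples[[nm]]$sites)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_experiment(e1, d1); write_experiment(e2, d2)
  f <- "ctl_1.CX_report.txt"
  expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  e3 <- simulate_experiment(small_genome(), sim_design(seed = 22))
  expect_false(identical(e1$samples$ctl_1$sites, e3$samples$ctl_1$sites))
})

test_that("zero effect and zero epimutation leave only binomial noise", {
  e <- simulate_experiment(small_genome(),
                           sim_design(effect_size = 0, epimutation_rate = 0,
                                      n_signal_genes = 0L, seed = 23))
  tt <- e$truth$site_truth
  expect_equal(tt$level_control, tt$level_treatment)
  expect_false(any(tt$in_signal_gene))
})

test_that("empirical mean levels converge to the truth table over many replicates", {
  e <- simulate_experiment(
    genome_spec(chrom_lengths = c(Chr1 = 30000L), n_genes = 5L,
                n_sites = 800L),
    sim_design(n_control = 50L, n_treatment = 1L, n_signal_genes = 0L,
               effect_size = 0, seed = 29))
  sites <- data.table::rbindlist(lapply(e$samples[1:50],
                                        function(s) s$sites))
  agg <- sites[, .(m = sum(n_meth), u = sum(n_unmeth)),
               by = .(chrom, pos, strand)]
  merged <- merge(agg[m + u > 0], e$truth$site_truth,
                  by = c("chrom", "pos", "strand"))
  expect_lt(mean(abs(merged$m / (merged$m + merged$u) -
                       merged$level_control)), 0.02)
})

test_that("the write manifest covers replicates and auxiliary files", {
  e <- simulate_experiment(small_genome(), sim_design(seed = 24))
  d <- withr::local_tempdir()
  man <- write_experiment(e, d)
  expect_length(man, 6 + 4)       # 3v3 CX reports + gff3/sheet/truth/design
  expect_true(all(file.exists(man)))
  # re-read CX files satisfy all site invariants
  s <- read_cx_report(man[["cx_trt_1"]])
  expect_s3_class(s, "methylome")
  expect_identical(s$sites, e$samples$trt_1$sites)
  # gene annotation round-trips through the GFF3 reader
  genes <- read_gff3_genes(man[["gff3"]])
  expect_equal(genes, e$genes)
  # truth table has one row per gene
  truth <- data.table::fread(man[["gene_truth"]])
  expect_equal(nrow(truth), nrow(e$genes))
  # the sample sheet loads and names every replicate
  sheet <- read_sample_sheet(man[["sample_sheet"]])
  expect_equal(sort(sheet$sample_id), sort(names(e$samples)))
})

test_that("genes are non-overlapping and inside their chromosome", {
  e <- simulate_experiment(small_genome(), sim_design(seed = 25))
  g <- e$genes
  expect_true(all(g$start >= 1))
  expect_true(all(g$end <= 60000))
  expect_true(all(g$start <= g$end))
  by_chr <- split(g, g$chrom)
  for (gg in by_chr)
    expect_true(all(utils::head(gg$end, -1) < utils::tail(gg$start, -1)))
})

test_that("context mix and signal placement follow the design", {
  e <- simulate_experiment(small_genome(),
                           sim_design(n_signal_genes = 5L, seed = 26))
  expect_equal(sum(e$truth$gene_truth$signal), 5)
  mix <- prop.table(table(e$samples$ctl_1$sites$context))
  expect_equal(as.numeric(mix[c("CG", "CHG", "CHH")]),
               c(0.25, 0.15, 0.60), tolerance = 0.1)
  # signal sites lie inside signal genes
  sig <- e$truth$site_truth[in_signal_gene == TRUE]
  sg <- e$truth$gene_truth[signal == TRUE]
  inside <- vapply(seq_len(nrow(sig)), function(i)
    any(sg$chrom == sig$chrom[i] & sg$start <= sig$pos[i] &
          sg$end >= sig$pos[i]), logical(1))
  expect_true(all(inside))
})

test_that("planted signal genes carry the largest observed group difference", {
  # 20 signal genes of 500, effect 0.4, 3v3, coverage mean 20
  e <- simulate_experiment(
    genome_spec(chrom_lengths = c(Chr1 = 2000000L), n_genes = 500L,
                n_sites = 40000L),
    sim_design(n_signal_genes = 20L, effect_size = 0.4, seed = 27))
  sites <- data.table::rbindlist(lapply(e$samples, function(s)
    cbind(s$sites, group = s$group)))
  pooled <- sites[, .(lv = sum(n_meth) / pmax(1, sum(n_meth) + sum(n_unmeth))),
                  by = .(chrom, pos, group)]
  wide <- data.table::dcast(pooled, chrom + pos ~ group, value.var = "lv")
  wide[, adiff := abs(treatment - control)]
  g <- e$truth$gene_truth
  gene_diff <- vapply(seq_len(nrow(g)), function(i) {
    v <- wide[chrom == g$chrom[i] & pos >= g$start[i] & pos <= g$end[i]]$adiff
    if (length(v)) mean(v, na.rm = TRUE) else 0
  }, numeric(1))
  top20 <- g$gene_id[order(-gene_diff)[1:20]]
  expect_gte(sum(g[signal == TRUE]$gene_id %in% top20), 18)
})

test_that("raising the effect size raises divergence at signal sites", {
  meds <- vapply(c(0.1, 0.3, 0.5), function(es) {
    e <- simulate_experiment(small_genome(),
                             sim_design(n_signal_genes = 10L,
                                        effect_size = es, seed = 28))
    ctl <- lapply(e$samples[1:3], filter_coverage, 4)
    ref <- pool_centroid(ctl)
    div <- divergence_table(e$samples[4:6], ref)
    sig <- e$truth$site_truth[in_signal_gene == TRUE]
    median(div[sig, on = c("chrom", "pos", "strand"), nomatch = NULL]$hdiv)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("a signal gene outside the genome is rejected", {
  expect_error(sim_design(effect_size = 1.5), "effect_size")
  expect_error(sim_design(epimutation_rate = -0.1), "epimutation_rate")
})
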