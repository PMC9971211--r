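test_that("CX report lines map directly onto cytosine sites", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Chr1\t100\t+\t5\t3\tCG\tCGT",
               "Chr1\t150\t-\t0\t8\tCHH\tCAT",
               "Chr2\t10\t+\t2\t2\tCHG\tCAG"), f)
  s <- read_cx_report(f)
  expect_s3_class(s, "methylome")
  expect_equal(nrow(s$sites), 3)
  first <- as.list(s$sites[1])
  expect_equal(first[c("chrom", "pos", "strand", "context", "n_meth",
                       "n_unmeth")],
               list(chrom = "Chr1", pos = 100L, strand = "+",
                    context = "CG", n_meth = 5L, n_unmeth = 3L))
  # context subsetting skips other lines
  expect_equal(nrow(read_cx_report(f, contexts = "CG")$sites), 1)
  expect_equal(nrow(read_cx_report(f, contexts = c("CG", "CHG"))$sites), 2)
})

test_that("malformed CX lines are rejected with their line number", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Chr1\t100\t+\t5\t3\tXYZ\tCGT"), f)
  expect_error(read_cx_report(f), "line 1")
  writeLines(c("Chr1\t100\t+\t5\t3\tCG\tCGT",
               "Chr1\t200\t*\t5\t3\tCG\tCGT"), f)
  expect_error(read_cx_report(f), "line 2")
  writeLines(c("Chr1\t100\t+\tfive\t3\tCG\tCGT"), f)
  expect_error(read_cx_report(f), "malformed")
})

test_that("write then read round-trips the site collection exactly", {
  s <- methylome_sample(
    make_sites(pos = c(5, 50, 500), context = c("CG", "CHG", "CHH"),
               strand = c("+", "-", "+"),
               n_meth = c(0, 4, 9), n_unmeth = c(7, 0, 1)),
    "roundtrip", "control")
  f <- withr::local_tempfile(fileext = ".txt")
  write_cx_report(s, f)
  s2 <- read_cx_report(f, sample_id = "roundtrip", group = "control")
  expect_equal(s2$sites, s$sites)
  # empty sample -> empty header-free file
  empty <- methylome_sample(make_sites(pos = integer(), n_meth = integer(),
                                       n_unmeth = integer()), "e")
  write_cx_report(empty, f)
  expect_equal(length(readLines(f)), 0)
  expect_equal(nrow(read_cx_report(f)$sites), 0)
})

test_that("duplicate site keys are an error, not a merge", {
  expect_error(
    methylome_sample(make_sites(pos = c(100, 100), n_meth = c(1, 2),
                                n_unmeth = c(3, 4)), "dup"),
    "duplicate")
  # same position on opposite strands is two distinct cytosines
  s <- methylome_sample(make_sites(pos = c(100, 100), strand = c("+", "-"),
                                   n_meth = c(1, 2), n_unmeth = c(3, 4)),
                        "ok")
  expect_equal(nrow(s$sites), 2)
})

test_that("GFF3 reader returns gene records only, with ID and coordinates", {
  f <- withr::local_tempfile(fileext = ".gff3")
  write_tiny_gff3(f, data.frame(
    chrom = c("Chr1", "Chr1", "Chr1", "Chr2"),
    type = c("gene", "mRNA", "exon", "gene"),
    start = c(1000, 1000, 1000, 50), end = c(3000, 3000, 1500, 90),
    strand = c("+", "+", "+", "-"),
    id = c("AT1G01010", "AT1G01010.1", "AT1G01010.1.e1", "AT2G00050")))
  genes <- read_gff3_genes(f)
  expect_equal(nrow(genes), 2)
  expect_equal(genes[gene_id == "AT1G01010"],
               data.table::data.table(gene_id = "AT1G01010", chrom = "Chr1",
                                      start = 1000L, end = 3000L,
                                      strand = "+"))
  expect_equal(genes[gene_id == "AT2G00050"]$end, 90L)
  # only non-gene features -> empty collection
  write_tiny_gff3(f, data.frame(chrom = "Chr1", type = c("mRNA", "exon"),
                                start = c(1, 1), end = c(10, 5),
                                strand = "+", id = c("m1", "e1")))
  expect_equal(nrow(read_gff3_genes(f)), 0)
})

test_that("coverage filter keeps exactly the sites at or above the cutoff", {
  s <- methylome_sample(make_sites(pos = c(1, 2, 3),
                                   n_meth = c(1, 2, 2),
                                   n_unmeth = c(2, 2, 3)), "cov")
  expect_equal(nrow(filter_coverage(s, 4)$sites), 2)
  expect_equal(filter_coverage(s, 4)$sites$pos, c(2L, 3L))
  expect_equal(nrow(filter_coverage(s, 6)$sites), 0)   # empty is valid
  expect_error(filter_coverage(s, 0), "min_coverage")
  # zero-coverage sites are dropped even at min_coverage = 1
  z <- methylome_sample(make_sites(pos = 1:2, n_meth = c(0, 1),
                                   n_unmeth = c(0, 0)), "z")
  expect_equal(filter_coverage(z, 1)$sites$pos, 2L)
})

test_that("coverage filter is idempotent and monotone", {
  set.seed(42)
  s <- methylome_sample(make_sites(pos = 1:50,
                                   n_meth = rpois(50, 3),
                                   n_unmeth = rpois(50, 3)), "prop")
  for (mc in c(1, 3, 5, 8)) {
    once <- filter_coverage(s, mc)
    expect_equal(filter_coverage(once, mc)$sites, once$sites)
  }
  kept <- sapply(1:10, function(mc) nrow(filter_coverage(s, mc)$sites))
  expect_true(all(diff(kept) <= 0))
})

test_that("sample sheet requires header, valid groups and a control", {
  d <- withr::local_tempdir()
  f <- file.path(d, "samples.tsv")
  writeLines(c("sample_id\tpath\tgroup",
               "c1\tc1.txt\tcontrol", "t1\tt1.txt\ttreatment"), f)
  sheet <- read_sample_sheet(f)
  expect_equal(sheet$sample_id, c("c1", "t1"))
  expect_equal(sheet$path, file.path(d, c("c1.txt", "t1.txt")))
  writeLines(c("sample_id\tpath\tgroup", "t1\tt1.txt\ttreatment"), f)
  expect_error(read_sample_sheet(f), "control")
  writeLines(c("sample_id\tpath\tgroup", "c1\tc1.txt\tmock"), f)
  expect_error(read_sample_sheet(f), "group")
})

test_that("BED export converts to 0-based half-open at the writer only", {
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed6(data.frame(chrom = "Chr1", start = 100, end = 100,
                        name = "CG", score = 5, strand = "+"), f)
  expect_equal(strsplit(readLines(f), "\t")[[1]],
               c("Chr1", "99", "100", "CG", "5", "+"))
})
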