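#' @title Synthetic bisulfite count experiments with ground truth
#' @description Generates desk-scale whole-genome bisulfite experiments
#'   whose statistical structure mirrors a typical plant methylome study:
#'   three biological replicates per condition; context-specific methylation
#'   level distributions (CG bimodal near 0 and 1, CHG intermediate, CHH
#'   low); shared stochastic epimutation noise, in which any replicate of
#'   either group can redraw a site's level; and treatment-restricted signal
#'   in which a chosen subset of genes shifts methylation in the treatment
#'   replicates only. Read coverage is negative-binomial and observed counts
#'   are binomial draws from the replicate's underlying level, so observed
#'   divergence mixes true signal, epimutational noise, and sampling noise
#'   exactly as the analysis pipeline assumes. A truth table records every
#'   underlying level and the planted genes.
#' @name simulate
NULL

#' Genome specification for the simulator
#'
#' The default is a desk-scale genome: one 200 kbp chromosome carrying 100
#' non-overlapping genes of 1-3 kbp and about 10,000 cytosines mixed 60%
#' CHH, 25% CG, 15% CHG (a plant-like context mix).
#'
#' @param chrom_lengths named integer vector (chromosome name -> length).
#' @param n_genes number of genes.
#' @param gene_length_range min/max gene length in bp.
#' @param n_sites total cytosines.
#' @param context_mix proportions for CG/CHG/CHH (must sum to 1).
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(chrom_lengths = c(Chr1 = 200000L),
                        n_genes = 100L,
                        gene_length_range = c(1000L, 3000L),
                        n_sites = 10000L,
                        context_mix = c(CG = 0.25, CHG = 0.15, CHH = 0.60)) {
  stopifnot(all(chrom_lengths >= 1), n_genes >= 1,
            gene_length_range[1] <= gene_length_range[2],
            abs(sum(context_mix) - 1) < 1e-8,
            identical(sort(names(context_mix)), c("CG", "CHG", "CHH")))
  structure(list(chrom_lengths = chrom_lengths, n_genes = n_genes,
                 gene_length_range = gene_length_range, n_sites = n_sites,
                 context_mix = context_mix),
            class = "genome_spec")
}

#' Simulation design
#'
#' Defaults follow the experimental-design guidance the pipeline is built
#' around: 3 control and 3 treatment replicates, negative-binomial coverage
#' with mean 20 and dispersion 5, a per-site per-replicate epimutation
#' (level redraw) probability of 0.01, and a treatment level shift of 0.4 at
#' the planted signal genes with an even hyper/hypo direction mix per gene.
#'
#' @param n_control,n_treatment replicate counts.
#' @param coverage_mean,coverage_dispersion negative-binomial coverage
#'   parameters (dispersion = NB size; smaller = more variable).
#' @param epimutation_rate per-site per-replicate probability that the
#'   methylation level is redrawn from its context distribution (applies to
#'   both groups).
#' @param n_signal_genes number of genes carrying treatment signal.
#' @param effect_size treatment level shift magnitude in (0, 1].
#' @param hyper_fraction fraction of signal genes shifted upward.
#' @param signal_site_fraction fraction of a signal gene's cytosines that
#'   carry the shift; recycled across signal genes, so e.g. `c(1, 0.3)`
#'   plants alternating dense and sparse signal genes (default 1 = every
#'   site).
#' @param seed integer seed; every random draw derives from it.
#' @return A `sim_design` list.
#' @export
sim_design <- function(n_control = 3L, n_treatment = 3L,
                       coverage_mean = 20, coverage_dispersion = 5,
                       epimutation_rate = 0.01,
                       n_signal_genes = 20L, effect_size = 0.4,
                       hyper_fraction = 0.5, signal_site_fraction = 1,
                       seed = 1L) {
  stopifnot(n_control >= 1, n_treatment >= 1, coverage_mean > 0,
            coverage_dispersion > 0,
            epimutation_rate >= 0, epimutation_rate <= 1,
            effect_size >= 0, effect_size <= 1,
            hyper_fraction >= 0, hyper_fraction <= 1,
            all(signal_site_fraction > 0), all(signal_site_fraction <= 1))
  structure(list(n_control = n_control, n_treatment = n_treatment,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 epimutation_rate = epimutation_rate,
                 n_signal_genes = n_signal_genes,
                 effect_size = effect_size,
                 hyper_fraction = hyper_fraction,
                 signal_site_fraction = signal_site_fraction, seed = seed),
            class = "sim_design")
}

# context-specific baseline level distributions (plant-like):
# CG: bimodal mixture concentrated near 0 and 1; CHG: intermediate;
# CHH: low.
.draw_levels <- function(context, n) {
  switch(context,
         CG = {
           hi <- runif(n) < 0.4
           ifelse(hi, rbeta(n, 8, 1.2), rbeta(n, 1.2, 8))
         },
         CHG = rbeta(n, 1.5, 3),
         CHH = rbeta(n, 0.8, 6))
}

#' Simulate a bisulfite experiment with ground truth
#'
#' @param genome a [genome_spec()].
#' @param design a [sim_design()].
#' @return list: `samples` (list of [methylome_sample()]), `genes`
#'   (data.table as from [read_gff3_genes()]), `truth` (list with
#'   `gene_truth`, `site_truth`, `design`, `genome`).
#' @export
simulate_experiment <- function(genome = genome_spec(),
                                design = sim_design()) {
  stopifnot(inherits(genome, "genome_spec"), inherits(design, "sim_design"))
  set.seed(design$seed)
  chroms <- names(genome$chrom_lengths)

  # --- genes: non-overlapping, placed left to right with random gaps
  genes_per_chrom <- table(sample(chroms, genome$n_genes, replace = TRUE,
                                  prob = genome$chrom_lengths))
  genes <- rbindlist(lapply(chroms, function(ch) {
    ng <- if (ch %in% names(genes_per_chrom)) genes_per_chrom[[ch]] else 0L
    if (ng == 0) return(NULL)
    len <- genome$chrom_lengths[[ch]]
    glens <- sample(seq(genome$gene_length_range[1],
                        genome$gene_length_range[2]), ng, replace = TRUE)
    # the default genome packs genes densely; when a draw does not fit,
    # lengths are rescaled proportionally to leave a small gap budget
    max_total <- len - 2L * (ng + 1L)
    if (max_total < ng)
      stop("genes do not fit on chromosome ", ch,
           "; reduce gene number/length")
    if (sum(glens) > max_total)
      glens <- pmax(100L, as.integer(floor(glens * max_total / sum(glens))))
    slack <- len - sum(glens)
    gaps <- as.integer(stats::rmultinom(1, slack - ng - 1,
                                        rep(1, ng + 1))) + 1L
    starts <- cumsum(c(0L, glens[-ng])) + cumsum(gaps[-(ng + 1)])
    data.table(chrom = ch, start = starts + 1L,
               end = starts + glens,
               strand = sample(c("+", "-"), ng, replace = TRUE))
  }))
  setorder(genes, chrom, start)
  genes[, gene_id := sprintf("GENE%04d", .I)]
  setcolorder(genes, c("gene_id", "chrom", "start", "end", "strand"))

  # --- cytosine sites
  sites_per_chrom <- table(sample(chroms, genome$n_sites, replace = TRUE,
                                  prob = genome$chrom_lengths))
  sites <- rbindlist(lapply(chroms, function(ch) {
    ns <- if (ch %in% names(sites_per_chrom)) sites_per_chrom[[ch]] else 0L
    if (ns == 0) return(NULL)
    data.table(chrom = ch,
               pos = sort(sample.int(genome$chrom_lengths[[ch]], ns)),
               strand = sample(c("+", "-"), ns, replace = TRUE))
  }))
  sites[, context := sample(names(genome$context_mix), nrow(sites),
                            replace = TRUE, prob = genome$context_mix)]
  setorder(sites, chrom, pos, strand)
  sites[, site_id := .I]

  # --- baseline levels per context
  sites[, level := 0.0]
  for (ctx in names(genome$context_mix))
    sites[context == ctx, level := .draw_levels(ctx, .N)]

  # --- signal genes & site-level treatment effect
  n_sig <- min(design$n_signal_genes, nrow(genes))
  signal_ids <- sort(sample(genes$gene_id, n_sig))
  gene_truth <- copy(genes)[, signal := gene_id %in% signal_ids]
  dirs <- rep("hypo", n_sig)
  if (n_sig > 0) {
    n_hyper <- round(design$hyper_fraction * n_sig)
    dirs[seq_len(n_hyper)] <- "hyper"
    dirs <- sample(dirs)
  }
  gene_truth[, direction := NA_character_]
  gene_truth[gene_id %in% signal_ids,
             direction := dirs[match(gene_id[gene_id %in% signal_ids],
                                     signal_ids)]]
  # map sites to signal genes (first covering signal gene wins); only a
  # signal_site_fraction share of a gene's cytosines carries the shift
  sites[, effect := 0.0]
  sig_genes <- gene_truth[signal == TRUE]
  fracs <- rep_len(design$signal_site_fraction, nrow(sig_genes))
  gene_truth[, site_fraction := NA_real_]
  gene_truth[signal == TRUE, site_fraction := fracs]
  for (i in seq_len(nrow(sig_genes))) {
    sgn <- if (sig_genes$direction[i] == "hyper") 1 else -1
    idx <- sites[, which(chrom == sig_genes$chrom[i] &
                           pos >= sig_genes$start[i] &
                           pos <= sig_genes$end[i])]
    if (fracs[i] < 1)
      idx <- idx[runif(length(idx)) < fracs[i]]
    sites[idx, effect := sgn * design$effect_size]
  }

  # --- replicates
  mk_rep <- function(sid, group) {
    lv <- sites$level
    epi <- runif(nrow(sites)) < design$epimutation_rate
    if (any(epi)) {
      for (ctx in unique(sites$context[epi])) {
        idx <- which(epi & sites$context == ctx)
        lv[idx] <- .draw_levels(ctx, length(idx))
      }
    }
    if (group == "treatment")
      lv <- pmin(1, pmax(0, lv + sites$effect))
    cov <- as.integer(rnbinom(nrow(sites), size = design$coverage_dispersion,
                              mu = design$coverage_mean))
    nm <- as.integer(rbinom(nrow(sites), cov, lv))
    methylome_sample(
      data.table(chrom = sites$chrom, pos = sites$pos,
                 strand = sites$strand, context = sites$context,
                 n_meth = nm, n_unmeth = cov - nm),
      sid, group)
  }
  samples <- c(
    lapply(seq_len(design$n_control), function(i)
      mk_rep(sprintf("ctl_%d", i), "control")),
    lapply(seq_len(design$n_treatment), function(i)
      mk_rep(sprintf("trt_%d", i), "treatment")))
  names(samples) <- vapply(samples, `[[`, character(1), "sample_id")

  site_truth <- sites[, .(chrom, pos, strand, context,
                          level_control = level,
                          level_treatment = pmin(1, pmax(0, level + effect)),
                          in_signal_gene = effect != 0)]
  list(samples = samples, genes = genes,
       truth = list(gene_truth = gene_truth[], site_truth = site_truth,
                    design = design, genome = genome))
}

#' Write a simulated experiment to disk
#'
#' Emits one CX report per replicate, a GFF3 of the simulated genes, a
#' sample sheet, the gene truth table (TSV) and the design (JSON).
#'
#' @param experiment a [simulate_experiment()] result.
#' @param out_dir output directory (created if needed).
#' @return Named character vector: the file manifest.
#' @export
write_experiment <- function(experiment, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c()
  sheet <- data.table(sample_id = character(), path = character(),
                      group = character())
  for (s in experiment$samples) {
    f <- file.path(out_dir, paste0(s$sample_id, ".CX_report.txt"))
    write_cx_report(s, f)
    manifest[paste0("cx_", s$sample_id)] <- f
    sheet <- rbind(sheet, data.table(sample_id = s$sample_id,
                                     path = basename(f), group = s$group))
  }
  gff <- file.path(out_dir, "genes.gff3")
  genes <- experiment$genes
  lines <- c("##gff-version 3",
             sprintf("%s\tmethylSD_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id))
  writeLines(lines, gff)
  manifest["gff3"] <- gff
  ss <- file.path(out_dir, "samples.tsv")
  fwrite(sheet, ss, sep = "\t")
  manifest["sample_sheet"] <- ss
  tt <- file.path(out_dir, "gene_truth.tsv")
  fwrite(experiment$truth$gene_truth, tt, sep = "\t")
  manifest["gene_truth"] <- tt
  dj <- file.path(out_dir, "design.json")
  jsonlite::write_json(unclass(experiment$truth$design), dj,
                       auto_unbox = TRUE, digits = NA)
  manifest["design"] <- dj
  manifest
}
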