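#' @title Prevalent-methodology baseline pipeline
#' @description The comparison pipeline that most published methylome
#'   analyses follow: replicates are pooled within group, each shared site
#'   gets a two-sided Fisher exact test on its 2x2 methylated/unmethylated
#'   table, significant sites must additionally pass an arbitrary
#'   methylation-level-difference cutoff (20% by default; the literature
#'   ranges from 10 to 40%), and DMPs are binned into fixed genomic windows
#'   to form DMRs. This pipeline is implemented faithfully — including its
#'   arbitrary cutoffs — so its gene calls can be contrasted with the
#'   signal-detection calls.
#' @name baseline_prevalent
NULL

#' Two-sided Fisher exact test for one site
#'
#' Exact p for the 2x2 table `(ctl_meth, ctl_unmeth; trt_meth, trt_unmeth)`
#' by hypergeometric enumeration: the sum of probabilities of all tables
#' with the same margins whose probability does not exceed the observed
#' table's (the "probability mass <= observed" two-sided convention, with a
#' one-sided relative tolerance guard against floating-point ties).
#'
#' @param ctl,trt length-2 vectors `(n_meth, n_unmeth)`.
#' @return Two-sided p-value.
#' @export
fisher_site_test <- function(ctl, trt) {
  stopifnot(length(ctl) == 2, length(trt) == 2, all(c(ctl, trt) >= 0))
  m <- ctl[1] + trt[1]            # methylated margin
  n <- ctl[2] + trt[2]            # unmethylated margin
  k <- sum(ctl)                   # control row total
  if (m + n == 0) stop("all-zero 2x2 table: Fisher test undefined")
  if (m == 0 || n == 0 || k == 0 || sum(trt) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  d <- dhyper(support, m, n, k)
  obs <- dhyper(ctl[1], m, n, k)
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

#' Methylation-difference filter
#'
#' Passes iff `|p_trt - p_ctl| >= min_diff`; a difference exactly at the
#' cutoff passes. Vectorized.
#'
#' @param p_ctl,p_trt methylation levels in `[0, 1]`.
#' @param min_diff minimum absolute difference (default 0.20).
#' @export
delta_filter <- function(p_ctl, p_trt, min_diff = 0.20) {
  stopifnot(min_diff > 0, min_diff < 1)
  # small tolerance so a difference exactly at the cutoff passes despite
  # floating-point representation (e.g. 0.6 - 0.4 < 0.2 in binary)
  abs(p_trt - p_ctl) >= min_diff - 1e-12
}

#' Baseline DMP calling on pooled groups
#'
#' Pools counts within group, keeps sites where both pooled groups pass
#' `min_coverage`, Fisher-tests each site, BH-adjusts, and calls DMPs at
#' `p_adjusted < alpha` AND the methylation-difference filter. Direction is
#' `hyper` when the pooled treatment level exceeds the pooled control level.
#'
#' @param controls,treatments lists of [methylome_sample()] objects.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_diff level-difference cutoff (default 0.20).
#' @param min_coverage per-group pooled coverage floor (default 4).
#' @return data.table of DMP sites: key columns, pooled counts and levels,
#'   `p_value`, `p_adjusted`, `direction`.
#' @export
call_baseline_dmps <- function(controls, treatments, alpha = 0.05,
                               min_diff = 0.20, min_coverage = 4L) {
  pool <- function(samples) {
    rbindlist(lapply(samples, function(s) s$sites))[
      , .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
      by = .(chrom, pos, strand, context)]
  }
  cp <- pool(controls)[n_meth + n_unmeth >= min_coverage]
  tp <- pool(treatments)[n_meth + n_unmeth >= min_coverage]
  shared <- cp[tp, on = c("chrom", "pos", "strand", "context"),
               nomatch = NULL]
  if (nrow(shared) == 0) return(.empty_baseline_dmps())
  setnames(shared, c("n_meth", "n_unmeth", "i.n_meth", "i.n_unmeth"),
           c("ctl_meth", "ctl_unmeth", "trt_meth", "trt_unmeth"))
  shared[, p_value := mapply(function(a, b, c, d)
    fisher_site_test(c(a, b), c(c, d)),
    ctl_meth, ctl_unmeth, trt_meth, trt_unmeth)]
  shared[, p_adjusted := adjust_pvalues(p_value)]
  shared[, p_ctl := ctl_meth / (ctl_meth + ctl_unmeth)]
  shared[, p_trt := trt_meth / (trt_meth + trt_unmeth)]
  out <- shared[p_adjusted < alpha & delta_filter(p_ctl, p_trt, min_diff)]
  out[, direction := ifelse(p_trt > p_ctl, "hyper", "hypo")]
  setorder(out, chrom, pos, strand)
  out[]
}

.empty_baseline_dmps <- function() {
  data.table(chrom = character(), pos = integer(), strand = character(),
             context = character(), ctl_meth = integer(),
             ctl_unmeth = integer(), trt_meth = integer(),
             trt_unmeth = integer(), p_value = numeric(),
             p_adjusted = numeric(), p_ctl = numeric(), p_trt = numeric(),
             direction = character())
}

#' Bin DMPs into fixed-window DMRs
#'
#' Partitions each chromosome into non-overlapping tiles
#' `[k*window + 1, (k+1)*window]` and reports the tiles holding at least
#' `min_dmps` DMPs (all of the same direction when `uniform_direction`).
#'
#' @param dmps a [call_baseline_dmps()] table (needs `chrom`, `pos`,
#'   `direction`).
#' @param window tile width in bp (default 100).
#' @param min_dmps minimum DMPs per tile (default 3).
#' @param uniform_direction require one direction per tile (default FALSE).
#' @return data.table of DMRs: `chrom`, `start`, `end`, `n_dmps`,
#'   `direction` (`mixed` when both directions occur).
#' @export
bin_dmrs <- function(dmps, window = 100L, min_dmps = 3L,
                     uniform_direction = FALSE) {
  stopifnot(window >= 1)
  dmps <- as.data.table(dmps)
  if (nrow(dmps) == 0)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), n_dmps = integer(),
                      direction = character()))
  dmps[, tile := (pos - 1L) %/% as.integer(window)]
  dmr <- dmps[, .(n_dmps = .N,
                  direction = if (uniqueN(direction) == 1) direction[1]
                              else "mixed"),
              by = .(chrom, tile)]
  dmr <- dmr[n_dmps >= min_dmps]
  if (uniform_direction) dmr <- dmr[direction != "mixed"]
  dmr[, `:=`(start = tile * as.integer(window) + 1L,
             end = (tile + 1L) * as.integer(window))]
  setorder(dmr, chrom, start)
  dmr[, .(chrom, start, end, n_dmps, direction)]
}

#' Genes overlapped by baseline DMRs
#'
#' A gene is a baseline DMG iff it intersects at least one DMR.
#'
#' @param dmrs [bin_dmrs()] output.
#' @param genes gene table ([read_gff3_genes()]).
#' @return Character vector of gene ids.
#' @export
baseline_dmgs <- function(dmrs, genes) {
  genes <- as.data.table(genes)
  if (nrow(dmrs) == 0 || nrow(genes) == 0) return(character())
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  dmr_gr <- GenomicRanges::GRanges(
    dmrs$chrom, IRanges::IRanges(dmrs$start, dmrs$end))
  hits <- GenomicRanges::countOverlaps(gene_gr, dmr_gr)
  sort(unique(genes$gene_id[hits > 0]))
}

#' Compare two gene sets
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return list: `a_only`, `overlap`, `b_only` (counts) and `jaccard`
#'   (`|intersection| / |union|`, 0 when both sets are empty).
#' @export
compare_gene_sets <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  inter <- length(intersect(a, b))
  uni <- length(union(a, b))
  list(a_only = length(setdiff(a, b)), overlap = inter,
       b_only = length(setdiff(b, a)),
       jaccard = if (uni == 0) 0 else inter / uni)
}
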