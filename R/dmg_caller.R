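#' @title Gene-level differential methylation calling
#' @description DMPs are aggregated within annotated genes and per-sample
#'   DMP counts per gene become the response of a generalized linear model.
#'   Genes first pass a count/density gate — at least 3 treatment-group
#'   DMPs and a density of at least 3 DMPs per 10 kbp — then the group
#'   effect is tested with a likelihood-ratio test under the better of a
#'   Poisson and a negative-binomial regression (NB is considered only when
#'   the pooled counts are overdispersed). Genes with Benjamini-Hochberg
#'   adjusted p below 0.05 and log2 fold change above 1 are called DMGs.
#' @name dmg_caller
NULL

#' Count DMPs inside genes, per sample
#'
#' A DMP at position `p` counts for gene `g` iff
#' `g.start <= p <= g.end` on the same chromosome; strand is ignored and a
#' DMP inside two overlapping genes counts for both. Every gene appears in
#' the result, zero counts included. DMPs on chromosomes absent from the
#' annotation are left unassigned (with a message).
#'
#' @param dmp_sets named list (by sample id) of DMP tables with `chrom`,
#'   `pos` columns, or one combined table with a `sample_id` column.
#' @param genes gene table from [read_gff3_genes()] (columns `gene_id`,
#'   `chrom`, `start`, `end`).
#' @return data.table: one row per gene, `gene_id`, `gene_length`, one
#'   integer count column per sample.
#' @export
count_dmps_in_genes <- function(dmp_sets, genes) {
  genes <- as.data.table(genes)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (is.data.frame(dmp_sets)) {
    dmp_sets <- split(as.data.table(dmp_sets), by = "sample_id")
  }
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  out <- data.table(gene_id = genes$gene_id,
                    gene_length = genes$end - genes$start + 1L)
  for (sid in names(dmp_sets)) {
    dmp <- as.data.table(dmp_sets[[sid]])
    if (nrow(dmp) == 0) { out[, (sid) := 0L]; next }
    orphan <- setdiff(unique(dmp$chrom), unique(genes$chrom))
    if (length(orphan))
      message("DMPs on chromosome(s) ", paste(orphan, collapse = ", "),
              " have no annotated genes and are unassigned")
    dmp <- dmp[chrom %in% genes$chrom]
    if (nrow(dmp) == 0) { out[, (sid) := 0L]; next }
    dmp_gr <- GenomicRanges::GRanges(dmp$chrom,
                                     IRanges::IRanges(dmp$pos, dmp$pos))
    out[, (sid) := GenomicRanges::countOverlaps(gene_gr, dmp_gr)]
  }
  out[]
}

#' Count/density gene filter
#'
#' A gene is retained iff its pooled treatment-group DMP count is at least
#' `min_dmps` and its treatment DMP density is at least `min_density` per
#' 10 kbp: `(count / gene_length) * 10000 >= min_density`.
#'
#' @param counts output of [count_dmps_in_genes()].
#' @param groups named character vector mapping sample id to
#'   `control`/`treatment`.
#' @param min_dmps minimum pooled treatment DMP count (default 3).
#' @param min_density minimum treatment DMPs per 10 kbp (default 3).
#' @return The retained subset of `counts`, with helper columns
#'   `trt_total` and `density_per_10kb`.
#' @export
filter_density <- function(counts, groups, min_dmps = 3, min_density = 3) {
  stopifnot(min_dmps > 0, min_density > 0)
  counts <- as.data.table(counts)
  trt <- names(groups)[groups == "treatment"]
  stopifnot(length(trt) >= 1, all(trt %in% names(counts)))
  out <- copy(counts)
  out[, trt_total := rowSums(as.matrix(.SD)), .SDcols = trt]
  out[, density_per_10kb := trt_total / gene_length * 1e4]
  out[trt_total >= min_dmps & density_per_10kb >= min_density]
}

.pois_loglik <- function(y, mu) sum(dpois(y, pmax(mu, 1e-300), log = TRUE))

#' Likelihood-ratio group test for one gene
#'
#' Fits intercept-only and group-effect GLMs to the per-sample DMP counts.
#' Both models are fitted under Poisson; when the pooled sample variance
#' exceeds the pooled mean the negative binomial (ML dispersion) is fitted
#' as well, and the family with the lower AIC on the group model is used.
#' The statistic is `2 * (logLik_group - logLik_null)` within that family,
#' with p from a chi-square with 1 df. The fold change is
#' `log2(mean_treatment / mean_control)` (`+Inf` when only the control mean
#' is zero; 0 when both are zero).
#'
#' @param y per-sample DMP counts.
#' @param groups `control`/`treatment` labels aligned with `y`.
#' @return list: `family_used`, `mean_ctl`, `mean_trt`, `log2fc`,
#'   `lrt_stat`, `p_value`, `note`.
#' @export
test_gene <- function(y, groups) {
  stopifnot(length(y) == length(groups),
            all(groups %in% c("control", "treatment")))
  if (!any(groups == "control") || !any(groups == "treatment"))
    stop("need at least one sample per group")
  y <- as.numeric(y)
  g <- factor(groups, levels = c("control", "treatment"))
  m_ctl <- mean(y[groups == "control"])
  m_trt <- mean(y[groups == "treatment"])
  log2fc <- if (m_ctl == 0 && m_trt == 0) 0
            else if (m_ctl == 0) Inf
            else log2(m_trt / m_ctl)
  overdispersed <- var(y) > mean(y)
  fits <- list()
  fits$poisson <- tryCatch({
    f0 <- glm(y ~ 1, family = stats::poisson())
    f1 <- glm(y ~ g, family = stats::poisson())
    list(ll0 = as.numeric(logLik(f0)), ll1 = as.numeric(logLik(f1)),
         aic = f1$aic)
  }, error = function(e) NULL)
  if (overdispersed) {
    fits$negbin <- tryCatch(suppressWarnings({
      f0 <- MASS::glm.nb(y ~ 1)
      f1 <- MASS::glm.nb(y ~ g)
      # glm.nb AIC counts the dispersion parameter
      list(ll0 = as.numeric(logLik(f0)), ll1 = as.numeric(logLik(f1)),
           aic = f1$aic)
    }), error = function(e) NULL)
  }
  if (length(fits) == 0 || all(vapply(fits, is.null, logical(1))))
    return(list(family_used = NA_character_, mean_ctl = m_ctl,
                mean_trt = m_trt, log2fc = log2fc, lrt_stat = NA_real_,
                p_value = 1, note = "fit_failure"))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  fam <- names(fits)[which.min(vapply(fits, `[[`, numeric(1), "aic"))]
  lrt <- max(0, 2 * (fits[[fam]]$ll1 - fits[[fam]]$ll0))
  list(family_used = fam, mean_ctl = m_ctl, mean_trt = m_trt,
       log2fc = log2fc, lrt_stat = lrt,
       p_value = pchisq(lrt, df = 1, lower.tail = FALSE), note = "")
}

#' Test all retained genes
#'
#' Applies [test_gene()] to every row of a filtered count table and adjusts
#' p-values with [adjust_pvalues()].
#'
#' @param counts filtered gene count table ([filter_density()] output).
#' @param groups named `control`/`treatment` vector (names = sample ids).
#' @return data.table: `gene_id`, `family_used`, `mean_ctl`, `mean_trt`,
#'   `log2fc`, `lrt_stat`, `p_value`, `p_adjusted`.
#' @export
test_genes <- function(counts, groups) {
  counts <- as.data.table(counts)
  sids <- intersect(names(counts), names(groups))
  stopifnot(length(sids) >= 2)
  res <- rbindlist(lapply(seq_len(nrow(counts)), function(i) {
    y <- as.numeric(counts[i, sids, with = FALSE])
    r <- test_gene(y, unname(groups[sids]))
    data.table(gene_id = counts$gene_id[i], family_used = r$family_used,
               mean_ctl = r$mean_ctl, mean_trt = r$mean_trt,
               log2fc = r$log2fc, lrt_stat = r$lrt_stat,
               p_value = r$p_value)
  }))
  if (nrow(res)) res[, p_adjusted := adjust_pvalues(p_value)]
  else res[, p_adjusted := numeric()]
  res[]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment,
#' `p_adj(i) = min_{j >= i} (m * p(j) / j)` capped at 1 and mapped back to
#' the input order.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
adjust_pvalues <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Flag differentially methylated genes
#'
#' `is_dmg = p_adjusted < alpha` and `log2fc > lfc_min` (one-sided,
#' treatment above control, the default) or `|log2fc| > lfc_min`
#' (`direction = "two_sided"`).
#'
#' @param results [test_genes()] output.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc_min log2 fold-change threshold (default 1).
#' @param direction `"greater"` (default) or `"two_sided"`.
#' @return `results` with an `is_dmg` logical column.
#' @export
call_dmgs <- function(results, alpha = 0.05, lfc_min = 1,
                      direction = c("greater", "two_sided")) {
  direction <- match.arg(direction)
  results <- as.data.table(results)
  stopifnot("p_adjusted" %in% names(results))
  fc_ok <- if (direction == "greater") results$log2fc > lfc_min
           else abs(results$log2fc) > lfc_min
  results[, is_dmg := p_adjusted < alpha & fc_ok]
  results[]
}
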