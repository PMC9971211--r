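#' @title Centroid reference and per-site methylation divergence
#' @description The signal-detection pipeline compares every sample —
#'   including each control — against a single reference methylome obtained
#'   by pooling the control replicates. Pooling is an element-wise sum of
#'   read counts, so the reference methylation level at a site equals the
#'   coverage-weighted mean of the control levels there, and read depth is
#'   preserved for the coverage-weighted divergence. Divergence between the
#'   sample and reference Bernoulli methylation distributions is reported as
#'   squared Hellinger divergence (unweighted and coverage-weighted) and as
#'   total variation distance.
#' @name divergence
NULL

#' Pool control replicates into a centroid reference methylome
#'
#' Counts are summed element-wise over the union of site keys; a control
#' lacking a site contributes zero there. Background (non-treatment)
#' methylome variation cannot be estimated from fewer than three control
#' replicates, so pooling fewer is an error unless `strict = FALSE`, in
#' which case a warning is issued and pooling proceeds.
#'
#' @param controls list of [methylome_sample()] objects (the control group).
#' @param strict require >= 3 controls (default `TRUE`).
#' @return A `methylome` object with attribute `n_pooled`.
#' @export
pool_centroid <- function(controls, strict = TRUE) {
  if (length(controls) == 0) stop("no control samples to pool")
  lapply(controls, function(s) stopifnot(inherits(s, "methylome")))
  if (length(controls) < 3) {
    msg <- sprintf(
      "reference methylome pooled from %d control(s); at least 3 control replicates are required to capture background variation",
      length(controls))
    if (strict) stop(msg) else warning(msg)
  }
  all_sites <- rbindlist(lapply(controls, function(s) s$sites))
  pooled <- all_sites[, .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
                      by = .(chrom, pos, strand, context)]
  ref <- methylome_sample(pooled, "reference", "control")
  attr(ref, "n_pooled") <- length(controls)
  ref
}

#' Methylation level estimator
#'
#' Returns `(n_meth + a) / (n_meth + n_unmeth + a + b)` for pseudo-count
#' prior `(a, b)`. The default prior `(0, 0)` is the maximum-likelihood
#' proportion; the divergence computations use the Jeffreys-type prior
#' `(0.5, 0.5)` to avoid undefined levels and extreme square-root terms at
#' low coverage. Vectorized over counts.
#'
#' @param n_meth,n_unmeth read counts.
#' @param prior length-2 non-negative pseudo-counts `(a, b)`.
#' @return Methylation level(s) in `[0, 1]`.
#' @export
methylation_level <- function(n_meth, n_unmeth, prior = c(0, 0)) {
  stopifnot(length(prior) == 2, all(prior >= 0))
  tot <- n_meth + n_unmeth + prior[1] + prior[2]
  if (any(tot <= 0))
    stop("methylation level undefined: zero coverage and zero prior")
  (n_meth + prior[1]) / tot
}

#' Squared Hellinger divergence between two Bernoulli distributions
#'
#' `hdiv = (sqrt(p) - sqrt(q))^2 + (sqrt(1-p) - sqrt(1-q))^2`, bounded in
#' `[0, 2]`. Vectorized.
#'
#' @param p,q methylation levels in `[0, 1]`.
#' @export
hellinger_div <- function(p, q) {
  (sqrt(p) - sqrt(q))^2 + (sqrt(1 - p) - sqrt(1 - q))^2
}

#' Per-site divergence between a sample and the reference
#'
#' Computes methylation levels under `prior`, the squared Hellinger
#' divergence `hdiv`, its coverage-weighted form
#' `hdiv_w = w * hdiv` with `w = 2 * n_ref * n_smp / (n_ref + n_smp)` (the
#' harmonic-mean read depth, so deeply covered sites carry more signal), and
#' the total variation distance `tv = |p_smp - p_ref|`.
#'
#' @param ref_site,smp_site single-row site records (lists or 1-row
#'   data.frames with `chrom`, `pos`, `strand`, `context`, `n_meth`,
#'   `n_unmeth`) sharing the same key.
#' @param prior pseudo-count prior for the level estimate.
#' @return One-row data.table: key columns plus `p_ref`, `p_smp`, `hdiv`,
#'   `hdiv_w`, `tv`.
#' @export
site_divergence <- function(ref_site, smp_site, prior = c(0.5, 0.5)) {
  r <- as.list(ref_site); s <- as.list(smp_site)
  key <- c("chrom", "pos", "strand", "context")
  if (!identical(unname(r[key]), unname(s[key])))
    stop("site keys do not match: reference ",
         paste(unlist(r[key]), collapse = ":"), " vs sample ",
         paste(unlist(s[key]), collapse = ":"))
  p <- methylation_level(r$n_meth, r$n_unmeth, prior)
  q <- methylation_level(s$n_meth, s$n_unmeth, prior)
  n_ref <- r$n_meth + r$n_unmeth
  n_smp <- s$n_meth + s$n_unmeth
  w <- 2 * n_ref * n_smp / (n_ref + n_smp)
  hd <- hellinger_div(p, q)
  data.table(chrom = r$chrom, pos = r$pos, strand = r$strand,
             context = r$context, p_ref = p, p_smp = q,
             hdiv = hd, hdiv_w = w * hd, tv = abs(q - p))
}

#' Divergence table for a set of samples against the reference
#'
#' One record per (site, sample) at the intersection of the sample's and
#' the reference's site keys, where both pass `min_coverage`. Controls are
#' included deliberately: their divergences against the (self-inclusive)
#' pooled reference supply the null distribution used for cutoff learning.
#'
#' @param samples list of [methylome_sample()] objects (controls and
#'   treatments).
#' @param reference the [pool_centroid()] reference.
#' @param prior pseudo-count prior for level estimates (default Jeffreys).
#' @param min_coverage minimum coverage required of both the reference and
#'   the sample at a site.
#' @return data.table with columns `chrom`, `pos`, `strand`, `context`,
#'   `sample_id`, `group`, `cov_ref`, `cov_smp`, `p_ref`, `p_smp`, `hdiv`,
#'   `hdiv_w`, `tv`.
#' @export
divergence_table <- function(samples, reference, prior = c(0.5, 0.5),
                             min_coverage = 4L) {
  stopifnot(inherits(reference, "methylome"))
  ref <- reference$sites[n_meth + n_unmeth >= min_coverage]
  setkey(ref, chrom, pos, strand, context)
  out <- rbindlist(lapply(samples, function(s) {
    stopifnot(inherits(s, "methylome"))
    smp <- s$sites[n_meth + n_unmeth >= min_coverage]
    m <- ref[smp, on = c("chrom", "pos", "strand", "context"), nomatch = NULL]
    # i. columns come from smp with prefix i.
    if (nrow(m) == 0) return(NULL)
    p <- methylation_level(m$n_meth, m$n_unmeth, prior)
    q <- methylation_level(m$i.n_meth, m$i.n_unmeth, prior)
    n_ref <- m$n_meth + m$n_unmeth
    n_smp <- m$i.n_meth + m$i.n_unmeth
    hd <- hellinger_div(p, q)
    data.table(chrom = m$chrom, pos = m$pos, strand = m$strand,
               context = m$context, sample_id = s$sample_id,
               group = s$group, cov_ref = n_ref, cov_smp = n_smp,
               p_ref = p, p_smp = q, hdiv = hd,
               hdiv_w = 2 * n_ref * n_smp / (n_ref + n_smp) * hd,
               tv = abs(q - p))
  }))
  if (is.null(out) || nrow(out) == 0) {
    warning("empty divergence table: no site keys shared at the requested coverage")
    out <- data.table(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      sample_id = character(), group = character(),
                      cov_ref = integer(), cov_smp = integer(),
                      p_ref = numeric(), p_smp = numeric(), hdiv = numeric(),
                      hdiv_w = numeric(), tv = numeric())
  }
  setorder(out, sample_id, chrom, pos, strand)
  out[]
}
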