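#' @title End-to-end pipeline drivers
#' @description `run_signal_detection()` chains the eleven
#'   signal-detection stages — coverage filter, centroid pooling, divergence
#'   table, distribution fit per sample and context, percentile candidates,
#'   cutoff learning, DMP calling, gene counting, density filter, GLM
#'   testing, DMG calling — writing every intermediate table and a run
#'   manifest. `run_baseline()` runs the pooled Fisher pipeline on the same
#'   inputs and `run_compare()` contrasts the two DMG sets. Reruns with the
#'   same config and inputs are deterministic.
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' All tunables of every stage with their package defaults. Values supplied
#' in `...` (or as a list) override the defaults; unknown keys are an error.
#'
#' @param ... overrides, e.g. `min_coverage = 10`.
#' @return Named list of validated configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_coverage = 4L,           # site coverage floor
    strict_controls = TRUE,      # require >= 3 control replicates
    prior = c(0.5, 0.5),         # pseudo-counts for level estimates
    divergence = "hdiv_w",       # modeled divergence column
    families = c("gamma2p", "gamma3p"),  # candidate fit families
    prob = 0.95,                 # candidate DMP percentile
    criterion = "youden",        # cutoff learning criterion
    min_tv = NULL,               # optional TV floor for candidates
    dmg_min_dmps = 3,            # gene count gate
    dmg_min_density = 3,         # DMPs per 10 kbp gate
    dmg_alpha = 0.05,
    dmg_lfc_min = 1,
    dmg_direction = "greater",
    baseline_alpha = 0.05,
    baseline_min_diff = 0.20,
    baseline_window = 100L,
    baseline_min_dmps = 3L,
    seed = 1L)
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$min_coverage >= 1, cfg$prob > 0, cfg$prob < 1,
            cfg$divergence %in% c("hdiv_w", "hdiv"),
            cfg$criterion %in% c("youden", "accuracy"),
            cfg$dmg_alpha > 0, cfg$dmg_alpha < 1,
            cfg$baseline_window >= 1)
  cfg
}

.load_samples <- function(sample_sheet) {
  sheet <- if (is.character(sample_sheet)) read_sample_sheet(sample_sheet)
           else as.data.table(sample_sheet)
  samples <- lapply(seq_len(nrow(sheet)), function(i)
    read_cx_report(sheet$path[i], sample_id = sheet$sample_id[i],
                   group = sheet$group[i]))
  names(samples) <- sheet$sample_id
  samples
}

.manifest <- function(out_dir, stages, config, extra = list()) {
  man <- c(list(
    package = "methylSD",
    version = as.character(utils::packageVersion("methylSD")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config,
    config_hash = .config_hash(config),
    stages = stages), extra)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  man
}

.config_hash <- function(config) {
  # order-independent digest of the configuration
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 2^31
}

#' Run the signal-detection pipeline
#'
#' @param samples list of [methylome_sample()] objects, a sample sheet path,
#'   or a sample sheet data.frame (`sample_id`, `path`, `group`).
#' @param genes gene table ([read_gff3_genes()] output) or a GFF3 path.
#' @param out_dir output directory for intermediate tables and the
#'   manifest.
#' @param config a [pipeline_config()] list.
#' @return list: `divergence`, `models`, `cutoffs`, `dmps`, `gene_counts`,
#'   `filtered_counts`, `dmg_table`, `dmgs` (called gene ids), `manifest`.
#' @export
run_signal_detection <- function(samples, genes, out_dir = NULL,
                                 config = pipeline_config()) {
  t0 <- Sys.time()
  if (is.character(samples) || is.data.frame(samples))
    samples <- .load_samples(samples)
  if (is.character(genes)) genes <- read_gff3_genes(genes)
  genes <- as.data.table(genes)
  groups <- setNames(vapply(samples, `[[`, character(1), "group"),
                     vapply(samples, `[[`, character(1), "sample_id"))
  if (sum(groups == "control") < 3 && isTRUE(config$strict_controls))
    stop("signal detection requires >= 3 control replicates ",
         "(set strict_controls = FALSE to override); got ",
         sum(groups == "control"))
  log_stage <- function(s) message("[methylSD] stage: ", s)

  log_stage("filter_coverage")
  filtered <- lapply(samples, filter_coverage, config$min_coverage)

  log_stage("pool_centroid")
  reference <- pool_centroid(filtered[groups == "control"],
                             strict = config$strict_controls)

  log_stage("divergence_table")
  div <- divergence_table(filtered, reference, prior = config$prior,
                          min_coverage = config$min_coverage)

  log_stage("fit_models")
  fits <- list()
  for (sid in names(filtered)) for (ctx in .CONTEXTS) {
    vals <- div[sample_id == sid & context == ctx][[config$divergence]]
    if (length(vals[vals > 0]) >= 30)
      fits[[paste(sid, ctx, sep = ".")]] <-
        tryCatch(select_model(vals, config$families),
                 error = function(e) NULL)
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]

  log_stage("potential_dmps")
  candidates <- rbindlist(lapply(names(fits), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    sid <- paste(parts[-length(parts)], collapse = ".")
    ctx <- parts[length(parts)]
    potential_dmps(div[sample_id == sid & context == ctx], fits[[key]],
                   prob = config$prob, min_tv = config$min_tv,
                   value = config$divergence)
  }))
  if (is.null(candidates) || ncol(candidates) == 0)
    candidates <- copy(div[0])[, divergence := numeric()]

  log_stage("learn_cutoff")
  cutoffs <- list()
  for (ctx in .CONTEXTS) {
    cand <- candidates[context == ctx]
    ctl <- cand[group == "control"]$divergence
    trt <- cand[group == "treatment"]$divergence
    cutoffs[[ctx]] <- if (length(ctl) && length(trt))
      learn_cutoff(ctl, trt, criterion = config$criterion, context = ctx)
    else {
      message("[methylSD] context ", ctx, ": a candidate class is empty; ",
              "falling back to the percentile threshold alone")
      structure(list(context = ctx, cutoff = 0, metric = "percentile_only",
                     accuracy = NA_real_, sensitivity = NA_real_,
                     specificity = NA_real_, fdr = NA_real_,
                     youden = NA_real_),
                class = "cutoff_model")
    }
  }

  log_stage("call_dmps")
  trt_ids <- names(groups)[groups == "treatment"]
  ctl_ids <- names(groups)[groups == "control"]
  # The learned cutoff is a raw divergence value, but control divergences
  # against the self-inclusive pooled reference run structurally smaller
  # than treatment divergences. Each potential DMP is therefore assessed
  # against its own replicate's fitted distribution: the cutoff is mapped
  # to the probability level it occupies under the treatment-sample models
  # and each sample applies its own quantile-matched cutoff.
  cutoff_prob <- function(ctx) {
    keys <- paste(trt_ids, ctx, sep = ".")
    keys <- keys[keys %in% names(fits)]
    if (length(keys) == 0) return(NA_real_)
    mean(vapply(keys, function(k)
      model_cdf(fits[[k]], cutoffs[[ctx]]$cutoff), numeric(1)))
  }
  sample_cutoff <- function(sid, ctx, u) {
    key <- paste(sid, ctx, sep = ".")
    if (is.na(u) || !key %in% names(fits)) return(cutoffs[[ctx]]$cutoff)
    if (u <= 0) return(0)
    model_quantile(fits[[key]], min(u, 1 - 1e-12))
  }
  all_dmps <- rbindlist(lapply(.CONTEXTS, function(ctx) {
    u <- cutoff_prob(ctx)
    rbindlist(lapply(names(groups), function(sid) {
      cand <- candidates[context == ctx & sample_id == sid]
      if (nrow(cand) == 0) return(NULL)
      cm <- cutoffs[[ctx]]
      cm$cutoff <- sample_cutoff(sid, ctx, u)
      call_dmps(cand, cm)
    }))
  }))
  if (is.null(all_dmps) || ncol(all_dmps) == 0)
    all_dmps <- copy(candidates[0])[, direction := character()]
  dmps <- all_dmps[group == "treatment"]

  log_stage("count_dmps_in_genes")
  dmp_sets <- lapply(setNames(nm = c(ctl_ids, trt_ids)), function(sid) {
    if (nrow(all_dmps) == 0) all_dmps else all_dmps[sample_id == sid]
  })
  counts <- count_dmps_in_genes(dmp_sets, genes)

  log_stage("filter_density")
  kept <- filter_density(counts, groups, min_dmps = config$dmg_min_dmps,
                         min_density = config$dmg_min_density)

  log_stage("test_genes")
  dmg_table <- test_genes(kept, groups)

  log_stage("call_dmgs")
  if (nrow(dmg_table)) {
    dmg_table <- call_dmgs(dmg_table, alpha = config$dmg_alpha,
                           lfc_min = config$dmg_lfc_min,
                           direction = config$dmg_direction)
  } else dmg_table[, is_dmg := logical()]
  dmgs <- sort(dmg_table[is_dmg == TRUE]$gene_id)

  stages <- c("filter_coverage", "pool_centroid", "divergence_table",
              "fit_models", "potential_dmps", "learn_cutoff", "call_dmps",
              "count_dmps_in_genes", "filter_density", "test_genes",
              "call_dmgs")
  res <- list(divergence = div, models = fits, cutoffs = cutoffs,
              dmps = dmps, gene_counts = counts, filtered_counts = kept,
              dmg_table = dmg_table, dmgs = dmgs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(div, file.path(out_dir, "divergence.tsv"), sep = "\t")
    for (key in names(fits))
      write_divfit(fits[[key]],
                   file.path(out_dir, paste0("model_", key, ".json")))
    jsonlite::write_json(lapply(cutoffs, unclass),
                         file.path(out_dir, "cutoffs.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    fwrite(dmps, file.path(out_dir, "dmps.tsv"), sep = "\t")
    if (nrow(dmps))
      write_bed6(dmps[, .(chrom, start = pos, end = pos, name = context,
                          score = pmin(1000, round(divergence * 10)),
                          strand)],
                 file.path(out_dir, "dmps.bed"))
    fwrite(counts, file.path(out_dir, "gene_dmp_counts.tsv"), sep = "\t")
    fwrite(dmg_table, file.path(out_dir, "dmg_table.tsv"), sep = "\t")
    writeLines(dmgs, file.path(out_dir, "dmgs.txt"))
    res$manifest <- .manifest(out_dir, stages, config,
                              list(elapsed_sec =
                                     as.numeric(difftime(Sys.time(), t0,
                                                         units = "secs"))))
  } else {
    res$manifest <- list(stages = stages, config = config)
  }
  res
}

#' Run the baseline (prevalent-methodology) pipeline
#'
#' @inheritParams run_signal_detection
#' @return list: `dmps`, `dmrs`, `dmgs`, `manifest`.
#' @export
run_baseline <- function(samples, genes, out_dir = NULL,
                         config = pipeline_config()) {
  t0 <- Sys.time()
  if (is.character(samples) || is.data.frame(samples))
    samples <- .load_samples(samples)
  if (is.character(genes)) genes <- read_gff3_genes(genes)
  genes <- as.data.table(genes)
  groups <- vapply(samples, `[[`, character(1), "group")
  if (!any(groups == "control") || !any(groups == "treatment"))
    stop("baseline pipeline needs >= 1 sample per group")
  filtered <- lapply(samples, filter_coverage, config$min_coverage)
  dmps <- call_baseline_dmps(filtered[groups == "control"],
                             filtered[groups == "treatment"],
                             alpha = config$baseline_alpha,
                             min_diff = config$baseline_min_diff,
                             min_coverage = config$min_coverage)
  dmrs <- bin_dmrs(dmps, window = config$baseline_window,
                   min_dmps = config$baseline_min_dmps)
  dmgs <- baseline_dmgs(dmrs, genes)
  stages <- c("filter_coverage", "call_baseline_dmps", "bin_dmrs",
              "baseline_dmgs")
  res <- list(dmps = dmps, dmrs = dmrs, dmgs = dmgs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(dmps, file.path(out_dir, "baseline_dmps.tsv"), sep = "\t")
    fwrite(dmrs, file.path(out_dir, "baseline_dmrs.tsv"), sep = "\t")
    writeLines(dmgs, file.path(out_dir, "dmgs.txt"))
    res$manifest <- .manifest(out_dir, stages, config,
                              list(elapsed_sec =
                                     as.numeric(difftime(Sys.time(), t0,
                                                         units = "secs"))))
  } else {
    res$manifest <- list(stages = stages, config = config)
  }
  res
}

#' Compare the two pipelines' DMG sets
#'
#' @param dir_signal,dir_baseline run directories (each containing
#'   `dmgs.txt`) or character vectors of gene ids.
#' @param out_dir optional output directory for the comparison TSV.
#' @return list: `venn` (`a_only`, `overlap`, `b_only`), `jaccard`,
#'   `signal_only`, `both`, `baseline_only`.
#' @export
run_compare <- function(dir_signal, dir_baseline, out_dir = NULL) {
  get_set <- function(x) {
    if (length(x) == 1 && dir.exists(x)) {
      f <- file.path(x, "dmgs.txt")
      if (!file.exists(f)) stop("no DMG table found under ", x)
      readLines(f)
    } else as.character(x)
  }
  a <- get_set(dir_signal); b <- get_set(dir_baseline)
  cmp <- compare_gene_sets(a, b)
  res <- list(venn = c(a_only = cmp$a_only, overlap = cmp$overlap,
                       b_only = cmp$b_only),
              jaccard = cmp$jaccard,
              signal_only = sort(setdiff(a, b)),
              both = sort(intersect(a, b)),
              baseline_only = sort(setdiff(b, a)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(data.table(region = c("signal_only", "overlap", "baseline_only"),
                      n = c(cmp$a_only, cmp$overlap, cmp$b_only),
                      jaccard = cmp$jaccard),
           file.path(out_dir, "venn_summary.tsv"), sep = "\t")
  }
  res
}
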