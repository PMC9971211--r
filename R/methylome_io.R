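#' @title Methylome container and cytosine-report I/O
#' @description Readers and writers for Bismark-style per-cytosine (CX)
#'   reports, TAIR-style GFF3 gene annotation, sample sheets, and the shared
#'   coverage filter. All genomic coordinates are 1-based inclusive
#'   throughout the package; BED export converts at write time only.
#' @name methylome_io
NULL

.CONTEXTS <- c("CG", "CHG", "CHH")

#' Construct a methylome sample
#'
#' A methylome sample holds one replicate's per-cytosine methylated and
#' unmethylated read counts together with its sample id and group label.
#' Sites are stored sorted by (chrom, pos, strand); duplicate
#' (chrom, pos, strand) keys are an error — duplicates indicate an upstream
#' extraction fault, and are never silently merged. Cytosines on opposite
#' strands are distinct records (single-cytosine resolution); symmetric CpG
#' pairs are never collapsed.
#'
#' @param sites data.frame/data.table with columns `chrom`, `pos` (1-based),
#'   `strand` (`+`/`-`), `context` (`CG`/`CHG`/`CHH`), `n_meth`, `n_unmeth`.
#' @param sample_id character scalar.
#' @param group `"control"` or `"treatment"` (or `NA` when unknown).
#' @return An object of class `methylome`.
#' @export
methylome_sample <- function(sites, sample_id, group = NA_character_) {
  st <- as.data.table(sites)
  need <- c("chrom", "pos", "strand", "context", "n_meth", "n_unmeth")
  miss <- setdiff(need, names(st))
  if (length(miss)) stop("missing site columns: ", paste(miss, collapse = ", "))
  st <- st[, need, with = FALSE]
  st[, chrom := as.character(chrom)]
  st[, strand := as.character(strand)]
  st[, context := as.character(context)]
  if (nrow(st)) {
    if (any(!st$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(!st$context %in% .CONTEXTS))
      stop("context must be one of CG, CHG, CHH")
    if (any(st$pos < 1)) stop("positions must be >= 1")
    if (any(st$n_meth < 0) || any(st$n_unmeth < 0)) stop("negative counts")
  }
  setorder(st, chrom, pos, strand)
  if (anyDuplicated(st, by = c("chrom", "pos", "strand")))
    stop("duplicate (chrom, pos, strand) keys in sample '", sample_id, "'")
  if (!is.na(group) && !group %in% c("control", "treatment"))
    stop("group must be 'control' or 'treatment'")
  structure(list(sample_id = as.character(sample_id), group = group,
                 sites = st),
            class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("<methylome> %s (%s): %d sites [%s]\n", x$sample_id,
              ifelse(is.na(x$group), "?", x$group), nrow(x$sites),
              paste(sprintf("%s=%d", .CONTEXTS,
                            sapply(.CONTEXTS, function(k)
                              sum(x$sites$context == k))), collapse = " ")))
  invisible(x)
}

#' Read a Bismark-style cytosine (CX) report
#'
#' Parses the 7-column tab-separated per-cytosine report: chromosome,
#' 1-based position, strand, methylated count, unmethylated count, context,
#' trinucleotide. Lines whose context is outside `contexts` are skipped.
#'
#' @param path path to an (uncompressed) CX report.
#' @param contexts contexts to load; default all three.
#' @param sample_id sample id; defaults to the file base name.
#' @param group optional group label.
#' @return A [methylome_sample()] object.
#' @export
read_cx_report <- function(path, contexts = .CONTEXTS,
                           sample_id = sub("\\.[^.]*$", "", basename(path)),
                           group = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  contexts <- match.arg(contexts, .CONTEXTS, several.ok = TRUE)
  dt <- if (file.size(path) == 0) data.table() else tryCatch(
    fread(path, header = FALSE, sep = "\t", colClasses = list(character = 1),
          fill = FALSE),
    error = function(e) stop("failed to parse CX report ", path, ": ",
                             conditionMessage(e)))
  if (nrow(dt) == 0) {
    empty <- data.table(chrom = character(), pos = integer(),
                        strand = character(), context = character(),
                        n_meth = integer(), n_unmeth = integer())
    return(methylome_sample(empty, sample_id, group))
  }
  if (ncol(dt) < 7)
    stop("CX report ", path, " has ", ncol(dt), " columns; expected >= 7")
  setnames(dt, 1:7, c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                      "context", "tri"))
  bad <- which(!dt$strand %in% c("+", "-") | !dt$context %in% .CONTEXTS |
                 is.na(suppressWarnings(as.integer(dt$pos))) |
                 is.na(suppressWarnings(as.integer(dt$n_meth))) |
                 is.na(suppressWarnings(as.integer(dt$n_unmeth))))
  if (length(bad))
    stop("malformed CX report line ", bad[1], " in ", path)
  dt[, `:=`(pos = as.integer(pos), n_meth = as.integer(n_meth),
            n_unmeth = as.integer(n_unmeth))]
  dt <- dt[context %in% contexts]
  methylome_sample(dt[, .(chrom, pos, strand, context, n_meth, n_unmeth)],
                   sample_id, group)
}

.TRI_PLACEHOLDER <- c(CG = "CGA", CHG = "CAG", CHH = "CAA")

#' Write a methylome sample as a CX report
#'
#' Emits the 7-column tab-separated format read by [read_cx_report()];
#' the trinucleotide column is filled with a context-consistent placeholder.
#'
#' @param sample a [methylome_sample()] object.
#' @param path output path.
#' @export
write_cx_report <- function(sample, path) {
  stopifnot(inherits(sample, "methylome"))
  out <- copy(sample$sites)
  out[, tri := .TRI_PLACEHOLDER[context]]
  setcolorder(out, c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                     "context", "tri"))
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene records from a GFF3 annotation
#'
#' Returns only records whose feature type is `gene`, with the gene id taken
#' from the `ID` attribute. Coordinates are 1-based inclusive as in GFF3.
#'
#' @param path path to a GFF3 file.
#' @return data.table with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  ids <- as.character(gr$ID)
  if (length(gr) && any(is.na(ids) | ids == ""))
    stop("gene record without ID attribute in ", path)
  genes <- data.table(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  genes[strand == "*", strand := "."]
  if (nrow(genes) && any(genes$start > genes$end))
    stop("gene with start > end in ", path)
  setorder(genes, chrom, start)
  genes[]
}

#' Coverage filter
#'
#' Retains the sites whose total read coverage (methylated + unmethylated)
#' is at least `min_coverage`. The cutoff is a field convention rather than
#' a principled quantity; the default of 4 is deliberately conservative and
#' is surfaced in every pipeline configuration and log.
#'
#' @param sample a [methylome_sample()] object.
#' @param min_coverage positive integer; default 4.
#' @return The filtered `methylome` object (order preserved).
#' @export
filter_coverage <- function(sample, min_coverage = 4L) {
  stopifnot(inherits(sample, "methylome"))
  if (!is.numeric(min_coverage) || length(min_coverage) != 1 ||
      min_coverage < 1)
    stop("min_coverage must be a single integer >= 1")
  kept <- sample$sites[n_meth + n_unmeth >= min_coverage]
  methylome_sample(kept, sample$sample_id, sample$group)
}

#' Read a sample sheet
#'
#' Tab-separated file with header columns `sample_id`, `path`, `group`.
#' Relative paths are resolved against the sheet's directory.
#'
#' @param path sample sheet path.
#' @return data.table with columns `sample_id`, `path`, `group`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  need <- c("sample_id", "path", "group")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (any(!sheet$group %in% c("control", "treatment")))
    stop("sample sheet group values must be 'control' or 'treatment'")
  if (!any(sheet$group == "control"))
    stop("sample sheet must contain at least one control sample")
  rel <- !grepl("^(/|[A-Za-z]:)", sheet$path)
  sheet$path[rel] <- file.path(dirname(path), sheet$path[rel])
  sheet[]
}

#' Export intervals as BED6
#'
#' Converts 1-based inclusive intervals to BED's 0-based half-open
#' convention at write time.
#'
#' @param dt data.table with `chrom`, `start`, `end` (1-based inclusive) and
#'   optionally `name`, `score`, `strand`.
#' @param path output path.
#' @export
write_bed6 <- function(dt, path) {
  dt <- as.data.table(dt)
  bed <- data.table(
    chrom = dt$chrom,
    start = dt$start - 1L,
    end = dt$end,
    name = if ("name" %in% names(dt)) dt$name else ".",
    score = if ("score" %in% names(dt)) dt$score else 0,
    strand = if ("strand" %in% names(dt)) dt$strand else ".")
  fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
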