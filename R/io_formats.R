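#' @import methods
#' @importFrom stats median na.omit p.adjust phyper prcomp quantile rbeta
#'   rbinom rnbinom rnorm runif sd setNames var wilcox.test cor rgamma
#'   pnorm
#' @importFrom utils read.table write.table
NULL

# ---------------------------------------------------------------------------
# genotype_set: the in-memory substrate of all population-genetic statistics.
# Per-site fields are parallel vectors; genotypes are two allele-index
# matrices (0 = REF, 1.. = ALT index, NA = missing call).
# ---------------------------------------------------------------------------

#' Construct a genotype set
#'
#' Bundles per-site variant fields and per-sample diploid genotypes into the
#' container used by the filtering and sweep-scan stages. Coordinates are
#' 1-based inclusive throughout the package; conversion to 0-based half-open
#' happens only in [write_bed()].
#'
#' @param chrom character vector of chromosome ids (one per site).
#' @param pos integer vector of 1-based positions.
#' @param ref reference allele strings (non-empty).
#' @param alt comma-separated alternate allele strings (multi-allelic sites
#'   are kept intact; downstream filters restrict to biallelic sites).
#' @param a1,a2 integer matrices (sites x samples) of allele indices;
#'   `NA` marks a missing call.
#' @param samples character vector of sample ids (unique).
#' @param info data frame of per-site INFO annotations; columns among
#'   `QD`, `MQ`, `FS`, `MQRankSum`, `ReadPosRankSum`; `NA` where absent.
#' @return An object of class `genotype_set`.
#' @export
genotype_set <- function(chrom, pos, ref, alt, a1, a2, samples,
                         info = NULL) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n)
  if (any(pos < 1L)) stop("positions must be >= 1")
  if (any(!nzchar(ref))) stop("REF alleles must be non-empty")
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (!is.matrix(a1)) a1 <- matrix(as.integer(a1), nrow = n)
  if (!is.matrix(a2)) a2 <- matrix(as.integer(a2), nrow = n)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  stopifnot(ncol(a1) == length(samples), ncol(a2) == length(samples))
  n_alt <- lengths(strsplit(alt, ",", fixed = TRUE))
  amax <- pmax(a1, a2)
  rmax <- suppressWarnings(apply(amax, 1L, max, na.rm = TRUE))
  bad <- which(is.finite(rmax) & rmax > n_alt)
  if (length(bad))
    stop("genotype allele index exceeds ALT count at site ", bad[1L])
  if (is.null(info))
    info <- data.frame(QD = rep(NA_real_, n), MQ = rep(NA_real_, n),
                       FS = rep(NA_real_, n), MQRankSum = rep(NA_real_, n),
                       ReadPosRankSum = rep(NA_real_, n))
  colnames(a1) <- colnames(a2) <- samples
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 a1 = a1, a2 = a2, samples = as.character(samples),
                 info = info),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("genotype_set: %d sites x %d samples (%d chromosome%s)\n",
              n_sites(x), length(x$samples), length(unique(x$chrom)),
              if (length(unique(x$chrom)) == 1L) "" else "s"))
  invisible(x)
}

#' Number of sites in a genotype set
#' @param gs a `genotype_set`.
#' @return integer site count.
#' @export
n_sites <- function(gs) length(gs$pos)

#' Site-type predicates
#'
#' `is_snp()` is true where REF and every ALT allele have length 1;
#' `is_indel()` where any allele length differs from 1; `is_biallelic()`
#' where exactly one ALT allele is present.
#' @param gs a `genotype_set`.
#' @return logical vector, one element per site.
#' @export
is_snp <- function(gs) {
  alt_l <- vapply(strsplit(gs$alt, ",", fixed = TRUE),
                  function(a) max(nchar(a)), 1L)
  nchar(gs$ref) == 1L & alt_l == 1L
}

#' @rdname is_snp
#' @export
is_indel <- function(gs) !is_snp(gs)

#' @rdname is_snp
#' @export
is_biallelic <- function(gs) !grepl(",", gs$alt, fixed = TRUE)

#' Subset a genotype set by site and/or sample
#' @param gs a `genotype_set`.
#' @param sites logical or integer index over sites.
#' @param samples logical/integer/character index over samples.
#' @return a `genotype_set`.
#' @export
gs_subset <- function(gs, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(gs))
  if (is.null(samples)) samples <- seq_along(gs$samples)
  if (is.character(samples)) samples <- match(samples, gs$samples)
  genotype_set(gs$chrom[sites], gs$pos[sites], gs$ref[sites], gs$alt[sites],
               gs$a1[sites, samples, drop = FALSE],
               gs$a2[sites, samples, drop = FALSE],
               gs$samples[samples],
               info = gs$info[sites, , drop = FALSE])
}

#' Alternate-allele dosage matrix
#'
#' For biallelic sites, counts ALT alleles per genotype (0/1/2, `NA`
#' missing). Multi-allelic sites yield `NA` rows: they are never consumed
#' by the statistics, which operate after the biallelic restriction.
#' @param gs a `genotype_set`.
#' @return integer matrix (sites x samples).
#' @export
gs_dosage <- function(gs) {
  d <- gs$a1 + gs$a2
  d[!is_biallelic(gs), ] <- NA_integer_
  d
}

.info_keys <- c("QD", "MQ", "FS", "MQRankSum", "ReadPosRankSum")

# ---------------------------------------------------------------------------
# VCF
# ---------------------------------------------------------------------------

#' Read a VCF into a genotype set
#'
#' Parses a VCF 4.x file (plain or bgzipped) with `vcfR` and extracts the
#' genotype matrix plus the five INFO keys used by the hard filter
#' (QD, MQ, FS, MQRankSum, ReadPosRankSum). Other INFO keys are ignored,
#' with one message per run listing them. Multi-allelic records are kept
#' intact; missing genotypes (`./.`) stay missing, never reference.
#'
#' @param path VCF file path.
#' @param region optional `"chrom"` or `"chrom:start-end"` string; sites
#'   outside it are dropped after parsing.
#' @return a [genotype_set()].
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  meta <- v@meta
  hdr_keys <- sub("^##INFO=<ID=([^,]+),.*$", "\\1",
                  grep("^##INFO=", meta, value = TRUE))
  unknown <- setdiff(hdr_keys, .info_keys)
  if (length(unknown))
    message("read_vcf: ignoring INFO keys ", paste(unknown, collapse = ", "))
  info <- as.data.frame(lapply(.info_keys, function(k) {
    if (n == 0L) return(numeric(0))
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = k)))
  }))
  names(info) <- .info_keys
  samples <- colnames(v@gt)[-1L]
  if (n > 0L) {
    gt <- vcfR::extract.gt(v, element = "GT")
    al <- .parse_gt(gt)
  } else {
    al <- list(a1 = matrix(integer(0), 0L, length(samples)),
               a2 = matrix(integer(0), 0L, length(samples)))
  }
  gs <- genotype_set(fix[, "CHROM"], as.integer(fix[, "POS"]),
                     fix[, "REF"], fix[, "ALT"], al$a1, al$a2,
                     samples, info = info)
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1L]]
    keep <- gs$chrom == m[2L]
    if (nzchar(m[3L]))
      keep <- keep & gs$pos >= as.integer(m[4L]) & gs$pos <= as.integer(m[5L])
    gs <- gs_subset(gs, sites = keep)
  }
  gs
}

.parse_gt <- function(gt) {
  gt[is.na(gt)] <- "./."
  sp <- strsplit(gsub("|", "/", gt, fixed = TRUE), "/", fixed = TRUE)
  g1 <- vapply(sp, `[`, "", 1L)
  g2 <- vapply(sp, function(x) if (length(x) >= 2L) x[2L] else x[1L], "")
  a1 <- suppressWarnings(as.integer(g1))
  a2 <- suppressWarnings(as.integer(g2))
  # a half-missing diploid call is treated as missing
  a2[is.na(a1)] <- NA_integer_
  a1[is.na(a2)] <- NA_integer_
  list(a1 = matrix(a1, nrow = nrow(gt)), a2 = matrix(a2, nrow = nrow(gt)))
}

#' Write a genotype set as VCF 4.2
#'
#' Emits a minimal valid VCF with contig headers and INFO headers for the
#' keys actually present. Input must be coordinate-sorted.
#'
#' @param gs a [genotype_set()].
#' @param path output file path (plain text).
#' @param contig_lengths optional named integer vector of chromosome
#'   lengths; defaults to the maximum observed position per chromosome.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gs, path, contig_lengths = NULL) {
  o <- order(gs$chrom, gs$pos)
  if (is.unsorted(match(gs$chrom, unique(gs$chrom))) ||
      !identical(o, seq_along(o)))
    stop("records must be sorted by (chrom, pos)")
  chroms <- unique(gs$chrom)
  if (is.null(contig_lengths))
    contig_lengths <- vapply(chroms, function(ch)
      max(gs$pos[gs$chrom == ch], 1L), 1L)
  used <- .info_keys[vapply(.info_keys, function(k)
    any(!is.na(gs$info[[k]])), TRUE)]
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", chroms,
                   as.integer(contig_lengths[chroms])),
           sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="%s">',
                   used, used),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "FORMAT" = "INFO", "FORMAT", gs$samples),
                 collapse = "\t"))
  n <- n_sites(gs)
  if (n > 0L) {
    info_str <- vapply(seq_len(n), function(i) {
      kv <- vapply(used, function(k) {
        v <- gs$info[[k]][i]
        if (is.na(v)) NA_character_ else sprintf("%s=%.17g", k, v)
      }, "")
      kv <- kv[!is.na(kv)]
      if (length(kv)) paste(kv, collapse = ";") else "."
    }, "")
    gt_chr <- matrix(paste0(ifelse(is.na(gs$a1), ".", gs$a1), "/",
                            ifelse(is.na(gs$a2), ".", gs$a2)),
                     nrow = n)
    body <- paste(gs$chrom, gs$pos, ".", gs$ref, gs$alt, ".", "PASS",
                  info_str, "GT",
                  apply(gt_chr, 1L, paste, collapse = "\t"),
                  sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GTF gene models
# ---------------------------------------------------------------------------

#' Read gene models from a GTF file
#'
#' Imports gene/transcript/exon/CDS features via `rtracklayer` and builds
#' one gene model per `gene_id`. Exons and CDS keep genomic (1-based,
#' inclusive) coordinates sorted ascending; for minus-strand genes the
#' transcription order is the reverse, which the coding-sequence
#' reconstruction in the annotation stage handles strand-aware.
#'
#' @param path GTF file path.
#' @return list of `gene_model` objects, each with fields `gene_id`,
#'   `gene_name`, `chrom`, `strand` and `transcripts` (per transcript:
#'   `exons` and `cds` data frames with `start`, `end`, and for CDS
#'   `phase`).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  feat <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(feat) && any(is.na(feat$transcript_id)))
    stop("exon/CDS feature without transcript_id parent")
  gene_ids <- unique(df$gene_id[!is.na(df$gene_id)])
  models <- lapply(gene_ids, function(g) {
    sub <- df[!is.na(df$gene_id) & df$gene_id == g, , drop = FALSE]
    txs <- unique(sub$transcript_id[!is.na(sub$transcript_id)])
    transcripts <- lapply(txs, function(tx) {
      tsub <- sub[!is.na(sub$transcript_id) & sub$transcript_id == tx, ,
                  drop = FALSE]
      ex <- tsub[tsub$type == "exon", c("start", "end"), drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
        stop("overlapping exons in transcript ", tx)
      cds <- tsub[tsub$type == "CDS", c("start", "end", "phase"),
                  drop = FALSE]
      cds <- cds[order(cds$start), , drop = FALSE]
      rownames(ex) <- rownames(cds) <- NULL
      cds_len <- sum(cds$end - cds$start + 1L)
      list(transcript_id = tx, exons = ex, cds = cds,
           cds_complete = cds_len %% 3L == 0L && cds_len > 0L)
    })
    names(transcripts) <- txs
    gn <- if ("gene_name" %in% names(sub)) sub$gene_name[1L] else NA_character_
    structure(list(gene_id = g,
                   gene_name = if (is.na(gn)) g else gn,
                   chrom = as.character(sub$seqnames[1L]),
                   strand = as.character(sub$strand[1L]),
                   start = min(sub$start), end = max(sub$end),
                   transcripts = transcripts),
              class = "gene_model")
  })
  names(models) <- gene_ids
  models
}

#' Gene spans as a GRanges
#' @param models list of gene models from [read_gtf()].
#' @return `GRanges` with one range per gene, names = gene ids.
#' @export
gene_ranges <- function(models) {
  if (!length(models)) stop("no gene models loaded")
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(models, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(models, function(m) as.numeric(m$start), 1),
      end = vapply(models, function(m) as.numeric(m$end), 1)),
    strand = vapply(models, `[[`, "", "strand"))
  names(gr) <- vapply(models, `[[`, "", "gene_id")
  gr
}

# ---------------------------------------------------------------------------
# Counts, population map, GMT, BED
# ---------------------------------------------------------------------------

#' Read a gene-level count matrix
#'
#' Expects a TSV whose first column is the gene id, with a `length` column
#' (bp) and one column per sample. Counts must be non-negative integers.
#' Sample condition/timepoint/replicate metadata are taken from `meta`
#' (a TSV path or data frame with columns `sample`, `condition`,
#' `timepoint`, `replicate`) or, failing that, parsed from sample names of
#' the form `FE6_1`.
#'
#' @param path counts TSV path.
#' @param meta optional metadata TSV path or data frame.
#' @return a `count_matrix`: list with `counts` (genes x samples integer
#'   matrix), `lengths`, `genes`, `samples`, `meta`.
#' @export
read_counts <- function(path, meta = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  genes <- df[[1L]]
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", path)
  if (!"length" %in% names(df)) stop("counts TSV needs a 'length' column")
  lens <- df[["length"]]
  scols <- setdiff(names(df)[-1L], "length")
  if (anyDuplicated(scols)) stop("duplicate sample ids in ", path)
  cm <- as.matrix(df[, scols, drop = FALSE])
  if (any(cm < 0) || any(cm != round(cm)))
    stop("counts must be non-negative integers")
  storage.mode(cm) <- "integer"
  rownames(cm) <- genes
  if (is.character(meta)) meta <- read.table(meta, header = TRUE, sep = "\t",
                                             stringsAsFactors = FALSE)
  if (is.null(meta)) meta <- parse_sample_names(scols)
  meta <- meta[match(scols, meta$sample), , drop = FALSE]
  if (any(is.na(meta$sample))) stop("metadata does not cover all samples")
  count_matrix(cm, lens, meta)
}

#' Construct a count matrix object
#' @param counts genes x samples non-negative integer matrix with rownames.
#' @param lengths per-gene length in bp (> 0).
#' @param meta data frame with columns `sample`, `condition`, `timepoint`,
#'   `replicate` covering all columns of `counts`.
#' @return a `count_matrix`.
#' @export
count_matrix <- function(counts, lengths, meta) {
  stopifnot(nrow(counts) == length(lengths))
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (!all(colnames(counts) %in% meta$sample))
    stop("metadata does not cover all samples")
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, lengths = as.numeric(lengths),
                 genes = rownames(counts), samples = colnames(counts),
                 meta = meta),
            class = "count_matrix")
}

#' Parse condition/timepoint/replicate from sample names
#' @param samples names like `"FE6_1"` (condition FE, embryonic day 6,
#'   replicate 1).
#' @return data frame with `sample`, `condition`, `timepoint`, `replicate`.
#' @export
parse_sample_names <- function(samples) {
  m <- regmatches(samples, regexec("^([A-Za-z]+)([0-9]+)_([0-9]+)$", samples))
  if (any(lengths(m) != 4L))
    stop("cannot parse sample names; supply a metadata table")
  data.frame(sample = samples,
             condition = vapply(m, `[`, "", 2L),
             timepoint = as.integer(vapply(m, `[`, "", 3L)),
             replicate = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Read a two-column population map
#' @param path TSV path, columns: sample id, population label. A header
#'   line is detected and skipped if its first field is `sample`.
#' @return named character vector: sample id -> population label.
#' @export
read_population_map <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (identical(tolower(df[1L, 1L]), "sample")) df <- df[-1L, , drop = FALSE]
  if (anyDuplicated(df[[1L]])) stop("duplicate sample ids in population map")
  setNames(as.character(df[[2L]]), df[[1L]])
}

#' Read a GMT gene-set file
#' @param path GMT path (term, description, genes... tab-separated).
#' @return named list of character vectors (term -> gene set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sp <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(sp) < 3L)
  if (length(bad)) stop("malformed GMT line ", bad[1L])
  sets <- lapply(sp, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(sp, `[`, "", 1L)
  sets
}

#' Write regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open,
#' so `start` is decremented by one exactly here.
#'
#' @param regions data frame with `chrom`, `start`, `end` and optionally
#'   `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  nm <- if ("name" %in% names(regions)) regions$name
        else sprintf("region_%d", seq_len(nrow(regions)))
  df <- data.frame(regions$chrom, as.integer(regions$start) - 1L,
                   as.integer(regions$end), nm)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data frame as a TSV with fixed numeric formatting
#'
#' Used by the analysis scripts so reruns with the same seed are
#' byte-identical.
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
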