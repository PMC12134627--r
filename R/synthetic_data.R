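# Synthetic inputs with the statistical structure the analysis assumes:
# Balding-Nichols population genotypes with planted sweeps, a toy genome
# with planted variant effects, and NB time-course count matrices with
# planted temporal templates and DE genes. Truth tables accompany every
# output so downstream recovery is checkable without external data.

#' Genotype simulation configuration
#'
#' Defaults mirror the study design: three populations (wild reference
#' RJF plus the four-toed PPNT and five-toed PPP breeds, 17/22/21
#' samples), one 5-Mb chromosome at one SNP per 250 bp, background
#' differentiation F = 0.05, and five non-overlapping 100-kb sweeps in
#' the focal population with near-fixed focal allele frequencies
#' (Beta(18, 2), mean 0.9).
#'
#' @param pops named integer vector: population -> sample count.
#' @param chrom chromosome name.
#' @param chrom_len chromosome length in bp.
#' @param site_density expected SNPs per bp.
#' @param f_bg background Balding-Nichols F.
#' @param sweeps data frame `start`, `end`, `focal`; NULL plants the five
#'   default 100-kb sweeps in `default_focal`.
#' @param f_sweep sweep-site F for non-focal populations (kept for
#'   completeness; focal frequencies are drawn from `sweep_beta`).
#' @param sweep_beta Beta shape parameters of the focal allele frequency
#'   at sweep sites.
#' @param info_fail_frac fraction of sites given a failing QD value
#'   (planted hard-filter casualties).
#' @return a `genotype_sim_config` list.
#' @export
genotype_sim_config <- function(pops = c(RJF = 17L, PPNT = 22L, PPP = 21L),
                                chrom = "chr1", chrom_len = 5e6,
                                site_density = 1 / 250,
                                f_bg = 0.05,
                                sweeps = NULL, default_focal = "PPP",
                                f_sweep = 0.6, sweep_beta = c(18, 2),
                                info_fail_frac = 0) {
  if (is.null(sweeps)) {
    starts <- round(seq(0.5e6, 4.3e6, length.out = 5))
    sweeps <- data.frame(start = starts, end = starts + 1e5 - 1,
                         focal = default_focal)
  }
  o <- order(sweeps$start)
  sweeps <- sweeps[o, , drop = FALSE]
  if (nrow(sweeps) > 1L &&
      any(sweeps$start[-1L] <= sweeps$end[-nrow(sweeps)]))
    stop("sweeps must not overlap")
  if (any(sweeps$end > chrom_len)) stop("sweep outside genome")
  stopifnot(f_bg > 0, f_bg < 1, f_sweep > 0, f_sweep < 1)
  structure(list(pops = pops, chrom = chrom, chrom_len = chrom_len,
                 site_density = site_density, f_bg = f_bg,
                 sweeps = sweeps, f_sweep = f_sweep,
                 sweep_beta = sweep_beta,
                 info_fail_frac = info_fail_frac),
            class = "genotype_sim_config")
}

#' Simulate population genotypes under the Balding-Nichols model
#'
#' Per site, an ancestral frequency `p ~ U(0.05, 0.95)` and per
#' population `p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = f_bg`;
#' at sweep sites the focal population's frequency is drawn from
#' `Beta(sweep_beta)` instead (near fixation, hence high differentiation
#' and depressed diversity). Genotypes are `Binomial(2, p_k)`; INFO
#' fields are drawn from clearly passing ranges except the planted
#' failing fraction. Sites are independent (no linkage).
#'
#' @param config a [genotype_sim_config()].
#' @param seed RNG seed.
#' @return list with `gs` (a [genotype_set()]), `popmap` (named vector),
#'   `truth` (list: `sweeps`, per-site `freq` matrix and `in_sweep`
#'   flag).
#' @export
simulate_genotypes <- function(config = genotype_sim_config(), seed = 1L) {
  set.seed(seed)
  n_sites <- round(config$chrom_len * config$site_density)
  pos <- sort(sample.int(config$chrom_len, n_sites))
  p_anc <- runif(n_sites, 0.05, 0.95)
  F <- config$f_bg
  pops <- names(config$pops)
  in_sweep_focal <- matrix(FALSE, n_sites, length(pops),
                           dimnames = list(NULL, pops))
  for (i in seq_len(nrow(config$sweeps))) {
    sw <- config$sweeps[i, ]
    in_sweep_focal[pos >= sw$start & pos <= sw$end, sw$focal] <- TRUE
  }
  freq <- matrix(NA_real_, n_sites, length(pops),
                 dimnames = list(NULL, pops))
  for (k in pops) {
    a <- p_anc * (1 - F) / F
    b <- (1 - p_anc) * (1 - F) / F
    pk <- rbeta(n_sites, a, b)
    sel <- in_sweep_focal[, k]
    if (any(sel))
      pk[sel] <- rbeta(sum(sel), config$sweep_beta[1L],
                       config$sweep_beta[2L])
    freq[, k] <- pk
  }
  n_tot <- sum(config$pops)
  a1 <- matrix(NA_integer_, n_sites, n_tot)
  a2 <- matrix(NA_integer_, n_sites, n_tot)
  samples <- character(n_tot)
  popmap <- character(n_tot)
  col <- 1L
  for (k in pops) {
    for (s in seq_len(config$pops[[k]])) {
      g <- rbinom(n_sites, 2L, freq[, k])
      a1[, col] <- as.integer(g >= 1L)
      a2[, col] <- as.integer(g == 2L)
      samples[col] <- sprintf("%s_%02d", k, s)
      popmap[col] <- k
      col <- col + 1L
    }
  }
  names(popmap) <- samples
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  info <- data.frame(QD = runif(n_sites, 15, 35),
                     MQ = runif(n_sites, 50, 60),
                     FS = runif(n_sites, 0, 10),
                     MQRankSum = runif(n_sites, -2, 2),
                     ReadPosRankSum = runif(n_sites, -2, 2))
  if (config$info_fail_frac > 0) {
    bad <- runif(n_sites) < config$info_fail_frac
    info$QD[bad] <- runif(sum(bad), 0, 9.9)
  }
  gs <- genotype_set(rep(config$chrom, n_sites), pos, ref, unname(alt),
                     a1, a2, samples, info = info)
  list(gs = gs, popmap = popmap,
       truth = list(sweeps = config$sweeps, freq = freq,
                    in_sweep = rowSums(in_sweep_focal) > 0L,
                    p_anc = p_anc))
}

# ---------------------------------------------------------------------------
# Toy genome with planted variant effects
# ---------------------------------------------------------------------------

.codons_nonstop <- function() {
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

# build one gene: returns genome fragment edits + model rows + cds map
.plant_gene <- function(gene_id, tx_id, chrom, strand, exon_bounds,
                        cds_seq) {
  # exon_bounds: matrix of (start, end); CDS fills the exons completely
  stopifnot(sum(exon_bounds[, 2L] - exon_bounds[, 1L] + 1L) ==
              nchar(cds_seq))
  genomic <- unlist(lapply(seq_len(nrow(exon_bounds)), function(i)
    exon_bounds[i, 1L]:exon_bounds[i, 2L]))
  if (strand == "-") {
    tx_order <- rev(genomic)
    plant <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds_seq)))
  } else {
    tx_order <- genomic
    plant <- cds_seq
  }
  list(gene_id = gene_id, tx_id = tx_id, chrom = chrom, strand = strand,
       exons = exon_bounds, genomic = genomic, tx_order = tx_order,
       plant_seq = plant)
}

#' Simulate a toy genome with planted variant categories
#'
#' Builds a short random chromosome carrying four genes (both strands,
#' two exons each, complete ORFs) and a panel of variants whose effect
#' categories are known by construction: intergenic, upstream,
#' downstream, joint upstream/downstream, intronic, splice-site,
#' synonymous, nonsynonymous, stopgain and stoploss SNPs, plus
#' frameshift/nonframeshift insertions and deletions and an intronic
#' deletion. Writes FASTA and GTF files and returns the variants as a
#' genotype set together with the truth table.
#'
#' @param dir output directory for `toy.fa` and `toy.gtf`.
#' @param seed RNG seed for the background sequence.
#' @return list with `fasta`, `gtf` (paths), `genome`
#'   (`DNAStringSet`), `variants` (a [genotype_set()]) and `truth`
#'   (data frame `pos`, `ref`, `alt`, `class`, `category`).
#' @export
simulate_toy_genome <- function(dir = tempdir(), seed = 42L) {
  set.seed(seed)
  chrom <- "toy1"
  L <- 12000L
  bases <- c("A", "C", "G", "T")
  seqv <- sample(bases, L, replace = TRUE)

  nonstop <- .codons_nonstop()
  mk_cds <- function(n_codon, fixed = list()) {
    cod <- sample(setdiff(nonstop, "ATG"), n_codon - 2L, replace = TRUE)
    cds <- c("ATG", cod, "TAA")
    for (i in seq_along(fixed)) cds[[as.integer(names(fixed)[i])]] <-
      fixed[[i]]
    paste(cds, collapse = "")
  }

  # G1 (+): exons 3001-3060 and 3161-3250, CDS 150 nt = 50 codons.
  # codon 2 = GCT (Ala), codon 3 = TAC (Tyr): substrates for the
  # planted synonymous/nonsynonymous/stopgain SNPs.
  g1_cds <- mk_cds(50L, fixed = list(`2` = "GCT", `3` = "TAC"))
  g1 <- .plant_gene("G1", "G1.t1", chrom, "+",
                    rbind(c(3001L, 3060L), c(3161L, 3250L)), g1_cds)
  # G2 (-): exons 7001-7090 and 7191-7250, CDS 150 nt; codon 2 = GCT
  g2_cds <- mk_cds(50L, fixed = list(`2` = "GCT"))
  g2 <- .plant_gene("G2", "G2.t1", chrom, "-",
                    rbind(c(7001L, 7090L), c(7191L, 7250L)), g2_cds)
  # G3 (+) ending 9500 and G4 (+) starting 10000: their flanks overlap,
  # so a point between them is downstream of G3 AND upstream of G4
  g3 <- .plant_gene("G3", "G3.t1", chrom, "+",
                    rbind(c(9341L, 9400L), c(9441L, 9500L)), mk_cds(40L))
  g4 <- .plant_gene("G4", "G4.t1", chrom, "+",
                    rbind(c(10000L, 10059L), c(10100L, 10159L)),
                    mk_cds(40L))
  genes <- list(g1, g2, g3, g4)
  for (g in genes) {
    seqv[g$genomic] <- strsplit(g$plant_seq, "")[[1L]]
    if (g$strand == "-") {
      # planted sequence is already the genomic (plus) strand
      seqv[g$genomic] <- strsplit(g$plant_seq, "")[[1L]]
    }
  }
  seq_chr <- paste(seqv, collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(seq_chr, chrom))

  # genomic position of a 0-based CDS offset, in transcription order
  cds_pos <- function(g, off) {
    if (g$strand == "+") g$tx_order[off + 1L] else g$tx_order[off + 1L]
  }
  base_at <- function(p) seqv[p]
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  tr <- list()
  addv <- function(pos, ref, alt, class, category) {
    tr[[length(tr) + 1L]] <<- data.frame(pos = pos, ref = ref, alt = alt,
                                         class = class,
                                         category = category)
  }
  snp_alt <- function(p, want) {
    stopifnot(base_at(p) != want)
    want
  }
  # --- SNPs -------------------------------------------------------------
  addv(500L, base_at(500L),
       setdiff(bases, base_at(500L))[1L], "SNP", "intergenic")
  addv(2500L, base_at(2500L),
       setdiff(bases, base_at(2500L))[1L], "SNP", "upstream")      # G1 5'
  addv(3500L, base_at(3500L),
       setdiff(bases, base_at(3500L))[1L], "SNP", "downstream")    # G1 3'
  addv(9700L, base_at(9700L),
       setdiff(bases, base_at(9700L))[1L], "SNP",
       "upstream/downstream")                                      # G3/G4
  addv(3110L, base_at(3110L),
       setdiff(bases, base_at(3110L))[1L], "SNP", "intronic")      # G1 intron
  addv(3062L, base_at(3062L),
       setdiff(bases, base_at(3062L))[1L], "SNP", "splicing")      # 2nd base
  # codon 2 GCT: offset 3 G>A nonsynonymous (Ala>Thr); offset 5 T>A
  # synonymous (GCT>GCA); codon 3 TAC: offset 8 C>A stopgain (TAC>TAA);
  # final codon TAA: offset 147 T>C stoploss (TAA>CAA)
  p_nonsyn <- cds_pos(g1, 3L); addv(p_nonsyn, "G", "A", "SNP",
                                    "exonic_nonsynonymous")
  p_syn <- cds_pos(g1, 5L); addv(p_syn, "T", "A", "SNP",
                                 "exonic_synonymous")
  p_sg <- cds_pos(g1, 8L); addv(p_sg, "C", "A", "SNP", "exonic_stopgain")
  p_sl <- cds_pos(g1, 147L); addv(p_sl, "T", "C", "SNP",
                                  "exonic_stoploss")
  # minus-strand nonsynonymous: G2 codon 2 GCT offset 3 (CDS G>A); the
  # genomic strand carries the complement
  p2 <- cds_pos(g2, 3L)
  addv(p2, unname(comp["G"]), unname(comp["A"]), "SNP",
       "exonic_nonsynonymous")
  # --- InDels (all in G1 exon 2, codons 21..40 => offsets 60..119) ------
  at_off <- function(off) cds_pos(g1, off)
  p_fsdel <- at_off(63L)   # delete 2 bp after this base -> frameshift
  addv(p_fsdel, paste0(base_at(p_fsdel), base_at(p_fsdel + 1L),
                       base_at(p_fsdel + 2L)),
       base_at(p_fsdel), "InDel", "frameshift_deletion")
  p_nfdel <- at_off(71L)   # offset 71 = codon-final; delete codon 25
  addv(p_nfdel, paste0(base_at(p_nfdel), base_at(p_nfdel + 1L),
                       base_at(p_nfdel + 2L), base_at(p_nfdel + 3L)),
       base_at(p_nfdel), "InDel", "nonframeshift_deletion")
  p_fsins <- at_off(80L)
  addv(p_fsins, base_at(p_fsins), paste0(base_at(p_fsins), "A"),
       "InDel", "frameshift_insertion")
  p_nfins <- at_off(89L)   # codon-final base: insert one clean Ala codon
  addv(p_nfins, base_at(p_nfins), paste0(base_at(p_nfins), "GCT"),
       "InDel", "nonframeshift_insertion")
  addv(3120L, paste0(base_at(3120L), base_at(3121L)), base_at(3120L),
       "InDel", "intronic")
  addv(700L, base_at(700L), paste0(base_at(700L), "TT"), "InDel",
       "intergenic")

  truth <- do.call(rbind, tr)
  o <- order(truth$pos)
  truth <- truth[o, , drop = FALSE]
  rownames(truth) <- NULL
  n <- nrow(truth)
  gsv <- genotype_set(rep(chrom, n), truth$pos, truth$ref, truth$alt,
                      a1 = matrix(0L, n, 2L),
                      a2 = matrix(1L, n, 2L),
                      samples = c("S1", "S2"))

  fasta <- file.path(dir, "toy.fa")
  Biostrings::writeXStringSet(genome, fasta)
  gtf <- file.path(dir, "toy.gtf")
  .write_toy_gtf(genes, gtf)
  list(fasta = fasta, gtf = gtf, genome = genome, variants = gsv,
       truth = truth)
}

.write_toy_gtf <- function(genes, path) {
  lines <- character(0)
  for (g in genes) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     g$gene_id, g$tx_id, g$gene_id)
    span <- c(min(g$exons), max(g$exons))
    lines <- c(lines,
               paste(g$chrom, "toy", "gene", span[1L], span[2L], ".",
                     g$strand, ".", sprintf('gene_id "%s"; gene_name "%s";',
                                            g$gene_id, g$gene_id),
                     sep = "\t"),
               paste(g$chrom, "toy", "transcript", span[1L], span[2L],
                     ".", g$strand, ".", attrs, sep = "\t"))
    ex <- g$exons
    ord <- if (g$strand == "-") rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
    cum <- 0L
    for (i in ord) {
      frame <- (3L - (cum %% 3L)) %% 3L
      lines <- c(lines,
                 paste(g$chrom, "toy", "exon", ex[i, 1L], ex[i, 2L], ".",
                       g$strand, ".", attrs, sep = "\t"),
                 paste(g$chrom, "toy", "CDS", ex[i, 1L], ex[i, 2L], ".",
                       g$strand, frame, attrs, sep = "\t"))
      cum <- cum + (ex[i, 2L] - ex[i, 1L] + 1L)
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# NB time-course counts
# ---------------------------------------------------------------------------

#' Count simulation configuration
#'
#' Defaults mirror the study's RNA-seq design: two conditions (FE =
#' four-toed embryo, VE = five-toed embryo) at embryonic days 6-9 with
#' six replicates, NB dispersion 0.1, six temporal templates (flat,
#' rise, fall, peak at day 8, peak at day 9, dip) assigned uniformly,
#' and a planted day-9 condition effect (150 genes, 8-fold in VE).
#'
#' @param n_genes number of genes.
#' @param conditions,timepoints,n_reps the factorial design.
#' @param alpha NB dispersion (variance `mu + alpha mu^2`).
#' @param n_de,de_fold,de_timepoint,de_condition the planted DE block;
#'   `n_de = 0` disables it.
#' @param templates named list of positive multiplier vectors over the
#'   timepoints; `flat_only = TRUE` collapses all genes onto the flat
#'   template (null configuration).
#' @param flat_only logical.
#' @return a `counts_sim_config` list.
#' @export
counts_sim_config <- function(n_genes = 5000L,
                              conditions = c("FE", "VE"),
                              timepoints = 6:9, n_reps = 6L,
                              alpha = 0.1,
                              n_de = 150L, de_fold = 8,
                              de_timepoint = 9L, de_condition = "VE",
                              templates = NULL, flat_only = FALSE) {
  if (is.null(templates))
    templates <- list(flat = c(1, 1, 1, 1),
                      rise = c(0.3, 0.7, 1.6, 3.6),
                      fall = c(3.6, 1.6, 0.7, 0.3),
                      peak8 = c(0.4, 1.0, 3.5, 0.7),
                      peak9 = c(1.0, 0.5, 0.9, 3.8),
                      dip = c(2.6, 0.5, 0.4, 2.4))
  stopifnot(all(vapply(templates, length, 1L) == length(timepoints)),
            all(unlist(templates) > 0), de_fold > 0)
  structure(list(n_genes = n_genes, conditions = conditions,
                 timepoints = timepoints, n_reps = n_reps, alpha = alpha,
                 n_de = n_de, de_fold = de_fold,
                 de_timepoint = de_timepoint, de_condition = de_condition,
                 templates = templates, flat_only = flat_only),
            class = "counts_sim_config")
}

#' Simulate an NB time-course count matrix
#'
#' Gene means follow `mu = baseline * template(t) * sizefactor(sample)`,
#' multiplied by the DE fold for planted genes in the affected
#' (condition, timepoint) cell; counts are NB with dispersion `alpha`.
#' Baselines are log-normal (median 150), gene lengths log-normal
#' (median 1.5 kb), library size factors log-normal around 1.
#'
#' @param config a [counts_sim_config()].
#' @param seed RNG seed.
#' @return list with `cm` (a [count_matrix()]) and `truth` (data frame
#'   `gene`, `template`, `is_de`).
#' @export
simulate_counts <- function(config = counts_sim_config(), seed = 1L) {
  set.seed(seed)
  ng <- config$n_genes
  genes <- sprintf("gene_%05d", seq_len(ng))
  baseline <- rlnorm(ng, log(150), 1)
  lengths <- pmax(200, round(rlnorm(ng, log(1500), 0.5)))
  tnames <- names(config$templates)
  template <- if (config$flat_only) rep("flat", ng)
              else sample(tnames, ng, replace = TRUE)
  tmpl_mat <- do.call(rbind, config$templates)[template, , drop = FALSE]
  de_genes <- if (config$n_de > 0) sample(genes, config$n_de) else character(0)
  is_de <- genes %in% de_genes

  meta <- expand.grid(replicate = seq_len(config$n_reps),
                      timepoint = config$timepoints,
                      condition = config$conditions,
                      stringsAsFactors = FALSE)
  meta$sample <- sprintf("%s%d_%d", meta$condition, meta$timepoint,
                         meta$replicate)
  meta <- meta[, c("sample", "condition", "timepoint", "replicate")]
  sf <- rlnorm(nrow(meta), 0, 0.1)
  counts <- matrix(0L, ng, nrow(meta),
                   dimnames = list(genes, meta$sample))
  for (j in seq_len(nrow(meta))) {
    ti <- match(meta$timepoint[j], config$timepoints)
    mu <- baseline * tmpl_mat[, ti] * sf[j]
    if (config$n_de > 0 && meta$condition[j] == config$de_condition &&
        meta$timepoint[j] == config$de_timepoint)
      mu[is_de] <- mu[is_de] * config$de_fold
    counts[, j] <- rnbinom(ng, mu = mu, size = 1 / config$alpha)
  }
  storage.mode(counts) <- "integer"
  cm <- count_matrix(counts, lengths, meta)
  list(cm = cm,
       truth = data.frame(gene = genes, template = template,
                          is_de = is_de, stringsAsFactors = FALSE))
}

#' Write a simulated count matrix and metadata to TSV
#' @param sim result of [simulate_counts()].
#' @param dir output directory.
#' @return named vector of the paths written.
#' @export
write_counts_sim <- function(sim, dir) {
  cm <- sim$cm
  counts_path <- file.path(dir, "counts.tsv")
  df <- data.frame(gene_id = cm$genes, length = as.integer(cm$lengths),
                   cm$counts, check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta_path <- file.path(dir, "samples.tsv")
  write.table(cm$meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  c(counts = counts_path, meta = meta_path, truth = truth_path)
}

#' Write a simulated genotype set, population map and truth table
#' @param sim result of [simulate_genotypes()].
#' @param dir output directory.
#' @return named vector of the paths written.
#' @export
write_genotype_sim <- function(sim, dir) {
  vcf <- file.path(dir, "sim.vcf")
  write_vcf(sim$gs, vcf)
  pop <- file.path(dir, "popmap.tsv")
  write.table(data.frame(names(sim$popmap), unname(sim$popmap)),
              pop, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  tr <- file.path(dir, "sweep_truth.tsv")
  write.table(sim$truth$sweeps, tr, sep = "\t", quote = FALSE,
              row.names = FALSE)
  c(vcf = vcf, popmap = pop, truth = tr)
}
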