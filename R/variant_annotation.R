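# Simplified variant-effect classifier: places SNPs and InDels into the
# standard genic category taxonomy (upstream/downstream, intronic,
# splicing, exonic with coding consequence, intergenic) against a set of
# gene models plus the genome sequence.

.snp_severity <- c("stopgain", "stoploss", "nonsynonymous", "synonymous",
                   "unknown")

# relation of one variant interval to one transcript:
# "splicing", "exonic", "exonic/splicing", "intronic" or NA (outside span)
.tx_relation <- function(v_start, v_end, tx, splice_bp) {
  ex <- tx$exons
  if (!nrow(ex)) return(NA_character_)
  span <- c(min(ex$start), max(ex$end))
  if (v_end < span[1L] || v_start > span[2L]) return(NA_character_)
  in_exon <- any(v_start <= ex$end & v_end >= ex$start)
  in_splice <- FALSE
  if (nrow(ex) > 1L && splice_bp > 0L) {
    don <- cbind(ex$end[-nrow(ex)] + 1L, ex$end[-nrow(ex)] + splice_bp)
    acc <- cbind(ex$start[-1L] - splice_bp, ex$start[-1L] - 1L)
    sw <- rbind(don, acc)
    in_splice <- any(v_start <= sw[, 2L] & v_end >= sw[, 1L])
  }
  if (in_exon && in_splice) "exonic/splicing"
  else if (in_splice) "splicing"
  else if (in_exon) "exonic"
  else "intronic"
}

# CDS sequence (transcription orientation) and a map from genomic position
# to 0-based CDS offset
.cds_layout <- function(tx, strand, chrom_seq) {
  cds <- tx$cds
  if (!nrow(cds)) return(NULL)
  segs <- lapply(seq_len(nrow(cds)), function(i)
    as.character(Biostrings::subseq(chrom_seq, cds$start[i], cds$end[i])))
  seq_fwd <- paste(segs, collapse = "")
  if (strand == "-") {
    cds_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq_fwd)))
  } else cds_seq <- seq_fwd
  list(cds = cds, cds_seq = cds_seq, strand = strand,
       total = nchar(seq_fwd))
}

# 0-based offset of genomic position pos within the CDS, in transcription
# orientation; NA when pos is not coding
.cds_offset <- function(layout, pos) {
  cds <- layout$cds
  seg <- which(pos >= cds$start & pos <= cds$end)
  if (!length(seg)) return(NA_integer_)
  if (layout$strand == "+") {
    before <- if (seg > 1L) sum(cds$end[seq_len(seg - 1L)] -
                                  cds$start[seq_len(seg - 1L)] + 1L) else 0L
    before + (pos - cds$start[seg])
  } else {
    after <- if (seg < nrow(cds))
      sum(cds$end[(seg + 1L):nrow(cds)] -
            cds$start[(seg + 1L):nrow(cds)] + 1L) else 0L
    after + (cds$end[seg] - pos)
  }
}

.translate <- function(s) {
  if (!nchar(s)) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X"))
}

# coding consequence of a biallelic SNP at pos within a complete CDS
.snp_coding_effect <- function(layout, pos, ref, alt) {
  off <- .cds_offset(layout, pos)
  if (is.na(off)) return("unknown")            # exon but UTR
  if (layout$total %% 3L != 0L) return("unknown")
  base_ref <- ref
  base_alt <- alt
  if (layout$strand == "-") {
    base_ref <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ref)))
    base_alt <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(alt)))
  }
  if (substr(layout$cds_seq, off + 1L, off + 1L) != base_ref)
    stop("REF allele inconsistent with genome sequence at CDS offset ", off)
  codon_i <- off %/% 3L
  within <- off %% 3L
  codon <- substr(layout$cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  mut <- codon
  substr(mut, within + 1L, within + 1L) <- base_alt
  aa_ref <- .translate(codon)
  aa_alt <- .translate(mut)
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*" && aa_ref != "*") "stopgain"
  else if (aa_ref == "*" && aa_alt != "*") "stoploss"
  else "nonsynonymous"
}

# consequence of an indel whose REF interval intersects the CDS
.indel_coding_effect <- function(layout, pos, ref, alt) {
  d <- nchar(alt) - nchar(ref)
  kind <- if (d < 0L && nchar(alt) == 1L) "deletion"
          else if (d > 0L && nchar(ref) == 1L) "insertion"
          else "substitution"
  frame <- if (abs(d) %% 3L != 0L) "frameshift" else "nonframeshift"
  cat0 <- paste(frame, kind, sep = "_")
  if (frame == "frameshift" || layout$total %% 3L != 0L) return(cat0)
  # nonframeshift in a complete CDS: look for stop gain/loss by mutating
  # the CDS (only when the REF interval lies fully inside the CDS)
  offs <- vapply(pos:(pos + nchar(ref) - 1L),
                 function(p) .cds_offset(layout, p), 1L)
  if (anyNA(offs)) return(cat0)
  lo <- min(offs); hi <- max(offs)
  s <- layout$cds_seq
  ref_tx <- ref; alt_tx <- alt
  if (layout$strand == "-") {
    ref_tx <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ref)))
    alt_tx <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(alt)))
  }
  if (substr(s, lo + 1L, hi + 1L) != ref_tx)
    stop("REF allele inconsistent with genome sequence in CDS")
  mutated <- paste0(substr(s, 1L, lo), alt_tx,
                    substr(s, hi + 2L, nchar(s)))
  prot_ref <- .translate(substr(s, 1L, (nchar(s) %/% 3L) * 3L))
  prot_alt <- .translate(substr(mutated, 1L, (nchar(mutated) %/% 3L) * 3L))
  ref_has_term <- nchar(prot_ref) > 0L &&
    substr(prot_ref, nchar(prot_ref), nchar(prot_ref)) == "*"
  alt_has_term <- nchar(prot_alt) > 0L &&
    substr(prot_alt, nchar(prot_alt), nchar(prot_alt)) == "*"
  internal_stop <- function(p) {
    body <- if (nchar(p) > 1L) substr(p, 1L, nchar(p) - 1L) else ""
    grepl("*", body, fixed = TRUE)
  }
  if (internal_stop(prot_alt) && !internal_stop(prot_ref)) "stopgain"
  else if (ref_has_term && !alt_has_term && !internal_stop(prot_alt))
    "stoploss"
  else cat0
}

#' Classify variants against gene models
#'
#' Places every biallelic variant into the genic category taxonomy.
#' Precedence when a variant relates to several features or genes:
#' exonic/splicing > splicing > exonic > intronic > upstream/downstream
#' (upstream of one gene AND downstream of another) > upstream >
#' downstream > intergenic. Exonic SNPs in a complete CDS are translated
#' codon-wise (strand- and phase-aware) into synonymous / nonsynonymous /
#' stopgain / stoploss; exonic SNPs outside a CDS, or in an incomplete
#' CDS, are `exonic_unknown`. Coding InDels are split into
#' frameshift/nonframeshift deletion/insertion/substitution by length
#' change mod 3, with stopgain/stoploss overriding a nonframeshift call
#' when the altered codons gain or lose a stop.
#'
#' @param gs a biallelic [genotype_set()].
#' @param models gene models from [read_gtf()].
#' @param genome a `Biostrings::DNAStringSet` named by chromosome.
#' @param upstream_bp promoter/terminator flank width (default 1000).
#' @param splice_bp intronic splice-window width (default 2).
#' @return data frame with `chrom`, `pos`, `ref`, `alt`, `class`
#'   (`"SNP"`/`"InDel"`), `category`, `gene_id`.
#' @export
classify_variants <- function(gs, models, genome,
                              upstream_bp = 1000L, splice_bp = 2L) {
  if (!all(is_biallelic(gs))) stop("classify_variants requires biallelic records")
  snp <- is_snp(gs)
  n <- n_sites(gs)
  cats <- character(n)
  gene_hit <- rep(NA_character_, n)
  g_chrom <- vapply(models, `[[`, "", "chrom")

  for (i in seq_len(n)) {
    ch <- gs$chrom[i]
    if (!ch %in% names(genome)) stop("missing chromosome sequence: ", ch)
    pos <- gs$pos[i]
    ref <- gs$ref[i]; alt <- gs$alt[i]
    gref <- as.character(Biostrings::subseq(genome[[ch]], pos,
                                            pos + nchar(ref) - 1L))
    if (gref != ref)
      stop("REF allele mismatch with genome at ", ch, ":", pos)
    v_end <- pos + nchar(ref) - 1L
    rel <- character(0); rel_gene <- character(0)
    up <- down <- character(0)
    for (g in models[g_chrom == ch]) {
      if (v_end >= g$start && pos <= g$end) {
        tx_rel <- vapply(g$transcripts, function(tx)
          .tx_relation(pos, v_end, tx, splice_bp), "")
        tx_rel <- tx_rel[!is.na(tx_rel)]
        if (!length(tx_rel)) next
        r <- if (any(tx_rel == "exonic/splicing") ||
                 (any(tx_rel == "exonic") && any(tx_rel == "splicing")))
          "exonic/splicing"
        else if (any(tx_rel == "splicing")) "splicing"
        else if (any(tx_rel == "exonic")) "exonic"
        else "intronic"
        rel <- c(rel, r); rel_gene <- c(rel_gene, g$gene_id)
      } else {
        five_prime <- g$strand != "-"
        if (five_prime) {
          if (v_end >= g$start - upstream_bp && v_end < g$start)
            up <- c(up, g$gene_id)
          if (pos > g$end && pos <= g$end + upstream_bp)
            down <- c(down, g$gene_id)
        } else {
          if (pos > g$end && pos <= g$end + upstream_bp)
            up <- c(up, g$gene_id)
          if (v_end >= g$start - upstream_bp && v_end < g$start)
            down <- c(down, g$gene_id)
        }
      }
    }
    pick <- function(r) rel_gene[match(r, rel)]
    if ("exonic/splicing" %in% rel) {
      cats[i] <- "exonic/splicing"; gene_hit[i] <- pick("exonic/splicing")
    } else if ("splicing" %in% rel) {
      cats[i] <- "splicing"; gene_hit[i] <- pick("splicing")
    } else if ("exonic" %in% rel) {
      gid <- pick("exonic")
      gene_hit[i] <- gid
      g <- models[[gid]]
      effs <- character(0)
      for (tx in g$transcripts) {
        layout <- .cds_layout(tx, g$strand, genome[[ch]])
        if (is.null(layout)) next
        hit_cds <- any(pos <= layout$cds$end & v_end >= layout$cds$start)
        if (!hit_cds) next
        effs <- c(effs,
                  if (snp[i]) .snp_coding_effect(layout, pos, ref, alt)
                  else .indel_coding_effect(layout, pos, ref, alt))
      }
      if (snp[i]) {
        eff <- if (length(effs))
          .snp_severity[min(match(effs, .snp_severity))] else "unknown"
        cats[i] <- paste0("exonic_", eff)
      } else {
        sev <- c("stopgain", "stoploss",
                 "frameshift_deletion", "frameshift_insertion",
                 "frameshift_substitution",
                 "nonframeshift_deletion", "nonframeshift_insertion",
                 "nonframeshift_substitution")
        cats[i] <- if (length(effs)) sev[min(match(effs, sev))]
                   else "exonic_unknown"
      }
    } else if ("intronic" %in% rel) {
      cats[i] <- "intronic"; gene_hit[i] <- pick("intronic")
    } else if (length(up) && length(down)) {
      cats[i] <- "upstream/downstream"; gene_hit[i] <- up[1L]
    } else if (length(up)) {
      cats[i] <- "upstream"; gene_hit[i] <- up[1L]
    } else if (length(down)) {
      cats[i] <- "downstream"; gene_hit[i] <- down[1L]
    } else {
      cats[i] <- "intergenic"
    }
  }
  data.frame(chrom = gs$chrom, pos = gs$pos, ref = gs$ref, alt = gs$alt,
             class = ifelse(snp, "SNP", "InDel"),
             category = cats, gene_id = gene_hit,
             stringsAsFactors = FALSE)
}

#' Summarise annotation categories
#'
#' Counts and percentage per category, SNPs and InDels tabulated
#' separately. Percentages are raw roundings to 2 decimals (they need not
#' sum to exactly 100 after rounding; rare categories can print 0.00).
#'
#' @param ann output of [classify_variants()].
#' @return data frame `class`, `category`, `count`, `pct`.
#' @export
summarize_annotations <- function(ann) {
  if (!nrow(ann))
    return(data.frame(class = character(0), category = character(0),
                      count = integer(0), pct = numeric(0)))
  do.call(rbind, lapply(split(ann, ann$class), function(sub) {
    tb <- sort(table(sub$category), decreasing = TRUE)
    data.frame(class = sub$class[1L], category = names(tb),
               count = as.integer(tb),
               pct = round(100 * as.integer(tb) / nrow(sub), 2L),
               row.names = NULL)
  }))
}
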