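# Readers and writers for the standard inputs: VCF (via vcfR), GFF3 (via
# rtracklayer), FASTA (via Biostrings), and the documented TSV layouts for
# chip genotypes, known sites, cohort genotype counts and gene-term maps.

#' Read a multi-sample VCF into a variant set
#'
#' Records are kept in file order; multiallelic records stay one row.
#' Missing genotypes are preserved as `"./."`.  Only the GT field is used.
#'
#' @param path VCF 4.x file (plain or bgzipped).
#' @return a [variant_set()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
  fix <- v@fix
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L) {
    stop("VCF has no genotype columns: ", path)
  }
  fmt <- gt_raw[, 1L]
  no_gt <- !grepl("(^|:)GT(:|$)", fmt)
  if (any(no_gt)) {
    stop(sprintf("record %d has no GT entry in FORMAT", which(no_gt)[1]))
  }
  gt <- gt_raw[, -1L, drop = FALSE]
  # GT is required to be the first sub-field when present (VCF 4.x)
  gt[] <- sub(":.*$", "", gt)
  gt[is.na(gt) | gt == "."] <- "./."
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    stop(sprintf("malformed POS in record %d of %s", which(is.na(pos))[1], path))
  }
  variants <- data.frame(chrom = fix[, "CHROM"], pos = pos,
                         id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
                         ref = toupper(fix[, "REF"]), alt = toupper(fix[, "ALT"]),
                         stringsAsFactors = FALSE)
  variant_set(variants, gt)
}

#' Write a variant set as VCF 4.2
#'
#' @param vset a [variant_set()].
#' @param path output path.
#' @param contigs optional named integer vector of chromosome lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vset, path, contigs = NULL) {
  v <- vset$variants
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs)) {
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs))
           },
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vset$samples), collapse = "\t"))
  gt_cols <- apply(vset$gt, 1L, paste, collapse = "\t")
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".", ".", "GT",
                gt_cols, sep = "\t")
  writeLines(c(hdr, if (nrow(v)) body), path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Resolves the gene/transcript/exon/CDS hierarchy through `Parent`
#' attributes and returns validated transcript models.  Transcript biotype is
#' taken from a `biotype` attribute when present, else inferred
#' (`protein_coding` when the transcript has CDS features, otherwise
#' `other_noncoding`).
#'
#' @param path GFF3 file.
#' @return named list of [transcript_model()] objects.
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::import(path)
  df <- as.data.frame(g)
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p)) as.character(p[1]) else NA_character_
  }, character(1))
  tx_rows <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (!nrow(tx_rows)) stop("no mRNA/transcript features in ", path)
  models <- lapply(seq_len(nrow(tx_rows)), function(i) {
    tid <- tx_rows$ID[i]
    kids <- df[!is.na(df$Parent) & df$Parent == tid, , drop = FALSE]
    exons <- kids[kids$type == "exon", c("start", "end")]
    cds <- kids[kids$type == "CDS", c("start", "end")]
    strand <- as.character(tx_rows$strand[i])
    if (!strand %in% c("+", "-")) {
      stop("transcript ", tid, " has unknown strand '", strand, "'")
    }
    biotype <- tx_rows$biotype[i] %||% NA_character_
    if (is.na(biotype)) {
      biotype <- if (nrow(cds)) "protein_coding" else "other_noncoding"
    }
    transcript_model(transcript_id = tid,
                     gene_id = tx_rows$Parent[i] %||% tid,
                     chrom = as.character(tx_rows$seqnames[i]),
                     strand = strand, biotype = biotype,
                     exons = exons[order(exons$start), , drop = FALSE],
                     cds = cds[order(cds$start), , drop = FALSE])
  })
  names(models) <- tx_rows$ID
  models
}

#' Write transcript models as GFF3
#'
#' @param models list of [transcript_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  genes <- split(models, vapply(models, function(m) m$gene_id, character(1)))
  for (gid in names(genes)) {
    txs <- genes[[gid]]
    span <- range(unlist(lapply(txs, function(m) unlist(m$exons))))
    chrom <- txs[[1]]$chrom; strand <- txs[[1]]$strand
    lines <- c(lines, paste(chrom, "lofscreen", "gene", span[1], span[2], ".",
                            strand, ".", paste0("ID=", gid), sep = "\t"))
    for (m in txs) {
      tspan <- range(unlist(m$exons))
      ftype <- if (m$biotype == "protein_coding") "mRNA" else "transcript"
      lines <- c(lines, paste(chrom, "lofscreen", ftype, tspan[1], tspan[2],
                              ".", strand, ".",
                              sprintf("ID=%s;Parent=%s;biotype=%s",
                                      m$transcript_id, gid, m$biotype),
                              sep = "\t"))
      lines <- c(lines, paste(chrom, "lofscreen", "exon", m$exons$start,
                              m$exons$end, ".", strand, ".",
                              paste0("Parent=", m$transcript_id), sep = "\t"))
      if (nrow(m$cds)) {
        lines <- c(lines, paste(chrom, "lofscreen", "CDS", m$cds$start,
                                m$cds$end, ".", strand, "0",
                                paste0("Parent=", m$transcript_id), sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a reference FASTA
#'
#' @param path FASTA file.
#' @return named [Biostrings::DNAStringSet]; names are truncated at the first
#'   whitespace.
#' @export
read_reference <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  names(s) <- sub("\\s.*$", "", names(s))
  s
}

#' Read per-sample chip genotypes
#'
#' TSV with header `chrom pos alleleA alleleB genotype` (genotype in
#' `AA/AB/BB/missing`).  Records with a missing chromosome or position and
#' records on excluded sequences (mitochondrial, unplaced scaffolds) are
#' dropped; the number dropped is reported via [message()].
#'
#' @param path chip TSV.
#' @param exclude_chroms chromosome names to drop (default `"MT"`).
#' @param valid_chroms optional whitelist; when given, records on any other
#'   sequence are dropped as unplaced.
#' @return data.frame of retained chip records.
#' @export
read_chip_genotypes <- function(path, exclude_chroms = "MT",
                                valid_chroms = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "alleleA", "alleleB", "genotype")
  if (!all(need %in% names(d))) {
    stop("chip file lacks required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  n0 <- nrow(d)
  keep <- !is.na(d$chrom) & d$chrom != "" & !is.na(d$pos) &
    !(d$chrom %in% exclude_chroms)
  if (!is.null(valid_chroms)) keep <- keep & d$chrom %in% valid_chroms
  d <- d[keep, , drop = FALSE]
  if (n0 - nrow(d) > 0) {
    message(sprintf("read_chip_genotypes: dropped %d of %d records (excluded or unplaced)",
                    n0 - nrow(d), n0))
  }
  if (anyDuplicated(paste(d$chrom, d$pos))) {
    stop("duplicate chip position in ", path)
  }
  d$pos <- as.integer(d$pos)
  d
}

#' Read a known-sites set
#'
#' TSV with header `chrom pos ref alt id`.  Novelty in this package is an
#' exact match of the normalized `(chrom, pos, ref, alt)` key against this
#' set; the ID column of the variant VCF plays no role.
#'
#' @param path known-sites TSV.
#' @return data.frame with an additional `key` column.
#' @export
read_known_sites <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(d)))
  d$pos <- as.integer(d$pos)
  d$key <- variant_key(d$chrom, d$pos, d$ref, d$alt)
  d
}

#' Read cohort genotype counts
#'
#' Accepts either a genotype-count TSV with header
#' `chrom pos ref alt n_hom_ref n_het n_hom_alt n_missing`, or a multi-sample
#' VCF whose genotypes are collapsed to counts per site (any ALT allele
#' counts as the variant allele).
#'
#' @param path cohort TSV or VCF.
#' @return data.frame of per-variant genotype counts with a `key` column.
#' @export
read_cohort <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    vs <- read_vcf(path)
    counts <- t(apply(vs$gt, 1L, function(row) {
      g <- parse_genotypes(row)
      cls <- gt_class(g[, 1], g[, 2])
      c(sum(cls == "hom_ref"), sum(cls == "het"),
        sum(cls == "hom_alt"), sum(cls == "missing"))
    }))
    alt1 <- sub(",.*$", "", vs$variants$alt)
    d <- data.frame(chrom = vs$variants$chrom, pos = vs$variants$pos,
                    ref = vs$variants$ref, alt = alt1,
                    n_hom_ref = counts[, 1], n_het = counts[, 2],
                    n_hom_alt = counts[, 3], n_missing = counts[, 4],
                    stringsAsFactors = FALSE)
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt",
              "n_hom_ref", "n_het", "n_hom_alt", "n_missing")
    stopifnot(all(need %in% names(d)))
  }
  if (any(d$n_hom_ref < 0 | d$n_het < 0 | d$n_hom_alt < 0 | d$n_missing < 0)) {
    stop("negative cohort genotype count")
  }
  d$key <- variant_key(d$chrom, d$pos, d$ref, d$alt)
  d
}

#' Read a gene-to-term annotation map
#'
#' TSV with header `gene_id term_id`, one row per annotation.
#'
#' @param path TSV path.
#' @return data.frame with columns `gene_id`, `term_id`.
#' @export
read_term_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "term_id") %in% names(d)))
  d
}

# fixed-format TSV writer used for all report tables
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
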