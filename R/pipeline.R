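# End-to-end orchestration: read inputs, annotate, summarize, concordance,
# LoF screen, enrichment; write one TSV per report table.

#' Run the full analysis pipeline
#'
#' Reads the study inputs, runs consequence annotation, the cohort summary,
#' per-sample chip concordance, the LoF screen (zygosity partition, cohort
#' homozygote-absence filter, cross-dataset consistency, MAF spectrum,
#' hotspot densities) and term enrichment, and writes one TSV per report:
#' `summary.tsv`, `functional_classes.tsv`, `density.tsv`,
#' `concordance.tsv`, `lof_records.tsv`, `lof_report.tsv`,
#' `maf_spectrum.tsv`, `hotspot_regions.tsv`, `enrichment.tsv`, plus the
#' serialized configuration `run_config.yaml`.  Optional stages (chip,
#' cohort, other call set, term map) are skipped when their input is `NULL`.
#' On a stage error all partial outputs are removed and the error is
#' re-thrown with the stage name.
#'
#' @param vcf,gff,fasta paths to the call set, gene models and reference.
#' @param out_dir report directory (created).
#' @param known optional known-sites TSV path.
#' @param chip optional named character vector of per-sample chip TSV paths.
#' @param cohort optional cohort genotype path (TSV or VCF).
#' @param other optional cross-check call-set TSV path.
#' @param term_map optional gene-to-term TSV path.
#' @param exclude_chroms chromosomes dropped from chip records.
#' @param hotspot_k hotspot threshold in SD units.
#' @param maf_cutoff MAF spectrum cutoff.
#' @param bin_bp density bin width.
#' @return invisible list of the computed objects.
#' @export
run_pipeline <- function(vcf, gff, fasta, out_dir, known = NULL, chip = NULL,
                         cohort = NULL, other = NULL, term_map = NULL,
                         exclude_chroms = "MT", hotspot_k = 3,
                         maf_cutoff = 0.05, bin_bp = 1e6) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(d, name) {
    p <- file.path(out_dir, name)
    write_tsv(d, p)
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  res <- tryCatch({
    stage <- "read_inputs"
    vset <- read_vcf(vcf)
    models <- read_gene_models(gff)
    ref_seqs <- read_reference(fasta)
    chrom_lengths <- stats::setNames(Biostrings::width(ref_seqs),
                                     names(ref_seqs))
    known_keys <- if (!is.null(known)) read_known_sites(known)$key else character(0)

    stage <- "annotate"
    alleles <- normalize_alleles(split_alleles(vset), ref_seqs)
    idx <- build_annotation_index(models, ref_seqs)
    ann <- annotate_variants(alleles, index = idx)
    pv <- ann$per_variant
    pv$vtype <- variant_type(pv$ref, pv$alt)
    fc <- as.data.frame.matrix(table(
      factor(pv$most_severe, levels = SEVERITY_ORDER),
      factor(pv$vtype, levels = c("SNP", "indel", "MNP"))))
    fc <- data.frame(functional_class = rownames(fc), fc, row.names = NULL)
    emit(fc, "functional_classes.tsv")

    stage <- "summarize"
    summ <- summarize_variants(vset, known_keys, ref_seqs = NULL)
    emit(summ$table, "summary.tsv")
    emit(variant_density(vset$variants$chrom, vset$variants$pos,
                         chrom_lengths, bin_bp), "density.tsv")
    cds_ind <- pv[pv$vtype == "indel" &
                    pv$most_severe %in% c("frameshift", "inframe_deletion",
                                          "inframe_insertion"), ]
    all_ind <- pv[pv$vtype == "indel", ]
    three_n <- if (nrow(cds_ind) && nrow(all_ind)) {
      three_n_enrichment(indel_length(cds_ind$ref, cds_ind$alt),
                         indel_length(all_ind$ref, all_ind$alt))
    } else NULL
    if (!is.null(three_n)) {
      emit(data.frame(three_n[c("proportion_3n_cds",
                                "proportion_3n_background", "k", "n",
                                "p_value")]), "three_n.tsv")
    }

    stage <- "concordance"
    conc <- NULL
    if (!is.null(chip)) {
      conc <- do.call(rbind, lapply(names(chip), function(s) {
        ch <- read_chip_genotypes(chip[[s]], exclude_chroms = exclude_chroms,
                                  valid_chroms = names(ref_seqs))
        concordance_report(ch, vset, s, ref_seqs)
      }))
      emit(as.data.frame(conc), "concordance.tsv")
    }

    stage <- "lof_screen"
    lof <- extract_lof(pv, vset, known_keys)
    genes <- per_gene_counts(lof)
    filt <- ms <- hot <- NULL
    if (!is.null(cohort)) {
      filt <- absence_filter(lof, read_cohort(cohort))
      if (!is.null(other)) {
        oth <- utils::read.delim(other, stringsAsFactors = FALSE)
        filt$cross_dataset <- cross_dataset_consistency(filt, oth)
      }
      ms <- maf_spectrum(filt[filt$passes_absence_filter, , drop = FALSE],
                         cutoff = maf_cutoff)
      emit(ms, "maf_spectrum.tsv")
      emit(filt, "lof_records.tsv")
      report <- lof_report_table(lof, filt)
      emit(report, "lof_report.tsv")
    } else {
      emit(lof, "lof_records.tsv")
    }
    hot <- hotspot_density(lof$chrom, lof$pos, chrom_lengths,
                           bin_bp = bin_bp, k_sd = hotspot_k)
    emit(hot$track, "lof_density.tsv")
    emit(hot$regions, "hotspot_regions.tsv")

    stage <- "enrichment"
    enr <- NULL
    if (!is.null(term_map) && nrow(lof)) {
      enr <- test_term_enrichment(unique(lof$gene_id), read_term_map(term_map))
      emit(enr, "enrichment.tsv")
    }

    stage <- "finalize"
    cfg <- list(vcf = vcf, gff = gff, fasta = fasta, known = known,
                chip = as.list(chip %||% list()), cohort = cohort,
                other = other, term_map = term_map,
                exclude_chroms = exclude_chroms, hotspot_k = hotspot_k,
                maf_cutoff = maf_cutoff, bin_bp = bin_bp)
    yaml::write_yaml(cfg, file.path(out_dir, "run_config.yaml"))
    list(summary = summ, functional_classes = fc, three_n = three_n,
         concordance = conc, lof = lof, lof_filtered = filt,
         per_gene = genes, maf_spectrum = ms, hotspots = hot,
         enrichment = enr, annotation = ann)
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# Table-6-style report: one row per LoF class plus a total row
lof_report_table <- function(lof, filt) {
  classes <- c("stop_gained", "splice_site", "frameshift")
  rows <- lapply(c(classes, "total"), function(cl) {
    sel <- if (cl == "total") rep(TRUE, nrow(lof)) else lof$lof_class == cl
    fsel <- if (cl == "total") rep(TRUE, nrow(filt)) else filt$lof_class == cl
    ret <- fsel & filt$passes_absence_filter
    data.frame(
      lof_class = cl,
      total = sum(sel),
      novel = sum(lof$novel[sel]),
      gene_count = length(unique(lof$gene_id[sel])),
      hom_all_samples = sum(lof$zygosity_partition[sel] == "hom_all_samples"),
      het_in_ge1_sample = sum(lof$zygosity_partition[sel] == "het_in_ge1_sample"),
      absent_homozygote = sum(ret),
      consistent = if ("cross_dataset" %in% names(filt))
        sum(filt$cross_dataset[ret] == "consistent") else NA_integer_,
      inconsistent = if ("cross_dataset" %in% names(filt))
        sum(filt$cross_dataset[ret] == "inconsistent") else NA_integer_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
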