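# Gene-set over/under-representation of a study gene list against a
# gene-to-term annotation map, by two-sided Fisher exact test with
# Bonferroni correction.

#' Term over/under-representation test
#'
#' For each term, a two-sided Fisher exact (hypergeometric) test of the
#' study-set count against the background; direction is the sign of
#' observed minus expected.  The background universe is every gene in the
#' annotation map; study genes absent from the map are dropped and logged.
#' Bonferroni correction is over the number of terms tested (terms with a
#' nonzero background count).
#'
#' @param study_genes character vector of gene ids.
#' @param term_map data.frame with `gene_id`, `term_id`
#'   ([read_term_map()]).
#' @return data.frame with one row per term: `term_id`,
#'   `n_study_with_term`, `n_study`, `n_background_with_term`,
#'   `n_background`, `direction`, `p_raw`, `p_bonferroni`.
#' @export
test_term_enrichment <- function(study_genes, term_map) {
  if (!length(study_genes)) stop("empty study gene set")
  background <- unique(term_map$gene_id)
  study <- unique(study_genes)
  absent <- setdiff(study, background)
  if (length(absent)) {
    message(sprintf("test_term_enrichment: %d of %d study genes absent from the annotation map",
                    length(absent), length(study)))
  }
  study <- intersect(study, background)
  if (!length(study)) stop("no study gene is present in the annotation map")
  N <- length(background); n <- length(study)
  terms <- split(term_map$gene_id, term_map$term_id)
  res <- lapply(names(terms), function(tid) {
    tg <- unique(terms[[tid]])
    K <- length(tg)
    if (K == 0L) return(NULL)
    k <- length(intersect(study, tg))
    tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    data.frame(term_id = tid, n_study_with_term = k, n_study = n,
               n_background_with_term = K, n_background = N,
               direction = if (k >= n * K / N) "over" else "under",
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out[order(out$p_raw), ]
}
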