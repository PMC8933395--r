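# m7G-tRNA-decoded codon counting per mRNA and the TE-class / gene-set
# comparisons.

#' Count m7G-tRNA-decoded codons in one CDS
#'
#' Counts frame-0 codons of the CDS that belong to the m7G-decoded codon
#' set; stop codons are never counted (they are removed from the set).
#'
#' @param cds CDS string, length divisible by 3.
#' @param m7g_codons non-empty character vector of m7G-tRNA-decoded codons.
#' @return list with `m7g_codon_count`, `cds_codons` (total codons) and
#'   `density` (count / cds_codons).
#' @examples
#' count_m7g_codons("GTTAAGGTC", c("GTT", "GTC", "GTA", "AAG"))
#' @export
count_m7g_codons <- function(cds, m7g_codons) {
  if (length(m7g_codons) == 0) m7g_stop("empty m7G codon set", "input")
  m7g_codons <- setdiff(toupper(m7g_codons), STOP_CODONS)
  codons <- split_codons(toupper(cds))
  cnt <- sum(codons %in% m7g_codons)
  list(m7g_codon_count = cnt, cds_codons = length(codons),
       density = if (length(codons) > 0) cnt / length(codons) else NA_real_)
}

#' Per-gene m7G codon-count records
#'
#' @param genes a [gene_models()] table.
#' @param m7g_codons m7G-decoded codon set.
#' @return data frame: `gene`, `m7g_codon_count`, `cds_codons`, `density`.
#' @export
codon_count_records <- function(genes, m7g_codons) {
  recs <- lapply(genes$cds, count_m7g_codons, m7g_codons = m7g_codons)
  data.frame(gene = genes$id,
             m7g_codon_count = vapply(recs, `[[`, numeric(1), "m7g_codon_count"),
             cds_codons = vapply(recs, `[[`, numeric(1), "cds_codons"),
             density = vapply(recs, `[[`, numeric(1), "density"),
             stringsAsFactors = FALSE)
}

#' Compare m7G codon counts between TE classes
#'
#' Two-sided Mann-Whitney U tests of the per-mRNA m7G-decoded codon count
#' between TE classes (down vs non, up vs non, down vs up by default),
#' with per-class medians and sizes.  A density-based variant (count per
#' codon) runs alongside when `density = TRUE`.
#'
#' @param records output of [codon_count_records()].
#' @param te a `te_results` data frame ([te_table()]).
#' @param comparisons list of length-2 character vectors of class labels.
#' @param density also test the length-normalized density?
#' @return list with `tests` (data frame: comparison, statistic used,
#'   U, p, medians, class sizes) and `class_medians`.
#' @export
compare_counts_by_te_class <- function(records, te,
                                       comparisons = list(c("down", "non"),
                                                          c("up", "non"),
                                                          c("down", "up")),
                                       density = FALSE) {
  merged <- merge(records, te[, c("gene", "te_class")], by = "gene")
  stat_cols <- c("m7g_codon_count", if (density) "density")
  res <- list()
  for (cmp in comparisons) {
    for (cls in cmp) {
      if (!any(merged$te_class == cls))
        m7g_stop(paste0("TE class '", cls, "' is empty"), "input")
    }
    a <- merged[merged$te_class == cmp[1], ]
    b <- merged[merged$te_class == cmp[2], ]
    for (sc in stat_cols) {
      t <- mann_whitney_u(a[[sc]], b[[sc]])
      res[[length(res) + 1L]] <- data.frame(
        comparison = paste(cmp, collapse = "_vs_"), statistic = sc,
        U = t$U, p = t$p,
        median_1 = stats::median(a[[sc]]), median_2 = stats::median(b[[sc]]),
        n_1 = nrow(a), n_2 = nrow(b), stringsAsFactors = FALSE)
    }
  }
  cm <- stats::aggregate(m7g_codon_count ~ te_class, merged, stats::median)
  list(tests = do.call(rbind, res), class_medians = cm)
}

#' Gene-set comparison of m7G codon counts among TE-down mRNAs
#'
#' Compares the m7G-decoded codon counts of gene-set members that are
#' TE-down against all other detected mRNAs (the universe minus those
#' members), by a two-sided Mann-Whitney U test.
#'
#' @param records output of [codon_count_records()].
#' @param te a `te_results` data frame; the default universe is every
#'   gene passing the TE filter (class != "filtered").
#' @param geneset character vector of member gene ids (e.g. one set from
#'   [read_gmt()]).
#' @param universe optional explicit universe of gene ids.
#' @return list with `test`, `median_members`, `median_others`,
#'   `n_members`, `n_others`.
#' @export
geneset_codon_comparison <- function(records, te, geneset, universe = NULL) {
  if (is.null(universe)) universe <- te$gene[te$te_class != "filtered"]
  geneset <- unique(geneset)
  down <- te$gene[te$te_class == "down"]
  members <- intersect(intersect(geneset, universe), down)
  others <- setdiff(universe, members)
  if (length(members) == 0)
    m7g_stop("gene set has no TE-down members in the universe", "input")
  if (length(others) == 0)
    m7g_stop("gene-set complement in the universe is empty", "input")
  cnt <- stats::setNames(records$m7g_codon_count, records$gene)
  a <- cnt[members]; b <- cnt[others]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0)
    m7g_stop("no codon-count records for one of the groups", "input")
  t <- mann_whitney_u(a, b)
  list(test = t, median_members = stats::median(a),
       median_others = stats::median(b),
       n_members = length(a), n_others = length(b))
}
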