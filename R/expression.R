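# tRNA expression statistics: isotype aggregation, depth and
# relative-to-mean normalization, and the m7G vs non-m7G class comparison.

#' Construct a tRNA count matrix
#'
#' @param counts non-negative integer matrix, rows = isodecoders (or
#'   isotypes), columns = samples; must carry unique dimnames.
#' @param condition character vector of condition labels, one per column
#'   (e.g. `"control"` / `"kd"`).
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    m7g_stop("count matrix must have row and column names", "input")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    m7g_stop("duplicate row or column ids", "input")
  if (length(condition) != ncol(counts))
    m7g_stop("one condition label per column is required", "input")
  if (any(counts < 0)) m7g_stop("negative counts", "input")
  structure(list(counts = counts,
                 condition = stats::setNames(as.character(condition),
                                             colnames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples (", paste(unique(x$condition), collapse = "/"), ")\n")
  invisible(x)
}

#' Aggregate isodecoder counts to isotypes
#'
#' Rows are summed within the isotype key (amino acid + anticodon) of the
#' gene each isodecoder belongs to; column sums are preserved.
#'
#' @param mat a [count_matrix()] over isodecoders.
#' @param genes a `trna_reference` data frame mapping `isodecoder_id` to
#'   `isotype_key`.
#' @return a [count_matrix()] over isotype keys.
#' @export
aggregate_isotypes <- function(mat, genes) {
  ids <- rownames(mat$counts)
  idx <- match(ids, genes$isodecoder_id)
  missing <- ids[is.na(idx) | is.na(genes$isotype_key[idx])]
  if (length(missing) > 0)
    m7g_stop(paste0("row id(s) without an isotype mapping: ",
                    paste(missing, collapse = ", ")), "input")
  keys <- genes$isotype_key[idx]
  agg <- rowsum(mat$counts, group = keys)
  count_matrix(agg[order(rownames(agg)), , drop = FALSE],
               unname(mat$condition))
}

#' Counts-per-million depth normalization
#'
#' @param mat a [count_matrix()]; every column sum must be positive.
#' @return a [count_matrix()] with real-valued entries; each column sums
#'   to 1e6.
#' @export
cpm_normalize <- function(mat) {
  cs <- colSums(mat$counts)
  if (any(cs <= 0)) m7g_stop("column with zero total count", "degenerate_input")
  out <- mat
  out$counts <- sweep(mat$counts, 2, cs, "/") * 1e6
  out
}

#' log2 expression relative to the overall mean
#'
#' Each value v of a per-isotype vector (spanning all samples of both
#' groups) maps to `log2(v / mean(v))`.  Zeros would give -Inf; with
#' `floor = TRUE` (default) they are raised to half the smallest nonzero
#' value first.
#'
#' @param values numeric vector with positive mean.
#' @param floor replace zeros by half the smallest nonzero value?
#' @return numeric vector; the equally-weighted mean of `2^result` is 1
#'   (exactly so when no flooring was needed).
#' @examples
#' log2_relative_to_mean(c(4, 1))
#' @export
log2_relative_to_mean <- function(values, floor = TRUE) {
  if (any(values < 0)) m7g_stop("negative expression values", "input")
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    m7g_stop("mean of the vector is not positive", "degenerate_input")
  if (floor && any(values == 0)) {
    nz <- min(values[values > 0])
    values[values == 0] <- nz / 2
  }
  log2(values / m)
}

#' Normalize an expression matrix for the m7G/non-m7G comparison
#'
#' CPM depth normalization, then [log2_relative_to_mean()] applied to each
#' isotype row across all samples of both groups.
#'
#' @param mat a [count_matrix()] (isotype rows).
#' @param floor passed to [log2_relative_to_mean()].
#' @return a [count_matrix()] of log2 relative expression values.
#' @export
normalize_expression_matrix <- function(mat, floor = TRUE) {
  cpm <- cpm_normalize(mat)
  out <- cpm
  out$counts <- t(apply(cpm$counts, 1, log2_relative_to_mean, floor = floor))
  dimnames(out$counts) <- dimnames(cpm$counts)
  out
}

#' Mann-Whitney U test
#'
#' `U = #{(i, j): a_i > b_j} + #ties / 2`.  The p-value is exact (by
#' enumeration of the permutation distribution) when `min(n, m) <= 8` and
#' there are no ties across the pooled sample, and otherwise uses the
#' normal approximation with tie and continuity corrections.
#'
#' @param a,b non-empty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with elements `U`, `p`, `n` (= `length(a)`), `m`
#'   (= `length(b)`) and `exact` (logical).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(a, b, alternative = c("two.sided", "less",
                                                 "greater")) {
  alternative <- match.arg(alternative)
  if (length(a) == 0 || length(b) == 0)
    m7g_stop("both samples must be non-empty", "input")
  ties <- any(duplicated(c(a, b)))
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       n = length(a), m = length(b), exact = exact)
}

#' Compare m7G vs non-m7G tRNA expression change under knockdown
#'
#' For each isotype, the replicate-mean normalized expression difference
#' (knockdown minus control) is computed; the m7G-class differences are
#' then compared to the non-m7G-class differences by a two-sided
#' Mann-Whitney U test.
#'
#' @param norm a [count_matrix()] of normalized values (e.g. from
#'   [normalize_expression_matrix()]).
#' @param m7g_isotypes character vector of isotype keys in the m7G class;
#'   all other rows form the non-m7G class.  Both classes must be
#'   non-empty.
#' @param conditions length-2 character vector `c(control, knockdown)`
#'   naming the condition labels.
#' @param replicate_mean average replicates before differencing (default)
#'   or difference per replicate pair (paired by order within condition).
#' @return list with `per_isotype` (data frame: isotype, m7g, diff),
#'   `test` ([mann_whitney_u()] result), `median_m7g`, `median_non`,
#'   and `direction` (`"down"`, `"up"` or `"none"` for the m7G class).
#' @export
compare_m7g_vs_non <- function(norm, m7g_isotypes,
                               conditions = c("control", "kd"),
                               replicate_mean = TRUE) {
  keys <- rownames(norm$counts)
  is_m7g <- keys %in% m7g_isotypes
  if (!any(is_m7g) || all(is_m7g))
    m7g_stop("both the m7G and the non-m7G class must be non-empty", "input")
  ctrl_cols <- which(norm$condition == conditions[1])
  kd_cols <- which(norm$condition == conditions[2])
  if (length(ctrl_cols) == 0 || length(kd_cols) == 0)
    m7g_stop("both conditions must have at least one sample", "input")
  if (replicate_mean) {
    d <- rowMeans(norm$counts[, kd_cols, drop = FALSE]) -
      rowMeans(norm$counts[, ctrl_cols, drop = FALSE])
    per <- data.frame(isotype = keys, m7g = is_m7g, diff = unname(d),
                      stringsAsFactors = FALSE)
  } else {
    r <- min(length(ctrl_cols), length(kd_cols))
    d <- norm$counts[, kd_cols[seq_len(r)], drop = FALSE] -
      norm$counts[, ctrl_cols[seq_len(r)], drop = FALSE]
    per <- data.frame(isotype = rep(keys, r), m7g = rep(is_m7g, r),
                      diff = as.vector(d), stringsAsFactors = FALSE)
  }
  test <- mann_whitney_u(per$diff[per$m7g], per$diff[!per$m7g])
  med_m <- stats::median(per$diff[per$m7g])
  med_n <- stats::median(per$diff[!per$m7g])
  list(per_isotype = per, test = test,
       median_m7g = med_m, median_non = med_n,
       direction = if (med_m < med_n) "down" else if (med_m > med_n) "up"
                   else "none")
}

#' LC-MS m7G modification level
#'
#' Ratio of the m7G nucleoside's normalized peak area to the summed
#' normalized peak areas of all detected nucleosides.
#'
#' @param peak_areas named non-negative numeric vector of normalized peak
#'   areas; the m7G entry is looked up by `m7g_name` and treated as 0 when
#'   absent.
#' @param m7g_name name of the m7G entry, default `"m7G"`.
#' @return m7G level in `[0, 1]`.
#' @examples
#' lcms_m7g_level(c(m7G = 2, C = 50, G = 48))
#' @export
lcms_m7g_level <- function(peak_areas, m7g_name = "m7G") {
  if (length(peak_areas) == 0)
    m7g_stop("peak table contains no nucleosides", "empty_input")
  if (any(peak_areas < 0)) m7g_stop("negative peak area", "input")
  total <- sum(peak_areas)
  if (total == 0) m7g_stop("total peak area is zero", "degenerate_input")
  m7g <- if (m7g_name %in% names(peak_areas)) peak_areas[[m7g_name]] else 0
  m7g / total
}
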