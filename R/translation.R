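# Translation efficiency from input/polysome/footprint libraries, TE
# classification, and codon-level ribosome occupancy / pause statistics.

#' Construct a gene (CDS) model table
#'
#' @param id gene ids.
#' @param cds CDS sequences (A/C/G/T, length divisible by 3).
#' @param transcript_length transcript lengths in nt for FPKM; defaults to
#'   the CDS length.
#' @return a `gene_models` data frame with columns `id`, `cds`,
#'   `cds_length`, `transcript_length`.
#' @export
gene_models <- function(id, cds, transcript_length = NULL) {
  cds <- toupper(cds)
  if (any(nchar(cds) %% 3 != 0))
    m7g_stop("CDS length not divisible by 3", "input")
  if (any(grepl("[^ACGT]", cds)))
    m7g_stop("CDS contains non-DNA characters", "input")
  if (anyDuplicated(id)) m7g_stop("duplicate gene ids", "input")
  cl <- nchar(cds)
  if (is.null(transcript_length)) transcript_length <- cl
  if (any(transcript_length < cl))
    m7g_stop("transcript_length shorter than the CDS", "input")
  out <- data.frame(id = as.character(id), cds = cds, cds_length = cl,
                    transcript_length = as.integer(transcript_length),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Construct a per-gene count library
#'
#' @param counts named non-negative numeric vector of per-gene counts.
#' @param type library type: `"input_rna"`, `"polysome"` or
#'   `"ribo_footprint"`.
#' @param condition condition label (e.g. `"control"`, `"kd"`).
#' @param total positive library total; defaults to `sum(counts)` and may
#'   exceed it (multi-feature libraries).
#' @param id library id.
#' @return an object of class `library_counts`.
#' @export
library_counts <- function(counts, type = c("input_rna", "polysome",
                                            "ribo_footprint"),
                           condition, total = NULL, id = NULL) {
  type <- match.arg(type)
  if (is.null(names(counts))) m7g_stop("counts must be named by gene", "input")
  if (any(counts < 0)) m7g_stop("negative counts", "input")
  if (is.null(total)) total <- sum(counts)
  if (total <= 0) m7g_stop("library total must be positive", "input")
  if (total < sum(counts))
    m7g_stop("library total smaller than the summed counts", "input")
  structure(list(id = if (is.null(id)) paste(type, condition, sep = "_") else id,
                 type = type, condition = condition,
                 counts = counts, total = total),
            class = "library_counts")
}

#' Fragments per kilobase per million (FPKM)
#'
#' `count / ((length_nt / 1000) * (library_total / 1e6))`; invariant under
#' joint scaling of count and total.
#'
#' @param count read count(s).
#' @param length_nt feature length(s) in nt, positive.
#' @param library_total library total, positive.
#' @return FPKM value(s).
#' @examples
#' fpkm(10, 1000, 1e6)
#' @export
fpkm <- function(count, length_nt, library_total) {
  if (any(length_nt <= 0)) m7g_stop("feature length must be positive", "input")
  if (any(library_total <= 0)) m7g_stop("library total must be positive", "input")
  count / ((length_nt / 1000) * (library_total / 1e6))
}

#' Translation efficiency
#'
#' The ratio of ribosome-associated FPKM (polysome or CDS footprint) to
#' input mRNA FPKM; undefined (`NA`) when the input FPKM is zero, in which
#' case the gene is filtered downstream.
#'
#' @param fpkm_translated,fpkm_input non-negative FPKM value(s).
#' @return TE value(s), `NA` where the input FPKM is 0.
#' @export
translation_efficiency <- function(fpkm_translated, fpkm_input) {
  if (any(fpkm_translated < 0) || any(fpkm_input < 0))
    m7g_stop("negative FPKM", "input")
  ifelse(fpkm_input > 0, fpkm_translated / fpkm_input, NA_real_)
}

#' Classify per-gene TE change between control and knockdown
#'
#' `filtered` if either TE is undefined or an input-FPKM floor fails;
#' otherwise `down` when `log2(te_kd / te_control) <= -lfc_threshold`,
#' `up` when `>= +lfc_threshold`, `non` in between.
#'
#' @param te_control,te_kd TE values (may be `NA` = undefined).
#' @param input_fpkm_control,input_fpkm_kd input FPKMs for the expression
#'   floor; pass `NULL` to skip the floor.
#' @param lfc_threshold |log2 fold change| needed to call up/down, default 1.
#' @param min_input_fpkm expression floor on the input FPKM, default 1.
#' @return character vector over `{"up", "down", "non", "filtered"}`.
#' @export
classify_te <- function(te_control, te_kd,
                        input_fpkm_control = NULL, input_fpkm_kd = NULL,
                        lfc_threshold = 1, min_input_fpkm = 1) {
  if (lfc_threshold <= 0 || min_input_fpkm <= 0)
    m7g_stop("thresholds must be positive", "input")
  n <- max(length(te_control), length(te_kd))
  te_control <- rep_len(te_control, n); te_kd <- rep_len(te_kd, n)
  filtered <- is.na(te_control) | is.na(te_kd) | te_control <= 0 | te_kd <= 0
  if (!is.null(input_fpkm_control))
    filtered <- filtered | rep_len(input_fpkm_control, n) < min_input_fpkm
  if (!is.null(input_fpkm_kd))
    filtered <- filtered | rep_len(input_fpkm_kd, n) < min_input_fpkm
  lfc <- log2(te_kd / te_control)
  out <- rep("non", n)
  out[!filtered & lfc <= -lfc_threshold] <- "down"
  out[!filtered & lfc >= lfc_threshold] <- "up"
  out[filtered] <- "filtered"
  out
}

#' Per-gene TE table for a condition pair
#'
#' Runs the full FPKM -> TE -> classification pipeline for one input +
#' translated library per condition.  Polysome-seq and Ribo-seq share this
#' code path: the translated library's FPKM uses the CDS length for
#' `ribo_footprint` libraries and the transcript length otherwise, and the
#' input FPKM uses `input_length` (default `"transcript"`).
#'
#' @param genes a [gene_models()] table.
#' @param input_control,input_kd input-RNA [library_counts()].
#' @param trans_control,trans_kd polysome or footprint [library_counts()].
#' @param lfc_threshold,min_input_fpkm passed to [classify_te()].
#' @param input_length `"transcript"` (default) or `"cds"`: length used
#'   for the input FPKM.
#' @return a `te_results` data frame with per-gene FPKMs, TEs,
#'   `log2_ratio` and `te_class`.
#' @export
te_table <- function(genes, input_control, input_kd, trans_control, trans_kd,
                     lfc_threshold = 1, min_input_fpkm = 1,
                     input_length = c("transcript", "cds")) {
  input_length <- match.arg(input_length)
  if (input_control$type != "input_rna" || input_kd$type != "input_rna")
    m7g_stop("input libraries must have type 'input_rna'", "input")
  if (trans_control$type == "input_rna" || trans_kd$type == "input_rna")
    m7g_stop("translated libraries must be polysome or ribo_footprint", "input")
  g <- genes$id
  cnt <- function(lib) ifelse(is.na(lib$counts[g]), 0, lib$counts[g])
  in_len <- if (input_length == "cds") genes$cds_length else genes$transcript_length
  tr_len <- if (trans_control$type == "ribo_footprint") genes$cds_length else
    genes$transcript_length
  fi_c <- fpkm(cnt(input_control), in_len, input_control$total)
  fi_k <- fpkm(cnt(input_kd), in_len, input_kd$total)
  ft_c <- fpkm(cnt(trans_control), tr_len, trans_control$total)
  ft_k <- fpkm(cnt(trans_kd), tr_len, trans_kd$total)
  te_c <- translation_efficiency(ft_c, fi_c)
  te_k <- translation_efficiency(ft_k, fi_k)
  cls <- classify_te(te_c, te_k, fi_c, fi_k, lfc_threshold, min_input_fpkm)
  lr <- ifelse(cls == "filtered", NA_real_, log2(te_k / te_c))
  out <- data.frame(gene = g, input_fpkm_control = unname(fi_c),
                    input_fpkm_kd = unname(fi_k),
                    te_control = unname(te_c), te_kd = unname(te_k),
                    log2_ratio = unname(lr), te_class = cls,
                    stringsAsFactors = FALSE)
  class(out) <- c("te_results", "data.frame")
  out
}

#' Default ribosome A-site offset rule
#'
#' Footprints of 28-31 nt get a +15 nt offset from their 5' end to the
#' A-site; other lengths are discarded.
#'
#' @return data frame with columns `length` and `offset`.
#' @export
default_offset_rule <- function() {
  data.frame(length = 28:31, offset = 15L)
}

#' Assign ribosome footprints to CDS codons
#'
#' The A-site nucleotide of each footprint is its 5' end plus the
#' length-specific offset; footprints whose length has no offset, or whose
#' A-site falls outside the CDS, are discarded (and tallied).
#'
#' @param footprints data frame with columns `five_prime_pos` (0-based on
#'   the transcript), `length`, and optionally `count` (aggregated reads
#'   per row, default 1).
#' @param gene one row of a [gene_models()] table (or any list with
#'   `cds_length`).
#' @param offset_rule data frame mapping `length` to `offset`
#'   ([default_offset_rule()]).
#' @param cds_start 0-based CDS start on the transcript, default 0.
#' @return list with `counts` (per-codon occupancy, length
#'   `cds_length / 3`) and `discarded` (reads dropped).
#' @export
assign_codon_occupancy <- function(footprints, gene,
                                   offset_rule = default_offset_rule(),
                                   cds_start = 0L) {
  if (any(footprints$five_prime_pos < 0))
    m7g_stop("negative footprint position", "input")
  w <- if ("count" %in% names(footprints)) footprints$count else
    rep(1, nrow(footprints))
  n_codons <- gene$cds_length %/% 3L
  off <- offset_rule$offset[match(footprints$length, offset_rule$length)]
  asite <- footprints$five_prime_pos + off
  codon <- (asite - cds_start) %/% 3L
  ok <- !is.na(off) & asite >= cds_start & codon >= 0 & codon < n_codons
  counts <- numeric(n_codons)
  if (any(ok)) {
    tab <- rowsum(w[ok], group = codon[ok])
    counts[as.integer(rownames(tab)) + 1L] <- tab[, 1]
  }
  list(counts = counts, discarded = sum(w[!ok]))
}

#' Per-codon pause scores for one gene
#'
#' Each codon's occupancy divided by the gene's mean per-codon occupancy;
#' the mean score over an included gene is 1.  Genes below `min_mean`
#' mean occupancy are excluded (`NULL`).
#'
#' @param counts per-codon occupancy vector.
#' @param min_mean minimum mean occupancy, default 0.5.
#' @return numeric vector of pause scores, or `NULL` when excluded.
#' @examples
#' pause_scores(c(2, 2, 8))
#' @export
pause_scores <- function(counts, min_mean = 0.5) {
  if (length(counts) == 0) m7g_stop("empty occupancy vector", "input")
  m <- mean(counts)
  if (m < min_mean) return(NULL)
  counts / m
}

#' Codon-level pause shift between control and knockdown
#'
#' Aggregates within-gene mean-normalized pause scores by codon type (61
#' sense codons; stops excluded) in each condition, reports the per-type
#' mean pause in each condition, the shift `delta = kd - control`, and a
#' two-sided Mann-Whitney U test of `delta` over m7G-decoded codon types
#' versus all other types.  The m7G pause ratio reported as `ratio_ratio`
#' is the m7G-class KD/control pause ratio divided by the non-m7G-class
#' ratio, which cancels the within-gene mean renormalization.
#'
#' @param occ_control,occ_kd named lists of per-codon occupancy vectors
#'   (same genes in both; see [assign_codon_occupancy()]).
#' @param genes a [gene_models()] table supplying the CDSs.
#' @param m7g_codons non-empty character vector of m7G-tRNA-decoded codons.
#' @param min_mean gene inclusion floor, passed to [pause_scores()].
#' @param summary_fun `"mean"` (default) or `"median"` aggregation of
#'   pause scores within a codon type.
#' @return list with `per_codon` (data frame: codon, m7g, n,
#'   pause_control, pause_kd, delta), `test`, `median_delta_m7g`,
#'   `median_delta_non`, `ratio_m7g`, `ratio_non`, `ratio_ratio`,
#'   `genes_used`.
#' @export
m7g_pause_shift <- function(occ_control, occ_kd, genes, m7g_codons,
                            min_mean = 0.5,
                            summary_fun = c("mean", "median")) {
  summary_fun <- match.arg(summary_fun)
  if (length(m7g_codons) == 0) m7g_stop("empty m7G codon set", "input")
  ids <- genes$id
  if (!setequal(names(occ_control), names(occ_kd)))
    m7g_stop("control and knockdown cover different gene sets", "input")
  ids <- ids[ids %in% names(occ_control)]
  codon_all <- character(0); sc_c_all <- numeric(0); sc_k_all <- numeric(0)
  used <- 0L
  for (g in ids) {
    i <- match(g, genes$id)
    sc_c <- pause_scores(occ_control[[g]], min_mean)
    sc_k <- pause_scores(occ_kd[[g]], min_mean)
    if (is.null(sc_c) || is.null(sc_k)) next
    cod <- split_codons(genes$cds[i])
    keep <- !(cod %in% STOP_CODONS)
    codon_all <- c(codon_all, cod[keep])
    sc_c_all <- c(sc_c_all, sc_c[keep])
    sc_k_all <- c(sc_k_all, sc_k[keep])
    used <- used + 1L
  }
  if (used == 0L)
    m7g_stop("no gene passed the occupancy floor in both conditions",
             "degenerate_input")
  f <- if (summary_fun == "mean") mean else stats::median
  pc <- tapply(sc_c_all, codon_all, f)
  pk <- tapply(sc_k_all, codon_all, f)
  nn <- tapply(sc_c_all, codon_all, length)
  per <- data.frame(codon = names(pc),
                    m7g = names(pc) %in% m7g_codons,
                    n = as.integer(nn),
                    pause_control = as.numeric(pc),
                    pause_kd = as.numeric(pk),
                    stringsAsFactors = FALSE)
  per$delta <- per$pause_kd - per$pause_control
  if (!any(per$m7g) || all(per$m7g))
    m7g_stop("both m7G and non-m7G codon types must be observed", "input")
  test <- mann_whitney_u(per$delta[per$m7g], per$delta[!per$m7g])
  ratio_m7g <- mean(per$pause_kd[per$m7g] / per$pause_control[per$m7g])
  ratio_non <- mean(per$pause_kd[!per$m7g] / per$pause_control[!per$m7g])
  list(per_codon = per, test = test,
       median_delta_m7g = stats::median(per$delta[per$m7g]),
       median_delta_non = stats::median(per$delta[!per$m7g]),
       ratio_m7g = ratio_m7g, ratio_non = ratio_non,
       ratio_ratio = ratio_m7g / ratio_non,
       genes_used = used)
}
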