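# Seeded generators for every pipeline input: tRNA references with
# implanted variable-loop motifs, TRAC-seq pileups, tRNA count matrices
# with knockdown depletion, codon-gradient transcriptomes, mRNA
# input/polysome libraries with TE coupling, and ribosome footprints with
# codon-specific pausing.  Every generator is a pure function of
# (config$seed, parameters): one global seed fans out to per-stream
# substreams so each stage can be regenerated independently.

#' Simulation configuration
#'
#' Nested parameter list for all generators; pass overrides as nested
#' lists, e.g. `simulation_config(seed = 7, trac = list(cleavage_rate = 0.1))`.
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' 50 tRNA isotypes of which 40% are m7G-modified; TRAC-seq libraries of
#' 2e5 read starts with per-position background weight 5e-3 and cleavage
#' weight 0.15 at sites; 40% knockdown depletion of m7G tRNAs with 2
#' replicates per arm; 2000 mRNAs with an m7G-codon propensity gradient
#' and TE-loss coupling `te_beta` per m7G codon; ribosome footprints at a
#' mean 50 counts/codon with a 2x knockdown pause multiplier at m7G
#' codons.
#'
#' @param seed integer seed fixing every stream.
#' @param ... nested overrides of the defaults (see source for the full
#'   set: `n_isotypes`, `n_isodecoders_per_isotype`, `fraction_m7g`,
#'   `trna_length_range`, and the `trac`, `expr`, `mrna`, `ribo` blocks).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_isotypes = 50L,
    n_isodecoders_per_isotype = 1L,
    fraction_m7g = 0.4,
    trna_length_range = c(74L, 80L),
    trac = list(library_reads = 2e5, cleavage_rate = 0.15,
                background_rate = 5e-3),
    expr = list(depletion_factor = 0.6, dispersion = 20, replicates = 2L,
                mean_count = 500, meanlog_sd = 0.5),
    mrna = list(n_genes = 2000L, cds_meanlog = log(300), cds_sdlog = 0.35,
                cds_min_codons = 60L, propensity_range = c(0.02, 0.15),
                te_beta = 0.04, te_log2_sd = 0.25, library_total = 2e7,
                dispersion = 15, abundance_sdlog = 1.2),
    ribo = list(mean_counts_per_codon = 50, pause_multiplier = 2,
                lengths = 28:31, gene_sdlog = 0.3)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], overrides[[nm]])
    else cfg[[nm]] <- overrides[[nm]]
  }
  if (cfg$fraction_m7g <= 0 || cfg$fraction_m7g >= 1)
    m7g_stop("fraction_m7g must lie in (0, 1)", "config")
  if (cfg$trac$cleavage_rate < 0 || cfg$trac$cleavage_rate > 1 ||
      cfg$trac$background_rate < 0 || cfg$trac$background_rate > 1)
    m7g_stop("TRAC rates must lie in [0, 1]", "config")
  if (cfg$expr$replicates < 1) m7g_stop("replicates must be >= 1", "config")
  if (cfg$expr$depletion_factor <= 0)
    m7g_stop("depletion_factor must be positive", "config")
  class(cfg) <- "simulation_config"
  cfg
}

sample_motif_instance <- function(pattern = motif_pattern()) {
  chars <- strsplit(pattern$iupac, "", fixed = TRUE)[[1]]
  paste(vapply(IUPAC_SETS[chars], function(s)
    if (length(s) == 1) s else sample(s, 1), character(1)), collapse = "")
}

#' Simulate a tRNA gene reference with implanted m7G motifs
#'
#' m7G genes carry exactly one implanted ABGWY-style instance inside the
#' variable loop (at a ground-truth position); non-m7G genes are
#' rejection-sampled until their variable loop contains no motif match.
#'
#' @param config a [simulation_config()].
#' @param pattern a [motif_pattern()].
#' @return list with `genes` (a `trna_reference` data frame with an extra
#'   logical `m7g` column), `truth` (data frame `trna_id`, `position`:
#'   0-based modified-G positions), and `m7g_isotypes`.
#' @export
simulate_trna_reference <- function(config, pattern = motif_pattern()) {
  set.seed(substream_seed(config$seed, "reference"))
  n_iso <- config$n_isotypes
  n_dec <- config$n_isodecoders_per_isotype
  sense <- sense_codons()
  if (n_iso > length(sense))
    m7g_stop("more isotypes than sense codons", "config")
  wc_codons <- sample(sense, n_iso)
  anticodons <- revcomp(wc_codons)
  aas <- codon_to_aa3(wc_codons)
  n_m7g <- round(config$fraction_m7g * n_iso)
  m7g_iso <- sort(sample.int(n_iso, n_m7g))
  len_rng <- config$trna_length_range
  k <- nchar(pattern$iupac)
  rows <- list(); truth_id <- character(0); truth_pos <- integer(0)
  for (i in seq_len(n_iso)) {
    for (d in seq_len(n_dec)) {
      L <- if (len_rng[1] == len_rng[2]) len_rng[1] else
        sample(seq.int(len_rng[1], len_rng[2]), 1)
      vl <- locate_variable_loop(strrep("N", L))
      if (vl[2] - vl[1] < k)
        m7g_stop("variable loop shorter than the motif", "config")
      repeat {
        s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
        if (L >= 40) s[34:36] <- strsplit(anticodons[i], "")[[1]]
        seqc <- paste(s, collapse = "")
        if (i %in% m7g_iso) {
          start0 <- vl[1] + sample.int(vl[2] - vl[1] - k + 1L, 1) - 1L
          substr(seqc, start0 + 1L, start0 + k) <- sample_motif_instance(pattern)
          break
        }
        if (length(scan_motif(seqc, vl, pattern)) == 0) break
      }
      id <- sprintf("tRNA-%s-%s-%d-%d", aas[i], anticodons[i], i, d)
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, amino_acid = aas[i], anticodon = anticodons[i],
        isotype_key = paste(aas[i], anticodons[i], sep = "-"),
        isodecoder_id = id, sequence = seqc,
        vl_start = vl[1], vl_end = vl[2], flagged = FALSE,
        m7g = i %in% m7g_iso, stringsAsFactors = FALSE)
      if (i %in% m7g_iso) {
        truth_id <- c(truth_id, id)
        truth_pos <- c(truth_pos, start0 + pattern$modified_offset)
      }
    }
  }
  genes <- do.call(rbind, rows)
  class(genes) <- c("trna_reference", "data.frame")
  list(genes = genes,
       truth = data.frame(trna_id = truth_id, position = truth_pos,
                          stringsAsFactors = FALSE),
       m7g_isotypes = unique(genes$isotype_key[genes$m7g]))
}

multinomial_library <- function(weights_by_gene, library_reads) {
  lens <- vapply(weights_by_gene, length, integer(1))
  w <- unlist(weights_by_gene, use.names = FALSE)
  draws <- as.vector(stats::rmultinom(1, library_reads, prob = w / sum(w)))
  split_idx <- rep(seq_along(lens), lens)
  counts <- split(draws, split_idx)
  names(counts) <- names(weights_by_gene)
  trac_library(counts, library_reads)
}

#' Simulate a treated/control TRAC-seq library pair
#'
#' Read starts are drawn multinomially over all positions of all tRNAs.
#' The control library has uniform per-position background weight; the
#' treated library adds the cleavage weight at each ground-truth site + 1
#' (the cleavage read-start position).
#'
#' @param reference output of [simulate_trna_reference()].
#' @param config a [simulation_config()] (`trac` block).
#' @param truth ground-truth site list; defaults to `reference$truth`.
#' @return list with `treated` and `control` [trac_library()] objects.
#' @export
simulate_trac_libraries <- function(reference, config,
                                    truth = reference$truth) {
  set.seed(substream_seed(config$seed, "trac"))
  p <- config$trac
  genes <- reference$genes
  base <- lapply(stats::setNames(nchar(genes$sequence), genes$id),
                 function(L) rep(p$background_rate, L))
  treated_w <- base
  for (i in seq_len(nrow(truth))) {
    id <- truth$trna_id[i]
    pos <- truth$position[i] + 1L            # cleavage read start, 0-based
    if (pos < length(treated_w[[id]]))
      treated_w[[id]][pos + 1L] <- treated_w[[id]][pos + 1L] + p$cleavage_rate
  }
  treated <- multinomial_library(treated_w, p$library_reads)
  control <- multinomial_library(base, p$library_reads)
  list(treated = treated, control = control)
}

#' Simulate tRNA isodecoder counts under knockdown depletion
#'
#' Negative-binomial counts with a lognormal baseline per isodecoder; the
#' knockdown mean of m7G isodecoders is the control mean times
#' `depletion_factor`, non-m7G isodecoders are unchanged.
#'
#' @param reference output of [simulate_trna_reference()].
#' @param config a [simulation_config()] (`expr` block).
#' @return a [count_matrix()] over isodecoders with condition labels
#'   `control` / `kd`; the true baseline means are in
#'   `attr(, "true_means")`.
#' @export
simulate_trna_counts <- function(reference, config) {
  set.seed(substream_seed(config$seed, "trna_counts"))
  p <- config$expr
  genes <- reference$genes
  n <- nrow(genes)
  base <- p$mean_count * stats::rlnorm(n, 0, p$meanlog_sd)
  kd_mean <- ifelse(genes$m7g, base * p$depletion_factor, base)
  r <- p$replicates
  draw <- function(mu) stats::rnbinom(n, mu = mu, size = p$dispersion)
  cols <- c(lapply(seq_len(r), function(i) draw(base)),
            lapply(seq_len(r), function(i) draw(kd_mean)))
  m <- do.call(cbind, cols)
  rownames(m) <- genes$isodecoder_id
  colnames(m) <- c(paste0("control_", seq_len(r)), paste0("kd_", seq_len(r)))
  out <- count_matrix(m, c(rep("control", r), rep("kd", r)))
  attr(out, "true_means") <- base
  out
}

#' Simulate a transcriptome with an m7G codon-content gradient
#'
#' Per-gene m7G-codon propensity is drawn uniformly from
#' `propensity_range`; each CDS codon is an m7G-decoded codon with that
#' probability (sampled uniformly within the set) and otherwise a uniform
#' other sense codon.  A terminal stop is appended; no internal stops
#' occur.
#'
#' @param config a [simulation_config()] (`mrna` block).
#' @param m7g_codons the m7G-decoded codon set (stops are ignored).
#' @return list with `genes` (a [gene_models()] table) and `propensity`
#'   (named per-gene true propensity).
#' @export
simulate_transcriptome <- function(config, m7g_codons) {
  set.seed(substream_seed(config$seed, "transcriptome"))
  p <- config$mrna
  m7g_codons <- setdiff(m7g_codons, STOP_CODONS)
  if (length(m7g_codons) == 0) m7g_stop("empty m7G codon set", "input")
  other <- setdiff(sense_codons(), m7g_codons)
  n <- p$n_genes
  n_codons <- pmax(p$cds_min_codons,
                   round(stats::rlnorm(n, p$cds_meanlog, p$cds_sdlog)))
  prop <- stats::runif(n, p$propensity_range[1], p$propensity_range[2])
  gene_idx <- rep.int(seq_len(n), n_codons)
  is_m7g <- stats::rbinom(length(gene_idx), 1, prop[gene_idx]) == 1
  cods <- character(length(gene_idx))
  cods[is_m7g] <- sample(m7g_codons, sum(is_m7g), replace = TRUE)
  cods[!is_m7g] <- sample(other, sum(!is_m7g), replace = TRUE)
  cds <- vapply(split(cods, gene_idx), paste, character(1), collapse = "")
  cds <- paste0(cds, "TAA")
  ids <- sprintf("gene_%04d", seq_len(n))
  utr <- round(stats::runif(n, 100, 500))
  genes <- gene_models(ids, cds, transcript_length = nchar(cds) + utr)
  list(genes = genes, propensity = stats::setNames(prop, ids))
}

#' Simulate input and polysome libraries with TE coupling
#'
#' Input abundance is lognormal and shared across conditions; the
#' polysome mean is the input mean times the gene's TE.  Knockdown TE is
#' the control TE times `2^(-te_beta * m7g_codon_count)`, so TE loss grows
#' with m7G codon content.  Counts are negative binomial; each library is
#' depth-matched to `library_total`.
#'
#' @param genes a [gene_models()] table.
#' @param config a [simulation_config()] (`mrna` block).
#' @param m7g_counts named per-gene m7G codon counts (e.g.
#'   `codon_count_records()$m7g_codon_count`).
#' @return list of four [library_counts()]: `input_control`, `input_kd`,
#'   `polysome_control`, `polysome_kd`, plus `true_te_control`,
#'   `true_te_kd`.
#' @export
simulate_mrna_libraries <- function(genes, config, m7g_counts) {
  set.seed(substream_seed(config$seed, "mrna"))
  p <- config$mrna
  n <- nrow(genes)
  cnt <- m7g_counts[genes$id]
  if (any(is.na(cnt))) m7g_stop("m7g_counts missing genes", "input")
  abundance <- stats::rlnorm(n, 0, p$abundance_sdlog)
  te_c <- 2^stats::rnorm(n, 0, p$te_log2_sd)
  te_k <- te_c * 2^(-p$te_beta * cnt)
  draw <- function(weights) {
    mu <- weights / sum(weights) * p$library_total
    stats::setNames(stats::rnbinom(n, mu = mu, size = p$dispersion), genes$id)
  }
  w_in <- abundance * genes$transcript_length
  libs <- list(
    input_control = library_counts(draw(w_in), "input_rna", "control"),
    input_kd = library_counts(draw(w_in), "input_rna", "kd"),
    polysome_control = library_counts(draw(w_in * te_c), "polysome",
                                      "control"),
    polysome_kd = library_counts(draw(w_in * te_k), "polysome", "kd")
  )
  libs$true_te_control <- stats::setNames(te_c, genes$id)
  libs$true_te_kd <- stats::setNames(te_k, genes$id)
  libs
}

#' Simulate ribosome footprints with m7G-codon pausing
#'
#' Per-codon occupancy is Poisson around a per-gene baseline; in the
#' knockdown the mean at m7G-decoded codons is multiplied by
#' `pause_multiplier`.  Records are emitted as (gene, five_prime_pos,
#' length, count) rows consistent with the default +15 A-site offset, so
#' [assign_codon_occupancy()] inverts them exactly.  The first five
#' codons (whose read 5' end would be negative) carry no occupancy.
#'
#' @param genes a [gene_models()] table.
#' @param config a [simulation_config()] (`ribo` block).
#' @param m7g_codons the m7G-decoded codon set.
#' @return list with `control` and `kd` footprint data frames and
#'   `true_multiplier`.
#' @export
simulate_footprints <- function(genes, config, m7g_codons) {
  set.seed(substream_seed(config$seed, "footprints"))
  p <- config$ribo
  n <- nrow(genes)
  gene_base <- p$mean_counts_per_codon * stats::rlnorm(n, 0, p$gene_sdlog)
  n_codons <- genes$cds_length %/% 3L
  gene_idx <- rep.int(seq_len(n), n_codons)
  codon_idx <- unlist(lapply(n_codons, function(k) seq_len(k) - 1L),
                      use.names = FALSE)
  cods <- unlist(lapply(genes$cds, split_codons), use.names = FALSE)
  mu_base <- gene_base[gene_idx]
  mu_base[codon_idx < 5L] <- 0               # no valid 5' end upstream
  is_m7g <- cods %in% m7g_codons
  mu_kd <- mu_base * ifelse(is_m7g, p$pause_multiplier, 1)
  emit <- function(mu) {
    cnt <- stats::rpois(length(mu), mu)
    keep <- cnt > 0
    data.frame(gene = genes$id[gene_idx[keep]],
               five_prime_pos = codon_idx[keep] * 3L - 15L,
               length = sample(p$lengths, sum(keep), replace = TRUE),
               count = cnt[keep], stringsAsFactors = FALSE)
  }
  list(control = emit(mu_base), kd = emit(mu_kd),
       true_multiplier = p$pause_multiplier)
}

#' Occupancy list from footprint records
#'
#' Convenience wrapper running [assign_codon_occupancy()] for every gene
#' of a footprint table.
#'
#' @param fp footprint data frame (gene, five_prime_pos, length, count).
#' @param genes a [gene_models()] table.
#' @param offset_rule passed to [assign_codon_occupancy()].
#' @return named list of per-codon occupancy vectors.
#' @export
occupancy_from_footprints <- function(fp, genes,
                                      offset_rule = default_offset_rule()) {
  sp <- split(fp, fp$gene)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    d <- sp[[genes$id[i]]]
    if (is.null(d)) return(numeric(genes$cds_length[i] %/% 3L))
    assign_codon_occupancy(d, genes[i, ], offset_rule)$counts
  })
  names(out) <- genes$id
  out
}
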