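# TRAC-seq cleavage scoring and m7G site calling.
#
# The chemistry: NaBH4 reduction followed by aniline cleaves the tRNA
# backbone at m7G, so the cleaved (treated) library gains read 5' ends one
# nucleotide 3' of the modified G relative to the uncleaved control.  The
# cleavage score is the log2 ratio of pseudocounted 5'-end start
# frequencies, treated over control.

#' Construct a TRAC-seq library of 5'-end pileups
#'
#' @param counts named list of non-negative integer vectors, one per tRNA,
#'   each of the tRNA's sequence length (read 5'-end starts per position).
#' @param library_size total read starts in the library; defaults to the
#'   sum over all profiles.
#' @return an object of class `trac_library`.
#' @export
trac_library <- function(counts, library_size = NULL) {
  stopifnot(is.list(counts), !is.null(names(counts)))
  if (any(vapply(counts, function(x) any(x < 0), logical(1))))
    m7g_stop("negative pileup counts", "input")
  total <- sum(vapply(counts, sum, numeric(1)))
  if (is.null(library_size)) library_size <- total
  if (library_size < total)
    m7g_stop("library_size smaller than the summed counts", "input")
  structure(list(counts = counts, library_size = library_size),
            class = "trac_library")
}

#' @export
print.trac_library <- function(x, ...) {
  cat("TRAC-seq library:", length(x$counts), "tRNA profiles,",
      format(x$library_size, big.mark = ","), "read starts\n")
  invisible(x)
}

#' Pseudocounted 5'-end start frequency at one position
#'
#' `(count + pc) / (library_size + pc * positions)`, where `positions` is
#' the profile length.
#'
#' @param lib a [trac_library()].
#' @param trna_id profile to look in.
#' @param position 0-based position.
#' @param pseudocount non-negative pseudocount per position.
#' @return frequency in `[0, 1]` (when `pseudocount = 0`).
#' @export
position_frequency <- function(lib, trna_id, position, pseudocount = 0.5) {
  if (pseudocount < 0) m7g_stop("pseudocount must be >= 0", "input")
  prof <- lib$counts[[trna_id]]
  if (is.null(prof)) m7g_stop(paste("no profile for", trna_id), "input")
  position <- as.integer(position)
  if (position < 0L || position >= length(prof))
    m7g_stop("position out of bounds", "input")
  if (lib$library_size == 0 && pseudocount == 0)
    m7g_stop("library_size 0 with zero pseudocount", "degenerate_input")
  (prof[position + 1L] + pseudocount) /
    (lib$library_size + pseudocount * length(prof))
}

#' Cleavage score at one position
#'
#' log2 of the pseudocounted start frequency in the treated (cleaved)
#' library over the control (uncleaved) one; antisymmetric under swapping
#' the libraries.
#'
#' @param treated,control [trac_library()] objects over the same reference.
#' @param trna_id tRNA id.
#' @param position 0-based position (typically the read-start position,
#'   one base 3' of the putative m7G).
#' @param pseudocount shared pseudocount, default 0.5.
#' @return cleavage score in log2 units.
#' @export
cleavage_score <- function(treated, control, trna_id, position,
                           pseudocount = 0.5) {
  nt <- length(treated$counts[[trna_id]])
  nc <- length(control$counts[[trna_id]])
  if (is.null(treated$counts[[trna_id]]) || is.null(control$counts[[trna_id]]) ||
      nt != nc)
    m7g_stop("treated and control profiles do not match for this tRNA", "input")
  log2(position_frequency(treated, trna_id, position, pseudocount) /
       position_frequency(control, trna_id, position, pseudocount))
}

#' Call m7G sites from a treated/control TRAC-seq library pair
#'
#' Every position of each tRNA's variable loop is treated as a putative
#' modified-G site; its cleavage read-start position is `site + offset`
#' (default +1, the aniline cleavage chemistry).  A site is *called* iff
#' it coincides with the modified G of an ABGWY-style motif match
#' (`motif_ok`), its cleavage score reaches `min_score`, and the treated
#' read-start count there reaches `min_coverage`.  Positions failing the
#' motif gate are still reported when their score clears `min_score`, with
#' `motif_ok = FALSE` and `called = FALSE`.  A tRNA is m7G-modified iff it
#' has at least one called site.
#'
#' @param treated,control [trac_library()] objects.
#' @param genes a `trna_reference` data frame (provides sequences and
#'   variable loops).
#' @param pattern a [motif_pattern()].
#' @param min_score minimum cleavage score (log2 units), default 1.
#' @param min_coverage minimum treated read-start count, default 10.
#' @param pseudocount shared pseudocount, default 0.5.
#' @param offset cleavage read-start offset from the modified G, default +1.
#' @return a `cleavage_calls` data frame with columns `trna_id`, `position`
#'   (0-based G position), `read_start`, `score`, `coverage`, `motif_ok`,
#'   `called`; genes lacking a profile are listed in
#'   `attr(, "uncovered")`, and the parameters in `attr(, "params")`.
#' @export
call_m7g_sites <- function(treated, control, genes, pattern = motif_pattern(),
                           min_score = 1, min_coverage = 10,
                           pseudocount = 0.5, offset = 1L) {
  known <- genes$id
  extra <- setdiff(union(names(treated$counts), names(control$counts)), known)
  if (length(extra) > 0)
    m7g_stop(paste0("profiles without a reference gene: ",
                    paste(utils::head(extra, 5), collapse = ", ")), "input")
  covered <- known %in% names(treated$counts) & known %in% names(control$counts)
  rows <- vector("list", sum(covered))
  k <- 0L
  for (i in which(covered)) {
    id <- genes$id[i]
    seqlen <- nchar(genes$sequence[i])
    if (length(treated$counts[[id]]) != seqlen ||
        length(control$counts[[id]]) != seqlen)
      m7g_stop(paste("profile length does not match sequence for", id), "input")
    vl <- c(genes$vl_start[i], genes$vl_end[i])
    motif_pos <- scan_motif(genes$sequence[i], vl, pattern)
    cand <- seq.int(vl[1], vl[2] - 1L)
    rs <- cand + as.integer(offset)
    ok <- rs >= 0L & rs < seqlen
    cand <- cand[ok]; rs <- rs[ok]
    if (length(cand) == 0) next
    score <- vapply(rs, function(p)
      cleavage_score(treated, control, id, p, pseudocount), numeric(1))
    coverage <- treated$counts[[id]][rs + 1L]
    motif_ok <- cand %in% motif_pos
    called <- motif_ok & score >= min_score & coverage >= min_coverage
    keep <- motif_ok | score >= min_score
    if (!any(keep)) next
    k <- k + 1L
    rows[[k]] <- data.frame(trna_id = id, position = cand[keep],
                            read_start = rs[keep], score = score[keep],
                            coverage = coverage[keep],
                            motif_ok = motif_ok[keep], called = called[keep],
                            stringsAsFactors = FALSE)
  }
  out <- if (k > 0) do.call(rbind, rows[seq_len(k)]) else
    data.frame(trna_id = character(0), position = integer(0),
               read_start = integer(0), score = numeric(0),
               coverage = numeric(0), motif_ok = logical(0),
               called = logical(0))
  rownames(out) <- NULL
  attr(out, "uncovered") <- known[!covered]
  attr(out, "params") <- list(pattern = pattern$iupac,
                              modified_offset = pattern$modified_offset,
                              min_score = min_score,
                              min_coverage = min_coverage,
                              pseudocount = pseudocount, offset = offset)
  class(out) <- c("cleavage_calls", "data.frame")
  out
}

#' tRNAs reported as m7G-modified
#'
#' @param calls a `cleavage_calls` data frame.
#' @return character vector of tRNA ids with at least one called site.
#' @export
m7g_modified_trnas <- function(calls) {
  sort(unique(calls$trna_id[calls$called]))
}

#' Change in m7G cleavage level between two conditions
#'
#' Pairs calls by (tRNA, position) and reports per-site score differences
#' (condition B minus A), a per-tRNA mean difference, and a two-sided
#' Mann-Whitney U test of the per-site scores in A versus B.
#'
#' @param calls_a,calls_b `cleavage_calls` produced with identical
#'   parameters (condition A, e.g. control; condition B, e.g. knockdown).
#' @param sites `"called_any"` (default): sites called in at least one
#'   condition; `"all"`: every shared motif site.
#' @return list with `per_site` (data frame: trna_id, position, score_a,
#'   score_b, delta), `per_trna` (mean delta by tRNA), `unpaired`
#'   (sites present in only one condition), `test` (a [mann_whitney_u()]
#'   result) and `median_delta`.
#' @export
m7g_level_change <- function(calls_a, calls_b,
                             sites = c("called_any", "all")) {
  sites <- match.arg(sites)
  pa <- attr(calls_a, "params"); pb <- attr(calls_b, "params")
  if (!identical(pa, pb))
    m7g_stop("call sets were produced with different parameters", "input")
  a <- calls_a[calls_a$motif_ok, ]
  b <- calls_b[calls_b$motif_ok, ]
  key_a <- paste(a$trna_id, a$position)
  key_b <- paste(b$trna_id, b$position)
  shared <- intersect(key_a, key_b)
  if (sites == "called_any") {
    called_keys <- union(key_a[a$called], key_b[b$called])
    shared <- intersect(shared, called_keys)
  }
  if (length(shared) == 0)
    m7g_stop("no shared m7G sites between the two conditions",
             "degenerate_input")
  ia <- match(shared, key_a); ib <- match(shared, key_b)
  per_site <- data.frame(trna_id = a$trna_id[ia], position = a$position[ia],
                         score_a = a$score[ia], score_b = b$score[ib],
                         delta = b$score[ib] - a$score[ia],
                         stringsAsFactors = FALSE)
  per_trna <- stats::aggregate(delta ~ trna_id, per_site, mean)
  test <- mann_whitney_u(per_site$score_a, per_site$score_b)
  list(per_site = per_site, per_trna = per_trna,
       unpaired = c(setdiff(key_a, key_b), setdiff(key_b, key_a)),
       test = test, median_delta = stats::median(per_site$delta))
}
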