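# tRNA reference model: gene parsing, variable-loop location, m7G motif
# scanning, and anticodon -> codon decoding.

#' m7G motif pattern
#'
#' The m7G site on tRNAs sits inside a degenerate sequence motif in the
#' variable loop; the default, `ABGWY`, has the methylated G at offset 2
#' (0-based).  IUPAC codes: A = A, B = C/G/T, G = G, W = A/T, Y = C/T.
#'
#' @param iupac IUPAC-degenerate motif string.
#' @param modified_offset 0-based index of the modified G within the motif.
#' @return an object of class `motif_pattern`.
#' @examples
#' motif_pattern()
#' @export
motif_pattern <- function(iupac = "ABGWY", modified_offset = 2L) {
  chars <- strsplit(toupper(iupac), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0)
    m7g_stop(paste0("invalid IUPAC character(s) in pattern: ",
                    paste(bad, collapse = ", ")), "pattern")
  modified_offset <- as.integer(modified_offset)
  if (modified_offset < 0L || modified_offset >= length(chars))
    m7g_stop("modified_offset outside the pattern", "pattern")
  if (!"G" %in% IUPAC_SETS[[chars[modified_offset + 1L]]])
    m7g_stop("pattern character at modified_offset cannot be G", "pattern")
  structure(list(iupac = paste(chars, collapse = ""),
                 modified_offset = modified_offset),
            class = "motif_pattern")
}

iupac_to_regex <- function(iupac) {
  chars <- strsplit(toupper(iupac), "", fixed = TRUE)[[1]]
  sets <- IUPAC_SETS[chars]
  paste(vapply(sets, function(s)
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]"),
    character(1)), collapse = "")
}

#' Scan a sequence window for an m7G motif
#'
#' Reports the sequence coordinate of the modified G of every (possibly
#' overlapping) motif match whose first base lies inside `window`.  With
#' `allow_overhang = TRUE` (default) a match may extend past the window
#' end; this anchors the modified G, not the whole motif, to the loop.
#'
#' @param sequence DNA string.
#' @param window 0-based half-open interval `c(start, end)` into `sequence`.
#' @param pattern a [motif_pattern()].
#' @param allow_overhang may a match overhang the window end?
#' @return integer vector of 0-based positions of the modified G, ascending.
#' @examples
#' scan_motif("ACGAC", c(0, 5))
#' @export
scan_motif <- function(sequence, window, pattern = motif_pattern(),
                       allow_overhang = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  window <- as.integer(window)
  if (length(window) != 2 || window[1] < 0 || window[2] > n ||
      window[1] > window[2])
    m7g_stop("window outside sequence bounds", "input")
  k <- nchar(pattern$iupac)
  rx <- paste0("(?=", iupac_to_regex(pattern$iupac), ")")
  hits <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (hits[1] == -1) return(integer(0))
  starts0 <- as.integer(hits) - 1L        # 0-based match starts
  keep <- starts0 >= window[1] & starts0 < window[2]
  if (!allow_overhang) keep <- keep & (starts0 + k) <= window[2]
  sort(starts0[keep] + pattern$modified_offset)
}

# --- secondary-structure parsing ------------------------------------------

# Partner vector (1-based; NA for unpaired) from a dot-bracket string.
parse_dot_bracket <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c(".", "(", ")")))
    m7g_stop("dot-bracket string contains characters other than '.()'",
             "structure")
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0)
        m7g_stop("unbalanced dot-bracket string", "structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack) > 0)
    m7g_stop("unbalanced dot-bracket string", "structure")
  partner
}

# Hairpin arms of a cloverleaf: each is a loop (maximal unpaired run whose
# flanks pair with each other) plus the maximal contiguous stem enclosing
# only that loop.  Returns a list of c(stem5_outer, stem3_outer), 1-based.
find_hairpin_arms <- function(partner) {
  n <- length(partner)
  unpaired <- is.na(partner)
  arms <- list()
  i <- 1L
  while (i <= n) {
    if (unpaired[i]) {
      j <- i
      while (j < n && unpaired[j + 1L]) j <- j + 1L
      if (i > 1L && j < n && !is.na(partner[i - 1L]) &&
          partner[i - 1L] == j + 1L) {
        a <- i - 1L; b <- j + 1L
        while (a > 1L && b < n && !is.na(partner[a - 1L]) &&
               partner[a - 1L] == b + 1L) {
          a <- a - 1L; b <- b + 1L
        }
        arms[[length(arms) + 1L]] <- c(a, b)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  arms
}

#' Locate the tRNA variable loop
#'
#' With a secondary structure: the unpaired region strictly between the 3'
#' side of the anticodon stem and the 5' side of the T-stem, read off a
#' cloverleaf dot-bracket (three hairpin arms: D, anticodon, T).  Without
#' one: a heuristic window relative to the 3' end, by default
#' `[len - 27, len - 12)`, which brackets canonical positions 44-48 on a
#' 76-nt tRNA; a trailing CCA is excluded from `len` when `cca = TRUE`.
#'
#' @param sequence tRNA sequence (DNA alphabet).
#' @param dot_bracket optional dot-bracket string of the same length.
#' @param fallback_window offsets from the (CCA-trimmed) 3' end, default
#'   `c(-27, -12)`.
#' @param cca does the sequence carry a non-templated 3' CCA to exclude?
#' @return 0-based half-open interval `c(start, end)`.
#' @examples
#' locate_variable_loop(strrep("A", 76))
#' @export
locate_variable_loop <- function(sequence, dot_bracket = NULL,
                                 fallback_window = c(-27L, -12L),
                                 cca = FALSE) {
  n <- nchar(sequence)
  if (!is.null(dot_bracket)) {
    if (nchar(dot_bracket) != n)
      m7g_stop("dot-bracket length does not match sequence", "format")
    partner <- parse_dot_bracket(dot_bracket)
    arms <- find_hairpin_arms(partner)
    if (length(arms) < 3)
      m7g_stop("structure is not a cloverleaf (fewer than 3 hairpin arms)",
               "structure")
    anticodon_arm <- arms[[2]]
    t_arm <- arms[[length(arms)]]
    start0 <- anticodon_arm[2]           # 0-based: base after stem 3' end
    end0 <- t_arm[1] - 1L                # 0-based: first base of T-stem
    if (start0 >= end0)
      m7g_stop("no unpaired variable loop between anticodon and T stems",
               "degenerate_input")
    return(c(start0, end0))
  }
  eff <- n - if (isTRUE(cca)) 3L else 0L
  start0 <- eff + as.integer(fallback_window[1])
  end0 <- eff + as.integer(fallback_window[2])
  if (start0 < 0L || end0 > n || start0 >= end0)
    m7g_stop("fallback variable-loop window out of range for this sequence",
             "degenerate_input")
  c(start0, end0)
}

# --- reference loading ----------------------------------------------------

parse_trna_header <- function(header) {
  id <- sub("\\s.*$", "", header)
  m <- regmatches(id, regexec("tRNA-([A-Za-z]{3}|iMet|SeC|Sup|Und)-([ACGTUacgtu]{3})", id))[[1]]
  if (length(m) == 3) {
    list(id = id, amino_acid = m[2],
         anticodon = chartr("Uu", "Tt", toupper(m[3])), flagged = FALSE)
  } else {
    list(id = id, amino_acid = NA_character_, anticodon = NA_character_,
         flagged = TRUE)
  }
}

#' Load a tRNA gene reference from FASTA
#'
#' Headers are expected in gtRNAdb style (e.g. `tRNA-Val-AAC-1-1`,
#' optionally prefixed, as in `Homo_sapiens_tRNA-Val-AAC-1-1`).  U is
#' transliterated to T on ingest.  Records whose isotype cannot be parsed
#' are returned with `flagged = TRUE`, not dropped.  An optional
#' FASTA-like annotation file supplies one dot-bracket string per record
#' (matched by name), used to locate the variable loop; otherwise the
#' fallback window of [locate_variable_loop()] is used.
#'
#' @param fasta_path path to the tRNA FASTA.
#' @param annotation_path optional path to dot-bracket annotation.
#' @param cca sequences carry a 3' CCA (excluded from the fallback window).
#' @param fallback_window passed to [locate_variable_loop()].
#' @return a `trna_reference` data frame: one row per gene with columns
#'   `id`, `amino_acid`, `anticodon`, `isotype_key`, `isodecoder_id`,
#'   `sequence`, `vl_start`, `vl_end` (0-based half-open), `flagged`.
#' @export
load_trna_reference <- function(fasta_path, annotation_path = NULL,
                                cca = FALSE, fallback_window = c(-27L, -12L)) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0) m7g_stop("FASTA file contains no records", "empty_input")
  seq_chr <- chartr("Uu", "Tt", toupper(as.character(seqs)))
  bad <- grepl("[^ACGT]", seq_chr)
  if (any(bad))
    m7g_stop(paste0("non-DNA characters in record(s): ",
                    paste(utils::head(names(seqs)[bad], 5), collapse = ", ")),
             "format")
  parsed <- lapply(names(seqs), parse_trna_header)
  db <- NULL
  if (!is.null(annotation_path)) {
    ann <- Biostrings::readBStringSet(annotation_path)
    ann_chr <- as.character(ann)
    names(ann_chr) <- sub("\\s.*$", "", names(ann))
    ids <- vapply(parsed, `[[`, character(1), "id")
    if (!all(ids %in% names(ann_chr)))
      m7g_stop("annotation file is missing records present in the FASTA",
               "format")
    db <- unname(ann_chr[ids])
    if (any(nchar(db) != nchar(seq_chr)))
      m7g_stop("annotation length does not match sequence length", "format")
  }
  loops <- lapply(seq_along(seq_chr), function(i)
    locate_variable_loop(seq_chr[i],
                         dot_bracket = if (is.null(db)) NULL else db[i],
                         fallback_window = fallback_window, cca = cca))
  out <- data.frame(
    id = vapply(parsed, `[[`, character(1), "id"),
    amino_acid = vapply(parsed, `[[`, character(1), "amino_acid"),
    anticodon = vapply(parsed, `[[`, character(1), "anticodon"),
    stringsAsFactors = FALSE
  )
  out$isotype_key <- ifelse(out$flagged <- vapply(parsed, `[[`, logical(1), "flagged"),
                            NA_character_,
                            paste(out$amino_acid, out$anticodon, sep = "-"))
  out$isodecoder_id <- out$id
  out$sequence <- unname(seq_chr)
  out$vl_start <- vapply(loops, `[[`, numeric(1), 1)
  out$vl_end <- vapply(loops, `[[`, numeric(1), 2)
  if (!is.null(db)) out$dot_bracket <- db
  out <- out[, c("id", "amino_acid", "anticodon", "isotype_key",
                 "isodecoder_id", "sequence", "vl_start", "vl_end", "flagged",
                 if (!is.null(db)) "dot_bracket")]
  class(out) <- c("trna_reference", "data.frame")
  out
}

#' Write a tRNA reference back to FASTA
#'
#' @param genes a `trna_reference` data frame.
#' @param path output FASTA path.
#' @export
write_trna_reference <- function(genes, path) {
  x <- Biostrings::DNAStringSet(genes$sequence)
  names(x) <- genes$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# --- decoding -------------------------------------------------------------

#' Wobble-decoding policy
#'
#' Maps an anticodon position-34 base (its 5' base) to the codon
#' third-position bases it can read.  `strict_wc` is Watson-Crick only;
#' `crick_wobble` adds the classical wobble pairs (G34 reads C/U, U34 reads
#' A/G); `crick_wobble_inosine` (default elsewhere in the package) further
#' treats A34 as inosine, reading U/C/A -- the rule for eukaryotic
#' cytoplasmic tRNAs, where A34 is essentially always deaminated.
#'
#' @param mode one of `"strict_wc"`, `"crick_wobble"`, `"crick_wobble_inosine"`.
#' @return an object of class `decoding_policy` with the position-34 table.
#' @examples
#' decoding_policy("crick_wobble")$table
#' @export
decoding_policy <- function(mode = c("crick_wobble_inosine", "crick_wobble",
                                     "strict_wc")) {
  mode <- match.arg(mode)
  table <- switch(mode,
    strict_wc = list(A = "T", C = "G", G = "C", T = "A"),
    crick_wobble = list(A = "T", C = "G", G = c("C", "T"), T = c("A", "G")),
    crick_wobble_inosine = list(A = c("T", "C", "A"), C = "G",
                                G = c("C", "T"), T = c("A", "G"))
  )
  structure(list(mode = mode, table = table), class = "decoding_policy")
}

#' Codons decoded by an anticodon
#'
#' Codon positions 1-2 are the reverse complement of anticodon positions
#' 36-35; the allowed third-position bases come from the policy's
#' position-34 table.
#'
#' @param anticodon 3-mer over A/C/G/T, written 5' to 3' (position 34 first).
#' @param policy a [decoding_policy()].
#' @return sorted character vector of decoded codons (1-3 of them).
#' @examples
#' decoded_codons("AAC")                      # Val-AAC reads GTT/GTC/GTA
#' decoded_codons("CTT", decoding_policy("strict_wc"))
#' @export
decoded_codons <- function(anticodon, policy = decoding_policy()) {
  stopifnot(inherits(policy, "decoding_policy"))
  anticodon <- toupper(anticodon)
  if (!is.character(anticodon) || length(anticodon) != 1 ||
      nchar(anticodon) != 3 || grepl("[^ACGT]", anticodon))
    m7g_stop("anticodon must be a 3-mer over A/C/G/T", "input")
  first_two <- substr(revcomp(anticodon), 1, 2)
  thirds <- policy$table[[substr(anticodon, 1, 1)]]
  sort(paste0(first_two, thirds))
}

#' Union of codons decoded by a set of m7G tRNAs
#'
#' @param m7g_trnas a `trna_reference` data frame (or any data frame with
#'   an `anticodon` column) holding the m7G-modified tRNAs.
#' @param policy a [decoding_policy()].
#' @return sorted character vector of codons; idempotent under duplicated
#'   entries.
#' @export
m7g_codon_set <- function(m7g_trnas, policy = decoding_policy()) {
  if (is.null(m7g_trnas) || nrow(m7g_trnas) == 0)
    m7g_stop("empty m7G tRNA collection", "empty_input")
  acs <- unique(m7g_trnas$anticodon)
  acs <- acs[!is.na(acs)]
  if (length(acs) == 0) m7g_stop("no parseable anticodons", "empty_input")
  sort(unique(unlist(lapply(acs, decoded_codons, policy = policy))))
}

#' Dump an anticodon decoding table
#'
#' Writes a TSV with one row per anticodon: anticodon, policy mode, and
#' the comma-separated decoded codons.
#'
#' @param anticodons character vector of anticodons.
#' @param policy a [decoding_policy()].
#' @param path output TSV path.
#' @export
write_decoding_table <- function(anticodons, policy = decoding_policy(), path) {
  rows <- data.frame(
    anticodon = anticodons,
    policy = policy$mode,
    codons = vapply(anticodons, function(a)
      paste(decoded_codons(a, policy), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
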