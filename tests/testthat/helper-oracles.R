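# Independent oracles and small fixture builders used across the suite.

# Full-enumeration Mann-Whitney oracle: U statistic and exact two-sided
# p-value from the permutation distribution of all C(n+m, n) labelings.
# Independent of wilcox.test / pwilcox.
mw_enum_oracle <- function(a, b) {
  u_stat <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  pooled <- c(a, b)
  n <- length(a)
  labelings <- utils::combn(length(pooled), n)
  us <- apply(labelings, 2, function(idx)
    u_stat(pooled[idx], pooled[-idx]))
  u_obs <- u_stat(a, b)
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(lo, hi)))
}

# Brute-force motif oracle: expand ABGWY into its 12 literal 5-mers and
# substring-search each; returns 0-based modified-G positions of matches
# starting inside the window.
motif_expand_oracle <- function(sequence, window, allow_overhang = TRUE) {
  literals <- as.vector(outer(
    as.vector(outer(paste0("A", c("C", "G", "T"), "G"), c("A", "T"), paste0)),
    c("C", "T"), paste0))
  stopifnot(length(literals) == 12)
  starts <- integer(0)
  for (lit in literals) {
    from <- 1L
    repeat {
      i <- regexpr(lit, substring(sequence, from), fixed = TRUE)
      if (i == -1) break
      starts <- c(starts, from + i - 2L)   # 0-based
      from <- from + i
    }
  }
  starts <- starts[starts >= window[1] & starts < window[2]]
  if (!allow_overhang) starts <- starts[starts + 5 <= window[2]]
  sort(unique(starts)) + 2L
}

# Sliding-window codon-count oracle.
codon_slide_oracle <- function(cds, m7g_codons) {
  m7g_codons <- setdiff(m7g_codons, c("TAA", "TAG", "TGA"))
  n <- nchar(cds)
  cnt <- 0L
  for (i in seq(1, n, by = 3)) {
    if (substr(cds, i, i + 2) %in% m7g_codons) cnt <- cnt + 1L
  }
  cnt
}

# Canonical cloverleaf dot-bracket for a 76-nt tRNA whose variable loop is
# the 0-based interval [44, 49).
build_cloverleaf_76 <- function() {
  paste0(
    strrep("(", 7), "..",                 # acceptor 5' + spacer
    strrep("(", 4), strrep(".", 8), strrep(")", 4), "..",   # D arm
    strrep("(", 5), strrep(".", 7), strrep(")", 5),          # anticodon arm
    strrep(".", 5),                        # variable loop  [44, 49)
    strrep("(", 5), strrep(".", 7), strrep(")", 5),          # T arm
    strrep(")", 7), "..."                 # acceptor 3' + NCCA tail
  )
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Minimal two-gene reference table for unit tests.
tiny_reference <- function() {
  genes <- data.frame(
    id = c("tRNA-Val-AAC-1-1", "tRNA-Lys-CTT-1-1"),
    amino_acid = c("Val", "Lys"),
    anticodon = c("AAC", "CTT"),
    isotype_key = c("Val-AAC", "Lys-CTT"),
    isodecoder_id = c("tRNA-Val-AAC-1-1", "tRNA-Lys-CTT-1-1"),
    sequence = c(random_dna(76), random_dna(76)),
    vl_start = 49, vl_end = 64, flagged = FALSE,
    stringsAsFactors = FALSE
  )
  class(genes) <- c("trna_reference", "data.frame")
  genes
}
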