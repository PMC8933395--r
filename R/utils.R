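#' @keywords internal
"_PACKAGE"

# Classed error helper so callers can distinguish bad input from bugs.
m7g_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("m7gseq_", class), "m7gseq_error")))
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings over {A,C,G,T}.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("CTT")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# IUPAC nucleotide codes -> base sets (DNA alphabet).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# All 64 codons, the 61 sense codons and the 3 stops (standard code).
STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

sense_codons <- function() setdiff(all_codons(), STOP_CODONS)

# Standard genetic code as 3-letter amino-acid names keyed by codon.
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Stop")

codon_to_aa3 <- function(codon) {
  gc1 <- Biostrings::GENETIC_CODE[codon]
  unname(AA3[gc1])
}

# Split a CDS into its frame-0 codons.
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) m7g_stop("CDS length is not divisible by 3", "input")
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(cds, starts, starts + 2L)
}

# Derive a per-stream seed from the global seed so stages can be
# regenerated independently.  Keeps the result inside 32-bit range.
substream_seed <- function(seed, stream) {
  offsets <- c(reference = 11L, trac = 23L, trna_counts = 37L,
               transcriptome = 53L, mrna = 71L, footprints = 89L)
  if (!stream %in% names(offsets)) m7g_stop("unknown stream", "internal")
  as.integer((as.numeric(seed) * 1009 + offsets[[stream]] * 9973) %% 2147483587)
}
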