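# Shared file-format readers and writers.  All genomic coordinates in
# files are 0-based half-open; TSVs carry '#'-prefixed header metadata.

#' Write a TRAC-seq pileup library to TSV
#'
#' Format: a `#library_size=<N>` line, then a header and one row per
#' (trna_id, position, count), positions 0-based.
#'
#' @param lib a [trac_library()].
#' @param path output path.
#' @export
write_pileup <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#library_size=", format(lib$library_size,
                                             scientific = FALSE)), con)
  writeLines("trna_id\tposition\tcount", con)
  for (id in names(lib$counts)) {
    v <- lib$counts[[id]]
    writeLines(paste(id, seq_along(v) - 1L, v, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a TRAC-seq pileup library from TSV
#'
#' @param path path written by [write_pileup()].
#' @return a [trac_library()].
#' @export
read_pileup <- function(path) {
  lines <- readLines(path)
  ls_line <- grep("^#library_size=", lines, value = TRUE)
  if (length(ls_line) != 1)
    m7g_stop("pileup file lacks a single #library_size line", "format")
  library_size <- as.numeric(sub("^#library_size=", "", ls_line))
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "numeric"))
  if (any(df$count < 0)) {
    bad <- which(df$count < 0)[1]
    m7g_stop(paste0("negative count at data line ", bad), "format")
  }
  counts <- lapply(split(df, df$trna_id), function(d) {
    v <- numeric(max(d$position) + 1L)
    v[d$position + 1L] <- d$count
    v
  })
  trac_library(counts[unique(df$trna_id)], library_size)
}

#' Write cleavage calls as BED-like TSV
#'
#' Columns: trna_id, start, end (0-based half-open interval of the
#' modified G), score, coverage, motif_ok, called; parameters are echoed
#' in '#'-prefixed header lines.
#'
#' @param calls a `cleavage_calls` data frame from [call_m7g_sites()].
#' @param path output path.
#' @export
write_calls <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- attr(calls, "params")
  for (nm in names(p))
    writeLines(paste0("#", nm, "=", p[[nm]]), con)
  writeLines("trna_id\tstart\tend\tscore\tcoverage\tmotif_ok\tcalled", con)
  if (nrow(calls) > 0)
    writeLines(paste(calls$trna_id, calls$position, calls$position + 1L,
                     formatC(calls$score, digits = 6, format = "g"),
                     calls$coverage, calls$motif_ok, calls$called,
                     sep = "\t"), con)
  invisible(path)
}

#' Read cleavage calls written by [write_calls()]
#'
#' @param path input path.
#' @return a `cleavage_calls` data frame.
#' @export
read_calls <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- data.frame(trna_id = as.character(df$trna_id), position = df$start,
                    read_start = df$start + attr_num(hdr, "offset"),
                    score = df$score, coverage = df$coverage,
                    motif_ok = as.logical(df$motif_ok),
                    called = as.logical(df$called), stringsAsFactors = FALSE)
  params <- list()
  for (h in hdr) {
    kv <- sub("^#", "", h)
    k <- sub("=.*$", "", kv); v <- sub("^[^=]*=", "", kv)
    num <- suppressWarnings(as.numeric(v))
    params[[k]] <- if (is.na(num)) v else num
  }
  attr(out, "params") <- params
  class(out) <- c("cleavage_calls", "data.frame")
  out
}

attr_num <- function(hdr, key) {
  line <- grep(paste0("^#", key, "="), hdr, value = TRUE)
  if (length(line) == 0) return(0)
  as.numeric(sub(paste0("^#", key, "="), "", line[1]))
}

#' Write a count matrix with a two-line header
#'
#' Line 1: `id` followed by the sample ids; line 2: `#condition` followed
#' by the per-sample condition labels.
#'
#' @param mat a [count_matrix()].
#' @param path output path.
#' @export
write_count_matrix <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(mat$counts)), collapse = "\t"), con)
  writeLines(paste(c("#condition", unname(mat$condition)), collapse = "\t"),
             con)
  utils::write.table(mat$counts, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param path input path.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  lines <- readLines(path)
  samples <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  cond_line <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (cond_line[1] != "#condition")
    m7g_stop("count matrix lacks the #condition header line", "format")
  condition <- cond_line[-1]
  df <- utils::read.table(text = lines[-(1:2)], sep = "\t",
                          row.names = 1, stringsAsFactors = FALSE)
  if (any(df < 0)) {
    bad <- which(apply(df < 0, 1, any))[1]
    m7g_stop(paste0("negative count in row '", rownames(df)[bad], "'"),
             "format")
  }
  m <- as.matrix(df)
  colnames(m) <- samples
  count_matrix(m, condition)
}

#' Write a per-gene count library to TSV
#'
#' '#'-prefixed header lines carry the library id, type, condition and
#' total; body is (gene, count).
#'
#' @param lib a [library_counts()].
#' @param path output path.
#' @export
write_library_counts <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#id=", lib$id), paste0("#type=", lib$type),
               paste0("#condition=", lib$condition),
               paste0("#total=", format(lib$total, scientific = FALSE))), con)
  writeLines("gene\tcount", con)
  writeLines(paste(names(lib$counts),
                   format(lib$counts, scientific = FALSE, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a per-gene count library written by [write_library_counts()]
#'
#' @param path input path.
#' @return a [library_counts()].
#' @export
read_library_counts <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    l <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(l) != 1) m7g_stop(paste0("missing #", key, " header"), "format")
    sub(paste0("^#", key, "="), "", l)
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric"))
  neg <- which(df$count < 0)
  if (length(neg) > 0)
    m7g_stop(paste0("negative count at data line ", neg[1], " (gene ",
                    df$gene[neg[1]], ")"), "format")
  library_counts(stats::setNames(df$count, df$gene), type = get("type"),
                 condition = get("condition"),
                 total = as.numeric(get("total")), id = get("id"))
}

#' Read gene sets from a GMT file
#'
#' Tab-delimited: set name, description, member genes.  Duplicated genes
#' within a set are removed with a warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors of member gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) m7g_stop("empty GMT file", "empty_input")
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      m7g_stop(paste0("malformed GMT line ", i, ": fewer than 3 fields"),
               "format")
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) in set '", f[1], "'; deduplicated")
      genes <- unique(genes)
    }
    out[[f[1]]] <- genes
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field, recycled.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write CDS models to FASTA
#'
#' @param genes a [gene_models()] table.
#' @param path output path.
#' @export
write_cds_fasta <- function(genes, path) {
  x <- Biostrings::DNAStringSet(genes$cds)
  names(x) <- genes$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read CDS models from FASTA
#'
#' @param path input path.
#' @param transcript_length optional named vector of transcript lengths.
#' @return a [gene_models()] table.
#' @export
read_cds_fasta <- function(path, transcript_length = NULL) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) m7g_stop("FASTA file contains no records", "empty_input")
  ids <- sub("\\s.*$", "", names(x))
  tl <- if (is.null(transcript_length)) NULL else
    unname(transcript_length[ids])
  gene_models(ids, as.character(x), tl)
}

#' Write footprint records to TSV
#'
#' Columns: gene, five_prime_pos (0-based), length, count.
#'
#' @param fp footprint data frame.
#' @param path output path.
#' @export
write_footprints <- function(fp, path) {
  utils::write.table(fp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read footprint records written by [write_footprints()]
#'
#' @param path input path.
#' @return footprint data frame.
#' @export
read_footprints <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (any(df$five_prime_pos < 0))
    m7g_stop(paste0("negative footprint position at data line ",
                    which(df$five_prime_pos < 0)[1]), "format")
  df
}

#' Write a run manifest
#'
#' Records the command, full parameter set, input-file MD5 digests, seed,
#' package version, and a timestamp, as JSON; sufficient to re-run a
#' deterministic stage bit-identically.
#'
#' @param path output JSON path.
#' @param command command or function name.
#' @param params named list of parameters.
#' @param inputs character vector of input file paths (digested).
#' @param seed the seed used, if any.
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(path, command, params = list(),
                               inputs = character(0), seed = NULL) {
  manifest <- list(
    command = command,
    params = params,
    inputs = lapply(stats::setNames(inputs, basename(inputs)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    seed = seed,
    version = as.character(utils::packageVersion("m7Gseq")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
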