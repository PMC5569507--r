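## Format readers/writers. Sequences move through FASTA (plain or
## collapsed ">id_count"), FASTQ (qualities ignored), TSV with a header
## row, and YAML configs. Reports use 1-based inclusive coordinates; the
## internal model is 0-based half-open, converted only here.

#' Read a FASTA file
#'
#' @param path FASTA file (plain text).
#' @param collapsed parse `>id_count` headers into per-sequence counts.
#' @return data.frame: id, seq (RNA alphabet) and, if `collapsed`, count.
#' @export
read_fasta <- function(path, collapsed = FALSE) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) stop("duplicate ids in ", path)
  seqs <- as_rna(as.character(x), paste0("FASTA record in ", path))
  out <- data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
  if (collapsed) {
    m <- regmatches(ids, regexec("^(.*)_([0-9]+)$", ids))
    bad <- vapply(m, length, integer(1)) == 0
    if (any(bad))
      stop("header without _count suffix in collapsed FASTA: ", ids[bad][1])
    out$id <- vapply(m, `[`, character(1), 2)
    out$count <- as.numeric(vapply(m, `[`, character(1), 3))
  }
  out
}

#' Read a FASTQ file (qualities ignored)
#'
#' @param path FASTQ file.
#' @return data.frame: id, seq (RNA alphabet).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(x)),
             seq = unname(as_rna(as.character(x),
                                 paste0("FASTQ record in ", path))),
             stringsAsFactors = FALSE)
}

#' Read small-RNA reads into a ReadSet
#'
#' Accepts collapsed FASTA (`>id_count` headers), plain FASTA (each
#' record counts once) or FASTQ.
#'
#' @param path input file.
#' @param format "auto" (by extension), "fasta", "collapsed_fasta" or
#'   "fastq".
#' @param ... passed to [read_set()].
#' @return a [read_set()].
#' @export
read_reads <- function(path, format = c("auto", "collapsed_fasta", "fasta",
                                        "fastq"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE))
      "fastq" else "collapsed_fasta"
  }
  if (format == "fastq") {
    d <- read_fastq(path)
    return(read_set(d$seq, rep(1, nrow(d)), ...))
  }
  if (format == "collapsed_fasta") {
    d <- read_fasta(path, collapsed = TRUE)
    return(read_set(d$seq, d$count, ...))
  }
  d <- read_fasta(path)
  read_set(d$seq, rep(1, nrow(d)), ...)
}

#' Write a ReadSet as collapsed FASTA
#'
#' Headers follow the `>id_count` convention with serial ids.
#'
#' @param rs a [read_set()].
#' @param path output path.
#' @export
write_collapsed_fasta <- function(rs, path) {
  ids <- sprintf(">r%d_%d", seq_along(rs$seqs), as.integer(rs$counts))
  writeLines(rbind(ids, rs$seqs), path, sep = "\n")
  invisible(path)
}

#' Write a FASTA file from id/seq vectors
#'
#' @param ids,seqs parallel character vectors.
#' @param path output path.
#' @export
write_fasta <- function(ids, seqs, path) {
  writeLines(rbind(paste0(">", ids), seqs), path, sep = "\n")
  invisible(path)
}

#' Read a catalog FASTA with `family|arm` headers
#'
#' The arm field is optional; headers may be plain family names.
#'
#' @param path FASTA file.
#' @return a [mirna_catalog()].
#' @export
read_catalog <- function(path) {
  d <- read_fasta(path)
  parts <- strsplit(d$id, "|", fixed = TRUE)
  fam <- vapply(parts, `[`, character(1), 1)
  arm <- vapply(parts, function(p) if (length(p) > 1) p[2]
                else NA_character_, character(1))
  mirna_catalog(fam, d$seq, arm)
}

#' Write a TSV with a stable schema
#'
#' Header row, tab separator, LF line endings, no quoting, no row names.
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write ground truth as a sidecar TSV
#' @param truth a data.frame of ground-truth records.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) write_tsv(truth, path)
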