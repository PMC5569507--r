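## Read filtering and normalization for small-RNA libraries.
##
## A ReadSet holds the unique sequences of one library with their raw
## counts, plus the two library totals the downstream rules need:
## total_raw (all reads that entered the filter chain) and total_18_26
## (reads of 18-26 nt, the RPM denominator).

#' Construct a ReadSet
#'
#' @param seqs character vector of unique sequences (RNA or DNA alphabet;
#'   converted to RNA). Duplicated sequences have their counts summed.
#' @param counts integer vector of raw read counts (>= 1), parallel to
#'   `seqs`.
#' @param library_id,species labels carried through to reports.
#' @param total_raw total raw reads of the library before any filtering;
#'   defaults to `sum(counts)`.
#' @param total_18_26 count of reads 18-26 nt long, used as the
#'   reads-per-million denominator; defaults to the 18-26-nt reads present
#'   in `seqs`.
#' @return a `ReadSet` object.
#' @export
read_set <- function(seqs, counts, library_id = "lib", species = "Unk",
                     total_raw = NULL, total_18_26 = NULL) {
  stopifnot(length(seqs) == length(counts))
  seqs <- as_rna(seqs, "read")
  counts <- as.numeric(counts)
  if (length(counts) && any(counts < 1)) stop("counts must be >= 1")
  if (anyDuplicated(seqs)) {
    agg <- tapply(counts, seqs, sum)
    seqs <- names(agg)
    counts <- as.numeric(agg)
  }
  o <- order(seqs)
  seqs <- seqs[o]; counts <- counts[o]
  if (is.null(total_raw)) total_raw <- sum(counts)
  if (is.null(total_18_26)) {
    len <- nchar(seqs)
    total_18_26 <- sum(counts[len >= 18 & len <= 26])
  }
  structure(list(seqs = seqs, counts = counts, library_id = library_id,
                 species = species, total_raw = total_raw,
                 total_18_26 = total_18_26),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat("ReadSet '", x$library_id, "' (", x$species, "): ",
      length(x$seqs), " unique sequences, ", sum(x$counts),
      " reads (total_raw=", x$total_raw,
      ", total 18-26 nt=", x$total_18_26, ")\n", sep = "")
  invisible(x)
}

#' @export
length.ReadSet <- function(x) length(x$seqs)

#' @export
as.data.frame.ReadSet <- function(x, ...) {
  data.frame(seq = x$seqs, count = x$counts, length = nchar(x$seqs),
             stringsAsFactors = FALSE)
}

## Subset a ReadSet by a logical/integer index, preserving library totals.
rs_subset <- function(rs, keep) {
  rs$seqs <- rs$seqs[keep]
  rs$counts <- rs$counts[keep]
  rs
}

#' Retain reads within a length window
#'
#' Keeps reads with `min_len <= length <= max_len` (both inclusive) and
#' records the 18-26-nt read total of the retained set as the RPM
#' denominator. The defaults implement the standard small-RNA window:
#' 16-26 nt retained for candidate discovery, 18-26 nt counted for
#' normalization.
#'
#' @param rs a [read_set()].
#' @param min_len,max_len inclusive length bounds in nt.
#' @return the filtered `ReadSet`, with `total_18_26` updated.
#' @export
filter_by_length <- function(rs, min_len = 16, max_len = 26) {
  stopifnot(inherits(rs, "ReadSet"))
  if (min_len > max_len) stop("min_len > max_len")
  len <- nchar(rs$seqs)
  out <- rs_subset(rs, len >= min_len & len <= max_len)
  len2 <- nchar(out$seqs)
  out$total_18_26 <- sum(out$counts[len2 >= 18 & len2 <= 26])
  out
}

#' Remove fragments of structural RNAs
#'
#' Drops any read that matches a same-length substring of a structural
#' reference (rRNA, tRNA, snoRNA, snRNA), on either strand, with at most
#' `max_mismatch` substitutions.
#'
#' @param rs a [read_set()].
#' @param structural_ref character vector of structural RNA sequences; an
#'   empty vector makes the filter a no-op.
#' @param max_mismatch maximum substitutions for a read to count as a
#'   structural fragment.
#' @return the filtered `ReadSet`.
#' @export
filter_structural <- function(rs, structural_ref, max_mismatch = 2) {
  stopifnot(inherits(rs, "ReadSet"))
  if (length(structural_ref) == 0 || length(rs$seqs) == 0) return(rs)
  refs <- as_rna(structural_ref, "structural reference")
  refs <- c(refs, rc(refs))
  hit <- .structural_hit_cpp(rs$seqs, refs, as.integer(max_mismatch))
  rs_subset(rs, !hit)
}

#' Shorten 3' uridine tails to a single U
#'
#' Nontemplated 3' U-tails mark small RNAs for degradation and inflate
#' apparent isoform diversity. A trailing run of two or more U is collapsed
#' to one U; a single trailing U, or none, is left unchanged. An all-U
#' sequence collapses to "U" (degenerate; it is removed by any sensible
#' length filter).
#'
#' @param seqs character vector over \{A,C,G,U\}.
#' @return character vector of the same length.
#' @export
shorten_u_tail <- function(seqs) {
  sub("U{2,}$", "U", as_rna(seqs, "sequence"))
}

#' Apply U-tail shortening to a ReadSet
#'
#' Sequences made identical by tail shortening have their counts summed.
#'
#' @param rs a [read_set()].
#' @return a `ReadSet` with shortened, re-aggregated sequences.
#' @export
collapse_u_tails <- function(rs) {
  stopifnot(inherits(rs, "ReadSet"))
  if (length(rs$seqs) == 0) return(rs)
  short <- shorten_u_tail(rs$seqs)
  agg <- tapply(rs$counts, short, sum)
  rs$seqs <- names(agg)
  rs$counts <- as.numeric(agg)
  o <- order(rs$seqs)
  rs$seqs <- rs$seqs[o]; rs$counts <- rs$counts[o]
  rs
}

#' Reads per million of 18-26-nt library reads
#'
#' @param count raw read count (vectorized).
#' @param total_18_26 library total of 18-26-nt reads (>= 1).
#' @return `count * 1e6 / total_18_26`.
#' @export
compute_rpm <- function(count, total_18_26) {
  if (length(total_18_26) != 1 || is.na(total_18_26) || total_18_26 < 1)
    stop("total_18_26 must be a single value >= 1")
  count * 1e6 / total_18_26
}

#' Run the full preprocessing chain
#'
#' Length filter (16-26 nt), structural-RNA filter (<= 2 mismatches, both
#' strands), then 3' U-tail shortening with count re-aggregation. The RPM
#' denominator (18-26-nt total) is fixed after the length filter, before
#' tail shortening.
#'
#' @param rs a [read_set()].
#' @param structural_ref structural RNA sequences (may be empty).
#' @param min_len,max_len length window.
#' @param max_mismatch structural filter mismatch allowance.
#' @return preprocessed `ReadSet`.
#' @export
preprocess_reads <- function(rs, structural_ref = character(),
                             min_len = 16, max_len = 26, max_mismatch = 2) {
  rs <- filter_by_length(rs, min_len, max_len)
  denom <- rs$total_18_26
  rs <- filter_structural(rs, structural_ref, max_mismatch)
  rs <- collapse_u_tails(rs)
  ## drop sequences that fell below the window after tail collapse
  rs <- rs_subset(rs, nchar(rs$seqs) >= min_len)
  rs$total_18_26 <- denom
  rs
}
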