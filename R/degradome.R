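## Degradome/PARE analysis: tag mapping, four-rule peak calling, and
## linking of cleavage peaks to candidate miRNAs.
##
## A degradome tag's 5' end marks the first nucleotide of the 3' cleavage
## fragment. Under the standard plant slicing convention the cut falls
## between the target bases opposite miRNA positions 10 and 11, so the tag
## 5' end sits opposite miRNA position 10.

#' Map degradome tags onto transcripts
#'
#' Tags shorter than `min_len` are removed; retained tags are mapped
#' exactly, sense strand only, and the 5'-end position of every occurrence
#' is accumulated. Multi-mapping tags count fully at every occurrence.
#'
#' @param tags a [read_set()] of degradome tags (counts = tag copies).
#' @param transcripts named character vector of transcript sequences.
#' @param min_len minimum tag length in nt.
#' @return list of `DegradomeProfile` objects (one per transcript with at
#'   least one mapped tag): transcript, counts (per-position 5'-end
#'   counts, 0-based via index-1), n_unique_tags, total_tags (library
#'   size, the RPM denominator).
#' @export
map_tags <- function(tags, transcripts, min_len = 19) {
  stopifnot(inherits(tags, "ReadSet"))
  if (is.null(names(transcripts)))
    names(transcripts) <- paste0("t", seq_along(transcripts))
  transcripts <- vapply(transcripts, as_rna, character(1),
                        name = "transcript")
  keep <- nchar(tags$seqs) >= min_len
  seqs <- tags$seqs[keep]; counts <- tags$counts[keep]
  total <- sum(counts)
  profiles <- lapply(names(transcripts), function(id) {
    tx <- transcripts[[id]]
    pos_counts <- numeric(nchar(tx))
    uniq <- character()
    for (i in seq_along(seqs)) {
      m <- gregexpr(seqs[i], tx, fixed = TRUE)[[1]]
      if (m[1] > 0) {
        pos_counts[m] <- pos_counts[m] + counts[i]
        uniq <- c(uniq, seqs[i])
      }
    }
    if (!any(pos_counts > 0)) return(NULL)
    structure(list(transcript = id, counts = pos_counts,
                   n_unique_tags = length(unique(uniq)),
                   total_tags = total),
              class = "DegradomeProfile")
  })
  profiles <- Filter(Negate(is.null), profiles)
  names(profiles) <- vapply(profiles, `[[`, character(1), "transcript")
  profiles
}

#' Call cleavage peaks with the four-rule local algorithm
#'
#' A position is a peak iff all four rules hold:
#' 1. at least `min_unique` unique tag sequences mapped to the transcript;
#' 2. the position ranks among the top `top_n` positions by count (ties at
#'    the boundary are all admitted);
#' 3. its RPM exceeds `min_rpm`;
#' 4. its RPM exceeds mean + `se_multiplier` x SE of the RPM of all
#'    positions with mapped reads on this transcript, where SE is the
#'    sample standard deviation over those positions divided by sqrt(n).
#'
#' @param profile a `DegradomeProfile` from [map_tags()].
#' @param min_unique,top_n,min_rpm,se_multiplier rule parameters.
#' @param only_passed return only passing positions (default) or all
#'   mapped positions with per-rule columns.
#' @return data.frame: position (0-based), count, RPM, rank, rule1-rule4,
#'   passed.
#' @export
call_peaks <- function(profile, min_unique = 12, top_n = 12, min_rpm = 5,
                       se_multiplier = 5, only_passed = TRUE) {
  stopifnot(inherits(profile, "DegradomeProfile"))
  pos <- which(profile$counts > 0)
  if (length(pos) == 0) {
    out <- data.frame(position = integer(), count = numeric(),
                      RPM = numeric(), rank = integer(), rule1 = logical(),
                      rule2 = logical(), rule3 = logical(),
                      rule4 = logical(), passed = logical())
    return(out)
  }
  cnt <- profile$counts[pos]
  rpm <- compute_rpm(cnt, profile$total_tags)
  rk <- rank(-cnt, ties.method = "min")
  r1 <- profile$n_unique_tags >= min_unique
  r2 <- rk <= top_n
  r3 <- rpm > min_rpm
  n <- length(pos)
  se <- if (n > 1) sd(rpm) / sqrt(n) else 0
  r4 <- rpm > mean(rpm) + se_multiplier * se
  out <- data.frame(position = pos - 1L, count = cnt, RPM = rpm,
                    rank = rk, rule1 = r1, rule2 = r2, rule3 = r3,
                    rule4 = r4, passed = r1 & r2 & r3 & r4)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  if (only_passed) out[out$passed, , drop = FALSE] else out
}

#' Link a cleavage peak to candidate miRNAs
#'
#' For each candidate, the transcript window whose pairing would place the
#' peak position opposite miRNA position 10 is scored with [score_site()];
#' the pair is linked when the score is at or below the cutoff.
#'
#' @param peak_position 0-based 5'-end position of the peak.
#' @param transcript transcript sequence.
#' @param transcript_id label for the output.
#' @param candidates data.frame with columns `name` and `seq` (e.g. from
#'   [identify_mirnas()]).
#' @param score_cutoff maximum penalty score for a link.
#' @return data.frame: mirna, transcript, site_start, site_end,
#'   cleavage_position, score; zero rows if nothing links.
#' @export
link_peak_to_mirna <- function(peak_position, transcript, transcript_id,
                               candidates, score_cutoff = 2.5) {
  transcript <- as_rna(transcript, "transcript")
  n <- nchar(transcript)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    mir <- candidates$seq[i]
    L <- nchar(mir)
    ## tag 5' end opposite miRNA position 10: site spans
    ## [p - L + 10, p + 10) on the transcript, 0-based half-open
    s <- peak_position - L + 10L
    e <- peak_position + 10L
    if (s < 0 || e > n) return(NULL)
    window <- substr(transcript, s + 1, e)
    aln <- score_site(mir, window)
    if (aln$score > score_cutoff) return(NULL)
    data.frame(mirna = candidates$name[i], transcript = transcript_id,
               site_start = s, site_end = e,
               cleavage_position = peak_position, score = aln$score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(mirna = character(), transcript = character(),
                      site_start = integer(), site_end = integer(),
                      cleavage_position = integer(), score = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Peak calling and miRNA linking over a whole degradome library
#'
#' @param tags degradome tag [read_set()].
#' @param transcripts named transcript sequences.
#' @param candidates candidate table with `name` and `seq` columns.
#' @param min_len,min_unique,top_n,min_rpm,se_multiplier see [map_tags()]
#'   and [call_peaks()].
#' @param score_cutoff see [link_peak_to_mirna()].
#' @return list: `peaks` (per-transcript passed peaks, transcript column
#'   added) and `links` (miRNA-peak links).
#' @export
degradome_analysis <- function(tags, transcripts, candidates,
                               min_len = 19, min_unique = 12, top_n = 12,
                               min_rpm = 5, se_multiplier = 5,
                               score_cutoff = 2.5) {
  if (is.null(names(transcripts)))
    names(transcripts) <- paste0("t", seq_along(transcripts))
  profiles <- map_tags(tags, transcripts, min_len = min_len)
  peak_tabs <- lapply(profiles, function(p) {
    pk <- call_peaks(p, min_unique, top_n, min_rpm, se_multiplier)
    if (nrow(pk)) cbind(transcript = p$transcript, pk,
                        stringsAsFactors = FALSE) else NULL
  })
  peaks <- do.call(rbind, Filter(Negate(is.null), peak_tabs))
  if (is.null(peaks)) {
    peaks <- data.frame(transcript = character(), position = integer(),
                        count = numeric(), RPM = numeric(),
                        rank = integer(), rule1 = logical(),
                        rule2 = logical(), rule3 = logical(),
                        rule4 = logical(), passed = logical())
  }
  rownames(peaks) <- NULL
  links <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(i) {
    link_peak_to_mirna(peaks$position[i],
                       transcripts[[peaks$transcript[i]]],
                       peaks$transcript[i], candidates,
                       score_cutoff = score_cutoff)
  }))
  if (is.null(links)) {
    links <- data.frame(mirna = character(), transcript = character(),
                        site_start = integer(), site_end = integer(),
                        cleavage_position = integer(), score = numeric(),
                        stringsAsFactors = FALSE)
  }
  rownames(links) <- NULL
  list(peaks = peaks, links = links)
}
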