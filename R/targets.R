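## Plant-style miRNA target scoring and orthogroup conservation profiles.
##
## Scoring scheme (classical plant target rules): per miRNA position,
## penalty 0 for a Watson-Crick pair, 0.5 for a G:U wobble, 1 for a
## mismatch, 2 for a gap (at most one single-nucleotide bulge, disallowed
## at miRNA positions 10-11); all penalties are doubled at miRNA positions
## 2-13 (the seed-extended core). A site is accepted at a total score at
## or below the cutoff (default 2.5).

PENALTY_MATCH <- 0
PENALTY_WOBBLE <- 0.5
PENALTY_MISMATCH <- 1
PENALTY_GAP <- 2
SEED_RANGE <- 2:13
GAP_FORBIDDEN <- c(10L, 11L)

## Per-position penalty for miRNA base m vs target base t (both 5'->3'
## characters, already placed opposite each other).
base_penalty <- function(m, t) {
  wc <- (m == "A" & t == "U") | (m == "U" & t == "A") |
    (m == "G" & t == "C") | (m == "C" & t == "G")
  gu <- (m == "G" & t == "U") | (m == "U" & t == "G")
  ifelse(wc, PENALTY_MATCH, ifelse(gu, PENALTY_WOBBLE, PENALTY_MISMATCH))
}

## weight vector: x2 inside the seed-extended core
seed_weight <- function(pos) ifelse(pos %in% SEED_RANGE, 2, 1)

#' Score a miRNA against one target window
#'
#' The miRNA (5' to 3') is aligned against the target window (5' to 3')
#' in antiparallel orientation: miRNA position 1 pairs the window's 3'
#' end. Windows of the miRNA's length are scored gaplessly; windows one
#' nucleotide longer (bulged target base) or shorter (unopposed miRNA
#' base) are scored over all admissible single-bulge placements and the
#' minimum is returned.
#'
#' @param mirna mature miRNA sequence, 5' to 3'.
#' @param window target window, 5' to 3'; length within 1 nt of the
#'   miRNA.
#' @param allow_gap permit the single-nucleotide bulge.
#' @return list: `score`, `states` (per-miRNA-position string of
#'   `=` match, `o` G:U, `x` mismatch, `-` gap), `cleavage_offset`
#'   (0-based offset within the window of the base opposite miRNA
#'   position 10).
#' @export
score_site <- function(mirna, window, allow_gap = TRUE) {
  m <- strsplit(as_rna(mirna, "miRNA"), "")[[1]]
  w <- rev(strsplit(as_rna(window, "window"), "")[[1]]) # 3'->5' becomes index 1..n
  L <- length(m)
  n <- length(w)
  state_of <- function(p) c("=", "o", "x")[match(p, c(0, 0.5, 1))]
  best <- NULL
  consider <- function(score, states, cleav) {
    if (is.null(best) || score < best$score)
      best <<- list(score = score, states = states,
                    cleavage_offset = cleav)
  }
  if (n == L) {
    p <- base_penalty(m, w)
    consider(sum(p * seed_weight(seq_len(L))),
             paste(state_of(p), collapse = ""),
             ## reversed index 10 -> forward 0-based offset n - 10
             n - 10L)
  } else if (allow_gap && n == L + 1) {
    for (b in setdiff(2:L, GAP_FORBIDDEN)) {   # bulged target base before pos b
      idx <- c(seq_len(b - 1), seq(b + 1, n))  # window indices paired 1..L
      p <- base_penalty(m, w[idx])
      sc <- sum(p * seed_weight(seq_len(L))) + PENALTY_GAP * seed_weight(b)
      st <- state_of(p)
      states <- paste(c(st[seq_len(b - 1)], "-", st[b:L]), collapse = "")
      fwd10 <- n - idx[10]                    # 0-based forward offset
      consider(sc, states, as.integer(fwd10))
    }
  } else if (allow_gap && n == L - 1) {
    for (k in setdiff(2:(L - 1), GAP_FORBIDDEN)) { # miRNA base k unopposed
      idx_m <- setdiff(seq_len(L), k)
      p <- base_penalty(m[idx_m], w)
      wt <- seed_weight(idx_m)
      sc <- sum(p * wt) + PENALTY_GAP * seed_weight(k)
      st <- state_of(p)
      states <- paste(append(st, "-", after = k - 1), collapse = "")
      wi10 <- match(10L, idx_m)               # window index opposite pos 10
      consider(sc, states, as.integer(n - wi10))
    }
  } else {
    stop("window length must be within 1 nt of the miRNA",
         if (!allow_gap) " (gaps disabled)")
  }
  if (is.null(best)) stop("no admissible alignment")
  best
}

#' Predict target sites over transcripts
#'
#' Slides [score_site()] over every window of each transcript (lengths L
#' and, when gaps are allowed, L-1 and L+1) for every candidate and
#' reports all sites scoring at or below the cutoff. Sense strand only.
#'
#' @param candidates data.frame with `name` and `seq` columns.
#' @param transcripts named character vector of transcript sequences.
#' @param cutoff maximum penalty score.
#' @param allow_gap permit single-nucleotide bulges.
#' @return data.frame: mirna, transcript, site_start, site_end (0-based
#'   half-open), score, states, cleavage_position (0-based), ordered by
#'   (transcript, mirna, site_start).
#' @export
predict_targets <- function(candidates, transcripts, cutoff = 2.5,
                            allow_gap = TRUE) {
  if (length(transcripts) == 0) stop("transcripts must be non-empty")
  if (is.null(names(transcripts)))
    names(transcripts) <- paste0("t", seq_along(transcripts))
  transcripts <- vapply(transcripts, as_rna, character(1),
                        name = "transcript")
  rows <- list()
  for (tid in names(transcripts)) {
    tx <- transcripts[[tid]]
    n <- nchar(tx)
    for (ci in seq_len(nrow(candidates))) {
      mir <- candidates$seq[ci]
      L <- nchar(mir)
      lens <- if (allow_gap) c(L - 1, L, L + 1) else L
      for (wl in lens) {
        if (wl > n || wl < 2) next
        for (s in 0:(n - wl)) {
          win <- substr(tx, s + 1, s + wl)
          aln <- score_site(mir, win, allow_gap = allow_gap)
          if (aln$score <= cutoff) {
            rows[[length(rows) + 1L]] <- data.frame(
              mirna = candidates$name[ci], transcript = tid,
              site_start = s, site_end = s + wl, score = aln$score,
              states = aln$states,
              cleavage_position = s + aln$cleavage_offset,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(mirna = character(), transcript = character(),
                      site_start = integer(), site_end = integer(),
                      score = numeric(), states = character(),
                      cleavage_position = integer(),
                      stringsAsFactors = FALSE))
  }
  out[order(out$transcript, out$mirna, out$site_start), , drop = FALSE]
}

#' Sliding-window nucleotide variation across an orthogroup alignment
#'
#' For each window offset, each member's variation is its substitution
#' count against the group consensus (per-column majority, alphabetical
#' tie-break) within the window; the profile reports the mean and the
#' standard error of those per-member counts.
#'
#' @param aln character vector of aligned, equal-length sequences
#'   (>= 2 members). Gap characters are treated as a fifth symbol.
#' @param window window length in nt.
#' @param site optional 0-based half-open interval `c(start, end)`
#'   annotating a binding site; carried into the output.
#' @return list: `start` (0-based window starts), `mean`, `se`,
#'   `consensus`, `site`.
#' @export
sliding_window_variation <- function(aln, window = 30, site = NULL) {
  if (length(aln) < 2) stop("need at least 2 aligned sequences")
  L <- unique(nchar(aln))
  if (length(L) != 1) stop("sequences must be aligned to equal length")
  if (L < window) stop("alignment shorter than window")
  mat <- do.call(rbind, strsplit(aln, ""))
  cons <- apply(mat, 2, function(col) {
    tb <- table(col)
    names(tb)[tb == max(tb)][1]   # alphabetical tie-break (table is sorted)
  })
  mism <- t(mat) != cons          # L x n_members
  n <- length(aln)
  starts <- 0:(L - window)
  per_win <- vapply(starts, function(s) {
    block <- mism[(s + 1):(s + window), , drop = FALSE]
    colSums(block)
  }, numeric(n))
  per_win <- matrix(per_win, nrow = n)   # members x windows
  list(start = starts,
       mean = colMeans(per_win),
       se = apply(per_win, 2, sd) / sqrt(n),
       consensus = paste(cons, collapse = ""),
       site = site)
}
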