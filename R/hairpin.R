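## Genomic hairpin validation of miRNA candidates.
##
## Candidates are mapped to the genome with no mismatches, a flanking
## window is extracted around each hit, the window is folded by base-pair
## maximization (Watson-Crick + G:U, non-crossing, minimum loop 3), and
## the candidate passes when fewer than 4 of its positions are unpaired in
## the predicted structure and it sits entirely on one arm.

#' Exact genome mapping of a candidate
#'
#' Finds all exact occurrences of `candidate` on both strands of each
#' genome sequence. Coordinates are 0-based half-open on the forward
#' strand. Results are ordered by (genome id, start, strand), '+' first.
#'
#' @param candidate sequence over \{A,C,G,U\}.
#' @param genome named character vector of genome sequences.
#' @return data.frame: genome, start, end, strand. Zero rows if absent.
#' @export
map_exact <- function(candidate, genome) {
  candidate <- as_rna(candidate, "candidate")
  if (is.null(names(genome))) names(genome) <- paste0("g", seq_along(genome))
  genome <- vapply(genome, as_rna, character(1), name = "genome")
  L <- nchar(candidate)
  hits <- lapply(names(genome), function(id) {
    fwd <- gregexpr(candidate, genome[[id]], fixed = TRUE)[[1]]
    rev <- gregexpr(rc(candidate), genome[[id]], fixed = TRUE)[[1]]
    starts <- c(if (fwd[1] > 0) fwd - 1L else integer(),
                if (rev[1] > 0) rev - 1L else integer())
    strands <- c(rep("+", sum(fwd > 0)), rep("-", sum(rev > 0)))
    if (length(starts) == 0) return(NULL)
    data.frame(genome = id, start = as.integer(starts),
               end = as.integer(starts) + L, strand = strands,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(genome = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  out[order(out$genome, out$start, out$strand), , drop = FALSE]
}

#' Extract the flanking window around a mapped hit
#'
#' Returns the hit plus `flank` nt on each side (truncated at genome
#' ends). Minus-strand hits are reverse-complemented so the candidate
#' reads 5' to 3' in the returned window.
#'
#' @param locus one row of [map_exact()] output (list or data.frame row).
#' @param genome named character vector of genome sequences.
#' @param flank nt of flank on each side; the default gives 400 nt of
#'   total flanking sequence.
#' @return list: `window` (sequence), `offset` (0-based position of the
#'   candidate within the window), `locus`.
#' @export
extract_window <- function(locus, genome, flank = 200) {
  g <- as_rna(genome[[locus$genome]], "genome")
  n <- nchar(g)
  if (locus$start < 0 || locus$end > n) stop("locus outside genome")
  ws <- max(0L, locus$start - as.integer(flank))
  we <- min(n, locus$end + as.integer(flank))
  win <- substr(g, ws + 1, we)
  if (identical(locus$strand, "-")) {
    win <- rc(win)
    offset <- we - locus$end
  } else {
    offset <- locus$start - ws
  }
  list(window = win, offset = as.integer(offset), locus = locus)
}

#' Fold a sequence by base-pair maximization
#'
#' Computes a non-crossing secondary structure maximizing the number of
#' Watson-Crick plus G:U pairs, with hairpin loops of at least `min_loop`
#' unpaired bases, via a Nussinov-style dynamic program with deterministic
#' traceback. This is a self-contained stand-in for a thermodynamic
#' folder; see [fold_window()] for the plug-in point.
#'
#' @param seq sequence over \{A,C,G,U\}.
#' @param min_loop minimum hairpin loop length.
#' @return list: `structure` (dot-bracket), `pairs` (count).
#' @export
fold_maxpair <- function(seq, min_loop = 3) {
  seq <- as_rna(seq, "sequence")
  .fold_maxpair_cpp(seq, as.integer(min_loop))
}

#' Fold a window with the configured engine
#'
#' The default engine is [fold_maxpair()]. A thermodynamic folder can be
#' plugged in as a function `function(seq) -> dot-bracket string` (e.g.
#' wrapping an external RNAfold binary); the downstream pass/fail contract
#' is unchanged.
#'
#' @param seq window sequence.
#' @param engine `NULL` for the built-in maximizer, or a function
#'   returning a dot-bracket string for a sequence.
#' @param min_loop passed to the built-in engine.
#' @return dot-bracket string.
#' @export
fold_window <- function(seq, engine = NULL, min_loop = 3) {
  if (is.null(engine)) return(fold_maxpair(seq, min_loop)$structure)
  db <- engine(seq)
  if (nchar(db) != nchar(seq)) stop("folding engine returned wrong length")
  db
}

## Parse a dot-bracket string into a pairing table (0-based partner index,
## NA when unpaired).
pair_table <- function(db) {
  ch <- strsplit(db, "")[[1]]
  partner <- rep(NA_integer_, length(ch))
  stack <- integer()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j - 1L
      partner[j] <- i - 1L
    }
  }
  partner
}

#' Validate a candidate against a folded window
#'
#' The candidate's "hairpin mismatches" are its positions left unpaired in
#' the predicted structure; it passes when fewer than `max_mismatch`
#' positions are unpaired and no candidate base pairs with another
#' candidate base (the mature miRNA must lie on a single arm).
#'
#' @param candidate candidate sequence.
#' @param window window sequence containing the candidate.
#' @param structure dot-bracket structure of the window.
#' @param offset 0-based position of the candidate in the window.
#' @param max_mismatch pass threshold (strictly fewer than this many
#'   unpaired candidate positions).
#' @return list: `mature_arm_mismatches`, `one_arm`, `passed`.
#' @export
validate_hairpin <- function(candidate, window, structure, offset,
                             max_mismatch = 4) {
  candidate <- as_rna(candidate, "candidate")
  window <- as_rna(window, "window")
  if (nchar(structure) != nchar(window))
    stop("structure and window lengths disagree")
  L <- nchar(candidate)
  if (substr(window, offset + 1, offset + L) != candidate)
    stop("candidate not found at the recorded offset")
  partner <- pair_table(structure)
  idx <- offset + seq_len(L)            # 1-based window positions
  p <- partner[idx]                     # 0-based partners
  mismatches <- sum(is.na(p))
  one_arm <- !any(!is.na(p) & p >= offset & p < offset + L)
  list(mature_arm_mismatches = as.integer(mismatches),
       one_arm = one_arm,
       passed = mismatches < max_mismatch && one_arm)
}

#' Best star-arm duplex for a candidate within a window
#'
#' Scans every gapless antiparallel register of a putative star arm (a
#' same-length window region separated from the candidate by at least
#' `min_loop` nt on either side) and returns the register pairing the
#' most candidate bases (Watson-Crick + G:U). This emulates what a
#' thermodynamic folder reports for the mature arm of a genuine
#' stem-loop: the mature pairs the star, and substitutions in the star
#' show up as unpaired mature positions. A global base-pair maximizer
#' over a window with hundreds of nt of flanking sequence instead pairs
#' nearly every base somewhere and loses the stem signal; see the
#' methods vignette.
#'
#' @param candidate candidate sequence.
#' @param window window sequence containing the candidate.
#' @param offset 0-based candidate position in the window.
#' @param min_loop minimum separation between the arms.
#' @return list: `mismatches` (candidate positions unpaired in the best
#'   duplex), `star_start` (0-based register start, NA if no admissible
#'   register), `structure` (dot-bracket of the duplex over the window).
#' @export
hairpin_arm_fit <- function(candidate, window, offset, min_loop = 3) {
  candidate <- as_rna(candidate, "candidate")
  window <- as_rna(window, "window")
  L <- nchar(candidate)
  n <- nchar(window)
  if (substr(window, offset + 1, offset + L) != candidate)
    stop("candidate not found at the recorded offset")
  cand <- strsplit(candidate, "")[[1]]
  win <- strsplit(window, "")[[1]]
  starts <- c(if (offset - min_loop - L >= 0) 0:(offset - min_loop - L),
              if (offset + L + min_loop <= n - L)
                (offset + L + min_loop):(n - L))
  best <- list(pairs = -1L, start = NA_integer_, mask = rep(FALSE, L))
  for (p in starts) {
    region <- win[(p + L):(p + 1)]      # reversed: antiparallel register
    ok <- is_pair(cand, region)
    np <- sum(ok)
    if (np > best$pairs) best <- list(pairs = np, start = p, mask = ok)
  }
  if (is.na(best$start)) {
    return(list(mismatches = L, star_start = NA_integer_,
                structure = strrep(".", n)))
  }
  db <- rep(".", n)
  idx_c <- offset + seq_len(L)              # 1-based candidate positions
  idx_s <- best$start + L + 1 - seq_len(L)  # paired star positions
  open_c <- best$start > offset             # candidate arm is 5' of star
  db[idx_c[best$mask]] <- if (open_c) "(" else ")"
  db[idx_s[best$mask]] <- if (open_c) ")" else "("
  list(mismatches = as.integer(L - best$pairs), star_start = best$start,
       structure = paste(db, collapse = ""))
}

#' Hairpin-validate a candidate across all its genomic loci
#'
#' Maps the candidate exactly, folds each flanking window, and evaluates
#' the mismatch rule at every locus. The candidate passes if any locus
#' passes. Candidates mapping to more than `high_copy` loci are flagged as
#' repeat-like.
#'
#' @param candidate candidate sequence.
#' @param genome named character vector of genome sequences.
#' @param flank flank size per side.
#' @param max_mismatch pass threshold.
#' @param method `"duplex"` (default) evaluates the mature arm with
#'   [hairpin_arm_fit()]; `"fold"` folds the whole window with
#'   [fold_window()] (optionally a plugged-in engine) and counts unpaired
#'   candidate positions in the global structure.
#' @param engine folding engine for `method = "fold"` (see
#'   [fold_window()]).
#' @param high_copy locus count above which the candidate is flagged.
#' @return list: `passed`, `n_loci`, `high_copy`, and a `loci` data.frame
#'   (genome, start, end, strand, mismatches, one_arm, passed, structure).
#' @export
hairpin_validate_candidate <- function(candidate, genome, flank = 200,
                                       max_mismatch = 4,
                                       method = c("duplex", "fold"),
                                       engine = NULL, high_copy = 20) {
  method <- match.arg(method)
  loci <- map_exact(candidate, genome)
  if (nrow(loci) == 0) {
    return(list(passed = FALSE, n_loci = 0L, high_copy = FALSE,
                loci = cbind(loci, mismatches = integer(),
                             one_arm = logical(), passed = logical(),
                             structure = character())))
  }
  res <- lapply(seq_len(nrow(loci)), function(i) {
    w <- extract_window(loci[i, ], genome, flank = flank)
    db <- if (method == "duplex") {
      hairpin_arm_fit(candidate, w$window, w$offset)$structure
    } else {
      fold_window(w$window, engine = engine)
    }
    v <- validate_hairpin(candidate, w$window, db, w$offset,
                          max_mismatch = max_mismatch)
    data.frame(mismatches = v$mature_arm_mismatches, one_arm = v$one_arm,
               passed = v$passed, structure = db, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  loci <- cbind(loci, res)
  list(passed = any(loci$passed), n_loci = nrow(loci),
       high_copy = nrow(loci) > high_copy, loci = loci)
}
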