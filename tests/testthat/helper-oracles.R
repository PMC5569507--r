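# Independent brute-force oracles. Each one literally encodes the rule it
# checks, using a different code path from the package implementation.

rna_bases <- c("A", "C", "G", "U")

rand_seq <- function(len) paste(sample(rna_bases, len, TRUE), collapse = "")

# TRUE where a and b form a Watson-Crick or G:U pair (vectorized)
is_pair_chr <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# homology rule, literal: mismatches over the 5'-anchored overlap via a
# character loop; match iff fewer than 3 mismatches and fewer than 2 nt
# length difference
oracle_match <- function(q, r) {
  qc <- strsplit(q, "")[[1]]; rc_ <- strsplit(r, "")[[1]]
  ov <- min(length(qc), length(rc_))
  mm <- 0L
  for (i in seq_len(ov)) if (qc[i] != rc_[i]) mm <- mm + 1L
  list(substitutions = mm,
       length_difference = length(qc) - length(rc_),
       is_match = mm < 3 && abs(length(qc) - length(rc_)) < 2)
}

# abundance rule, literal: "more than ten raw reads or five in RPM
# (whichever is higher)"
oracle_abundance_keep <- function(raw_count, total_18_26) {
  five_rpm_in_reads <- 5 * total_18_26 / 1e6
  threshold <- max(10, five_rpm_in_reads)
  raw_count > threshold
}

# peak rules 1-4, literal re-implementation on a raw profile
oracle_call_peaks <- function(counts, n_unique, total_tags,
                              min_unique = 12, top_n = 12, min_rpm = 5,
                              se_mult = 5) {
  pos <- which(counts > 0)
  if (!length(pos)) return(integer())
  rpm <- counts[pos] * 1e6 / total_tags
  mu <- mean(rpm)
  n <- length(pos)
  se <- if (n > 1) stats::sd(rpm) / sqrt(n) else 0
  sorted <- sort(counts[pos], decreasing = TRUE)
  boundary <- sorted[min(top_n, length(sorted))]
  keep <- logical(length(pos))
  for (k in seq_along(pos)) {
    r1 <- n_unique >= min_unique
    r2 <- counts[pos[k]] >= boundary
    r3 <- rpm[k] > min_rpm
    r4 <- rpm[k] > mu + se_mult * se
    keep[k] <- r1 && r2 && r3 && r4
  }
  pos[keep] - 1L   # 0-based
}

# exhaustive recursion over all non-crossing structures with loop >= min_loop
# (plain recursion, no memo table; tractable for n <= 14)
oracle_max_pairs <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  pairable <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i, j - 1)
    for (k in i:(j - min_loop - 1)) {
      if (pairable(ch[k], ch[j])) {
        v <- 1L + (if (k > i) rec(i, k - 1) else 0L) + rec(k + 1, j - 1)
        if (v > best) best <- v
      }
    }
    best
  }
  if (length(ch) < min_loop + 2) return(0L)
  rec(1L, length(ch))
}

# exhaustive substring scan for the structural filter
oracle_structural_hit <- function(read, refs, max_mm = 2) {
  both <- c(refs, rc(refs))
  L <- nchar(read)
  for (ref in both) {
    if (nchar(ref) < L) next
    for (off in 0:(nchar(ref) - L)) {
      mm <- sum(strsplit(read, "")[[1]] !=
                  strsplit(substr(ref, off + 1, off + L), "")[[1]])
      if (mm <= max_mm) return(TRUE)
    }
  }
  FALSE
}

# transitive closure of the family-similarity graph by boolean matrix
# powering (independent of the union-find in the package)
oracle_merge_groups <- function(catalog) {
  fams <- unique(catalog$family)
  n <- length(fams)
  adj <- diag(TRUE, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    sa <- catalog$seq[catalog$family == fams[a]]
    sb <- catalog$seq[catalog$family == fams[b]]
    if (any(outer(sa, sb, Vectorize(function(x, y)
      oracle_match(x, y)$is_match)))) adj[a, b] <- TRUE
  }
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  groups <- apply(reach, 1, function(r) paste(sort(fams[r]), collapse = "+"))
  stats::setNames(groups, fams)
}

# literal target-site scorer, gapless only: penalties 0 / 0.5 / 1,
# doubled at miRNA positions 2-13
oracle_score_gapless <- function(mirna, window) {
  m <- strsplit(mirna, "")[[1]]
  w <- rev(strsplit(window, "")[[1]])
  stopifnot(length(m) == length(w))
  total <- 0
  for (i in seq_along(m)) {
    pair <- paste0(m[i], w[i])
    p <- if (pair %in% c("AU", "UA", "GC", "CG")) 0
    else if (pair %in% c("GU", "UG")) 0.5
    else 1
    if (i >= 2 && i <= 13) p <- 2 * p
    total <- total + p
  }
  total
}
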