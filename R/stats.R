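## Descriptive and comparative statistics for cross-species small-RNA
## surveys: size distributions, 24/21-nt ratios with a rank-sum test,
## 5' nucleotide composition with chi-squared tests, per-family consensus
## and variation, and conservation-class clustering of the family-by-
## species expression matrix.

#' Read-length distribution of a library
#'
#' @param rs a [read_set()].
#' @param lengths length range to tabulate.
#' @return data.frame: length, count, proportion (of reads within the
#'   tabulated range; proportions sum to 1).
#' @export
size_distribution <- function(rs, lengths = 16:26) {
  stopifnot(inherits(rs, "ReadSet"))
  if (length(rs$seqs) == 0) stop("empty ReadSet")
  len <- nchar(rs$seqs)
  counts <- vapply(lengths, function(l) sum(rs$counts[len == l]),
                   numeric(1))
  total <- sum(counts)
  if (total == 0) stop("no reads within the tabulated length range")
  data.frame(length = lengths, count = counts, proportion = counts / total)
}

#' Ratio of 24-nt to 21-nt read counts
#'
#' The 24/21 ratio contrasts the heterochromatic siRNA peak against the
#' miRNA peak. Undefined (NA) when no 21-nt reads are present.
#'
#' @param rs a [read_set()].
#' @return a single number, or `NA` when count(21 nt) is zero.
#' @export
ratio_24_21 <- function(rs) {
  stopifnot(inherits(rs, "ReadSet"))
  len <- nchar(rs$seqs)
  n21 <- sum(rs$counts[len == 21])
  n24 <- sum(rs$counts[len == 24])
  if (n21 == 0) return(NA_real_)
  n24 / n21
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact by enumeration (dynamic programming over the rank-sum
#' distribution, midranks for ties) when both groups have at most
#' `exact_max` observations; otherwise the normal approximation with tie
#' correction and continuity correction. The two-sided p is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param a,b numeric vectors (non-empty).
#' @param exact_max largest per-group size for the exact mode.
#' @return list: `p.value`, `statistic` (rank sum of `a`), `exact`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  exact <- na <= exact_max && nb <= exact_max
  if (exact) {
    ## doubled midranks are integers; DP over #chosen x achievable sums
    r2 <- as.integer(round(2 * r))
    maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(na)])
    ## ways[k+1, s+1] = number of na-subsets of the first i ranks ... built
    ## incrementally over all N ranks
    ways <- matrix(0, nrow = na + 1, ncol = maxs + 1)
    ways[1, 1] <- 1
    for (ri in r2) {
      for (k in min(na, 1e9):1) {
        nz <- which(ways[k, ] > 0)
        if (length(nz)) {
          tgt <- nz - 1 + ri
          ok <- tgt <= maxs
          ways[k + 1, tgt[ok] + 1] <- ways[k + 1, tgt[ok] + 1] +
            ways[k, nz[ok]]
        }
      }
    }
    distn <- ways[na + 1, ]
    total <- sum(distn)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(distn[seq_len(min(w2 + 1, length(distn)))]) / total
    p_ge <- sum(distn[(w2 + 1):length(distn)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- na * (N + 1) / 2
    ties <- table(r)
    tiecor <- sum(ties^3 - ties)
    sigma2 <- na * nb / 12 * ((N + 1) - tiecor / (N * (N - 1)))
    if (sigma2 <= 0) return(list(p.value = 1, statistic = w, exact = FALSE))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(p.value = p, statistic = w, exact = exact)
}

#' 5' nucleotide composition
#'
#' Fractions of A/C/G/U at position 1, optionally weighted (e.g. by read
#' count), optionally split by a grouping factor (species or family).
#'
#' @param seqs character vector of candidate sequences.
#' @param weights optional numeric weights, default 1 per candidate.
#' @param by optional grouping factor.
#' @return data.frame: group (if `by` given), nt, fraction; fractions sum
#'   to 1 within each group.
#' @export
five_prime_composition <- function(seqs, weights = NULL, by = NULL) {
  if (length(seqs) == 0) stop("no candidates")
  seqs <- as_rna(seqs, "candidate")
  if (is.null(weights)) weights <- rep(1, length(seqs))
  first <- factor(substr(seqs, 1, 1), levels = c("A", "C", "G", "U"))
  one_group <- function(f, wt) {
    tot <- vapply(levels(first), function(n) sum(wt[f == n]), numeric(1))
    data.frame(nt = levels(first), fraction = tot / sum(tot),
               stringsAsFactors = FALSE)
  }
  if (is.null(by)) return(one_group(first, weights))
  by <- as.factor(by)
  out <- do.call(rbind, lapply(levels(by), function(g) {
    cbind(group = g, one_group(first[by == g], weights[by == g]),
          stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Chi-squared test on 2x2 5'-composition counts
#'
#' Pearson chi-squared without continuity correction, df = 1, upper-tail
#' p-value, on counts of (5' U, non-U) in two groups.
#'
#' @param counts_a,counts_b length-2 integer vectors `c(U, nonU)`.
#' @return list: `statistic`, `p.value`.
#' @export
chi2_composition_test <- function(counts_a, counts_b) {
  tab <- rbind(as.numeric(counts_a), as.numeric(counts_b))
  if (any(rowSums(tab) < 1) || any(colSums(tab) < 1))
    stop("all marginals must be >= 1")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Consensus sequence and per-member variation of a miRNA family
#'
#' The consensus is the per-position majority over the members
#' (alphabetical tie-break), 5'-anchored, with length equal to the modal
#' member length (smallest mode on ties). Each member's variation is its
#' substitution count against the consensus over the 5'-anchored overlap
#' plus the absolute length difference.
#'
#' @param seqs member sequences (>= 2), e.g. the top one or two most
#'   abundant members per species.
#' @return list: `consensus`, `variation` (per member), `mean`, `sd`.
#' @export
consensus_and_variation <- function(seqs) {
  if (length(seqs) < 2) stop("need >= 2 member sequences")
  seqs <- as_rna(seqs, "member")
  lens <- nchar(seqs)
  tb <- table(lens)
  clen <- as.integer(names(tb)[tb == max(tb)][1])
  cons <- vapply(seq_len(clen), function(p) {
    col <- substr(seqs[lens >= p], p, p)
    tc <- table(col)
    names(tc)[tc == max(tc)][1]
  }, character(1))
  consensus <- paste(cons, collapse = "")
  variation <- vapply(seqs, function(s) {
    ov <- min(nchar(s), clen)
    subs <- sum(strsplit(substr(s, 1, ov), "")[[1]] !=
                  cons[seq_len(ov)])
    subs + abs(nchar(s) - clen)
  }, numeric(1), USE.NAMES = FALSE)
  list(consensus = consensus, variation = variation,
       mean = mean(variation), sd = sd(variation))
}

#' Build a family-by-species expression matrix
#'
#' @param tables named list of per-species candidate tables from
#'   [identify_mirnas()] (names = species codes).
#' @return numeric matrix of summed RPM per (family, species); families
#'   as rows.
#' @export
family_expression_matrix <- function(tables) {
  fams <- sort(unique(unlist(lapply(tables, `[[`, "family"))))
  m <- matrix(0, nrow = length(fams), ncol = length(tables),
              dimnames = list(fams, names(tables)))
  for (sp in names(tables)) {
    tab <- tables[[sp]]
    agg <- tapply(tab$RPM, tab$family, sum)
    m[names(agg), sp] <- agg
  }
  m
}

#' Cluster highly expressed families into conservation classes
#'
#' Selects the top `top` families by mean RPM across species, transforms
#' to log2(RPM + 1), clusters with average-linkage hierarchical
#' clustering on Euclidean distances, and cuts into `k` groups. The log
#' matrix is deliberately not row-scaled: z-scoring a family expressed
#' uniformly across species leaves only unit-variance noise, which
#' destroys exactly the "high everywhere" signature that defines class I
#' (see the methods vignette). Groups are labeled I, II, ... in order of descending
#' (detection breadth, then mean expression), so class I holds the
#' families found at high levels in the most species.
#'
#' @param rpm numeric matrix, families x species, RPM values.
#' @param top number of families to keep by mean RPM.
#' @param k number of classes.
#' @param conserved_min_species detection-count threshold above which a
#'   family is flagged as broadly conserved.
#' @return data.frame: family, class (roman), detected_in (species
#'   count), mean_rpm, conserved flag; ordered by class then family.
#' @export
classify_conservation <- function(rpm, top = 50, k = 5,
                                  conserved_min_species = 15) {
  mean_rpm <- rowMeans(rpm)
  keep <- head(order(-mean_rpm, rownames(rpm)), top)
  m <- rpm[keep, , drop = FALSE]
  if (nrow(m) < k) stop("fewer than k families after top-N selection")
  lg <- log2(m + 1)
  hc <- hclust(dist(lg), method = "average")
  grp <- cutree(hc, k = k)
  detected <- rowSums(m > 0)
  breadth <- tapply(detected, grp, mean)
  level <- tapply(rowMeans(lg), grp, mean)
  o <- order(-breadth, -level)          # group ids, most conserved first
  roman <- as.character(utils::as.roman(seq_len(k)))
  lab <- character(k)
  lab[as.integer(names(breadth))[o]] <- roman
  out <- data.frame(family = rownames(m),
                    class = lab[grp],
                    detected_in = as.integer(detected),
                    mean_rpm = rowMeans(m),
                    conserved = detected > conserved_min_species,
                    stringsAsFactors = FALSE)
  out[order(match(out$class, roman), out$family), , drop = FALSE]
}
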