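## Conserved-miRNA candidate identification by homology to a reference
## catalog of annotated plant mature miRNAs.
##
## The homology rule: a read is a candidate for a reference family when it
## has fewer than 3 substitutions and its length differs by fewer than 2 nt,
## i.e. <= 2 substitutions and <= 1 nt length difference. Substitutions are
## counted 5'-anchored (both 5' ends aligned, mismatches over the overlap);
## the 3' overhang contributes only to the length difference. Plant miRNA
## identity and AGO sorting are 5'-defined, and the downstream clustering
## keys on nucleotides 1-16, so the 5' anchor is the natural comparison
## frame.

#' Compare a read against one reference mature miRNA
#'
#' @param query,reference sequences over \{A,C,G,U\}, 15-30 nt.
#' @param max_sub maximum substitutions for a match (default 2, i.e.
#'   "fewer than 3").
#' @param max_len_diff maximum absolute length difference (default 1,
#'   i.e. "fewer than 2").
#' @return a list with `substitutions`, `length_difference`
#'   (query minus reference) and `is_match`.
#' @export
match_candidate <- function(query, reference, max_sub = 2, max_len_diff = 1) {
  query <- as_rna(query, "query"); reference <- as_rna(reference, "reference")
  stopifnot(length(query) == 1, length(reference) == 1)
  L <- min(nchar(query), nchar(reference))
  subs <- as.integer(.prefix_mismatch_cpp(query, reference)[1, 1])
  ld <- nchar(query) - nchar(reference)
  list(substitutions = subs, length_difference = ld,
       is_match = subs <= max_sub && abs(ld) <= max_len_diff)
}

#' Read a reference catalog into a canonical data frame
#'
#' @param family,arm,seq parallel vectors; `arm` may be `NA` where the
#'   reference header does not carry a 5p/3p label.
#' @return data.frame with columns family, arm, seq.
#' @export
mirna_catalog <- function(family, seq, arm = NA_character_) {
  data.frame(family = as.character(family),
             arm = rep_len(as.character(arm), length(family)),
             seq = as_rna(seq, "catalog sequence"),
             stringsAsFactors = FALSE)
}

#' Assign reads to their closest reference family
#'
#' Each read is compared against every catalog entry under the homology
#' rule; matching reads are assigned to the reference with the minimal
#' (substitutions, |length difference|) pair, lexicographically, with ties
#' broken by alphabetical family name. Non-matching reads are dropped.
#'
#' @param rs a [read_set()].
#' @param catalog a [mirna_catalog()].
#' @param max_sub,max_len_diff homology rule bounds.
#' @return data.frame: seq, count, family, arm, substitutions,
#'   length_difference.
#' @export
identify_candidates <- function(rs, catalog, max_sub = 2, max_len_diff = 1) {
  stopifnot(inherits(rs, "ReadSet"), nrow(catalog) >= 1)
  if (length(rs$seqs) == 0) {
    return(data.frame(seq = character(), count = numeric(),
                      family = character(), arm = character(),
                      substitutions = integer(),
                      length_difference = integer(),
                      stringsAsFactors = FALSE))
  }
  mm <- .prefix_mismatch_cpp(rs$seqs, catalog$seq)
  ld <- outer(nchar(rs$seqs), nchar(catalog$seq), `-`)
  ok <- mm <= max_sub & abs(ld) <= max_len_diff
  ## order references per read by (subs, |ld|, family name)
  fam_rank <- rank(catalog$family, ties.method = "first")
  pick <- vapply(seq_along(rs$seqs), function(i) {
    j <- which(ok[i, ])
    if (length(j) == 0) return(NA_integer_)
    key <- order(mm[i, j], abs(ld[i, j]), fam_rank[j])
    j[key[1]]
  }, integer(1))
  keep <- !is.na(pick)
  pick <- pick[keep]
  data.frame(seq = rs$seqs[keep], count = rs$counts[keep],
             family = catalog$family[pick], arm = catalog$arm[pick],
             substitutions = mm[cbind(which(keep), pick)],
             length_difference = ld[cbind(which(keep), pick)],
             stringsAsFactors = FALSE)
}

#' Merge near-identical reference families
#'
#' Families whose reference sequences mutually satisfy the homology rule
#' are unioned (transitive closure), reflecting that e.g. miR156 and
#' miR157 reads cannot be told apart. Merged names join the numeric
#' suffixes with "/": miR156 + miR157 becomes "miR156/157" (short form
#' "miR156/7", with the shared leading digits elided).
#'
#' @param catalog a [mirna_catalog()].
#' @param short_names elide shared leading digits in merged names
#'   (miR156/7 instead of miR156/157).
#' @return named character vector mapping each input family to its merged
#'   family name.
#' @export
merge_families <- function(catalog, short_names = FALSE) {
  fams <- unique(catalog$family)
  parent <- seq_along(fams)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_along(fams)) {
    sa <- catalog$seq[catalog$family == fams[a]]
    for (b in seq_len(a - 1L)) {
      sb <- catalog$seq[catalog$family == fams[b]]
      linked <- any(vapply(sa, function(x) any(vapply(sb, function(y)
        match_candidate(x, y)$is_match, logical(1))), logical(1)))
      if (linked) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_along(fams), find, integer(1))
  merged <- vapply(seq_along(fams), function(i) {
    members <- sort(fams[root == root[i]])
    merge_family_name(members, short = short_names)
  }, character(1))
  stats::setNames(merged, fams)
}

## Join family names like c("miR156","miR157") into "miR156/157" (or
## "miR156/7" in short form). Non "prefix+number" names are joined whole.
merge_family_name <- function(members, short = FALSE) {
  if (length(members) == 1) return(members)
  m <- regmatches(members, regexec("^([A-Za-z-]+)([0-9]+)([a-z]*)$", members))
  prefixes <- vapply(m, function(x) if (length(x)) x[2] else NA_character_,
                     character(1))
  nums <- vapply(m, function(x) if (length(x)) x[3] else NA_character_,
                 character(1))
  if (anyNA(prefixes) || length(unique(prefixes)) != 1) {
    return(paste(members, collapse = "/"))
  }
  o <- order(as.integer(nums))
  nums <- nums[o]
  suff <- nums[-1]
  if (short) {
    suff <- vapply(seq_along(suff), function(i) {
      a <- nums[1]; b <- suff[i]
      if (nchar(a) == nchar(b)) {
        k <- 0
        while (k < nchar(b) - 1 &&
               substr(a, k + 1, k + 1) == substr(b, k + 1, k + 1)) k <- k + 1
        substr(b, k + 1, nchar(b))
      } else b
    }, character(1))
  }
  paste0(prefixes[1], nums[1], "/", paste(suff, collapse = "/"))
}

#' Cluster candidate isoforms by their 5' 1-16 nucleotides
#'
#' Predicted miRNAs with identical 5' nucleotides 1-16 are combined into
#' one cluster with the most abundant member as the representative
#' (ties: shorter sequence, then alphabetical). Candidates shorter than the
#' prefix are clustered by their full sequence and flagged.
#'
#' @param candidates data.frame from [identify_candidates()] (columns seq,
#'   count, family at least).
#' @param prefix_len clustering prefix length in nt.
#' @return data.frame, one row per cluster: prefix, seq (representative),
#'   family, arm, raw_count (representative), cluster_count (sum over
#'   members), n_members, short_prefix flag.
#' @export
cluster_by_prefix <- function(candidates, prefix_len = 16) {
  if (nrow(candidates) == 0) {
    return(data.frame(prefix = character(), seq = character(),
                      family = character(), arm = character(),
                      raw_count = numeric(), cluster_count = numeric(),
                      n_members = integer(), short_prefix = logical(),
                      stringsAsFactors = FALSE))
  }
  pref <- ifelse(nchar(candidates$seq) < prefix_len, candidates$seq,
                 substr(candidates$seq, 1, prefix_len))
  idx <- split(seq_len(nrow(candidates)), pref)
  rows <- lapply(idx, function(i) {
    sub <- candidates[i, , drop = FALSE]
    o <- order(-sub$count, nchar(sub$seq), sub$seq)
    rep <- sub[o[1], , drop = FALSE]
    data.frame(prefix = if (nchar(rep$seq) < prefix_len) rep$seq
               else substr(rep$seq, 1, prefix_len),
               seq = rep$seq, family = rep$family,
               arm = if ("arm" %in% names(sub)) rep$arm else NA_character_,
               raw_count = rep$count, cluster_count = sum(sub$count),
               n_members = nrow(sub),
               short_prefix = nchar(rep$seq) < prefix_len,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$cluster_count, out$seq), , drop = FALSE]
}

#' Abundance filter on clustered candidates
#'
#' Candidates with more than ten raw reads or five RPM, whichever is
#' higher, are retained: the effective threshold is
#' `T = max(10, 5 * total_18_26 / 1e6)` reads, and a cluster is kept iff
#' its representative's raw count exceeds T strictly.
#'
#' @param clusters data.frame from [cluster_by_prefix()].
#' @param total_18_26 library RPM denominator.
#' @param min_reads,min_rpm the two thresholds.
#' @param rule `"max"` (the more stringent of the two, default) or
#'   `"either"` (pass if either threshold is exceeded).
#' @return the retained rows of `clusters`.
#' @export
apply_abundance_filter <- function(clusters, total_18_26, min_reads = 10,
                                   min_rpm = 5, rule = c("max", "either")) {
  rule <- match.arg(rule)
  if (total_18_26 < 1) stop("total_18_26 must be >= 1")
  rpm_reads <- min_rpm * total_18_26 / 1e6
  keep <- if (rule == "max") {
    clusters$raw_count > max(min_reads, rpm_reads)
  } else {
    clusters$raw_count > min_reads | clusters$raw_count > rpm_reads
  }
  clusters[keep, , drop = FALSE]
}

#' Candidate name string
#'
#' Format: `{Species}-{family}.{serial}_{raw_count}`, e.g.
#' `Smo-miR170/1-3p.2380_3761`.
#'
#' @param species_code three-letter species code.
#' @param family family name, optionally with arm suffix.
#' @param serial serial number (>= 1).
#' @param raw_count raw read count of the representative.
#' @return character vector of names.
#' @export
name_candidate <- function(species_code, family, serial, raw_count) {
  stopifnot(all(serial >= 1))
  sprintf("%s-%s.%d_%d", species_code, family, as.integer(serial),
          as.integer(round(raw_count)))
}

#' End-to-end candidate identification for one library
#'
#' Homology matching, family merging, 5' 1-16 clustering, abundance
#' filtering, RPM computation and naming. Serial numbers are assigned in
#' descending cluster-count order.
#'
#' @param rs preprocessed [read_set()].
#' @param catalog a [mirna_catalog()].
#' @param species_code label for names.
#' @param prefix_len clustering prefix.
#' @param min_reads,min_rpm,abundance_rule see [apply_abundance_filter()].
#' @param merge merge near-identical families before naming.
#' @param short_names see [merge_families()].
#' @return data.frame of retained candidate clusters with name, family,
#'   seq, length, raw_count, cluster_count, RPM, n_members, five_prime.
#' @export
identify_mirnas <- function(rs, catalog, species_code = "Unk",
                            prefix_len = 16, min_reads = 10, min_rpm = 5,
                            abundance_rule = "max", merge = TRUE,
                            short_names = FALSE) {
  cand <- identify_candidates(rs, catalog)
  if (merge && nrow(cand)) {
    map <- merge_families(catalog, short_names = short_names)
    cand$family <- unname(map[cand$family])
  }
  cl <- cluster_by_prefix(cand, prefix_len = prefix_len)
  cl <- apply_abundance_filter(cl, rs$total_18_26, min_reads, min_rpm,
                               rule = abundance_rule)
  if (nrow(cl) == 0) {
    return(data.frame(name = character(), family = character(),
                      seq = character(), length = integer(),
                      raw_count = numeric(), cluster_count = numeric(),
                      RPM = numeric(), n_members = integer(),
                      five_prime = character(), stringsAsFactors = FALSE))
  }
  cl <- cl[order(-cl$cluster_count, cl$seq), , drop = FALSE]
  fam_label <- ifelse(is.na(cl$arm) | cl$arm == "", cl$family,
                      paste0(cl$family, "-", cl$arm))
  data.frame(name = name_candidate(species_code, fam_label,
                                   seq_len(nrow(cl)), cl$raw_count),
             family = cl$family, seq = cl$seq, length = nchar(cl$seq),
             raw_count = cl$raw_count, cluster_count = cl$cluster_count,
             RPM = compute_rpm(cl$raw_count, rs$total_18_26),
             n_members = cl$n_members,
             five_prime = substr(cl$seq, 1, 1),
             stringsAsFactors = FALSE, row.names = NULL)
}
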