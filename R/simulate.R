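## Ground-truthed synthetic data: reference catalogs, genomes with planted
## hairpins, small-RNA libraries with isomiR structure, and degradome tags
## concentrated at planted cleavage sites. Every generator is driven by an
## explicit seed and leaves the caller's RNG state untouched, so fixtures
## are byte-reproducible.

#' Simulation configuration
#'
#' Defaults describe a typical lycophyte/fern small-RNA library: a
#' dominant 21-nt mature-miRNA peak with minor 20/22-nt classes, low
#' per-read substitution (sequencing error scale), short 3' truncations
#' and U-tails, a 24-nt genomic siRNA background, and log-normal
#' per-family expression.
#'
#' @param seed integer seed driving every draw.
#' @param n_families number of miRNA families to simulate.
#' @param mature_length_weights named numeric vector over lengths 18-24;
#'   normalized to sum to 1.
#' @param substitution_rate probability that a read carries one random
#'   substitution.
#' @param truncation_max maximum 3' truncation in nt.
#' @param utail_max maximum nontemplated 3' U-tail in nt.
#' @param depth total reads per library.
#' @param background_fraction fraction of reads that are 24-nt genomic
#'   siRNA background.
#' @param abundance_dispersion log-normal sigma of per-family expression.
#' @return a `SimulationConfig` list, validated.
#' @export
sim_config <- function(seed = 1L, n_families = 20L,
                       mature_length_weights = c("20" = 0.15, "21" = 0.6,
                                                 "22" = 0.2, "23" = 0.05),
                       substitution_rate = 0.02, truncation_max = 2L,
                       utail_max = 3L, depth = 1e5,
                       background_fraction = 0.3,
                       abundance_dispersion = 1) {
  stopifnot(n_families >= 1, depth >= 1,
            substitution_rate >= 0 && substitution_rate <= 1,
            background_fraction >= 0 && background_fraction <= 1,
            truncation_max >= 0, utail_max >= 0, abundance_dispersion >= 0)
  lens <- as.integer(names(mature_length_weights))
  if (any(is.na(lens)) || any(lens < 18) || any(lens > 24) ||
      any(mature_length_weights < 0) || sum(mature_length_weights) <= 0)
    stop("mature_length_weights must be a nonnegative distribution over 18-24")
  mature_length_weights <- mature_length_weights / sum(mature_length_weights)
  structure(list(seed = as.integer(seed),
                 n_families = as.integer(n_families),
                 mature_length_weights = mature_length_weights,
                 substitution_rate = substitution_rate,
                 truncation_max = as.integer(truncation_max),
                 utail_max = as.integer(utail_max),
                 depth = as.integer(depth),
                 background_fraction = background_fraction,
                 abundance_dispersion = abundance_dispersion),
            class = "SimulationConfig")
}

#' Generate a reference catalog of mature miRNAs
#'
#' Draws `n_families` mature sequences with lengths from the configured
#' distribution, enforcing that distinct families do not satisfy the
#' homology match rule (so no two independent families are confusable);
#' `n_similar_pairs` extra families violating this on purpose (one
#' substitution from an existing family) can be appended for
#' family-merging tests.
#'
#' @param config a [sim_config()].
#' @param n_similar_pairs number of deliberate near-duplicate families.
#' @return a [mirna_catalog()] with families miR101, miR102, ... and
#'   random 5p/3p arms.
#' @export
generate_reference_catalog <- function(config, n_similar_pairs = 0) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(config$seed, {
    lens <- as.integer(names(config$mature_length_weights))
    seqs <- character(0)
    attempts <- 0
    while (length(seqs) < config$n_families) {
      attempts <- attempts + 1
      if (attempts > 200 * config$n_families)
        stop("cannot generate the requested family diversity")
      len <- lens[sample.int(length(lens), 1,
                             prob = config$mature_length_weights)]
      s <- random_rna(1, len)
      clash <- any(vapply(seqs, function(x)
        match_candidate(s, x)$is_match, logical(1)))
      if (!clash) seqs <- c(seqs, s)
    }
    fam <- paste0("miR", 100 + seq_along(seqs))
    arm <- sample(c("5p", "3p"), length(seqs), replace = TRUE)
    if (n_similar_pairs > 0) {
      for (i in seq_len(n_similar_pairs)) {
        base <- seqs[i]
        pos <- sample(nchar(base), 1)
        alt <- sample(setdiff(c("A", "C", "G", "U"),
                              substr(base, pos, pos)), 1)
        substr(base, pos, pos) <- alt
        seqs <- c(seqs, base)
        fam <- c(fam, paste0("miR", 100 + config$n_families + i))
        arm <- c(arm, arm[i])
      }
    }
    mirna_catalog(fam, seqs, arm)
  })
}

#' Plant a hairpin precursor into a genome
#'
#' Splices `flank + mature + loop + star + flank` into the genome at a
#' random position, where the star arm is the reverse complement of the
#' mature arm with `star_mismatches` positions mutated to non-pairing
#' bases. Coordinates of the mature arm and of the whole hairpin are
#' returned as ground truth (0-based half-open, forward strand).
#'
#' @param genome a single genome sequence.
#' @param mature mature miRNA sequence.
#' @param star_mismatches mutated star positions (<= mature length).
#' @param loop_len loop length (>= 3).
#' @param flank_len random flank on each side of the hairpin.
#' @param seed integer seed.
#' @return list: `genome` (modified), `locus` (genome id "g1", start,
#'   end, strand of the mature arm), `hairpin` (start, end of the whole
#'   stem-loop).
#' @export
plant_hairpin <- function(genome, mature, star_mismatches = 0,
                          loop_len = 8, flank_len = 20, seed = 1L) {
  genome <- as_rna(genome, "genome")
  mature <- as_rna(mature, "mature")
  if (loop_len < 3) stop("loop_len must be >= 3")
  if (star_mismatches > nchar(mature))
    stop("star_mismatches exceeds mature length")
  with_seed(seed, {
    star <- rc(mature)
    if (star_mismatches > 0) {
      schars <- strsplit(star, "")[[1]]
      mchars <- rev(strsplit(mature, "")[[1]])  # mature base opposite star i
      pos <- sample(nchar(star), star_mismatches)
      for (p in pos) {
        ok <- c("A", "C", "G", "U")
        ok <- ok[!is_pair(mchars[p], ok) & ok != schars[p]]
        schars[p] <- sample(ok, 1)
      }
      star <- paste(schars, collapse = "")
    }
    loop <- random_rna(1, loop_len)
    insert <- paste0(random_rna(1, flank_len), mature, loop, star,
                     random_rna(1, flank_len))
    if (nchar(genome) < nchar(insert))
      stop("genome shorter than the hairpin insert")
    at <- sample(0:nchar(genome), 1)        # insertion point, 0-based
    newg <- paste0(substr(genome, 1, at), insert,
                   substr(genome, at + 1, nchar(genome)))
    mstart <- at + flank_len
    list(genome = newg,
         locus = list(genome = "g1", start = mstart,
                      end = mstart + nchar(mature), strand = "+"),
         hairpin = list(start = mstart,
                        end = mstart + nchar(mature) + loop_len +
                          nchar(star)))
  })
}

## one isomiR read derived from a mature sequence
isomir_read <- function(mature, sub_rate, trunc_max, utail_max) {
  s <- mature
  if (stats::runif(1) < sub_rate) {
    p <- sample(nchar(s), 1)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "U"),
                                      substr(s, p, p)), 1)
  }
  if (trunc_max > 0) {
    tr <- sample(0:trunc_max, 1, prob = 2^-(0:trunc_max))
    if (tr > 0) s <- substr(s, 1, nchar(s) - tr)
  }
  if (utail_max > 0) {
    ut <- sample(0:utail_max, 1, prob = 2^-(0:utail_max))
    if (ut > 0) s <- paste0(s, strrep("U", ut))
  }
  s
}

#' Simulate a small-RNA library with ground truth
#'
#' Emits `depth` reads: miRNA-derived isomiRs (per-read substitution,
#' geometric-ish 3' truncation and U-tailing) for each catalog family with
#' log-normal expression, plus 24-nt substrings of the genome as siRNA
#' background. Every non-background read is attributable to exactly one
#' family.
#'
#' @param catalog a [mirna_catalog()] (non-empty).
#' @param genome genome sequence used for background reads.
#' @param config a [sim_config()].
#' @return list: `reads` (a [read_set()]), `truth` (list with
#'   `family_counts` data.frame (family, mature, arm, true_count) and
#'   `read_attribution` data.frame (seq, family, count) for non-background
#'   unique reads).
#' @export
simulate_library <- function(catalog, genome, config) {
  stopifnot(inherits(config, "SimulationConfig"), nrow(catalog) >= 1)
  genome <- as_rna(genome, "genome")
  with_seed(config$seed + 1L, {
    n_bg <- round(config$background_fraction * config$depth)
    n_mir <- config$depth - n_bg
    w <- rlnorm(nrow(catalog), 0, config$abundance_dispersion)
    fam_counts <- as.integer(rmultinom(1, n_mir, w))
    attribution <- list()
    all_seqs <- character(0); all_counts <- numeric(0)
    for (i in seq_len(nrow(catalog))) {
      if (fam_counts[i] == 0) next
      reads <- vapply(seq_len(fam_counts[i]), function(j)
        isomir_read(catalog$seq[i], config$substitution_rate,
                    config$truncation_max, config$utail_max),
        character(1))
      tb <- table(reads)
      attribution[[i]] <- data.frame(seq = names(tb),
                                     family = catalog$family[i],
                                     count = as.numeric(tb),
                                     stringsAsFactors = FALSE)
      all_seqs <- c(all_seqs, names(tb))
      all_counts <- c(all_counts, as.numeric(tb))
    }
    if (n_bg > 0) {
      glen <- nchar(genome)
      if (glen < 24) stop("genome too short for 24-nt background reads")
      ## background siRNAs are non-miRNA by construction: reject genome
      ## substrings that would satisfy the homology rule vs the catalog
      ## (e.g. windows overlapping a planted hairpin's mature arm)
      ok_start <- vapply(seq_len(glen - 23), function(s) {
        w <- substr(genome, s, s + 23)
        mm <- .prefix_mismatch_cpp(w, catalog$seq)
        ld <- 24 - nchar(catalog$seq)
        !any(mm <= 2 & abs(ld) <= 1)
      }, logical(1))
      starts <- sample(which(ok_start), n_bg, replace = TRUE)
      bg <- substring(genome, starts, starts + 23)
      tb <- table(bg)
      all_seqs <- c(all_seqs, names(tb))
      all_counts <- c(all_counts, as.numeric(tb))
    }
    rs <- read_set(all_seqs, all_counts, library_id = "sim",
                   species = "Sim")
    truth <- list(
      family_counts = data.frame(family = catalog$family,
                                 mature = catalog$seq, arm = catalog$arm,
                                 true_count = fam_counts,
                                 stringsAsFactors = FALSE),
      read_attribution = do.call(rbind, attribution))
    list(reads = rs, truth = truth)
  })
}

#' Plant a miRNA target site into a transcript
#'
#' Splices the reverse complement of the miRNA into the transcript so the
#' site is a perfect target; returns the modified transcript, the site
#' interval, and the expected cleavage position (target base opposite
#' miRNA position 10, 0-based).
#'
#' @param transcript transcript sequence.
#' @param mirna mature miRNA sequence.
#' @param at 0-based insertion point; random when `NULL`.
#' @param seed seed for the random insertion point.
#' @return list: `transcript`, `site_start`, `site_end`,
#'   `cleavage_position`.
#' @export
plant_target_site <- function(transcript, mirna, at = NULL, seed = 1L) {
  transcript <- as_rna(transcript, "transcript")
  mirna <- as_rna(mirna, "miRNA")
  site <- rc(mirna)
  L <- nchar(mirna)
  if (is.null(at)) at <- with_seed(seed, sample(0:nchar(transcript), 1))
  tx <- paste0(substr(transcript, 1, at), site,
               substr(transcript, at + 1, nchar(transcript)))
  list(transcript = tx, site_start = at, site_end = at + L,
       cleavage_position = at + L - 10L)
}

#' Simulate a degradome/PARE tag library
#'
#' Signal tags are 20-nt transcript substrings starting at the planted
#' cleavage positions; noise tags start at uniform random positions.
#' `depth` tags are emitted in total.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param planted_sites data.frame: transcript, position (0-based tag
#'   5'-end), mirna (label carried to truth).
#' @param depth total tag count.
#' @param noise_fraction fraction of tags at uniform random positions.
#' @param seed integer seed.
#' @param tag_len tag length (>= 19).
#' @return list: `tags` (a [read_set()]), `truth` (the planted sites).
#' @export
simulate_degradome <- function(transcripts, planted_sites, depth = 1e4,
                               noise_fraction = 0.2, seed = 1L,
                               tag_len = 20L) {
  if (is.null(names(transcripts)))
    names(transcripts) <- paste0("t", seq_along(transcripts))
  transcripts <- vapply(transcripts, as_rna, character(1),
                        name = "transcript")
  for (i in seq_len(nrow(planted_sites))) {
    tx <- transcripts[[planted_sites$transcript[i]]]
    p <- planted_sites$position[i]
    if (p < 0 || p + tag_len > nchar(tx))
      stop("planted site outside transcript")
  }
  with_seed(seed, {
    n_noise <- round(noise_fraction * depth)
    n_sig <- depth - n_noise
    seqs <- character(0)
    if (n_sig > 0 && nrow(planted_sites) > 0) {
      site_of <- sample(nrow(planted_sites), n_sig, replace = TRUE)
      seqs <- vapply(site_of, function(i) {
        tx <- transcripts[[planted_sites$transcript[i]]]
        substr(tx, planted_sites$position[i] + 1,
               planted_sites$position[i] + tag_len)
      }, character(1))
    }
    if (n_noise > 0) {
      tx_of <- sample(length(transcripts), n_noise, replace = TRUE)
      noise <- vapply(tx_of, function(i) {
        tx <- transcripts[[i]]
        s <- sample(nchar(tx) - tag_len + 1, 1)
        substr(tx, s, s + tag_len - 1)
      }, character(1))
      seqs <- c(seqs, noise)
    }
    tb <- table(seqs)
    tags <- read_set(names(tb), as.numeric(tb), library_id = "pare",
                     species = "Sim")
    list(tags = tags, truth = planted_sites)
  })
}
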