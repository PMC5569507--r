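test_that("match_candidate enforces <3 substitutions and <2 nt length diff", {
  s <- "UGACAGAAGAGAGUGAGCACA"
  expect_true(match_candidate(s, s)$is_match)
  expect_equal(match_candidate(s, s)$substitutions, 0)

  s3 <- s
  for (p in c(3, 10, 18))
    substr(s3, p, p) <- setdiff(rna_bases, substr(s3, p, p))[1]
  expect_false(match_candidate(s3, s)$is_match)   # 3 subs: out

  expect_false(match_candidate(substr(s, 1, 19), s)$is_match)  # 2 nt shorter

  s2 <- substr(s, 1, 20)                           # 1 nt shorter
  for (p in c(4, 12))
    substr(s2, p, p) <- setdiff(rna_bases, substr(s2, p, p))[1]
  m <- match_candidate(s2, s)
  expect_true(m$is_match)                          # boundary: 2 subs + 1 nt
  expect_equal(m$substitutions, 2)
  expect_equal(m$length_difference, -1)
})

test_that("match_candidate agrees with the literal oracle and is symmetric", {
  set.seed(52)
  for (i in 1:300) {
    q <- rand_seq(sample(18:24, 1))
    r <- if (i %% 2) rand_seq(sample(18:24, 1)) else {
      x <- q
      for (p in sample(nchar(x), sample(0:4, 1)))
        substr(x, p, p) <- sample(setdiff(rna_bases, substr(x, p, p)), 1)
      if (i %% 4 == 0) substr(x, 1, nchar(x) - sample(0:2, 1)) else x
    }
    got <- match_candidate(q, r)
    want <- oracle_match(q, r)
    expect_equal(got$substitutions, want$substitutions)
    expect_equal(got$is_match, want$is_match)
    if (nchar(q) == nchar(r)) {
      expect_equal(got$substitutions, match_candidate(r, q)$substitutions)
    }
  }
})

test_that("identify_candidates assigns the minimal (subs, |len diff|) reference", {
  cat <- mirna_catalog(c("miR166", "miR399"),
                       c("UCGGACCAGGCUUCAUUCCCC", "UGCCAAAGGAGAGUUGCCCUG"))
  rs <- read_set("UCGGACCAGGCUUCAUUCCCC", 10)
  hit <- identify_candidates(rs, cat)
  expect_equal(hit$family, "miR166")
  expect_equal(hit$substitutions, 0)

  ## read at distance (1,0) from A and (2,0) from B -> A wins
  a <- "AAGCUCAGGAGGGAUAGCGCC"
  b <- a; substr(b, 5, 5) <- "A"; substr(b, 15, 15) <- "C"
  q <- a; substr(q, 5, 5) <- "A"
  cat2 <- mirna_catalog(c("famA", "famB"), c(a, b))
  hit2 <- identify_candidates(read_set(q, 3), cat2)
  expect_equal(hit2$family, "famA")
  expect_equal(hit2$substitutions, 1)

  ## non-matching reads are dropped
  none <- identify_candidates(read_set(rand_seq(16), 5), cat)
  expect_equal(nrow(none), 0)
})

test_that("merge_families unions mutually matching families transitively", {
  a <- "UGACAGAAGAGAGUGAGCACA"
  b <- a; substr(b, 7, 7) <- "C"                  # 1 sub from a
  c_ <- b; substr(c_, 14, 14) <- "G"; substr(c_, 20, 20) <- "U"
  ## c_ is 1-2 subs from b but 3 from a -> chain a~b, b~c, a!~c
  expect_false(match_candidate(a, c_)$is_match)
  far <- "CCCCAAAAGGGGUUUUCCCCA"
  cat <- mirna_catalog(c("miR156", "miR157", "miR158", "miR399"),
                       c(a, b, c_, far))
  map <- merge_families(cat)
  expect_equal(unname(map["miR156"]), "miR156/157/158")  # closure
  expect_equal(unname(map["miR157"]), map[["miR156"]])
  expect_equal(unname(map["miR399"]), "miR399")           # >2 subs: kept apart

  ## agree with the matrix-powering closure oracle
  want <- oracle_merge_groups(cat)
  got_groups <- split(names(map), map)
  want_groups <- split(names(want), want)
  expect_setequal(unname(lapply(got_groups, sort)),
                  unname(lapply(want_groups, sort)))
})

test_that("merged names join numeric suffixes, short form elides shared digits", {
  a <- "UGACAGAAGAGAGUGAGCACA"
  b <- a; substr(b, 7, 7) <- "C"
  cat <- mirna_catalog(c("miR156", "miR157"), c(a, b))
  expect_equal(unname(merge_families(cat)["miR156"]), "miR156/157")
  expect_equal(unname(merge_families(cat, short_names = TRUE)["miR156"]),
               "miR156/7")
})

test_that("cluster_by_prefix groups on the 5' 16-mer with stated tie-breaks", {
  p16 <- rand_seq(16)
  s21 <- paste0(p16, "ACGUA")
  s22 <- paste0(p16, "ACGUAC")
  other <- paste0(substr(p16, 1, 15),
                  setdiff(rna_bases, substr(p16, 16, 16))[1], "GGGGG")
  cand <- data.frame(seq = c(s21, s22, other),
                     count = c(100, 10, 7),
                     family = "miR166", arm = "3p",
                     stringsAsFactors = FALSE)
  cl <- cluster_by_prefix(cand)
  expect_equal(nrow(cl), 2)             # position-16 difference splits
  top <- cl[cl$prefix == p16, ]
  expect_equal(top$seq, s21)            # most abundant is representative
  expect_equal(top$cluster_count, 110)
  expect_equal(top$n_members, 2)

  ## equal counts: the shorter sequence wins
  tie <- data.frame(seq = c(s22, s21), count = c(50, 50),
                    family = "miR166", arm = "3p", stringsAsFactors = FALSE)
  expect_equal(cluster_by_prefix(tie)$seq, s21)
})

test_that("clustering is a partition preserving total counts", {
  set.seed(61)
  prefixes <- replicate(5, rand_seq(16))
  cand <- data.frame(
    seq = vapply(1:40, function(i)
      paste0(sample(prefixes, 1), rand_seq(sample(4:6, 1))), character(1)),
    count = sample(1:100, 40, TRUE),
    family = "miRX", arm = NA_character_, stringsAsFactors = FALSE)
  cl <- cluster_by_prefix(cand)
  expect_equal(sum(cl$cluster_count), sum(cand$count))
  expect_equal(sum(cl$n_members), nrow(cand))
  expect_equal(anyDuplicated(cl$prefix), 0)
})

test_that("abundance filter takes the higher of 10 reads and 5 RPM", {
  mk <- function(counts) data.frame(raw_count = counts)
  ## total 1e6: 5 RPM = 5 reads, so T = 10
  out <- apply_abundance_filter(mk(c(11, 10)), 1e6)
  expect_equal(out$raw_count, 11)
  ## total 1e7: 5 RPM = 50 reads, so T = 50; 30 reads dropped
  expect_equal(nrow(apply_abundance_filter(mk(30), 1e7)), 0)
  expect_equal(apply_abundance_filter(mk(51), 1e7)$raw_count, 51)
  ## tiny library: the 10-read floor still applies
  expect_equal(nrow(apply_abundance_filter(mk(10), 1)), 0)
  expect_equal(apply_abundance_filter(mk(11), 1)$raw_count, 11)
  ## "either" rule admits anything above the lower threshold
  expect_equal(apply_abundance_filter(mk(30), 1e7, rule = "either")$raw_count,
               30)
})

test_that("abundance filter agrees with the literal rule oracle", {
  set.seed(62)
  for (i in 1:1000) {
    count <- sample(1:200, 1)
    total <- sample(c(1e3, 1e5, 1e6, 2e6, 1e7, 4e7), 1)
    kept <- nrow(apply_abundance_filter(data.frame(raw_count = count),
                                        total)) == 1
    expect_equal(kept, oracle_abundance_keep(count, total),
                 info = paste(count, total))
  }
})

test_that("name_candidate formats Species-family.serial_count", {
  expect_equal(name_candidate("Smo", "miR170/1-3p", 2380, 3761),
               "Smo-miR170/1-3p.2380_3761")
  expect_equal(name_candidate("Era", "miR168", 921, 57), "Era-miR168.921_57")
  expect_equal(name_candidate("Xxx", "miR1", 1, 1), "Xxx-miR1.1_1")
  expect_error(name_candidate("Xxx", "miR1", 0, 1))
})

test_that("no-noise library yields exactly the expressed families, no extras", {
  cfg <- sim_config(seed = 5, n_families = 8, substitution_rate = 0,
                    truncation_max = 0, utail_max = 0, depth = 20000,
                    background_fraction = 0.25)
  catalog <- generate_reference_catalog(cfg)
  genome <- { set.seed(99); rand_seq(3000) }
  sim <- simulate_library(catalog, genome, cfg)
  rs <- preprocess_reads(sim$reads)
  res <- identify_mirnas(rs, catalog, "Sim")
  truth <- sim$truth$family_counts
  thr <- max(10, 5 * rs$total_18_26 / 1e6)
  expressed <- truth$family[truth$true_count > thr]
  expect_setequal(res$family, expressed)
  ## one cluster per 5'-16-mer (all reads are exact matures here)
  expect_equal(nrow(res), length(expressed))
})

test_that("identify pipeline is deterministic", {
  cfg <- sim_config(seed = 6, n_families = 5, depth = 5000)
  catalog <- generate_reference_catalog(cfg)
  genome <- { set.seed(98); rand_seq(2000) }
  sim <- simulate_library(catalog, genome, cfg)
  rs <- preprocess_reads(sim$reads)
  r1 <- identify_mirnas(rs, catalog, "Sim")
  r2 <- identify_mirnas(rs, catalog, "Sim")
  expect_identical(r1, r2)
})
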