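test_that("size_distribution tabulates counts and proportions", {
  rs <- read_set(c(rand_seq(21), rand_seq(24)), c(100, 300))
  d <- size_distribution(rs)
  expect_equal(d$proportion[d$length == 21], 0.25)
  expect_equal(d$proportion[d$length == 24], 0.75)
  expect_equal(sum(d$proportion), 1, tolerance = 1e-12)

  all21 <- read_set(rand_seq(21), 50)
  expect_equal(size_distribution(all21)$proportion[6], 1)
  expect_error(size_distribution(read_set(character(), numeric())), "empty")
})

test_that("proportions sum to 1 on simulated libraries", {
  cfg <- sim_config(seed = 15, n_families = 5, depth = 5000)
  catalog <- generate_reference_catalog(cfg)
  set.seed(111); genome <- rand_seq(2000)
  sim <- simulate_library(catalog, genome, cfg)
  d <- size_distribution(sim$reads)
  expect_equal(sum(d$proportion), 1, tolerance = 1e-12)
})

test_that("ratio_24_21 is count(24)/count(21), NA when undefined", {
  rs <- read_set(c(rand_seq(21), rand_seq(24)), c(100, 200))
  expect_equal(ratio_24_21(rs), 2)
  only21 <- read_set(rand_seq(21), 10)
  expect_equal(ratio_24_21(only21), 0)
  only24 <- read_set(rand_seq(24), 10)
  expect_true(is.na(ratio_24_21(only24)))
})

test_that("exact Wilcoxon p for {1,2,3} vs {4,5,6} is 0.1 by enumeration", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$p.value, 0.1)
  ## independent check: enumerate all C(6,3) rank assignments
  ranks <- 1:6
  sums <- apply(combn(6, 3), 2, function(idx) sum(ranks[idx]))
  w <- sum(1:3)
  p_enum <- min(1, 2 * min(mean(sums <= w), mean(sums >= w)))
  expect_equal(res$p.value, p_enum)
})

test_that("identical groups give p = 1", {
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2))$p.value, 1)
  expect_equal(wilcoxon_rank_sum(c(1, 5, 9), c(1, 5, 9))$p.value, 1)
})

test_that("exact mode matches stats::wilcox.test on untied data", {
  set.seed(112)
  for (i in 1:100) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    x <- sample(1:1000, na + nb)    # no ties
    a <- x[1:na]; b <- x[-(1:na)]
    ours <- wilcoxon_rank_sum(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_true(ours$exact)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9,
                 info = paste("case", i))
  }
})

test_that("large samples fall back to the corrected normal approximation", {
  set.seed(113)
  a <- rnorm(20); b <- rnorm(25, 0.5)
  ours <- wilcoxon_rank_sum(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_false(ours$exact)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
  ## with ties
  a2 <- sample(1:5, 20, TRUE); b2 <- sample(2:6, 20, TRUE)
  expect_equal(wilcoxon_rank_sum(a2, b2)$p.value,
               suppressWarnings(stats::wilcox.test(a2, b2, exact = FALSE,
                                                   correct = TRUE)$p.value),
               tolerance = 1e-9)
})

test_that("five_prime_composition returns fractions summing to 1", {
  seqs <- c("UAAG", "UCCG", "UGGA", "CAAA")
  comp <- five_prime_composition(seqs)
  expect_equal(comp$fraction[comp$nt == "U"], 0.75)
  expect_equal(comp$fraction[comp$nt == "C"], 0.25)
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-12)

  allU <- five_prime_composition(c("UAAA", "UCCC"))
  expect_equal(allU$fraction[allU$nt == "U"], 1)

  by_sp <- five_prime_composition(rep(seqs, 2),
                                  by = rep(c("a", "b"), each = 4))
  sums <- tapply(by_sp$fraction, by_sp$group, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-12)
})

test_that("chi-squared test matches the closed form, monotone in the gap", {
  same <- chi2_composition_test(c(80, 20), c(40, 10))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p.value, 1)

  tab <- rbind(c(90, 10), c(50, 50))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  by_hand <- sum((tab - E)^2 / E)
  res <- chi2_composition_test(c(90, 10), c(50, 50))
  expect_equal(res$statistic, by_hand, tolerance = 1e-12)
  expect_equal(res$p.value,
               stats::chisq.test(tab, correct = FALSE)$p.value,
               tolerance = 1e-12)

  ## widening the composition gap at fixed totals shrinks p
  ps <- vapply(0:4, function(k)
    chi2_composition_test(c(60 + k * 5, 40 - k * 5), c(50, 50))$p.value,
    numeric(1))
  expect_true(all(diff(ps) < 0))

  expect_error(chi2_composition_test(c(0, 0), c(5, 5)), "marginal")
})

test_that("consensus_and_variation counts substitutions + length diff", {
  s <- "UGAGGUAGUAGGUUGUAUAGU"
  expect_equal(consensus_and_variation(c(s, s, s))$mean, 0)
  expect_equal(consensus_and_variation(c(s, s, s))$consensus, s)

  s1 <- s; substr(s1, 9, 9) <- "C"
  cv <- consensus_and_variation(c(s, s, s1))
  expect_equal(cv$consensus, s)
  expect_equal(cv$variation, c(0, 0, 1))
  expect_equal(cv$mean, 1 / 3, tolerance = 1e-12)

  ## truncated member: length difference adds to variation
  cv2 <- consensus_and_variation(c(s, s, substr(s, 1, 19)))
  expect_equal(cv2$variation, c(0, 0, 2))

  ## engineered family lands in the "<1 average variation" band
  fam <- c(s, s, s, s1, substr(s, 1, 20))
  expect_lt(consensus_and_variation(fam)$mean, 1)

  ## mean variation is 0 iff all identical
  expect_gt(consensus_and_variation(c(s, s1))$mean, 0)
})

test_that("classify_conservation labels broad/high families class I", {
  set.seed(114)
  n_sp <- 20
  sp <- paste0("sp", 1:n_sp)
  m <- matrix(0, 12, n_sp, dimnames = list(paste0("fam", 1:12), sp))
  m[1:4, ] <- matrix(runif(4 * n_sp, 800, 1200), 4)     # everywhere, high
  m[5:8, 11:20] <- matrix(runif(40, 400, 600), 4)       # "ferns" only
  m[9:12, sample(n_sp, 3)] <- runif(12, 900, 1100)      # sporadic
  cls <- classify_conservation(m, top = 12, k = 3)
  broad <- cls$family[cls$class == "I"]
  expect_setequal(broad, paste0("fam", 1:4))
  expect_true(all(cls$conserved[cls$family %in% paste0("fam", 1:4)]))
  fern_cls <- unique(cls$class[cls$family %in% paste0("fam", 5:8)])
  expect_equal(fern_cls, "II")

  ## invariant to column permutation
  perm <- sample(n_sp)
  cls_p <- classify_conservation(m[, perm], top = 12, k = 3)
  expect_equal(cls_p[order(cls_p$family), c("family", "class")],
               cls[order(cls$family), c("family", "class")])

  ## robust to uniform rescaling of RPMs on well-separated blocks
  cls_s <- classify_conservation(m * 3, top = 12, k = 3)
  expect_equal(cls_s[order(cls_s$family), c("family", "class")],
               cls[order(cls$family), c("family", "class")])

  expect_error(classify_conservation(m[1:2, ], top = 2, k = 3), "fewer")
})
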