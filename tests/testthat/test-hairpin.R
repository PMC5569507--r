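test_that("map_exact finds planted loci on both strands, ordered", {
  set.seed(81)
  g <- rand_seq(400)
  cand <- rand_seq(21)
  gp <- paste0(substr(g, 1, 100), cand, substr(g, 101, 250),
               rc(cand), substr(g, 251, 400))
  hits <- map_exact(cand, c(chr1 = gp))
  expect_equal(nrow(hits), 2)
  expect_equal(hits$start, c(100, 271))
  expect_equal(hits$strand, c("+", "-"))
  expect_equal(hits$end - hits$start, rep(21, 2))

  expect_equal(nrow(map_exact(rand_seq(21), c(chr1 = gp))), 0)
})

test_that("map_exact reports every copy of a high-copy candidate", {
  set.seed(82)
  cand <- rand_seq(21)
  g <- paste(replicate(50, paste0(rand_seq(30), cand)), collapse = "")
  hits <- map_exact(cand, c(chr1 = g))
  expect_equal(nrow(hits), 50)
  v <- hairpin_validate_candidate(cand, c(chr1 = g))
  expect_true(v$high_copy)
  expect_equal(v$n_loci, 50)
})

test_that("extract_window takes 200-nt flanks, truncated at ends", {
  set.seed(83)
  g <- c(chr = rand_seq(10000))
  cand <- substr(g[[1]], 501, 521)
  loc <- list(genome = "chr", start = 500L, end = 521L, strand = "+")
  w <- extract_window(loc, g)
  expect_equal(nchar(w$window), 421)          # [300, 721)
  expect_equal(w$offset, 200)
  expect_equal(substr(w$window, 201, 221), cand)

  loc2 <- list(genome = "chr", start = 10L, end = 31L, strand = "+")
  w2 <- extract_window(loc2, g)
  expect_equal(w2$offset, 10)                 # left flank truncated
  expect_equal(nchar(w2$window), 10 + 21 + 200)
})

test_that("minus-strand windows contain the candidate verbatim", {
  set.seed(84)
  cand <- rand_seq(21)
  g <- c(chr = paste0(rand_seq(300), rc(cand), rand_seq(300)))
  hit <- map_exact(cand, g)
  expect_equal(hit$strand, "-")
  w <- extract_window(hit[1, ], g)
  expect_equal(substr(w$window, w$offset + 1, w$offset + 21), cand)
})

test_that("fold_maxpair handles the contract examples", {
  expect_equal(fold_maxpair("GGGAAAACCC")$pairs, 3)
  expect_equal(fold_maxpair("GGGAAAACCC")$structure, "(((....)))")
  expect_equal(fold_maxpair("AAAAAA")$pairs, 0)
})

test_that("fold_maxpair equals the enumeration oracle on random 12-mers", {
  set.seed(85)
  for (i in 1:60) {
    s <- rand_seq(12)
    expect_equal(fold_maxpair(s)$pairs, oracle_max_pairs(s), info = s)
  }
})

test_that("fold_maxpair structures are well-formed and consistent", {
  set.seed(86)
  for (i in 1:40) {
    s <- rand_seq(sample(8:30, 1))
    f <- fold_maxpair(s)
    expect_equal(nchar(f$structure), nchar(s))
    ch <- strsplit(f$structure, "")[[1]]
    expect_equal(sum(ch == "("), f$pairs)
    expect_equal(sum(ch == "("), sum(ch == ")"))
    ## every reported pair is a legal pairing with loop >= 3
    sc <- strsplit(s, "")[[1]]
    stack <- integer()
    for (k in seq_along(ch)) {
      if (ch[k] == "(") stack <- c(stack, k)
      if (ch[k] == ")") {
        j <- stack[length(stack)]; stack <- stack[-length(stack)]
        expect_true(paste0(sc[j], sc[k]) %in%
                      c("AU", "UA", "GC", "CG", "GU", "UG"))
        expect_gte(k - j - 1, 3)
      }
    }
  }
})

test_that("validate_hairpin counts unpaired candidate positions", {
  set.seed(87)
  cand <- rand_seq(21)
  loop <- rand_seq(8)
  window <- paste0(cand, loop, rc(cand))
  fit <- hairpin_arm_fit(cand, window, 0)
  expect_equal(fit$mismatches, 0)
  v <- validate_hairpin(cand, window, fit$structure, 0)
  expect_equal(v$mature_arm_mismatches, 0)
  expect_true(v$passed)

  expect_error(validate_hairpin(cand, window, "...", 0), "length")
  expect_error(validate_hairpin(rand_seq(21), window, fit$structure, 0),
               "offset")
})

test_that("self-pairing candidates fail the one-arm requirement", {
  ## palindromic candidate folds onto itself inside the window
  cand <- paste0("GGGGGGGGG", "AAAA", "CCCCCCCCC")  # 22 nt self-hairpin
  window <- paste0("AAAAA", cand, "AAAAA")
  db <- fold_window(window)
  v <- validate_hairpin(cand, window, db, 5)
  expect_false(v$one_arm)
  expect_false(v$passed)
})

test_that("planted star mismatches are recovered exactly at the boundary", {
  set.seed(88)
  for (sm in c(0, 3, 4, 5)) {
    m <- rand_seq(21)
    g <- rand_seq(300)
    ph <- plant_hairpin(g, m, star_mismatches = sm, seed = 200 + sm)
    v <- hairpin_validate_candidate(m, c(g1 = ph$genome))
    if (sm < 4) {
      expect_equal(min(v$loci$mismatches), sm, info = paste("sm", sm))
    } else {
      ## a random register can beat the mutated star by a little, but
      ## never below the pass threshold
      expect_gte(min(v$loci$mismatches), 4)
    }
    expect_equal(v$passed, sm < 4, info = paste("sm", sm))
  }
})

test_that("arm mismatches are monotone under nested star mutations", {
  ## mutate the same window incrementally so each step only adds damage
  set.seed(89)
  m <- rand_seq(21)
  star <- rc(m)
  flank <- rand_seq(60)
  mut_order <- sample(21)
  mism <- numeric(9)
  for (k in 0:8) {
    st <- strsplit(star, "")[[1]]
    mrev <- rev(strsplit(m, "")[[1]])
    for (p in mut_order[seq_len(k)]) {
      ok <- setdiff(c("A", "C", "G", "U"), st[p])
      ok <- ok[!is_pair_chr(mrev[p], ok)]
      st[p] <- ok[1]
    }
    window <- paste0(flank, m, "GCAAAAGC", paste(st, collapse = ""), flank)
    mism[k + 1] <- hairpin_arm_fit(m, window, 60)$mismatches
  }
  expect_true(all(diff(mism) >= 0))
})
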