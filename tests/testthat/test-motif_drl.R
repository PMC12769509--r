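test_that("canonical_label pools cyclic permutations and reverse complements", {
  expect_equal(canonical_label("CTG")$label, "AGC")
  expect_equal(canonical_label("A")$label, "A")
  expect_equal(canonical_label("GCA")$label, "AGC") # min of {CAG,AGC,GCA,CTG,TGC,GCT}
  expect_setequal(canonical_label("A")$members, c("A", "T"))
  expect_error(canonical_label("AXT"), "alphabet")
  expect_error(canonical_label("AA"), "degenerate")
  expect_error(canonical_label("CACA"), "degenerate")
})

test_that("canonical_label is idempotent and constant on each class", {
  for (k in 1:4) {
    for (cl in motif_classes_of_length(k)) {
      labs <- vapply(cl$members, function(m) canonical_label(m)$label,
                     character(1))
      expect_true(all(labs == cl$label))
      expect_equal(canonical_label(cl$label)$label, cl$label)
      expect_true(all(nchar(cl$members) == k))
    }
  }
})

test_that("extract_drl counts maximal tracts and isolated single units", {
  # strand-pooled (class A includes T runs)
  d <- extract_drl("AATAAAT", 1L)
  expect_equal(d$A$counts, c(2, 1, 1)) # two isolated T's, one AA, one AAA
  # without reverse-complement pooling, A and T tracts are separate
  d2 <- extract_drl("AATAAAT", 1L, reverse_complement = FALSE)
  expect_equal(d2$A$counts, c(0, 1, 1))
  expect_equal(d2$T$counts, c(2))

  d3 <- extract_drl("CAGCAGCAG", 3L)
  expect_equal(d3$AGC$counts, c(0, 0, 1)) # one maximal 9-nt region, L = 3

  d4 <- extract_drl("ATATAT", c(1L, 2L))
  expect_equal(d4$AT$counts, c(0, 0, 1))
  expect_equal(sum(d4$AC$counts), 0)
  d5 <- extract_drl("ATATAT", c(1L, 2L), reverse_complement = FALSE)
  expect_equal(d5$A$counts, c(3))  # each isolated A is an L = 1 tract
  expect_equal(d5$T$counts, c(3))
  expect_equal(sum(d5$C$counts), 0)

  expect_equal(sum(extract_drl("", 1L)$A$counts), 0)
  # N breaks tracts
  d6 <- extract_drl("AANAA", 1L)
  expect_equal(d6$A$counts, c(0, 2))
})

test_that("extract_drl agrees with a brute-force scanner on random strings", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    s <- paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                      prob = c(0.3, 0.25, 0.2, 0.2, 0.05)), collapse = "")
    for (k in 1:3) {
      got <- extract_drl(s, k)
      want <- brute_extract(s, k)
      for (lab in names(got)) {
        w <- want[[lab]]
        if (is.null(w)) w <- numeric(0)
        g <- got[[lab]]$counts
        length(g) <- max(length(g), length(w), 1)
        length(w) <- length(g)
        g[is.na(g)] <- 0; w[is.na(w)] <- 0
        expect_equal(g, w, info = sprintf("seq %s k=%d class %s", s, k, lab))
      }
    }
  }
})

test_that("non-motif histogram measures stretches without the motif", {
  expect_equal(extract_nonmotif_histogram("AATAAAT", "A"), c("1" = 2))
  expect_equal(length(extract_nonmotif_histogram("AAAA", "A")), 0)
  expect_equal(extract_nonmotif_histogram("TTTT", "A"), c("4" = 1))
  # member pooling sums the per-orientation histograms
  pooled <- extract_nonmotif_histogram("AATAAAT", "A", pool_members = TRUE)
  expect_equal(pooled, c("1" = 2, "2" = 1, "3" = 1))
})

test_that("coverage bookkeeping: tracts plus B stretches tile the sequence", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(20:80, 1)
    s <- paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")
    d <- extract_drl(s, 1L, reverse_complement = FALSE)
    a_len <- sum(seq_along(d$A$counts) * d$A$counts)
    bh <- extract_nonmotif_histogram(s, "A")
    b_len <- sum(as.integer(names(bh)) * bh)
    expect_equal(a_len + b_len, n)
  }
})

test_that("normalization is conditional on L >= L_min and invertible", {
  d <- drl(c("4" = 3, "5" = 1))
  nd <- normalize_drl(d, 4L)
  expect_equal(nd$probs[4:5], c(0.75, 0.25))
  d2 <- drl(c("1" = 100, "4" = 1))
  expect_equal(normalize_drl(d2, 4L)$probs[[4]], 1)
  d3 <- drl(c("1" = 7, "2" = 3, "5" = 2))
  expect_equal(sum(normalize_drl(d3, 1L)$probs), 1)
  # round trip restores counts on bins >= L_min exactly
  back <- rescale_to(normalize_drl(d3, 2L))
  expect_equal(back$counts[2:5], d3$counts[2:5])
  expect_error(normalize_drl(drl(c("1" = 5)), 4L), "degenerate")
})

test_that("truncation removes everything from the first low bin upward", {
  d <- drl(c(100, 50, 10, 40))
  expect_equal(truncate_low_counts(d)$counts, c(100, 50))
  d2 <- drl(c(100, 50, 40))
  expect_equal(truncate_low_counts(d2)$counts, c(100, 50, 40))
  expect_equal(length(truncate_low_counts(drl(c("1" = 5)))$counts), 0)
})

test_that("median DRL takes per-bin medians (mean of central two when even)", {
  mk <- function(v) structure(list(motif = canonical_label("A"), L_min = 1L,
                                   probs = v, total = 1),
                              class = "normalized_drl")
  e1 <- list(mk(c(0.1, 0.9)))
  expect_equal(median_drl(e1)$probs, c(0.1, 0.9))
  e3 <- list(mk(c(0.1, 0.9)), mk(c(0.2, 0.8)), mk(c(0.9, 0.1)))
  expect_equal(median_drl(e3)$probs[1], 0.2)
  e2 <- list(mk(c(0.1, 0.9)), mk(c(0.3, 0.7)))
  expect_equal(median_drl(e2)$probs[1], 0.2)
})

test_that("shuffle control preserves composition and is seed-reproducible", {
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  sh1 <- shuffle_control(s, seed = 3)
  sh2 <- shuffle_control(s, seed = 3)
  expect_identical(sh1, sh2)
  expect_equal(sort(strsplit(sh1, "")[[1]]), sort(strsplit(s, "")[[1]]))
  expect_false(identical(sh1, shuffle_control(s, seed = 4)))
})

test_that("shuffled-genome mono-A tract counts follow the i.i.d. expectation", {
  G <- 1e7
  p <- 0.37
  g <- generate_genome(G, p_A = p, alphabet = "four_letter", seed = 21)
  d <- extract_drl(g, 1L, reverse_complement = FALSE)$A$counts
  for (L in 1:8) {
    expected <- G * (1 - p)^2 * p^L
    tol <- 4 * sqrt(expected)
    expect_lt(abs(d[L] - expected), tol)
  }
})

test_that("segment bootstrap drops extremes and is deterministic", {
  set.seed(11)
  s <- paste(sample(c("A", "C"), 4000, replace = TRUE,
                    prob = c(0.4, 0.6)), collapse = "")
  ci <- bootstrap_ci(s, "A", segment_length = 1000, n_boot = 200, seed = 2)
  expect_equal(ci$n_drop, floor(25 * 200 / 1000))
  ci2 <- bootstrap_ci(s, "A", segment_length = 1000, n_boot = 200, seed = 2)
  expect_identical(ci, ci2)
  expect_true(all(ci$lo <= ci$hi))
  # identical segments give zero-width intervals
  seg <- paste(rep("AACAA", 200), collapse = "")
  four <- paste(rep(seg, 4), collapse = "")
  ci3 <- bootstrap_ci(four, "A", segment_length = 1000, n_boot = 100, seed = 1)
  expect_equal(ci3$lo, ci3$hi)
  expect_error(bootstrap_ci("ACGT", "A", segment_length = 1e6),
               "insufficient")
})
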