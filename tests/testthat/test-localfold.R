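test_that("span-bounded folding with L = n reproduces the global fold", {
  hits <- lfold("GGGAAACCC", TOY, L = 9)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$structure, "(((...)))")
  expect_equal(hits$energy, -1.20)
  expect_equal(hits$start, 1L)
  set.seed(801)
  for (rep in 1:8) {
    s <- random_rna(sample(20:35, 1), gc = 0.6)
    r <- fold(s, TURNER)
    hits <- lfold(s, TURNER, L = nchar(s))
    if (r$energy == 0) {
      expect_equal(nrow(hits), 0L)
    } else if (length(loopfold:::.branches(r$pair_table, 1L, nchar(s))) == 1L) {
      expect_equal(min(hits$energy), r$energy, tolerance = 1e-9)
    } else {
      expect_lte(min(hits$energy), 0)
      expect_gte(min(hits$energy), r$energy - 1e-9)
    }
  }
})

test_that("identical cassettes far apart give translated hits with equal energies", {
  cassette <- "GGGGGAAACCCCC"
  s <- paste0("AAAA", cassette, paste(rep("A", 40), collapse = ""),
              cassette, "AAAA")
  hits <- lfold(s, TURNER, L = 20)
  best <- hits[hits$energy == min(hits$energy), ]
  expect_equal(nrow(best), 2L)
  expect_equal(diff(best$start), 13L + 40L)
  expect_equal(best$structure[1], best$structure[2])
  expect_equal(best$energy[1], best$energy[2])
})

test_that("homopolymers yield no local hits and small spans are rejected", {
  expect_equal(nrow(lfold(paste(rep("A", 50), collapse = ""), TURNER, L = 20)), 0L)
  expect_error(lfold("GGGAAACCC", TURNER, L = 4), "exceed 4")
})

test_that("every hit respects the span bound and evaluates to its energy", {
  set.seed(802)
  s <- random_rna(60, gc = 0.6)
  L <- 15
  hits <- lfold(s, TURNER, L = L)
  for (r in seq_len(nrow(hits))) {
    expect_lte(hits$end[r] - hits$start[r], L)
    pt <- parse_dot_bracket(hits$structure[r])
    spans <- which(pt > seq_along(pt))
    expect_true(all(pt[spans] - spans <= L))
  }
})

test_that("single-window scanning reproduces the global pair probabilities", {
  set.seed(803)
  s <- random_rna(13, gc = 0.7)
  pf <- partition_function(s, TURNER)
  pl <- plfold(s, TURNER, W = 13)
  expect_lt(max(abs(pl$bpp - pf$bpp)), 1e-12)
})

test_that("windowed probabilities are the arithmetic mean over qualifying windows", {
  set.seed(804)
  s <- random_rna(14, gc = 0.7)
  W <- 12
  pl <- plfold(s, TURNER, W = W)
  n <- 14
  ref <- matrix(0, n, n); cnt <- matrix(0, n, n)
  for (a in 1:(n - W + 1)) {
    wpf <- partition_function(substr(unclass(s), a, a + W - 1), TURNER)
    idx <- a:(a + W - 1)
    ref[idx, idx] <- ref[idx, idx] + wpf$bpp
    cnt[idx, idx] <- cnt[idx, idx] + 1
  }
  ref <- ifelse(cnt > 0, ref / pmax(cnt, 1), 0)
  ref[lower.tri(ref, diag = TRUE)] <- 0
  expect_lt(max(abs(pl$bpp - ref)), 1e-12)
})

test_that("the span bound zeroes probabilities of wide pairs", {
  set.seed(805)
  s <- random_rna(14, gc = 0.8)
  pl <- plfold(s, TURNER, W = 14, L = 6)
  for (i in 1:13) for (j in (i + 1):14)
    if (j - i > 6) expect_equal(pl$bpp[i, j], 0)
})

test_that("accessibilities are window-averaged unpaired probabilities, monotone in length", {
  # homopolymer: everything single-stranded with certainty
  pl <- plfold(paste(rep("A", 10), collapse = ""), TURNER, W = 8, u = 3)
  expect_true(all(abs(pl$accessibility - 1) < 1e-12, na.rm = TRUE))
  set.seed(806)
  s <- random_rna(12, gc = 0.7)
  pl <- plfold(s, TURNER, W = 12, u = 4)
  acc <- pl$accessibility
  # monotone: longer intervals are never more accessible
  for (i in 2:12) for (l in 2:min(4, i))
    expect_lte(acc[i, l], acc[i, l - 1] + 1e-12)
  # enumeration oracle for the single-window case
  bz <- brute_boltzmann(s, TURNER)
  for (i in c(4, 9, 12)) for (l in 1:2) {
    idx <- (i - l + 1):i
    ref <- sum(bz$p[vapply(bz$tables, function(pt) all(pt[idx] == 0), TRUE)])
    expect_equal(acc[i, l], ref, tolerance = 1e-9)
  }
  expect_error(plfold(s, TURNER, W = 14), "exceeds")
  expect_error(plfold(s, TURNER, W = 10, L = 12), "must not exceed")
})
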