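test_that("confusion counts follow set arithmetic with the TN estimator", {
  # identical structures: k pairs, n = 10 -> TP = k, TN = 45 - k
  ct <- count_basepairs("(((...))).", "(((...))).")
  expect_equal(ct$TP, 3); expect_equal(ct$FP, 0); expect_equal(ct$FN, 0)
  expect_equal(ct$TN, 45 - 3)
  # disjoint pair sets
  ct <- count_basepairs("(((...))).", ".((....)).")
  expect_equal(ct$TP, 0); expect_equal(ct$FN, 3); expect_equal(ct$FP, 2)
  expect_error(count_basepairs("....", "....."), "different lengths")
})

test_that("randomized structure pairs match an independent set-operation oracle", {
  set.seed(1001)
  for (rep in 1:20) {
    n <- sample(8:14, 1)
    s <- random_rna(n, gc = 0.7)
    tabs <- enumerate_structures(s)
    a <- tabs[[sample(length(tabs), 1)]]
    b <- tabs[[sample(length(tabs), 1)]]
    ps <- function(pt) {
      i <- which(pt > seq_along(pt)); paste(i, pt[i])
    }
    ct <- count_basepairs(a, b)
    expect_equal(ct$TP, length(intersect(ps(a), ps(b))))
    expect_equal(ct$FN, length(setdiff(ps(a), ps(b))))
    expect_equal(ct$FP, length(setdiff(ps(b), ps(a))))
    expect_equal(ct$TN, n * (n - 1) / 2 - ct$TP)
    expect_equal(ct$TP + ct$FN, length(ps(a)))
    expect_equal(ct$TP + ct$FP, length(ps(b)))
  }
})

test_that("scores follow their closed forms and an independent arithmetic check", {
  # perfect prediction: all four scores are 1
  sc <- bp_scores(count_basepairs("(((...)))", "(((...)))"))
  expect_equal(unlist(sc[c("TPR", "PPV", "MCC", "F1")]),
               c(TPR = 1, PPV = 1, MCC = 1, F1 = 1))
  expect_false(sc$degenerate)
  # TP = 0 with FP, FN > 0: MCC and F1 collapse to zero
  sc <- bp_scores(list(TP = 0, FP = 2, FN = 3, TN = 40))
  expect_equal(sc$MCC, 0)
  expect_equal(sc$F1, 0)
  # harmonic-mean identity at PPV = TPR = 0.5
  sc <- bp_scores(list(TP = 2, FP = 2, FN = 2, TN = 40))
  expect_equal(sc$PPV, 0.5); expect_equal(sc$TPR, 0.5); expect_equal(sc$F1, 0.5)
  # independent arithmetic on random counts
  set.seed(1002)
  for (rep in 1:25) {
    TP <- sample(0:10, 1); FP <- sample(0:10, 1); FN <- sample(0:10, 1)
    TN <- sample(5:100, 1)
    sc <- bp_scores(list(TP = TP, FP = FP, FN = FN, TN = TN))
    tpr <- if (TP + FN > 0) TP / (TP + FN) else 0
    ppv <- if (TP + FP > 0) TP / (TP + FP) else 0
    expect_equal(sc$TPR, tpr); expect_equal(sc$PPV, ppv)
    den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    mcc <- if (den > 0) max(0, (TP * TN - FP * FN) / sqrt(den)) else 0
    expect_equal(sc$MCC, mcc, tolerance = 1e-12)
    f1 <- if (ppv + tpr > 0) 2 * ppv * tpr / (ppv + tpr) else 0
    expect_equal(sc$F1, f1, tolerance = 1e-12)
  }
  expect_error(bp_scores(list(TP = -1, FP = 0, FN = 0, TN = 0)), "negative")
})

test_that("scores lie in [0, 1] under the TN estimator and MCC = 1 iff exact", {
  set.seed(1003)
  for (rep in 1:15) {
    n <- sample(8:14, 1)
    s <- random_rna(n, gc = 0.7)
    tabs <- enumerate_structures(s)
    a <- tabs[[sample(length(tabs), 1)]]
    b <- tabs[[sample(length(tabs), 1)]]
    sc <- bp_scores(count_basepairs(a, b))
    expect_true(all(unlist(sc[c("TPR", "PPV", "MCC", "F1")]) >= 0))
    expect_true(all(unlist(sc[c("TPR", "PPV", "MCC", "F1")]) <= 1))
    if (sc$MCC == 1) expect_identical(as.integer(a), as.integer(b))
  }
})

test_that("the benchmark table aggregates per-record counts and scores", {
  tab <- benchmark_structures(c("(((...)))", "....."),
                              c("(((...)))", "....."))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$TPR[1], 1)
  expect_true(tab$TP[2] == 0)
})
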