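# Prediction-performance measures for comparing a predicted secondary
# structure against a reference: base pairs are the predicted property,
# counted at exact positions.  Because only a vanishing fraction of the
# n(n-1)/2 conceivable pairs can occur in any structure, the true-negative
# count is estimated by its upper bound n(n-1)/2 - TP.

#' Confusion counts between a reference and a predicted structure
#'
#' @param reference,predicted Pair tables (or dot-bracket strings) of the
#'   same length.
#' @return A list of class `bp_counts`: `TP`, `FP`, `FN`, `TN`
#'   (estimated as `n(n-1)/2 - TP`), and `n`.
#' @export
count_basepairs <- function(reference, predicted) {
  as_pt <- function(x) if (inherits(x, "pair_table")) x else parse_dot_bracket(x)
  ref <- as_pt(reference); pred <- as_pt(predicted)
  n <- length(ref)
  if (length(pred) != n)
    stop("reference and prediction have different lengths")
  pair_ids <- function(pt) {
    i <- which(pt > seq_along(pt))
    i * (n + 1) + pt[i]
  }
  rp <- pair_ids(ref); pp <- pair_ids(pred)
  TP <- length(intersect(rp, pp))
  FP <- length(setdiff(pp, rp))
  FN <- length(setdiff(rp, pp))
  structure(list(TP = TP, FP = FP, FN = FN,
                 TN = n * (n - 1) / 2 - TP, n = n),
            class = "bp_counts")
}

#' Prediction scores from confusion counts
#'
#' Sensitivity (true positive rate) `TPR = TP/(TP+FN)`, precision
#' (positive predictive value) `PPV = TP/(TP+FP)`, the Matthews
#' correlation coefficient, and the F-measure (harmonic mean of PPV and
#' TPR).  Any score whose denominator is zero is reported as 0 and flagged.
#' All four scores are reported on the `[0, 1]` accuracy scale: an MCC
#' below zero (a prediction anti-correlated with the reference, possible
#' only when `TP = 0` with the true-negative estimator) is truncated to 0.
#'
#' @param counts A `bp_counts` object (or list with TP/FP/FN/TN).
#' @return A list: `TPR`, `PPV`, `MCC`, `F1`, and `degenerate` (TRUE if
#'   any denominator was zero).
#' @export
bp_scores <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN; TN <- counts$TN
  if (any(c(TP, FP, FN, TN) < 0)) stop("negative counts")
  degenerate <- FALSE
  div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  TPR <- div(TP, TP + FN)
  PPV <- div(TP, TP + FP)
  MCC <- {
    den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
    if (den == 0) { degenerate <- TRUE; 0 }
    else max(0, (TP * TN - FP * FN) / den)
  }
  F1 <- div(2 * PPV * TPR, PPV + TPR)
  list(TPR = TPR, PPV = PPV, MCC = MCC, F1 = F1, degenerate = degenerate)
}

#' Benchmark a set of predictions against references
#'
#' @param reference,predicted Character vectors of dot-bracket structures
#'   (element-wise comparison).
#' @return A data.frame with one row per pair: counts and scores.
#' @export
benchmark_structures <- function(reference, predicted) {
  stopifnot(length(reference) == length(predicted))
  rows <- lapply(seq_along(reference), function(k) {
    ct <- count_basepairs(reference[[k]], predicted[[k]])
    sc <- bp_scores(ct)
    data.frame(n = ct$n, TP = ct$TP, FP = ct$FP, FN = ct$FN, TN = ct$TN,
               TPR = sc$TPR, PPV = sc$PPV, MCC = sc$MCC, F1 = sc$F1)
  })
  do.call(rbind, rows)
}
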