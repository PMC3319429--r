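# McCaskill partition function over the same loop-energy model as the MFE
# recursions (dangle models 0 and 2 are pair-local, so the decomposition is
# exact).  All matrices carry a per-nucleotide scale factor s to keep the
# numbers in floating range: a quantity covering k nucleotides is stored
# multiplied by s^k.  Scale factors cancel in every probability.
#
#   QB[i,j]  sum of Boltzmann weights of structures closed by pair (i,j)
#   QM[i,j]  multiloop segment with >= 1 branch
#   QM1[i,j] multiloop segment whose single branch starts at i
#   Q[i,j]   unrestricted segment evaluated with exterior-loop energies

#' McCaskill partition function and base-pair probabilities
#'
#' Computes the equilibrium ensemble of secondary structures: the partition
#' function Z, the ensemble free energy -RT ln Z, and the matrix of
#' base-pair probabilities from the inside/outside recursions.
#'
#' @param seq Sequence ([rna_sequence] or string).
#' @param params Energy parameters (default: bundled set).
#' @param dangles Dangle model, 0 or 2.
#' @param constraints Optional hard constraints (string or
#'   [parse_constraints()] object); the ensemble is restricted to
#'   satisfying structures.
#' @param max_span Optional upper bound on the span `j - i` of any pair
#'   (used by the scanning/local modes).
#' @return An object of class `pf_result`: `ensemble_energy` (kcal/mol),
#'   `lnZ`, `bpp` (n x n upper-triangular probability matrix),
#'   `q_unpaired` (per-position unpaired probabilities), plus the inside
#'   matrices and model options (used by [sample_structures()]).
#' @examples
#' pf <- partition_function("GGGAAACCC", toy_energy_params(terminal_au = 0))
#' pf$ensemble_energy
#' @export
partition_function <- function(seq, params = default_energy_params(),
                               dangles = 2, constraints = NULL,
                               max_span = Inf) {
  ctx <- fold_ctx(seq, params, dangles)
  n <- ctx$n
  P <- ctx$params
  cons <- if (is.null(constraints)) NULL
          else if (inherits(constraints, "fold_constraints")) constraints
          else parse_constraints(constraints, ctx$n)
  PT <- .ptype_matrix(ctx, cons, max_span)
  must <- if (is.null(cons)) rep(FALSE, n) else cons$paired
  cmust <- cumsum(must)
  free_rgn <- function(a, b) a > b || (cmust[[b]] - (if (a > 1L) cmust[[a - 1L]] else 0L)) == 0L
  can_unp <- !must

  # per-nucleotide scale from a quick MFE estimate (with 7% headroom)
  mfe_dk <- build_mfe_matrices(ctx, cons = cons, max_span = max_span)$F[[n + 1L]]
  if (mfe_dk >= INF_ENERGY / 2) mfe_dk <- 0
  lns <- 1.07 * mfe_dk / (n * RT_DEKACAL)
  spow <- exp(lns * (0:(n + 1L)))
  bw <- function(e_dk) exp(-e_dk / RT_DEKACAL)   # unscaled Boltzmann factor
  emlb <- exp(-P$ml_base / RT_DEKACAL) * spow[[2L]]  # one scaled ML base
  expMLbase <- emlb ^ (0:n)

  QB <- matrix(0, n, n); QM <- matrix(0, n, n); QM1 <- matrix(0, n, n)
  Q <- matrix(0, n, n)
  stem_f <- function(k, jj) QB[k, jj] * bw(.ml_stem_ij(ctx, k, jj))

  for (span in 4L:max(4L, n - 1L)) {
    if (span > n - 1L) break
    for (i in seq_len(n - span)) {
      j <- i + span
      tt <- PT[i, j]
      if (tt > 0L) {
        qb <- 0
        if (free_rgn(i + 1L, j - 1L))
          qb <- bw(E_hairpin_ij(ctx, i, j)) * spow[[span + 2L]]
        pmax <- min(i + MAXLOOP + 1L, j - 5L)
        if (pmax >= i + 1L) for (p in (i + 1L):pmax) {
          n1 <- p - i - 1L
          if (!free_rgn(i + 1L, p - 1L)) break
          qmin <- max(p + 4L, j - 1L - (MAXLOOP - n1))
          if (qmin > j - 1L) next
          for (q in (j - 1L):qmin) {
            if (!free_rgn(q + 1L, j - 1L)) break
            if (PT[p, q] == 0L || QB[p, q] == 0) next
            qb <- qb + QB[p, q] * bw(E_intloop_ij(ctx, i, j, p, q)) *
              spow[[(p - i) + (j - q) + 1L]]
          }
        }
        if (j - i >= 10L) {
          close_f <- bw(P$ml_closing + .ml_close_ij(ctx, i, j)) * spow[[3L]]
          acc <- 0
          for (u in (i + 1L):(j - 2L)) {
            if (QM[i + 1L, u] > 0 && QM1[u + 1L, j - 1L] > 0)
              acc <- acc + QM[i + 1L, u] * QM1[u + 1L, j - 1L]
          }
          qb <- qb + acc * close_f
        }
        QB[i, j] <- qb
      }
      # QM1
      qm1 <- if (QB[i, j] > 0) stem_f(i, j) else 0
      if (can_unp[[j]] && j > i && QM1[i, j - 1L] > 0)
        qm1 <- qm1 + QM1[i, j - 1L] * expMLbase[[2L]]
      QM1[i, j] <- qm1
      # QM
      qm <- if (can_unp[[j]] && j > i) QM[i, j - 1L] * expMLbase[[2L]] else 0
      for (k in i:(j - 4L)) {
        if (QB[k, j] == 0) next
        st <- stem_f(k, j)
        if (k == i) qm <- qm + st
        else {
          if (free_rgn(i, k - 1L)) qm <- qm + expMLbase[[k - i + 1L]] * st
          qm <- qm + QM[i, k - 1L] * st
        }
      }
      QM[i, j] <- qm
    }
  }

  # exterior segment partition functions
  for (i in seq_len(n)) {
    acc <- 1
    for (j in i:n) {
      qq <- if (can_unp[[j]]) (if (j == i) spow[[2L]] else Q[i, j - 1L] * spow[[2L]]) else 0
      if (j >= i + 4L) for (k in i:(j - 4L)) {
        if (QB[k, j] == 0) next
        left <- if (k == i) 1 else Q[i, k - 1L]
        if (left > 0)
          qq <- qq + left * QB[k, j] * bw(.ext_stem_ij(ctx, k, j))
      }
      Q[i, j] <- qq
    }
  }
  Ztot <- Q[1L, n]
  if (Ztot <= 0) {
    # constraints unsatisfiable
    warning("constraints exclude every structure; empty ensemble")
    return(structure(list(ensemble_energy = Inf, lnZ = -Inf,
                          bpp = matrix(0, n, n), q_unpaired = rep(1, n)),
                     class = "pf_result"))
  }

  # outside: base-pair probabilities
  prob <- matrix(0, n, n)
  pairs <- which(QB > 0, arr.ind = TRUE)
  if (nrow(pairs) > 0L) {
    spans <- pairs[, 2L] - pairs[, 1L]
    pairs <- pairs[order(-spans), , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      # exterior
      left <- if (i > 1L) Q[1L, i - 1L] else 1
      right <- if (j < n) Q[j + 1L, n] else 1
      pr <- left * right * QB[i, j] * bw(.ext_stem_ij(ctx, i, j)) / Ztot
      prob[i, j] <- prob[i, j] + pr
    }
    for (r in seq_len(nrow(pairs))) {
      k <- pairs[r, 1L]; l <- pairs[r, 2L]
      pkl <- prob[k, l]
      if (pkl <= 0 || l - k < 6L) next
      out_f <- pkl / QB[k, l]
      # interior loops: inner pair (i, j) inside (k, l)
      imax <- min(k + MAXLOOP + 1L, l - 5L)
      if (imax >= k + 1L) for (i in (k + 1L):imax) {
        n1 <- i - k - 1L
        if (!free_rgn(k + 1L, i - 1L)) break
        jmin <- max(i + 4L, l - 1L - (MAXLOOP - n1))
        if (jmin > l - 1L) next
        for (j in (l - 1L):jmin) {
          if (!free_rgn(j + 1L, l - 1L)) break
          if (QB[i, j] == 0) next
          prob[i, j] <- prob[i, j] + out_f * QB[i, j] *
            bw(E_intloop_ij(ctx, k, l, i, j)) * spow[[(i - k) + (l - j) + 1L]]
        }
      }
      # multiloop: (i, j) a branch of the loop closed by (k, l)
      if (l - k >= 10L) {
        close_f <- bw(P$ml_closing + .ml_close_ij(ctx, k, l)) * spow[[3L]]
        for (i in (k + 1L):(l - 5L)) for (j in (i + 4L):(l - 1L)) {
          if (QB[i, j] == 0) next
          st <- QB[i, j] * bw(.ml_stem_ij(ctx, i, j))
          lqm <- if (i - 1L >= k + 1L) QM[k + 1L, i - 1L] else 0
          lunp <- if (free_rgn(k + 1L, i - 1L)) expMLbase[[i - k]] else 0
          rqm <- if (l - 1L >= j + 1L) QM[j + 1L, l - 1L] else 0
          runp <- if (free_rgn(j + 1L, l - 1L)) expMLbase[[l - j]] else 0
          combo <- lqm * runp + lunp * rqm + lqm * rqm
          if (combo > 0)
            prob[i, j] <- prob[i, j] + out_f * close_f * st * combo
        }
      }
    }
  }
  q_unp <- 1 - (rowSums(prob) + colSums(prob))
  # every stored quantity covering k nucleotides carries s^k, so Q[1,n]
  # carries s^n exactly
  lnZ <- log(Ztot) - n * lns
  G <- -RT_DEKACAL * lnZ / 100

  structure(list(ensemble_energy = G, lnZ = lnZ, Z_scaled = Ztot,
                 bpp = prob, q_unpaired = q_unp,
                 QB = QB, QM = QM, QM1 = QM1, Q = Q, PT = PT,
                 spow = spow, lns = lns, expMLbase = expMLbase,
                 ctx = ctx, cons = cons, free_rgn = free_rgn,
                 can_unp = can_unp, dangles = dangles),
            class = "pf_result")
}

#' @export
print.pf_result <- function(x, ...) {
  cat(sprintf("free energy of ensemble = %s kcal/mol\n",
              format_energy(x$ensemble_energy)))
  invisible(x)
}

#' Centroid structure of the ensemble
#'
#' The structure with the smallest expected base-pair distance to the
#' ensemble: it contains exactly the pairs with probability > 1/2 (such
#' pairs are automatically mutually compatible).  The reported distance is
#' `sum(1 - p)` over included pairs plus `sum(p)` over excluded pairs.
#'
#' @param pf A `pf_result` (or a bare base-pair probability matrix).
#' @return A list: `structure` (dot-bracket), `pair_table`, `distance`.
#' @export
centroid_structure <- function(pf) {
  bpp <- if (inherits(pf, "pf_result")) pf$bpp else pf
  n <- nrow(bpp)
  pt <- integer(n)
  sel <- which(bpp > 0.5, arr.ind = TRUE)
  if (nrow(sel) > 0L) {
    pt[sel[, 1L]] <- sel[, 2L]
    pt[sel[, 2L]] <- sel[, 1L]
  }
  inc <- if (nrow(sel) > 0L) bpp[sel] else numeric(0)
  dist <- sum(1 - inc) + (sum(bpp) - sum(inc))
  list(structure = write_dot_bracket(pt),
       pair_table = structure(as.integer(pt), class = "pair_table"),
       distance = dist)
}

#' Maximum-expected-accuracy structure
#'
#' Maximizes `sum over pairs (i,j) of 2 * gamma * p[i,j] + sum over
#' unpaired i of q_unpaired[i]` over all valid structures, by a
#' Nussinov-style recursion over the probability matrix.  Larger `gamma`
#' favors including more pairs.
#'
#' @param pf A `pf_result`.
#' @param gamma Pair weight (> 0), default 1.
#' @return A list: `structure`, `pair_table`, `score` (the maximized
#'   expected accuracy).
#' @export
mea_structure <- function(pf, gamma = 1) {
  stopifnot(inherits(pf, "pf_result"), gamma > 0)
  bpp <- pf$bpp
  q <- pf$q_unpaired
  n <- nrow(bpp)
  Mmat <- matrix(0, n + 1L, n)  # Mmat[i, j] over interval i..j; row n+1 = empty guard
  Mget <- function(i, j) if (i > j) 0 else Mmat[i, j]
  for (span in 0L:(n - 1L)) for (i in seq_len(n - span)) {
    j <- i + span
    best <- Mget(i, j - 1L) + q[[j]]
    if (span >= 4L) for (k in i:(j - 4L)) {
      if (bpp[k, j] <= 0) next
      v <- Mget(i, k - 1L) + 2 * gamma * bpp[k, j] + Mget(k + 1L, j - 1L)
      if (v > best) best <- v
    }
    Mmat[i, j] <- best
  }
  # traceback
  pt <- integer(n)
  stack <- list(c(1L, n))
  eq <- function(a, b) abs(a - b) < 1e-9
  while (length(stack) > 0L) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- iv[[1L]]; j <- iv[[2L]]
    while (j >= i) {
      if (eq(Mget(i, j), Mget(i, j - 1L) + q[[j]])) { j <- j - 1L; next }
      found <- FALSE
      for (k in i:(j - 4L)) {
        if (bpp[k, j] <= 0) next
        if (eq(Mget(i, j), Mget(i, k - 1L) + 2 * gamma * bpp[k, j] + Mget(k + 1L, j - 1L))) {
          pt[[k]] <- j; pt[[j]] <- k
          if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
          j <- k - 1L
          found <- TRUE
          break
        }
      }
      if (!found) stop("MEA traceback failure")
    }
  }
  list(structure = write_dot_bracket(pt),
       pair_table = structure(pt, class = "pair_table"),
       score = Mmat[1L, n], gamma = gamma)
}

#' Positional entropy of the pairing distribution
#'
#' `S[i] = -sum_j p[i,j] log p[i,j] - q_i log q_i` with `0 log 0 = 0`:
#' a per-position measure of structural uncertainty (0 where the
#' prediction is certain).
#'
#' @param pf A `pf_result` (or bare probability matrix).
#' @return Numeric vector of entropies (natural log units).
#' @export
positional_entropy <- function(pf) {
  bpp <- if (inherits(pf, "pf_result")) pf$bpp else pf
  n <- nrow(bpp)
  full <- bpp + t(bpp)
  q <- pmax(0, 1 - rowSums(full))
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  -(rowSums(xlx(full)) + xlx(q))
}

#' Boltzmann-weighted structure sampling (stochastic backtracking)
#'
#' Draws independent structures from the equilibrium distribution
#' `P(S) = exp(-E(S)/RT)/Z` by backtracking through the partition-function
#' matrices, choosing each decomposition step with probability proportional
#' to its weight.
#'
#' @param pf A `pf_result` from [partition_function()].
#' @param count Number of samples (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Character vector of dot-bracket structures.
#' @export
sample_structures <- function(pf, count, seed = NULL) {
  stopifnot(inherits(pf, "pf_result"))
  if (count < 1) stop("count must be >= 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  ctx <- pf$ctx
  n <- ctx$n
  P <- ctx$params
  QB <- pf$QB; QM <- pf$QM; QM1 <- pf$QM1; Q <- pf$Q
  spow <- pf$spow; expMLbase <- pf$expMLbase
  bw <- function(e_dk) exp(-e_dk / RT_DEKACAL)
  free_rgn <- pf$free_rgn; can_unp <- pf$can_unp
  # the decomposition choices at each cell never change, so the option
  # lists (choice descriptor + weight) are computed once and cached
  cache <- new.env(parent = emptyenv())
  memo <- function(key, make) {
    hit <- cache[[key]]
    if (is.null(hit)) { hit <- make(); cache[[key]] <- hit }
    hit
  }
  qb_opts <- function(i, j) memo(paste0("B", i, ":", j), function() {
    ch <- list(); w <- numeric()
    if (free_rgn(i + 1L, j - 1L)) {
      ch[[length(ch) + 1L]] <- list(kind = "H")
      w[[length(w) + 1L]] <- bw(E_hairpin_ij(ctx, i, j)) * spow[[j - i + 2L]]
    }
    pmax <- min(i + MAXLOOP + 1L, j - 5L)
    if (pmax >= i + 1L) for (p in (i + 1L):pmax) {
      n1 <- p - i - 1L
      if (!free_rgn(i + 1L, p - 1L)) break
      qmin <- max(p + 4L, j - 1L - (MAXLOOP - n1))
      if (qmin > j - 1L) next
      for (q in (j - 1L):qmin) {
        if (!free_rgn(q + 1L, j - 1L)) break
        if (QB[p, q] == 0) next
        ch[[length(ch) + 1L]] <- list(kind = "I", p = p, q = q)
        w[[length(w) + 1L]] <- QB[p, q] * bw(E_intloop_ij(ctx, i, j, p, q)) *
          spow[[(p - i) + (j - q) + 1L]]
      }
    }
    if (j - i >= 10L) {
      close_f <- bw(P$ml_closing + .ml_close_ij(ctx, i, j)) * spow[[3L]]
      for (u in (i + 1L):(j - 2L)) {
        if (QM[i + 1L, u] > 0 && QM1[u + 1L, j - 1L] > 0) {
          ch[[length(ch) + 1L]] <- list(kind = "M", u = u)
          w[[length(w) + 1L]] <- QM[i + 1L, u] * QM1[u + 1L, j - 1L] * close_f
        }
      }
    }
    list(ch = ch, w = w)
  })
  qm1_opts <- function(i, j) memo(paste0("1", i, ":", j), function() {
    ch <- list(); w <- numeric()
    if (QB[i, j] > 0) {
      ch[[1L]] <- list(kind = "S")
      w[[1L]] <- QB[i, j] * bw(.ml_stem_ij(ctx, i, j))
    }
    if (can_unp[[j]] && j - 1L >= i && QM1[i, j - 1L] > 0) {
      ch[[length(ch) + 1L]] <- list(kind = "U")
      w[[length(w) + 1L]] <- QM1[i, j - 1L] * expMLbase[[2L]]
    }
    list(ch = ch, w = w)
  })
  qm_opts <- function(i, j) memo(paste0("M", i, ":", j), function() {
    ch <- list(); w <- numeric()
    if (can_unp[[j]] && j - 1L >= i && QM[i, j - 1L] > 0) {
      ch[[length(ch) + 1L]] <- list(kind = "U")
      w[[length(w) + 1L]] <- QM[i, j - 1L] * expMLbase[[2L]]
    }
    for (k in i:(j - 4L)) {
      if (QB[k, j] == 0) next
      st <- QB[k, j] * bw(.ml_stem_ij(ctx, k, j))
      if (k == i) {
        ch[[length(ch) + 1L]] <- list(kind = "S1", k = k)
        w[[length(w) + 1L]] <- st
      } else {
        if (free_rgn(i, k - 1L)) {
          ch[[length(ch) + 1L]] <- list(kind = "S1", k = k)
          w[[length(w) + 1L]] <- expMLbase[[k - i + 1L]] * st
        }
        if (QM[i, k - 1L] > 0) {
          ch[[length(ch) + 1L]] <- list(kind = "S2", k = k)
          w[[length(w) + 1L]] <- QM[i, k - 1L] * st
        }
      }
    }
    list(ch = ch, w = w)
  })
  ext_opts <- function(j) memo(paste0("E", j), function() {
    ch <- list(); w <- numeric()
    if (can_unp[[j]]) {
      ch[[1L]] <- list(kind = "U")
      w[[1L]] <- if (j == 1L) spow[[2L]] else Q[1L, j - 1L] * spow[[2L]]
    }
    if (j >= 5L) for (k in 1L:(j - 4L)) {
      if (QB[k, j] == 0) next
      left <- if (k == 1L) 1 else Q[1L, k - 1L]
      if (left > 0) {
        ch[[length(ch) + 1L]] <- list(kind = "P", k = k)
        w[[length(w) + 1L]] <- left * QB[k, j] * bw(.ext_stem_ij(ctx, k, j))
      }
    }
    list(ch = ch, w = w)
  })
  pick <- function(o) o$ch[[sample.int(length(o$w), 1L, prob = o$w)]]

  sample_qb <- function(pt, i, j) {
    pt[[i]] <- j; pt[[j]] <- i
    ch <- pick(qb_opts(i, j))
    if (ch$kind == "I") pt <- sample_qb(pt, ch$p, ch$q)
    else if (ch$kind == "M") {
      pt <- sample_qm(pt, i + 1L, ch$u)
      pt <- sample_qm1(pt, ch$u + 1L, j - 1L)
    }
    pt
  }
  sample_qm1 <- function(pt, i, j) {
    repeat {
      ch <- pick(qm1_opts(i, j))
      if (ch$kind == "S") return(sample_qb(pt, i, j))
      j <- j - 1L
    }
  }
  sample_qm <- function(pt, i, j) {
    repeat {
      ch <- pick(qm_opts(i, j))
      if (ch$kind == "U") { j <- j - 1L; next }
      pt <- sample_qb(pt, ch$k, j)
      if (ch$kind == "S2") return(sample_qm(pt, i, ch$k - 1L))
      return(pt)
    }
  }
  sample_ext <- function() {
    pt <- integer(n)
    j <- n
    while (j >= 1L) {
      ch <- pick(ext_opts(j))
      if (ch$kind == "U") { j <- j - 1L; next }
      pt <- sample_qb(pt, ch$k, j)
      j <- ch$k - 1L
    }
    pt
  }
  vapply(seq_len(count), function(s) write_dot_bracket(sample_ext()), "")
}
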