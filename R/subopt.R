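# Suboptimal structures.
#
# subopt_band: complete enumeration of every structure within an energy
# band above the MFE, by backtracking through the folding matrices with
# partial structures kept on a stack.  Each partial structure carries the
# energy already fixed plus a list of unresolved intervals; the sum of the
# fixed energy and the matrix entries of the unresolved intervals is an
# exact lower bound, so a partial structure is discarded exactly when no
# completion fits the band.  The decomposition is unambiguous, hence every
# structure is produced exactly once.
#
# subopt_zuker: for every admissible pair, the minimum free energy of a
# structure containing that pair, via inside (C) plus outside (Cout)
# minimization.

#' Complete suboptimal structures within an energy band
#'
#' Enumerates every secondary structure whose energy is within
#' `band` kcal/mol of the minimum free energy (with `noLP`, of the
#' canonical-only minimum).
#'
#' @param seq Sequence ([rna_sequence] or string).
#' @param params Energy parameters.
#' @param band Energy band in kcal/mol (>= 0), 0.01 resolution.
#' @param dangles Dangle model, 0 or 2.
#' @param noLP Restrict to structures without isolated pairs.
#' @param max_structures Safety cap; exceeding it raises an error naming
#'   the count reached.
#' @param sorted Sort by energy, then lexicographically (default); if
#'   `FALSE`, generation order.
#' @return A data.frame with columns `structure` and `energy` (kcal/mol).
#' @export
subopt_band <- function(seq, params = default_energy_params(), band = 1,
                        dangles = 2, noLP = FALSE, max_structures = 50000L,
                        sorted = TRUE) {
  if (band < 0) stop("band must be >= 0")
  ctx <- fold_ctx(seq, params, dangles)
  n <- ctx$n
  mm <- build_mfe_matrices(ctx, noLP = noLP)
  mfe <- mm$F[[n + 1L]]
  thr <- mfe + round(band * 100) + 1e-6
  INF <- INF_ENERGY
  if (mfe >= INF / 2) return(data.frame(structure = character(), energy = numeric()))
  C1 <- mm$C1; C2 <- mm$C2; CA <- mm$CA; M <- mm$M; M1 <- mm$M1; F <- mm$F
  PT <- mm$PT
  P <- ctx$params
  mlb <- P$ml_base; mlc <- P$ml_closing
  inner_kind <- if (noLP) "C2" else "CA"
  mval <- function(iv) switch(iv$what,
    F = F[[iv$j + 1L]], CA = CA[iv$i, iv$j], C1 = C1[iv$i, iv$j],
    C2 = C2[iv$i, iv$j], M = M[iv$i, iv$j], M1 = M1[iv$i, iv$j])

  results_s <- character(); results_e <- numeric()
  # state: acc (fixed energy), ivs (list of intervals), pt (pairs so far)
  st0 <- list(acc = 0, ivs = list(list(what = "F", j = n)), pt = integer(n))
  stack <- list(st0)
  push_child <- function(stack, st, dacc, new_ivs, pairs = NULL) {
    acc <- st$acc + dacc
    ivs <- c(st$ivs, new_ivs)
    lb <- acc + sum(vapply(ivs, mval, 0))
    if (lb > thr) return(stack)
    pt <- st$pt
    if (!is.null(pairs)) { pt[[pairs[[1L]]]] <- pairs[[2L]]; pt[[pairs[[2L]]]] <- pairs[[1L]] }
    stack[[length(stack) + 1L]] <- list(acc = acc, ivs = ivs, pt = pt)
    stack
  }
  while (length(stack) > 0L) {
    st <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    if (length(st$ivs) == 0L) {
      results_s[[length(results_s) + 1L]] <- write_dot_bracket(st$pt)
      results_e[[length(results_e) + 1L]] <- st$acc
      if (length(results_s) > max_structures)
        stop(sprintf("suboptimal set exceeds the cap of %d structures", max_structures))
      next
    }
    iv <- st$ivs[[length(st$ivs)]]
    st$ivs[[length(st$ivs)]] <- NULL
    if (iv$what == "F") {
      j <- iv$j
      if (j < 1L) { stack <- push_child(stack, st, 0, list()); next }
      stack <- push_child(stack, st, 0, list(list(what = "F", j = j - 1L)))
      if (j >= 5L) for (k in 1L:(j - 4L)) {
        cb <- if (noLP) C2[k, j] else CA[k, j]
        if (cb >= INF) next
        stack <- push_child(stack, st, .ext_stem_ij(ctx, k, j),
                            list(list(what = "F", j = k - 1L),
                                 list(what = inner_kind, i = k, j = j)))
      }
    } else if (iv$what %in% c("CA", "C1", "C2")) {
      i <- iv$i; j <- iv$j
      st$pt[[i]] <- j; st$pt[[j]] <- i
      do_c2 <- iv$what %in% c("CA", "C2")
      do_c1 <- iv$what %in% c("CA", "C1")
      if (do_c2 && j - i > 5L && PT[i + 1L, j - 1L] > 0L &&
          CA[i + 1L, j - 1L] < INF) {
        stack <- push_child(stack, st,
                            stack_energy(PT[i, j], pair_type(ctx$S[[j - 1L]], ctx$S[[i + 1L]]), P),
                            list(list(what = "CA", i = i + 1L, j = j - 1L)))
      }
      if (do_c1) {
        stack <- push_child(stack, st, E_hairpin_ij(ctx, i, j), list())
        pmax <- min(i + MAXLOOP + 1L, j - 5L)
        if (pmax >= i + 1L) for (p in (i + 1L):pmax) {
          n1 <- p - i - 1L
          qmin <- max(p + 4L, j - 1L - (MAXLOOP - n1))
          if (qmin > j - 1L) next
          for (q in (j - 1L):qmin) {
            if (p == i + 1L && q == j - 1L) next
            if (PT[p, q] == 0L) next
            inner <- if (noLP) C2[p, q] else CA[p, q]
            if (inner >= INF) next
            stack <- push_child(stack, st, E_intloop_ij(ctx, i, j, p, q),
                                list(list(what = inner_kind, i = p, j = q)))
          }
        }
        if (j - i >= 10L) {
          close_e <- mlc + .ml_close_ij(ctx, i, j)
          for (u in (i + 1L):(j - 2L)) {
            if (M[i + 1L, u] >= INF || M1[u + 1L, j - 1L] >= INF) next
            stack <- push_child(stack, st, close_e,
                                list(list(what = "M", i = i + 1L, j = u),
                                     list(what = "M1", i = u + 1L, j = j - 1L)))
          }
        }
      }
    } else if (iv$what == "M1") {
      i <- iv$i; j <- iv$j
      cb <- if (noLP) C2[i, j] else CA[i, j]
      if (cb < INF)
        stack <- push_child(stack, st, .ml_stem_ij(ctx, i, j),
                            list(list(what = inner_kind, i = i, j = j)))
      if (j - 1L >= i && M1[i, j - 1L] < INF)
        stack <- push_child(stack, st, mlb, list(list(what = "M1", i = i, j = j - 1L)))
    } else if (iv$what == "M") {
      i <- iv$i; j <- iv$j
      if (j - 1L >= i && M[i, j - 1L] < INF)
        stack <- push_child(stack, st, mlb, list(list(what = "M", i = i, j = j - 1L)))
      for (k in i:(j - 4L)) {
        cb <- if (noLP) C2[k, j] else CA[k, j]
        if (cb >= INF) next
        stem <- .ml_stem_ij(ctx, k, j)
        if (k == i) {
          stack <- push_child(stack, st, stem,
                              list(list(what = inner_kind, i = k, j = j)))
        } else {
          stack <- push_child(stack, st, mlb * (k - i) + stem,
                              list(list(what = inner_kind, i = k, j = j)))
          if (M[i, k - 1L] < INF)
            stack <- push_child(stack, st, stem,
                                list(list(what = "M", i = i, j = k - 1L),
                                     list(what = inner_kind, i = k, j = j)))
        }
      }
    }
  }
  out <- data.frame(structure = results_s, energy = results_e / 100)
  if (sorted && nrow(out) > 0L)
    out <- out[order(out$energy, out$structure), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Zuker-style suboptimal structures
#'
#' For every admissible base pair `(i, j)` of the sequence, computes the
#' energetically best structure containing that pair (inside energy from
#' the folding matrices plus an outside minimization), and returns the
#' distinct structures among these per-pair optima.
#'
#' @param seq Sequence.
#' @param params Energy parameters.
#' @param dangles Dangle model, 0 or 2.
#' @return A data.frame `structure`, `energy`, sorted by energy; attribute
#'   `pair_energies` holds the per-pair minima (matrix, NA where no pair).
#' @export
subopt_zuker <- function(seq, params = default_energy_params(), dangles = 2) {
  ctx <- fold_ctx(seq, params, dangles)
  n <- ctx$n
  if (n < 5L) return(data.frame(structure = character(), energy = numeric()))
  P <- ctx$params
  INF <- INF_ENERGY
  mm <- build_mfe_matrices(ctx)
  CAm <- mm$CA; M <- mm$M; F <- mm$F; PT <- mm$PT
  mlb <- P$ml_base; mlc <- P$ml_closing
  # suffix exterior array: G[j] = best energy on j..n
  G <- rep(0, n + 2L)
  for (j in n:1L) {
    best <- G[[j + 1L]]
    if (j <= n - 4L) for (l in (j + 4L):n) {
      if (CAm[j, l] >= INF) next
      e <- CAm[j, l] + .ext_stem_ij(ctx, j, l) + G[[l + 1L]]
      if (e < best) best <- e
    }
    G[[j]] <- best
  }
  pairs <- which(PT > 0L & CAm < INF, arr.ind = TRUE)
  if (nrow(pairs) == 0L)
    return(data.frame(structure = character(), energy = numeric()))
  ord <- order(-(pairs[, 2L] - pairs[, 1L]))
  pairs <- pairs[ord, , drop = FALSE]
  Cout <- matrix(INF, n, n)
  mlseg <- function(a, b) {
    # best ML filling of segment a..b: branches or all-unpaired (or empty)
    if (a > b) return(0)
    min(mlb * (b - a + 1L), M[a, b])
  }
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    best <- F[[i]] + .ext_stem_ij(ctx, i, j) + G[[j + 1L]]
    # enclosed in an interior loop of (k, l)
    kmin <- max(1L, i - MAXLOOP - 1L)
    for (k in kmin:(i - 1L)) {
      if (k < 1L || k == i) break
      n1 <- i - k - 1L
      lmax <- min(n, j + 1L + (MAXLOOP - n1))
      if (lmax < j + 1L) next
      for (l in (j + 1L):lmax) {
        if (PT[k, l] == 0L || Cout[k, l] >= INF) next
        e <- Cout[k, l] + E_intloop_ij(ctx, k, l, i, j)
        if (e < best) best <- e
      }
    }
    # a branch of a multiloop closed by (k, l)
    for (k in 1L:max(1L, i - 1L)) {
      if (k >= i) break
      for (l in (j + 1L):n) {
        if (l > n) break
        if (l - k < 10L) next
        if (PT[k, l] == 0L || Cout[k, l] >= INF) next
        lm <- if (i - 1L >= k + 1L) mlseg(k + 1L, i - 1L) else 0
        rm <- if (l - 1L >= j + 1L) mlseg(j + 1L, l - 1L) else 0
        lM <- if (i - 1L >= k + 1L) M[k + 1L, i - 1L] else INF
        rM <- if (l - 1L >= j + 1L) M[j + 1L, l - 1L] else INF
        # at least one more branch besides (i, j) and the closing pair
        fill <- min(if (lM < INF) lM + rm else INF,
                    if (rM < INF) mlb * max(0L, i - k - 1L) + rM else INF)
        if (fill >= INF) next
        e <- Cout[k, l] + mlc + .ml_close_ij(ctx, k, l) +
          .ml_stem_ij(ctx, i, j) + fill
        if (e < best) best <- e
      }
    }
    Cout[i, j] <- best
  }
  pair_e <- CAm + Cout
  pair_e[PT == 0L | CAm >= INF | Cout >= INF] <- NA
  # collect distinct optimal structures, cheapest pair first
  valid <- which(!is.na(pair_e), arr.ind = TRUE)
  ev <- pair_e[valid]
  ordv <- order(ev)
  seen <- list()
  res_s <- character(); res_e <- numeric()
  for (idx in ordv) {
    i <- valid[idx, 1L]; j <- valid[idx, 2L]
    e <- ev[[idx]]
    covered <- FALSE
    for (q in seq_along(res_s)) {
      if (abs(res_e[[q]] - e / 100) < 1e-9 && seen[[q]][[i]] == j) { covered <- TRUE; break }
    }
    if (covered) next
    cvec <- rep(".", n); cvec[[i]] <- "("; cvec[[j]] <- ")"
    fr <- fold(ctx$seq, P, dangles = ctx$dangles,
               constraints = paste(cvec, collapse = ""))
    res_s[[length(res_s) + 1L]] <- fr$structure
    res_e[[length(res_e) + 1L]] <- fr$energy
    seen[[length(seen) + 1L]] <- fr$pair_table
    if (abs(fr$energy - e / 100) > 1e-6)
      warning(sprintf("inconsistent per-pair minimum at (%d,%d): %g vs %g",
                      i, j, fr$energy, e / 100))
  }
  keep <- !duplicated(res_s)
  out <- data.frame(structure = res_s[keep], energy = res_e[keep])
  out <- out[order(out$energy, out$structure), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pair_energies") <- pair_e / 100
  out
}
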