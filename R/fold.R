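# Zuker-style minimum-free-energy folding.
#
# Matrices (all energies dekacal, INF_ENERGY = forbidden):
#   C1[i,j]  best structure closed by pair (i,j) whose first enclosed loop
#            is NOT a stacked pair (hairpin, interior loop, or multiloop)
#   C2[i,j]  best structure closed by (i,j) stacking on pair (i+1,j-1)
#   CA[i,j]  min(C1, C2): closed structure usable under an enclosing stack
#   CB[i,j]  closed structure usable as a free-standing helix (a branch of
#            a multiloop or the exterior loop).  Without the canonical-only
#            restriction CB == CA; with it (no lonely pairs) CB == C2, so
#            every helix that is not supported from outside must contain a
#            stacked pair inside.
#   M[i,j]   multiloop segment with >= 1 branch; M1[i,j] multiloop segment
#            whose single leftmost branch starts at i
#   F[j]     best exterior-decomposed structure on 1..j
#
# Interior loops are capped at MAXLOOP unpaired bases total, the standard
# restriction that keeps folding O(n^3).

MAXLOOP <- 30L

# pair-type matrix honoring the minimum hairpin span and hard constraints
.ptype_matrix <- function(ctx, cons = NULL, max_span = Inf) {
  n <- ctx$n
  PT <- matrix(0L, n, n)
  if (n >= 5L) {
    for (i in seq_len(n - 4L)) {
      jmax <- if (is.finite(max_span)) min(n, i + as.integer(max_span)) else n
      for (j in (i + 4L):jmax) {
        PT[i, j] <- pair_type(ctx$S[[i]], ctx$S[[j]])
      }
    }
  }
  if (!is.null(cons)) {
    for (i in seq_len(n)) {
      if (cons$unpaired[[i]]) { PT[i, ] <- 0L; PT[, i] <- 0L }
      p <- cons$partner[[i]]
      if (p > 0L) {
        row <- PT[i, ]; col <- PT[, i]
        PT[i, ] <- 0L; PT[, i] <- 0L
        if (i < p) PT[i, p] <- row[[p]] else PT[p, i] <- col[[p]]
      }
    }
    # forbid pairs crossing a forced specific pair
    for (i in which(cons$partner > 0L)) {
      j <- cons$partner[[i]]
      if (j <= i) next
      if (i > 1L) for (k in seq_len(i - 1L)) {
        kl <- which(PT[k, ] > 0L)
        kl <- kl[kl >= i & kl < j]
        PT[k, kl] <- 0L
      }
      for (k in (i + 1L):(j - 1L)) {
        if (k > ctx$n) break
        kl <- which(PT[k, ] > 0L)
        kl <- kl[kl > j]
        PT[k, kl] <- 0L
      }
    }
  }
  PT
}

# Stem terms used by the DP (position-indexed, linear chain).
.ext_stem_ij <- function(ctx, i, j) {
  ext_stem_energy(pair_type(ctx$S[[i]], ctx$S[[j]]),
                  if (i > 1L) ctx$S[[i - 1L]] else -1L,
                  if (j < ctx$n) ctx$S[[j + 1L]] else -1L,
                  ctx$dangles, ctx$params)
}

.ml_stem_ij <- function(ctx, i, j, circular = FALSE) {
  ml_stem_energy(pair_type(ctx$S[[i]], ctx$S[[j]]),
                 .nt_at(ctx, i - 1L, circular),
                 .nt_at(ctx, j + 1L, circular),
                 ctx$dangles, ctx$params)
}

.ml_close_ij <- function(ctx, i, j) {
  ml_stem_energy(pair_type(ctx$S[[j]], ctx$S[[i]]),
                 ctx$S[[j - 1L]], ctx$S[[i + 1L]],
                 ctx$dangles, ctx$params)
}

# Build the MFE matrices.  `cons` is a fold_constraints object or NULL;
# `max_span` bounds j - i for every pair (local folding).
build_mfe_matrices <- function(ctx, noLP = FALSE, cons = NULL,
                               max_span = Inf) {
  n <- ctx$n
  P <- ctx$params
  PT <- .ptype_matrix(ctx, cons, max_span)
  must <- if (is.null(cons)) rep(FALSE, n) else cons$paired
  cmust <- cumsum(must)
  free_rgn <- function(a, b) a > b || (cmust[[b]] - (if (a > 1L) cmust[[a - 1L]] else 0L)) == 0L
  can_unp <- !must

  INF <- INF_ENERGY
  C1 <- matrix(INF, n, n); C2 <- matrix(INF, n, n); CA <- matrix(INF, n, n)
  M  <- matrix(INF, n, n); M1 <- matrix(INF, n, n)
  mlb <- P$ml_base; mlc <- P$ml_closing

  CB <- function(i, j) if (noLP) C2[i, j] else CA[i, j]

  for (span in 4L:max(4L, n - 1L)) {
    if (span > n - 1L) break
    for (i in seq_len(n - span)) {
      j <- i + span
      tt <- PT[i, j]
      if (tt > 0L) {
        # hairpin
        e1 <- if (free_rgn(i + 1L, j - 1L)) E_hairpin_ij(ctx, i, j) else INF
        # interior loops (excluding the pure stack, which lives in C2)
        pmax <- min(i + MAXLOOP + 1L, j - 5L)
        if (pmax >= i + 1L) for (p in (i + 1L):pmax) {
          n1 <- p - i - 1L
          if (!free_rgn(i + 1L, p - 1L)) break
          qmin <- max(p + 4L, j - 1L - (MAXLOOP - n1))
          if (qmin > j - 1L) next
          for (q in (j - 1L):qmin) {
            n2 <- j - q - 1L
            if (n1 == 0L && n2 == 0L) next
            if (!free_rgn(q + 1L, j - 1L)) break
            if (PT[p, q] == 0L) next
            inner <- if (noLP) C2[p, q] else CA[p, q]
            if (inner >= INF) next
            e <- inner + E_intloop_ij(ctx, i, j, p, q)
            if (e < e1) e1 <- e
          }
        }
        # multiloop closing
        if (j - i >= 10L) {
          close_e <- mlc + .ml_close_ij(ctx, i, j)
          for (u in (i + 1L):(j - 2L)) {
            a <- M[i + 1L, u]; b <- M1[u + 1L, j - 1L]
            if (a >= INF || b >= INF) next
            e <- a + b + close_e
            if (e < e1) e1 <- e
          }
        }
        C1[i, j] <- e1
        # stacked continuation
        if (j - i > 5L && PT[i + 1L, j - 1L] > 0L && CA[i + 1L, j - 1L] < INF)
          C2[i, j] <- CA[i + 1L, j - 1L] +
            stack_energy(tt, pair_type(ctx$S[[j - 1L]], ctx$S[[i + 1L]]), P)
        CA[i, j] <- min(C1[i, j], C2[i, j])
      }
      # M1
      cb <- CB(i, j)
      m1 <- if (cb < INF) cb + .ml_stem_ij(ctx, i, j) else INF
      if (can_unp[[j]] && M1[i, j - 1L] < INF)
        m1 <- min(m1, M1[i, j - 1L] + mlb)
      M1[i, j] <- m1
      # M
      m <- if (can_unp[[j]] && M[i, j - 1L] < INF) M[i, j - 1L] + mlb else INF
      for (k in i:(j - 4L)) {
        cb <- CB(k, j)
        if (cb >= INF) next
        stem <- cb + .ml_stem_ij(ctx, k, j)
        left <- INF
        if (k == i) left <- 0
        else {
          if (free_rgn(i, k - 1L)) left <- mlb * (k - i)
          if (M[i, k - 1L] < INF) left <- min(left, M[i, k - 1L])
        }
        if (left < INF) m <- min(m, left + stem)
      }
      M[i, j] <- m
    }
  }

  F <- rep(0, n + 1L)  # F[j + 1] holds prefix 1..j; F[1] = empty
  for (j in seq_len(n)) {
    best <- if (can_unp[[j]]) F[[j]] else INF
    if (j >= 5L) for (i in 1L:(j - 4L)) {
      cb <- CB(i, j)
      if (cb >= INF) next
      e <- F[[i]] + cb + .ext_stem_ij(ctx, i, j)
      if (e < best) best <- e
    }
    F[[j + 1L]] <- best
  }

  list(PT = PT, C1 = C1, C2 = C2, CA = CA, M = M, M1 = M1, F = F,
       noLP = noLP, cons = cons, must = must, free_rgn = free_rgn,
       can_unp = can_unp, max_span = max_span)
}

# Closed-structure traceback from matrix state `what0` at (i0, j0).
# Deterministic: cases are examined in a fixed order (stacked continuation,
# hairpin, interior loop with 5'-most inner pair first, multiloop with the
# 5'-most split), so ties always resolve the same way.
.trace_closed <- function(ctx, mm, i0, j0, what0 = if (mm$noLP) "C2" else "CA") {
  n <- ctx$n; INF <- INF_ENERGY
  P <- ctx$params
  mlb <- P$ml_base; mlc <- P$ml_closing
  C1 <- mm$C1; C2 <- mm$C2; CA <- mm$CA; M <- mm$M; M1 <- mm$M1
  PT <- mm$PT
  CBv <- function(i, j) if (mm$noLP) C2[i, j] else CA[i, j]
  pt <- integer(n)
  eq <- function(a, b) abs(a - b) < 1e-6
  stack <- list(list(what = what0, i = i0, j = j0))
  while (length(stack) > 0L) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    if (fr$what %in% c("CA", "C2", "C1")) {
      i <- fr$i; j <- fr$j
      pt[[i]] <- j; pt[[j]] <- i
      kind <- fr$what
      if (kind == "CA") kind <- if (eq(CA[i, j], C2[i, j])) "C2" else "C1"
      if (kind == "C2") {
        stack[[length(stack) + 1L]] <- list(what = "CA", i = i + 1L, j = j - 1L)
        next
      }
      e <- C1[i, j]
      if (mm$free_rgn(i + 1L, j - 1L) && eq(e, E_hairpin_ij(ctx, i, j))) next
      found <- FALSE
      pmax <- min(i + MAXLOOP + 1L, j - 5L)
      if (pmax >= i + 1L) for (p in (i + 1L):pmax) {
        n1 <- p - i - 1L
        if (!mm$free_rgn(i + 1L, p - 1L)) break
        qmin <- max(p + 4L, j - 1L - (MAXLOOP - n1))
        if (qmin > j - 1L) next
        for (q in (j - 1L):qmin) {
          if (p == i + 1L && q == j - 1L) next
          if (!mm$free_rgn(q + 1L, j - 1L)) break
          if (PT[p, q] == 0L) next
          inner <- if (mm$noLP) C2[p, q] else CA[p, q]
          if (inner < INF && eq(e, inner + E_intloop_ij(ctx, i, j, p, q))) {
            stack[[length(stack) + 1L]] <-
              list(what = if (mm$noLP) "C2" else "CA", i = p, j = q)
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (found) next
      if (j - i >= 10L) {
        close_e <- mlc + .ml_close_ij(ctx, i, j)
        for (u in (i + 1L):(j - 2L)) {
          if (M[i + 1L, u] < INF && M1[u + 1L, j - 1L] < INF &&
              eq(e, M[i + 1L, u] + M1[u + 1L, j - 1L] + close_e)) {
            stack[[length(stack) + 1L]] <- list(what = "M", i = i + 1L, j = u)
            stack[[length(stack) + 1L]] <- list(what = "M1", i = u + 1L, j = j - 1L)
            found <- TRUE
            break
          }
        }
      }
      if (!found) stop(sprintf("traceback failure at closed pair (%d,%d)", i, j))
    } else if (fr$what == "M1") {
      i <- fr$i; j <- fr$j
      repeat {
        cb <- CBv(i, j)
        if (cb < INF && eq(M1[i, j], cb + .ml_stem_ij(ctx, i, j))) {
          stack[[length(stack) + 1L]] <-
            list(what = if (mm$noLP) "C2" else "CA", i = i, j = j)
          break
        }
        if (mm$can_unp[[j]] && eq(M1[i, j], M1[i, j - 1L] + mlb)) { j <- j - 1L; next }
        stop("traceback failure in M1")
      }
    } else if (fr$what == "M") {
      i <- fr$i; j <- fr$j
      repeat {
        if (mm$can_unp[[j]] && M[i, j - 1L] < INF &&
            eq(M[i, j], M[i, j - 1L] + mlb)) { j <- j - 1L; next }
        found <- FALSE
        for (k in i:(j - 4L)) {
          cb <- CBv(k, j)
          if (cb >= INF) next
          stem <- cb + .ml_stem_ij(ctx, k, j)
          if (k == i && eq(M[i, j], stem)) {
            stack[[length(stack) + 1L]] <-
              list(what = if (mm$noLP) "C2" else "CA", i = k, j = j)
            found <- TRUE
          } else if (k > i) {
            if (mm$free_rgn(i, k - 1L) && eq(M[i, j], mlb * (k - i) + stem)) {
              stack[[length(stack) + 1L]] <-
                list(what = if (mm$noLP) "C2" else "CA", i = k, j = j)
              found <- TRUE
            } else if (M[i, k - 1L] < INF && eq(M[i, j], M[i, k - 1L] + stem)) {
              stack[[length(stack) + 1L]] <-
                list(what = if (mm$noLP) "C2" else "CA", i = k, j = j)
              stack[[length(stack) + 1L]] <- list(what = "M", i = i, j = k - 1L)
              found <- TRUE
            }
          }
          if (found) break
        }
        if (!found) stop("traceback failure in M")
        break
      }
    }
  }
  pt
}

# full traceback: walk the exterior array F, then trace each branch
.traceback <- function(ctx, mm, j_end = ctx$n) {
  INF <- INF_ENERGY
  F <- mm$F
  CBv <- function(i, j) if (mm$noLP) mm$C2[i, j] else mm$CA[i, j]
  eq <- function(a, b) abs(a - b) < 1e-6
  pt <- integer(ctx$n)
  j <- j_end
  while (j >= 1L) {
    if (mm$can_unp[[j]] && eq(F[[j + 1L]], F[[j]])) { j <- j - 1L; next }
    found <- FALSE
    if (j >= 5L) for (i in 1L:(j - 4L)) {
      cb <- CBv(i, j)
      if (cb < INF && eq(F[[j + 1L]], F[[i]] + cb + .ext_stem_ij(ctx, i, j))) {
        sub <- .trace_closed(ctx, mm, i, j)
        pt[sub != 0L] <- sub[sub != 0L]
        j <- i - 1L
        found <- TRUE
        break
      }
    }
    if (!found) stop("traceback failure in exterior loop")
  }
  structure(pt, class = "pair_table")
}

#' Minimum-free-energy folding
#'
#' Computes the MFE over all secondary structures of `seq` satisfying the
#' pairing rules (canonical pairs, minimum hairpin span of 3, no
#' pseudoknots), any hard constraints, and optionally the canonical-only
#' restriction (`noLP`: no isolated pairs), and backtraces one optimal
#' structure.  O(n^3) time, O(n^2) memory; interior loops are capped at 30
#' unpaired bases as usual.
#'
#' @param seq Sequence ([rna_sequence] or string).
#' @param params Energy parameters (default: bundled set).
#' @param dangles Dangle model, 0 or 2 (default 2).
#' @param noLP Disallow isolated (lonely) base pairs.
#' @param constraints A constraint string or [parse_constraints()] object:
#'   `.` free, `x` unpaired, `|` paired, matched `()` a specific pair.
#' @return A list of class `fold_result`: `structure` (dot-bracket),
#'   `pair_table`, `energy` (kcal/mol), and the options used.  If the
#'   constraints are unsatisfiable the energy is `Inf`, the structure is
#'   the open chain, and a warning is raised.
#' @examples
#' fold("GGGAAACCC", toy_energy_params(terminal_au = 0))
#' @export
fold <- function(seq, params = default_energy_params(), dangles = 2,
                 noLP = FALSE, constraints = NULL) {
  ctx <- fold_ctx(seq, params, dangles)
  cons <- if (is.null(constraints)) NULL
          else if (inherits(constraints, "fold_constraints")) constraints
          else parse_constraints(constraints, ctx$n)
  mm <- build_mfe_matrices(ctx, noLP = noLP, cons = cons)
  e <- mm$F[[ctx$n + 1L]]
  if (e >= INF_ENERGY / 2) {
    warning("constraints are unsatisfiable; returning the open chain with +Inf energy")
    pt <- structure(integer(ctx$n), class = "pair_table")
    return(structure(list(structure = write_dot_bracket(pt), pair_table = pt,
                          energy = Inf, dangles = dangles, noLP = noLP,
                          circular = FALSE), class = "fold_result"))
  }
  pt <- .traceback(ctx, mm)
  structure(list(structure = write_dot_bracket(pt), pair_table = pt,
                 energy = e / 100, dangles = dangles, noLP = noLP,
                 circular = FALSE), class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$structure, sprintf("(%s)", format_energy(x$energy)), "\n")
  invisible(x)
}

#' Minimum-free-energy folding of a circular sequence
#'
#' The linear recursions are unchanged; the region outside all pairs, which
#' for a linear molecule is the energy-neutral exterior loop, is evaluated
#' as a real loop on the circle: hairpin-like when a single outermost helix
#' remains, interior-loop-like for two, multiloop-like for three or more.
#' Dangle terms of outermost helices use the circular neighbor positions.
#'
#' @inheritParams fold
#' @return A `fold_result` (with `circular = TRUE`).
#' @export
fold_circular <- function(seq, params = default_energy_params(), dangles = 2,
                          noLP = FALSE) {
  ctx <- fold_ctx(seq, params, dangles)
  n <- ctx$n
  P <- ctx$params
  INF <- INF_ENERGY
  mm <- build_mfe_matrices(ctx, noLP = noLP)
  CBm <- if (noLP) mm$C2 else mm$CA
  best <- 0; best_kind <- "open"; best_args <- NULL

  # one outermost helix: the outer face is a hairpin loop
  if (n >= 5L) for (i in seq_len(n - 4L)) for (j in (i + 4L):n) {
    if (CBm[i, j] >= INF) next
    size <- n - (j - i + 1L)
    if (size < 3L) next
    s <- unclass(ctx$seq)
    loop_seq <- paste0(substr(s, j, n), substr(s, 1L, i))
    e <- CBm[i, j] +
      hairpin_energy(size, pair_type(ctx$S[[j]], ctx$S[[i]]),
                     .nt_at(ctx, j + 1L, TRUE), .nt_at(ctx, i - 1L, TRUE),
                     P, loop_seq)
    if (e < best) { best <- e; best_kind <- "H"; best_args <- c(i, j) }
  }

  # two outermost helices: the outer face is an interior loop
  if (n >= 10L) for (j1 in 5L:(n - 5L)) for (i1 in seq_len(j1 - 4L)) {
    if (CBm[i1, j1] >= INF) next
    for (i2 in (j1 + 1L):(n - 4L)) {
      n1 <- i2 - j1 - 1L
      if (n1 > MAXLOOP) break
      for (j2 in (i2 + 4L):n) {
        if (CBm[i2, j2] >= INF) next
        n2 <- n - j2 + i1 - 1L
        if (n1 + n2 > MAXLOOP) next
        e <- CBm[i1, j1] + CBm[i2, j2] +
          interior_loop_energy(n1, n2,
                               pair_type(ctx$S[[j1]], ctx$S[[i1]]),
                               pair_type(ctx$S[[j2]], ctx$S[[i2]]),
                               .nt_at(ctx, j1 + 1L, TRUE), .nt_at(ctx, i1 - 1L, TRUE),
                               .nt_at(ctx, i2 - 1L, TRUE), .nt_at(ctx, j2 + 1L, TRUE),
                               P)
        if (e < best) { best <- e; best_kind <- "I"; best_args <- c(i1, j1, i2, j2) }
      }
    }
  }

  # three or more outermost helices: the outer face is a multiloop without
  # a closing pair.  Mc = >= 1 exterior stem on a segment, Mc2 = >= 2.
  Mc <- NULL; Mc2 <- NULL
  cstem <- function(k, j) {
    if (CBm[k, j] >= INF) return(INF)
    CBm[k, j] + .ml_stem_ij(ctx, k, j, circular = TRUE)
  }
  mlb <- P$ml_base
  if (n >= 15L) {
    Mc <- matrix(INF, n, n); Mc2 <- matrix(INF, n, n)
    for (j in 5L:n) for (i in seq_len(j - 4L)) {
      m <- if (Mc[i, j - 1L] < INF) Mc[i, j - 1L] + mlb else INF
      for (k in i:(j - 4L)) {
        st <- cstem(k, j)
        if (st >= INF) next
        left <- if (k == i) 0
                else min(mlb * (k - i),
                         if (Mc[i, k - 1L] < INF) Mc[i, k - 1L] else INF)
        if (left < INF) m <- min(m, left + st)
      }
      Mc[i, j] <- m
      m2 <- if (Mc2[i, j - 1L] < INF) Mc2[i, j - 1L] + mlb else INF
      if (j - i >= 9L) for (k in (i + 5L):(j - 4L)) {
        st <- cstem(k, j)
        if (st >= INF || Mc[i, k - 1L] >= INF) next
        m2 <- min(m2, Mc[i, k - 1L] + st)
      }
      Mc2[i, j] <- m2
    }
    for (k in 11L:(n - 4L)) for (j in (k + 4L):n) {
      st <- cstem(k, j)
      if (st >= INF || Mc2[1L, k - 1L] >= INF) next
      e <- P$ml_closing + Mc2[1L, k - 1L] + st + mlb * (n - j)
      if (e < best) { best <- e; best_kind = "M"; best_args <- c(k, j) }
    }
  }

  # backtrace
  pt <- integer(n)
  add_closed <- function(pt, i, j) {
    sub <- .trace_closed(ctx, mm, i, j)
    pt[sub != 0L] <- sub[sub != 0L]
    pt
  }
  eq <- function(a, b) abs(a - b) < 1e-6
  if (best_kind == "H") {
    pt <- add_closed(pt, best_args[[1L]], best_args[[2L]])
  } else if (best_kind == "I") {
    pt <- add_closed(pt, best_args[[1L]], best_args[[2L]])
    pt <- add_closed(pt, best_args[[3L]], best_args[[4L]])
  } else if (best_kind == "M") {
    pt <- add_closed(pt, best_args[[1L]], best_args[[2L]])
    # unwind Mc2[1, k-1], then Mc
    i <- 1L; j <- best_args[[1L]] - 1L; two <- TRUE
    while (j > 0L) {
      if (two) {
        if (Mc2[i, j - 1L] < INF && eq(Mc2[i, j], Mc2[i, j - 1L] + mlb)) { j <- j - 1L; next }
        found <- FALSE
        for (k in (i + 5L):(j - 4L)) {
          st <- cstem(k, j)
          if (st < INF && Mc[i, k - 1L] < INF && eq(Mc2[i, j], Mc[i, k - 1L] + st)) {
            pt <- add_closed(pt, k, j)
            j <- k - 1L; two <- FALSE; found <- TRUE
            break
          }
        }
        if (!found) stop("traceback failure in circular exterior (Mc2)")
      } else {
        if (j > i && Mc[i, j - 1L] < INF && eq(Mc[i, j], Mc[i, j - 1L] + mlb)) { j <- j - 1L; next }
        found <- FALSE
        for (k in i:(j - 4L)) {
          st <- cstem(k, j)
          if (st >= INF) next
          left <- if (k == i) 0
                  else min(mlb * (k - i),
                           if (Mc[i, k - 1L] < INF) Mc[i, k - 1L] else INF)
          if (left < INF && eq(Mc[i, j], left + st)) {
            pt <- add_closed(pt, k, j)
            if (k > i && Mc[i, k - 1L] < INF && eq(left, Mc[i, k - 1L]) &&
                !eq(left, mlb * (k - i))) {
              j <- k - 1L
            } else j <- 0L
            found <- TRUE
            break
          }
        }
        if (!found) stop("traceback failure in circular exterior (Mc)")
        if (j == 0L) break
      }
    }
  }
  pt <- structure(pt, class = "pair_table")
  structure(list(structure = write_dot_bracket(pt), pair_table = pt,
                 energy = best / 100, dangles = dangles, noLP = noLP,
                 circular = TRUE), class = "fold_result")
}
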