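# Intermolecular duplex prediction: hybridization of two strands with only
# intermolecular pairs and no multibranch loops -- the interaction is a
# single helical region interrupted by bulges and interior loops, opened
# and closed by terminal ends that receive initiation, terminal-AU and
# dangle contributions.

#' Predict the optimal RNA-RNA duplex between two sequences
#'
#' Dynamic program over pairs `(i, j)` (position `i` in the first strand
#' paired with `j` in the second): consecutive pairs must be monotone
#' (`i` increasing, `j` decreasing along the second strand read 5' to 3')
#' and are joined by stacks, bulges, or interior loops capped at
#' `MAXLOOP` unpaired bases.  The duplex initiation penalty is charged
#' once; both helix ends receive terminal-AU penalties and, under dangle
#' model 2, dangle/mismatch terms from available flanking nucleotides.
#'
#' @param seq1,seq2 The two sequences (5' to 3').
#' @param params Energy parameters.
#' @param dangles Dangle model, 0 or 2.
#' @param band Report every hit within `band` kcal/mol of the best
#'   (default 0: best only).
#' @return A data.frame of hits (best first): `structure` (dot-bracket
#'   with `&` separating the strands, covering `i1..i2` and `j1..j2`),
#'   `i1`, `i2`, `j1`, `j2` (1-based inclusive interaction ranges) and
#'   `energy` (kcal/mol).  Empty (zero rows) when no stabilizing
#'   interaction exists; the attribute `best_energy` carries the optimum
#'   over all interactions (`Inf` when none is possible).
#' @export
duplex_fold <- function(seq1, seq2, params = default_energy_params(),
                        dangles = 2, band = 0) {
  s1 <- as_rna_sequence(seq1); s2 <- as_rna_sequence(seq2)
  S1 <- seq_codes(s1); S2 <- seq_codes(s2)
  n1 <- length(S1); n2 <- length(S2)
  if (n1 < 2L || n2 < 2L) stop("both sequences must have length >= 2")
  P <- params
  INF <- INF_ENERGY
  type <- function(i, j) pair_type(S1[[i]], S2[[j]])
  open_term <- function(i, j) {
    ext_stem_energy(type(i, j),
                    if (i > 1L) S1[[i - 1L]] else -1L,
                    if (j < n2) S2[[j + 1L]] else -1L,
                    dangles, P)
  }
  close_term <- function(i, j) {
    ext_stem_energy(.RTYPE[[type(i, j)]],
                    if (j > 1L) S2[[j - 1L]] else -1L,
                    if (i < n1) S1[[i + 1L]] else -1L,
                    dangles, P)
  }
  E <- matrix(INF, n1, n2)
  back <- array(0L, dim = c(n1, n2, 2L))
  for (i in seq_len(n1)) for (j in n2:1L) {
    if (type(i, j) == 0L) next
    best <- P$duplex_init + open_term(i, j)
    bk <- c(0L, 0L)
    kmin <- max(1L, i - MAXLOOP - 1L)
    if (i > 1L && j < n2) for (k in (i - 1L):kmin) {
      d1 <- i - k - 1L
      lmax <- min(n2, j + 1L + (MAXLOOP - d1))
      for (l in (j + 1L):lmax) {
        if (E[k, l] >= INF) next
        d2 <- l - j - 1L
        e <- E[k, l] + interior_loop_energy(
          d1, d2, type(k, l), pair_type(S2[[j]], S1[[i]]),
          S1[[k + 1L]], S2[[l - 1L]], S1[[i - 1L]], S2[[j + 1L]], P)
        if (e < best) { best <- e; bk <- c(k, l) }
      }
    }
    E[i, j] <- best
    back[i, j, ] <- bk
  }
  tot <- E
  for (i in seq_len(n1)) for (j in seq_len(n2))
    if (E[i, j] < INF) tot[i, j] <- E[i, j] + close_term(i, j)
  best_e <- min(tot)
  hits <- list()
  if (best_e < 0) {
    sel <- which(tot <= best_e + round(band * 100) + 1e-6, arr.ind = TRUE)
    sel <- sel[order(tot[sel]), , drop = FALSE]
    for (r in seq_len(nrow(sel))) {
      i <- sel[r, 1L]; j <- sel[r, 2L]
      # backtrack the pair chain
      pi <- integer(); pj <- integer()
      ci <- i; cj <- j
      repeat {
        pi <- c(ci, pi); pj <- c(cj, pj)
        nb <- back[ci, cj, ]
        if (nb[[1L]] == 0L) break
        ci <- nb[[1L]]; cj <- nb[[2L]]
      }
      i1 <- min(pi); i2 <- max(pi); j1 <- min(pj); j2 <- max(pj)
      part1 <- rep(".", i2 - i1 + 1L); part1[pi - i1 + 1L] <- "("
      part2 <- rep(".", j2 - j1 + 1L); part2[pj - j1 + 1L] <- ")"
      hits[[length(hits) + 1L]] <- data.frame(
        structure = paste0(paste(part1, collapse = ""), "&",
                           paste(part2, collapse = "")),
        i1 = i1, i2 = i2, j1 = j1, j2 = j2, energy = tot[i, j] / 100)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits)
         else data.frame(structure = character(), i1 = integer(),
                         i2 = integer(), j1 = integer(), j2 = integer(),
                         energy = numeric())
  rownames(out) <- NULL
  attr(out, "best_energy") <- if (best_e >= INF / 2) Inf else best_e / 100
  out
}
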