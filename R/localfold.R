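# Scanning (local) folding: locally stable substructures with bounded pair
# span, and window-averaged pair probabilities / accessibilities.

#' Locally stable secondary structures with bounded pair span
#'
#' Folds the whole sequence with every pair restricted to span at most `L`
#' and reports locally optimal hits: helix-closing pairs `(i, j)` whose
#' structure (including its exterior stem term) is stabilizing
#' (energy < 0) and cannot be improved by extending the helix outward to
#' `(i - 1, j + 1)`.  With `L >= n` and a single-component MFE structure,
#' the best hit reproduces the global fold.
#'
#' @param seq Sequence.
#' @param params Energy parameters.
#' @param L Maximum pair span (`j - i`), `4 < L <= n` (values above `n`
#'   are clamped).
#' @param dangles Dangle model, 0 or 2.
#' @return A data.frame of hits sorted by start position: `start`, `end`,
#'   `structure` (dot-bracket of the subsequence `start..end`), `energy`
#'   (kcal/mol, including the hit's exterior stem term).
#' @export
lfold <- function(seq, params = default_energy_params(), L,
                  dangles = 2) {
  ctx <- fold_ctx(seq, params, dangles)
  n <- ctx$n
  if (L <= 4) stop("L must exceed 4")
  L <- min(L, n)
  mm <- build_mfe_matrices(ctx, max_span = L)
  CAm <- mm$CA
  INF <- INF_ENERGY
  hit_e <- function(i, j) CAm[i, j] + .ext_stem_ij(ctx, i, j)
  starts <- integer(); ends <- integer(); strs <- character(); es <- numeric()
  for (i in seq_len(max(0L, n - 4L))) for (j in (i + 4L):min(n, i + L)) {
    if (CAm[i, j] >= INF) next
    e <- hit_e(i, j)
    if (e >= 0) next
    # locally optimal: growing the helix outward must not help
    if (i > 1L && j < n && j + 1L - (i - 1L) <= L &&
        mm$PT[i - 1L, j + 1L] > 0L && CAm[i - 1L, j + 1L] < INF &&
        hit_e(i - 1L, j + 1L) <= e) next
    pt <- .trace_closed(ctx, mm, i, j)
    loc <- pt[i:j]
    loc[loc != 0L] <- loc[loc != 0L] - (i - 1L)
    strs[[length(strs) + 1L]] <- write_dot_bracket(loc)
    starts[[length(starts) + 1L]] <- i
    ends[[length(ends) + 1L]] <- j
    es[[length(es) + 1L]] <- e / 100
  }
  out <- data.frame(start = starts, end = ends, structure = strs, energy = es)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Windowed base-pair probabilities and accessibilities
#'
#' Computes, for every admissible pair, the equilibrium pairing probability
#' averaged over all sequence windows of length `W` that contain the pair
#' (pair span limited to `L`), and the accessibility profile: the
#' probability that the interval of length `l` ending at position `i` is
#' completely unpaired, likewise averaged over windows.  Positions near the
#' sequence ends belong to fewer windows; averages divide by the actual
#' window count.
#'
#' @param seq Sequence.
#' @param params Energy parameters.
#' @param W Window length (`<= n`; `W = n` reproduces the global ensemble).
#' @param L Maximum pair span within a window (default `W`).
#' @param u Maximum accessibility interval length (default 0: skip).
#' @param dangles Dangle model, 0 or 2.
#' @return A list: `bpp` (n x n averaged pair probabilities), and if
#'   `u > 0` `accessibility`, an n x u matrix with `[i, l]` the averaged
#'   probability that `(i - l + 1)..i` is unpaired (NA where `l > i`).
#' @export
plfold <- function(seq, params = default_energy_params(), W, L = W, u = 0,
                   dangles = 2) {
  ctx <- fold_ctx(seq, params, dangles)
  n <- ctx$n
  if (W > n) stop("window length W exceeds the sequence length")
  if (L > W) stop("pair span bound L must not exceed W")
  if (W < 5) stop("window length W must be at least 5")
  s <- unclass(ctx$seq)
  nw <- n - W + 1L
  psum <- matrix(0, n, n); pcnt <- matrix(0, n, n)
  asum <- if (u > 0) matrix(0, n, u) else NULL
  acnt <- if (u > 0) matrix(0, n, u) else NULL
  for (a in seq_len(nw)) {
    b <- a + W - 1L
    wseq <- substr(s, a, b)
    pf <- partition_function(wseq, params, dangles = dangles, max_span = L)
    idx <- a:b
    psum[idx, idx] <- psum[idx, idx] + pf$bpp
    pcnt[idx, idx] <- pcnt[idx, idx] + 1
    if (u > 0) {
      lnZ <- pf$lnZ
      for (e_loc in seq_len(W)) {
        i_glob <- a + e_loc - 1L
        for (l in seq_len(min(u, e_loc))) {
          cvec <- rep(".", W)
          cvec[(e_loc - l + 1L):e_loc] <- "x"
          pfm <- partition_function(wseq, params, dangles = dangles,
                                    max_span = L,
                                    constraints = paste(cvec, collapse = ""))
          asum[i_glob, l] <- asum[i_glob, l] + exp(pfm$lnZ - lnZ)
          acnt[i_glob, l] <- acnt[i_glob, l] + 1
        }
      }
    }
  }
  bpp <- matrix(0, n, n)
  nz <- pcnt > 0
  bpp[nz] <- psum[nz] / pcnt[nz]
  bpp[lower.tri(bpp, diag = TRUE)] <- 0
  res <- list(bpp = bpp, W = W, L = L)
  if (u > 0) {
    acc <- matrix(NA_real_, n, u)
    nz <- acnt > 0
    acc[nz] <- asum[nz] / acnt[nz]
    res$accessibility <- acc
  }
  res
}
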