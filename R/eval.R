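# Loop decomposition and free-energy evaluation of a sequence/structure
# pair.  This is the arithmetic backbone of the package: the folding,
# suboptimal and partition-function modules all promise that the energies
# they report equal the loop-sum computed here.

# Folding context: precomputed integer codes and model options.
fold_ctx <- function(seq, params, dangles = 2) {
  seq <- as_rna_sequence(seq)
  S <- seq_codes(seq)
  if (!dangles %in% c(0, 2))
    stop("only dangle models 0 and 2 are supported")
  list(seq = seq, S = S, n = length(S), params = params, dangles = dangles)
}

# modular position (circular sequences); returns 0 outside 1..n for linear
.wrap <- function(i, n, circular) {
  if (circular) ((i - 1L) %% n) + 1L else if (i >= 1L && i <= n) i else 0L
}

# nucleotide code at modular position, -1 when outside the sequence
.nt_at <- function(ctx, i, circular = FALSE) {
  i <- .wrap(i, ctx$n, circular)
  if (i == 0L) -1L else ctx$S[[i]]
}

# hairpin loop closed by (i, j) on the linear sequence
E_hairpin_ij <- function(ctx, i, j) {
  size <- j - i - 1L
  loop_seq <- substr(unclass(ctx$seq), i, j)
  hairpin_energy(size, pair_type(ctx$S[[i]], ctx$S[[j]]),
                 ctx$S[[i + 1L]], ctx$S[[j - 1L]], ctx$params, loop_seq)
}

# interior loop / bulge / stack between outer (i, j) and inner (p, q)
E_intloop_ij <- function(ctx, i, j, p, q) {
  interior_loop_energy(p - i - 1L, j - q - 1L,
                       pair_type(ctx$S[[i]], ctx$S[[j]]),
                       pair_type(ctx$S[[q]], ctx$S[[p]]),
                       ctx$S[[i + 1L]], ctx$S[[j - 1L]],
                       ctx$S[[p - 1L]], ctx$S[[q + 1L]], ctx$params)
}

# stem term of branch (i, j) seen from the loop that lies 5' of i and 3' of
# j (an enclosing multiloop or the exterior loop); `closing` flips the
# orientation for a closing pair seen from inside its loop.
.stem_term <- function(ctx, i, j, where = c("ext", "ml"), closing = FALSE,
                       circular = FALSE) {
  where <- match.arg(where)
  if (closing) {
    type <- pair_type(ctx$S[[j]], ctx$S[[i]])
    si1 <- ctx$S[[j - 1L]]; sj1 <- ctx$S[[i + 1L]]
  } else {
    type <- pair_type(ctx$S[[i]], ctx$S[[j]])
    si1 <- .nt_at(ctx, i - 1L, circular)
    sj1 <- .nt_at(ctx, j + 1L, circular)
  }
  if (where == "ext")
    ext_stem_energy(type, si1, sj1, ctx$dangles, ctx$params)
  else
    ml_stem_energy(type, si1, sj1, ctx$dangles, ctx$params)
}

# top-level branches of segment i..j in pair table pt
.branches <- function(pt, i, j) {
  out <- list(); k <- i
  while (k <= j) {
    if (pt[[k]] > k) { out[[length(out) + 1L]] <- c(k, pt[[k]]); k <- pt[[k]] + 1L }
    else k <- k + 1L
  }
  out
}

#' Decompose a structure into loops
#'
#' Partitions a secondary structure into its constituent loops: hairpins,
#' stacks, interior loops/bulges, multibranch loops, and (for linear
#' sequences) the exterior loop.  For circular sequences there is no
#' exterior loop; the region outside all pairs is itself evaluated as a
#' loop (hairpin-like for one outermost helix, interior-like for two,
#' multiloop-like for three or more).
#'
#' @param seq Sequence ([rna_sequence] or string).
#' @param structure Dot-bracket string or pair table.
#' @param circular Treat the sequence as circular.
#' @return A list of loops, each a list with `kind`, closing pair `i`, `j`
#'   (0 for the exterior loop), `branches` (list of enclosed pairs) and
#'   `unpaired` count.
#' @export
decompose_structure <- function(seq, structure, circular = FALSE) {
  seq <- as_rna_sequence(seq)
  pt <- if (inherits(structure, "pair_table")) structure
        else parse_dot_bracket(structure)
  n <- length(pt)
  if (nchar(seq) != n)
    stop("sequence and structure have different lengths")
  validate_pair_table(pt)
  loops <- list()
  for (i in seq_len(n)) {
    j <- pt[[i]]
    if (j <= i) next
    br <- .branches(pt, i + 1L, j - 1L)
    unp <- (j - i - 1L) - sum(vapply(br, function(b) b[[2L]] - b[[1L]] + 1L, 0))
    kind <- if (length(br) == 0L) "hairpin"
            else if (length(br) == 1L) { if (unp == 0L) "stack" else "interior" }
            else "multiloop"
    loops[[length(loops) + 1L]] <-
      list(kind = kind, i = i, j = j, branches = br, unpaired = unp)
  }
  top <- .branches(pt, 1L, n)
  paired_span <- sum(vapply(top, function(b) b[[2L]] - b[[1L]] + 1L, 0))
  if (!circular) {
    loops[[length(loops) + 1L]] <-
      list(kind = "exterior", i = 0L, j = 0L, branches = top,
           unpaired = n - paired_span)
  } else if (length(top) > 0L) {
    kind <- c("closing-hairpin", "closing-interior")[min(length(top), 2L)]
    if (length(top) > 2L) kind <- "closing-multiloop"
    loops[[length(loops) + 1L]] <-
      list(kind = kind, i = 0L, j = 0L, branches = top,
           unpaired = n - paired_span)
  }
  loops
}

# energy (dekacal) of the loop closed by pair (i, j)
.closed_loop_energy <- function(ctx, pt, i, j) {
  br <- .branches(pt, i + 1L, j - 1L)
  if (length(br) == 0L) return(E_hairpin_ij(ctx, i, j))
  if (length(br) == 1L)
    return(E_intloop_ij(ctx, i, j, br[[1L]][[1L]], br[[1L]][[2L]]))
  unp <- (j - i - 1L) - sum(vapply(br, function(b) b[[2L]] - b[[1L]] + 1L, 0))
  e <- ctx$params$ml_closing + ctx$params$ml_base * unp +
    .stem_term(ctx, i, j, "ml", closing = TRUE)
  for (b in br) e <- e + .stem_term(ctx, b[[1L]], b[[2L]], "ml")
  e
}

# energy (dekacal) of the circular closing loop formed by top-level helices
.circular_closing_energy <- function(ctx, top) {
  n <- ctx$n
  if (length(top) == 0L) return(0)
  if (length(top) == 1L) {
    i <- top[[1L]][[1L]]; j <- top[[1L]][[2L]]
    size <- n - (j - i + 1L)
    # on the circle the outer face of a lone helix is itself a hairpin loop,
    # so it must enclose at least 3 unpaired bases as well
    if (size < 3) return(INF_ENERGY)
    s <- unclass(ctx$seq)
    loop_seq <- paste0(substr(s, j, n), substr(s, 1L, i))
    return(hairpin_energy(size, pair_type(ctx$S[[j]], ctx$S[[i]]),
                          .nt_at(ctx, j + 1L, TRUE), .nt_at(ctx, i - 1L, TRUE),
                          ctx$params, loop_seq))
  }
  if (length(top) == 2L) {
    i1 <- top[[1L]][[1L]]; j1 <- top[[1L]][[2L]]
    i2 <- top[[2L]][[1L]]; j2 <- top[[2L]][[2L]]
    return(interior_loop_energy(
      i2 - j1 - 1L, n - j2 + i1 - 1L,
      pair_type(ctx$S[[j1]], ctx$S[[i1]]),
      pair_type(ctx$S[[j2]], ctx$S[[i2]]),
      .nt_at(ctx, j1 + 1L, TRUE), .nt_at(ctx, i1 - 1L, TRUE),
      .nt_at(ctx, i2 - 1L, TRUE), .nt_at(ctx, j2 + 1L, TRUE),
      ctx$params))
  }
  unp <- n - sum(vapply(top, function(b) b[[2L]] - b[[1L]] + 1L, 0))
  e <- ctx$params$ml_closing + ctx$params$ml_base * unp
  for (b in top)
    e <- e + .stem_term(ctx, b[[1L]], b[[2L]], "ml", circular = TRUE)
  e
}

# total energy in dekacal for a pair table
eval_energy_dk <- function(ctx, pt, circular = FALSE) {
  n <- ctx$n
  if (length(pt) != n) stop("sequence and structure have different lengths")
  e <- 0
  for (i in seq_len(n)) {
    j <- pt[[i]]
    if (j > i) e <- e + .closed_loop_energy(ctx, pt, i, j)
  }
  top <- .branches(pt, 1L, n)
  if (circular) {
    e <- e + .circular_closing_energy(ctx, top)
  } else {
    for (b in top) e <- e + .stem_term(ctx, b[[1L]], b[[2L]], "ext")
  }
  # INF is absorbing: a structure with any forbidden loop is forbidden
  if (e >= INF_ENERGY / 2) e <- INF_ENERGY
  e
}

#' Free energy of a given sequence/structure pair
#'
#' Decomposes the structure into loops and sums the nearest-neighbor loop
#' energies.  Structures violating the minimum hairpin span are rejected.
#'
#' @param seq Sequence ([rna_sequence] or string).
#' @param structure Dot-bracket string or pair table.
#' @param params Energy parameters (default: bundled set).
#' @param dangles Dangle model: 2 (default; both-side dangles always count)
#'   or 0 (no dangle/terminal-stacking contributions in multiloops and the
#'   exterior loop).
#' @param circular Evaluate on the circular sequence.
#' @return Energy in kcal/mol.
#' @examples
#' eval_energy("GGGAAACCC", "(((...)))", toy_energy_params(terminal_au = 0))
#' @export
eval_energy <- function(seq, structure, params = default_energy_params(),
                        dangles = 2, circular = FALSE) {
  ctx <- fold_ctx(seq, params, dangles)
  pt <- if (inherits(structure, "pair_table")) structure
        else parse_dot_bracket(structure)
  validate_pair_table(pt)
  eval_energy_dk(ctx, pt, circular) / 100
}
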