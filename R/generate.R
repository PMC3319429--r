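# Deterministic test-input generation: random sequences, and the exhaustive
# structure enumerator used as the ground-truth oracle for the folding,
# partition-function and suboptimal modules at small n.

#' Enumerate all secondary structures of a sequence
#'
#' Complete, duplicate-free enumeration of every pseudoknot-free structure
#' over the canonical pairs of `seq` (minimum hairpin span 3).  Intended as
#' a brute-force oracle for small sequences; refuses `n > max_n` because the
#' count grows exponentially.
#'
#' @param seq Sequence ([rna_sequence] or string).
#' @param noLP Keep only structures without isolated pairs.
#' @param constraints Optional constraint string or [parse_constraints()]
#'   object; only satisfying structures are returned.
#' @param max_n Refusal guard (default 16).
#' @return A list of `pair_table` objects (the open chain is always first).
#' @export
enumerate_structures <- function(seq, noLP = FALSE, constraints = NULL,
                                 max_n = 16L) {
  seq <- as_rna_sequence(seq)
  S <- seq_codes(seq)
  n <- length(S)
  if (n > max_n)
    stop(sprintf("refusing to enumerate structures for n = %d > %d", n, max_n))
  pairable <- function(i, j) pair_type(S[[i]], S[[j]]) > 0L
  memo <- new.env(parent = emptyenv())
  # list of "pair sets" (2-column matrices) for interval i..j
  structs <- function(i, j) {
    if (j - i < 4L) return(list(matrix(0L, 0L, 2L)))
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- structs(i + 1L, j)                     # i unpaired
    for (k in (i + 4L):j) {
      if (!pairable(i, k)) next
      left <- structs(i + 1L, k - 1L)
      right <- structs(k + 1L, j)
      for (a in left) for (b in right)
        out[[length(out) + 1L]] <- rbind(a, b, c(i, k))
    }
    memo[[key]] <- out
    out
  }
  all_sets <- structs(1L, n)
  tables <- lapply(all_sets, function(ps) {
    pt <- integer(n)
    if (nrow(ps) > 0L) { pt[ps[, 1L]] <- ps[, 2L]; pt[ps[, 2L]] <- ps[, 1L] }
    structure(pt, class = "pair_table")
  })
  if (noLP) tables <- Filter(function(pt) !.has_lonely_pair(pt), tables)
  if (!is.null(constraints)) {
    cons <- if (inherits(constraints, "fold_constraints")) constraints
            else parse_constraints(constraints, n)
    tables <- Filter(function(pt) satisfies_constraints(pt, cons), tables)
  }
  tables
}

.has_lonely_pair <- function(pt) {
  n <- length(pt)
  for (i in seq_len(n)) {
    j <- pt[[i]]
    if (j <= i) next
    inner <- i + 1L <= n && pt[[i + 1L]] == j - 1L
    outer <- i > 1L && j < n && pt[[i - 1L]] == j + 1L
    if (!inner && !outer) return(TRUE)
  }
  FALSE
}

#' Does a structure satisfy a set of hard constraints?
#'
#' @param pt Pair table.
#' @param cons A [parse_constraints()] object.
#' @return `TRUE` or `FALSE`.
#' @export
satisfies_constraints <- function(pt, cons) {
  n <- length(pt)
  for (i in seq_len(n)) {
    if (cons$unpaired[[i]] && pt[[i]] != 0L) return(FALSE)
    if (cons$paired[[i]] && pt[[i]] == 0L) return(FALSE)
    p <- cons$partner[[i]]
    if (p > 0L && pt[[i]] != p) return(FALSE)
  }
  TRUE
}

# independent structure counter (interval recursion on counts only),
# used to validate the enumerator
count_structures <- function(seq) {
  S <- seq_codes(as_rna_sequence(seq))
  n <- length(S)
  cnt <- matrix(NA_real_, n + 1L, n + 1L)
  cget <- function(i, j) {
    if (j - i < 4L) return(1)
    if (!is.na(cnt[i, j])) return(cnt[i, j])
    tot <- cget(i + 1L, j)
    for (k in (i + 4L):j)
      if (pair_type(S[[i]], S[[k]]) > 0L)
        tot <- tot + cget(i + 1L, k - 1L) * cget(k + 1L, j)
    cnt[i, j] <<- tot
    tot
  }
  cget(1L, n)
}

#' Generate a random RNA sequence
#'
#' @param length Sequence length (>= 1).
#' @param gc Probability of a position being G or C (split evenly); A and U
#'   share the remainder.  Default 0.5.
#' @param seed Optional integer seed (local to this call).
#' @return An [rna_sequence].
#' @export
random_rna <- function(length, gc = 0.5, seed = NULL) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  draw <- function() {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
    paste(sample(names(probs), length, replace = TRUE, prob = probs),
          collapse = "")
  }
  s <- if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    draw()
  } else draw()
  rna_sequence(s)
}
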