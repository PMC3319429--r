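# Loop free energies (integer dekacal).  These are the additive building
# blocks of the nearest-neighbor model: every secondary structure decomposes
# uniquely into loops, and its energy is the sum of the loop energies.
#
# Conventions:
#  * pair types are 1..7 (see params.R); type > 2 means the helix end is
#    AU/GU/nonstandard and attracts the terminal-AU penalty where the
#    parameter set applies it (hairpin closings of size-3 loops, bulges of
#    size > 1, multiloop and exterior-loop stems).
#  * nucleotide arguments are integer codes (A=1..U=4, N=0); 0 also encodes
#    "no neighbor" at sequence ends.
#  * lxc extrapolation beyond tabulated loop size 30:
#    tab[30] + round(lxc * ln(size/30)), rounded half away from zero.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

.loop_length_energy <- function(tab, size, lxc) {
  if (size <= 30) tab[[size + 1L]]
  else tab[[31L]] + round_half_away(lxc * log(size / 30))
}

#' Free energy of a hairpin loop
#'
#' Computes the energy of a hairpin of `size` unpaired bases closed by a
#' pair of type `type`: the tabulated (or log-extrapolated) length penalty,
#' plus the terminal mismatch for loops of size > 3, or the terminal-AU
#' penalty for size-3 loops closed by AU/GU.  If the closing pair plus loop
#' sequence matches a tabulated special hairpin (tri-, tetra-, hexaloop),
#' the tabulated energy replaces the generic terms entirely.
#'
#' @param size Number of unpaired loop bases (>= 3).
#' @param type Closing pair type (1..7).
#' @param si1,sj1 Nucleotide codes of the loop bases adjacent to the closing
#'   pair (5' and 3' side).
#' @param params An `energy_params` object.
#' @param loop_seq Optional string: closing pair + loop sequence
#'   (`size + 2` characters), used for the special-hairpin lookup.
#' @return Energy in dekacal (10 cal/mol).
#' @export
hairpin_energy <- function(size, type, si1 = 0L, sj1 = 0L, params,
                           loop_seq = NULL) {
  if (size < 3) stop("hairpin loops require at least 3 unpaired bases")
  e <- .loop_length_energy(params$hairpin, size, params$lxc)
  if (!is.null(loop_seq)) {
    tab <- if (size == 3) params$triloops
           else if (size == 4) params$tetraloops
           else if (size == 6) params$hexaloops
           else NULL
    if (!is.null(tab) && nrow(tab) > 0L) {
      hit <- match(loop_seq, tab$seq)
      if (!is.na(hit)) return(tab$energy[[hit]])
    }
  }
  if (size == 3) {
    if (type > 2) e <- e + params$terminal_au
  } else {
    e <- e + params$mismatch_hairpin[type, si1 + 1L, sj1 + 1L]
  }
  e
}

#' Stacking energy of two adjacent base pairs
#'
#' Lookup of the stacking contribution for an outer pair of type `type`
#' enclosing an inner pair whose type, seen from the opposite strand
#' direction, is `type2` (i.e. `type2 = pair_type(S[q], S[p])` for inner
#' pair `(p, q)`).  The table is symmetric under simultaneous strand
#' reversal of both pairs.
#'
#' @param type Outer pair type (1..7).
#' @param type2 Inner pair type viewed from the 3' side (1..7).
#' @param params An `energy_params` object.
#' @return Energy in dekacal.
#' @export
stack_energy <- function(type, type2, params) {
  params$stack[type, type2]
}

#' Free energy of an interior loop or bulge
#'
#' Dispatches on the two unpaired strand lengths `n1` (5' side) and `n2`
#' (3' side) between an outer pair and an enclosed pair:
#' bulges (`min = 0`) use the bulge length table, retaining the stacking
#' term for size-1 bulges and adding terminal-AU penalties for larger ones;
#' 1x1, 2x1 and 2x2 loops use the tabulated `int11`/`int21`/`int22` values;
#' 1xn (n > 2) and 2x3 loops use their dedicated mismatch tables; all other
#' loops use the generic length table plus the Ninio asymmetry term
#' `min(cap, |n1 - n2| * ninio)` and both terminal mismatches.
#'
#' @param n1,n2 Unpaired lengths on the two sides (not both 0).
#' @param type Outer closing pair type.
#' @param type2 Enclosed pair type viewed from the 3' side.
#' @param si1,sj1 Mismatch nucleotides adjacent to the outer pair.
#' @param sp1,sq1 Mismatch nucleotides adjacent to the enclosed pair.
#' @param params An `energy_params` object.
#' @return Energy in dekacal.
#' @export
interior_loop_energy <- function(n1, n2, type, type2, si1 = 0L, sj1 = 0L,
                                 sp1 = 0L, sq1 = 0L, params) {
  if (n1 < 0 || n2 < 0) stop("negative loop size")
  nl <- max(n1, n2); ns <- min(n1, n2)
  if (nl == 0) return(params$stack[type, type2])
  if (ns == 0) {                                   # bulge
    e <- .loop_length_energy(params$bulge, nl, params$lxc)
    if (nl == 1) {
      e <- e + params$stack[type, type2]
    } else {
      if (type  > 2) e <- e + params$terminal_au
      if (type2 > 2) e <- e + params$terminal_au
    }
    return(e)
  }
  if (ns == 1 && nl == 1)
    return(params$int11[type, type2, si1 + 1L, sj1 + 1L])
  if (ns == 1 && nl == 2) {
    if (n1 == 1)                                   # 1 on 5' side, 2 on 3'
      return(params$int21[type, type2, si1 + 1L, sq1 + 1L, sj1 + 1L])
    else                                           # mirrored orientation
      return(params$int21[type2, type, sq1 + 1L, si1 + 1L, sp1 + 1L])
  }
  if (ns == 1) {                                   # 1 x n, n > 2
    e <- .loop_length_energy(params$interior, nl + 1, params$lxc) +
      min(params$max_ninio, (nl - ns) * params$ninio)
    e + params$mismatch_interior_1n[type, si1 + 1L, sj1 + 1L] +
      params$mismatch_interior_1n[type2, sq1 + 1L, sp1 + 1L]
  } else if (ns == 2 && nl == 2) {
    params$int22[type, type2, si1 + 1L, sp1 + 1L, sq1 + 1L, sj1 + 1L]
  } else if (ns == 2 && nl == 3) {                 # 2 x 3
    e <- .loop_length_energy(params$interior, 5, params$lxc) + params$ninio
    e + params$mismatch_interior_23[type, si1 + 1L, sj1 + 1L] +
      params$mismatch_interior_23[type2, sq1 + 1L, sp1 + 1L]
  } else {                                         # generic interior loop
    e <- .loop_length_energy(params$interior, n1 + n2, params$lxc) +
      min(params$max_ninio, (nl - ns) * params$ninio)
    e + params$mismatch_interior[type, si1 + 1L, sj1 + 1L] +
      params$mismatch_interior[type2, sq1 + 1L, sp1 + 1L]
  }
}

# Contribution of a helix end ("stem") inside a multiloop, including the
# per-branch affine term.  Under dangle model 2 the stem always receives the
# both-side mismatch of its neighboring (inside-loop) nucleotides; under
# model 0 no dangle terms apply.  Terminal-AU is added for type > 2.
ml_stem_energy <- function(type, si1, sj1, dangles, params) {
  e <- params$ml_intern
  if (dangles == 2) {
    if (si1 >= 0 && sj1 >= 0)
      e <- e + params$mismatch_multi[type, si1 + 1L, sj1 + 1L]
    else if (si1 >= 0) e <- e + params$dangle5[type, si1 + 1L]
    else if (sj1 >= 0) e <- e + params$dangle3[type, sj1 + 1L]
  }
  if (type > 2) e <- e + params$terminal_au
  e
}

# Contribution of a helix end in the exterior loop.  si1/sj1 are the codes
# of the flanking nucleotides, or -1 when the helix abuts a sequence end.
ext_stem_energy <- function(type, si1, sj1, dangles, params) {
  e <- 0
  if (dangles == 2) {
    if (si1 >= 0 && sj1 >= 0)
      e <- e + params$mismatch_exterior[type, si1 + 1L, sj1 + 1L]
    else if (si1 >= 0) e <- e + params$dangle5[type, si1 + 1L]
    else if (sj1 >= 0) e <- e + params$dangle3[type, sj1 + 1L]
  }
  if (type > 2) e <- e + params$terminal_au
  e
}

#' Free energy of a multibranch loop
#'
#' Affine multiloop model: `a + b * branches + c * unpaired`, where
#' `branches` counts every helix end in the loop including the closing one,
#' plus per-branch terminal-AU penalties and (under dangle model 2) the
#' both-side mismatch of each branch.  No asymmetry or branch-number
#' special cases apply.
#'
#' @param branch_types Integer vector of pair types, one per branch
#'   (closing pair first, viewed from inside the loop).
#' @param unpaired Number of unpaired bases in the loop.
#' @param mismatches Optional 2-column matrix of flanking nucleotide codes
#'   (5', 3') per branch; required for dangle model 2.
#' @param dangles Dangle model, 0 or 2.
#' @param params An `energy_params` object.
#' @return Energy in dekacal.
#' @export
multiloop_energy <- function(branch_types, unpaired, mismatches = NULL,
                             dangles = 2, params) {
  k <- length(branch_types)
  if (k < 3) stop("multibranch loops have at least 3 branches")
  if (unpaired < 0) stop("negative unpaired count")
  e <- params$ml_closing + params$ml_base * unpaired
  for (b in seq_len(k)) {
    si1 <- if (is.null(mismatches)) -1L else mismatches[b, 1L]
    sj1 <- if (is.null(mismatches)) -1L else mismatches[b, 2L]
    e <- e + ml_stem_energy(branch_types[[b]], si1, sj1, dangles, params)
  }
  e
}
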