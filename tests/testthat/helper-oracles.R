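# Shared fixtures and brute-force oracles.  Oracle energies always go
# through eval_energy (the loop-sum evaluator), never through the dynamic
# programs under test.

TOY <- toy_energy_params(terminal_au = 0)        # hand-auditable set
TOY_AU <- toy_energy_params()                    # with terminal-AU = 50
TOY_DANGLE <- toy_energy_params(terminal_au = 0, dangle5 = -10,
                                dangle3 = -20, mismatch = -30)
TURNER <- default_energy_params()

RT_DK <- loopfold:::RT_DEKACAL
INF_E <- loopfold:::INF_ENERGY

# all structures + loop-sum energies (dekacal)
brute <- function(seq, params, dangles = 2, circular = FALSE, noLP = FALSE,
                  constraints = NULL) {
  ctx <- loopfold:::fold_ctx(seq, params, dangles)
  tabs <- enumerate_structures(seq, noLP = noLP, constraints = constraints)
  es <- vapply(tabs, function(pt) loopfold:::eval_energy_dk(ctx, pt, circular), 0)
  list(tables = tabs, energies = es)
}

brute_min <- function(...) {
  b <- brute(...)
  list(energy = min(b$energies),
       table = b$tables[[which.min(b$energies)]])
}

# Boltzmann distribution over all structures
brute_boltzmann <- function(seq, params, dangles = 2) {
  b <- brute(seq, params, dangles)
  w <- exp(-b$energies / RT_DK)
  list(tables = b$tables, Z = sum(w), p = w / sum(w),
       structures = vapply(b$tables, write_dot_bracket, ""))
}

# reference bpp matrix from enumeration
brute_bpp <- function(seq, params, dangles = 2) {
  bz <- brute_boltzmann(seq, params, dangles)
  n <- nchar(as.character(seq))
  m <- matrix(0, n, n)
  for (k in seq_along(bz$tables)) {
    pt <- bz$tables[[k]]
    for (i in seq_len(n)) if (pt[[i]] > i) m[i, pt[[i]]] <- m[i, pt[[i]]] + bz$p[[k]]
  }
  m
}

# random satisfiable constraint string derived from an actual structure
random_constraint <- function(seq, density = 0.4) {
  tabs <- enumerate_structures(seq)
  target <- tabs[[sample(length(tabs), 1L)]]
  n <- length(target)
  cvec <- rep(".", n)
  for (i in seq_len(n)) {
    if (runif(1) < density) {
      if (target[[i]] == 0L) cvec[[i]] <- "x"
      else if (target[[i]] > i && runif(1) < 0.5) {
        cvec[[i]] <- "("; cvec[[target[[i]]]] <- ")"
      } else if (cvec[[i]] == ".") cvec[[i]] <- "|"
    }
  }
  paste(cvec, collapse = "")
}

# monotone intermolecular pairings of two coded sequences (duplex oracle)
duplex_oracle_min <- function(s1, s2, params, dangles = 2) {
  S1 <- loopfold:::seq_codes(loopfold:::as_rna_sequence(s1))
  S2 <- loopfold:::seq_codes(loopfold:::as_rna_sequence(s2))
  n1 <- length(S1); n2 <- length(S2)
  rtype <- loopfold:::.RTYPE
  best <- Inf
  eval_chain <- function(pr) {
    e <- params$duplex_init
    k <- nrow(pr)
    e <- e + loopfold:::ext_stem_energy(
      pair_type_of(S1[[pr[1, 1]]], S2[[pr[1, 2]]]),
      if (pr[1, 1] > 1) S1[[pr[1, 1] - 1]] else -1L,
      if (pr[1, 2] < n2) S2[[pr[1, 2] + 1]] else -1L, dangles, params)
    e <- e + loopfold:::ext_stem_energy(
      rtype[[pair_type_of(S1[[pr[k, 1]]], S2[[pr[k, 2]]])]],
      if (pr[k, 2] > 1) S2[[pr[k, 2] - 1]] else -1L,
      if (pr[k, 1] < n1) S1[[pr[k, 1] + 1]] else -1L, dangles, params)
    if (k > 1) for (r in 2:k) {
      a <- pr[r - 1, ]; b <- pr[r, ]
      e <- e + interior_loop_energy(
        b[[1]] - a[[1]] - 1L, a[[2]] - b[[2]] - 1L,
        pair_type_of(S1[[a[[1]]]], S2[[a[[2]]]]),
        pair_type_of(S2[[b[[2]]]], S1[[b[[1]]]]),
        S1[[a[[1]] + 1]], S2[[a[[2]] - 1]],
        S1[[b[[1]] - 1]], S2[[b[[2]] + 1]], params)
    }
    e
  }
  gen <- function(pairs, imin, jmax) {
    if (imin <= n1 && jmax >= 1L) for (i in imin:n1) for (j in jmax:1L) {
      if (pair_type_of(S1[[i]], S2[[j]]) > 0L) {
        chain <- do.call(rbind, c(pairs, list(c(i, j))))
        e <- eval_chain(chain)
        if (e < best) best <<- e
        gen(c(pairs, list(c(i, j))), i + 1L, j - 1L)
      }
    }
  }
  gen(list(), 1L, n2)
  best
}

pair_type_of <- function(a, b) loopfold:::pair_type(a, b)

# run a CLI tool capturing stdout lines
cli_run <- function(tool, args = character(), input = character()) {
  out <- character()
  con <- textConnection("out", "w", local = TRUE)
  status <- suppressMessages(loopfold_cli(tool, args, input = input, output = con))
  close(con)
  list(status = status, out = out)
}
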