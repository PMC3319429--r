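test_that("parameter files round-trip bitwise through load -> dump -> load", {
  for (p in list(TOY, TOY_DANGLE, TURNER)) {
    p2 <- read_energy_params(write_energy_params(p))
    for (fld in c("stack", "hairpin", "bulge", "interior", "int11", "int21",
                  "int22", "mismatch_hairpin", "mismatch_interior",
                  "mismatch_interior_1n", "mismatch_interior_23",
                  "mismatch_multi", "mismatch_exterior", "dangle5", "dangle3"))
      expect_equal(p2[[fld]], p[[fld]], info = fld)
    expect_equal(p2$ml_closing, p$ml_closing)
    expect_equal(p2$ninio, p$ninio)
    expect_equal(p2$lxc, p$lxc)
    expect_equal(p2$tetraloops, p$tetraloops)
  }
})

test_that("parameter parser flags unknown sections and wrong entry counts", {
  expect_error(read_energy_params(c("# not_a_section", "1 2 3")),
               "unknown parameter section 'not_a_section'")
  expect_error(read_energy_params(c("# stack", "1 2 3")),
               "expected 49 entries, got 3")
  expect_error(read_energy_params(c("# NINIO", "60 abc 300")),
               "non-numeric entry")
})

test_that("INF entries are absorbing: a loop using them can never win", {
  p <- toy_energy_params(terminal_au = 0, hairpin = -100)  # stabilizing loops
  p$stack[, ] <- INF_E          # ... but all stacking forbidden
  set.seed(42)
  s <- random_rna(11, gc = 0.8)
  r <- fold(s, p)
  # the fold avoids every INF loop yet still attains the exhaustive optimum
  ref <- brute_min(s, p)
  expect_equal(r$energy * 100, ref$energy, tolerance = 1e-6)
  expect_lt(r$energy * 100, INF_E / 2)
  pt <- r$pair_table
  stacked <- vapply(which(pt > seq_along(pt)), function(i)
    i > 1 && pt[i - 1] == pt[i] + 1, TRUE)
  expect_false(any(stacked))
})

test_that("hairpin energies follow the length table, mismatch and lxc extrapolation", {
  # flat table: size-3 loop closed by GC is the bare table value
  expect_equal(hairpin_energy(3, 2, 1, 1, TOY), 540)
  # terminal-AU applies to size-3 loops closed by AU/GU type
  expect_equal(hairpin_energy(3, 5, 1, 1, TOY_AU), 540 + 50)
  expect_equal(hairpin_energy(4, 2, 1, 1, TOY), 540)  # no mismatch in toy
  # log extrapolation beyond 30, rounded half away from zero
  e32 <- hairpin_energy(32, 2, 1, 1, TOY)
  expect_equal(e32 - TOY$hairpin[31], floor(abs(107.856 * log(32 / 30)) + 0.5))
  expect_error(hairpin_energy(2, 1, 1, 1, TOY), "at least 3")
})

test_that("special tabulated hairpins replace the generic energy", {
  # GGGGAC tetraloop: CG closing pair written as C...G in the table
  p <- TOY
  p$tetraloops <- data.frame(seq = "CAACGG", energy = -300)
  e <- loopfold:::E_hairpin_ij(loopfold:::fold_ctx("ACAACGGA", p), 2L, 7L)
  expect_equal(e, -300)
})

test_that("stacking is a symmetric table lookup with least-stabilizing fallback", {
  expect_equal(stack_energy(1, 1, TOY), -330)
  # reading the stacked pairs from the other strand swaps the two lookup
  # indices, so the table must be symmetric
  for (a in 1:6) for (b in 1:6)
    expect_equal(stack_energy(a, b, TURNER), stack_energy(b, a, TURNER))
  # nonstandard entries equal the maximum over canonical completions
  expect_equal(TURNER$stack[7, 7], max(TURNER$stack[1:6, 1:6]))
  for (b in 1:6) expect_gte(TURNER$stack[7, b] + 1e-9, max(TURNER$stack[1:6, b]))
})

test_that("interior loops dispatch to the right table with the Ninio asymmetry rule", {
  # 1x1 is a pure int11 lookup, no asymmetry term
  expect_equal(interior_loop_energy(1, 1, 1, 1, 1, 1, 1, 1, params = TOY), 40)
  # 2x2 -> int22, 2x1 -> int21
  expect_equal(interior_loop_energy(2, 2, 1, 1, 1, 1, 1, 1, params = TOY), 120)
  expect_equal(interior_loop_energy(1, 2, 1, 1, 1, 1, 1, 1, params = TOY), 110)
  # 3x1 loop: toy ninio 60, cap 300 -> asymmetry min(300, 2*60) = 120
  e <- interior_loop_energy(3, 1, 1, 1, 1, 1, 1, 1, params = TOY)
  expect_equal(e, TOY$interior[5] + min(300, 2 * 60))
  # wide asymmetry hits the cap
  e2 <- interior_loop_energy(20, 1, 1, 1, 1, 1, 1, 1, params = TOY)
  expect_equal(e2, TOY$interior[22] + 300)
  # size-1 bulge keeps the stack term; bigger bulges get terminal-AU ends
  expect_equal(interior_loop_energy(1, 0, 1, 1, params = TOY),
               TOY$bulge[2] + TOY$stack[1, 1])
  expect_equal(interior_loop_energy(0, 3, 5, 6, params = TOY_AU),
               TOY_AU$bulge[4] + 2 * 50)
  expect_error(interior_loop_energy(-1, 2, 1, 1, params = TOY), "negative")
})

test_that("multiloop energy is affine with per-branch dangles and AU penalties", {
  # toy a=340, b=40, c=0: 3 branches, 6 unpaired, no dangles
  expect_equal(multiloop_energy(c(1, 1, 1), 6, dangles = 0, params = TOY),
               340 + 3 * 40)
  # c > 0 makes energy strictly increasing in the unpaired count
  p <- toy_energy_params(terminal_au = 0, ml_base = 10)
  e1 <- multiloop_energy(c(1, 1, 1), 3, dangles = 0, params = p)
  e2 <- multiloop_energy(c(1, 1, 1), 4, dangles = 0, params = p)
  expect_gt(e2, e1)
  # AU-type branches each pay the terminal penalty
  expect_equal(multiloop_energy(c(5, 6, 3), 4, dangles = 0, params = TOY_AU),
               340 + 3 * 40 + 3 * 50)
  expect_error(multiloop_energy(c(1, 1), 0, params = TOY), "at least 3")
})

test_that("d2 and d0 differ on a multiloop by exactly the branch mismatch terms", {
  s <- "GGAAGGGAAACCCAAGGGAAACCCAACC"
  st <- "((..(((...)))..(((...)))..))"
  e0 <- eval_energy(s, st, TOY_DANGLE, dangles = 0)
  e2 <- eval_energy(s, st, TOY_DANGLE, dangles = 2)
  # 3 multiloop stems (incl. closing), each with flat mismatch -30 dekacal
  expect_equal(round((e2 - e0) * 100), -30 * 3)
})

test_that("a modified hairpin table entry shifts fold energies by exactly the delta", {
  p <- TOY
  p$hairpin[4] <- TOY$hairpin[4] + 100   # size-3 loops cost 1 kcal more
  s <- "GGGAAACCC"
  expect_equal(fold(s, p)$energy, fold(s, TOY)$energy + 1)
})

test_that("the bundled default set loads completely and carries Turner-style values", {
  p <- TURNER
  expect_equal(dim(p$stack), c(7, 7))
  expect_equal(length(p$hairpin), 31)
  expect_equal(dim(p$int22), c(7, 7, 5, 5, 5, 5))
  expect_true(nrow(p$tetraloops) > 0)
  expect_true(all(is.finite(p$stack[1:6, 1:6])))
  expect_true(all(p$hairpin[1:3] >= INF_E))     # loops of size < 3 impossible
  expect_equal(p$lxc, 107.856)
})
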