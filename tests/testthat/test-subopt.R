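test_that("band enumeration is complete and sound against brute force", {
  set.seed(701)
  for (rep in 1:15) {
    n <- sample(8:14, 1)
    s <- random_rna(n, gc = runif(1, 0.4, 0.8))
    pp <- if (rep %% 2) TOY else TURNER
    d <- if (rep %% 3 == 0) 0 else 2
    nolp <- rep %% 4 == 0
    b <- brute(s, pp, dangles = d, noLP = nolp)
    mfe <- min(b$energies)
    for (band in c(0, 2, 5)) {
      keep <- b$energies <= mfe + band * 100 + 1e-9
      ref <- sort(paste(vapply(b$tables[keep], write_dot_bracket, ""),
                        sprintf("%.2f", b$energies[keep] / 100)))
      so <- subopt_band(s, pp, band = band, dangles = d, noLP = nolp)
      got <- sort(paste(so$structure, sprintf("%.2f", so$energy)))
      expect_identical(got, ref,
                       info = sprintf("%s d%d noLP %d band %g", unclass(s), d, nolp, band))
    }
  }
})

test_that("band zero returns exactly the MFE tie set and counts grow with the band", {
  expect_equal(subopt_band("AAAA", TOY, band = 5)$structure, "....")
  set.seed(702)
  for (rep in 1:5) {
    s <- random_rna(12, gc = 0.7)
    so0 <- subopt_band(s, TURNER, band = 0)
    r <- fold(s, TURNER)
    expect_true(r$structure %in% so0$structure)
    expect_true(all(abs(so0$energy - r$energy) < 1e-9))
    sizes <- vapply(c(0, 1, 3, 6), function(b)
      nrow(subopt_band(s, TURNER, band = b)), 0L)
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("every reported energy equals the loop-sum of its structure", {
  set.seed(703)
  s <- random_rna(14, gc = 0.6)
  so <- subopt_band(s, TURNER, band = 4)
  for (r in seq_len(nrow(so)))
    expect_equal(eval_energy(s, so$structure[r], TURNER), so$energy[r],
                 tolerance = 1e-9)
  # no duplicates, sorted by energy
  expect_false(any(duplicated(so$structure)))
  expect_true(!is.unsorted(so$energy))
})

test_that("Boltzmann mass inside the band approaches Z from below as the band grows", {
  set.seed(704)
  s <- random_rna(11, gc = 0.7)
  pf <- partition_function(s, TOY)
  Z <- exp(pf$lnZ)
  last <- 0
  for (band in c(0, 2, 5, 20)) {
    so <- subopt_band(s, TOY, band = band)
    mass <- sum(exp(-so$energy * 100 / RT_DK))
    expect_lte(mass, Z * (1 + 1e-9))
    expect_gte(mass, last - 1e-12)
    last <- mass
  }
  expect_equal(last, Z, tolerance = 1e-9)  # huge band covers everything
})

test_that("the enumeration cap raises a truncation error", {
  set.seed(705)
  s <- random_rna(14, gc = 0.9)
  expect_error(subopt_band(s, TOY, band = 30, max_structures = 5L),
               "exceeds the cap of 5")
})

test_that("the band set matches the reference implementation", {
  set.seed(706)
  for (rep in 1:3) {
    s <- unclass(random_rna(sample(20:35, 1), gc = 0.6))
    out <- suppressWarnings(system2("RNAsubopt", c("-e", "3", "-d2"),
                                    stdout = TRUE, stderr = FALSE, input = s))
    out <- out[-1]
    ref <- sort(vapply(strsplit(out, "\\s+"), function(x)
      paste(x[1], sprintf("%.2f", as.numeric(x[2]))), ""))
    so <- subopt_band(s, TURNER, band = 3)
    got <- sort(paste(so$structure, sprintf("%.2f", so$energy)))
    expect_identical(got, ref, info = s)
  }
})

test_that("Zuker suboptimals realize every per-pair minimum", {
  set.seed(707)
  for (rep in 1:8) {
    n <- sample(8:12, 1)
    s <- random_rna(n, gc = 0.7)
    pp <- if (rep %% 2) TOY else TURNER
    b <- brute(s, pp)
    z <- subopt_zuker(s, pp)
    pe <- attr(z, "pair_energies")
    for (i in seq_len(n - 4)) for (j in (i + 4):n) {
      containing <- which(vapply(b$tables, function(pt) pt[i] == j, TRUE))
      ref <- if (length(containing)) min(b$energies[containing]) / 100 else NA_real_
      expect_equal(pe[i, j], ref, tolerance = 1e-9,
                   info = sprintf("%s pair (%d,%d)", unclass(s), i, j))
    }
    # per-pair minima are bounded below by the MFE, with equality on MFE pairs
    mfe <- fold(s, pp)
    expect_true(all(pe >= mfe$energy - 1e-9, na.rm = TRUE))
    for (i in which(mfe$pair_table > seq_len(n)))
      expect_equal(pe[i, mfe$pair_table[i]], mfe$energy, tolerance = 1e-9)
    # the reported set contains the best structure for every listed energy
    for (r in seq_len(nrow(z)))
      expect_equal(eval_energy(s, z$structure[r], pp), z$energy[r],
                   tolerance = 1e-9)
  }
})
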