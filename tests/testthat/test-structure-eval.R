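test_that("loop decomposition partitions a structure into the expected loops", {
  loops <- decompose_structure("GGGAAACCC", "(((...)))")
  kinds <- vapply(loops, `[[`, "", "kind")
  expect_equal(sort(kinds), sort(c("stack", "stack", "hairpin", "exterior")))
  # loop count = number of pairs + 1 (exterior included) for linear chains
  expect_length(loops, 3 + 1)

  loops <- decompose_structure("AAAA", "....")
  expect_equal(vapply(loops, `[[`, "", "kind"), "exterior")

  # circular: no exterior loop; the outermost region is itself a loop
  loops <- decompose_structure("GGAAACCAGGAAACCA", "((...))((...))..",
                               circular = TRUE)
  kinds <- vapply(loops, `[[`, "", "kind")
  expect_equal(sum(kinds == "hairpin"), 2)
  expect_equal(sum(kinds == "stack"), 2)
  expect_equal(sum(kinds == "closing-interior"), 1)
  expect_false("exterior" %in% kinds)

  expect_error(decompose_structure("AAAA", "....."), "different lengths")
})

test_that("open chains have zero energy and the toy helix sums by hand", {
  expect_equal(eval_energy("ACGUACGU", "........", TOY), 0)
  # two CG-type stacks at -330 plus a size-3 hairpin at +540
  expect_equal(eval_energy("GGGAAACCC", "(((...)))", TOY),
               (-330 - 330 + 540) / 100)
  expect_error(eval_energy("GGGGCCCC", "((()))..", TOY), "span violation")
})

test_that("energies are additive over loops", {
  # changing a distant hairpin's closing context changes only that loop
  s1 <- "GGGAAACCCAAAGGGAAACCC"
  s2 <- "GGGAAACCCAAAGGGAGACCC"   # mutate inside the second hairpin loop
  st <- "(((...)))...(((...)))"
  d1 <- eval_energy(s1, st, TURNER) - eval_energy(s2, st, TURNER)
  h1 <- loopfold:::E_hairpin_ij(loopfold:::fold_ctx(s1, TURNER), 13L, 21L)
  h2 <- loopfold:::E_hairpin_ij(loopfold:::fold_ctx(s2, TURNER), 13L, 21L)
  expect_equal(d1 * 100, h1 - h2)
})

test_that("evaluation agrees exactly with the reference implementation", {
  # independent cross-check against the installed ViennaRNA RNAeval
  seqs <- c("GGGAAACCC", "GCGAAAGC",
            "GGCGCAAGGCUAGCAAAGCUAGCCAAGCGCAAACC",
            "UAGGGAAACCCUAGGGAAACCCUA")
  cases <- list()
  for (s in seqs) {
    cases[[length(cases) + 1]] <- c(s, fold(s, TURNER)$structure)
    so <- subopt_band(s, TURNER, band = 3)
    cases[[length(cases) + 1]] <- c(s, so$structure[nrow(so)])
  }
  for (cs in cases) for (d in c(0, 2)) {
    out <- suppressWarnings(system2("RNAeval", paste0("-d", d),
                                    stdout = TRUE, stderr = FALSE,
                                    input = paste0(cs[1], "\n", cs[2], "\n")))
    ref <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1", out[length(out)]))
    expect_equal(eval_energy(cs[1], cs[2], TURNER, dangles = d), ref,
                 tolerance = 1e-9,
                 info = paste(cs[1], cs[2], "d", d))
  }
})

test_that("circular evaluation treats the outer face as a real loop", {
  # structure whose outer face is a hairpin-like loop of 3 bases
  e_lin <- eval_energy("GGGAAACCCAAA", "(((...)))...", TOY)
  e_circ <- eval_energy("GGGAAACCCAAA", "(((...)))...", TOY, circular = TRUE)
  # circular closing adds the outer hairpin penalty (540 in the toy set)
  expect_equal(round((e_circ - e_lin) * 100), 540)
  # an outer face with fewer than 3 unpaired bases is forbidden
  expect_equal(eval_energy("GGGAAACCC", "(((...)))", TOY, circular = TRUE),
               INF_E / 100)
  # open chain on a circle has zero energy
  expect_equal(eval_energy("AAAAAA", "......", TOY, circular = TRUE), 0)
})

test_that("eval of the folded structure reproduces the reported MFE", {
  set.seed(202)
  for (rep in 1:10) {
    s <- random_rna(sample(10:25, 1), gc = 0.6)
    for (d in c(0, 2)) {
      r <- fold(s, TURNER, dangles = d)
      expect_equal(eval_energy(s, r$structure, TURNER, dangles = d),
                   r$energy, tolerance = 1e-9)
    }
  }
})
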