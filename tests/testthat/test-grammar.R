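test_that("context frequencies pool both directions within the element", {
  # one helix, one K center at position 10; E at +4, A at -4
  seq <- rep("G", 20)
  seq[10] <- "K"; seq[14] <- "E"; seq[6] <- "A"
  m <- build_ideal_helix(20, sequence = paste(seq, collapse = ""))
  ass <- list(X = stats::setNames(rep("H", 20), 1:20))
  cf <- context_frequencies(data.frame(accession = "X", pos = 10),
                            list(X = m), ass, category = "helix", D = 10)
  expect_equal(unname(cf$f["E", 4]), 0.5)
  expect_equal(unname(cf$f["A", 4]), 0.5)
  expect_equal(unname(cf$f["G", 4]), 0)
  # frequencies sum to 1 at every occupied offset
  occ <- cf$occupied > 0
  expect_equal(unname(colSums(cf$f[, occ, drop = FALSE])),
               rep(1, sum(occ)), tolerance = 1e-12)
})

test_that("offsets beyond the element boundary leave the denominator", {
  # helix runs 1..12; center at 10: +3 exists (12 is still helix at +2);
  # +d beyond 12 must not count
  seq <- rep("A", 20); seq[10] <- "K"
  m <- build_ideal_helix(20, sequence = paste(seq, collapse = ""))
  lab <- stats::setNames(c(rep("H", 12), rep("C", 8)), 1:20)
  cf <- context_frequencies(data.frame(accession = "X", pos = 10),
                            list(X = m), list(X = lab), category = "helix",
                            D = 10)
  expect_equal(unname(cf$occupied["2"]), 2)   # 8 and 12
  expect_equal(unname(cf$occupied["3"]), 1)   # 13 is coil: only -3 counts
  expect_equal(unname(cf$occupied["10"]), 0)  # both sides out of the element
})

test_that("centers that are not lysine in the stated category are dropped", {
  seq <- rep("A", 20); seq[10] <- "K"
  m <- build_ideal_helix(20, sequence = paste(seq, collapse = ""))
  lab <- stats::setNames(rep("H", 20), 1:20)
  centers <- data.frame(accession = "X", pos = c(10, 5, 10))
  cf <- context_frequencies(centers, list(X = m), list(X = lab),
                            category = "helix")
  expect_equal(cf$n_centers, 2L)   # position 5 is A, dropped
  expect_equal(cf$dropped, 1L)
  expect_error(context_frequencies(centers[0, ], list(X = m), list(X = lab)),
               "zero centers")
})

test_that("percent difference is zero on identical inputs and +50 on 1.5x", {
  f <- matrix(0.10, 20, 10, dimnames = list(xlspan:::.aa20, 1:10))
  g <- f
  pd <- percent_difference(f, g)
  expect_true(all(pd$value == 0))
  f2 <- f; f2["E", 4] <- 0.15
  pd2 <- percent_difference(f2, g)
  expect_equal(unname(pd2$value["E", 4]), 50)
  expect_identical(pd2$ranking[1], "E")
  # zero background with nonzero foreground is flagged undefined
  g3 <- g; g3["W", 2] <- 0
  f3 <- f; f3["W", 2] <- 0.05
  pd3 <- percent_difference(f3, g3)
  expect_true(is.na(pd3$value["W", 2]))
  # absolute mode reports percentage points
  pda <- percent_difference(f2, g, mode = "absolute")
  expect_equal(unname(pda$value["E", 4]), 5)
})

test_that("helix-vs-coil grammar flips sign under the symmetric variant", {
  f_h <- matrix(0.05, 20, 10, dimnames = list(xlspan:::.aa20, 1:10))
  f_c <- f_h
  f_h["E", 3] <- 0.10; f_c["L", 3] <- 0.10
  gm <- helix_vs_coil(f_h, f_c)
  expect_gt(gm$value["E", 3], 0)    # helix-enriched
  expect_lt(gm$value["L", 3], 0)    # coil-enriched
  sym_ab <- helix_vs_coil(f_h, f_c, symmetric = TRUE)
  sym_ba <- helix_vs_coil(f_c, f_h, symmetric = TRUE)
  expect_equal(sym_ab$value, -sym_ba$value)
  zero <- helix_vs_coil(f_h, f_h)
  expect_true(all(zero$value == 0))
})

test_that("a planted helix enrichment is recovered from simulated contexts", {
  spec <- synthetic_spec(seed = 31, n_proteins = 30, n_links = 0,
                         enrich = list(aa = "E", offset = 4, factor = 1.5,
                                       category = "helix"))
  pro <- simulate_proteome(spec)
  ass <- lapply(pro$models, assign_secondary_structure)
  centers <- do.call(rbind, lapply(pro$models, function(m) {
    k <- m$residues$seq_index[model_sequence(m) == "K"]
    if (length(k)) data.frame(accession = m$accession, pos = k) else NULL
  }))
  fg <- context_frequencies(centers, pro$models, ass, category = "helix",
                            D = 10)
  g <- matrix(rep(spec$composition[xlspan:::.aa20], 10), 20, 10,
              dimnames = list(xlspan:::.aa20, 1:10))
  pd <- percent_difference(fg$f, g)
  expect_gt(pd$value["E", 4], 10)   # clearly positive at the planted cell
  # the planted offset is the strongest E cell
  expect_equal(unname(which.max(pd$value["E", ])), 4L)
})
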