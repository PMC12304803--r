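test_that("element extraction yields maximal runs in author numbering", {
  lab <- stats::setNames(strsplit("HHHHCCEE", "")[[1]], 1:8)
  runs <- extract_elements(lab, "P1")
  expect_equal(runs$category, c("helix", "coil", "strand"))
  expect_equal(runs$start, c(1L, 5L, 7L))
  expect_equal(runs$end, c(4L, 6L, 8L))
  one <- extract_elements(stats::setNames(rep("C", 5), 1:5))
  expect_equal(nrow(one), 1L)
  expect_equal(one$end - one$start + 1L, 5L)
  alt <- extract_elements(stats::setNames(strsplit("HCHC", "")[[1]], 1:4))
  expect_equal(nrow(alt), 4L)
  expect_true(all(alt$start == alt$end))
})

test_that("identical-residue pairs attribute to elements or mixed", {
  m <- build_ideal_helix(6, sequence = "KAAKAA")
  models <- list(SYNHELIX1 = m)
  # force labels by hand: all-helix vs helix-coil-coil-helix
  ass_h <- list(SYNHELIX1 = stats::setNames(rep("H", 6), 1:6))
  prof <- pair_spacing_profile(models, ass_h, aa = "K")
  expect_equal(unname(prof$counts["helix", 3]), 1)
  expect_equal(sum(prof$counts), 1)
  ass_m <- list(SYNHELIX1 = stats::setNames(strsplit("HCCHHH", "")[[1]], 1:6))
  prof_m <- pair_spacing_profile(models, ass_m, aa = "K")
  expect_equal(unname(prof_m$counts["mixed", 3]), 1)
  # absent amino acid: flagged all-zero profile
  prof_w <- pair_spacing_profile(models, ass_h, aa = "W")
  expect_true(prof_w$absent)
  expect_equal(sum(prof_w$counts), 0)
})

test_that("category pair counts partition the whole-sequence pair count", {
  pro <- fixture("proteome")
  ass <- lapply(pro$models, assign_secondary_structure)
  within <- pair_spacing_profile(pro$models, ass, aa = "K")
  whole <- pair_spacing_profile(pro$models, mode = "whole_sequence", aa = "K")
  expect_equal(colSums(within$counts), whole$counts["all", ])
  # input order of proteins does not matter
  rev_prof <- pair_spacing_profile(rev(pro$models), ass, aa = "K")
  expect_equal(rev_prof$counts, within$counts)
  # sum normalization gives per-category frequencies summing to 1
  nz <- rowSums(within$counts) > 0
  expect_equal(unname(rowSums(within$freq)[nz]),
               rep(1, sum(nz)), tolerance = 1e-9)
})

test_that("a planted 3-4 spacing preference shows up in the element profile", {
  # helices whose E residues recur every 3-4 positions
  seqs <- c("AEAAEAAAEAAEAAAEAAAE", "EAAAEAAEAAAEAAEAAAEA")
  models <- list()
  ass <- list()
  for (i in seq_along(seqs)) {
    acc <- paste0("SYNHEL", i)
    models[[acc]] <- build_ideal_helix(20, sequence = seqs[i],
                                       accession = acc)
    ass[[acc]] <- stats::setNames(rep("H", 20), 1:20)
  }
  prof <- pair_spacing_profile(models, ass, aa = "E")
  f <- prof$freq["helix", ]
  expect_gt(f["3"] + f["4"], f["1"] + f["2"])
  expect_gt(f["3"] + f["4"], f["5"] + f["6"])
})

test_that("lysine availability conserves counts across categories", {
  pro <- fixture("proteome")
  ass <- lapply(pro$models, assign_secondary_structure)
  av <- lysine_availability(pro$models, ass)
  totK <- sum(vapply(pro$models,
                     function(m) sum(model_sequence(m) == "K"), numeric(1)))
  expect_equal(sum(av$n_lysine), totK)
  expect_equal(sum(av$n_residues),
               sum(vapply(pro$models, n_residues, numeric(1))))
  expect_true(all(av$density >= 0 & av$density <= 1))
  # direct density check on a hand-built case
  m <- build_ideal_helix(20, sequence = paste(c("K", rep("A", 9), "K",
                                                rep("A", 9)), collapse = ""))
  av2 <- lysine_availability(list(X = m),
                             list(X = stats::setNames(rep("H", 20), 1:20)))
  expect_equal(av2$density[av2$category == "helix"], 0.1)
})

test_that("bundle FASTA sequences match their models", {
  spec <- synthetic_spec(seed = 13, n_proteins = 3, n_links = 10)
  d <- withr::local_tempdir()
  paths <- write_fixture_bundle(spec, d)
  models <- lapply(list.files(d, pattern = "\\.pdb$", full.names = TRUE),
                   read_structure)
  names(models) <- vapply(models, function(m) m$accession, character(1))
  chk <- check_sequences(models, paths$fasta)
  expect_true(all(chk$in_fasta))
  expect_true(all(chk$matches))
  # a mismatching model is reported, not an error
  models[[1]]$residues$aa[5] <- if (models[[1]]$residues$aa[5] == "A") "G" else "A"
  chk2 <- check_sequences(models, paths$fasta)
  expect_false(chk2$matches[1])
})
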