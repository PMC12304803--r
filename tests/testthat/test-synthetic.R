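test_that("ideal helix geometry: CA steps, rise, and helical periodicity", {
  h <- build_ideal_helix(20)
  d <- vapply(1:19, function(i) sqrt(sum((h$CA[i + 1, ] - h$CA[i, ])^2)),
              numeric(1))
  expect_equal(d, rep(3.8, 19), tolerance = 0.01)   # trans peptide step
  rise <- sqrt(sum((h$CA[19, ] - h$CA[1, ])^2)) / 18
  expect_equal(rise, 1.5, tolerance = 0.05)          # ~1.5 A per residue
  expect_error(build_ideal_helix(5), "n >= 6")
})

test_that("hairpin side chains alternate faces; turn is not strand", {
  hp <- build_antiparallel_hairpin(8)
  tm <- xlspan:::build_backbone(8, -139, 135, 180)
  p <- xlspan:::unit(xlspan:::pracma_cross(tm$CA[2, ] - tm$CA[1, ],
                                           tm$C[1, ] - tm$N[1, ]))
  proj <- (hp$reactive[1:8, ] - hp$CA[1:8, ]) %*% p
  expect_true(all(sign(proj[-1]) != sign(proj[-8])))   # strict alternation
  lab <- assign_secondary_structure(hp)
  expect_true(all(lab[9:11] != "E"))                   # turn residues
  expect_error(build_antiparallel_hairpin(3), ">= 4")
})

test_that("fixture bundles are byte-identical under one seed", {
  spec <- synthetic_spec(seed = 42, n_proteins = 3, n_links = 25)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_fixture_bundle(spec, d1)
  p2 <- write_fixture_bundle(spec, d2)
  sums <- function(d) tools::md5sum(sort(list.files(d, full.names = TRUE)))
  expect_identical(unname(sums(d1)), unname(sums(d2)))
  # a different seed draws different cross-links
  d3 <- withr::local_tempdir()
  write_fixture_bundle(synthetic_spec(seed = 43, n_proteins = 3,
                                      n_links = 25), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "crosslinks.csv"))),
                         unname(tools::md5sum(file.path(d3, "crosslinks.csv")))))
})

test_that("bundles parse through the readers without skips", {
  spec <- synthetic_spec(seed = 8, n_proteins = 3, n_links = 20)
  d <- withr::local_tempdir()
  paths <- write_fixture_bundle(spec, d)
  csv <- read_xl_table(paths$csv)
  mz <- read_mzid(paths$mzid)
  expect_equal(attr(csv, "skipped"), 0L)
  expect_equal(attr(mz, "skipped"), 0L)
  expect_equal(nrow(csv), 20L)
  expect_equal(csv$pos_a, mz$pos_a)
  expect_equal(csv$pos_b, mz$pos_b)
  m <- read_structure(file.path(d, "AF-SYN0001-F1-model_syn.pdb"))
  expect_identical(m$accession, "SYN0001")
  expect_equal(attr(m, "skipped_nonstandard"), 0L)
})

test_that("zero false positives means every link carries its true category", {
  spec <- synthetic_spec(seed = 3, n_proteins = 4, n_links = 40,
                         fp_fraction = 0)
  links <- simulate_crosslinks(spec)
  expect_false(any(links$is_fp))
  expect_true(all(links$true_category %in% c("helix", "coil", "mixed")))
  expect_true(all(abs(links$pos_b - links$pos_a) >= 1))
  expect_true(all(abs(links$pos_b - links$pos_a) <= 19))
  expect_true(all(links$linked_aa_a == "K" & links$linked_aa_b == "K"))
})

test_that("all-false-positive spacing histograms match the background law", {
  # Expected probabilities enumerated from the sampler's definition: pick a
  # protein uniformly, a spacing from the background law, a start uniform
  # over 1..len-s, accept only lysine pairs.
  spec <- synthetic_spec(seed = 17, n_proteins = 6, n_links = 5000,
                         fp_fraction = 1)
  pro <- simulate_proteome(spec)
  law <- spacing_law("background", max_spacing = spec$max_spacing)
  expected <- vapply(seq_len(spec$max_spacing), function(s) {
    law[s] * mean(vapply(pro$models, function(m) {
      seqaa <- model_sequence(m)
      len <- length(seqaa)
      if (len <= s) return(0)
      a <- seq_len(len - s)
      sum(seqaa[a] == "K" & seqaa[a + s] == "K") / (len - s)
    }, numeric(1)))
  }, numeric(1))
  expected <- expected / sum(expected)
  links <- simulate_crosslinks(spec, pro)
  obs <- tabulate(abs(links$pos_b - links$pos_a), spec$max_spacing)
  pval <- stats::chisq.test(obs, p = expected)$p.value
  expect_gt(pval, 0.01)
})

test_that("the helix sampling law leaves a recoverable 3.6-residue period", {
  law <- spacing_law("helix", lambda = 1e9)   # undamped oscillation
  draws <- xlspan:::with_seed(12, sample(1:19, 5000, TRUE, prob = law))
  per <- dominant_period(tabulate(draws, 19), detrend = "exp")$period
  expect_gte(per, 3.4)
  expect_lte(per, 3.8)
})

test_that("ground-truth labels agree with the assigner on >= 95% of links", {
  spec <- synthetic_spec(seed = 7, n_proteins = 4, n_links = 150)
  pro <- simulate_proteome(spec)
  links <- simulate_crosslinks(spec, pro)
  ass <- lapply(pro$models, assign_secondary_structure)
  ann <- annotate_xl(proximity_filter(links), pro$models, ass)
  key <- paste(links$accession_a, pmin(links$pos_a, links$pos_b),
               pmax(links$pos_a, links$pos_b))
  akey <- paste(ann$accession, ann$pos_a, ann$pos_b)
  obs <- ann$category[match(key, akey)]
  ok <- !is.na(obs) & obs == links$true_category
  expect_gte(mean(ok), 0.95)
})

test_that("an infeasible spec without lysines is rejected", {
  comp <- xlspan:::.default_composition()
  comp["K"] <- 0
  spec <- synthetic_spec(seed = 1, n_proteins = 2, n_links = 5,
                         composition = comp)
  expect_error(simulate_crosslinks(spec), "lysine")
})
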