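test_that("proximity filter keeps intra-protein pairs within the ceiling", {
  rec <- data.frame(
    dataset_id = "d", accession_a = rep("P1", 32), accession_b = rep("P1", 32),
    pos_a = 1L, pos_b = c(1L, 1L + 1:30, 100L), linked_aa_a = "K",
    linked_aa_b = "K", score = 1, linker_name = "DSS", ambiguous = FALSE,
    stringsAsFactors = FALSE)
  rec$accession_b[32] <- "P2"   # one inter-protein record
  out <- proximity_filter(rec)
  expect_true(all(out$spacing >= 1 & out$spacing <= 19))
  expect_equal(max(out$spacing), 19L)
  expect_equal(nrow(out), 19L)
  d <- attr(out, "dropped")
  expect_equal(unname(d["self_link"]), 1)
  expect_equal(unname(d["inter_protein"]), 1)
  expect_equal(unname(d["beyond_max_spacing"]), 11)
  # worked residue pairs: 45-52 spans 7, 204-207 spans 3, 5-7 spans 2
  orc <- data.frame(dataset_id = "d", accession_a = "O43929",
                    accession_b = "O43929", pos_a = c(45L, 204L, 5L),
                    pos_b = c(52L, 207L, 7L), linked_aa_a = "K",
                    linked_aa_b = "K", score = 1, linker_name = "DSS",
                    ambiguous = FALSE, stringsAsFactors = FALSE)
  expect_equal(proximity_filter(orc)$spacing, c(7L, 3L, 2L))
})

test_that("annotation extracts category and minimum confidence over the span", {
  m <- build_ideal_helix(20, plddt = c(rep(90, 9), 85, rep(92, 10)))
  rec <- data.frame(dataset_id = "d", accession_a = "SYNHELIX1",
                    accession_b = "SYNHELIX1", pos_a = c(8L, 15L),
                    pos_b = c(12L, 25L), linked_aa_a = c("K", "K"),
                    linked_aa_b = c("K", "K"), score = 1,
                    linker_name = "DSS", ambiguous = FALSE,
                    stringsAsFactors = FALSE)
  out <- proximity_filter(rec, max_spacing = 19)
  ann <- annotate_xl(out, list(SYNHELIX1 = m))
  expect_equal(nrow(ann), 1L)            # pos 25 is outside the model
  expect_identical(ann$category, "helix")
  expect_equal(ann$min_plddt, 85)        # the dip at residue 10 dominates
  expect_equal(unname(attr(ann, "dropped")["mapping_failure"]), 1)
  # span crossing the helix terminus is mixed
  ann2 <- annotate_xl(data.frame(dataset_id = "d", accession_a = "SYNHELIX1",
                                 accession_b = "SYNHELIX1", pos_a = 1L,
                                 pos_b = 4L, linked_aa_a = NA_character_,
                                 linked_aa_b = NA_character_, score = 1,
                                 linker_name = "DSS", ambiguous = FALSE,
                                 stringsAsFactors = FALSE),
                      list(SYNHELIX1 = m))
  expect_identical(ann2$category, "mixed")
  expect_false(ann2$continuous)
})

test_that("a stated residue that contradicts the model is a mapping failure", {
  m <- build_ideal_helix(10, sequence = "KKKKRKKKKK")
  rec <- data.frame(dataset_id = "d", accession_a = "SYNHELIX1",
                    accession_b = "SYNHELIX1", pos_a = 3L, pos_b = 5L,
                    linked_aa_a = "K", linked_aa_b = "K", score = 1,
                    linker_name = "DSS", ambiguous = FALSE,
                    stringsAsFactors = FALSE)
  ann <- annotate_xl(proximity_filter(rec), list(SYNHELIX1 = m))
  expect_equal(nrow(ann), 0L)
  expect_equal(unname(attr(ann, "dropped")["mapping_failure"]), 1)
})

test_that("confidence filter spares coils and mixed spans", {
  rec <- make_annotated(c("helix", "helix", "strand", "coil", "mixed"),
                        c(4L, 4L, 2L, 3L, 8L),
                        min_plddt = c(85, 75, 80, 30, 20))
  out <- plddt_filter(rec)
  expect_identical(out$category, c("helix", "coil", "mixed"))
  expect_equal(unname(attr(out, "dropped")["low_plddt"]), 2)
  # strand at exactly the cutoff is excluded (> 80 is required)
  expect_false("strand" %in% out$category)
})

test_that("spacing distribution normalizes each category to max 100", {
  rec <- make_annotated(rep("coil", 85), rep(c(1L, 2L, 3L), c(10, 50, 25)))
  d <- spacing_distribution(rec, seed = 4)
  expect_equal(unname(d$normalized["coil", 1:3]), c(20, 100, 50))
  expect_equal(sum(d$counts), 85)
  expect_true("helix" %in% d$zero_categories)
  expect_true(all(d$normalized["helix", ] == 0))
  # duplicating every record leaves normalized values unchanged
  d2 <- spacing_distribution(rbind(rec, rec), seed = 4)
  expect_equal(d2$normalized, d$normalized)
  # subset standard errors exist and are finite for occupied bins
  expect_true(all(is.finite(d$stderr["coil", 1:3])))
})

test_that("a single record gives a degenerate distribution", {
  d <- spacing_distribution(make_annotated("helix", 7L))
  expect_equal(unname(d$normalized["helix", 7]), 100)
  expect_equal(sum(d$normalized), 100)
  expect_true(d$degenerate)
  expect_true(all(is.na(d$stderr)))
})

test_that("structure probabilities are conditional on spacing", {
  rec <- make_annotated(c("helix", "strand", "coil", "mixed",
                          rep("coil", 5)),
                        c(rep(4L, 4), rep(9L, 5)))
  p <- structure_probability(rec)
  expect_equal(unname(p["4", ]), rep(0.25, 4), ignore_attr = TRUE)
  expect_equal(unname(p["9", "coil"]), 1)
  rs <- rowSums(p, na.rm = FALSE)
  expect_equal(unname(rs[!is.na(rs)]), rep(1, 2), tolerance = 1e-9)
  expect_true(all(is.na(p["2", ])))
  expect_true(2L %in% attr(p, "undefined_spacings"))
})

test_that("confidence strata are half-open with an inclusive top", {
  rec <- make_annotated(rep("coil", 4), rep(3L, 4),
                        min_plddt = c(59.9, 60, 80, 100))
  st <- stratify_by_plddt(rec)
  expect_equal(sum(st[["0-60"]]$counts), 1)
  expect_equal(sum(st[["60-80"]]$counts), 1)    # exactly 60 goes to 60-80
  expect_equal(sum(st[["80-100"]]$counts), 2)   # 100 is included at the top
  expect_error(stratify_by_plddt(rec, ranges = list(c(0, 70), c(60, 100))),
               "overlap")
  # conservation: strata partition the records
  expect_equal(sum(vapply(st, function(d) sum(d$counts), numeric(1))),
               nrow(rec))
})

test_that("periodicity score separates damped sinusoid from plain decay", {
  s <- 1:19
  clean <- exp(-s / 8) * (1 + cos(2 * pi * s / 3.6))
  clean <- 100 * clean / max(clean)
  flat <- 100 * exp(-s / 8) / exp(-1 / 8)
  expect_gt(periodicity_score(clean), 0.8)
  expect_lt(periodicity_score(flat), 0.1)
  expect_error(periodicity_score(c(5, 3, rep(0, 17))), "nonzero-support")
})

test_that("quality comparison ranks contaminated sets below clean ones", {
  law_clean <- spacing_law("helix")
  law_bg <- spacing_law("background")
  draw <- function(n, law, seed) {
    xlspan:::with_seed(seed, sample(1:19, n, replace = TRUE, prob = law))
  }
  mk <- function(sp_helix, sp_coil) {
    rbind(make_annotated(rep("helix", length(sp_helix)), sp_helix),
          make_annotated(rep("coil", length(sp_coil)), sp_coil))
  }
  coil_sp <- draw(800, spacing_law("coil"), 99)
  clean <- mk(draw(800, law_clean, 1), coil_sp)
  dirty <- mk(c(draw(400, law_clean, 2), draw(400, law_bg, 3)), coil_sp)
  q <- compare_quality(list(clean = clean, dirty = dirty), seed = 7)
  expect_identical(q$label[1], "clean")
  expect_gt(q$periodicity[q$label == "clean"],
            q$periodicity[q$label == "dirty"])
  # identical sets score identically; tiny sets are flagged
  q2 <- compare_quality(list(a = clean, b = clean, tiny = clean[1:10, ]),
                        seed = 7)
  expect_equal(q2$periodicity[q2$label == "a"],
               q2$periodicity[q2$label == "b"])
  expect_true(q2$low_confidence[q2$label == "tiny"])
})

test_that("record counts never increase along the pipeline", {
  spec <- synthetic_spec(seed = 21, n_proteins = 5, n_links = 120,
                         fp_fraction = 0.2)
  pro <- simulate_proteome(spec)
  links <- simulate_crosslinks(spec, pro)
  dd <- deduplicate(links)
  px <- proximity_filter(dd)
  ann <- annotate_xl(px, pro$models)
  fl <- plddt_filter(ann)
  ns <- c(nrow(links), nrow(dd), nrow(px), nrow(ann), nrow(fl))
  expect_true(all(diff(ns) <= 0))
  # conservation into the distribution
  expect_equal(sum(spacing_distribution(ann)$counts), nrow(ann))
})
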