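write_csv_fixture <- function(path, rows) {
  writeLines(c("Protein1,AbsPos1,Protein2,AbsPos2,Score", rows), path)
}

test_that("tabular reader resolves header synonyms and skips bad rows", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_csv_fixture(p, c("P1,10,P1,20,120", "P1,5,P2,7,80", "P2,3,P2,9,60"))
  rec <- read_xl_table(p, dataset_id = "dsA")
  expect_equal(nrow(rec), 3L)
  expect_identical(rec$accession_a, c("P1", "P1", "P2"))
  expect_equal(rec$pos_b, c(20L, 7L, 9L))
  expect_equal(rec$score, c(120, 80, 60))
  expect_identical(unique(rec$dataset_id), "dsA")

  write_csv_fixture(p, c("P1,10,P1,20,1", "P1,NA,P1,7,1"))
  rec <- read_xl_table(p)
  expect_equal(nrow(rec), 1L)
  expect_equal(attr(rec, "skipped"), 1L)

  writeLines(c("foo,bar", "1,2"), p)
  expect_error(read_xl_table(p), "accession_a")
})

test_that("a user header map overrides the synonym table", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("acc1,site1,acc2,site2", "P1,4,P1,12"), p)
  rec <- read_xl_table(p, header_map = list(accession_a = "acc1",
                                            accession_b = "acc2",
                                            pos_a = "site1", pos_b = "site2"))
  expect_equal(rec$pos_a, 4L)
  expect_equal(rec$pos_b, 12L)
})

test_that("zipped archives delegate to the tabular reader", {
  csv <- c("Protein1,AbsPos1,Protein2,AbsPos2", "P1,10,P1,20", "P2,5,P2,9")
  direct <- withr::local_tempfile(fileext = ".csv")
  writeLines(csv, direct)
  zp <- withr::local_tempfile(fileext = ".zhrm")
  make_store_zip(zp, list("result.csv" = csv))
  a <- read_merox_archive(zp, dataset_id = "ds")
  b <- read_xl_table(direct, dataset_id = "ds")
  expect_equal(a, b, ignore_attr = TRUE)

  empty <- withr::local_tempfile(fileext = ".zhrm")
  make_store_zip(empty, list("readme.bin.dat" = "x"))
  expect_error(read_merox_archive(empty), "no recognizable table")

  two <- withr::local_tempfile(fileext = ".zhrm")
  make_store_zip(two, list("small.csv" = csv[1:2],
                           "big.csv" = c(csv, "P3,1,P3,5")))
  expect_warning(rec <- read_merox_archive(two), "largest")
  expect_equal(nrow(rec), 3L)
})

test_that("mzIdentML donor/acceptor pairs map to protein coordinates", {
  spec <- synthetic_spec(seed = 5, n_proteins = 3, n_links = 12)
  pro <- simulate_proteome(spec)
  links <- simulate_crosslinks(spec, pro)
  mz <- withr::local_tempfile(fileext = ".mzid")
  write_minimal_mzid(links, lapply(pro$models, model_sequence), mz)
  rec <- read_mzid(mz, dataset_id = "synthetic")
  expect_equal(nrow(rec), nrow(links))
  expect_equal(rec$pos_a, links$pos_a)
  expect_equal(rec$pos_b, links$pos_b)
  expect_identical(rec$accession_a, links$accession_a)
  expect_equal(attr(rec, "skipped"), 0L)
})

test_that("peptide start plus link offset gives the protein position", {
  links <- data.frame(dataset_id = "d", accession_a = "P40X", accession_b = "P40X",
                      pos_a = 45L, pos_b = 52L, linked_aa_a = "K",
                      linked_aa_b = "K", score = 1, linker_name = "DSS",
                      ambiguous = FALSE)
  seqs <- list(P40X = rep("K", 60))
  mz <- withr::local_tempfile(fileext = ".mzid")
  write_minimal_mzid(links, seqs, mz)
  # the writer uses 7-residue windows: start 42, offset 4 -> 42 + 4 - 1 = 45
  txt <- readLines(mz)
  expect_true(any(grepl('start="42"', txt)))
  rec <- read_mzid(mz)
  expect_equal(rec$pos_a, 45L)
  expect_equal(rec$pos_b, 52L)
})

test_that("an unpaired donor yields no record and one counted skip", {
  links <- data.frame(dataset_id = "d", accession_a = "P00X01",
                      accession_b = "P00X01", pos_a = 5L, pos_b = 9L,
                      linked_aa_a = "K", linked_aa_b = "K", score = 1,
                      linker_name = "DSS", ambiguous = FALSE)
  mz <- withr::local_tempfile(fileext = ".mzid")
  write_minimal_mzid(links, list(P00X01 = rep("K", 20)), mz)
  txt <- readLines(mz)
  txt <- txt[!grepl("MS:1002510", txt)]   # drop the acceptor cvParam
  writeLines(txt, mz)
  rec <- read_mzid(mz)
  expect_equal(nrow(rec), 0L)
  expect_equal(attr(rec, "skipped"), 1L)
})

test_that("redundancy removal keys on unordered site pairs within a dataset", {
  rec <- data.frame(
    dataset_id = c("d1", "d1", "d2", "d1"),
    accession_a = c("P1", "P1", "P1", "P2"),
    accession_b = c("P1", "P1", "P1", "P2"),
    pos_a = c(10L, 20L, 10L, 3L), pos_b = c(20L, 10L, 20L, 8L),
    linked_aa_a = "K", linked_aa_b = "K", score = 1:4,
    linker_name = "DSS", ambiguous = FALSE, stringsAsFactors = FALSE)
  out <- deduplicate(rec)
  # swapped duplicate collapses; the same pair in dataset d2 survives
  expect_equal(nrow(out), 3L)
  expect_equal(out$score, c(1, 3, 4))   # first occurrence kept, order stable
  expect_identical(deduplicate(out), out)   # idempotent
  expect_equal(nrow(deduplicate(rec[0, ])), 0L)
})
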