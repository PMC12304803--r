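# Readers for the three supported cross-link identification formats
# (mzIdentML 1.3, zipped result archives, xlsx/CSV tables) plus
# within-dataset redundancy removal. All readers emit the same record
# layout, so downstream code never needs to know the source format.

.xl_cols <- c("dataset_id", "accession_a", "accession_b", "pos_a", "pos_b",
              "linked_aa_a", "linked_aa_b", "score", "linker_name",
              "ambiguous")

.empty_xl <- function() {
  data.frame(dataset_id = character(), accession_a = character(),
             accession_b = character(), pos_a = integer(), pos_b = integer(),
             linked_aa_a = character(), linked_aa_b = character(),
             score = numeric(), linker_name = character(),
             ambiguous = logical(), stringsAsFactors = FALSE)
}

# Header synonyms accepted by the tabular reader; a user header map
# (standard name -> file column name) overrides these.
.default_header_map <- list(
  accession_a = c("accession_a", "protein1", "protein_1", "protein 1",
                  "accession1", "prot_a", "proteina"),
  accession_b = c("accession_b", "protein2", "protein_2", "protein 2",
                  "accession2", "prot_b", "proteinb"),
  pos_a = c("pos_a", "position1", "position_1", "abspos1", "from", "pos1",
            "residue1"),
  pos_b = c("pos_b", "position2", "position_2", "abspos2", "to", "pos2",
            "residue2"),
  linked_aa_a = c("linked_aa_a", "aa1", "residue_type1", "site1_aa"),
  linked_aa_b = c("linked_aa_b", "aa2", "residue_type2", "site2_aa"),
  score = c("score", "xl_score", "best_score"),
  linker_name = c("linker_name", "crosslinker", "linker")
)

#' Read cross-link identifications from a tabular file
#'
#' Accepts CSV or xlsx. Column names are matched case-insensitively against
#' a configurable header map; the two accessions and positions are
#' mandatory, the rest optional. Rows whose positions fail integer coercion
#' are skipped and counted (attribute `skipped`).
#'
#' @param path input file.
#' @param dialect `"csv"`, `"xlsx"` or `"auto"` (by extension). xlsx support
#'   requires the readxl package.
#' @param dataset_id dataset label stamped on every record (defaults to the
#'   file base name).
#' @param header_map optional named list mapping standard field names
#'   (`accession_a`, `pos_a`, ...) to the column names used in the file.
#' @return cross-link record data frame.
#' @export
read_xl_table <- function(path, dialect = c("auto", "csv", "xlsx"),
                          dataset_id = NULL, header_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (tolower(tools::file_ext(path)) %in% c("xlsx", "xls"))
      "xlsx" else "csv"
  }
  raw <- if (dialect == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the readxl package")
    }
    as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (is.null(dataset_id)) dataset_id <- tools::file_path_sans_ext(basename(path))
  map <- .default_header_map
  for (nm in names(header_map)) map[[nm]] <- header_map[[nm]]
  resolve <- function(field) {
    hit <- match(tolower(map[[field]]), tolower(names(raw)))
    hit <- hit[!is.na(hit)]
    if (length(hit)) names(raw)[hit[1]] else NA_character_
  }
  cols <- vapply(names(.default_header_map), resolve, character(1))
  mandatory <- c("accession_a", "accession_b", "pos_a", "pos_b")
  missing <- mandatory[is.na(cols[mandatory])]
  if (length(missing)) {
    stop("mandatory columns not found: ", paste(missing, collapse = ", "))
  }
  get_col <- function(field, default) {
    if (is.na(cols[[field]])) rep(default, nrow(raw)) else raw[[cols[[field]]]]
  }
  pos_a <- suppressWarnings(as.integer(get_col("pos_a", NA)))
  pos_b <- suppressWarnings(as.integer(get_col("pos_b", NA)))
  acc_a <- trimws(as.character(get_col("accession_a", NA)))
  acc_b <- trimws(as.character(get_col("accession_b", NA)))
  bad <- is.na(pos_a) | is.na(pos_b) | pos_a < 1 | pos_b < 1 |
    is.na(acc_a) | acc_a == "" | is.na(acc_b) | acc_b == ""
  out <- data.frame(
    dataset_id = dataset_id, accession_a = acc_a, accession_b = acc_b,
    pos_a = pos_a, pos_b = pos_b,
    linked_aa_a = toupper(as.character(get_col("linked_aa_a", NA))),
    linked_aa_b = toupper(as.character(get_col("linked_aa_b", NA))),
    score = suppressWarnings(as.numeric(get_col("score", NA))),
    linker_name = as.character(get_col("linker_name", NA)),
    ambiguous = FALSE, stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, skipped = sum(bad))
}

#' Read cross-links from a zipped result archive
#'
#' Result archives of the MeroX kind are zip files holding one or more
#' delimited tables; the largest recognizable table member is extracted (a
#' warning names it when several candidates exist) and handed to
#' [read_xl_table()].
#'
#' @inheritParams read_xl_table
#' @export
read_merox_archive <- function(path, dataset_id = NULL, header_map = NULL) {
  if (!file.exists(path)) stop("archive not found: ", path)
  listing <- utils::unzip(path, list = TRUE)
  cand <- listing[grepl("\\.(csv|tsv|txt)$", listing$Name, ignore.case = TRUE), ,
                  drop = FALSE]
  if (nrow(cand) == 0L) stop("archive holds no recognizable table member: ", path)
  pick <- cand$Name[which.max(cand$Length)]
  if (nrow(cand) > 1L) {
    warning("archive holds ", nrow(cand), " table members; using largest: ", pick)
  }
  tmp <- tempfile("merox_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  utils::unzip(path, files = pick, exdir = tmp)
  if (is.null(dataset_id)) dataset_id <- tools::file_path_sans_ext(basename(path))
  read_xl_table(file.path(tmp, pick), dialect = "csv",
                dataset_id = dataset_id, header_map = header_map)
}

#' Read cross-links from mzIdentML 1.3
#'
#' Parses the donor/acceptor cross-link encoding: each linked peptide
#' carries a modification cvParam ("cross-link donor" MS:1002509 or
#' "cross-link acceptor" MS:1002510) whose value pairs the two peptides.
#' Residue positions are mapped to protein coordinates as
#' `peptide evidence start + modification location - 1`. Donors without a
#' matching acceptor (or vice versa), and peptides without a protein
#' mapping, are skipped and counted (attribute `skipped`). Peptides mapping
#' to several proteins expand to one record per mapping, flagged
#' `ambiguous`.
#'
#' @param path mzIdentML file.
#' @param dataset_id dataset label (defaults to the file base name).
#' @return cross-link record data frame.
#' @export
read_mzid <- function(path, dataset_id = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(dataset_id)) dataset_id <- tools::file_path_sans_ext(basename(path))
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  dbseq <- xml2::xml_find_all(doc, ".//DBSequence")
  db_acc <- stats::setNames(xml2::xml_attr(dbseq, "accession"),
                            xml2::xml_attr(dbseq, "id"))
  peps <- xml2::xml_find_all(doc, ".//Peptide")
  pep_link <- list()  # peptide id -> list(role, value, location)
  for (p in peps) {
    pid <- xml2::xml_attr(p, "id")
    for (m in xml2::xml_find_all(p, "./Modification")) {
      cv <- xml2::xml_find_all(m, "./cvParam")
      accs <- xml2::xml_attr(cv, "accession")
      role <- if ("MS:1002509" %in% accs) "donor"
              else if ("MS:1002510" %in% accs) "acceptor" else NA
      if (is.na(role)) next
      val <- xml2::xml_attr(cv[accs %in% c("MS:1002509", "MS:1002510")][[1]],
                            "value")
      loc <- as.integer(xml2::xml_attr(m, "location"))
      pep_link[[pid]] <- list(role = role, value = val, location = loc)
    }
  }
  ev <- xml2::xml_find_all(doc, ".//PeptideEvidence")
  ev_df <- data.frame(
    peptide_ref = xml2::xml_attr(ev, "peptide_ref"),
    db_ref = xml2::xml_attr(ev, "dBSequence_ref"),
    start = as.integer(xml2::xml_attr(ev, "start")),
    stringsAsFactors = FALSE)
  skipped <- 0L
  rows <- list()
  values <- unique(vapply(pep_link, `[[`, character(1), "value"))
  for (v in values) {
    members <- pep_link[vapply(pep_link, function(x) x$value == v, logical(1))]
    roles <- vapply(members, `[[`, character(1), "role")
    if (!("donor" %in% roles && "acceptor" %in% roles)) {
      skipped <- skipped + 1L
      next
    }
    don_id <- names(members)[roles == "donor"][1]
    acc_id <- names(members)[roles == "acceptor"][1]
    site <- function(pid) {
      e <- ev_df[ev_df$peptide_ref == pid, , drop = FALSE]
      if (nrow(e) == 0L) return(NULL)
      data.frame(accession = unname(db_acc[e$db_ref]),
                 pos = e$start + members[[pid]]$location - 1L,
                 stringsAsFactors = FALSE)
    }
    sa <- site(don_id); sb <- site(acc_id)
    if (is.null(sa) || is.null(sb)) {
      skipped <- skipped + 1L
      next
    }
    amb <- nrow(sa) > 1L || nrow(sb) > 1L
    for (ia in seq_len(nrow(sa))) for (ib in seq_len(nrow(sb))) {
      rows[[length(rows) + 1L]] <- data.frame(
        dataset_id = dataset_id,
        accession_a = sa$accession[ia], accession_b = sb$accession[ib],
        pos_a = sa$pos[ia], pos_b = sb$pos[ib],
        linked_aa_a = NA_character_, linked_aa_b = NA_character_,
        score = NA_real_, linker_name = NA_character_, ambiguous = amb,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else .empty_xl()
  structure(out, skipped = skipped)
}

#' Remove redundant cross-links within each dataset
#'
#' A record is redundant when the same unordered pair of (accession,
#' position) sites was already seen under the same `dataset_id`; the first
#' occurrence survives and input order is preserved. The same pair observed
#' in two datasets is kept twice — redundancy is defined within a dataset.
#'
#' @param records cross-link record data frame.
#' @return de-duplicated records.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0L) return(records)
  a <- paste(records$accession_a, records$pos_a, sep = ":")
  b <- paste(records$accession_b, records$pos_b, sep = ":")
  key <- paste(records$dataset_id, pmin(a, b), pmax(a, b), sep = "|")
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a minimal mzIdentML 1.3 document for a cross-link set
#'
#' Emits just enough of the standard — DBSequence, Peptide with
#' donor/acceptor modification cvParams, PeptideEvidence with peptide start
#' positions — for [read_mzid()] (and other standard-compliant readers) to
#' recover every record. Peptides are 7-residue windows around each linked
#' site taken from the supplied sequences.
#'
#' @param records cross-link record data frame.
#' @param sequences named list of one-letter sequence vectors by accession.
#' @param path output path.
#' @export
write_minimal_mzid <- function(records, sequences, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<MzIdentML version="1.3.0" xmlns="http://psidev.info/psi/pi/mzIdentML/1.3">')
  w('  <SequenceCollection>')
  accs <- unique(c(records$accession_a, records$accession_b))
  for (acc in accs) {
    w('    <DBSequence id="DBSeq_', esc(acc), '" accession="', esc(acc),
      '" searchDatabase_ref="SDB1"/>')
  }
  pep_lines <- character(); ev_lines <- character()
  for (i in seq_len(nrow(records))) {
    for (side in c("a", "b")) {
      acc <- records[[paste0("accession_", side)]][i]
      pos <- records[[paste0("pos_", side)]][i]
      seq <- sequences[[acc]]
      start <- max(1L, pos - 3L)
      end <- min(length(seq), pos + 3L)
      pid <- sprintf("Pep_%d_%s", i, side)
      role <- if (side == "a") {
        c("MS:1002509", "cross-link donor")
      } else c("MS:1002510", "cross-link acceptor")
      pep_lines <- c(pep_lines,
        paste0('    <Peptide id="', pid, '">'),
        paste0('      <PeptideSequence>',
               paste(seq[start:end], collapse = ""), '</PeptideSequence>'),
        paste0('      <Modification location="', pos - start + 1L,
               '" monoisotopicMassDelta="138.068">'),
        paste0('        <cvParam cvRef="PSI-MS" accession="', role[1],
               '" name="', role[2], '" value="XL_', i, '"/>'),
        '      </Modification>',
        '    </Peptide>')
      ev_lines <- c(ev_lines,
        paste0('    <PeptideEvidence id="PE_', i, '_', side,
               '" peptide_ref="', pid, '" dBSequence_ref="DBSeq_', esc(acc),
               '" start="', start, '" end="', end, '"/>'))
    }
  }
  writeLines(pep_lines, con)
  writeLines(ev_lines, con)
  w('  </SequenceCollection>')
  w('</MzIdentML>')
  invisible(path)
}
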