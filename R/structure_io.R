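#' Read a predicted protein structure model
#'
#' Parses a PDB or mmCIF file into a [protein_model()]. The per-residue
#' confidence (pLDDT) is taken verbatim from the B-factor / isotropic
#' displacement column, following the AlphaFold convention of storing model
#' confidence there; no rescaling is applied. The lysine epsilon-nitrogen
#' (`NZ`) is captured as the reactive side-chain atom when present.
#'
#' Only the first chain is used (predicted single-protein models are
#' single-chain); additional chains trigger a warning. Non-standard residues
#' are skipped and counted in the `skipped_nonstandard` attribute. Residues
#' missing any backbone atom (N, CA, C, O) are kept but flagged
#' `incomplete`.
#'
#' @param path path to the structure file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (from the file extension).
#' @param accession accession to record; defaults to a guess from an
#'   `AF-<accession>-F1-model*` file name, else the file base name.
#' @return A [protein_model()]. Attribute `skipped_nonstandard` counts
#'   skipped non-standard residues.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           accession = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "mmcif",
                     mmcif = "mmcif",
                     stop("cannot infer structure format from extension '",
                          ext, "'; pass format explicitly"))
  }
  obj <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("unparseable ", format, " file '", path, "': ",
                             conditionMessage(e))
  )
  at <- obj$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in '", path, "'")
  chains <- unique(at$chain)
  if (length(chains) > 1L) {
    warning("multi-chain file; using first chain '", chains[1], "' only")
    at <- at[at$chain == chains[1], , drop = FALSE]
  }
  std <- at$resid %in% names(.aa321)
  n_skip <- length(unique(at$resno[!std]))
  at <- at[std, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain has zero standard residues in '", path, "'")
  resno <- sort(unique(at$resno))
  n <- length(resno)
  N <- CA <- C <- O <- reactive <- matrix(NA_real_, n, 3)
  aa <- character(n); plddt <- numeric(n)
  pick <- function(rows, name) {
    i <- which(rows & at$elety == name)
    if (length(i) == 0L) return(NULL)
    as.numeric(at[i[1], c("x", "y", "z")])
  }
  for (k in seq_len(n)) {
    rows <- at$resno == resno[k]
    aa[k] <- .aa321[[at$resid[which(rows)[1]]]]
    plddt[k] <- at$b[which(rows)[1]]
    for (nm in c("N", "CA", "C", "O")) {
      xyz <- pick(rows, nm)
      if (!is.null(xyz)) {
        switch(nm, N = {N[k, ] <- xyz}, CA = {CA[k, ] <- xyz},
               C = {C[k, ] <- xyz}, O = {O[k, ] <- xyz})
      }
    }
    if (aa[k] == "K") {
      xyz <- pick(rows, "NZ")
      if (!is.null(xyz)) reactive[k, ] <- xyz
    }
  }
  if (any(!is.na(plddt) & (plddt < 0 | plddt > 100))) {
    stop("B-factor column of '", path,
         "' holds values outside [0, 100]; not a pLDDT-annotated model")
  }
  incomplete <- apply(cbind(N, CA, C, O), 1L, anyNA)
  if (is.null(accession)) {
    base <- basename(path)
    m <- regmatches(base, regexec("^AF-([A-Z0-9]+)-F[0-9]+-model", base))[[1]]
    accession <- if (length(m) == 2L) m[2] else tools::file_path_sans_ext(base)
  }
  res <- data.frame(chain_id = at$chain[1], seq_index = resno, aa = aa,
                    plddt = plddt, incomplete = incomplete,
                    stringsAsFactors = FALSE)
  out <- protein_model(accession, res, N, CA, C, O, reactive,
                       source = basename(path))
  attr(out, "skipped_nonstandard") <- n_skip
  out
}

#' Locate a cached predicted model by accession
#'
#' Looks for `AF-<accession>-F1-model*.pdb` / `.cif` in `cache_dir`. When the
#' model is absent and `fetch = FALSE` (the default, and the only mode used
#' by tests), returns `NA_character_` — a "model unavailable" outcome the
#' pipeline counts rather than an error, so one missing model skips its
#' cross-links instead of aborting a run.
#'
#' @param accession UniProt accession (6-10 alphanumerics).
#' @param cache_dir directory holding model files.
#' @param fetch if `TRUE`, attempt to download the model from the public
#'   AlphaFold database into `cache_dir` when it is not cached.
#' @return file path, or `NA_character_` when unavailable.
#' @export
locate_model <- function(accession, cache_dir, fetch = FALSE) {
  if (!is.character(accession) || length(accession) != 1L ||
      !grepl("^[A-Z0-9]{6,10}$", accession)) {
    stop("malformed accession: ", deparse(accession))
  }
  if (!dir.exists(cache_dir)) stop("cache_dir does not exist: ", cache_dir)
  hits <- list.files(cache_dir,
                     pattern = paste0("^AF-", accession, "-F1-model.*\\.(pdb|cif)$"),
                     full.names = TRUE)
  if (length(hits) > 0L) return(sort(hits)[1])
  if (!fetch) return(NA_character_)
  url <- paste0("https://alphafold.ebi.ac.uk/files/AF-", accession,
                "-F1-model_v4.pdb")
  dest <- file.path(cache_dir, basename(url))
  ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE) == 0L,
                 error = function(e) FALSE)
  if (ok) dest else NA_character_
}

# Stable column order of the annotated cross-link table.
.xl_annot_cols <- c("dataset_id", "accession", "pos_a", "pos_b",
                    "linked_aa_a", "linked_aa_b", "spacing", "category",
                    "min_plddt", "continuous", "score", "linker_name",
                    "source")

#' Write / read the annotated short-range cross-link table
#'
#' Tab-separated, one row per annotated cross-link, fixed column order;
#' `read_annotated_tsv()` is the lossless inverse.
#'
#' @param records annotated cross-link data frame (see [annotate_xl()]).
#' @param path output file path.
#' @export
write_annotated_tsv <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- as.data.frame(records)[, intersect(.xl_annot_cols, names(records)),
                                drop = FALSE]
  for (miss in setdiff(.xl_annot_cols, names(out))) out[[miss]] <- NA
  out <- out[, .xl_annot_cols]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_annotated_tsv
#' @export
read_annotated_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA",
                          colClasses = c(dataset_id = "character",
                                         accession = "character",
                                         category = "character",
                                         linker_name = "character",
                                         source = "character"))
  df[, .xl_annot_cols]
}

#' Write a protein model as PDB or minimal mmCIF
#'
#' Emits backbone atoms (N, CA, C, O) and, for lysines with a reactive atom,
#' the epsilon-nitrogen `NZ`, with pLDDT in the B-factor column. The mmCIF
#' writer produces a minimal `atom_site` loop of the kind predicted-model
#' archives use. Round-trips through [read_structure()].
#'
#' @param model a [protein_model()].
#' @param path output path; `write_model()` picks the format from the
#'   extension (`.pdb` vs `.cif`).
#' @export
write_model <- function(model, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") write_model_pdb(model, path)
  else if (ext %in% c("cif", "mmcif")) write_model_cif(model, path)
  else stop("unsupported model extension: ", ext)
}

.model_atom_table <- function(model) {
  res <- model$residues
  rows <- list()
  for (k in seq_len(nrow(res))) {
    atoms <- list(N = model$N[k, ], CA = model$CA[k, ], C = model$C[k, ],
                  O = model$O[k, ])
    if (res$aa[k] == "K" && !anyNA(model$reactive[k, ])) {
      atoms$NZ <- model$reactive[k, ]
    }
    for (nm in names(atoms)) {
      if (anyNA(atoms[[nm]])) next
      rows[[length(rows) + 1L]] <- data.frame(
        elety = nm, resid = .aa123[[res$aa[k]]], chain = res$chain_id[k],
        resno = res$seq_index[k], x = atoms[[nm]][1], y = atoms[[nm]][2],
        z = atoms[[nm]][3], b = res$plddt[k],
        elesy = substr(nm, 1, 1), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @rdname write_model
#' @export
write_model_pdb <- function(model, path) {
  at <- .model_atom_table(model)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)),
    ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety),
    at$resid, substr(at$chain, 1, 1), at$resno, at$x, at$y, at$z,
    1.00, at$b, at$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @rdname write_model
#' @export
write_model_cif <- function(model, path) {
  at <- .model_atom_table(model)
  hdr <- c(
    paste0("data_", model$accession),
    "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num")
  body <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 %.2f ? %d %s %s %s 1",
    seq_len(nrow(at)), at$elesy, at$elety, at$resid, substr(at$chain, 1, 1),
    at$resno, at$x, at$y, at$z, at$b, at$resno, at$resid,
    substr(at$chain, 1, 1), at$elety)
  writeLines(c(hdr, body, "#"), path)
  invisible(path)
}
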