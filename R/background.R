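# Proteome-wide identical-residue spacing profiles within continuous
# secondary-structure elements: the null model against which experimental
# cross-link spacing distributions are compared. A pair of identical
# residues at spacing s is attributed to helix/strand/coil when the whole
# inclusive span lies inside one element run, to "mixed" when the span
# crosses an element boundary, or counted once overall in whole-sequence
# mode.

#' Extract continuous element runs from an assignment
#'
#' Maximal runs of identical labels, reported in author numbering.
#'
#' @param labels output of [assign_secondary_structure()] (named by
#'   `seq_index`).
#' @param accession accession recorded on each run.
#' @return data frame: `accession`, `category` (helix/strand/coil),
#'   `start`, `end` (inclusive `seq_index`).
#' @export
extract_elements <- function(labels, accession = NA_character_) {
  seqi <- as.integer(names(labels))
  r <- rle(unname(labels))
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  data.frame(accession = accession,
             category = c(H = "helix", E = "strand", C = "coil")[r$values],
             start = seqi[starts], end = seqi[ends],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Identical-residue pair spacing profile
#'
#' Counts ordered pairs of identical residues `aa` at spacings
#' `1..max_spacing` across a set of models. In `within_elements` mode each
#' pair is attributed to helix, strand or coil when its full inclusive span
#' lies within one continuous element, and to `mixed` otherwise; in
#' `whole_sequence` mode structure is ignored and a single profile is
#' returned. Counts are normalized per category, either to sum 1 or to a
#' maximum of 100 (the scale used when overlaying experimental spacing
#' distributions).
#'
#' @param models named list of [protein_model()] objects.
#' @param assignments named list of label vectors (computed when missing;
#'   ignored in whole-sequence mode).
#' @param aa one-letter amino-acid code (e.g. `"K"`).
#' @param mode `"within_elements"` or `"whole_sequence"`.
#' @param max_spacing spacing ceiling.
#' @param normalize `"sum"` (frequencies summing to 1) or `"max"` (largest
#'   bin 100).
#' @return object of class `pair_spacing_profile`: list with `aa`, `counts`
#'   and `freq` (category x spacing matrices), `mode`, `normalize`,
#'   `absent` (TRUE when `aa` never occurs).
#' @export
pair_spacing_profile <- function(models, assignments = NULL, aa = "K",
                                 mode = c("within_elements", "whole_sequence"),
                                 max_spacing = 19L,
                                 normalize = c("sum", "max")) {
  mode <- match.arg(mode)
  normalize <- match.arg(normalize)
  stopifnot(length(models) >= 1L)
  cats <- if (mode == "within_elements") .categories else "all"
  counts <- matrix(0, length(cats), max_spacing,
                   dimnames = list(cats, seq_len(max_spacing)))
  if (is.null(assignments)) assignments <- list()
  for (acc in names(models)) {
    model <- models[[acc]]
    seqaa <- model_sequence(model)
    seqi <- model$residues$seq_index
    hits <- which(seqaa == aa)
    if (length(hits) < 2L) next
    labels <- NULL
    if (mode == "within_elements") {
      if (is.null(assignments[[acc]])) {
        assignments[[acc]] <- assign_secondary_structure(model)
      }
      labels <- assignments[[acc]]
    }
    for (ii in seq_along(hits)) {
      i <- hits[ii]
      for (jj in seq_along(hits)[-seq_len(ii)]) {
        j <- hits[jj]
        s <- seqi[j] - seqi[i]
        if (s > max_spacing) break
        if (s < 1L) next
        if (mode == "whole_sequence") {
          counts["all", s] <- counts["all", s] + 1
        } else {
          span <- labels[i:j]
          cat_ <- if (all(span == span[1])) {
            c(H = "helix", E = "strand", C = "coil")[[span[1]]]
          } else "mixed"
          counts[cat_, s] <- counts[cat_, s] + 1
        }
      }
    }
  }
  freq <- counts
  for (r in rownames(freq)) {
    tot <- if (normalize == "sum") sum(counts[r, ]) else max(counts[r, ])
    if (tot > 0) {
      freq[r, ] <- counts[r, ] / tot * if (normalize == "max") 100 else 1
    }
  }
  structure(list(aa = aa, counts = counts, freq = freq, mode = mode,
                 normalize = normalize, absent = sum(counts) == 0),
            class = "pair_spacing_profile")
}

#' @export
print.pair_spacing_profile <- function(x, ...) {
  cat("<pair_spacing_profile> ", x$aa, "-", x$aa, " pairs, mode=", x$mode,
      ", ", sum(x$counts), " pairs counted\n", sep = "")
  invisible(x)
}

#' Write a pair-spacing profile as TSV
#' @param profile a [pair_spacing_profile()].
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- expand.grid(category = rownames(profile$counts),
                    spacing = as.integer(colnames(profile$counts)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$aa <- profile$aa
  df$count <- profile$counts[cbind(df$category, as.character(df$spacing))]
  df$freq <- profile$freq[cbind(df$category, as.character(df$spacing))]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Lysine availability per structural category
#'
#' Lysines are the residues most cross-linker chemistry targets, and their
#' scarcity inside beta-strands is one driver of the low strand share among
#' short-range cross-links. Reports, per category, the lysine count, the
#' residue total, and the per-residue lysine density.
#'
#' @param models named list of [protein_model()] objects.
#' @param assignments named list of label vectors (computed when missing).
#' @return data frame: `category`, `n_lysine`, `n_residues`, `density`.
#' @export
lysine_availability <- function(models, assignments = NULL) {
  stopifnot(length(models) >= 1L)
  if (is.null(assignments)) assignments <- list()
  lab3 <- c(H = "helix", E = "strand", C = "coil")
  nK <- ntot <- stats::setNames(numeric(3), unname(lab3))
  for (acc in names(models)) {
    model <- models[[acc]]
    if (is.null(assignments[[acc]])) {
      assignments[[acc]] <- assign_secondary_structure(model)
    }
    cat_ <- lab3[assignments[[acc]]]
    for (c_ in unname(lab3)) {
      ntot[c_] <- ntot[c_] + sum(cat_ == c_)
      nK[c_] <- nK[c_] + sum(cat_ == c_ & model_sequence(model) == "K")
    }
  }
  data.frame(category = names(nK), n_lysine = unname(nK),
             n_residues = unname(ntot),
             density = unname(ifelse(ntot > 0, nK / ntot, 0)),
             stringsAsFactors = FALSE)
}

#' Check model sequences against a proteome FASTA
#'
#' Optional consistency guard: compares each model's residue sequence to
#' the entry of the same accession in a FASTA file (positions follow the
#' model's author numbering). Proteins absent from the FASTA are reported,
#' not errors.
#'
#' @param models named list of [protein_model()] objects.
#' @param fasta_path path to a FASTA file with accession headers.
#' @return data frame: `accession`, `in_fasta`, `matches` (TRUE when every
#'   model residue equals the FASTA residue at its position).
#' @export
check_sequences <- function(models, fasta_path) {
  lines <- readLines(fasta_path)
  hdr <- grepl("^>", lines)
  acc <- sub("^>([^ |]+).*", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  names(seqs) <- acc
  rows <- lapply(names(models), function(a) {
    m <- models[[a]]
    if (is.null(seqs[[a]])) {
      return(data.frame(accession = a, in_fasta = FALSE, matches = NA))
    }
    fa <- strsplit(toupper(seqs[[a]]), "")[[1]]
    idx <- m$residues$seq_index
    ok <- all(idx <= length(fa)) && all(fa[idx] == model_sequence(m))
    data.frame(accession = a, in_fasta = TRUE, matches = ok)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
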