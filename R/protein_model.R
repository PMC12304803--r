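#' Protein model container
#'
#' A `protein_model` holds one (single-chain) predicted protein structure in
#' the form the annotation pipeline consumes: an ordered residue table plus
#' backbone coordinate matrices and the reactive side-chain atom (lysine
#' epsilon-nitrogen when present). Per-residue model confidence (pLDDT,
#' 0-100) is carried alongside, read verbatim from the B-factor column of
#' AlphaFold-style files.
#'
#' @param accession protein accession (character scalar).
#' @param residues data frame with columns `chain_id`, `seq_index` (1-based,
#'   strictly increasing author numbering), `aa` (one-letter code), `plddt`
#'   (0-100) and `incomplete` (logical: backbone atom missing).
#' @param N,CA,C,O numeric `n x 3` backbone coordinate matrices (angstrom);
#'   `NA` rows for missing atoms.
#' @param reactive numeric `n x 3` matrix of reactive side-chain atom
#'   coordinates, `NA` rows where the atom is absent.
#' @param source free-text provenance (source file name), kept so outputs can
#'   record which model file produced them.
#'
#' @return An object of class `protein_model`.
#' @export
protein_model <- function(accession, residues, N, CA, C, O,
                          reactive = NULL, source = NA_character_) {
  n <- nrow(residues)
  stopifnot(is.character(accession), length(accession) == 1L, n >= 1L)
  req <- c("chain_id", "seq_index", "aa", "plddt", "incomplete")
  if (!all(req %in% names(residues))) {
    stop("residues must have columns: ", paste(req, collapse = ", "))
  }
  if (is.unsorted(residues$seq_index, strictly = TRUE)) {
    stop("seq_index must be strictly increasing")
  }
  if (any(residues$seq_index < 1L)) stop("seq_index must be >= 1")
  ok <- is.na(residues$plddt) | (residues$plddt >= 0 & residues$plddt <= 100)
  if (!all(ok)) stop("pLDDT values outside [0, 100]")
  if (is.null(reactive)) reactive <- matrix(NA_real_, n, 3)
  for (m in list(N, CA, C, O, reactive)) {
    stopifnot(is.matrix(m), nrow(m) == n, ncol(m) == 3)
  }
  structure(
    list(accession = accession, residues = residues,
         N = N, CA = CA, C = C, O = O, reactive = reactive,
         source = source),
    class = "protein_model"
  )
}

#' @export
print.protein_model <- function(x, ...) {
  n <- nrow(x$residues)
  cat("<protein_model> ", x$accession, ": ", n, " residues (",
      x$residues$seq_index[1], "-", x$residues$seq_index[n], "), ",
      sum(x$residues$incomplete), " incomplete; mean pLDDT ",
      round(mean(x$residues$plddt, na.rm = TRUE), 1), "\n", sep = "")
  invisible(x)
}

#' Number of residues in a protein model
#' @param model a `protein_model`.
#' @export
n_residues <- function(model) nrow(model$residues)

#' Map author residue numbers to row indices
#'
#' @param model a `protein_model`.
#' @param seq_index integer vector of author residue numbers.
#' @return integer row indices; `NA` where a number is absent from the model.
#' @export
residue_row <- function(model, seq_index) {
  match(seq_index, model$residues$seq_index)
}

#' Model sequence as a one-letter character vector
#' @param model a `protein_model`.
#' @export
model_sequence <- function(model) model$residues$aa
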