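# Three-state secondary structure assignment from backbone coordinates,
# following the hydrogen-bond pattern formalism of Kabsch & Sander: an
# electrostatic N-H...O=C energy identifies bonds, n-turns build helices and
# bridge patterns build strands. The 8-state alphabet is collapsed to
# {H, E, C} ({alpha, 3-10, pi} -> H; {bridge, extended} -> E; rest -> C),
# the granularity at which cross-link spans are categorized.

#' Place backbone amide hydrogens
#'
#' Adds an `H` coordinate matrix to the model: each amide hydrogen sits
#' 1.00 angstrom from its nitrogen along the direction opposing the
#' preceding residue's carbonyl C -> O vector. The first residue, prolines
#' (no amide H) and residues following an incomplete backbone get no
#' hydrogen.
#'
#' @param model a [protein_model()] with backbone coordinates.
#' @return the model with an `H` matrix (`NA` rows where no H is placed).
#' @export
place_amide_hydrogens <- function(model) {
  n <- n_residues(model)
  H <- matrix(NA_real_, n, 3)
  seqi <- model$residues$seq_index
  for (i in seq_len(n)[-1]) {
    if (model$residues$aa[i] == "P") next
    if (seqi[i] != seqi[i - 1] + 1L) next  # chain break in author numbering
    Cp <- model$C[i - 1, ]; Op <- model$O[i - 1, ]; Ni <- model$N[i, ]
    if (anyNA(Cp) || anyNA(Op) || anyNA(Ni)) next
    H[i, ] <- Ni + unit(Cp - Op) * 1.00
  }
  model$H <- H
  model
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic energy (kcal/mol) of a putative hydrogen bond from the
#' donor residue's N-H to the acceptor residue's C=O:
#' `E = 27.888 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)`.
#' An energy below -0.5 kcal/mol counts as a bond.
#'
#' @param N,H donor backbone nitrogen and amide hydrogen (3-vectors).
#' @param C,O acceptor carbonyl carbon and oxygen (3-vectors).
#' @return energy in kcal/mol.
#' @export
hbond_energy <- function(N, H, C, O) {
  r <- c(ON = vnorm(O - N), CH = vnorm(C - H),
         OH = vnorm(O - H), CN = vnorm(C - N))
  if (any(r < 0.3)) stop("coincident donor/acceptor atoms (non-physical input)")
  27.888 * (1 / r[["ON"]] + 1 / r[["CH"]] - 1 / r[["OH"]] - 1 / r[["CN"]])
}

.hbond_cutoff <- -0.5

# Logical n x n matrix: bond[i, j] TRUE when the amide of residue i donates
# to the carbonyl of residue j. Donor and acceptor must be >= 2 apart in
# sequence; a 4.5 angstrom CA prefilter (vs the 9 angstrom Kabsch-Sander
# book-keeping cutoff, conservative because only short bonds matter) keeps
# the scan near-linear.
.hbond_matrix <- function(model) {
  n <- n_residues(model)
  bond <- matrix(FALSE, n, n)
  can_donate <- !apply(model$H, 1L, anyNA) & !apply(model$N, 1L, anyNA)
  can_accept <- !apply(model$C, 1L, anyNA) & !apply(model$O, 1L, anyNA)
  ca_ok <- !apply(model$CA, 1L, anyNA)
  for (i in which(can_donate & ca_ok)) {
    d2 <- rowSums((model$CA - matrix(model$CA[i, ], n, 3, byrow = TRUE))^2)
    for (j in which(can_accept & ca_ok & d2 < 81 & abs(seq_len(n) - i) >= 2)) {
      e <- hbond_energy(model$N[i, ], model$H[i, ], model$C[j, ], model$O[j, ])
      bond[i, j] <- e < .hbond_cutoff
    }
  }
  bond
}

#' Assign three-state secondary structure
#'
#' Hydrogen-bond-pattern assignment on backbone coordinates. A residue is
#' `H` when it lies inside a run of at least two consecutive i -> i+4 (or
#' i+3 / i+5) turns, `E` when it takes part in a parallel or antiparallel
#' bridge (isolated bridges included), `C` otherwise. Chains shorter than 5
#' complete residues are assigned all-`C` with a warning.
#'
#' @param model a [protein_model()].
#' @return character vector of `H`/`E`/`C` labels, one per residue, with the
#'   model's `seq_index` as names.
#' @export
assign_secondary_structure <- function(model) {
  n <- n_residues(model)
  labels <- rep("C", n)
  names(labels) <- model$residues$seq_index
  if (sum(!model$residues$incomplete) < 5L) {
    warning("fewer than 5 residues with complete backbone; all-coil assignment")
    return(labels)
  }
  if (is.null(model$H)) model <- place_amide_hydrogens(model)
  bond <- .hbond_matrix(model)
  # acc_to[i, j]: CO of i accepts from NH of j  (Kabsch-Sander Hbond(i, j))
  hb <- function(i, j) {
    if (i < 1 || j < 1 || i > n || j > n) return(FALSE)
    bond[j, i]
  }
  helix <- rep(FALSE, n)
  for (turn in c(4L, 3L, 5L)) {
    tt <- rep(FALSE, n)                       # tt[i]: bond (i+turn) -> i
    idx <- seq_len(n - turn)
    tt[idx] <- bond[cbind(idx + turn, idx)]
    for (i in seq_len(n - turn - 1L)) {
      if (tt[i] && tt[i + 1]) helix[(i + 1):(i + turn)] <- TRUE
    }
  }
  bridge <- rep(FALSE, n)
  for (i in seq_len(n)) {
    js <- seq_len(n)
    js <- js[js >= i + 3L]
    for (j in js) {
      par <- (hb(i - 1, j) && hb(j, i + 1)) || (hb(j - 1, i) && hb(i, j + 1))
      anti <- (hb(i, j) && hb(j, i)) || (hb(i - 1, j + 1) && hb(j - 1, i + 1))
      if (par || anti) bridge[c(i, j)] <- TRUE
    }
  }
  labels[bridge] <- "E"
  labels[helix] <- "H"   # helix takes priority over bridge
  labels
}

#' Classify the residue span of a cross-link
#'
#' A cross-linked span (both endpoints inclusive) is `helix`, `strand` or
#' `coil` only when every residue between and including the two linked sites
#' carries the same label (`H`, `E`, `C` respectively) — i.e., the whole
#' span lies within one continuous structural element. Any label change
#' inside the span makes it `mixed`.
#'
#' @param labels assignment from [assign_secondary_structure()] (named by
#'   `seq_index`).
#' @param i,j author residue numbers of the two linked sites (order-free).
#' @return one of `"helix"`, `"strand"`, `"coil"`, `"mixed"`.
#' @export
classify_span <- function(labels, i, j) {
  lo <- min(i, j); hi <- max(i, j)
  seqi <- as.integer(names(labels))
  rows <- which(seqi >= lo & seqi <= hi)
  if (length(rows) == 0L || seqi[rows[1]] != lo || seqi[rows[length(rows)]] != hi) {
    stop("span [", lo, ", ", hi, "] not fully contained in the model")
  }
  span <- labels[rows]
  if (all(span == "H")) "helix"
  else if (all(span == "E")) "strand"
  else if (all(span == "C")) "coil"
  else "mixed"
}

#' Export per-residue labels as TSV
#'
#' @param model a [protein_model()].
#' @param labels assignment from [assign_secondary_structure()].
#' @param path output path.
#' @export
write_ss_tsv <- function(model, labels, path) {
  df <- data.frame(accession = model$accession,
                   seq_index = model$residues$seq_index,
                   aa = model$residues$aa, label = unname(labels),
                   plddt = model$residues$plddt)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
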