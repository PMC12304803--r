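# Context-dependent composition statistics around cross-linked lysines:
# which neighboring residues, at which sequence offsets within the same
# continuous element, promote or inhibit lysine cross-linking, and which
# distinguish helical from coil contexts.

#' Amino-acid frequencies around lysine centers
#'
#' For each offset `d = 1..D`, pools the residues found `d` positions to
#' either side of each center lysine, restricted to positions inside the
#' same continuous element as the center; positions falling outside the
#' element do not enter the denominator. Frequencies therefore sum to 1 at
#' every offset with occupied positions.
#'
#' @param centers data frame with columns `accession`, `pos` (author
#'   numbering) naming the center lysines.
#' @param models named list of [protein_model()] objects.
#' @param assignments named list of label vectors (computed when missing).
#' @param category element category (`"helix"`, `"strand"`, `"coil"`) every
#'   center must lie in; centers in other elements are dropped and counted.
#' @param D maximal offset (default 10, two helical turns).
#' @return object of class `context_freq`: list with `f` (20 x D frequency
#'   matrix), `occupied` (positions counted per offset), `n_centers`,
#'   `category`.
#' @export
context_frequencies <- function(centers, models, assignments = NULL,
                                category = "helix", D = 10L) {
  stopifnot(is.data.frame(centers), all(c("accession", "pos") %in% names(centers)))
  if (nrow(centers) == 0L) stop("zero centers")
  if (is.null(assignments)) assignments <- list()
  counts <- matrix(0, length(.aa20), D, dimnames = list(.aa20, seq_len(D)))
  occupied <- stats::setNames(numeric(D), seq_len(D))
  used <- 0L; dropped <- 0L
  lab1 <- c(helix = "H", strand = "E", coil = "C")[[category]]
  for (k in seq_len(nrow(centers))) {
    acc <- centers$accession[k]
    model <- models[[acc]]
    if (is.null(model)) {
      dropped <- dropped + 1L
      next
    }
    if (is.null(assignments[[acc]])) {
      assignments[[acc]] <- assign_secondary_structure(model)
    }
    labels <- assignments[[acc]]
    seqaa <- model_sequence(model)
    row <- residue_row(model, centers$pos[k])
    if (is.na(row) || seqaa[row] != "K" || labels[row] != lab1) {
      dropped <- dropped + 1L
      next
    }
    # continuous element containing the center
    lo <- row
    while (lo > 1L && labels[lo - 1L] == lab1) lo <- lo - 1L
    hi <- row
    while (hi < length(labels) && labels[hi + 1L] == lab1) hi <- hi + 1L
    used <- used + 1L
    for (d in seq_len(D)) {
      for (p in c(row - d, row + d)) {
        if (p >= lo && p <= hi) {
          counts[seqaa[p], d] <- counts[seqaa[p], d] + 1
          occupied[d] <- occupied[d] + 1
        }
      }
    }
  }
  if (used == 0L) stop("no usable centers (all dropped)")
  f <- sweep(counts, 2, ifelse(occupied > 0, occupied, NA_real_), "/")
  structure(list(f = f, occupied = occupied, n_centers = used,
                 dropped = dropped, category = category),
            class = "context_freq")
}

#' Percentage-difference grammar matrix
#'
#' Relative difference `100 * (f - g) / g` between a foreground context
#' frequency matrix (around cross-linked lysines) and a background one
#' (around all lysines of the proteome), per amino acid and offset, with
#' a per-amino-acid cumulative effect (row sum) used for ranking. The
#' relative form is the default because residues differ greatly in base
#' rate; `mode = "absolute"` instead reports the difference in percentage
#' points, `100 * (f - g)`.
#'
#' Cells with zero background frequency are undefined (`NA`), never
#' silently zero.
#'
#' @param f,g `context_freq` objects (or bare matrices) on the same amino
#'   acids and offsets.
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return object of class `grammar_matrix`: list with `value` (aa x offset),
#'   `cumulative` (named, sorted decreasing), `ranking`, `mode`.
#' @export
percent_difference <- function(f, g, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  fm <- if (inherits(f, "context_freq")) f$f else f
  gm <- if (inherits(g, "context_freq")) g$f else g
  if (!identical(dim(fm), dim(gm)) || !identical(dimnames(fm), dimnames(gm))) {
    stop("foreground and background matrices must share amino acids and offsets")
  }
  value <- if (mode == "relative") {
    out <- 100 * (fm - gm) / gm
    out[gm == 0] <- NA_real_   # undefined against an empty background
    out
  } else {
    100 * (fm - gm)
  }
  cumulative <- rowSums(value, na.rm = TRUE)
  cumulative <- sort(cumulative, decreasing = TRUE)
  structure(list(value = value, cumulative = cumulative,
                 ranking = names(cumulative), mode = mode),
            class = "grammar_matrix")
}

#' @export
print.grammar_matrix <- function(x, ...) {
  top <- utils::head(x$ranking, 3)
  bot <- utils::tail(x$ranking, 3)
  cat("<grammar_matrix> ", nrow(x$value), " aa x ", ncol(x$value),
      " offsets (", x$mode, "); top: ", paste(top, collapse = " "),
      " | bottom: ", paste(bot, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Helix-versus-coil grammar
#'
#' Percentage difference in composition around cross-linked lysines between
#' helical and coil contexts: positive values mark residues enriched in
#' helices (diagnostic of helical structure), negative values residues
#' enriched in coils. `symmetric = TRUE` divides by the mean of the two
#' frequencies instead of the coil frequency, making the matrix exactly
#' antisymmetric under swapping the inputs.
#'
#' @param f_helix,f_coil `context_freq` objects from cross-linked centers.
#' @param symmetric use the symmetric relative difference.
#' @return a `grammar_matrix`.
#' @export
helix_vs_coil <- function(f_helix, f_coil, symmetric = FALSE) {
  fm <- if (inherits(f_helix, "context_freq")) f_helix$f else f_helix
  gm <- if (inherits(f_coil, "context_freq")) f_coil$f else f_coil
  if (!symmetric) return(percent_difference(fm, gm))
  denom <- (fm + gm) / 2
  value <- 100 * (fm - gm) / denom
  value[denom == 0] <- NA_real_
  cumulative <- sort(rowSums(value, na.rm = TRUE), decreasing = TRUE)
  structure(list(value = value, cumulative = cumulative,
                 ranking = names(cumulative), mode = "symmetric"),
            class = "grammar_matrix")
}

#' Write a grammar matrix (and its ranking) as TSV
#' @param gm a `grammar_matrix`.
#' @param path output path for the matrix; the ranking goes to
#'   `<path>.ranking.tsv`.
#' @export
write_grammar_tsv <- function(gm, path) {
  df <- data.frame(aa = rownames(gm$value), gm$value, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rk <- data.frame(aa = names(gm$cumulative), cumulative = unname(gm$cumulative))
  utils::write.table(rk, paste0(path, ".ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
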