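# The annotation pipeline core: proximity filtering, structural annotation
# against assigned models, confidence filtering and stratification, spacing
# distributions with subset standard errors, structure probabilities
# conditional on spacing, and the periodicity-based dataset quality score.

#' Sequence-proximity filter for short-range cross-links
#'
#' Keeps intra-protein records whose spacing `|pos_b - pos_a|` lies in
#' `1..max_spacing`. Self-links (spacing 0) are dropped and counted, as are
#' inter-protein records and (by default) records flagged ambiguous.
#' Attribute `dropped` reports the per-reason counts.
#'
#' @param records cross-link record data frame.
#' @param max_spacing spacing ceiling (default 19: "short-range" means
#'   fewer than 20 positions apart).
#' @param drop_ambiguous drop records with ambiguous protein mapping.
#' @return filtered records with a `spacing` column added.
#' @export
proximity_filter <- function(records, max_spacing = 19L,
                             drop_ambiguous = TRUE) {
  spacing <- abs(records$pos_b - records$pos_a)
  inter <- records$accession_a != records$accession_b
  selflink <- !inter & spacing == 0L
  far <- !inter & spacing > max_spacing
  amb_col <- if ("ambiguous" %in% names(records)) records$ambiguous else
    rep(FALSE, nrow(records))
  amb <- isTRUE(drop_ambiguous) & !is.na(amb_col) & amb_col
  keep <- !inter & !selflink & !far & !amb
  out <- records[keep, , drop = FALSE]
  out$spacing <- spacing[keep]
  rownames(out) <- NULL
  structure(out, dropped = c(inter_protein = sum(inter),
                             self_link = sum(selflink),
                             beyond_max_spacing = sum(far),
                             ambiguous = sum(amb & !inter)))
}

#' Annotate short-range cross-links with secondary structure
#'
#' For each record, the residue span between (and including) the two linked
#' sites is looked up in the protein's assignment: the span category comes
#' from [classify_span()], `min_plddt` is the minimum confidence over the
#' inclusive span, and `continuous` records whether the span stayed within
#' one element. Records whose protein has no model, whose positions fall
#' outside the model, or whose stated linked residue disagrees with the
#' model sequence are excluded and counted (attribute `dropped`).
#'
#' @param records output of [proximity_filter()].
#' @param models named list of [protein_model()] objects by accession.
#' @param assignments optional named list of label vectors from
#'   [assign_secondary_structure()]; computed on demand when absent.
#' @return annotated record data frame (one row per retained cross-link).
#' @export
annotate_xl <- function(records, models, assignments = NULL) {
  if (is.null(assignments)) assignments <- list()
  n_unavailable <- 0L; n_mapfail <- 0L
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    acc <- records$accession_a[i]
    model <- models[[acc]]
    if (is.null(model)) {
      n_unavailable <- n_unavailable + 1L
      next
    }
    if (is.null(assignments[[acc]])) {
      assignments[[acc]] <- assign_secondary_structure(model)
    }
    labels <- assignments[[acc]]
    pos <- sort(c(records$pos_a[i], records$pos_b[i]))
    ra <- residue_row(model, pos[1]); rb <- residue_row(model, pos[2])
    if (is.na(ra) || is.na(rb)) {
      n_mapfail <- n_mapfail + 1L
      next
    }
    stated <- c(records$linked_aa_a[i], records$linked_aa_b[i])
    actual <- model$residues$aa[c(residue_row(model, records$pos_a[i]),
                                  residue_row(model, records$pos_b[i]))]
    if (any(!is.na(stated) & stated != actual)) {
      n_mapfail <- n_mapfail + 1L
      next
    }
    category <- classify_span(labels, pos[1], pos[2])
    span_rows <- ra:rb
    rows[[i]] <- data.frame(
      dataset_id = records$dataset_id[i], accession = acc,
      pos_a = records$pos_a[i], pos_b = records$pos_b[i],
      linked_aa_a = actual[1], linked_aa_b = actual[2],
      spacing = pos[2] - pos[1], category = category,
      min_plddt = min(model$residues$plddt[span_rows]),
      continuous = category != "mixed",
      score = records$score[i], linker_name = records$linker_name[i],
      source = model$source, stringsAsFactors = FALSE)
  }
  kept <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(kept)) {
    do.call(rbind, c(kept, make.row.names = FALSE))
  } else NULL
  if (is.null(out)) {
    out <- data.frame(dataset_id = character(), accession = character(),
                      pos_a = integer(), pos_b = integer(),
                      linked_aa_a = character(), linked_aa_b = character(),
                      spacing = integer(), category = character(),
                      min_plddt = numeric(), continuous = logical(),
                      score = numeric(), linker_name = character(),
                      source = character(), stringsAsFactors = FALSE)
  }
  structure(out, dropped = c(model_unavailable = n_unavailable,
                             mapping_failure = n_mapfail))
}

#' Confidence filter on annotated cross-links
#'
#' Helix and strand spans are kept only when every residue in the span is
#' high-confidence (`min_plddt > cutoff`); coil and mixed spans are kept at
#' any confidence, because flexible and disordered regions intrinsically
#' carry lower scores.
#'
#' @param records annotated records from [annotate_xl()].
#' @param cutoff pLDDT threshold (default 80).
#' @return filtered records; attribute `dropped` counts removals.
#' @export
plddt_filter <- function(records, cutoff = 80) {
  needs <- records$category %in% c("helix", "strand")
  keep <- !needs | records$min_plddt > cutoff
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, dropped = c(low_plddt = sum(!keep)))
}

#' Per-category spacing distribution
#'
#' Tallies annotated cross-links into a category x spacing table, scales
#' each category so its largest bin is 100, and estimates a per-bin
#' standard error by splitting the records into three equal seeded random
#' subsets, normalizing each subset the same way and taking the standard
#' deviation of the three values over sqrt(3).
#'
#' @param records annotated records.
#' @param seed seed for the random subset split.
#' @param max_spacing spacing ceiling of the table.
#' @return object of class `spacing_distribution`: list with `counts`,
#'   `normalized`, `stderr` (category x spacing matrices), `n`, and
#'   `zero_categories` (categories with no records, whose normalized rows
#'   are all zero by convention).
#' @export
spacing_distribution <- function(records, seed = 1L, max_spacing = 19L) {
  tab <- function(df) {
    m <- matrix(0, length(.categories), max_spacing,
                dimnames = list(.categories, seq_len(max_spacing)))
    if (nrow(df)) {
      t0 <- table(factor(df$category, levels = .categories),
                  factor(df$spacing, levels = seq_len(max_spacing)))
      m[] <- as.numeric(t0)
    }
    m
  }
  norm100 <- function(m) {
    mx <- apply(m, 1, max)
    out <- m
    nz <- mx > 0
    out[nz, ] <- 100 * m[nz, , drop = FALSE] / mx[nz]
    out
  }
  counts <- tab(records)
  normalized <- norm100(counts)
  n <- nrow(records)
  stderr <- matrix(NA_real_, length(.categories), max_spacing,
                   dimnames = dimnames(counts))
  degenerate <- n < 3L
  if (!degenerate) {
    idx <- with_seed(seed, sample.int(n))
    size <- n %/% 3L
    parts <- list(idx[seq_len(size)], idx[size + seq_len(size)],
                  idx[(2L * size + 1L):n])   # remainder joins the last part
    subs <- lapply(parts, function(p) norm100(tab(records[p, , drop = FALSE])))
    for (c_ in .categories) for (s_ in seq_len(max_spacing)) {
      v <- vapply(subs, function(m) m[c_, s_], numeric(1))
      stderr[c_, s_] <- stats::sd(v) / sqrt(3)
    }
  }
  structure(list(counts = counts, normalized = normalized, stderr = stderr,
                 n = n, zero_categories = .categories[apply(counts, 1, sum) == 0],
                 degenerate = degenerate),
            class = "spacing_distribution")
}

#' @export
print.spacing_distribution <- function(x, ...) {
  cat("<spacing_distribution> ", x$n, " cross-links; category totals: ",
      paste(rownames(x$counts), rowSums(x$counts), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a spacing distribution as TSV
#'
#' Long format: category, spacing, count, normalized, stderr.
#' @param dist a [spacing_distribution()].
#' @param path output path.
#' @export
write_distribution_tsv <- function(dist, path) {
  df <- expand.grid(category = rownames(dist$counts),
                    spacing = as.integer(colnames(dist$counts)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$count <- dist$counts[cbind(df$category, as.character(df$spacing))]
  df$normalized <- dist$normalized[cbind(df$category, as.character(df$spacing))]
  df$stderr <- dist$stderr[cbind(df$category, as.character(df$spacing))]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Probability of each structure category conditional on spacing
#'
#' `p[s, c] = count(c, s) / sum_c count(c, s)`: given that a short-range
#' cross-link spans `s` residues, the probability that the span is a
#' continuous helix, strand, coil, or mixed. Spacings with no observations
#' give `NA` rows (listed in attribute `undefined_spacings`).
#'
#' @param records annotated records.
#' @param max_spacing spacing ceiling.
#' @return spacing x category probability matrix.
#' @export
structure_probability <- function(records, max_spacing = 19L) {
  counts <- t(spacing_distribution(records, max_spacing = max_spacing)$counts)
  tot <- rowSums(counts)
  p <- counts / ifelse(tot > 0, tot, NA_real_)
  structure(p, undefined_spacings = as.integer(rownames(p)[tot == 0]))
}

#' Stratify annotated cross-links by model confidence
#'
#' Assigns each record to the confidence stratum containing its `min_plddt`
#' (half-open `[lo, hi)` intervals, last interval closed above) and
#' computes a spacing distribution per stratum. Use records that have NOT
#' been through [plddt_filter()], otherwise the low strata are empty by
#' construction.
#'
#' @param records annotated records.
#' @param ranges list of `c(lo, hi)` boundaries; the defaults split into
#'   low (0-60), medium (60-80), and high (80-100) local confidence.
#' @param seed seed forwarded to [spacing_distribution()].
#' @return named list of `spacing_distribution` objects (names "lo-hi").
#' @export
stratify_by_plddt <- function(records,
                              ranges = list(c(0, 60), c(60, 80), c(80, 100)),
                              seed = 1L) {
  b <- do.call(rbind, ranges)
  if (any(b[, 2] <= b[, 1])) stop("each range needs hi > lo")
  o <- order(b[, 1])
  b <- b[o, , drop = FALSE]
  if (any(utils::head(b[, 2], -1) > utils::tail(b[, 1], -1))) {
    stop("confidence ranges overlap")
  }
  out <- list()
  for (k in seq_len(nrow(b))) {
    lo <- b[k, 1]; hi <- b[k, 2]
    inb <- records$min_plddt >= lo &
      (records$min_plddt < hi | (k == nrow(b) & records$min_plddt <= hi))
    out[[paste0(lo, "-", hi)]] <-
      spacing_distribution(records[inb, , drop = FALSE], seed = seed)
  }
  out
}

#' Fit an exponential trend to positive bins
#'
#' Least squares of `log(y)` on `s` over bins with `y > 0`; returns the
#' fitted values `a * exp(-b * s)` over all of `s` plus the decay rate `b`.
#' @keywords internal
exp_trend <- function(y, s = seq_along(y)) {
  pos <- y > 0 & !is.na(y)
  if (sum(pos) < 2L) stop("need >= 2 positive bins to fit a trend")
  fit <- stats::lm(log(y[pos]) ~ s[pos])
  b <- -unname(stats::coef(fit)[2])
  a <- exp(unname(stats::coef(fit)[1]))
  list(trend = a * exp(-b * s), decay_rate = b)
}

#' Helical periodicity score of a spacing distribution
#'
#' Quantifies how much of a (normalized) helix spacing curve oscillates at
#' the alpha-helical pitch of 3.6 residues per turn. The curve is detrended
#' by dividing out a fitted decaying exponential, mean-centered, and the
#' discrete Fourier power at frequency 1/3.6 is taken relative to the total
#' variance of the detrended curve. A clean damped 3.6-periodic curve
#' scores near 1; a featureless decay scores near 0. Randomly distributed
#' false positives wash out the periodic pattern, so the score falls as a
#' dataset's false-positive fraction rises — which is what makes it a
#' dataset quality metric.
#'
#' @param x a `spacing_distribution` (its helix row is used) or a numeric
#'   curve over spacings `1..length(x)`.
#' @param period pitch to probe, in residues (default 3.6).
#' @param min_support minimum number of nonzero bins required.
#' @return score (non-negative, ~1 for a pure damped sinusoid at `period`).
#' @export
periodicity_score <- function(x, period = 3.6, min_support = 8L) {
  y <- if (inherits(x, "spacing_distribution")) x$normalized["helix", ] else x
  s <- seq_along(y)
  if (sum(y > 0, na.rm = TRUE) < min_support) {
    stop("periodicity score undefined: fewer than ", min_support,
         " nonzero-support bins")
  }
  det <- y / exp_trend(y, s)$trend
  yc <- det - mean(det)
  n <- length(yc)
  co <- sum(yc * cos(2 * pi * s / period))
  si <- sum(yc * sin(2 * pi * s / period))
  2 * (co^2 + si^2) / (n * sum(yc^2))
}

#' Dominant oscillation period of a profile
#'
#' Detrends a profile (fitted decaying exponential, fitted line, or
#' nothing), mean-centers it, evaluates the discrete Fourier power on a
#' fine period grid and returns the period of maximal power. Used both on
#' distance-versus-spacing profiles of ideal helices and on spacing
#' histograms of simulated cross-link sets.
#'
#' @param y numeric profile.
#' @param s sample positions (default `1..length(y)`).
#' @param periods candidate period grid (residues).
#' @param detrend `"exp"`, `"linear"` or `"none"`.
#' @return list with `period` (argmax) and `power` (vector over the grid).
#' @export
dominant_period <- function(y, s = seq_along(y),
                            periods = seq(2.5, 9, by = 0.005),
                            detrend = c("exp", "linear", "none")) {
  detrend <- match.arg(detrend)
  yd <- switch(detrend,
    exp = y / exp_trend(y, s)$trend,
    linear = stats::residuals(stats::lm(y ~ s)),
    none = y)
  yc <- yd - mean(yd)
  power <- vapply(periods, function(Tp) {
    sum(yc * cos(2 * pi * s / Tp))^2 + sum(yc * sin(2 * pi * s / Tp))^2
  }, numeric(1))
  list(period = periods[which.max(power)],
       power = stats::setNames(power, periods))
}

#' Compare dataset quality via spacing-pattern statistics
#'
#' For each labeled record set: the helix periodicity score and the coil
#' exponential decay rate (least-squares slope of log counts versus
#' spacing). Datasets with more random false positives lose helix
#' periodicity and flatten the coil decay. Labels with fewer than 50
#' short-range records are flagged low-confidence.
#'
#' @param sets named list of annotated record data frames.
#' @param seed seed forwarded to [spacing_distribution()].
#' @return data frame sorted by descending periodicity score.
#' @export
compare_quality <- function(sets, seed = 1L) {
  if (length(sets) < 2L) stop("compare_quality needs >= 2 labeled sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be named")
  }
  rows <- lapply(names(sets), function(lbl) {
    rec <- sets[[lbl]]
    n <- nrow(rec)
    dist <- spacing_distribution(rec, seed = seed)
    score <- tryCatch(periodicity_score(dist), error = function(e) NA_real_)
    coil <- dist$counts["coil", ]
    decay <- tryCatch(exp_trend(coil)$decay_rate, error = function(e) NA_real_)
    data.frame(label = lbl, n = n, periodicity = score,
               coil_decay_rate = decay, low_confidence = n < 50L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$periodicity), -Inf, out$periodicity)), ]
  rownames(out) <- NULL
  out
}
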