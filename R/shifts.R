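#' Load per-class chemical-shift statistics
#'
#' Gaussian Calpha/Cbeta chemical-shift statistics per residue type and
#' secondary-structure class (helix, sheet, coil). The bundled table
#' (`shift_stats_synthetic.csv`) holds synthetic, representative values on
#' the scale of published shift compilations — secondary-structure
#' sensitive nuclei such as Thr Cbeta move by several ppm between helix and
#' sheet — and is meant to be replaced or extended by the user's preferred
#' statistics table (same CSV columns).
#'
#' @param path CSV with columns `residue_type`, `ss_class`, `mean_ca`,
#'   `sd_ca`, `mean_cb`, `sd_cb`; defaults to the bundled synthetic table.
#' @return A data.frame of class `shift_statistics`.
#' @export
load_shift_statistics <- function(path = system.file(
  "extdata", "shift_stats_synthetic.csv", package = "condmat")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue_type", "ss_class", "mean_ca", "sd_ca",
            "mean_cb", "sd_cb")
  stopifnot(all(need %in% names(d)))
  d$residue_type <- toupper(d$residue_type)
  if (any(stats::na.omit(c(d$sd_ca, d$sd_cb)) <= 0))
    stop("standard deviations must be positive", call. = FALSE)
  class(d) <- c("shift_statistics", "data.frame")
  d
}

.stats_for <- function(stats, residue_type) {
  s <- stats[stats$residue_type == toupper(residue_type), , drop = FALSE]
  if (nrow(s) == 0)
    stop("no shift statistics for residue type ", residue_type,
         call. = FALSE)
  s
}

#' Secondary-structure posterior from Calpha/Cbeta shifts
#'
#' Posterior over {helix, sheet, coil} for an observed Calpha and/or
#' Cbeta shift, assuming independent Gaussians per dimension within each
#' class: posterior ~ prior x N(ca; mean_ca, sd_ca) x N(cb; mean_cb,
#' sd_cb), with the factor for a missing dimension omitted.
#'
#' @param residue_type three-letter residue code (e.g. "THR").
#' @param ca,cb observed shifts in ppm; at least one must be given.
#' @param stats a [load_shift_statistics()] table.
#' @param priors named prior weights over the classes present (default
#'   uniform).
#' @return Named numeric of posterior probabilities (sums to 1), with
#'   attribute `map` holding the maximum-posterior class.
#' @export
class_posterior <- function(residue_type, ca = NA, cb = NA,
                            stats = load_shift_statistics(),
                            priors = NULL) {
  if (is.na(ca) && is.na(cb))
    stop("at least one of ca, cb must be observed", call. = FALSE)
  s <- .stats_for(stats, residue_type)
  if (is.null(priors)) priors <- stats::setNames(rep(1, nrow(s)), s$ss_class)
  loglik <- vapply(seq_len(nrow(s)), function(i) {
    ll <- log(priors[[s$ss_class[i]]])
    if (!is.na(ca))
      ll <- ll + stats::dnorm(ca, s$mean_ca[i], s$sd_ca[i], log = TRUE)
    if (!is.na(cb)) {
      if (is.na(s$mean_cb[i])) return(-Inf)  # class lacks a Cbeta (e.g. Gly)
      ll <- ll + stats::dnorm(cb, s$mean_cb[i], s$sd_cb[i], log = TRUE)
    }
    ll
  }, numeric(1))
  w <- exp(loglik - max(loglik))
  post <- stats::setNames(w / sum(w), s$ss_class)
  attr(post, "map") <- s$ss_class[which.max(post)]
  post
}

#' Band assignment from the Cbeta shift alone
#'
#' Assigns the class whose 1D Gaussian density is highest at the observed
#' Cbeta shift (equivalently, the smallest width-penalized deviation
#' z^2/2 + ln sd; identical to the nearest class in |cb - mean|/sd when
#' the class widths are equal), reporting the z-score against every
#' class. Ties are broken deterministically in the order
#' helix < sheet < coil and flagged.
#'
#' @inheritParams class_posterior
#' @return A list with `class`, `z_scores` (named), `tie` (logical).
#' @export
classify_cb_band <- function(residue_type, cb,
                             stats = load_shift_statistics()) {
  stopifnot(is.finite(cb))
  s <- .stats_for(stats, residue_type)
  s <- s[!is.na(s$mean_cb), , drop = FALSE]
  if (nrow(s) == 0)
    stop("no Cbeta statistics for residue type ", residue_type,
         call. = FALSE)
  z <- stats::setNames(abs(cb - s$mean_cb) / s$sd_cb, s$ss_class)
  score <- z^2 / 2 + log(s$sd_cb)     # negative Gaussian log density
  ord <- c(helix = 1L, sheet = 2L, coil = 3L)[s$ss_class]
  best <- order(score, ord)[1]
  list(class = s$ss_class[best], z_scores = z,
       tie = sum(abs(score - score[best]) < 1e-12) > 1)
}

#' Assignment table constructor / reader
#'
#' @param residue_index residue numbers.
#' @param residue_type three-letter codes.
#' @param atom_name atom names ("N", "CA", "CB", "C", ...).
#' @param shift chemical shifts, ppm.
#' @return A data.frame of class `assignment_table`.
#' @export
assignment_table <- function(residue_index, residue_type, atom_name, shift) {
  d <- data.frame(residue_index = as.integer(residue_index),
                  residue_type = toupper(residue_type),
                  atom_name = toupper(atom_name),
                  shift = as.numeric(shift))
  if (anyDuplicated(d[, c("residue_index", "atom_name")]))
    stop("duplicate (residue_index, atom_name) entries", call. = FALSE)
  class(d) <- c("assignment_table", "data.frame")
  d
}

#' @rdname assignment_table
#' @param path CSV with the four columns above.
#' @export
read_assignment_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  assignment_table(d$residue_index, d$residue_type, d$atom_name, d$shift)
}

#' Back-predict 2D correlation peak lists from an assignment table
#'
#' Generates the peak positions a 2D solid-state correlation spectrum
#' should show for a given assignment: NCA correlates N(i) with CA(i);
#' NCO correlates N(i) with the preceding carbonyl C'(i-1); DARR at short
#' mixing (~20 ms) gives all intra-residue carbon-carbon pairs at both
#' symmetric positions, and optionally (`sequential = TRUE`, long mixing)
#' adds sequential CA(i)-CA(i+1) and CA(i)-C'(i+1-1) contacts. Residues
#' missing a required atom are skipped and counted.
#'
#' @param table an [assignment_table()].
#' @param experiment `"DARR"`, `"NCA"` or `"NCO"`.
#' @param sequential add sequential contacts for long-mixing DARR.
#' @return A data.frame of class `peak_list2d` with columns `dim1_ppm`,
#'   `dim2_ppm`, `label`; attribute `skipped` counts residues lacking the
#'   required atoms. Rows are sorted for order-independence.
#' @export
predict_correlation_peaks <- function(table,
                                      experiment = c("DARR", "NCA", "NCO"),
                                      sequential = FALSE) {
  experiment <- match.arg(experiment)
  get_shift <- function(idx, atom) {
    v <- table$shift[table$residue_index == idx & table$atom_name == atom]
    if (length(v) == 1) v else NA_real_
  }
  idxs <- sort(unique(table$residue_index))
  peaks <- list(); skipped <- 0L
  add <- function(d1, d2, lab)
    peaks[[length(peaks) + 1L]] <<- data.frame(dim1_ppm = d1, dim2_ppm = d2,
                                               label = lab)
  if (experiment == "NCA") {
    for (i in idxs) {
      n <- get_shift(i, "N"); ca <- get_shift(i, "CA")
      if (anyNA(c(n, ca))) { skipped <- skipped + 1L; next }
      add(n, ca, sprintf("N%d-CA%d", i, i))
    }
  } else if (experiment == "NCO") {
    for (i in idxs) {
      if (!(i - 1L) %in% idxs) next
      n <- get_shift(i, "N"); co <- get_shift(i - 1L, "C")
      if (anyNA(c(n, co))) { skipped <- skipped + 1L; next }
      add(n, co, sprintf("N%d-C%d", i, i - 1L))
    }
  } else {
    is_c <- startsWith(table$atom_name, "C") & table$atom_name != "N"
    for (i in idxs) {
      rows <- table[table$residue_index == i & is_c, , drop = FALSE]
      if (nrow(rows) < 2) { if (nrow(rows) == 0) skipped <- skipped + 1L; next }
      cmb <- utils::combn(nrow(rows), 2)
      for (k in seq_len(ncol(cmb))) {
        a <- cmb[1, k]; b <- cmb[2, k]
        lab <- sprintf("%s%d-%s%d", rows$atom_name[a], i, rows$atom_name[b], i)
        add(rows$shift[a], rows$shift[b], lab)
        add(rows$shift[b], rows$shift[a],
            sprintf("%s%d-%s%d", rows$atom_name[b], i, rows$atom_name[a], i))
      }
    }
    if (sequential) {
      for (i in idxs) {
        if (!(i + 1L) %in% idxs) next
        ca_i <- get_shift(i, "CA"); ca_n <- get_shift(i + 1L, "CA")
        co_i <- get_shift(i, "C")
        if (!anyNA(c(ca_i, ca_n))) {
          add(ca_i, ca_n, sprintf("CA%d-CA%d", i, i + 1L))
          add(ca_n, ca_i, sprintf("CA%d-CA%d", i + 1L, i))
        }
        if (!anyNA(c(co_i, ca_n))) {
          add(co_i, ca_n, sprintf("C%d-CA%d", i, i + 1L))
          add(ca_n, co_i, sprintf("CA%d-C%d", i + 1L, i))
        }
      }
    }
  }
  out <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(dim1_ppm = numeric(0), dim2_ppm = numeric(0),
               label = character(0))
  out <- out[order(out$label, out$dim1_ppm, out$dim2_ppm), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "experiment") <- experiment
  class(out) <- c("peak_list2d", "data.frame")
  out
}
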