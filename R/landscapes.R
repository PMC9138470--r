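#' Contact-based collective variables
#'
#' For each frame, counts the residue-pair contacts inside the CDR3
#' (q_intra) and between CDR3 and scaffold (q_scaffold), then normalises
#' each class so values lie in [0, 1]. The default normalisation divides
#' by the maximum count of that class observed over the ensemble; the
#' alternative `"max_pairs"` divides by the number of admissible residue
#' pairs of the class.
#'
#' @param ensemble a `conf_ensemble`.
#' @param regions a `region_set` defining `CDR3` (or the name in `loop`)
#'   and the derived scaffold.
#' @param cutoff heavy-atom contact cutoff in nm.
#' @param min_seq_sep minimum sequence separation for a contact.
#' @param loop name of the loop region (default "CDR3").
#' @param normalization `"ensemble_max"` or `"max_pairs"`.
#' @return A data.frame of class `contact_cv_series` with columns
#'   `q_intra`, `q_scaffold`, raw `n_intra`, `n_scaffold`, and attribute
#'   `norm` (the two normalisation constants).
#' @export
contact_cvs <- function(ensemble, regions, cutoff = 0.45, min_seq_sep = 2,
                        loop = "CDR3",
                        normalization = c("ensemble_max", "max_pairs")) {
  normalization <- match.arg(normalization)
  loop_res <- region_residues(regions, loop)
  scaf_res <- region_residues(regions, "scaffold")
  w <- rep(0, ensemble$n_frames)  # frequencies unused here
  intra <- .contact_stats(ensemble, loop_res, loop_res, cutoff,
                          min_seq_sep, w)$counts
  inter <- .contact_stats(ensemble, loop_res, scaf_res, cutoff,
                          min_seq_sep, w)$counts
  norm_const <- function(counts, nmax) {
    if (normalization == "max_pairs") return(nmax)
    m <- max(counts)
    if (m == 0) {
      warning("no contacts of one class in any frame; CV reported as 0")
      return(1)
    }
    m
  }
  n_loop <- length(loop_res)
  # admissible pairs respect min_seq_sep within the loop
  intra_pairs <- sum(outer(loop_res, loop_res,
                           function(a, b) a < b & abs(a - b) >= min_seq_sep))
  inter_pairs <- sum(outer(loop_res, scaf_res,
                           function(a, b) abs(a - b) >= min_seq_sep))
  c1 <- norm_const(intra, intra_pairs)
  c2 <- norm_const(inter, inter_pairs)
  structure(
    data.frame(q_intra = intra / c1, q_scaffold = inter / c2,
               n_intra = intra, n_scaffold = inter),
    class = c("contact_cv_series", "data.frame"),
    norm = c(intra = c1, scaffold = c2), cutoff = cutoff, loop = loop
  )
}

.cv_matrix <- function(cvs) {
  if (inherits(cvs, "contact_cv_series") || is.data.frame(cvs)) {
    cbind(cvs[[1]], cvs[[2]])
  } else as.matrix(cvs)
}

#' Weighted 2D free-energy surface over two collective variables
#'
#' Bins the CV samples on a regular grid, accumulates statistical
#' weights, and converts bin probabilities to free energies
#' `F = -kB T log(p / p_max)` (kJ/mol), so the most populated bin sits at
#' F = 0. Empty bins are NA (masked), never 0.
#'
#' @param cvs a `contact_cv_series` or two-column matrix of CV values.
#' @param weights per-frame weights (default uniform).
#' @param bins bins per dimension (scalar or length 2).
#' @param temperature kelvin.
#' @param limits optional list `list(x = c(lo, hi), y = c(lo, hi))`;
#'   default the data range.
#' @return An object of class `fes`: list with `F` (matrix, kJ/mol),
#'   `xedges`, `yedges`, `p` (bin probabilities), `temperature`.
#' @export
free_energy_surface <- function(cvs, weights = NULL, bins = 50,
                                temperature = 300, limits = NULL) {
  xy <- .cv_matrix(cvs)
  if (any(!is.finite(xy))) stop("non-finite CV values")
  w <- .as_weights(weights, nrow(xy))
  bins <- rep_len(as.integer(bins), 2)
  lx <- limits$x %||% range(xy[, 1])
  ly <- limits$y %||% range(xy[, 2])
  if (diff(lx) == 0) lx <- lx + c(-0.5, 0.5)
  if (diff(ly) == 0) ly <- ly + c(-0.5, 0.5)
  xe <- seq(lx[1], lx[2], length.out = bins[1] + 1)
  ye <- seq(ly[1], ly[2], length.out = bins[2] + 1)
  ix <- pmin(pmax(findInterval(xy[, 1], xe, rightmost.closed = TRUE), 1),
             bins[1])
  iy <- pmin(pmax(findInterval(xy[, 2], ye, rightmost.closed = TRUE), 1),
             bins[2])
  p <- matrix(0, bins[1], bins[2])
  acc <- rowsum(w, (iy - 1L) * bins[1] + ix)
  p[as.integer(rownames(acc))] <- acc
  if (all(p == 0)) stop("no occupied bins")
  f <- matrix(NA_real_, bins[1], bins[2])
  occ <- p > 0
  f[occ] <- -KB_KJ_MOL_K * temperature * log(p[occ] / max(p))
  structure(list(F = f, p = p, xedges = xe, yedges = ye,
                 temperature = temperature),
            class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  occ <- sum(is.finite(x$F))
  cat("<fes> ", nrow(x$F), "x", ncol(x$F), " bins, ", occ,
      " occupied, max F = ", round(max(x$F, na.rm = TRUE), 2),
      " kJ/mol at T = ", x$temperature, " K\n", sep = "")
  invisible(x)
}

#' Weighted residue-residue contact probability map
#'
#' Entry (a, b) is the total statistical weight of the frames in which
#' residues a and b are in contact; with uniform weights this is the
#' plain contact frequency.
#'
#' @param ensemble a `conf_ensemble`.
#' @param resA,resB residue id vectors for the two axes.
#' @param weights per-frame weights (default ensemble weights or
#'   uniform).
#' @param cutoff heavy-atom cutoff in nm.
#' @param min_seq_sep minimum sequence separation.
#' @return numeric `|resA| x |resB|` matrix in [0, 1] with residue-id
#'   dimnames, class `contact_map`.
#' @export
contact_probability_map <- function(ensemble, resA, resB, weights = NULL,
                                    cutoff = 0.45, min_seq_sep = 2) {
  w <- .as_weights(weights %||% ensemble$weights, ensemble$n_frames)
  resA <- sort(resA); resB <- sort(resB)
  st <- .contact_stats(ensemble, resA, resB, cutoff, min_seq_sep, w)
  m <- pmin(pmax(st$freq, 0), 1)   # guard accumulated rounding
  dim(m) <- dim(st$freq)
  dimnames(m) <- list(resA, resB)
  class(m) <- c("contact_map", class(m))
  m
}

#' Weighted population of a region of CV space
#'
#' Sums the statistical weights of all frames whose CVs fall inside a
#' rectangular selection (bounds inclusive). Used e.g. to measure the
#' population of a minor free-energy basin.
#'
#' @param cvs a `contact_cv_series` or two-column CV matrix.
#' @param xlim,ylim inclusive bounds on the two CVs.
#' @param weights per-frame weights (default uniform).
#' @return population fraction in [0, 1].
#' @export
state_population <- function(cvs, xlim, ylim = c(-Inf, Inf),
                             weights = NULL) {
  xy <- .cv_matrix(cvs)
  w <- .as_weights(weights, nrow(xy))
  inside <- xy[, 1] >= xlim[1] & xy[, 1] <= xlim[2] &
    xy[, 2] >= ylim[1] & xy[, 2] <= ylim[2]
  if (!any(inside)) {
    warning("selection contains no frames")
    return(0)
  }
  sum(w[inside])
}

#' Write a free-energy surface or contact map as a tab-separated grid
#'
#' The header lines record bin edges / residue labels and the parameters
#' that produced the object.
#'
#' @param x a `fes` or `contact_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grid <- function(x, path) {
  if (inherits(x, "fes")) {
    hdr <- c(paste("# free energy surface, kJ/mol, T =", x$temperature, "K"),
             paste("# xedges:", paste(signif(x$xedges, 8), collapse = " ")),
             paste("# yedges:", paste(signif(x$yedges, 8), collapse = " ")))
    writeLines(hdr, path)
    suppressWarnings(write.table(x$F, path, sep = "\t", append = TRUE,
                                 row.names = FALSE, col.names = FALSE))
  } else {
    writeLines("# contact probability map", path)
    suppressWarnings(write.table(as.matrix(unclass(x)), path, sep = "\t",
                                 append = TRUE, row.names = TRUE,
                                 col.names = NA))
  }
  invisible(path)
}
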