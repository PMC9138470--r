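#' Convert metadynamics bias potentials into statistical weights
#'
#' Each frame of a parallel-bias metadynamics trajectory carries a
#' time-independent bias potential V_PB. The unbiased Boltzmann weight of
#' frame i is
#' \deqn{w_i = \frac{\exp(V_{PB,i}/k_B T)}{\sum_j \exp(V_{PB,j}/k_B T)}}
#' Computed with log-sum-exp stabilisation (the maximum of V/kT is
#' subtracted before exponentiation), so the result is invariant under
#' adding any constant to all bias values and does not overflow for
#' realistic bias magnitudes.
#'
#' @param bias per-frame bias V_PB in kJ/mol, finite.
#' @param temperature temperature in kelvin, > 0.
#' @return An object of class `weight_vector`: list with `w` (normalised
#'   weights), `temperature` and `kB`.
#' @export
compute_weights <- function(bias, temperature = 300) {
  if (length(bias) == 0) stop("empty bias vector")
  if (any(!is.finite(bias))) {
    stop("non-finite bias at frame ", which(!is.finite(bias))[1])
  }
  if (temperature <= 0) stop("temperature must be > 0")
  v <- bias / (KB_KJ_MOL_K * temperature)
  v <- v - max(v)
  w <- exp(v)
  w <- w / sum(w)
  structure(list(w = w, temperature = temperature, kB = KB_KJ_MOL_K),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector> n =", length(x$w),
      " ESS =", round(effective_sample_size(x), 1), "\n")
  invisible(x)
}

.as_weights <- function(weights, n = NULL) {
  w <- if (inherits(weights, "weight_vector")) weights$w else weights
  if (is.null(w)) {
    if (is.null(n)) stop("weights required")
    w <- rep(1 / n, n)
  }
  if (any(w < 0)) stop("negative weight")
  if (abs(sum(w) - 1) > 1e-9) w <- w / sum(w)
  w
}

#' Weighted ensemble average of an observable
#'
#' @param values per-frame values: a vector, or a matrix with one row per
#'   frame (averaged per column).
#' @param weights a `weight_vector` or numeric weights.
#' @return scalar (or per-column vector) weighted mean.
#' @export
weighted_average <- function(values, weights) {
  w <- .as_weights(weights)
  if (is.matrix(values)) {
    if (nrow(values) != length(w)) stop("length mismatch")
    return(colSums(values * w))
  }
  if (length(values) != length(w)) stop("length mismatch")
  sum(values * w)
}

#' Kish effective sample size of a weight vector
#'
#' `1 / sum(w^2)` for normalised weights; ranges from 1 (all weight on a
#' single frame) to `n_frames` (uniform). A diagnostic for how much
#' statistical power survives reweighting.
#'
#' @param weights a `weight_vector` or numeric weights.
#' @return effective number of frames.
#' @export
effective_sample_size <- function(weights) {
  w <- .as_weights(weights)
  1 / sum(w^2)
}

#' Write/read weights as a two-column checkpoint table
#' @param weights a `weight_vector` or numeric weights.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  w <- .as_weights(weights)
  write.table(data.frame(frame = seq_along(w), weight = w), path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  structure(list(w = tab$weight, temperature = NA_real_, kB = KB_KJ_MOL_K),
            class = "weight_vector")
}
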