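#' Information entropy over cluster populations
#'
#' `S = -sum(p_i * log(p_i))` in nats over normalised cluster populations,
#' the heterogeneity measure used throughout this package: 0 for a single
#' cluster, `log(k)` for k equally populated clusters. Zero-population
#' clusters contribute 0 (`0 * log 0 := 0`).
#'
#' @param populations non-negative populations summing to 1 (tolerance
#'   1e-6), or a `cluster_result`.
#' @return entropy in nats.
#' @export
cluster_entropy <- function(populations) {
  if (inherits(populations, "cluster_result")) {
    populations <- populations$populations
  }
  p <- as.numeric(populations)
  if (any(p < 0)) stop("negative population")
  if (abs(sum(p) - 1) > 1e-6) stop("populations must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p))
}

# 2D histogram bin index on (-pi, pi]^2; values outside (numerical noise
# at the boundary) are clamped to the edge bins
.rama_bins <- function(phi, psi, bins) {
  ix <- ceiling((phi + pi) / (2 * pi) * bins)
  iy <- ceiling((psi + pi) / (2 * pi) * bins)
  ix <- pmin(pmax(ix, 1L), bins)
  iy <- pmin(pmax(iy, 1L), bins)
  (ix - 1L) * bins + iy
}

#' Ramachandran (dihedral) entropy of one residue
#'
#' Weighted 2D histogram of (phi, psi) on (-pi, pi]^2 with
#' `bins_per_dim^2` cells, normalised to sum to 1, then
#' `S = -sum(p_ij * log(p_ij))` in nats. Frames with a missing angle are
#' dropped (their weight is renormalised away).
#'
#' @param phi,psi per-frame angles in radians, range (-pi, pi].
#' @param weights optional per-frame weights.
#' @param bins_per_dim bins per dimension (default 100, i.e. a 100 x 100
#'   grid).
#' @return entropy in nats, in `[0, log(bins_per_dim^2)]`; `NA` if all
#'   angles are missing.
#' @export
dihedral_entropy <- function(phi, psi, weights = NULL, bins_per_dim = 100) {
  stopifnot(length(phi) == length(psi), bins_per_dim >= 1)
  w <- .as_weights(weights, length(phi))
  ok <- is.finite(phi) & is.finite(psi)
  if (!any(ok)) return(NA_real_)
  w <- w[ok] / sum(w[ok])
  cell <- .rama_bins(phi[ok], psi[ok], as.integer(bins_per_dim))
  p <- rowsum(w, cell)
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Per-residue dihedral entropy profile
#'
#' @param ensemble a `conf_ensemble`.
#' @param residues residue ids (default all).
#' @param weights optional weights (default ensemble weights).
#' @param bins_per_dim bins per dimension.
#' @return data.frame with columns `resid`, `entropy` (nats; NA where phi
#'   or psi is undefined, e.g. chain termini).
#' @export
dihedral_entropy_profile <- function(ensemble, residues = NULL,
                                     weights = NULL, bins_per_dim = 100) {
  w <- .as_weights(weights %||% ensemble$weights, ensemble$n_frames)
  dih <- backbone_dihedrals(ensemble, residues)
  ent <- vapply(seq_along(dih$residues), function(k) {
    phi <- dih$phi[, k]; psi <- dih$psi[, k]
    if (all(!is.finite(phi)) || all(!is.finite(psi))) return(NA_real_)
    dihedral_entropy(phi, psi, w, bins_per_dim)
  }, numeric(1))
  data.frame(resid = dih$residues, entropy = ent)
}

#' Bootstrap estimate of the cluster-population entropy
#'
#' Draws `n_samples` bootstrap samples of `frames_per_sample` frames with
#' replacement, with probability equal to the statistical weights, from
#' the ensemble; clusters each sample independently (GROMOS at the given
#' cutoff, uniform within-sample weights) and reports the per-sample
#' entropies, their mean, and the 95% percentile band. The RMSD submatrix
#' of each sample is sliced from the full matrix, and duplicated frames
#' are handled exactly through multiplicities, so re-clustering each
#' sample is exact and cheap. A fast approximate mode maps resampled
#' frames onto the whole-ensemble clustering instead of re-clustering.
#'
#' @param ensemble a `conf_ensemble`.
#' @param residues residue ids defining the C-alpha RMSD selection.
#' @param cutoff GROMOS cutoff in nm.
#' @param weights sampling weights (default ensemble weights or uniform).
#' @param n_samples number of bootstrap samples (>= 2).
#' @param frames_per_sample frames drawn per sample.
#' @param seed integer seed recorded in the result.
#' @param mode `"recluster"` (exact) or `"map"` (approximate).
#' @param mat optional precomputed RMSD matrix for these residues.
#' @return An `entropy_estimate`: list with `value` (whole-ensemble
#'   entropy), `samples`, `mean`, `band` (2.5/97.5 percentiles),
#'   `n_bootstrap`, `frames_per_sample`, `cutoff`, `seed`, `mode`.
#' @export
bootstrap_cluster_entropy <- function(ensemble, residues = NULL,
                                      cutoff = 0.15, weights = NULL,
                                      n_samples = 20,
                                      frames_per_sample = 10000,
                                      seed = 1,
                                      mode = c("recluster", "map"),
                                      mat = NULL) {
  mode <- match.arg(mode)
  if (n_samples < 2) stop("n_samples must be >= 2")
  stopifnot(frames_per_sample >= 1)
  w <- .as_weights(weights %||% ensemble$weights, ensemble$n_frames)
  mat <- mat %||% rmsd_matrix(ensemble, residues)
  whole <- gromos_cluster(mat, cutoff, weights = w)
  n <- nrow(mat)
  samples <- with_seed(seed, {
    vapply(seq_len(n_samples), function(s) {
      idx <- sample.int(n, frames_per_sample, replace = TRUE, prob = w)
      tab <- tabulate(idx, n)
      u <- which(tab > 0)
      if (mode == "map") {
        pops <- rowsum(tab[u] / frames_per_sample, whole$assignment[u])
        return(cluster_entropy(as.numeric(pops) / sum(pops)))
      }
      sub <- gromos_cluster(mat[u, u, drop = FALSE], cutoff,
                            counts = tab[u])
      cluster_entropy(sub)
    }, numeric(1))
  })
  structure(
    list(value = cluster_entropy(whole), samples = samples,
         mean = mean(samples),
         band = quantile(samples, c(0.025, 0.975), names = FALSE),
         n_bootstrap = n_samples, frames_per_sample = frames_per_sample,
         cutoff = cutoff, seed = seed, mode = mode),
    class = "entropy_estimate"
  )
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf(
    "<entropy_estimate> S = %.4f nats (bootstrap mean %.4f, 95%% band [%.4f, %.4f], %d x %d frames)\n",
    x$value, x$mean, x$band[1], x$band[2], x$n_bootstrap,
    x$frames_per_sample))
  invisible(x)
}

#' Write an entropy estimate as JSON
#' @param estimate an `entropy_estimate`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_entropy_estimate <- function(estimate, path) {
  jsonlite::write_json(unclass(estimate), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# run code under a local RNG seed without touching the global stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
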