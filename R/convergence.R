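#' Split-half convergence diagnostic for cluster populations
#'
#' Discards the first `discard_fraction` of frames, clusters the whole
#' remaining ensemble once (GROMOS at `cutoff`), then compares each
#' cluster's weighted population between the first and second halves of
#' the retained frames (weights renormalised within each half). Only
#' clusters whose whole-ensemble population reaches `population_floor`
#' are evaluated. A cluster passes when |delta p| is within its
#' tolerance: `3 x` the binomial standard error implied by the effective
#' sample sizes of the halves or, when `n_bootstrap > 0`, the
#' half-width of a weighted-bootstrap 95% band on its population,
#' whichever is larger.
#'
#' @param ensemble a `conf_ensemble`.
#' @param residues residue ids defining the C-alpha RMSD selection.
#' @param cutoff GROMOS cutoff (nm).
#' @param weights per-frame weights (default ensemble weights/uniform).
#' @param discard_fraction fraction of initial frames discarded.
#' @param population_floor minimum whole-ensemble population for a
#'   cluster to be evaluated (default 0.001, i.e. 10 of 10,000 frames).
#' @param mat optional precomputed RMSD matrix (full ensemble).
#' @param n_bootstrap bootstrap resamples for the population band
#'   (0 = binomial SE only).
#' @param seed seed for the bootstrap.
#' @return A `convergence_report`: data.frame `table` (cluster, overall /
#'   first-half / second-half populations, delta, tolerance, evaluated,
#'   converged) plus `clusters` (the `cluster_result`), parameters, and
#'   `converged` (TRUE when every evaluated cluster passes).
#' @export
split_half_convergence <- function(ensemble, residues = NULL,
                                   cutoff = 0.15, weights = NULL,
                                   discard_fraction = 0.10,
                                   population_floor = 10 / 10000,
                                   mat = NULL, n_bootstrap = 0,
                                   seed = 1) {
  stopifnot(discard_fraction >= 0, discard_fraction < 1)
  n <- ensemble$n_frames
  w_all <- .as_weights(weights %||% ensemble$weights, n)
  keep <- seq.int(floor(discard_fraction * n) + 1, n)
  if (length(keep) < 20) stop("fewer than 20 frames after discard")
  mat <- mat %||% rmsd_matrix(ensemble, residues)
  mat <- mat[keep, keep, drop = FALSE]
  w <- w_all[keep] / sum(w_all[keep])
  cl <- gromos_cluster(mat, cutoff, weights = w)
  m <- length(keep)
  first <- seq_len(floor(m / 2))
  second <- seq.int(floor(m / 2) + 1, m)
  pop_in <- function(idx) {
    wi <- w[idx] / sum(w[idx])
    vapply(seq_len(cl$n_clusters),
           function(k) sum(wi[cl$assignment[idx] == k]), numeric(1))
  }
  p1 <- pop_in(first); p2 <- pop_in(second)
  delta <- p2 - p1
  ess1 <- effective_sample_size(w[first] / sum(w[first]))
  ess2 <- effective_sample_size(w[second] / sum(w[second]))
  pbar <- (p1 + p2) / 2
  tol <- 3 * sqrt(pbar * (1 - pbar) * (1 / ess1 + 1 / ess2))
  if (n_bootstrap > 0) {
    bands <- with_seed(seed, {
      reps <- replicate(n_bootstrap, {
        idx <- sample.int(m, m, replace = TRUE, prob = w)
        tabulate(cl$assignment[idx], cl$n_clusters) / m
      })
      apply(reps, 1, function(x) diff(quantile(x, c(0.025, 0.975))) / 2)
    })
    tol <- pmax(tol, bands)
  }
  evaluated <- cl$populations >= population_floor
  converged <- abs(delta) <= tol
  tab <- data.frame(
    cluster = seq_len(cl$n_clusters), population = cl$populations,
    first_half = p1, second_half = p2, delta = delta, tolerance = tol,
    evaluated = evaluated, converged = converged | !evaluated
  )
  structure(
    list(table = tab, clusters = cl, discard_fraction = discard_fraction,
         population_floor = population_floor, n_bootstrap = n_bootstrap,
         seed = seed, converged = all(converged[evaluated])),
    class = "convergence_report"
  )
}

#' @export
print.convergence_report <- function(x, ...) {
  ev <- x$table[x$table$evaluated, ]
  cat("<convergence_report> ", nrow(ev), " of ", nrow(x$table),
      " clusters above floor ", x$population_floor, "; ",
      if (x$converged) "all converged" else
        paste(sum(!ev$converged), "NOT converged"), "\n", sep = "")
  invisible(x)
}

#' Write a convergence report as JSON + TSV
#' @param report a `convergence_report`.
#' @param path base path; writes `<path>.tsv` and `<path>.json`.
#' @return the two paths, invisibly.
#' @export
write_convergence_report <- function(report, path) {
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  write.table(report$table, tsv, sep = "\t", row.names = FALSE,
              quote = FALSE)
  jsonlite::write_json(
    list(converged = report$converged,
         discard_fraction = report$discard_fraction,
         population_floor = report$population_floor,
         n_bootstrap = report$n_bootstrap, seed = report$seed,
         table = report$table),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
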