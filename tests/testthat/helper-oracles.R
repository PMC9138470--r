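# Independent reference implementations used to validate the package's
# fast paths. Deliberately naive; kept free of any package internals.

# exhaustive neighbour-counting clustering (Daura scheme), multiplicity-free
oracle_gromos <- function(mat, cutoff) {
  n <- nrow(mat)
  active <- seq_len(n)
  assign <- integer(n)
  k <- 0
  while (length(active) > 0) {
    nb <- vapply(active, function(i) sum(mat[i, active] < cutoff),
                 numeric(1))
    center <- active[which.max(nb)]          # ties -> lowest frame index
    members <- active[mat[center, active] < cutoff]
    k <- k + 1
    assign[members] <- k
    active <- setdiff(active, members)
  }
  assign
}

# canonical partition labels: clusters numbered by first frame occurrence
canonical_partition <- function(assign) {
  match(assign, unique(assign))
}

# naive O(n^3) agglomerative average-linkage cut at `cutoff`
oracle_average_linkage <- function(mat, cutoff) {
  clusters <- as.list(seq_len(nrow(mat)))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(mat[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    if (best_d > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  assign <- integer(nrow(mat))
  for (k in seq_along(clusters)) assign[clusters[[k]]] <- k
  assign
}

# torsion angle by explicit plane-normal construction for a single
# quadruple of points
oracle_dihedral <- function(p1, p2, p3, p4) {
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cr(n1, n2) * b2) / sqrt(sum(b2^2))
  atan2(y, x)
}

# best rigid-fit RMSD by multi-start optimisation over Euler angles,
# independent of any SVD identity
oracle_min_rmsd <- function(a, b, n_starts = 60) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    matrix(c(cy * cz, cy * sz, -sy,
             sx * sy * cz - cx * sz, sx * sy * sz + cx * cz, sx * cy,
             cx * sy * cz + sx * sz, cx * sy * sz - sx * cz, cx * cy),
           3, 3)
  }
  obj <- function(ang) sqrt(mean(rowSums((ac %*% rot(ang) - bc)^2)))
  best <- Inf
  for (s in seq_len(n_starts)) {
    start <- runif(3, -pi, pi)
    fit <- optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# random symmetric "distance" matrix with zero diagonal
random_dist_matrix <- function(n, scale = 0.3) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0, scale)
  m + t(m)
}
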