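#' Extract one frame as an n_atoms x 3 coordinate matrix (nm)
#' @param ensemble a `conf_ensemble`.
#' @param frame frame index.
#' @return numeric matrix with columns x, y, z.
#' @export
frame_coords <- function(ensemble, frame = 1) {
  matrix(ensemble$xyz[frame, ], ncol = 3, byrow = TRUE)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `reference` over a selection of
#' atoms, returning the proper rotation (det = +1), translation and the
#' minimised RMSD. The fit is the global minimum over rigid transforms.
#'
#' @param mobile,reference `n x 3` coordinate matrices (nm).
#' @param selection atom indices used for the fit (default all). At least
#'   3 non-collinear atoms are required.
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (nm, over the selection) and `coords` (all mobile atoms transformed:
#'   `(x - center_mobile) %*% rotation + center_reference`).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  selection <- selection %||% seq_len(nrow(mobile))
  if (length(selection) < 3) stop("need >= 3 atoms to superpose")
  a <- mobile[selection, , drop = FALSE]
  b <- reference[selection, , drop = FALSE]
  if (nrow(a) != nrow(b)) stop("selections of unequal size")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  sv_a <- svd(ac)$d
  if (sv_a[2] < 1e-10 * max(sv_a[1], 1e-300)) {
    stop("degenerate (collinear) selection; rotation not unique")
  }
  s <- svd(t(ac) %*% bc)
  d <- sign(det(s$u) * det(s$v))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted_sel <- ac %*% rot
  rmsd <- sqrt(mean(rowSums((fitted_sel - bc)^2)))
  coords <- sweep(mobile, 2, ca) %*% rot
  coords <- sweep(coords, 2, cb, "+")
  list(rotation = rot, translation = cb - ca %*% rot, rmsd = rmsd,
       coords = coords)
}

#' Pairwise superposed C-alpha RMSD matrix
#'
#' Entry (i, j) is the RMSD between frames i and j over the C-alpha atoms
#' of the chosen residues, after per-pair optimal superposition on those
#' same atoms (fit-on-self, the convention of the GROMOS clustering tool).
#' Computed in C++.
#'
#' @param ensemble a `conf_ensemble`.
#' @param residues residue ids to use (default: all residues); the
#'   selection is their C-alpha atoms.
#' @return symmetric `n_frames x n_frames` matrix (nm) with attributes
#'   `selection` (atom indices) and `residues`.
#' @export
rmsd_matrix <- function(ensemble, residues = NULL) {
  top <- ensemble$topology
  residues <- residues %||% unique(top$atoms$resid)
  sel <- ca_indices(top, residues)
  if (length(sel) < 3) {
    stop("region has ", length(sel), " CA atoms; need >= 3")
  }
  m <- cpp_rmsd_matrix(ensemble$xyz, as.integer(sel - 1L))
  attr(m, "selection") <- sel
  attr(m, "residues") <- residues
  m
}

# vectorised torsion angle over four n x 3 point sets, IUPAC sign,
# range (-pi, pi]
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross(n1, b2n)
  ang <- atan2(-rowSums(m1 * n2), rowSums(n1 * n2))
  ang[ang <= -pi] <- pi
  ang
}

#' Backbone phi/psi dihedral angles
#'
#' phi(i) is the torsion C(i-1)-N(i)-CA(i)-C(i), psi(i) is
#' N(i)-CA(i)-C(i)-N(i+1). The first residue has no phi and the last no
#' psi; residues with missing backbone atoms yield NA with a warning.
#'
#' @param ensemble a `conf_ensemble`.
#' @param residues residue ids (default all). Neighbouring residues
#'   outside the set are still used to close the torsions.
#' @return list with matrices `phi` and `psi` (`n_frames x n_residues`,
#'   radians in (-pi, pi]) and `residues`.
#' @export
backbone_dihedrals <- function(ensemble, residues = NULL) {
  top <- ensemble$topology
  residues <- sort(residues %||% unique(top$atoms$resid))
  at <- top$atoms
  idx_of <- function(res, name) {
    i <- which(at$resid == res & at$name == name)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  nf <- ensemble$n_frames
  pts <- function(i) {
    matrix(ensemble$xyz[, c(3 * i - 2, 3 * i - 1, 3 * i)],
           nrow = nf, ncol = 3)
  }
  phi <- psi <- matrix(NA_real_, nf, length(residues),
                       dimnames = list(NULL, residues))
  missing_warned <- FALSE
  all_res <- unique(at$resid)
  for (k in seq_along(residues)) {
    r <- residues[k]
    iN <- idx_of(r, "N"); iCA <- idx_of(r, "CA"); iC <- idx_of(r, "C")
    if (anyNA(c(iN, iCA, iC))) { missing_warned <- TRUE; next }
    if ((r - 1) %in% all_res) {
      iCp <- idx_of(r - 1, "C")
      if (!is.na(iCp)) {
        phi[, k] <- .dihedral(pts(iCp), pts(iN), pts(iCA), pts(iC))
      } else missing_warned <- TRUE
    }
    if ((r + 1) %in% all_res) {
      iNn <- idx_of(r + 1, "N")
      if (!is.na(iNn)) {
        psi[, k] <- .dihedral(pts(iN), pts(iCA), pts(iC), pts(iNn))
      } else missing_warned <- TRUE
    }
  }
  if (missing_warned) {
    warning("missing backbone atoms; affected dihedrals reported as NA")
  }
  list(phi = phi, psi = psi, residues = residues)
}

.contact_stats <- function(ensemble, resA, resB, cutoff, min_seq_sep,
                           weights) {
  top <- ensemble$topology
  cpp_contact_stats(
    ensemble$xyz, as.integer(top$atoms$resid), top$atoms$heavy,
    as.integer(sort(resA)), as.integer(sort(resB)),
    cutoff, as.integer(min_seq_sep), weights
  )
}

#' Residue-residue contacts in one frame
#'
#' Two residues are in contact when any pair of their heavy atoms is
#' closer than `cutoff` (strictly below; a pair at exactly the cutoff is
#' not a contact) and their sequence separation is at least `min_seq_sep`
#' (near-neighbours carry no conformational signal and are excluded).
#'
#' @param ensemble a `conf_ensemble`.
#' @param resA,resB residue id vectors of the two regions.
#' @param frame frame index.
#' @param cutoff contact cutoff in nm.
#' @param min_seq_sep minimum |resid difference| for a pair to count.
#' @return logical `|resA| x |resB|` matrix with residue-id dimnames.
#' @export
residue_contacts <- function(ensemble, resA, resB, frame = 1,
                             cutoff = 0.45, min_seq_sep = 2) {
  stopifnot(cutoff > 0)
  resA <- sort(resA); resB <- sort(resB)
  one <- conf_ensemble(ensemble$topology,
                       ensemble$xyz[frame, , drop = FALSE],
                       temperature = ensemble$temperature)
  st <- .contact_stats(one, resA, resB, cutoff, min_seq_sep, 1.0)
  m <- st$freq > 0
  dimnames(m) <- list(resA, resB)
  m
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto the weighted mean structure (two
#' mean/refit iterations) using the C-alpha atoms of `fit_residues`
#' (default: all residues); the RMSF of residue r is the weighted RMS
#' deviation of its C-alpha from the converged mean. Weights are
#' normalised internally, so scaling all weights leaves the result
#' unchanged.
#'
#' @param ensemble a `conf_ensemble`.
#' @param weights optional weights (default ensemble weights or uniform).
#' @param residues residues to report (default all).
#' @param fit_residues residues whose C-alpha atoms define the fit
#'   (typically the scaffold).
#' @return named numeric vector of RMSF values (nm) per residue.
#' @export
rmsf <- function(ensemble, weights = NULL, residues = NULL,
                 fit_residues = NULL) {
  top <- ensemble$topology
  w <- .as_weights(weights %||% ensemble$weights, ensemble$n_frames)
  residues <- sort(residues %||% unique(top$atoms$resid))
  all_ca_res <- sort(unique(top$atoms$resid[top$atoms$name == "CA"]))
  fit_residues <- sort(fit_residues %||% all_ca_res)
  nf <- ensemble$n_frames
  if (nf < 2) {
    warning("single frame: RMSF is zero by construction")
    return(setNames(rep(0, length(residues)), residues))
  }
  ca <- ca_indices(top, all_ca_res)
  fit_sel <- match(ca_indices(top, fit_residues), ca)
  # n_frames x n_ca x 3 via per-frame matrices
  frames <- lapply(seq_len(nf), function(i) frame_coords(ensemble, i)[ca, , drop = FALSE])
  mean_of <- function(fr) Reduce(`+`, Map(`*`, fr, w))
  fitted <- frames
  for (iter in 1:2) {
    m <- mean_of(fitted)
    fitted <- lapply(fitted, function(x) superpose(x, m, fit_sel)$coords)
  }
  m <- mean_of(fitted)
  dev2 <- Reduce(`+`, Map(function(x, wi) wi * rowSums((x - m)^2), fitted, w))
  res_of_ca <- top$atoms$resid[ca]
  out <- sqrt(dev2)[match(residues, res_of_ca)]
  setNames(out, residues)
}
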