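#' Orthonormal rigid-body basis of a structure
#'
#' Three uniform translations plus three infinitesimal rotations about the
#' centroid, orthonormalised. Used to project rigid-body content out of
#' deformation vectors before completeness checks.
#'
#' @param s A `coarse_structure`, `elastic_network` or N x 3 coordinates.
#' @return A 3N x 6 matrix with orthonormal columns.
#' @export
rigid_body_basis <- function(s) {
  coords <- node_coords(s)
  n <- nrow(coords)
  cc <- sweep(coords, 2, colMeans(coords))
  B <- matrix(0, 3 * n, 6)
  for (a in 1:3) B[seq(a, 3 * n, by = 3), a] <- 1
  # infinitesimal rotations: omega x r for omega = ex, ey, ez
  B[, 4] <- as.vector(t(cbind(0, -cc[, 3], cc[, 2])))
  B[, 5] <- as.vector(t(cbind(cc[, 3], 0, -cc[, 1])))
  B[, 6] <- as.vector(t(cbind(-cc[, 2], cc[, 1], 0)))
  qr.Q(qr(B))[, 1:6, drop = FALSE]
}

#' Remove rigid-body content from a 3N displacement vector
#'
#' @param v Numeric 3N vector.
#' @param s Structure or coordinates defining the rigid-body basis.
#' @return The projected vector, orthogonal to all six rigid-body motions.
#' @export
project_out_rigid <- function(v, s) {
  B <- rigid_body_basis(s)
  as.numeric(v - B %*% crossprod(B, v))
}

#' Experimental deformation vector between two conformational states
#'
#' Superposes state `b` onto state `a` over the mapped C-alpha pairs and
#' returns the 3|map| difference vector of mapped C-alpha coordinates
#' (never raw coordinate differences).
#'
#' @param a,b `coarse_structure` objects of the two states.
#' @param map A `correspondence_map` with pairs (a id, b id); default is
#'   the identity map.
#' @return A `deformation_vector`: list with `values` (3|map| Angstrom
#'   displacements), `map`, `a_indices` (residue indices into `a`), and
#'   `rmsd_after_fit`.
#' @export
deformation_vector <- function(a, b, map = NULL) {
  if (is.null(map)) map <- identity_map(a, b)
  idx <- map_indices(map, a, b)
  # superpose b onto a over the mapped pairs
  sub_b <- select_residues(b, indices = idx$b)
  sub_a <- select_residues(a, indices = idx$a)
  sup <- superpose(sub_b, sub_a,
                   new_correspondence_map(sub_b$residues$res_id,
                                          sub_a$residues$res_id))
  b_fit <- apply_superposition(sub_b, sup)
  diff <- b_fit$ca - sub_a$ca
  structure(list(values = as.vector(t(diff)), map = map,
                 a_indices = idx$a, rmsd_after_fit = sup$rmsd),
            class = "deformation_vector")
}

#' @export
print.deformation_vector <- function(x, ...) {
  cat("<deformation_vector> ", length(x$values) / 3, " mapped residues, ",
      "rmsd after fit = ", format(x$rmsd_after_fit, digits = 5), " A\n",
      sep = "")
  invisible(x)
}

as_displacement <- function(v) {
  if (inherits(v, "deformation_vector")) return(v$values)
  as.numeric(v)
}

restrict3 <- function(v, residue_idx) v[expand3(residue_idx)]

#' Overlap (absolute correlation cosine) between two displacement vectors
#'
#' `|u . v| / (|u| |v|)` after optionally restricting the first vector to a
#' residue subset (for comparing assembly modes against a component that
#' lives on fewer residues) and renormalising. The absolute value makes the
#' statistic independent of the arbitrary eigenvector sign.
#'
#' @param u,v Numeric 3N vectors, or a `deformation_vector`.
#' @param restrict Optional integer residue indices: `u` is cut down to
#'   these residues (3-expanded) before comparison.
#' @return Scalar in `[0, 1]`.
#' @export
overlap <- function(u, v, restrict = NULL) {
  u <- as_displacement(u); v <- as_displacement(v)
  if (!is.null(restrict)) u <- restrict3(u, restrict)
  if (length(u) != length(v)) {
    stop("vectors have incompatible lengths (", length(u), " vs ",
         length(v), "); supply a residue restriction", call. = FALSE)
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-norm vector in overlap", call. = FALSE)
  min(abs(sum(u * v)) / (nu * nv), 1)
}

#' Cumulative overlap of the first m modes with a deformation
#'
#' `CO(m) = sqrt(sum_{k<=m} O(u_k, dr)^2)`; reaches 1 at m = 3N-6 once the
#' deformation's rigid-body content has been removed, since the nonzero
#' modes span the internal deformation space completely.
#'
#' @param modes A `mode_set`.
#' @param d A `deformation_vector` or numeric 3N vector.
#' @param m Number of modes to accumulate.
#' @param restrict Optional residue indices restricting each mode vector.
#' @return Scalar `CO(m)` in `[0, 1]`.
#' @export
cumulative_overlap <- function(modes, d, m, restrict = NULL) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (m > length(modes$values)) {
    stop("m exceeds the ", length(modes$values), " retained modes",
         call. = FALSE)
  }
  o <- vapply(seq_len(m), function(k)
    overlap(modes$vectors[, k], d, restrict = restrict), 1)
  sqrt(sum(o^2))
}

#' Per-mode overlaps and the cumulative-overlap curve
#'
#' @inheritParams cumulative_overlap
#' @param m_max Highest mode to include (default: all retained).
#' @return A `co_curve` tibble with columns `mode`, `overlap`, `co`.
#' @export
overlap_curve <- function(modes, d, m_max = length(modes$values),
                          restrict = NULL) {
  o <- vapply(seq_len(m_max), function(k)
    overlap(modes$vectors[, k], d, restrict = restrict), 1)
  out <- tibble::tibble(mode = seq_len(m_max), overlap = o,
                        co = sqrt(cumsum(o^2)))
  class(out) <- c("co_curve", class(out))
  out
}

#' Overlap matrix between two mode sets
#'
#' Entry (k, l) is the absolute correlation cosine between mode k of `A`
#' and mode l of `B`. When `A` lives on a residue superset of `B` (e.g.
#' hexamer modes against isolated-dimer modes), pass `restrict` with the
#' indices of `B`'s residues inside `A`; `A`'s vectors are restricted and
#' renormalised before the inner product.
#'
#' @param A,B `mode_set` objects.
#' @param m,n Numbers of modes of `A` and `B` to compare (defaults: all).
#' @param restrict Optional residue indices of `B`'s nodes within `A`.
#' @return An `overlap_matrix` (m x n numeric matrix subclass) with mode
#'   indices as dimnames.
#' @export
overlap_matrix <- function(A, B, m = length(A$values), n = length(B$values),
                           restrict = NULL) {
  UA <- A$vectors[, seq_len(m), drop = FALSE]
  if (!is.null(restrict)) UA <- UA[expand3(restrict), , drop = FALSE]
  UB <- B$vectors[, seq_len(n), drop = FALSE]
  if (nrow(UA) != nrow(UB)) {
    stop("mode sets have incompatible dimensions (", nrow(UA), " vs ",
         nrow(UB), "); supply a residue restriction", call. = FALSE)
  }
  norms <- sqrt(colSums(UA^2))
  # a superset mode with no amplitude on the restricted residues has no
  # defined direction there: its overlaps are reported as 0
  dead <- norms < 1e-12
  norms[dead] <- 1
  UA <- sweep(UA, 2, norms, "/")
  M <- pmin(abs(crossprod(UA, UB)), 1)
  M[dead, ] <- 0
  dimnames(M) <- list(seq_len(m), seq_len(n))
  structure(M, class = c("overlap_matrix", "matrix", "array"))
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("<overlap_matrix> ", nrow(x), " x ", ncol(x), " modes\n", sep = "")
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' Subspace overlap between two sets of modes
#'
#' Aggregate similarity of the spaces spanned by the first m modes of `A`
#' and the first n modes of `B`:
#' `sqrt( (1/r) * sum_k sum_l O(u_k, v_l)^2 )`, with r the size of the
#' reference set (`"first"` divides by m, `"second"` by n). Equals 1 when
#' the reference space is contained in the other, 0 for orthogonal spaces.
#'
#' @inheritParams overlap_matrix
#' @param reference Which set normalises the double sum (default the
#'   first).
#' @return Scalar in `[0, 1]`.
#' @export
subspace_overlap <- function(A, B, m = length(A$values),
                             n = length(B$values), restrict = NULL,
                             reference = c("first", "second")) {
  reference <- match.arg(reference)
  M <- overlap_matrix(A, B, m = m, n = n, restrict = restrict)
  r <- if (reference == "first") m else n
  sqrt(sum(M^2) / r)
}

#' Weighted linear fit of the mode correspondence in an overlap matrix
#'
#' Fits the assembly-mode index as a function of the component-mode index
#' by weighted least squares over all entries at or above `threshold`,
#' with weights equal to the squared overlap. A perfectly conserved
#' spectrum gives slope magnitude 1; magnitude 2 means each component
#' mode reappears two modes deeper in the assembly spectrum, i.e. half
#' the component modes are unrepresented among the assembly's
#' low-frequency modes. Under the heat-map plotting convention (mode 1 at
#' the top, inverted y axis) the signed slope of the conserved diagonal
#' is -1.
#'
#' @param M An `overlap_matrix` with component modes as rows and assembly
#'   modes as columns.
#' @param threshold Minimum overlap for an entry to enter the fit
#'   (default 0.5).
#' @param intercept Fit the intercept (default) or force it through zero.
#' @return A `slope_fit`: list with `slope` (signed, plotting convention),
#'   `abs_slope`, `intercept`, `n_points`, `threshold` and the underlying
#'   `lm` fit.
#' @export
correspondence_slope <- function(M, threshold = 0.5, intercept = TRUE) {
  idx <- which(M >= threshold, arr.ind = TRUE)
  if (nrow(idx) < 2) {
    stop("fewer than 2 overlap entries at or above ", threshold,
         call. = FALSE)
  }
  df <- data.frame(component = idx[, 1], assembly = idx[, 2],
                   w = M[idx]^2)
  fit <- if (intercept) {
    stats::lm(assembly ~ component, data = df, weights = w)
  } else {
    stats::lm(assembly ~ component + 0, data = df, weights = w)
  }
  cf <- stats::coef(fit)
  raw_slope <- unname(cf[["component"]])
  structure(list(slope = -raw_slope, abs_slope = abs(raw_slope),
                 intercept = if (intercept) unname(cf[[1]]) else 0,
                 n_points = nrow(df), threshold = threshold, fit = fit),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat("<slope_fit> |slope| = ", format(x$abs_slope, digits = 4),
      " over ", x$n_points, " entries >= ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Inter-residue distance variation induced by one mode
#'
#' `D_ij = lambda_k^(-q) * [(u_k)_i - (u_k)_j] . (R_ij / |R_ij|)`:
#' the rate of change of each equilibrium inter-residue distance along mode
#' k, scaled by the inverse frequency (default exponent q = 1/2, since the
#' eigenvalue is the squared frequency). Positive entries are distances
#' that grow, negative entries distances that shrink; a block of zeros over
#' a subunit signals rigid-body motion of that subunit.
#'
#' @param net The `elastic_network` (equilibrium geometry).
#' @param modes A `mode_set`.
#' @param k Mode index.
#' @param exponent Inverse-frequency exponent (0.5 default; 1.0 scales by
#'   1/lambda instead).
#' @return A `distvar_matrix`: symmetric signed N x N matrix, zero
#'   diagonal.
#' @export
distance_variation <- function(net, modes, k, exponent = 0.5) {
  u <- matrix(mode_vector(modes, k), ncol = 3, byrow = TRUE)
  X <- node_coords(net)
  if (nrow(u) != nrow(X)) stop("mode set does not match network size",
                               call. = FALSE)
  # (u_i - u_j).(x_i - x_j) = m_i + m_j - (u_i.x_j + u_j.x_i)
  m1 <- rowSums(u * X)
  cross <- u %*% t(X)
  num <- outer(m1, m1, "+") - (cross + t(cross))
  d <- as.matrix(stats::dist(X))
  diag(d) <- Inf
  D <- num / d / modes$values[k]^exponent
  diag(D) <- 0
  structure(D, class = c("distvar_matrix", "matrix", "array"))
}
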