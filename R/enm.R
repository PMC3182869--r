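#' Build an anisotropic elastic network from C-alpha coordinates
#'
#' Connects every pair of C-alpha nodes within `cutoff` by a Hookean spring
#' of uniform force constant `gamma`, bonded and non-bonded pairs alike.
#'
#' @param s A `coarse_structure` or an N x 3 coordinate matrix (Angstrom).
#' @param cutoff Spring cutoff distance in Angstrom (default 15).
#' @param gamma Uniform force constant (energy/A^2 units, default 1).
#' @return An `elastic_network`: list with `coords` (N x 3), `springs`
#'   (M x 2 integer matrix, i < j), `gamma`, `cutoff` and `res_id` labels.
#' @export
build_network <- function(s, cutoff = 15, gamma = 1) {
  coords <- node_coords(s)
  n <- nrow(coords)
  if (n < 2) stop("an elastic network needs at least 2 nodes", call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  pairs <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  springs <- cbind(i = as.integer(pairs[, 1]), j = as.integer(pairs[, 2]))
  springs <- springs[order(springs[, 1], springs[, 2]), , drop = FALSE]
  structure(list(coords = coords, springs = springs, gamma = gamma,
                 cutoff = cutoff, res_id = rownames(coords)),
            class = "elastic_network")
}

node_coords <- function(s) {
  if (inherits(s, "coarse_structure")) return(s$ca)
  if (inherits(s, "elastic_network")) return(s$coords)
  m <- as.matrix(s)
  if (ncol(m) != 3) stop("coordinates must be N x 3", call. = FALSE)
  m
}

#' @export
print.elastic_network <- function(x, ...) {
  cat("<elastic_network> ", nrow(x$coords), " nodes, ", nrow(x$springs),
      " springs (cutoff ", x$cutoff, " A, gamma ", x$gamma, ")\n", sep = "")
  invisible(x)
}

#' Assemble the ANM Hessian of an elastic network
#'
#' For each spring (i, j) the off-diagonal 3 x 3 superelement is
#' `-(gamma/|Rij|^2) Rij Rij^T` evaluated at the equilibrium geometry; the
#' diagonal superelements are minus the sum of their row's off-diagonal
#' blocks, so uniform translations (and infinitesimal rotations) are exact
#' null vectors.
#'
#' @param net An `elastic_network`.
#' @return A dense symmetric positive-semidefinite 3N x 3N matrix.
#' @export
build_hessian <- function(net) {
  stopifnot(inherits(net, "elastic_network"))
  coords <- net$coords
  n <- nrow(coords)
  H <- matrix(0, 3 * n, 3 * n)
  sp <- net$springs
  for (e in seq_len(nrow(sp))) {
    i <- sp[e, 1]; j <- sp[e, 2]
    rij <- coords[j, ] - coords[i, ]
    d2 <- sum(rij^2)
    if (d2 < 1e-12) {
      stop("coincident nodes connected by a spring: ", i, " and ", j,
           call. = FALSE)
    }
    blk <- -(net$gamma / d2) * tcrossprod(rij)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] + blk
    H[jj, ii] <- H[jj, ii] + blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  H
}

#' ANM potential energy of a displaced conformation
#'
#' Evaluates the full (anharmonic in coordinates, harmonic in distances)
#' network energy `V = (gamma/2) * sum_springs (|Rij| - |Rij0|)^2` of a
#' trial conformation against the network's equilibrium geometry.
#'
#' @param net An `elastic_network`.
#' @param coords N x 3 coordinates of the trial conformation.
#' @return Scalar energy.
#' @export
network_energy <- function(net, coords) {
  coords <- node_coords(coords)
  sp <- net$springs
  d0 <- sqrt(rowSums((net$coords[sp[, 1], ] - net$coords[sp[, 2], ])^2))
  d1 <- sqrt(rowSums((coords[sp[, 1], ] - coords[sp[, 2], ])^2))
  0.5 * net$gamma * sum((d1 - d0)^2)
}

#' Normal modes of an ANM Hessian
#'
#' Dense symmetric eigendecomposition of the Hessian. Eigenvalues at or
#' below `zero_tol` times the largest eigenvalue are counted as rigid-body
#' (zero) modes and discarded; mode numbering starts at 1 with the first
#' nonzero eigenvalue. Eigenvector signs are fixed so the largest-magnitude
#' component of each mode is positive.
#'
#' @param H A 3N x 3N Hessian, or an `elastic_network` (Hessian built
#'   internally).
#' @param n_modes Number of nonzero modes to retain, or `"all"`.
#' @param zero_tol Relative zero-eigenvalue threshold (default 1e-8).
#' @param expected_zero Expected count of zero modes; the default 6 asserts
#'   a connected free-standing network and raises an error (reporting the
#'   connected-component count when the network is available) otherwise.
#'   Use `NA` to accept any count, e.g. for effective-Hessian subsystems.
#' @return A `mode_set`: list with `values` (ascending nonzero eigenvalues),
#'   `vectors` (3N x K matrix of unit eigenvectors), `n_zero`, `n_nodes`.
#' @export
compute_modes <- function(H, n_modes = "all", zero_tol = 1e-8,
                          expected_zero = 6) {
  net <- NULL
  if (inherits(H, "elastic_network")) {
    net <- H
    H <- build_hessian(net)
  }
  stopifnot(nrow(H) == ncol(H), nrow(H) %% 3 == 0)
  eig <- eigen((H + t(H)) / 2, symmetric = TRUE)
  values <- rev(eig$values)
  vectors <- eig$vectors[, rev(seq_len(ncol(eig$vectors))), drop = FALSE]
  thr <- zero_tol * max(values, 0)
  zero <- values <= thr
  n_zero <- sum(zero)
  if (!is.na(expected_zero) && n_zero != expected_zero) {
    extra <- ""
    if (!is.null(net)) {
      nc <- network_components(net)
      extra <- paste0("; network has ", nc, " connected component(s)")
    }
    stop("expected ", expected_zero, " zero modes but found ", n_zero,
         " - the network is likely ",
         if (n_zero > expected_zero) "disconnected" else "over-constrained",
         extra, call. = FALSE)
  }
  values <- values[!zero]
  vectors <- vectors[, !zero, drop = FALSE]
  if (!identical(n_modes, "all")) {
    n_modes <- min(as.integer(n_modes), length(values))
    values <- values[seq_len(n_modes)]
    vectors <- vectors[, seq_len(n_modes), drop = FALSE]
  }
  # sign convention: largest-magnitude component positive
  for (k in seq_len(ncol(vectors))) {
    imax <- which.max(abs(vectors[, k]))
    if (vectors[imax, k] < 0) vectors[, k] <- -vectors[, k]
  }
  if (length(values) > 1) {
    rel <- diff(values) / values[-1]
    if (any(rel < 1e-6)) {
      message("compute_modes: ", sum(rel < 1e-6),
              " near-degenerate eigenvalue pair(s); subspace overlap is the ",
              "robust comparison for those modes")
    }
  }
  structure(list(values = values, vectors = vectors, n_zero = n_zero,
                 n_nodes = nrow(H) / 3),
            class = "mode_set")
}

network_components <- function(net) {
  n <- nrow(net$coords)
  parent <- seq_len(n)
  for (e in seq_len(nrow(net$springs))) {
    a <- net$springs[e, 1]; b <- net$springs[e, 2]
    while (parent[a] != a) a <- parent[a]
    while (parent[b] != b) b <- parent[b]
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), function(x) {
    while (parent[x] != x) x <- parent[x]; x
  }, 1L)
  length(unique(roots))
}

#' Convenience: normal modes straight from a structure
#'
#' @inheritParams build_network
#' @inheritParams compute_modes
#' @return A `mode_set`.
#' @export
anm_modes <- function(s, n_modes = "all", cutoff = 15, gamma = 1,
                      zero_tol = 1e-8) {
  compute_modes(build_network(s, cutoff = cutoff, gamma = gamma),
                n_modes = n_modes, zero_tol = zero_tol)
}

#' @export
print.mode_set <- function(x, ...) {
  cat("<mode_set> ", length(x$values), " nonzero mode(s) over ",
      x$n_nodes, " nodes (", x$n_zero, " zero modes removed)\n", sep = "")
  if (length(x$values) > 0) {
    cat("  lambda: ", paste(format(utils::head(x$values, 5), digits = 4),
                            collapse = ", "),
        if (length(x$values) > 5) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

mode_vector <- function(modes, k) {
  if (k < 1 || k > length(modes$values)) {
    stop("mode index ", k, " outside retained range 1..",
         length(modes$values), call. = FALSE)
  }
  modes$vectors[, k]
}

#' Mean-square fluctuation (mobility) profile from a mode subset
#'
#' Per-residue sum over modes of `|u_k,i|^2 / lambda_k`, the ANM
#' mean-square displacement of residue i contributed by the chosen modes.
#'
#' @param modes A `mode_set`.
#' @param mode_subset Integer mode indices, or `"all"`.
#' @return A tibble with columns `residue` (1..N) and `msf`.
#' @export
ms_fluctuations <- function(modes, mode_subset = "all") {
  if (identical(mode_subset, "all")) mode_subset <- seq_along(modes$values)
  if (length(mode_subset) == 0) stop("empty mode subset", call. = FALSE)
  if (any(mode_subset < 1 | mode_subset > length(modes$values))) {
    stop("mode subset outside retained range", call. = FALSE)
  }
  n <- modes$n_nodes
  prof <- numeric(n)
  for (k in mode_subset) {
    u2 <- matrix(modes$vectors[, k]^2, ncol = 3, byrow = TRUE)
    prof <- prof + rowSums(u2) / modes$values[k]
  }
  tibble::tibble(residue = seq_len(n), msf = prof)
}

#' Cross-correlation of residue displacements in one mode
#'
#' `C_ij = (u_k,i . u_k,j) / lambda_k`; the diagonal holds that mode's
#' per-residue square displacements.
#'
#' @param modes A `mode_set`.
#' @param k Mode index (1 = first nonzero mode).
#' @return A symmetric N x N matrix.
#' @export
cross_correlation <- function(modes, k) {
  u <- matrix(mode_vector(modes, k), ncol = 3, byrow = TRUE)
  tcrossprod(u) / modes$values[k]
}

#' Deform a structure along a normal mode
#'
#' Adds `s_amp * u_k` to the C-alpha coordinates (raw unit eigenvector, so
#' the amplitude is in Angstrom per unit eigenvector component); each
#' residue's heavy atoms ride rigidly with its C-alpha displacement.
#'
#' @param s The `coarse_structure` the modes were computed for.
#' @param modes A `mode_set`.
#' @param k Mode index.
#' @param s_amp Amplitude (e.g. +/-20 for visualisation-scale deformations).
#' @return A new `coarse_structure`.
#' @export
make_conformer <- function(s, modes, k, s_amp) {
  stopifnot(inherits(s, "coarse_structure"))
  if (modes$n_nodes != s$n) stop("mode set does not match structure size",
                                 call. = FALSE)
  disp <- matrix(mode_vector(modes, k), ncol = 3, byrow = TRUE) * s_amp
  heavy <- vector("list", s$n)
  for (i in seq_len(s$n)) {
    heavy[[i]] <- sweep(s$heavy[[i]], 2, disp[i, ], "+")
    rownames(heavy[[i]]) <- rownames(s$heavy[[i]])
  }
  new_coarse_structure(s$residues, s$ca + disp, heavy)
}

#' Locate hinge sites as strict local minima of a mobility profile
#'
#' A residue is a hinge if its profile value is strictly below every other
#' value inside a centred window. Plateau points never qualify, so a flat
#' profile yields no hinges.
#'
#' @param profile Numeric vector, or a tibble with an `msf` column as
#'   returned by [ms_fluctuations()].
#' @param window Odd window width in residues (default 5).
#' @return A tibble with columns `residue` and `value`, deepest minima
#'   first.
#' @export
find_hinges <- function(profile, window = 5) {
  if (is.data.frame(profile)) profile <- profile$msf
  if (window < 3 || window %% 2 == 0) {
    stop("window must be odd and >= 3", call. = FALSE)
  }
  n <- length(profile)
  if (n < window) stop("profile shorter than window", call. = FALSE)
  half <- (window - 1) / 2
  hits <- integer(0)
  # boundary residues (incomplete window) never qualify
  for (i in seq((1 + half), (n - half))) {
    others <- profile[setdiff((i - half):(i + half), i)]
    if (all(profile[i] < others)) hits <- c(hits, i)
  }
  out <- tibble::tibble(residue = hits, value = profile[hits])
  out[order(out$value), ]
}

#' Write a mode set in NMD format (VMD Normal Mode Wizard dialect)
#'
#' @param modes A `mode_set`.
#' @param s The `coarse_structure` (or N x 3 coordinates) the modes belong
#'   to.
#' @param path Output path.
#' @param name Dataset title written to the header.
#' @return `path`, invisibly.
#' @export
write_nmd <- function(modes, s, path, name = "oligodyn") {
  coords <- node_coords(s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("title", name), con)
  writeLines(paste("coordinates",
                   paste(format(as.vector(t(coords)), trim = TRUE),
                         collapse = " ")), con)
  for (k in seq_along(modes$values)) {
    writeLines(paste("mode", k, format(modes$values[k], trim = TRUE),
                     paste(format(modes$vectors[, k], trim = TRUE),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Write modes as TSV (one row per mode: index, eigenvalue, 3N components)
#'
#' @inheritParams write_nmd
#' @export
write_modes_tsv <- function(modes, path) {
  m <- cbind(mode = seq_along(modes$values), eigenvalue = modes$values,
             t(modes$vectors))
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = c("mode", "eigenvalue",
                                   paste0("c", seq_len(nrow(modes$vectors)))),
                     quote = FALSE)
  invisible(path)
}

#' Write a per-residue profile as two-column TSV
#'
#' @param profile Tibble with columns `residue` (or `res_id`) and a value
#'   column.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
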