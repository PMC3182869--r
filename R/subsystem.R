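#' Partition network nodes into subsystem and environment
#'
#' @param n_nodes Total node count of the network the partition refers to.
#' @param subsystem Integer residue indices of the subsystem S; the
#'   environment E is the complement.
#' @return A `partition`: list with integer `S` and `E`.
#' @export
make_partition <- function(n_nodes, subsystem) {
  subsystem <- sort(unique(as.integer(subsystem)))
  if (length(subsystem) == 0) stop("subsystem must be nonempty",
                                   call. = FALSE)
  if (any(subsystem < 1 | subsystem > n_nodes)) {
    stop("subsystem index out of range 1..", n_nodes, call. = FALSE)
  }
  E <- setdiff(seq_len(n_nodes), subsystem)
  if (length(E) == 0) stop("environment is empty: the partition must leave ",
                           "at least one environment node", call. = FALSE)
  structure(list(S = subsystem, E = E), class = "partition")
}

#' Partition a subsystem out of a structure by chain
#'
#' @param s A `coarse_structure`.
#' @param chains Chain ids forming the subsystem.
#' @return A `partition` over the residues of `s`.
#' @export
chain_partition <- function(s, chains) {
  stopifnot(inherits(s, "coarse_structure"))
  missing_ch <- setdiff(chains, unique(s$residues$chain))
  if (length(missing_ch) > 0) {
    stop("chain not present: ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  make_partition(s$n, which(s$residues$chain %in% chains))
}

expand3 <- function(idx) as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))

#' Split a Hessian into subsystem/environment blocks
#'
#' @param H A 3N x 3N Hessian.
#' @param p A `partition`.
#' @return List with `H_SS`, `H_SE`, `H_ES`, `H_EE` (3-expanded blocks).
#' @export
partition_hessian <- function(H, p) {
  stopifnot(inherits(p, "partition"))
  n <- nrow(H) / 3
  if (max(c(p$S, p$E)) > n) stop("partition exceeds Hessian size",
                                 call. = FALSE)
  if (length(intersect(p$S, p$E)) > 0) stop("S and E overlap", call. = FALSE)
  s3 <- expand3(p$S); e3 <- expand3(p$E)
  list(H_SS = H[s3, s3, drop = FALSE], H_SE = H[s3, e3, drop = FALSE],
       H_ES = H[e3, s3, drop = FALSE], H_EE = H[e3, e3, drop = FALSE])
}

#' Effective Hessian of a subsystem in an energy-minimizing environment
#'
#' Schur complement `H_SS - H_SE H_EE^-1 H_ES`, the quadratic form governing
#' subsystem displacements when the environment relaxes to minimise the
#' total elastic energy at every subsystem configuration. `H_EE` is
#' inverted by eigendecomposition pseudo-inverse so that internal rigid
#' freedoms of the environment (exact null directions) are handled exactly.
#'
#' @param H A 3N x 3N Hessian.
#' @param p A `partition`.
#' @param tol Relative pseudo-inverse cutoff on `H_EE` eigenvalues
#'   (default 1e-10).
#' @return The 3|S| x 3|S| effective Hessian (symmetric PSD).
#' @export
effective_hessian <- function(H, p, tol = 1e-10) {
  blocks <- partition_hessian(H, p)
  if (all(blocks$H_SE == 0)) return(blocks$H_SS)
  ee <- eigen((blocks$H_EE + t(blocks$H_EE)) / 2, symmetric = TRUE)
  lam_max <- max(ee$values, 0)
  keep <- ee$values > tol * lam_max
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message("effective_hessian: pseudo-inverse dropped ", n_drop,
            " near-null environment direction(s) (relative cutoff ", tol, ")")
  }
  small <- ee$values[keep] / lam_max
  if (any(small < 1e-12)) {
    warning("H_EE is ill-conditioned (condition estimate ",
            format(1 / min(small), digits = 3),
            "); effective Hessian may be inaccurate", call. = FALSE)
  }
  Vk <- ee$vectors[, keep, drop = FALSE]
  # H_SE V diag(1/lambda) V' H_ES, kept symmetric by construction
  W <- blocks$H_SE %*% Vk
  Ht <- blocks$H_SS - W %*% (t(W) / ee$values[keep])
  (Ht + t(Ht)) / 2
}

#' Normal modes of a subsystem coupled to its oligomeric environment
#'
#' Eigendecomposition of the effective Hessian. Unlike a free-standing
#' network the subsystem may retain anywhere between 0 and 6 rigid-body
#' freedoms (6 when the coupling vanishes, 0 when the environment pins all
#' rigid motion), so no fixed zero-mode count is asserted; near-zero modes
#' are filtered with the same relative threshold as [compute_modes()] and
#' numbering restarts at 1.
#'
#' @param H A 3N x 3N Hessian of the full assembly, or an
#'   `elastic_network` of it.
#' @param p A `partition` (subsystem indices refer to the full network).
#' @param n_modes Number of nonzero modes to keep, or `"all"`.
#' @param zero_tol Relative zero-mode threshold.
#' @param tol Pseudo-inverse cutoff passed to [effective_hessian()].
#' @return A `mode_set` over the 3|S| subsystem coordinates.
#' @export
subsystem_modes <- function(H, p, n_modes = "all", zero_tol = 1e-8,
                            tol = 1e-10) {
  if (inherits(H, "elastic_network")) H <- build_hessian(H)
  Ht <- effective_hessian(H, p, tol = tol)
  compute_modes(Ht, n_modes = n_modes, zero_tol = zero_tol,
                expected_zero = NA)
}
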