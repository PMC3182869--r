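#' Specification for a synthetic oligomer
#'
#' Describes a ring-shaped (Cn) or dihedral (alternating-orientation)
#' oligomer of identical protomers, with a target density of
#' inter-protomer springs and pseudo heavy-atom decoration for contact
#' counting. Generation is bit-reproducible under `seed`.
#'
#' @param n_protomers Number of subunits (>= 1).
#' @param protomer_size Residues per protomer (>= 10).
#' @param symmetry `"ring"` (Cn rotation about z) or `"dihedral"`
#'   (alternate protomers flipped about their radial axis, a
#'   dimer-of-trimers-like packing for even n).
#' @param interface_density Target fraction of springs that cross
#'   protomer boundaries, in `[0, 0.5]`; the realised fraction is tuned to
#'   within +/-20%.
#' @param seed RNG seed.
#' @param atoms_per_residue Integer range (min, max) of pseudo heavy atoms
#'   decorating each residue, the C-alpha included in the count.
#' @return An `oligomer_spec` list.
#' @export
oligomer_spec <- function(n_protomers = 6, protomer_size = 40,
                          symmetry = c("ring", "dihedral"),
                          interface_density = 0.05, seed = 1,
                          atoms_per_residue = c(4, 9)) {
  symmetry <- match.arg(symmetry)
  stopifnot(n_protomers >= 1, protomer_size >= 10,
            interface_density >= 0, interface_density <= 0.5,
            length(atoms_per_residue) == 2,
            atoms_per_residue[1] >= 1,
            atoms_per_residue[2] >= atoms_per_residue[1])
  structure(list(n_protomers = as.integer(n_protomers),
                 protomer_size = as.integer(protomer_size),
                 symmetry = symmetry,
                 interface_density = interface_density,
                 seed = as.integer(seed),
                 atoms_per_residue = as.integer(atoms_per_residue)),
            class = "oligomer_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# compact self-avoiding C-alpha walk: consecutive spacing ~3.8 A, no pair
# closer than 3 A, drift bias toward the running centroid keeps it globular
protomer_trace <- function(n_res, max_restarts = 50) {
  for (attempt in seq_len(max_restarts)) {
    coords <- matrix(NA_real_, n_res, 3)
    coords[1, ] <- c(0, 0, 0)
    dir <- c(1, 0, 0)
    ok <- TRUE
    for (i in 2:n_res) {
      placed <- FALSE
      for (try in 1:60) {
        centroid <- colMeans(coords[seq_len(i - 1), , drop = FALSE])
        bias <- centroid - coords[i - 1, ]
        nb <- sqrt(sum(bias^2))
        bias <- if (nb > 1e-6) bias / nb else c(0, 0, 0)
        step <- dir + 0.9 * stats::rnorm(3) + 0.35 * bias
        step <- step / sqrt(sum(step^2)) * stats::runif(1, 3.6, 4.0)
        cand <- coords[i - 1, ] + step
        d2 <- rowSums(sweep(coords[seq_len(i - 1), , drop = FALSE],
                            2, cand)^2)
        # only non-consecutive neighbours must stay 3 A away
        if (i > 2 && any(d2[seq_len(i - 2)] < 9)) next
        coords[i, ] <- cand
        dir <- step / sqrt(sum(step^2))
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(coords)
  }
  stop("could not generate a self-avoiding protomer trace", call. = FALSE)
}

#' Generate one synthetic protomer
#'
#' A compact self-avoiding C-alpha trace (consecutive spacing in
#' [3.6, 4.0] A, no non-bonded pair under 3 A) decorated with pseudo heavy
#' atoms placed within 2 A of each C-alpha. Chain id "A".
#'
#' @param spec An `oligomer_spec`.
#' @return A `coarse_structure`.
#' @export
make_protomer <- function(spec) {
  stopifnot(inherits(spec, "oligomer_spec"))
  with_seed(spec$seed, {
    ca <- protomer_trace(spec$protomer_size)
    decorate_structure(ca, chain = "A", spec$atoms_per_residue)
  })
}

decorate_structure <- function(ca, chain, atoms_per_residue) {
  n <- nrow(ca)
  heavy <- vector("list", n)
  for (i in seq_len(n)) {
    n_at <- sample(atoms_per_residue[1]:atoms_per_residue[2], 1)
    pts <- ca[i, , drop = FALSE]
    if (n_at > 1) {
      u <- matrix(stats::rnorm(3 * (n_at - 1)), ncol = 3)
      u <- u / sqrt(rowSums(u^2)) * stats::runif(n_at - 1, 0.8, 2.0)
      pts <- rbind(pts, sweep(u, 2, ca[i, ], "+"))
    }
    rownames(pts) <- c("CA", if (n_at > 1) paste0("Q", seq_len(n_at - 1)))
    heavy[[i]] <- pts
  }
  res <- tibble::tibble(chain = rep(chain, n), resno = seq_len(n),
                        insert = "", resid = "GLY",
                        res_id = res_id_string(chain, seq_len(n),
                                               rep("", n)))
  new_coarse_structure(res, ca, heavy)
}

place_protomers <- function(ca0, n, radius, symmetry, spin = c(0, 0)) {
  # protomer centred at origin, optionally spun about its own y then x
  # axis to reshape the contact patch, shifted radially, copies rotated
  # about z
  centred <- sweep(ca0, 2, colMeans(ca0))
  if (any(spin != 0)) {
    ay <- spin[1]; ax <- spin[2]
    ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0,
                   sin(ay), 0, cos(ay)), 3)
    rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3)
    centred <- centred %*% t(ry) %*% t(rx)
  }
  out <- vector("list", n)
  for (p in seq_len(n)) {
    m <- centred
    if (symmetry == "dihedral" && p %% 2 == 0) {
      # flip alternate protomers 180 degrees about the (local) x axis
      m[, 2] <- -m[, 2]; m[, 3] <- -m[, 3]
    }
    m <- sweep(m, 2, c(radius, 0, 0), "+")
    th <- 2 * pi * (p - 1) / n
    rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
    out[[p]] <- m %*% t(rot)
  }
  out
}

# a sound assembly has exactly the 6 rigid-body zero modes; extra exact
# zeros are internal mechanisms (e.g. ball-joint-like interfaces)
assembly_is_rigid <- function(placed, cutoff) {
  net <- build_network(do.call(rbind, placed), cutoff = cutoff)
  ev <- eigen(build_hessian(net), symmetric = TRUE,
              only.values = TRUE)$values
  sum(ev <= 1e-8 * max(ev)) == 6
}

interface_fraction <- function(placed, cutoff) {
  coords <- do.call(rbind, placed)
  prot <- rep(seq_along(placed), vapply(placed, nrow, 1L))
  d <- as.matrix(stats::dist(coords))
  sel <- upper.tri(d) & d <= cutoff
  total <- sum(sel)
  if (total == 0) return(c(frac = NA, total = 0))
  inter <- sum(sel & outer(prot, prot, "!="))
  c(frac = inter / total, total = total)
}

#' Assemble a synthetic oligomer with a target interface density
#'
#' Places `n_protomers` copies of one protomer on a ring about the z axis
#' and tunes the ring radius until the realised fraction of inter-protomer
#' springs (15 A network cutoff) is within +/-20% of
#' `spec$interface_density`. Chains are labelled A, B, C, ...
#' `interface_density = 0` places the protomers beyond spring range, which
#' yields a deliberately disconnected network.
#'
#' @param spec An `oligomer_spec`.
#' @param cutoff Spring cutoff used for the density tuning (default 15 A).
#' @return A `coarse_structure` of the full assembly.
#' @export
assemble_oligomer <- function(spec, cutoff = 15) {
  stopifnot(inherits(spec, "oligomer_spec"))
  with_seed(spec$seed, {
    ca0 <- protomer_trace(spec$protomer_size)
    n <- spec$n_protomers
    diam <- max(stats::dist(ca0))
    if (n == 1) {
      placed <- list(sweep(ca0, 2, colMeans(ca0)))
    } else if (spec$interface_density == 0) {
      placed <- place_protomers(ca0, n, radius = 3 * diam + 10 * cutoff,
                                symmetry = spec$symmetry)
    } else {
      target <- spec$interface_density
      placed <- NULL
      # outer loop re-spins the protomer if a candidate assembly has
      # floppy mechanisms (interface patch too point-like to be rigid)
      golden <- 2 * pi * 0.381966
      spin_grid <- as.matrix(expand.grid(golden * 0:7, (pi / 4) * 0:7))
      for (g in seq_len(nrow(spin_grid))) {
        spin <- spin_grid[g, ]
        cand <- NULL
        # fraction decreases monotonically (noisily) with radius: bisect
        lo <- diam * 0.2; hi <- 4 * diam + 2 * cutoff
        for (iter in 1:60) {
          mid <- (lo + hi) / 2
          pl <- place_protomers(ca0, n, mid, spec$symmetry, spin = spin)
          fr <- interface_fraction(pl, cutoff)["frac"]
          if (is.na(fr)) fr <- 0
          if (abs(fr - target) <= 0.2 * target) { cand <- pl; break }
          if (fr > target) lo <- mid else hi <- mid
        }
        if (is.null(cand)) next
        if (assembly_is_rigid(cand, cutoff)) { placed <- cand; break }
      }
      if (is.null(placed)) {
        stop("could not reach interface density ", target,
             " with a mechanism-free assembly", call. = FALSE)
      }
    }
    chains <- LETTERS[seq_len(n)]
    parts <- vector("list", n)
    for (p in seq_len(n)) {
      parts[[p]] <- decorate_structure(placed[[p]], chains[p],
                                       spec$atoms_per_residue)
    }
    bind_structures(parts)
  })
}

bind_structures <- function(parts) {
  res <- do.call(rbind, lapply(parts, function(s) s$residues))
  ca <- do.call(rbind, lapply(parts, function(s) s$ca))
  heavy <- do.call(c, lapply(parts, function(s) s$heavy))
  new_coarse_structure(res, ca, heavy)
}

#' Two-chain fixture with a contact-rich interface
#'
#' Builds a dimer of two roughly helical strands running side by side,
#' close enough (default 5 A axis separation) that heavy-atom contacts
#' within 4 A knit the two chains together along their whole length - the
#' interlocked-interface situation needed to exercise the communication
#' model. Chains "A" and "B".
#'
#' @param n_per_chain Residues per chain.
#' @param separation Distance between the two strand axes (A).
#' @param seed RNG seed for the heavy-atom decoration.
#' @param atoms_per_residue Heavy atoms per residue (range, C-alpha
#'   included).
#' @return A `coarse_structure`.
#' @export
make_interlocked_dimer <- function(n_per_chain = 20, separation = 8,
                                   seed = 1, atoms_per_residue = c(4, 9)) {
  with_seed(seed, {
    t <- seq_len(n_per_chain)
    # coarse helix: 1.5 A rise, 2.3 A radius, ~100 degrees per residue,
    # so consecutive C-alphas sit ~3.8 A apart as in a real backbone
    helix <- cbind(2.3 * cos(1.745 * t), 2.3 * sin(1.745 * t), 1.5 * t)
    a <- decorate_structure(helix, "A", atoms_per_residue)
    b_ca <- helix
    b_ca[, 1] <- -b_ca[, 1] + separation  # mirrored partner strand
    b <- decorate_structure(b_ca, "B", atoms_per_residue)
    bind_structures(list(a, b))
  })
}

#' Build a second conformer by deforming along known modes plus noise
#'
#' Ground-truth generator for deformation-recovery tests: displaces the
#' C-alphas by `sum_k c_k u_k` plus isotropic noise that is projected
#' orthogonal to the recipe modes and to the six rigid-body motions and
#' then scaled to `noise_frac` times the norm of the signal, so recovery
#' statistics have exact closed forms (e.g. single-mode overlap
#' `1/sqrt(1 + noise_frac^2)` for a one-mode recipe).
#'
#' @param s The reference `coarse_structure`.
#' @param modes Its `mode_set`.
#' @param recipe Named or two-column specification of (mode index,
#'   coefficient): a list of `c(mode, coeff)` pairs or a numeric vector
#'   with names as mode indices.
#' @param noise_frac Noise norm as a fraction of the signal norm, in
#'   `[0, 1)`.
#' @param seed RNG seed for the noise.
#' @return The displaced `coarse_structure`.
#' @export
make_deformation <- function(s, modes, recipe, noise_frac = 0, seed = 1) {
  stopifnot(inherits(s, "coarse_structure"), inherits(modes, "mode_set"),
            noise_frac >= 0, noise_frac < 1)
  if (is.list(recipe)) {
    ks <- vapply(recipe, function(x) x[1], 1)
    cs <- vapply(recipe, function(x) x[2], 1)
  } else {
    ks <- as.numeric(names(recipe)); cs <- as.numeric(recipe)
  }
  if (any(ks < 1 | ks > length(modes$values))) {
    stop("recipe mode index outside retained range", call. = FALSE)
  }
  U <- modes$vectors[, ks, drop = FALSE]
  disp <- as.numeric(U %*% cs)
  if (noise_frac > 0) {
    noise <- with_seed(seed, stats::rnorm(length(disp)))
    noise <- noise - U %*% crossprod(U, noise)
    noise <- project_out_rigid(noise, s)
    noise <- noise / sqrt(sum(noise^2)) * noise_frac * sqrt(sum(disp^2))
    disp <- disp + noise
  }
  dm <- matrix(disp, ncol = 3, byrow = TRUE)
  heavy <- vector("list", s$n)
  for (i in seq_len(s$n)) {
    heavy[[i]] <- sweep(s$heavy[[i]], 2, dm[i, ], "+")
    rownames(heavy[[i]]) <- rownames(s$heavy[[i]])
  }
  new_coarse_structure(s$residues, s$ca + dm, heavy)
}
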