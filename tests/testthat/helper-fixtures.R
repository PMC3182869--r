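# Fixture builders shared across the suite. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# random point cloud with a minimum pairwise separation, as a bare matrix
random_points <- function(n, box = 30, min_sep = 3.2, seed = 1) {
  set.seed(seed)
  pts <- matrix(NA_real_, n, 3)
  k <- 0
  while (k < n) {
    cand <- stats::runif(3, 0, box)
    if (k == 0 ||
        min(sqrt(rowSums(sweep(pts[seq_len(k), , drop = FALSE], 2,
                               cand)^2))) >= min_sep) {
      k <- k + 1
      pts[k, ] <- cand
    }
  }
  pts
}

# coarse structure straight from coordinates; heavy atoms default to the
# C-alpha alone unless per-residue atom matrices are supplied
structure_from_coords <- function(coords, chain = "A", heavy = NULL,
                                  resno = seq_len(nrow(coords))) {
  n <- nrow(coords)
  if (is.null(heavy)) {
    heavy <- lapply(seq_len(n), function(i) {
      m <- coords[i, , drop = FALSE]
      rownames(m) <- "CA"
      m
    })
  }
  res <- tibble::tibble(chain = rep(chain, n), resno = resno, insert = "",
                        resid = "GLY",
                        res_id = paste(chain, resno, sep = ":"))
  oligodyn:::new_coarse_structure(res, coords, heavy)
}

# compact random elastic network with exactly 6 zero modes (dense enough
# that no node is underconstrained; retries seeds if needed)
random_network <- function(n, seed = 1, box = 14, cutoff = 15) {
  for (s in seed + 0:20) {
    net <- build_network(random_points(n, box = box, seed = s),
                         cutoff = cutoff)
    ms <- tryCatch(compute_modes(net), error = function(e) NULL)
    if (!is.null(ms)) return(list(net = net, modes = ms))
  }
  stop("no connected network found")
}

# minimal hand-written PDB text (3 residues, one with an altloc pair)
write_mini_pdb <- function(path, altloc = FALSE) {
  fmt <- function(serial, name, alt, resno, x, y, z, occ) {
    sprintf("ATOM  %5d  %-3s%1sGLY A%4d    %8.3f%8.3f%8.3f%6.2f  0.00           %s",
            serial, name, alt, resno, x, y, z, occ,
            substr(name, 1, 1))
  }
  lines <- c(
    fmt(1, "N", " ", 1, 0, 0, 0, 1),
    fmt(2, "CA", " ", 1, 1.5, 0, 0, 1),
    fmt(3, "C", " ", 1, 2.2, 1.2, 0, 1),
    if (altloc) fmt(4, "CA", "A", 2, 5.4, 0, 0, 0.4),
    if (altloc) fmt(5, "CA", "B", 2, 5.0, 0, 0, 0.6),
    if (!altloc) fmt(4, "CA", " ", 2, 5.0, 0, 0, 1),
    fmt(6, "CA", " ", 3, 8.6, 0.5, 0, 1),
    fmt(7, "CB", " ", 3, 9.1, 1.9, 0, 1),
    "END")
  writeLines(lines, path)
  path
}

# hand-constructed mode_set wrapper for synthetic displacement fields
fake_mode_set <- function(vectors, values = rep(1, ncol(vectors))) {
  vectors <- as.matrix(vectors)
  vectors <- sweep(vectors, 2, sqrt(colSums(vectors^2)), "/")
  structure(list(values = values, vectors = vectors, n_zero = 0,
                 n_nodes = nrow(vectors) / 3),
            class = "mode_set")
}
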