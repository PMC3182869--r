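# Independent oracles. Each one re-derives a quantity by a different route
# than the implementation under test (quaternion superposition, numerical
# differentiation, exhaustive enumeration, igraph shortest paths).

# Horn's quaternion method for optimal rigid superposition of X onto Y
quaternion_superpose_rmsd <- function(X, Y) {
  xc <- colMeans(X); yc <- colMeans(Y)
  A <- sweep(X, 2, xc); B <- sweep(Y, 2, yc)
  M <- crossprod(A, B)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  fitted <- A %*% t(R)
  sqrt(mean(rowSums((fitted - B)^2)))
}

# Hessian by central-difference second derivatives of the network energy
numeric_hessian <- function(net, h = 1e-5) {
  coords0 <- net$coords
  n3 <- 3 * nrow(coords0)
  en <- function(x) network_energy(net, matrix(x, ncol = 3, byrow = TRUE))
  x0 <- as.vector(t(coords0))
  H <- matrix(0, n3, n3)
  for (a in seq_len(n3)) {
    for (b in a:n3) {
      xpp <- x0; xpp[a] <- xpp[a] + h; xpp[b] <- xpp[b] + h
      xpm <- x0; xpm[a] <- xpm[a] + h; xpm[b] <- xpm[b] - h
      xmp <- x0; xmp[a] <- xmp[a] - h; xmp[b] <- xmp[b] + h
      xmm <- x0; xmm[a] <- xmm[a] - h; xmm[b] <- xmm[b] - h
      H[a, b] <- (en(xpp) - en(xpm) - en(xmp) + en(xmm)) / (4 * h^2)
      H[b, a] <- H[a, b]
    }
  }
  H
}

# brute-force residue-residue contact counts over all atom pairs
brute_force_affinity <- function(s, cutoff = 4) {
  n <- s$n
  A <- matrix(0, n, n)
  ni <- vapply(s$heavy, nrow, 1L)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      nij <- 0
      for (p in seq_len(ni[i])) {
        for (q in seq_len(ni[j])) {
          d <- sqrt(sum((s$heavy[[i]][p, ] - s$heavy[[j]][q, ])^2))
          if (d <= cutoff + 1e-9) nij <- nij + 1
        }
      }
      if (nij > 0) {
        A[i, j] <- nij / sqrt(ni[i] * ni[j])
        A[j, i] <- A[i, j]
      }
    }
  }
  dimnames(A) <- list(s$residues$res_id, s$residues$res_id)
  A
}

# exhaustive enumeration of all simple paths, scored by likelihood product
enumerate_best_path <- function(net, source, target) {
  n <- length(net$density)
  best <- list(lik = -Inf, path = NULL)
  visit <- function(path, lik) {
    u <- path[length(path)]
    if (u == target) {
      if (lik > best$lik + 1e-12 ||
          (abs(lik - best$lik) <= 1e-12 &&
           oligodyn:::lex_less(path, best$path))) {
        best <<- list(lik = lik, path = path)
      }
      return(invisible(NULL))
    }
    for (v in which(net$transition[, u] > 0)) {
      if (v %in% path) next
      visit(c(path, v), lik * net$transition[v, u])
    }
  }
  visit(source, 1)
  best
}

# igraph directed shortest path as an independent Dijkstra
igraph_path <- function(net, source, target) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$from, to = net$edges$to,
               weight = net$edges$length),
    directed = TRUE,
    vertices = data.frame(name = seq_along(net$density)))
  sp <- igraph::shortest_paths(g, from = as.character(source),
                               to = as.character(target), mode = "out",
                               output = "vpath")
  as.integer(names(sp$vpath[[1]]))
}
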