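#' Residue-residue affinity matrix from heavy-atom contacts
#'
#' `a_ij = N_ij / sqrt(N_i * N_j)`, where `N_ij` counts heavy-atom pairs
#' (one atom from residue i, one from residue j) within `atom_cutoff` and
#' `N_i` is the number of heavy atoms of residue i. Hydrogens and HETATM
#' records never reach this stage (they are removed on reading). Residues
#' with zero heavy atoms are excluded with a warning.
#'
#' @param s A `coarse_structure` with heavy atoms attached.
#' @param atom_cutoff Atom-atom contact cutoff in Angstrom (default 4).
#' @return A symmetric affinity matrix with `res_id` dimnames and zero
#'   diagonal.
#' @export
affinity_matrix <- function(s, atom_cutoff = 4) {
  stopifnot(inherits(s, "coarse_structure"))
  n_atoms <- vapply(s$heavy, nrow, 1L)
  keep <- n_atoms > 0
  if (any(!keep)) {
    warning("excluding ", sum(!keep), " residue(s) with no heavy atoms",
            call. = FALSE)
  }
  ids <- s$residues$res_id[keep]
  heavy <- s$heavy[keep]
  n <- length(heavy)
  ni <- n_atoms[keep]
  # candidate residue pairs: C-alphas closer than cutoff + both atom radii
  radius <- vapply(seq_len(n), function(i) {
    max(sqrt(rowSums(sweep(heavy[[i]], 2, s$ca[keep, , drop = FALSE][i, ])^2)))
  }, 1)
  ca <- s$ca[keep, , drop = FALSE]
  dca <- as.matrix(stats::dist(ca))
  reach <- outer(radius, radius, "+") + atom_cutoff
  cand <- which(upper.tri(dca) & dca <= reach, arr.ind = TRUE)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  cut2 <- atom_cutoff^2
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    ai <- heavy[[i]]; aj <- heavy[[j]]
    d2 <- outer(rowSums(ai^2), rowSums(aj^2), "+") - 2 * ai %*% t(aj)
    nij <- sum(d2 <= cut2 + 1e-9)
    if (nij > 0) {
      a <- nij / sqrt(ni[i] * ni[j])
      A[i, j] <- a; A[j, i] <- a
    }
  }
  A
}

#' Markov model of inter-residue communication
#'
#' From a symmetric affinity matrix builds the contact densities
#' `d_j = sum_i a_ij`, the column-stochastic transition matrix
#' `m_ij = a_ij / d_j` (probability of passing a signal from residue j to
#' residue i in one step), and `-log(m_ij)` edge lengths so that shortest
#' paths are maximum-likelihood paths. Isolated residues (d_j = 0) are
#' excluded with a warning.
#'
#' @param affinity Symmetric nonnegative matrix with zero diagonal, e.g.
#'   from [affinity_matrix()].
#' @return A `markov_network`: list with `affinity`, `density`,
#'   `transition`, `edges` (tibble `from`, `to`, `affinity`, `length` for
#'   directed edges j -> i), and `res_id`.
#' @export
markov_model <- function(affinity) {
  affinity <- as.matrix(affinity)
  if (max(abs(affinity - t(affinity))) > 1e-9) {
    stop("affinity matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(affinity) != 0)) stop("affinity diagonal must be zero",
                                     call. = FALSE)
  if (any(affinity < 0)) stop("affinities must be nonnegative",
                              call. = FALSE)
  d <- colSums(affinity)
  iso <- d == 0
  if (any(iso)) {
    warning("excluding ", sum(iso), " isolated residue(s) from the graph",
            call. = FALSE)
    affinity <- affinity[!iso, !iso, drop = FALSE]
    d <- d[!iso]
  }
  trans <- sweep(affinity, 2, d, "/")
  nz <- which(affinity > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = nz[, 2], to = nz[, 1],
    affinity = affinity[nz],
    length = -log(trans[nz]))
  if (any(edges$length <= 0)) {
    # m_ij = 1 only for a single-neighbour donor; zero-length edge flagged
    message("markov_model: ", sum(edges$length <= 0),
            " deterministic (probability-1) edge(s) with zero length")
  }
  structure(list(affinity = affinity, density = d, transition = trans,
                 edges = edges, res_id = rownames(affinity)),
            class = "markov_network")
}

#' @export
print.markov_network <- function(x, ...) {
  cat("<markov_network> ", length(x$density), " residues, ",
      nrow(x$edges) / 2, " undirected contact pairs\n", sep = "")
  invisible(x)
}

node_index <- function(net, id) {
  if (is.character(id)) {
    i <- match(id, net$res_id)
    if (anyNA(i)) stop("residue not in graph: ", id[which(is.na(i))[1]],
                       call. = FALSE)
    return(i)
  }
  as.integer(id)
}

# Dijkstra from `source` over directed lengths -log(m_ij); on exact
# length ties the lexicographically smallest node sequence wins, which
# makes path extraction deterministic across platforms.
dijkstra_paths <- function(net, source) {
  n <- length(net$density)
  len <- matrix(Inf, n, n)  # len[from, to]
  len[cbind(net$edges$from, net$edges$to)] <- net$edges$length
  dist <- rep(Inf, n); dist[source] <- 0
  done <- rep(FALSE, n)
  paths <- vector("list", n)
  paths[[source]] <- source
  tol <- 1e-12
  for (iter in seq_len(n)) {
    u <- NA_integer_; best <- Inf
    for (v in seq_len(n)) {
      if (!done[v] && dist[v] < best) { best <- dist[v]; u <- v }
    }
    if (is.na(u)) break
    done[u] <- TRUE
    for (v in which(is.finite(len[u, ]))) {
      if (done[v]) next
      alt <- dist[u] + len[u, v]
      if (alt < dist[v] - tol) {
        dist[v] <- alt
        paths[[v]] <- c(paths[[u]], v)
      } else if (alt < dist[v] + tol && !is.null(paths[[v]])) {
        cand <- c(paths[[u]], v)
        if (lex_less(cand, paths[[v]])) {
          dist[v] <- min(dist[v], alt)
          paths[[v]] <- cand
        }
      }
    }
  }
  list(dist = dist, paths = paths)
}

lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Maximum-likelihood communication pathway between two residues
#'
#' Dijkstra shortest path on directed edge lengths `-log(m_ij)`; the path
#' minimising the summed lengths maximises the product of one-step
#' transition probabilities from source to target.
#'
#' @param net A `markov_network`.
#' @param source,target Residue ids (as in `net$res_id`) or node indices.
#' @return A `pathway`: list with `nodes` (residue ids source..target),
#'   `length` (summed `-log m`), `likelihood` (`exp(-length)`).
#' @export
max_likelihood_path <- function(net, source, target) {
  s <- node_index(net, source); t <- node_index(net, target)
  res <- dijkstra_paths(net, s)
  if (!is.finite(res$dist[t])) {
    stop("no communication path from ", net$res_id[s], " to ",
         net$res_id[t], " (disconnected graph)", call. = FALSE)
  }
  structure(list(nodes = net$res_id[res$paths[[t]]],
                 length = res$dist[t],
                 likelihood = exp(-res$dist[t])),
            class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat("<pathway> ", paste(x$nodes, collapse = " -> "), "\n  likelihood ",
      format(x$likelihood, digits = 4), " (length ",
      format(x$length, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Per-residue occurrence across all intersubunit pathways
#'
#' Computes the maximum-likelihood path for every ordered residue pair
#' (a, b) with a in `set_a` and b in `set_b`, and reports for each residue
#' of the graph the percentage of those paths that pass through it. Peaks
#' identify the residues that carry intersubunit communication.
#'
#' @param net A `markov_network`.
#' @param set_a,set_b Residue ids (or indices) of the two subunits.
#' @param include_endpoints Count path endpoints as on-pathway
#'   (default TRUE, matching occurrence profiles that peak at 100% for a
#'   bridging residue); FALSE counts intermediates only.
#' @return An `occurrence_profile` tibble with columns `res_id`,
#'   `occurrence` (percent), `n_paths`.
#' @export
occurrence_profile <- function(net, set_a, set_b, include_endpoints = TRUE) {
  ia <- node_index(net, set_a); ib <- node_index(net, set_b)
  if (length(ia) == 0 || length(ib) == 0) {
    stop("both residue sets must be nonempty", call. = FALSE)
  }
  n <- length(net$density)
  counts <- numeric(n)
  n_paths <- 0L; n_unreachable <- 0L
  for (a in ia) {
    res <- dijkstra_paths(net, a)
    for (b in ib) {
      if (!is.finite(res$dist[b])) { n_unreachable <- n_unreachable + 1L; next }
      p <- res$paths[[b]]
      if (!include_endpoints) p <- setdiff(p, c(a, b))
      counts[p] <- counts[p] + 1
      n_paths <- n_paths + 1L
    }
  }
  if (n_paths == 0) stop("no pair of the two sets is connected",
                         call. = FALSE)
  if (n_unreachable > 0) {
    message("occurrence_profile: ", n_unreachable,
            " unreachable pair(s) excluded from the denominator")
  }
  out <- tibble::tibble(res_id = net$res_id,
                        occurrence = 100 * counts / n_paths,
                        n_paths = n_paths)
  class(out) <- c("occurrence_profile", class(out))
  out
}

#' Write a Markov network as an edge list (TSV)
#'
#' Columns: from, to (residue ids), affinity, length (-log m).
#'
#' @param net A `markov_network`.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  e <- net$edges
  out <- data.frame(from = net$res_id[e$from], to = net$res_id[e$to],
                    affinity = e$affinity, length = e$length)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write pathways as text, one per line, residues joined by arrows
#'
#' @param pathways A list of `pathway` objects.
#' @param path Output path.
#' @export
write_pathways <- function(pathways, path) {
  writeLines(vapply(pathways, function(p)
    paste(p$nodes, collapse = " -> "), ""), path)
  invisible(path)
}
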