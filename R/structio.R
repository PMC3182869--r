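#' Read a PDB file into a coarse-grained structure
#'
#' Parses a PDB file and reduces it to one node per residue at the C-alpha
#' position, keeping all heavy (non-hydrogen) protein atoms of each residue
#' for contact counting. HETATM records (ligands, waters, ions) and hydrogens
#' are discarded; residues without a C-alpha are dropped with a message.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties: first in file).
#'
#' @param path Path to a PDB file.
#' @param chains Optional character vector of chain identifiers to keep, in
#'   the desired order (case-sensitive, as in the file). Default: all chains
#'   in file order.
#' @param model Model index for multi-model files (default 1).
#' @return A `coarse_structure` object: a list with `residues` (tibble with
#'   columns `chain`, `resno`, `insert`, `resid`, `res_id`), `ca` (N x 3
#'   matrix of C-alpha coordinates, Angstrom), `heavy` (list of per-residue
#'   heavy-atom coordinate matrices, C-alpha included), and `n`.
#' @export
read_structure <- function(path, chains = NULL, model = 1) {
  if (!file.exists(path)) {
    stop("PDB file not found: ", path, call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  atom <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (model < 1 || model > n_models) {
    stop("model ", model, " requested but file has ", n_models, " model(s)",
         call. = FALSE)
  }
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  atom$x <- xyz[, 1]; atom$y <- xyz[, 2]; atom$z <- xyz[, 3]

  atom <- atom[atom$type == "ATOM", , drop = FALSE]
  if (nrow(atom) == 0) stop("no ATOM records in ", path, call. = FALSE)
  elem <- toupper(trimws(atom$elesy))
  bad_elem <- is.na(elem) | elem == ""
  if (any(bad_elem)) {
    # fall back to the atom-name heuristic when the element column is absent
    nm <- gsub("[0-9]", "", trimws(atom$elety[bad_elem]))
    elem[bad_elem] <- substr(nm, 1, 1)
  }
  atom <- atom[!(elem %in% c("H", "D")), , drop = FALSE]

  atom$chain[is.na(atom$chain)] <- " "
  atom$insert[is.na(atom$insert)] <- ""
  atom$alt[is.na(atom$alt)] <- ""
  atom$o[is.na(atom$o)] <- 1

  file_chains <- unique(atom$chain)
  if (is.null(chains)) {
    chains <- file_chains
  } else {
    missing_ch <- setdiff(chains, file_chains)
    if (length(missing_ch) > 0) {
      stop("chain not present in ", path, ": ",
           paste(missing_ch, collapse = ", "), call. = FALSE)
    }
  }
  atom <- atom[atom$chain %in% chains, , drop = FALSE]
  atom$.ord <- seq_len(nrow(atom))

  # altloc policy: per residue+atom name, keep highest occupancy, first wins
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atom)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    occ <- atom$o[idx]
    idx[which(occ == max(occ))[1]]
  }), use.names = FALSE)
  atom <- atom[sort(keep), , drop = FALSE]

  res_key <- paste(atom$chain, atom$resno, atom$insert, sep = "\r")
  # residue order: chains in requested order, file order within chain
  chain_rank <- match(atom$chain, chains)
  first_seen <- tapply(atom$.ord, res_key, min)
  res_rank <- tapply(chain_rank, res_key, min)
  res_levels <- names(first_seen)[order(res_rank, first_seen)]

  residues <- list(); ca <- list(); heavy <- list()
  dropped <- character()
  for (rk in res_levels) {
    rows <- atom[res_key == rk, , drop = FALSE]
    ica <- which(trimws(rows$elety) == "CA")
    if (length(ica) == 0) {
      dropped <- c(dropped, rk)
      next
    }
    coords <- cbind(rows$x, rows$y, rows$z)
    rownames(coords) <- trimws(rows$elety)
    residues[[length(residues) + 1]] <- rows[ica[1], c("chain", "resno",
                                                       "insert", "resid")]
    ca[[length(ca) + 1]] <- coords[ica[1], ]
    heavy[[length(heavy) + 1]] <- coords
  }
  if (length(dropped) > 0) {
    message("read_structure: dropped ", length(dropped),
            " residue(s) lacking a C-alpha")
  }
  if (length(residues) == 0) stop("no C-alpha atoms found in ", path,
                                  call. = FALSE)
  res <- do.call(rbind, residues)
  res_tbl <- tibble::tibble(
    chain = res$chain, resno = res$resno, insert = res$insert,
    resid = res$resid,
    res_id = res_id_string(res$chain, res$resno, res$insert))
  if (anyDuplicated(res_tbl$res_id)) {
    stop("duplicate residue identifiers in ", path, call. = FALSE)
  }
  new_coarse_structure(res_tbl, do.call(rbind, ca), heavy)
}

res_id_string <- function(chain, resno, insert) {
  ifelse(insert == "" | is.na(insert),
         paste(chain, resno, sep = ":"),
         paste(chain, resno, insert, sep = ":"))
}

new_coarse_structure <- function(residues, ca, heavy) {
  ca <- as.matrix(ca)
  dimnames(ca) <- list(residues$res_id, c("x", "y", "z"))
  structure(list(residues = residues, ca = ca, heavy = heavy,
                 n = nrow(residues)),
            class = "coarse_structure")
}

#' @export
print.coarse_structure <- function(x, ...) {
  ch <- unique(x$residues$chain)
  cat("<coarse_structure> ", x$n, " residues, ", length(ch), " chain(s): ",
      paste(ch, collapse = ", "), "\n", sep = "")
  cat("  heavy atoms: ", sum(vapply(x$heavy, nrow, 1L)), "\n", sep = "")
  invisible(x)
}

#' Subset a coarse structure by chain or residue index
#'
#' @param s A `coarse_structure`.
#' @param chains Character vector of chain ids to keep (in the given order).
#' @param indices Integer residue indices to keep (alternative to `chains`).
#' @return A `coarse_structure` restricted to the selection.
#' @export
select_residues <- function(s, chains = NULL, indices = NULL) {
  stopifnot(inherits(s, "coarse_structure"))
  if (is.null(indices)) {
    if (is.null(chains)) return(s)
    missing_ch <- setdiff(chains, unique(s$residues$chain))
    if (length(missing_ch) > 0) {
      stop("chain not present: ", paste(missing_ch, collapse = ", "),
           call. = FALSE)
    }
    indices <- unlist(lapply(chains, function(ch)
      which(s$residues$chain == ch)))
  }
  new_coarse_structure(s$residues[indices, ], s$ca[indices, , drop = FALSE],
                       s$heavy[indices])
}

#' Write a coarse structure to a PDB file
#'
#' Writes all retained heavy atoms as ATOM records using the stored chain,
#' residue number, insertion code and atom names.
#'
#' @param s A `coarse_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "coarse_structure"))
  nat <- vapply(s$heavy, nrow, 1L)
  coords <- do.call(rbind, s$heavy)
  idx <- rep(seq_len(s$n), nat)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(coords)),
    resno = s$residues$resno[idx],
    chain = s$residues$chain[idx],
    insert = ifelse(s$residues$insert[idx] == "", NA,
                    s$residues$insert[idx]),
    resid = s$residues$resid[idx],
    elety = unlist(lapply(s$heavy, rownames)),
    o = rep(1, sum(nat)), b = rep(0, sum(nat)))
  invisible(path)
}

#' Identity correspondence between two structures with matching residues
#'
#' @param a,b `coarse_structure` objects sharing identical
#'   (chain, residue number, insertion code) sets.
#' @return A `correspondence_map`: tibble with columns `a`, `b` of residue
#'   identifiers, in `a`'s residue order.
#' @export
identity_map <- function(a, b) {
  stopifnot(inherits(a, "coarse_structure"), inherits(b, "coarse_structure"))
  only_a <- setdiff(a$residues$res_id, b$residues$res_id)
  only_b <- setdiff(b$residues$res_id, a$residues$res_id)
  if (length(only_a) > 0 || length(only_b) > 0) {
    first <- c(only_a, only_b)[1]
    stop("residue sets differ; first mismatch: ", first, call. = FALSE)
  }
  new_correspondence_map(a$residues$res_id, a$residues$res_id)
}

new_correspondence_map <- function(a_ids, b_ids) {
  if (anyDuplicated(a_ids)) {
    stop("duplicate residue on left side: ", a_ids[duplicated(a_ids)][1],
         call. = FALSE)
  }
  if (anyDuplicated(b_ids)) {
    stop("duplicate residue on right side: ", b_ids[duplicated(b_ids)][1],
         call. = FALSE)
  }
  structure(tibble::tibble(a = a_ids, b = b_ids),
            class = c("correspondence_map", "tbl_df", "tbl", "data.frame"))
}

#' Read a residue-correspondence map from a two-column text file
#'
#' Each non-empty, non-comment line holds two whitespace-separated tokens of
#' the form `chain:resnum` or `chain:resnum:icode`, pairing a residue of
#' structure A with one of structure B. This is the carrier format for
#' externally computed structural alignments (e.g. DALI output reduced to
#' residue pairs).
#'
#' @param path Path to the map file.
#' @return A `correspondence_map`.
#' @export
read_correspondence <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  a_ids <- character(length(keep)); b_ids <- character(length(keep))
  for (i in seq_along(keep)) {
    tok <- strsplit(trimws(lines[keep[i]]), "\\s+")[[1]]
    if (length(tok) != 2 || !all(grepl("^[^:]+:-?[0-9]+(:[A-Za-z])?$", tok))) {
      stop("malformed correspondence line ", keep[i], ": ",
           lines[keep[i]], call. = FALSE)
    }
    a_ids[i] <- tok[1]; b_ids[i] <- tok[2]
  }
  new_correspondence_map(a_ids, b_ids)
}

#' @rdname read_correspondence
#' @param map A `correspondence_map` to write.
#' @export
write_correspondence <- function(map, path) {
  writeLines(paste(map$a, map$b), path)
  invisible(path)
}

map_indices <- function(map, a, b) {
  ia <- match(map$a, a$residues$res_id)
  ib <- match(map$b, b$residues$res_id)
  if (anyNA(ia)) stop("map residue absent from first structure: ",
                      map$a[which(is.na(ia))[1]], call. = FALSE)
  if (anyNA(ib)) stop("map residue absent from second structure: ",
                      map$b[which(is.na(ib))[1]], call. = FALSE)
  list(a = ia, b = ib)
}

#' Optimal rigid-body superposition of mapped C-alpha pairs
#'
#' Least-squares (Kabsch) superposition of `mobile` onto `reference` over the
#' residue pairs of `map`. The returned transform acts as
#' `x_new = x %*% t(rotation) + translation`.
#'
#' @param mobile,reference `coarse_structure` objects.
#' @param map A `correspondence_map` with pairs (mobile id, reference id);
#'   default is the identity map.
#' @return A `superposition`: list with `rotation` (3 x 3, determinant +1),
#'   `translation` (length-3, Angstrom) and `rmsd` (post-fit C-alpha RMSD).
#' @export
superpose <- function(mobile, reference, map = NULL) {
  if (is.null(map)) map <- identity_map(mobile, reference)
  if (nrow(map) < 3) stop("superposition needs at least 3 mapped pairs",
                          call. = FALSE)
  idx <- map_indices(map, mobile, reference)
  X <- mobile$ca[idx$a, , drop = FALSE]
  Y <- reference$ca[idx$b, , drop = FALSE]
  kabsch(X, Y)
}

kabsch <- function(X, Y) {
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  sv_x <- svd(Xc)$d
  if (sv_x[2] < 1e-8 * max(sv_x[1], 1e-30)) {
    stop("degenerate (collinear) coordinates: superposition is undetermined",
         call. = FALSE)
  }
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  structure(list(rotation = R, translation = as.numeric(yc - R %*% xc),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd = ", format(x$rmsd, digits = 6), " A\n", sep = "")
  invisible(x)
}

#' Apply a superposition transform to a coarse structure
#'
#' @param s A `coarse_structure`.
#' @param sup A `superposition` from [superpose()].
#' @return The transformed `coarse_structure`.
#' @export
apply_superposition <- function(s, sup) {
  stopifnot(inherits(s, "coarse_structure"), inherits(sup, "superposition"))
  tr <- function(m) sweep(m %*% t(sup$rotation), 2, sup$translation, "+")
  heavy <- lapply(s$heavy, function(m) {
    out <- tr(m); rownames(out) <- rownames(m); out
  })
  new_coarse_structure(s$residues, tr(s$ca), heavy)
}
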