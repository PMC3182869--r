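test_that("deformation vectors vanish for identical or rigidly moved states", {
  s <- make_interlocked_dimer(10, seed = 6)
  d0 <- deformation_vector(s, s)
  expect_lt(max(abs(d0$values)), 1e-10)
  expect_lt(d0$rmsd_after_fit, 1e-10)

  th <- 1.1
  rot <- structure(list(rotation = matrix(c(cos(th), sin(th), 0,
                                            -sin(th), cos(th), 0,
                                            0, 0, 1), 3),
                        translation = c(5, -3, 2), rmsd = 0),
                   class = "superposition")
  moved <- apply_superposition(s, rot)
  d1 <- deformation_vector(s, moved)
  expect_lt(max(abs(d1$values)), 1e-8)
})

test_that("small mode-built deformations point along the generating mode", {
  fx <- random_network(12, seed = 2)
  s <- structure_from_coords(fx$net$coords)
  conf <- make_conformer(s, fx$modes, 3, 0.05)
  d <- deformation_vector(s, conf)
  expect_gt(overlap(fx$modes$vectors[, 3], d), 0.999)
})

test_that("overlap obeys the correlation-cosine identities", {
  u <- c(1, 0, 0, 0, 0, 0)
  v <- c(0, 1, 0, 0, 0, 0)
  expect_equal(overlap(u, u), 1)
  expect_equal(overlap(u, v), 0)
  expect_equal(overlap(u, -u), 1)          # sign-blind
  expect_equal(overlap(3.7 * u, u), 1)     # scale-invariant
  set.seed(5)
  a <- stats::rnorm(30); b <- stats::rnorm(30)
  expect_equal(overlap(a, b), overlap(b, a), tolerance = 1e-14)
  expect_equal(overlap(2 * a, -5 * b), overlap(a, b), tolerance = 1e-12)
  perm <- sample(10)
  idx <- as.vector(t(outer(perm, 1:3, function(p, c) 3 * (p - 1) + c)))
  expect_equal(overlap(a[idx], b[idx]), overlap(a, b), tolerance = 1e-12)
  expect_error(overlap(rep(0, 30), b), "zero-norm")
  expect_error(overlap(a, b[1:6]), "incompatible")
})

test_that("cumulative overlap is monotone and complete over the nonzero modes", {
  fx <- random_network(10, seed = 8)
  # a pure mode-5 deformation: invisible to modes 1-4, fully mode 5
  d5 <- fx$modes$vectors[, 5]
  expect_lt(cumulative_overlap(fx$modes, d5, 4), 1e-8)
  expect_equal(cumulative_overlap(fx$modes, d5, 5), 1, tolerance = 1e-10)

  set.seed(17)
  raw <- stats::rnorm(30)
  dr <- project_out_rigid(raw, fx$net)
  curve <- overlap_curve(fx$modes, dr)
  expect_true(all(diff(curve$co) >= -1e-12))
  expect_equal(curve$co[24], 1, tolerance = 1e-6)
  expect_error(cumulative_overlap(fx$modes, dr, 0), ">= 1")
  expect_error(cumulative_overlap(fx$modes, dr, 99), "exceeds")
})

test_that("a dominated mode recipe is recovered to two decimals", {
  fx <- random_network(14, seed = 3)
  set.seed(23)
  noise <- stats::rnorm(42)
  noise <- project_out_rigid(noise, fx$net)
  U3 <- fx$modes$vectors[, 1:3]
  noise <- noise - U3 %*% crossprod(U3, noise)
  noise <- noise / sqrt(sum(noise^2))
  dr <- 0.9 * fx$modes$vectors[, 3] + 0.1 * noise
  co3 <- cumulative_overlap(fx$modes, dr, 3)
  expect_equal(co3, 0.9 / sqrt(0.82), tolerance = 1e-8)
  expect_equal(round(co3, 2), 0.99)
})

test_that("overlap matrices are identity-like for self-comparison", {
  fx <- random_network(10, seed = 5)
  M <- overlap_matrix(fx$modes, fx$modes, m = 6, n = 6)
  expect_true(all(unclass(M) >= 0 & unclass(M) <= 1))
  expect_equal(unname(diag(unclass(M))), rep(1, 6), tolerance = 1e-10)
})

test_that("restriction recovers component modes from an uncoupled assembly", {
  # two geometrically distinct protomers far apart: every assembly mode
  # lives on exactly one protomer and restricts to an isolated mode
  c1 <- random_points(8, box = 10, seed = 1)
  c2 <- sweep(random_points(10, box = 12, seed = 9), 2, c(120, 0, 0), "+")
  net <- build_network(rbind(c1, c2), cutoff = 15)
  H <- build_hessian(net)
  assembly <- compute_modes(H, expected_zero = NA)
  iso <- compute_modes(build_network(c1, cutoff = 15))
  M <- overlap_matrix(assembly, iso, restrict = 1:8)
  best <- apply(unclass(M), 2, max)
  expect_true(all(best > 1 - 1e-8))
  # restriction-then-normalise preserves unit overlap when the assembly
  # vector vanishes outside the restriction
  k <- which(unclass(M)[, 1] > 1 - 1e-8)[1]
  v <- assembly$vectors[, k]
  expect_lt(max(abs(v[-oligodyn:::expand3(1:8)])), 1e-6)
})

test_that("subspace overlap spans [0, 1] with the documented normalisation", {
  fx <- random_network(12, seed = 6)
  expect_equal(subspace_overlap(fx$modes, fx$modes, m = 5, n = 5), 1,
               tolerance = 1e-10)
  A <- fx$modes
  B <- fx$modes
  B$vectors <- B$vectors[, 6:10]; B$values <- B$values[6:10]
  expect_lt(subspace_overlap(A, B, m = 5, n = 5), 1e-10)
  # reference-set choice: first 5 modes inside first 10 -> 1 vs 1/sqrt(2)
  C <- fx$modes
  C$vectors <- C$vectors[, 1:10]; C$values <- C$values[1:10]
  expect_equal(subspace_overlap(A, C, m = 5, n = 10, reference = "first"),
               1, tolerance = 1e-10)
  expect_equal(subspace_overlap(A, C, m = 5, n = 10, reference = "second"),
               sqrt(5 / 10), tolerance = 1e-10)
})

test_that("correspondence slopes read mode conservation off the overlap matrix", {
  Mdiag <- structure(diag(8) * 0.9 + 0.01,
                     class = c("overlap_matrix", "matrix", "array"))
  fit <- correspondence_slope(Mdiag)
  expect_equal(fit$abs_slope, 1, tolerance = 1e-10)
  expect_equal(fit$slope, -1, tolerance = 1e-10)

  # component mode l expressed by assembly mode 2l: half the component
  # spectrum is unrepresented among the assembly's low modes
  M2 <- matrix(0.02, 5, 10)
  for (l in 1:5) M2[l, 2 * l] <- 0.8
  M2 <- structure(M2, class = c("overlap_matrix", "matrix", "array"))
  fit2 <- correspondence_slope(M2)
  expect_equal(fit2$abs_slope, 2, tolerance = 1e-10)

  expect_error(correspondence_slope(Mdiag, threshold = 0.95), "fewer than 2")
})

test_that("weighted slope fits match the closed-form WLS solution", {
  M <- matrix(0, 5, 5)
  entries <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 4, 4, 5))
  ov <- c(0.9, 0.8, 0.6, 0.55, 0.7)
  M[entries] <- ov
  M <- structure(M, class = c("overlap_matrix", "matrix", "array"))
  fit <- correspondence_slope(M, threshold = 0.5)
  w <- ov^2; x <- entries[, 1]; y <- entries[, 2]
  xm <- sum(w * x) / sum(w); ym <- sum(w * y) / sum(w)
  slope_cf <- sum(w * (x - xm) * (y - ym)) / sum(w * (x - xm)^2)
  expect_equal(fit$abs_slope, abs(slope_cf), tolerance = 1e-12)
  expect_equal(fit$intercept, ym - slope_cf * xm, tolerance = 1e-12)
  fit0 <- correspondence_slope(M, intercept = FALSE)
  expect_equal(fit0$abs_slope, abs(sum(w * x * y) / sum(w * x^2)),
               tolerance = 1e-12)
  expect_equal(fit0$intercept, 0)
})

test_that("distance variation maps separate rigid-body from internal motion", {
  # synthetic mode translating nodes 1-5 rigidly, holding 6-10 fixed
  pts <- random_points(10, box = 12, seed = 4)
  net <- build_network(pts, cutoff = 20)
  vec <- numeric(30)
  vec[oligodyn:::expand3(1:5)] <- rep(c(1, 0.5, -0.2), 5)
  ms <- fake_mode_set(matrix(vec, ncol = 1), values = 2)
  D <- distance_variation(net, ms, 1)
  expect_lt(max(abs(unclass(D)[1:5, 1:5])), 1e-10)   # rigid block
  expect_gt(max(abs(unclass(D)[1:5, 6:10])), 1e-3)   # moving interface
  expect_equal(unclass(D), t(unclass(D)), tolerance = 1e-12)
  expect_equal(unname(diag(unclass(D))), rep(0, 10))

  # two nodes moving straight apart: positive entry
  net2 <- build_network(rbind(c(0, 0, 0), c(5, 0, 0)), cutoff = 6)
  ms2 <- fake_mode_set(matrix(c(-1, 0, 0, 1, 0, 0), ncol = 1), values = 1)
  D2 <- distance_variation(net2, ms2, 1)
  expect_gt(D2[1, 2], 0)
})

test_that("distance variation matches a finite-difference of the distances", {
  fx <- random_network(10, seed = 12)
  k <- 2
  D <- distance_variation(fx$net, fx$modes, k)
  s_amp <- 1e-5
  u <- matrix(fx$modes$vectors[, k], ncol = 3, byrow = TRUE)
  moved <- fx$net$coords + s_amp * u
  d0 <- as.matrix(stats::dist(fx$net$coords))
  d1 <- as.matrix(stats::dist(moved))
  fd <- (d1 - d0) / (s_amp * sqrt(fx$modes$values[k]))
  diag(fd) <- 0
  expect_equal(unclass(D), fd, tolerance = 1e-4)
  # exponent knob: 1.0 rescales by the extra 1/sqrt(lambda)
  D1 <- distance_variation(fx$net, fx$modes, k, exponent = 1)
  expect_equal(unclass(D1),
               unclass(D) / sqrt(fx$modes$values[k]), tolerance = 1e-10)
})

test_that("deformation recovery identifies the generating mode on a synthetic hexamer", {
  spec <- oligomer_spec(n_protomers = 6, protomer_size = 20,
                        interface_density = 0.05, seed = 10)
  hex <- assemble_oligomer(spec)
  modes <- anm_modes(hex)
  for (seed in 1:5) {
    j <- 2 + seed
    conf <- make_deformation(hex, modes, list(c(j, 4)), noise_frac = 0.05,
                             seed = seed)
    d <- deformation_vector(hex, conf)
    curve <- overlap_curve(modes, d, m_max = 20)
    expect_equal(which.max(curve$overlap), j)
    expect_gt(max(curve$overlap), 0.99)
  }
})
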