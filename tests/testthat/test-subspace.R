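test_that("alignment index matches explicit trace arithmetic on toys", {
  # cov = diag(4, 1, 0); basis spanning axes 2 and 3 captures (1+0)/(4+1)
  cov3 <- diag(c(4, 1, 0))
  basis <- diag(3)[, 2:3]
  expect_equal(alignment_index(basis, cov3, k = 2), 0.2, tolerance = 1e-12)

  # self-alignment is exactly 1; orthogonal support exactly 0
  expect_equal(alignment_index(diag(3)[, 1:2, drop = FALSE], cov3, k = 2), 1)
  expect_equal(alignment_index(diag(3)[, 3, drop = FALSE],
                               diag(c(4, 1, 0)), k = 1), 0)

  expect_error(alignment_index(cbind(c(1, 1, 0)), cov3), "orthonormal")
  expect_error(alignment_index(diag(3)[, 1:2], -diag(3)), "semi-definite")
})

test_that("alignment decreases monotonically as the basis rotates away", {
  cov2 <- diag(c(5, 2, 0.5, 0))
  vals <- vapply(seq(0, pi / 2, length.out = 10), function(th) {
    basis <- cbind(c(cos(th), 0, 0, sin(th)), c(0, cos(th), sin(th), 0))
    alignment_index(basis, cov2, k = 2)
  }, numeric(1))
  expect_equal(vals[1], 1)
  expect_true(all(diff(vals) < 1e-12))
  expect_equal(vals[10], 0.5 / 7, tolerance = 1e-10)
})

test_that("context PCA captures rank-1 structure and obeys the PCA identity", {
  m <- outer(c(1, -2, 3), stats::rnorm(40))
  rownames(m) <- c("a", "b", "c")
  cm <- structure(m, context = "contra", class = c("context_matrix", "matrix"))
  pca <- context_pca(cm, k = 1)
  expect_equal(pca$cum_var_own[1], 1, tolerance = 1e-12)

  cms <- demo_cms()
  pca10 <- context_pca(cms$contra, k = 10)
  eig <- pca10$eigenvalues
  expect_equal(pca10$cum_var_own, cumsum(eig[1:10]) / sum(eig))
  expect_lt(max(abs(crossprod(pca10$components) - diag(10))), 1e-10)
  expect_error(context_pca(cms$contra, k = 10000), "rank")
})

test_that("ground-truth-orthogonal low-noise activity stays in its own subspace", {
  # near-noiseless rank-3 structure per context, orthogonal across contexts
  set.seed(5)
  U <- qr.Q(qr(matrix(stats::rnorm(40 * 6), 40, 6)))
  lat <- matrix(stats::rnorm(3 * 240), 3, 240)
  m_c <- U[, 1:3] %*% lat
  m_i <- U[, 4:6] %*% (lat * c(1.2, 0.8, 1))
  wrap <- function(m, ctx) {
    rownames(m) <- sprintf("n%02d", seq_len(nrow(m)))
    structure(m, context = ctx, class = c("context_matrix", "matrix"))
  }
  pca <- context_pca(wrap(m_c, "contra"), k = 3, other_cm = wrap(m_i, "ipsi"))
  expect_gt(pca$cum_var_own[3], 0.999)
  expect_lt(pca$cum_var_other[3], 0.15)
})

test_that("joint orthogonalization solves the separable case exactly", {
  # disjoint eigen-supports: optimum is each context's own top-d eigenvectors
  set.seed(11)
  U <- qr.Q(qr(matrix(stats::rnorm(10 * 10), 10, 10)))
  cov_c <- U[, 1:3] %*% diag(c(5, 3, 2)) %*% t(U[, 1:3])
  cov_i <- U[, 4:6] %*% diag(c(4, 2, 1)) %*% t(U[, 4:6])
  res <- joint_orthogonal_subspaces(cov_c, cov_i, d = 3, seed = 2)
  expect_equal(res$objective, 1, tolerance = 1e-6)
  ang_c <- acos(pmin(svd(crossprod(res$Q_contra, U[, 1:3]))$d, 1))
  ang_i <- acos(pmin(svd(crossprod(res$Q_ipsi, U[, 4:6]))$d, 1))
  expect_lt(max(ang_c), 1e-4)
  expect_lt(max(ang_i), 1e-4)
  expect_lt(max(abs(crossprod(res$Q_contra, res$Q_ipsi))), 1e-8)
})

test_that("identity covariances make the objective flat across restarts", {
  vals <- vapply(1:10, function(s) {
    joint_orthogonal_subspaces(diag(8), diag(8), d = 2, seed = s)$objective
  }, numeric(1))
  expect_lt(max(vals) - min(vals), 1e-8)
  expect_equal(vals[1], 1, tolerance = 1e-10)
})

test_that("the optimizer never falls below the projected-PCA feasible start", {
  set.seed(19)
  for (i in 1:5) {
    cov_c <- random_psd(12, rank = 5)
    cov_i <- random_psd(12, rank = 5)
    res <- joint_orthogonal_subspaces(cov_c, cov_i, d = 2, seed = i)
    Q0 <- motorload:::pca_start(cov_c, cov_i, 2)
    f0 <- joint_objective(Q0[, 1:2], Q0[, 3:4], cov_c, cov_i)
    expect_gte(res$objective + 1e-10, f0)
    expect_lt(max(abs(crossprod(res$Q_contra, res$Q_ipsi))), 1e-8)
    expect_true(res$objective > 0 && res$objective <= 1 + 1e-12)
  }
})

test_that("relative projection difference hits its analytic limits", {
  set.seed(4)
  Q <- qr.Q(qr(matrix(stats::rnorm(20 * 2), 20, 2)))
  base <- matrix(stats::rnorm(20 * 40), 20, 40)
  wrap <- function(m, ctx) structure(m, context = ctx,
                                     class = c("context_matrix", "matrix"))
  cm_ref <- wrap(base, "contra")

  # identical projections: 0%
  expect_equal(relative_projection_difference(Q, cm_ref, wrap(base, "ipsi"),
                                              "contra")$percent, 0)
  # other context invisible to the basis: 100%
  ortho <- base - Q %*% crossprod(Q, base)
  expect_equal(relative_projection_difference(Q, cm_ref, wrap(ortho, "ipsi"),
                                              "contra")$percent, 100,
               tolerance = 1e-9)
  # antipodal projections: 200%
  expect_equal(relative_projection_difference(Q, cm_ref, wrap(-base, "ipsi"),
                                              "contra")$percent, 200,
               tolerance = 1e-9)
  zero <- wrap(matrix(0, 20, 40), "contra")
  expect_error(relative_projection_difference(Q, zero, wrap(base, "ipsi"),
                                              "contra"), "zero norm")
})

test_that("weight balance spots split populations and balanced ones", {
  mk_pcs <- function(m) {
    rownames(m) <- sprintf("n%03d", seq_len(nrow(m)))
    list(components = m)
  }
  # neuron loading only on ipsi components
  pc_c <- mk_pcs(rbind(c(0, 0), c(0.5, 0.5)))
  pc_i <- mk_pcs(rbind(c(0.7, 0.3), c(0.5, 0.5)))
  wb <- weight_balance_index(pc_c, pc_i)
  expect_equal(unname(wb$index[1]), 1)
  expect_equal(unname(wb$index[2]), 0)

  # disjoint groups: strongly non-normal index distribution
  set.seed(14)
  n <- 100
  w_c <- rbind(matrix(abs(stats::rnorm(n / 2 * 2, 1, 0.05)), n / 2),
               matrix(abs(stats::rnorm(n / 2 * 2, 0.01, 0.003)), n / 2))
  w_i <- rbind(matrix(abs(stats::rnorm(n / 2 * 2, 0.01, 0.003)), n / 2),
               matrix(abs(stats::rnorm(n / 2 * 2, 1, 0.05)), n / 2))
  wb2 <- weight_balance_index(mk_pcs(w_c), mk_pcs(w_i))
  expect_lt(wb2$ks_p, 0.05)

  pc_zero <- mk_pcs(rbind(c(0, 0), c(0.5, 0.5)))
  expect_warning(wb3 <- weight_balance_index(pc_zero, mk_pcs(rbind(c(0, 0),
                                                                   c(1, 1)))),
                 "zero total weight")
  expect_equal(wb3$n, 1)
})
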