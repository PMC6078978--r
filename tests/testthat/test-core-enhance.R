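test_that("knn transition matches hand-evaluated and degenerate cases", {
  expect_equal(unname(knn_transition(matrix(1, 2, 2), 2)[, ]),
               matrix(0.5, 2, 2), ignore_attr = TRUE)
  # self-weight 0 contributes nothing to the normalization
  expect_equal(unname(knn_transition(matrix(c(0, 1, 1, 0), 2), 2)[, ]),
               matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  # all-zero rows become self-absorbing
  expect_equal(unname(knn_transition(matrix(0, 2, 2), 2)[, ]),
               diag(2), ignore_attr = TRUE)
})

test_that("knn transition agrees with the top-k-and-normalize oracle", {
  for (seed in 1:5) {
    W <- rand_network(8, seed)
    for (k in c(2, 4, 8)) {
      P <- knn_transition(W, k)
      expect_equal(unname(unclass(P)[, ]), oracle_knn_transition(W, k),
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
      expect_true(all(rowSums(P > 0) <= k))
    }
  }
})

test_that("knn transition rejects bad k and bad matrices", {
  W <- rand_network(5, 1)
  expect_error(knn_transition(W, 0), class = "ne_parameter_error")
  expect_error(knn_transition(W, 6), class = "ne_parameter_error")
  Wneg <- W; Wneg[1, 2] <- Wneg[2, 1] <- -1
  expect_error(knn_transition(Wneg, 3), class = "ne_validation_error")
})

test_that("localized operator reproduces hand examples and the identity", {
  P <- matrix(0.5, 2, 2)
  expect_equal(localized_dsm(P), matrix(0.5, 2, 2), ignore_attr = TRUE)
  P2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(localized_dsm(P2), diag(2), ignore_attr = TRUE)
  expect_equal(localized_dsm(diag(4)), diag(4), ignore_attr = TRUE)
})

test_that("localized operator is a symmetric DSM and matches direct summation", {
  for (seed in 1:4) {
    P <- knn_transition(rand_network(10, seed), 4)
    Tm <- localized_dsm(P)
    expect_dsm(Tm, tol = 1e-10)
    expect_equal(unname(Tm), oracle_localized_dsm(unclass(P)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("eigenvalue map fixes 0 and 1, shrinks, and evaluates exactly", {
  expect_identical(map_eigenvalue(0, 0.5), 0)
  expect_equal(map_eigenvalue(1, 0.77), 1)
  expect_equal(map_eigenvalue(0.5, 0.9), 0.05 / 0.775)
  grid <- seq(0, 1, length.out = 201)
  expect_true(all(map_eigenvalue(grid, 0.9) <= grid + 1e-15))
  expect_error(map_eigenvalue(1.1, 0.9), class = "ne_parameter_error")
  expect_error(map_eigenvalue(0.5, 1), class = "ne_parameter_error")
})

test_that("iterative diffusion fixes idempotent and identity operators", {
  flat <- matrix(0.5, 2, 2)
  res <- diffuse_iterative(flat, alpha = 0.9, tol = 1e-12)
  expect_equal(res$denoised, flat, tolerance = 1e-12, ignore_attr = TRUE)
  res_id <- diffuse_iterative(diag(3), alpha = 0.37, tol = 1e-12)
  expect_equal(res_id$denoised, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(res$converged)
})

test_that("iterative diffusion limit is independent of the start", {
  Tm <- rand_operator(30, seed = 11, k = 10)
  a <- diffuse_iterative(Tm, 0.8, tol = 1e-12, max_iter = 400)
  b <- diffuse_iterative(Tm, 0.8, tol = 1e-12, max_iter = 400,
                         W0 = rand_network(30, 12))
  expect_lt(norm(a$denoised - b$denoised, "F"), 1e-6)
})

test_that("matrix update equals the entrywise double-sum expansion", {
  Tm <- rand_operator(5, seed = 3, k = 3)
  W <- Tm
  for (step in 1:3) {
    Wn <- suppressWarnings(
      diffuse_iterative(Tm, 0.85, tol = 1e-15, max_iter = 1, W0 = W))$denoised
    expect_equal(unname(Wn), oracle_diffusion_step(Tm, W, 0.85),
                 tolerance = 1e-12, ignore_attr = TRUE)
    W <- Wn
  }
})

test_that("closed form equals the converged iteration", {
  for (n in c(20, 50)) {
    Tm <- rand_operator(n, seed = n, k = max(3, n %/% 4))
    cf <- diffuse_closed_form(Tm, 0.8)
    it <- diffuse_iterative(Tm, 0.8, tol = 1e-12, max_iter = 500)
    expect_lt(norm(cf$denoised - it$denoised, "F") / norm(it$denoised, "F"),
              1e-6)
    expect_identical(cf$iterations, 0L)
    expect_dsm(cf$denoised, tol = 1e-6)
  }
})

test_that("non-convergence is a classed warning, not an error", {
  Tm <- rand_operator(20, seed = 5)
  expect_warning(res <- diffuse_iterative(Tm, 0.9, tol = 1e-15, max_iter = 2),
                 class = "ne_nonconvergence_warning")
  expect_false(res$converged)
  expect_length(res$residuals, 2)
})

test_that("degree rescaling restores the input scale symmetrically", {
  # identity scaling when all degrees are 1
  Wstar <- rand_operator(6, seed = 2)
  ones <- matrix(1 / 6, 6, 6)  # degrees all 1
  expect_equal(rescale_to_input_degrees(Wstar, ones), Wstar,
               ignore_attr = TRUE)
  # D^{1/2} I D^{1/2} = D
  Win <- diag(c(4, 9))
  expect_equal(rescale_to_input_degrees(diag(2), Win), diag(c(4, 9)),
               ignore_attr = TRUE)
  # symmetry and total-weight monotonicity on a random instance
  W <- rand_network(12, 7)
  out <- rescale_to_input_degrees(Wstar <- enhance(W, k = 5), W)
  expect_lt(max(abs(out - t(out))), 1e-10)
  expect_gt(sum(out), sum(Wstar))  # degrees exceed 1, scale restored upward
  expect_error(rescale_to_input_degrees(diag(3), diag(2)),
               class = "ne_validation_error")
})

test_that("enhance keeps disconnected flat blocks block-constant", {
  tb <- two_block_flat(c(4, 4))
  out <- enhance(tb$W, alpha = 0.9, k = 4, mode = "iterative", tol = 1e-10)
  expect_true(all(out[tb$labels == 1, tb$labels == 2] == 0))
  offdiag <- out[1, 2:4]
  expect_lt(max(abs(offdiag - offdiag[1])), 1e-10)
  expect_equal(rownames(out), rownames(tb$W))
})

test_that("enhance handles a single node and preserves ids", {
  W1 <- matrix(0, 1, 1, dimnames = list("solo", "solo"))
  expect_equal(enhance(W1), W1)
  W <- rand_network(9, 4)
  expect_identical(rownames(enhance(W, k = 3)), rownames(W))
})

test_that("enhancement widens the top eigengap of a noisy block network", {
  # gap growth is a large-eigenvalue property (f'(x) > 1 only near x = 1),
  # so the planted blocks must be strong enough that lambda_4 is close to 1
  sim <- generate_block_network(n = 80, n_blocks = 4, noise_sd = 0.2,
                                dropout = 0.1, seed = 21)
  det <- enhance(sim$network, k = 10, details = TRUE)
  expect_gt(eigen(det$operator, symmetric = TRUE,
                  only.values = TRUE)$values[4], 0.97)
  expect_gte(eigengap(det$diffusion$denoised, 4),
             eigengap(det$operator, 4))
})

test_that("enhance output is invariant to positive input rescaling", {
  W <- rand_network(25, 8)
  base <- enhance(W, k = 6)
  for (c in c(1e-4, 3, 1e5))
    expect_equal(enhance(c * W, k = 6), base, tolerance = 1e-9)
})
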