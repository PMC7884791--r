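test_that("activation base follows the threshold-plus-integer grid", {
  set.seed(1)
  base <- make_activation_base(8, 8, target_fr = 0.5)
  expect_equal(dim(base$u_base), c(5L, 8L))  # M/2 + 1 rows
  expect_true(all(base$theta %in% c(0.5, 1.5, 2.5)))
  r <- sweep(base$u_base - 0.5, 2, base$theta)
  expect_true(all(r == round(r)))
  expect_true(all(abs(r) >= 1 & abs(r) <= 5))
  # supra-threshold iff r > 0
  expect_equal(base$u_base > rep(base$theta, each = 5), r > 0,
               ignore_attr = TRUE)
})

test_that("target_fr = 1 - eps makes every entry supra-threshold in expectation", {
  set.seed(2)
  base <- make_activation_base(8, 16, target_fr = 1 - 1e-12)
  expect_true(all(base$u_base > rep(base$theta, each = 5)))
})

test_that("expansion preserves the delta-pair identity exactly and full rank", {
  g <- build_stask_graph(3)
  set.seed(3)
  for (rep in 1:20) {
    f_cc <- sample(c(1, 2, 3), 1)
    base <- make_activation_base(8, 8, f_cc = f_cc)
    exp <- expand_activations(base, g)
    expect_equal(nrow(exp$u_lc), 8L)
    for (k in 1:4) {
      expect_identical(exp$u_lc[2 * k, ] - exp$u_lc[2 * k - 1, ], exp$delta)
    }
    # rank(U_lc) = M/2 + 1
    expect_equal(ftpnet:::mat_rank(exp$u_lc), 5L)
  }
})

test_that("assembled system has the published shape and rank structure", {
  set.seed(4)
  sys <- construct_network(tau = 3, n_rec = 8)$system
  expect_equal(dim(sys$C), c(16L, 10L))
  expect_equal(dim(sys$U), c(16L, 8L))
  expect_equal(ftpnet:::mat_rank(sys$C), 9L)
  expect_equal(ftpnet:::mat_rank(cbind(sys$C, sys$U)), 9L)
  expect_equal(ftpnet:::mat_rank(sys$U), 5L)  # 2^tau/2 + 1
  expect_identical(sys$y_codes, rbind(c(1, 0), c(0, 1)))
})

test_that("duplicate thresholded states raise the dedicated error", {
  g <- build_stask_graph(2)
  theta <- rep(0.5, 4)
  u_lc <- matrix(2, 4, 4)          # all identical -> identical Z rows
  delta <- rep(0, 4)
  expect_error(assemble_system(g, u_lc, theta, delta),
               class = "ftp_duplicate_state_error")
})

test_that("solve_weights returns the minimum-norm solution", {
  sys <- structure(list(C = diag(2), U = diag(2)), class = "linear_system")
  expect_equal(solve_weights(sys), diag(2))

  set.seed(5)
  fit <- construct_network(tau = 3, n_rec = 12)
  W <- rbind(fit$network$w_in, fit$network$w_rec)
  kerC <- null_space_basis(fit$system$C)
  nw <- norm(W, "F")
  for (i in 1:100) {
    M <- matrix(rnorm(ncol(kerC) * ncol(W)), ncol(kerC), ncol(W))
    dW <- kerC %*% M
    expect_gt(norm(W + dW, "F"), nw)
  }
})

test_that("construct_network honours the redundancy factor and restarts", {
  set.seed(6)
  fit <- construct_network(tau = 4, f_r = 3)
  expect_equal(ncol(fit$network$w_rec), 48L)
  expect_equal(fit$network$meta$f_r, 3)
  # restarts are essentially absent for tau >= 5
  restarts <- replicate(5, construct_network(tau = 5)$restarts)
  expect_lte(mean(restarts), 1)
})

test_that("constructed networks replay the graph walk exactly", {
  set.seed(7)
  for (tau in 2:5) {
    fit <- construct_network(tau = tau)
    g <- fit$system$graph
    stim <- random_stimuli(10 * 2^tau)
    z0 <- fit$network$Z[1, ]
    tr <- simulate_network(fit$network, stim, z0 = z0, burn_in = 0)
    expect_equal(tr$state_ids, walk_graph(g, stim, start = 1L),
                 info = paste("tau =", tau))
  }
})

test_that("achieved firing rate tracks the target within 0.1", {
  set.seed(8)
  for (fr in c(0.2, 0.4, 0.6, 0.8)) {
    measured <- mean(replicate(4, {
      fit <- construct_network(tau = 4, target_fr = fr)
      mean(post_burn(quick_trace(fit, 160, 4)))
    }))
    expect_lt(abs(measured - fr), 0.1)
  }
})

test_that("weight distributions approach a normal and shrink as n_rec grows", {
  set.seed(9)
  stats <- sapply(c(8, 16, 32, 64), function(n) {
    v <- replicate(20, {
      fit <- construct_network(tau = 3, n_rec = n)
      c(ks_normal(fit$network$w_rec), mean(abs(fit$network$w_rec)))
    })
    rowMeans(v)
  })
  expect_true(all(diff(stats[1, ]) < 0))  # KS statistic decreases
  expect_true(all(diff(stats[2, ]) < 0))  # mean |W_rec| decreases
})

test_that("construction is seed-deterministic", {
  set.seed(123); a <- construct_network(tau = 3)
  set.seed(123); b <- construct_network(tau = 3)
  expect_identical(a$network$w_rec, b$network$w_rec)
  expect_identical(a$network$theta, b$network$theta)
})
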