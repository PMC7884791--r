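test_that("null space has dimension N - (M + 1) and annihilates C", {
  set.seed(20)
  fit <- construct_network(tau = 3, n_rec = 8)  # N = 10, rank 9
  kerC <- null_space_basis(fit$system$C)
  expect_equal(ncol(kerC), 1L)
  expect_lt(max(abs(fit$system$C %*% kerC)), 1e-8)
  expect_equal(crossprod(kerC), diag(ncol(kerC)), tolerance = 1e-10)

  expect_equal(ncol(null_space_basis(diag(3))), 0L)  # full column rank
})

test_that("isofunction samples keep behaviour, raise the norm, satisfy CW' = U", {
  set.seed(21)
  fit <- construct_network(tau = 4, n_rec = 16)
  W <- rbind(fit$network$w_in, fit$network$w_rec)
  stim <- random_stimuli(500)
  z0 <- fit$network$Z[1, ]
  base_tr <- simulate_network(fit$network, stim, z0 = z0)
  for (i in 1:25) {
    tnet <- sample_isofunction(fit$network, fit$system$C)
    W2 <- rbind(tnet$w_in, tnet$w_rec)
    expect_lt(max(abs(fit$system$C %*% W2 - fit$system$U)), 1e-8)
    expect_gte(norm(W2, "F"), norm(W, "F"))
    tr <- simulate_network(tnet, stim, z0 = z0)
    expect_identical(tr$raster, base_tr$raster)
  }
})

test_that("a trivial null space is reported as such", {
  net <- ftpnet:::new_binary_network(diag(3), rep(0.5, 1), NULL, list())
  expect_error(sample_isofunction(net, diag(3)),
               class = "ftp_no_null_space_error")
})

test_that("compute_delta_wd components match the defining formulas", {
  opts <- constraint_options(forbid_self = TRUE)
  # toy: n_in = 2, 2 integration neurons
  W <- rbind(c(0.1, -0.4), c(0.2, 0.3),      # input rows
             c(0.3, -0.2), c(0.5, 0.1))      # recurrent rows
  cd <- compute_delta_wd(W, opts, n_in = 2L)
  expect_equal(cd$dw_d[3, 1], -0.3)  # self connections negated
  expect_equal(cd$dw_d[4, 2], -0.1)
  expect_equal(sum(cd$dw_d != 0), 2L)

  # Dale on presynaptic rows: neuron 1 outgoing (0.4, -0.1) and excitatory
  optsD <- constraint_options(forbid_self = FALSE, ex_in_ratio = c(1, 1))
  WD <- rbind(matrix(0, 2, 2), c(0.4, -0.1), c(-0.2, -0.5))
  cdD <- compute_delta_wd(WD, optsD, n_in = 2L)
  expect_equal(cdD$neuron_types, c("Ex", "In"))
  expect_equal(cdD$dw_d[3, ], c(0, 0.1))   # negative entry of an Ex row zeroed
  expect_equal(cdD$dw_d[4, ], c(0, 0))     # In row already sign-pure

  # sparsity: sp = 0.5 over |values| {0.1, 0.2, 0.3, 0.4} kills the two smallest
  optsS <- constraint_options(forbid_self = FALSE, sparsity = 0.5)
  WS <- rbind(c(0.1, -0.2), c(0.3, 0.4))
  cdS <- compute_delta_wd(WS, optsS, n_in = 0L)
  expect_equal(cdS$dw_d, rbind(c(-0.1, 0.2), c(0, 0)))
})

test_that("disabled constraints succeed immediately with W unchanged", {
  set.seed(22)
  fit <- construct_network(tau = 3, n_rec = 16)
  rep <- constrain_structure(fit$network, fit$system,
                             constraint_options(forbid_self = FALSE))
  expect_equal(rep$status, "success")
  expect_equal(rep$iterations, 0L)
  expect_identical(rep$network$w_rec, fit$network$w_rec)
})

test_that("full constraint set succeeds and is verified entry-wise", {
  set.seed(23)
  opts <- constraint_options(ex_in_ratio = c(4, 1), sparsity = 0.4)
  rep <- build_constrained_network(tau = 3, n_rec = 64, target_fr = 0.1,
                                   opts = opts)
  expect_equal(rep$status, "success")
  expect_lte(tail(rep$loss_trajectory, 1), 1e-3)
  expect_lte(rep$e_clip, 1e-3)
  wr <- rep$network$w_rec
  expect_true(all(diag(wr) == 0))
  types <- rep$neuron_types
  expect_equal(sum(types == "Ex"), round(64 * 4 / 5))
  sign_pure <- vapply(seq_len(ncol(wr)), function(j) {
    if (types[j] == "Ex") all(wr[j, ] >= 0) else all(wr[j, ] <= 0)
  }, logical(1))
  expect_true(all(sign_pure))
  W <- rep$w_constrained
  expect_gte(mean(W == 0), 0.4)
  # behaviour preserved
  fit <- rep$fit
  stim <- random_stimuli(300)
  z0 <- fit$network$Z[1, ]
  t1 <- simulate_network(fit$network, stim, z0 = z0)
  t2 <- simulate_network(rep$network, stim, z0 = z0)
  expect_identical(t1$raster, t2$raster)
  expect_equal(decode_accuracy(t2, 3), 1.0)
})

test_that("every projected update stays in the null space of C", {
  set.seed(24)
  fit <- construct_network(tau = 3, n_rec = 32, target_fr = 0.1)
  W0 <- rbind(fit$network$w_in, fit$network$w_rec)
  rep <- constrain_structure(fit$network, fit$system,
                             constraint_options(ex_in_ratio = c(1, 1)))
  # regardless of outcome, the pre-clip weights still solve the system
  if (rep$status == "success") {
    dW <- rep$w_constrained
    expect_lt(mean(abs(fit$system$C %*% dW - fit$system$U)), 1e-3)
  }
  expect_lt(max(abs(fit$system$C %*% W0 - fit$system$U)), 1e-8)
})

test_that("feasibility improves with network size at fixed tau", {
  set.seed(25)
  opts <- constraint_options(ex_in_ratio = c(4, 1), sparsity = 0.4)
  rate <- vapply(c(32, 48, 64), function(n) {
    mean(replicate(10, {
      fit <- construct_network(tau = 3, n_rec = n, target_fr = 0.1)
      constrain_structure(fit$network, fit$system, opts)$status == "success"
    }))
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
  expect_gt(rate[3], rate[1])
  expect_gte(rate[3], 0.3)
})
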