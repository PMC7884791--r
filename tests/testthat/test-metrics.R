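test_that("firing rate is the raster mean with per-neuron detail", {
  expect_equal(as.numeric(firing_rate(matrix(1, 5, 3))), 1)
  alt <- matrix(c(1, 0), 10, 1)
  expect_equal(as.numeric(firing_rate(alt)), 0.5)
  r <- cbind(rep(1, 4), rep(0, 4))
  expect_equal(attr(firing_rate(r), "per_neuron"), c(1, 0))
  expect_error(firing_rate(matrix(numeric(0), 0, 0)), "empty")
})

test_that("pairwise rank correlation equals product-moment on binary trains", {
  set.seed(40)
  r <- matrix(rbinom(200, 1, 0.4), 50, 4)
  cm <- attr(pairwise_cc(r), "pairs")
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(cm[i, j], oracle_spearman(r[, i], r[, j]))
    expect_equal(cm[i, j], cor(r[, i], r[, j]))  # rank degeneracy
  }
  expect_equal(as.numeric(pairwise_cc(cbind(r[, 1], r[, 1]))), 1)
})

test_that("independent trains sit at the analytic absolute-correlation null", {
  set.seed(41)
  n <- 1280
  r <- matrix(rbinom(n * 40, 1, 0.5), n, 40)
  got <- pairwise_cc(r, absolute = TRUE, drop_constant = TRUE)
  expect_equal(as.numeric(got), sqrt(2 / (pi * (n - 1))), tolerance = 0.05)
})

test_that("noise correlation averages the per-stimulus means", {
  set.seed(42)
  stim <- rep(1:2, each = 30)
  r <- matrix(rbinom(60 * 4, 1, 0.5), 60, 4)
  got <- pairwise_cc(r, stim, mode = "noise")
  per <- sapply(1:2, function(s) {
    cm <- suppressWarnings(cor(r[stim == s, ], method = "spearman"))
    cm[is.na(cm)] <- 0
    mean(cm[upper.tri(cm)])
  })
  expect_equal(as.numeric(got), mean(per))
})

test_that("ISI shuffling conserves spike counts and the boundary convention", {
  set.seed(43)
  for (i in 1:20) {
    r <- matrix(rbinom(300, 1, runif(1, 0.05, 0.9)), 60, 5)
    s <- isi_shuffle(r)
    expect_equal(colSums(s), colSums(r))
    expect_true(all(s %in% c(0, 1)))
  }
  # single-spike trains are invariant (leading gap permuted alone)
  one <- matrix(0, 10, 1); one[4, 1] <- 1
  expect_equal(isi_shuffle(one), one)
  # empty trains unchanged
  expect_equal(isi_shuffle(matrix(0, 5, 2)), matrix(0, 5, 2))
  # two spikes: both gap orders occur, trailing remainder fixed
  two <- matrix(0, 6, 1); two[c(2, 5), 1] <- 1
  seen <- replicate(200, paste(which(isi_shuffle(two)[, 1] == 1),
                               collapse = ","))
  expect_setequal(unique(seen), c("2,5", "3,5"))
})

test_that("shuffling destroys the correlations of constructed networks", {
  set.seed(44)
  fit <- construct_network(tau = 5, target_fr = 0.5)
  r <- post_burn(quick_trace(fit, 640, 5))
  before <- pairwise_cc(r, absolute = TRUE, drop_constant = TRUE)
  after <- pairwise_cc(isi_shuffle(r), absolute = TRUE, drop_constant = TRUE)
  expect_lt(after, before / 2)
  expect_lt(abs(after - sqrt(2 / (pi * (nrow(r) - 1)))), 0.01)
})

test_that("reciprocity conventions: symmetry, scaling invariance, null", {
  set.seed(45)
  A <- matrix(runif(64), 8, 8)
  S <- (A + t(A)) / 2
  diag(S) <- 0
  expect_equal(reciprocity(S), 1)
  W <- matrix(rnorm(64 * 64), 64, 64)
  expect_equal(reciprocity(W), reciprocity(3.7 * W))
  # iid entries: null distribution around zero
  vals <- replicate(20, reciprocity(matrix(rnorm(64 * 64), 64, 64)))
  n_pairs <- 64 * 63
  expect_gt(mean(abs(vals) < 3 / sqrt(n_pairs)), 0.9)
  # degenerate inputs are flagged
  expect_warning(out <- reciprocity(matrix(1, 4, 4)), "degenerate")
  expect_true(is.na(out))
})

test_that("ks_normal behaves at the null and at a degenerate alternative", {
  set.seed(46)
  expect_lt(ks_normal(rnorm(1000)), 0.15)
  expect_warning(k1 <- ks_normal(rep(1, 100)), "degenerate")
  expect_equal(k1, 1)
})

test_that("signal correlation peaks at intermediate firing rates", {
  set.seed(47)
  ccs <- vapply(c(0.1, 0.5, 0.9), function(fr) {
    mean(replicate(3, {
      fit <- construct_network(tau = 6, target_fr = fr)
      r <- post_burn(quick_trace(fit, 640, 6))
      as.numeric(pairwise_cc(r, absolute = TRUE, drop_constant = TRUE))
    }))
  }, numeric(1))
  expect_gt(ccs[2], ccs[1])
  expect_gt(ccs[2], ccs[3])
})

test_that("metrics_report bundles the statistics coherently", {
  set.seed(48)
  fx <- make_fixture("toy_stask")
  rep <- metrics_report(fx$network, fx$trace)
  expect_s3_class(rep, "metrics_report")
  expect_true(rep$fr >= 0 && rep$fr <= 1)
  expect_true(abs(rep$cc_all) <= 1)
  expect_true(abs(rep$reciprocity) <= 1)
})
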