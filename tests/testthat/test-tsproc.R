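fake_confounds <- function(Tn, fd = NULL, seed = 1) {
  set.seed(seed)
  cf <- data.frame(trans_x = rnorm(Tn, sd = 0.01),
                   trans_y = rnorm(Tn, sd = 0.01),
                   trans_z = rnorm(Tn, sd = 0.01),
                   rot_x = rnorm(Tn, sd = 1e-4),
                   rot_y = rnorm(Tn, sd = 1e-4),
                   rot_z = rnorm(Tn, sd = 1e-4),
                   framewise_displacement = fd %||% runif(Tn, 0, 0.3),
                   global_signal = rnorm(Tn))
  for (i in 1:10) cf[[sprintf("a_comp_cor_%02d", i - 1)]] <- rnorm(Tn)
  cf
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("motion expansion yields 24 regressors plus the stated blocks", {
  cf <- fake_confounds(100)
  X <- build_confound_matrix(cf)
  prov <- attr(X, "provenance")
  expect_equal(sum(prov == "motion24"), 24)
  expect_equal(sum(prov == "global_signal"), 1)
  expect_equal(sum(prov == "compcor"), 10)
  expect_equal(sum(prov == "cosine"), 18)
})

test_that("each FD excursion above 0.9 mm gets its own spike column", {
  fd <- rep(0.1, 80); fd[c(20, 55)] <- 1.3
  X <- build_confound_matrix(fake_confounds(80, fd = fd))
  spikes <- X[, attr(X, "provenance") == "spike", drop = FALSE]
  expect_equal(ncol(spikes), 2)
  expect_equal(which(spikes[, 1] == 1), 20)
  expect_equal(which(spikes[, 2] == 1), 55)
  expect_true(all(colSums(spikes) == 1))
})

test_that("global signal column is controlled by its flag only", {
  cf <- fake_confounds(60)
  X1 <- build_confound_matrix(cf, use_global_signal = TRUE)
  X0 <- build_confound_matrix(cf, use_global_signal = FALSE)
  expect_true("global_signal" %in% colnames(X1))
  expect_false("global_signal" %in% colnames(X0))
  expect_equal(X1[, setdiff(colnames(X1), "global_signal")], X0,
               ignore_attr = TRUE)
  cf$rot_z <- NULL
  expect_error(build_confound_matrix(cf), "rot_z")
})

test_that("denoising projects out the confound span exactly", {
  set.seed(3)
  Tn <- 120
  cf <- fake_confounds(Tn)
  X <- build_confound_matrix(cf, n_cosine = 4)
  y <- matrix(rnorm(Tn * 3), Tn, 3, dimnames = list(NULL, c("a", "b", "c")))
  # a node equal to a confound is annihilated
  y[, 1] <- cf$global_signal
  expect_warning(res <- denoise(y, X), "constant after denoising")
  expect_lt(sqrt(sum(res[, 1]^2)) / sqrt(sum(y[, 1]^2)), 1e-10)
  # residuals orthogonal to every retained regressor
  keep <- apply(X, 2, sd) > 0
  expect_lt(max(abs(cor(res[, 2:3], X[, keep]))), 1e-8)
  expect_lt(max(abs(colMeans(res))), 1e-12)
})

test_that("regressors orthogonal to the signal leave it demeaned", {
  Tn <- 64
  t <- seq_len(Tn)
  y <- matrix(sin(2 * pi * t / 8) + 5, Tn, 1, dimnames = list(NULL, "n1"))
  # a single spike regressor far from the sinusoid's support structure
  X <- matrix(0, Tn, 1, dimnames = list(NULL, "spike"))
  X[32, 1] <- 1
  res <- denoise(y, X)
  y_dm <- y - mean(y)
  expect_equal(res[-32, 1], y_dm[-32, 1], tolerance = 1e-8)
  expect_error(denoise(y[1:3, , drop = FALSE], diag(4)[1:3, ]),
               "more regressors")
})

test_that("fisher transform has its closed form and round-trips", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
  expect_error(fisher_z(1), "< 1")
})

test_that("wiener deconvolution approximately inverts HRF convolution", {
  set.seed(9)
  k <- cppigraph:::hrf_kernel(2)
  x <- rnorm(300)
  y <- stats::convolve(x, rev(k), type = "open")[1:300]
  est <- wiener_deconvolve(y, k, lambda = 1e-4)
  expect_gt(cor(est, x), 0.95)
})

test_that("cPPI output is symmetric, zero-diagonal, and run-average stable", {
  d <- simulate_design(2, 2, seed = 3)
  set.seed(5)
  y <- matrix(rnorm(d$n_volumes_retained * 4), ncol = 4,
              dimnames = list(NULL, paste0("n", 1:4)))
  z1 <- cppi_matrix(y, d)
  expect_equal(unclass(z1), t(unclass(z1)), ignore_attr = TRUE)
  expect_equal(diag(z1), rep(0, 4), ignore_attr = TRUE)
  # averaging two identical runs changes nothing
  z2 <- cppi_matrix(list(y, y), d)
  expect_equal(unclass(z1), unclass(z2), ignore_attr = TRUE)
  expect_equal(attr(z2, "n_runs"), 2)
})

test_that("cPPI is invariant under affine rescaling of the input series", {
  d <- simulate_design(2, 2, seed = 3)
  set.seed(6)
  y <- matrix(rnorm(d$n_volumes_retained * 5), ncol = 5,
              dimnames = list(NULL, paste0("n", 1:5)))
  z1 <- cppi_matrix(y, d)
  z2 <- cppi_matrix(sweep(y * 7.3, 2, c(1, -2, 3, 0.5, 10), `+`), d)
  expect_equal(unclass(z1), unclass(z2), tolerance = 1e-8)
})

test_that("cPPI separates task-modulated from unmodulated coupling", {
  # n1-n2 is coupled at 0.8 during fluency blocks only (task-modulated);
  # n1-n3 carries a constant 0.2 coupling through the whole run. The PPI
  # covariance weights coupling by the squared psychological vector, so the
  # unmodulated pair keeps a smaller positive z while the modulated pair
  # stands clearly above it.
  d <- simulate_design(6, 6, seed = 2)
  part <- c(n1 = "A", n2 = "A", n3 = "B", n4 = "B")
  coup <- default_coupling()
  coup$young <- list(fluency = list(within = 0.8, between = 0.2),
                     counting = list(within = 0.0, between = 0.2),
                     rest = list(within = 0.0, between = 0.2))
  spec <- cohort_spec(n_young = 1, n_old = 1, partition = part,
                      coupling = coup, noise_sd = 0.2, signal_sd = 1.5,
                      motion_spike_rate = 0, seed = 77)
  zs <- sapply(1:10, function(r) {
    s <- simulate_subject(spec, d, "s1", "young", run = r)
    z <- cppi_matrix(s$series, d)
    c(modulated = z["n1", "n2"], constant = z["n1", "n3"])
  })
  expect_gt(mean(zs["modulated", ]), 0.2)
  expect_gt(mean(zs["modulated", ]) - mean(zs["constant", ]), 0.1)
})

test_that("network averaging collapses node series correctly", {
  y <- cbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(5, 5, 5))
  part <- c(a = "net1", b = "net1", c = "net2")
  avg <- network_average_series(y, part)
  expect_equal(avg[, "net1"], c(2, 2, 2), ignore_attr = TRUE)
  expect_equal(avg[, "net2"], c(5, 5, 5), ignore_attr = TRUE)
  # single-node community is its own series; opposite series cancel
  y2 <- cbind(a = 1:3, b = -(1:3))
  expect_equal(network_average_series(y2, c(a = "x", b = "x"))[, "x"],
               rep(0, 3), ignore_attr = TRUE)
  expect_error(network_average_series(y, part[1:2]), "not covered")
})

test_that("dropping global signal shifts connectivity positively", {
  d <- simulate_design(3, 3, seed = 4)
  spec <- cohort_spec(n_young = 2, n_old = 0, n_runs = 1, seed = 31)
  co <- simulate_cohort(spec, d)
  shift <- sapply(co$subjects$subject, function(s) {
    run <- co$runs[[s]][[1]]
    z_gsr <- cppi_matrix(denoise(run$series,
                                 build_confound_matrix(run$confounds, TRUE)), d)
    z_nogsr <- cppi_matrix(denoise(run$series,
                                   build_confound_matrix(run$confounds, FALSE)), d)
    mean(z_nogsr[upper.tri(z_nogsr)]) - mean(z_gsr[upper.tri(z_gsr)])
  })
  expect_true(all(shift > 0))
})
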