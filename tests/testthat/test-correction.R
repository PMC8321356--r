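test_that("quotient respects the object threshold", {
  m1 <- matrix(c(2.0, 1.0, 0.5), 1, 3)
  m2 <- matrix(c(1.0, 0.1, 0.25), 1, 3)
  q <- compute_quotient(m1, m2, m0 = 0.2)
  expect_equal(q$r[1, 1], 2.0)
  expect_false(q$mask[1, 2])      # m2 below 0.2 excluded regardless of m1
  expect_true(q$mask[1, 3])
  expect_equal(q$r[1, 2], 0)      # off-mask pixels carry 0, not garbage

  m2b <- matrix(2, 4, 4); m1b <- 2 * m2b
  qb <- compute_quotient(m1b, m2b)
  expect_true(all(qb$r == 2))

  expect_error(compute_quotient(m1, matrix(0.1, 1, 3)), "no object")
})

test_that("quadratic fit recovers planted coefficients and flags degeneracy", {
  set.seed(1)
  m2 <- matrix(runif(4000, 0.3, 3), 50, 80)
  r <- 0.01 * m2^2 - 0.1 * m2 + 2
  mask <- matrix(TRUE, 50, 80)
  fit <- fit_thickness_polynomial(r, m2, mask)
  expect_equal(c(fit$a, fit$b, fit$c), c(0.01, -0.1, 2), tolerance = 1e-8)
  expect_lt(fit$residual_rms, 1e-10)

  # constant quotient: pure intercept
  fitc <- fit_thickness_polynomial(matrix(2, 50, 80), m2, mask)
  expect_equal(c(fitc$a, fitc$b, fitc$c), c(0, 0, 2), tolerance = 1e-10)

  expect_error(fit_thickness_polynomial(r, matrix(1, 50, 80), mask),
               "degenerate")
})

test_that("correction removes its own fit and reduces to identity at zero fit", {
  set.seed(2)
  m2 <- matrix(runif(1000, 0.3, 3), 25, 40)
  mask <- matrix(TRUE, 25, 40)
  r <- 0.05 * m2^2 + 0.2 * m2 + 1.4
  fit <- fit_thickness_polynomial(r, m2, mask)
  rp <- apply_correction(r, m2, fit, mask)
  expect_lt(max(abs(rp)), 1e-8)

  zero <- structure(list(a = 0, b = 0, c = 0, residual_rms = 0,
                         n_pixels = 0), class = "dexa_fit")
  expect_equal(apply_correction(r, m2, zero, mask), r)

  # least-squares orthogonality: zero mean residual over the mask
  rn <- r + matrix(rnorm(1000, sd = 0.1), 25, 40)
  fitn <- fit_thickness_polynomial(rn, m2, mask)
  rpn <- apply_correction(rn, m2, fitn, mask)
  expect_lt(abs(mean(rpn[mask])), 1e-12)
})

test_that("bin-wise normalization standardizes each emitted bin", {
  # single bin, hand-computed: {2, 4} -> mean 3, sample sd sqrt(2)
  rp <- matrix(c(2, 4), 1, 2)
  m2 <- matrix(c(0.25, 0.25), 1, 2)
  mask <- matrix(TRUE, 1, 2)
  nm <- normalize_quotient(rp, m2, mask, min_count = 1)
  expect_equal(as.vector(nm$n), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  # {-1, 0, 1} is already standardized
  nm2 <- normalize_quotient(matrix(c(-1, 0, 1), 1, 3),
                            matrix(0.3, 1, 3), matrix(TRUE, 1, 3),
                            min_count = 1)
  expect_equal(as.vector(nm2$n), c(-1, 0, 1), tolerance = 1e-12)

  # every emitted bin: mean 0, sample sd 1 to machine precision
  set.seed(3)
  m2r <- matrix(runif(5000, 0.2, 1.4), 50, 100)
  rpr <- matrix(rnorm(5000), 50, 100)
  maskr <- matrix(TRUE, 50, 100)
  nr <- normalize_quotient(rpr, m2r, maskr, min_count = 1)
  idx <- pmax(floor((m2r - 0.2) / 0.1), 0)
  for (b in nr$bins$bin_index) {
    members <- nr$n[maskr & idx == b]
    expect_equal(length(members), nr$bins$count[nr$bins$bin_index == b])
    expect_lt(abs(mean(members)), 1e-12)
    expect_lt(abs(sd(members) - 1), 1e-12)
  }

  # degenerate single zero-spread bin: N == 0 with a warning
  expect_warning(
    nd <- normalize_quotient(matrix(1, 2, 2), matrix(0.25, 2, 2),
                             matrix(TRUE, 2, 2), min_count = 1),
    "degenerate")
  expect_true(all(nd$n == 0))
  expect_true(nd$degenerate)
})

test_that("small bins are merged into the nearest populated bin", {
  # 30 pixels at m2 ~ 0.25 (bin 0), 3 pixels at m2 ~ 0.95 (bin 7)
  m2 <- matrix(c(runif(30, 0.21, 0.29), runif(3, 0.91, 0.99)), 1, 33)
  rp <- matrix(rnorm(33), 1, 33)
  mask <- matrix(TRUE, 1, 33)
  nm <- normalize_quotient(rp, m2, mask, min_count = 20)
  expect_equal(nrow(nm$bins), 1)      # far bin merged in
  expect_equal(nm$bins$count, 33)
})

test_that("masked-out pixels never influence fit, bins, or N", {
  set.seed(4)
  m2 <- matrix(runif(900, 0.3, 2), 30, 30)
  r <- 0.02 * m2^2 + 1.5 + matrix(rnorm(900, sd = 0.02), 30, 30)
  mask <- matrix(TRUE, 30, 30); mask[1:10, 1:10] <- FALSE

  fit1 <- fit_thickness_polynomial(r, m2, mask)
  rp1 <- apply_correction(r, m2, fit1, mask)
  n1 <- normalize_quotient(rp1, m2, mask)

  # poison the masked-out region; nothing downstream may change
  r2 <- r; r2[!mask] <- 1e6
  m2b <- m2; m2b[!mask] <- -7
  fit2 <- fit_thickness_polynomial(r2, m2b, mask)
  expect_identical(c(fit1$a, fit1$b, fit1$c), c(fit2$a, fit2$b, fit2$c))
  rp2 <- apply_correction(r2, m2b, fit2, mask)
  n2 <- normalize_quotient(rp2, m2b, mask)
  expect_identical(n1$n[mask], n2$n[mask])
  expect_identical(n1$bins, n2$bins)
})

test_that("monochromatic spectra give a constant quotient and null correction", {
  acq <- acquisition_config(
    spectra = list(delta_spectrum(40, 40), delta_spectrum(70, 90)),
    noise = FALSE)
  ph <- generate_phantom(c(64, 64), "none", seed = 5)
  pr <- simulate_pair(ph, acq)
  q <- compute_quotient(pr$m1, pr$m2)
  vals <- q$r[q$mask]
  expect_lt(diff(range(vals)), 1e-12)
  fit <- fit_thickness_polynomial(q$r, pr$m2, q$mask)
  rp <- apply_correction(q$r, pr$m2, fit, q$mask)
  expect_lt(max(abs(rp[q$mask])), 1e-10)
})

test_that("preprocess chain behaves on noiseless and noisy phantoms", {
  # noiseless homogeneous phantom: N stays small everywhere
  ph <- generate_phantom(c(128, 128), "none", seed = 6)
  pp0 <- preprocess(simulate_pair(ph, acquisition_config(noise = FALSE)))
  expect_lt(quantile(abs(pp0$norm$n[pp0$mask]), 0.99), 3)

  # noiseless planted bone: bone pixels stand out positively
  phb <- generate_phantom(c(128, 128), "fan", seed = 7)
  prb <- simulate_pair(phb, acquisition_config(noise = FALSE))
  ppb <- preprocess(prb)
  expect_gt(mean(ppb$norm$n[prb$truth & ppb$mask]),
            mean(ppb$norm$n[!prb$truth & ppb$mask]))

  # paper-like noise at default acquisition: bone mean N of order units
  phn <- generate_phantom(defect_class = "fan", seed = 8)
  prn <- simulate_pair(phn, acquisition_config(seed = 8))
  ppn <- preprocess(prn)
  bn <- mean(ppn$norm$n[prn$truth & ppn$mask])
  expect_gt(bn, 1)
  expect_lt(bn, 7)
})
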