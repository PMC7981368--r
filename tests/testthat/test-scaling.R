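# Power-law fitting, bi-phasic analysis, region detection, the composite
# dipole model and energetics.

test_that("exact power laws are recovered exactly", {
  tr <- sim_powerlaw_hiis(gamma = 1.41, beta = -8.4, x = 1:200)
  fit <- powerlaw_fit(tr$x, tr$I)
  expect_equal(fit$gamma, 1.41, tolerance = 1e-12)
  expect_equal(fit$beta, -8.4, tolerance = 1e-9)
  expect_equal(fit$pc, 1, tolerance = 1e-12)
  # constant trace -> zero slope
  fit0 <- powerlaw_fit(1:50, rep(2.5, 50))
  expect_equal(fit0$gamma, 0, tolerance = 1e-12)
  # masking and minimum-point contract
  expect_warning(powerlaw_fit(1:10, c(rep(1, 8), -1, 0)), "masked")
  expect_error(suppressWarnings(powerlaw_fit(1:3, c(1, -1, -2))), "fewer than 3")
})

test_that("bi-phasic fits recover planted piecewise exponents", {
  l <- seq(2, 40, length.out = 500)
  xi <- 14; s <- 4
  I <- ifelse(l <= xi, l^1.41, xi^(1.41 + 2.76) * l^(-2.76))
  tr <- data.frame(alpha = seq_along(l), l = l, I = I)
  bf <- fit_biphasic(tr, s, xi, x_axis = "physical_l")
  expect_equal(bf$gamma_pre, 1.41, tolerance = 1e-6)
  expect_equal(bf$gamma_post, -2.76, tolerance = 1e-6)
  expect_equal(abs(bf$pc_pre), 1, tolerance = 1e-9)
  # a pure single power law yields equal slopes in both phases
  I2 <- l^0.8
  bf2 <- fit_biphasic(data.frame(alpha = seq_along(l), l = l, I = I2), s, xi,
                      x_axis = "physical_l")
  expect_equal(bf2$gamma_pre, bf2$gamma_post, tolerance = 1e-9)
  # segment with < 3 points errors
  expect_error(fit_biphasic(tr[1:5, ], 1.9, 39, x_axis = "physical_l"),
               "fewer than 3")
})

test_that("index-axis and physical-axis slopes differ (affine, not proportional map)", {
  l <- seq(10, 40, length.out = 400)
  tr <- data.frame(alpha = seq_along(l), l = l, I = l^2)
  pre <- fit_biphasic(tr, 12, 30, x_axis = "alpha_index")
  phys <- fit_biphasic(tr, 12, 30, x_axis = "physical_l")
  expect_equal(phys$gamma_pre, 2, tolerance = 1e-9)
  expect_gt(abs(pre$gamma_pre - phys$gamma_pre), 0.1)
})

test_that("noisy power-law recovery is unbiased", {
  g <- vapply(1:100, function(i) {
    tr <- sim_powerlaw_hiis(1.41, -8.4, x = 1:100, noise_sd = 0.01, seed = i)
    powerlaw_fit(tr$x, tr$I)$gamma
  }, 0)
  expect_lt(abs(mean(g) - 1.41), 0.02)
})

test_that("aggregation reduces to the exact mean and boundary indices", {
  mk_tr <- function(v, l = seq(2, 10, length.out = length(v))) {
    structure(data.frame(alpha = seq_along(v), l = l, N = v, I = v),
              class = c("radial_trace", "data.frame"))
  }
  # identical traces: mean equals the trace, zero-width band
  tr <- mk_tr(c(1, 2, 3))
  agg <- aggregate_traces(list(tr, tr), "N")
  expect_equal(agg$mean, c(1, 2, 3) / 3)
  expect_equal(agg$lo95, agg$hi95)
  # two mirrored traces -> constant mean
  agg2 <- aggregate_traces(list(mk_tr(c(1, 2, 3)), mk_tr(c(3, 2, 1))), "N",
                           normalize = FALSE)
  expect_equal(agg2$mean, c(2, 2, 2))
  # boundary indices equal the brute-force average of nearest indices
  set.seed(5)
  traces <- lapply(1:50, function(i) mk_tr(cumsum(runif(20)), l = seq(1, 20)))
  xi <- runif(50, 3, 18)
  agg3 <- aggregate_traces(traces, "N", boundaries = data.frame(xi = xi))
  brute <- mean(vapply(seq_along(traces),
                       function(i) which.min(abs(traces[[i]]$l - xi[i])), 0))
  expect_equal(agg3$alpha_xi, brute)
  expect_error(aggregate_traces(list(), "N"), "empty")
})

test_that("scale-invariant regions are the exact contiguous threshold runs", {
  pz <- seq(-20, -14, by = 0.5)
  per <- data.frame(p_z = pz, pc_pre = 0.5, pc_post = -0.5)
  inside <- pz >= -18 & pz <= -16.5
  per$pc_pre[inside] <- 0.995
  per$pc_post[inside] <- -0.99
  reg <- scale_invariant_regions(per, 0.97)
  expect_equal(nrow(reg), 1)
  expect_equal(c(reg$z_min, reg$z_max), c(-18, -16.5))
  # nothing above threshold -> empty
  expect_equal(nrow(scale_invariant_regions(
    data.frame(p_z = pz, pc_pre = 0.5, pc_post = 0.5), 0.97)), 0)
})

test_that("region detection is invariant to uniform rescaling of the imbalance", {
  l <- seq(5, 30, length.out = 200)
  tr <- data.frame(alpha = seq_along(l), l = l, I = 2 * l^1.2)
  b1 <- fit_biphasic(tr, 6, 15, x_axis = "physical_l")
  tr$I <- tr$I * 37.5
  b2 <- fit_biphasic(tr, 6, 15, x_axis = "physical_l")
  expect_equal(b1$gamma_pre, b2$gamma_pre, tolerance = 1e-12)
  expect_equal(b1$pc_pre, b2$pc_pre, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(b1$beta_pre, b2$beta_pre)))
})

test_that("the composite dipole model is exact when the data follow it", {
  par <- list(A = 1.05, t = 0.2, s = 18.02, q_tilde = 0.54)
  l <- seq(10, 40, length.out = 400)
  fit <- fit_packing(l, packing_curve("richards", par, l), "richards",
                     normalize = FALSE)
  ncurve <- packing_curve("richards", fit$par, l)
  gp <- 2.27; gq <- -4.36
  hz <- -ifelse(l <= fit$xi, ncurve * l^gp,
                ncurve * fit$xi^(gp - gq) * l^gq)
  trace <- data.frame(alpha = seq_along(l), l = l, h_z = hz,
                      I = abs(hz), N = ncurve)
  bi <- structure(list(x_axis = "physical_l", gamma_pre = gp, gamma_post = gq),
                  class = "biphasic_fit")
  cm <- chdf_composite(fit, bi, trace)
  expect_lt(cm$mafe_pre, 1e-9)
  expect_lt(cm$mafe_post, 1e-9)
  expect_equal(cm$orientation, -1)       # "out" state preserved
  expect_true(all(cm$model_h >= 0, na.rm = TRUE))
})

test_that("a zero exponent degenerates the composite model to a scaled sigmoid", {
  par <- list(A = 1, t = 0.2, s = 15, q_tilde = 0.6)
  l <- seq(8, 35, length.out = 300)
  n <- packing_curve("richards", par, l)
  fit <- fit_packing(l, n, "richards", normalize = FALSE)
  trace <- data.frame(alpha = seq_along(l), l = l, h_z = -3 * n, I = 3 * n,
                      N = n)
  bi <- structure(list(x_axis = "physical_l", gamma_pre = 0, gamma_post = 0),
                  class = "biphasic_fit")
  cm <- chdf_composite(fit, bi, trace)
  sel <- is.finite(cm$model_h)
  expect_equal(cm$model_h[sel], 3 * packing_curve("richards", fit$par, l)[sel],
               tolerance = 1e-6)
})

test_that("coupling energy respects the [nu, xi] window", {
  l <- seq(5, 30, length.out = 100)
  AE <- dnorm(l, mean = 15, sd = 3)     # peak at l = 15
  tr <- data.frame(alpha = seq_along(l), l = l, AE = AE)
  ce <- coupling_energy(tr, 12, 20)
  expect_equal(ce$l_at_max, 15, tolerance = diff(l[1:2]))
  expect_equal(ce$max, max(AE))
  expect_equal(ce$first, AE[1]); expect_equal(ce$last, AE[100])
  # a window excluding the peak returns the window-restricted maximum
  ce2 <- coupling_energy(tr, 20, 28)
  expect_lt(ce2$max, ce$max)
  expect_error(coupling_energy(tr, 40, 50), "nu < xi|empty")
})

test_that("crossover correlation summarizes xi-nu agreement", {
  pz <- seq(-10, 10, by = 1)
  xi <- 20 + 0.3 * pz^2 / 10
  per <- data.frame(p_z = pz, xi = xi, nu = xi)
  cc <- crossover_correlation(per)
  expect_equal(cc$mean_dist, 0)
  expect_equal(cc$spearman_pos, 1); expect_equal(cc$spearman_neg, 1)
  per$nu <- per$xi + 2
  cc2 <- crossover_correlation(per)
  expect_equal(cc2$mean_dist, 2); expect_equal(cc2$sd_dist, 0)
  expect_equal(cc2$spearman_pos, 1)
  # tiny subset -> NA
  cc3 <- crossover_correlation(per[per$p_z <= 0, ])
  expect_true(is.na(cc3$spearman_pos))
})

test_that("domain composition fractions are normalized and match hand counts", {
  # concentric labeled shells around the origin
  set.seed(77)
  u <- matrix(rnorm(300 * 3), ncol = 3); u <- u / sqrt(rowSums(u^2))
  xyz <- u * rep(c(5, 12, 25), each = 100)
  ch <- mk_channel(xyz, segment = rep(c("S5", "S6", "S1"), each = 100))
  comp <- domain_composition(ch, c(0, 0, 0), s = 8, o = 18)
  expect_equal(unname(comp["lag", "S5"]), 1)
  expect_equal(unname(comp["inflection", "S6"]), 1)
  expect_equal(unname(comp["asymptote", "S1"]), 1)
  expect_equal(unname(rowSums(comp)), rep(1, 3))
})
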