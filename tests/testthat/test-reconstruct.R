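score_model <- function() set_mode(tiny_trained()$model, "score")

test_that("objective components behave as an additive decomposition", {
  pc <- tiny_phantom_config()
  ph <- generate_phantom(pc, 1)
  g <- tiny_full()
  y <- forward_project(ph, g)
  m <- score_model()
  tv <- tv_config(epsilon = 1e-6)

  # consistent data, data term only -> exactly zero objective
  rc0 <- recon_config(alpha1 = 1, alpha2 = 0, alpha3 = 0)
  ob <- objective(ph, y, m, tv, rc0)
  expect_identical(ob$F, 0)
  expect_identical(ob$data_term, 0)

  # term isolation: alpha1 = alpha3 = 0
  rc_cnn <- recon_config(alpha1 = 0, alpha2 = 0.37, alpha3 = 0)
  ob2 <- objective(ph, y, m, tv, rc_cnn)
  expect_equal(ob2$F, 0.37 * cnn_score(m, ph), tolerance = 1e-14)

  # components always sum to F
  rc <- recon_config(alpha1 = 2, alpha2 = 0.5, alpha3 = 0.1)
  ob3 <- objective(ph, y, m, tv, rc)
  expect_equal(ob3$F,
               2 * ob3$data_term + 0.5 * ob3$cnn_score + 0.1 * ob3$tv_term,
               tolerance = 1e-12)
  # the CNN score is reported even when its weight is zero
  expect_true(is.finite(objective(ph, y, m, tv, rc0)$cnn_score))
})

test_that("objective gradient matches directional finite differences", {
  pc <- tiny_phantom_config()
  ph <- generate_phantom(pc, 2)
  g <- tiny_few()
  y <- forward_project(ph, g)
  # random weights keep the ReLU pre-activations away from their kinks,
  # where the finite-difference comparison is meaningful
  m <- set_mode(build_cnn(cnn_config(input_size = 32), seed = 47L), "score")
  tv <- tv_config(epsilon = 1e-3)
  rc <- recon_config(alpha1 = 1e-3, alpha2 = 0.05, alpha3 = 1e-3)

  # zero gradient at the minimum of the pure quadratic
  rc_data <- recon_config(alpha1 = 1, alpha2 = 0, alpha3 = 0)
  g0 <- objective_gradient(ph, y, m, tv, rc_data)
  expect_lt(max(abs(g0)), 1e-10)

  set.seed(21)
  x <- fbp(y, g)
  grad <- objective_gradient(x, y, m, tv, rc)
  expect_identical(dim(grad), dim(x))
  expect_true(all(is.finite(grad)))
  h <- 1e-3
  for (rep in 1:5) {
    d <- matrix(rnorm(32 * 32), 32)
    d <- d / sqrt(sum(d^2))
    fp <- objective(x + h * d, y, m, tv, rc)$F
    fm <- objective(x - h * d, y, m, tv, rc)$F
    num <- (fp - fm) / (2 * h)
    ana <- sum(grad * d)
    expect_lt(abs(ana - num), 1e-4 * (1 + abs(num)))
  }
})

test_that("backtracking descent is monotone and fully traced", {
  pc <- tiny_phantom_config()
  ph <- generate_phantom(pc, 3)
  g <- tiny_few()
  y <- forward_project(ph, g)
  m <- score_model()
  rc <- recon_config(alpha1 = 1, alpha2 = 0.2, alpha3 = 0.02, n_iter = 40,
                     step_size = 1, init = "fbp")
  tv <- tv_config(epsilon = 1e-3)
  res <- reconstruct(y, m, rc, tv)

  expect_identical(nrow(res$trace), 41L)
  expect_identical(res$trace$iteration, 0:40)
  expect_true(all(diff(res$trace$F) <= 0))
  expect_true(all(is.finite(res$image)))
  expect_identical(dim(res$image), c(32L, 32L))
})

test_that("pure data-fidelity descent converges on fully sampled data", {
  # smooth object, zero start: steepest descent on the consistent
  # least-squares problem must recover it almost exactly
  sm <- smooth_blob(32)
  g <- geometry(360, 32, image_size = 32)
  y <- forward_project(sm, g)
  m <- score_model()
  rc <- recon_config(alpha1 = 1, alpha2 = 0, alpha3 = 0, n_iter = 150,
                     step_size = 1, init = "zeros")
  res <- reconstruct(y, m, rc, tv_config(epsilon = 1e-3))
  expect_lt(rmse_in_circle(res$image, sm, relative = TRUE), 0.02)
  # and it beats its own starting point by a wide margin
  expect_lt(res$trace$F[151] / res$trace$F[1], 1e-4)
})

test_that("the CNN penalty lowers the final score it penalizes", {
  pc <- tiny_phantom_config()
  ph <- generate_phantom(pc, 5)
  g <- tiny_few()
  y <- forward_project(ph, g)
  m <- score_model()
  tv <- tv_config(epsilon = 1e-3)
  base <- recon_config(alpha1 = 1, alpha2 = 0, alpha3 = 0.02, n_iter = 60)
  with_cnn <- recon_config(alpha1 = 1, alpha2 = 0.2, alpha3 = 0.02,
                           n_iter = 60)
  r0 <- reconstruct(y, m, base, tv)
  r1 <- reconstruct(y, m, with_cnn, tv)
  n <- nrow(r0$trace)
  expect_gte(r0$trace$cnn_score[n], r1$trace$cnn_score[n])
})

test_that("solver guards fire on divergence and bad modes", {
  pc <- tiny_phantom_config()
  ph <- generate_phantom(pc, 6)
  g <- tiny_few()
  y <- forward_project(ph, g)
  m <- score_model()
  # a fixed, absurdly large step makes the quadratic blow up
  rc_bad <- recon_config(alpha1 = 1, alpha2 = 0, alpha3 = 0, n_iter = 50,
                         step_rule = "fixed", step_size = 1e6)
  expect_error(reconstruct(y, m, rc_bad, tv_config(epsilon = 1e-3)),
               "iteration")
  classifier <- set_mode(m, "classifier")
  expect_error(reconstruct(y, classifier, recon_config(n_iter = 1),
                           tv_config(epsilon = 1e-3)),
               "score mode")
})

test_that("nonnegativity clamp and zero initialization are honoured", {
  pc <- tiny_phantom_config()
  ph <- generate_phantom(pc, 7)
  g <- tiny_few()
  y <- forward_project(ph, g)
  m <- score_model()
  rc <- recon_config(alpha1 = 1, alpha2 = 0.1, alpha3 = 0.01, n_iter = 15,
                     init = "zeros", nonnegativity = TRUE)
  res <- reconstruct(y, m, rc, tv_config(epsilon = 1e-3))
  expect_true(all(res$image >= 0))
  expect_identical(res$trace$data_term[1], sum(y$values^2))
})
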