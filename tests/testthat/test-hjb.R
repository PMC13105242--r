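test_that("the reduced bound evaluates and clips correctly", {
  expect_equal(hjb_eval(1, hjb_params(1, 1, 0)), 2)
  expect_equal(hjb_eval(1, hjb_params(1, 1, 3)), 0)   # raw -1, clipped
  expect_error(hjb_eval(0, hjb_params(1, 1, 1)), "positive")
  expect_error(hjb_eval(-2, hjb_params(1, 1, 1)), "positive")
  expect_error(hjb_params(-1, 0, 0), "non-negative")
})

test_that("with no wind subsidy the minimum sits at (a/b)^(1/4)", {
  par <- hjb_params(4, 1, 0)
  Xstar <- (4 / 1)^(1 / 4)
  expect_equal(Xstar, sqrt(2))
  expect_equal(hjb_eval(Xstar, par), 2 * sqrt(4 * 1), tolerance = 1e-12)
  # cross-check by dense grid search
  g <- seq(0.2, 5, by = 1e-4)
  i <- which.min(hjb_eval(g, par))
  expect_equal(g[i], Xstar, tolerance = 1e-3)
  expect_equal(min(hjb_eval(g, par)), 4, tolerance = 1e-6)
})

test_that("the clipped bound is continuous at its zero crossings", {
  set.seed(14)
  checked <- 0
  while (checked < 100) {
    a <- runif(1, 0.05, 2); b <- runif(1, 0.05, 2); W <- runif(1, 0.5, 4)
    par <- hjb_params(a, b, W)
    # roots of b X^4 - W X^3 + a = 0 give the clip boundaries
    roots <- polyroot(c(a, 0, 0, -W, b))
    real <- Re(roots[abs(Im(roots)) < 1e-8])
    real <- real[real > 0]
    if (!length(real)) next
    for (r in real) {
      eps <- 1e-7
      expect_lt(abs(hjb_eval(r + eps, par) - hjb_eval(max(r - eps, eps), par)),
                1e-4)
    }
    checked <- checked + 1
  }
})

test_that("fit_hjb recovers parameters from noiseless frontiers", {
  x <- seq(0.6, 2.4, length.out = 10)
  truth <- hjb_params(0.5, 0.3, 0.2)
  curve <- data.frame(x_center = x, y_frontier = hjb_eval(x, truth))
  fit <- fit_hjb(curve)
  expect_lt(max(abs(coef(fit) - c(0.5, 0.3, 0.2))), 1e-3)
  expect_lt(fit$fit_loss, 1e-8)
})

test_that("recovery is exact for random truths with non-degenerate clipping", {
  set.seed(17)
  found <- 0
  while (found < 20) {
    a <- runif(1, 0.1, 2); b <- runif(1, 0.1, 2)
    W <- runif(1, 0.2, 1.5)
    truth <- c(a = a, b = b, W = W)
    x <- seq(0.5, 2.5, length.out = 14)
    y <- hjb_eval(x, hjb_params(a, b, W))
    # demand an informative frontier: several strictly positive bins
    if (sum(y > 1e-6) < 6) next
    fit <- fit_hjb(data.frame(x_center = x, y_frontier = y))
    expect_lt(max(abs(coef(fit) - truth)), 1e-3)
    found <- found + 1
  }
})

test_that("reported loss never regresses past the multi-start grid", {
  set.seed(19)
  x <- seq(0.6, 2.2, length.out = 12)
  y <- hjb_eval(x, hjb_params(0.8, 0.4, 0.6)) + rnorm(12, 0, 0.05)
  curve <- data.frame(x_center = x, y_frontier = y)
  fit <- fit_hjb(curve, fit_positive_only = FALSE)
  g <- 10^seq(-2, 1, length.out = 5)
  sse <- function(p) sum((y - hjb_eval(x, hjb_params(p[1], p[2], p[3])))^2)
  grid_losses <- apply(as.matrix(expand.grid(g, g, g)), 1, sse)
  expect_lte(fit$fit_loss, min(grid_losses) + 1e-12)
})

test_that("an all-zero frontier is flagged degenerate", {
  curve <- data.frame(x_center = seq(0.8, 1.6, by = 0.1),
                      y_frontier = 0)
  expect_warning(fit <- fit_hjb(curve), "degenerate")
  expect_equal(unname(coef(fit)), c(0, 0, 0))
  expect_true(fit$degenerate)
  expect_error(fit_hjb(curve[1:3, ]), "at least 4")
})

test_that("the fitted model object supports the standard methods", {
  x <- seq(0.6, 2.4, length.out = 12)
  truth <- hjb_params(0.5, 0.3, 0.2)
  set.seed(23)
  curve <- data.frame(x_center = x,
                      y_frontier = hjb_eval(x, truth) + rnorm(12, 0, 0.02))
  fit <- fit_hjb(curve)
  expect_named(coef(fit), c("a", "b", "W"))
  expect_length(predict(fit), 12)
  expect_equal(predict(fit, newdata = 1),
               hjb_eval(1, fit))
  expect_equal(residuals(fit), curve$y_frontier - predict(fit))
  expect_output(print(fit), "a =")
  s <- summary(fit)
  expect_s3_class(s, "summary.hjb_fit")
  expect_output(print(s), "coefficients")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_equal(sims[[1]]$x_center, x)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("noisy frontiers recover parameters within 10 percent", {
  truth <- c(a = 0.5, b = 0.3, W = 0.2)
  x <- seq(0.5, 2.4, length.out = 20)
  mu <- hjb_eval(x, hjb_params(0.5, 0.3, 0.2))
  ests <- matrix(NA_real_, 50, 3)
  for (s in 1:50) {
    set.seed(100 + s)
    y <- mu + rnorm(20, 0, 0.02)
    ests[s, ] <- coef(fit_hjb(data.frame(x_center = x, y_frontier = y),
                              fit_positive_only = FALSE))
  }
  rel <- abs(colMeans(ests) - truth) / truth
  expect_true(all(rel < 0.10))
})
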