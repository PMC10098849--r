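# Logistic regression: likelihood, fitting, prediction, evaluation.

test_that("predict_proba reproduces closed-form sigmoid values", {
  model <- structure(
    list(weights = c(0, 0, 0), raw_weights = c(0, 0, 0),
         feature_names = c("a", "b"),
         scaler = list(center = c(0, 0), scale = c(1, 1)), threshold = 0.5),
    class = "logit_model")
  expect_equal(predict_proba(model, c(3, -2)), 0.5)
  # w.x = ln 3 -> p = 0.75
  model$weights <- c(log(3), 0, 0)
  expect_equal(predict_proba(model, c(1, 0)), 0.75)
  # complement sums to one for random inputs
  set.seed(71)
  model$weights <- rnorm(3)
  for (i in 1:5) {
    x <- rnorm(2)
    p1 <- predict_proba(model, x)
    eta <- sum(model$weights * c(x, 1))
    expect_equal(p1 + 1 / (1 + exp(eta)), 1)
  }
  expect_error(predict_proba(model, c(1, 2, 3)), "mismatch")
  expect_error(predict_proba(model, c(1, NA)), "non-finite")
})

test_that("log-likelihood matches closed forms and the Bernoulli product", {
  n <- 7
  X <- cbind(matrix(rnorm(2 * n), n), 1)
  y <- rep(c(0, 1), length.out = n)
  expect_equal(log_likelihood(c(0, 0, 0), X, y), -n * log(2))
  expect_equal(log_likelihood(c(0, 0, 0), matrix(c(1, 1, 1), 1), 1), -log(2))
  # oracle: product of Bernoulli masses, then log
  set.seed(72)
  for (i in 1:5) {
    w <- rnorm(3)
    X5 <- cbind(matrix(rnorm(10), 5), 1)
    y5 <- rbinom(5, 1, 0.5)
    p <- 1 / (1 + exp(-drop(X5 %*% w)))
    expect_equal(log_likelihood(w, X5, y5),
                 log(prod(p^y5 * (1 - p)^(1 - y5))))
  }
  expect_error(log_likelihood(c(0, 0, 0), X, rep(2, n)), "0 or 1")
})

test_that("MLE recovers generating weights within 3 SE (Monte-Carlo)", {
  wstar <- c(1.2, -0.8)
  bstar <- 0.3
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    X <- cbind(a = rnorm(2000), b = rnorm(2000))
    p <- 1 / (1 + exp(-(X %*% wstar + bstar)))
    y <- rbinom(2000, 1, p)
    fit <- fit_mle(X, y)
    # SE from the inverse Hessian on the raw scale via glm's vcov analog:
    # refit information matrix at the solution
    eta <- cbind(X, 1) %*% fit$model$raw_weights
    pw <- as.numeric(1 / (1 + exp(-eta)))
    H <- crossprod(cbind(X, 1) * (pw * (1 - pw)), cbind(X, 1))
    se <- sqrt(diag(solve(H)))
    ok <- abs(fit$model$raw_weights - c(wstar, bstar)) <= 3 * se
    hits <- hits + all(ok)
  }
  expect_gte(hits, 19L) # 3 SE ~ 99.7% per weight; allow one MC failure
})

test_that("weight bias shrinks as the sample grows", {
  wstar <- c(1, -1)
  err <- vapply(c(200, 2000), function(n) {
    ws <- vapply(1:10, function(s) {
      set.seed(1000 + s + n)
      X <- matrix(rnorm(2 * n), n)
      y <- rbinom(n, 1, 1 / (1 + exp(-(X %*% wstar))))
      fit_mle(X, y)$model$raw_weights[1]
    }, numeric(1))
    abs(mean(ws) - wstar[1])
  }, numeric(1))
  expect_lt(err[2], err[1] + 0.05)
})

test_that("null data yield slope weights near zero", {
  set.seed(77)
  X <- matrix(rnorm(2000), 1000)
  y <- rbinom(1000, 1, 0.4)
  fit <- fit_mle(X, y)
  eta <- cbind(X, 1) %*% fit$model$raw_weights
  pw <- as.numeric(1 / (1 + exp(-eta)))
  H <- crossprod(cbind(X, 1) * (pw * (1 - pw)), cbind(X, 1))
  se <- sqrt(diag(solve(H)))
  expect_true(all(abs(fit$model$raw_weights[1:2]) <= 3 * se[1:2]))
})

test_that("newton and gradient ascent reach the same maximum", {
  set.seed(73)
  X <- matrix(rnorm(600), 300)
  y <- rbinom(300, 1, 1 / (1 + exp(-(X %*% c(0.8, -0.5) - 0.2))))
  fn <- fit_mle(X, y, method = "newton")
  fg <- fit_mle(X, y, method = "gradient", tol = 1e-10)
  lln <- utils::tail(fn$report$loglik_trace, 1)
  llg <- utils::tail(fg$report$loglik_trace, 1)
  expect_lt(abs(lln - llg), 1e-6)
  expect_true(all(diff(fn$report$loglik_trace) >= -1e-12))
  expect_true(all(diff(fg$report$loglik_trace) >= -1e-12))
})

test_that("fit matches the installed GLM solver on the same data", {
  set.seed(74)
  X <- matrix(rnorm(400), 200)
  colnames(X) <- c("u", "v")
  y <- rbinom(200, 1, 1 / (1 + exp(-(0.5 * X[, 1] - X[, 2]))))
  fit <- fit_mle(X, y)
  g <- stats::glm(y ~ X, family = stats::binomial())
  expect_equal(fit$model$raw_weights,
               unname(c(stats::coef(g)[-1], stats::coef(g)[1])),
               tolerance = 1e-6)
})

test_that("feature rescaling changes raw weights reciprocally, not predictions", {
  set.seed(75)
  X <- matrix(rnorm(400), 200)
  y <- rbinom(200, 1, 1 / (1 + exp(-X[, 1])))
  f1 <- fit_mle(X, y)
  X2 <- X
  X2[, 1] <- X2[, 1] * 10
  f2 <- fit_mle(X2, y)
  expect_equal(f2$model$raw_weights[1], f1$model$raw_weights[1] / 10,
               tolerance = 1e-6)
  expect_equal(predict_proba(f1$model, X), predict_proba(f2$model, X2),
               tolerance = 1e-6)
})

test_that("training-set probabilities reproduce the fitted log-likelihood", {
  set.seed(76)
  X <- matrix(rnorm(300), 150)
  y <- rbinom(150, 1, 1 / (1 + exp(-X[, 1])))
  fit <- fit_mle(X, y)
  ll <- log_likelihood(fit$model$raw_weights, cbind(X, 1), y)
  expect_equal(ll, utils::tail(fit$report$loglik_trace, 1), tolerance = 1e-8)
})

test_that("degenerate training inputs are rejected", {
  X <- matrix(rnorm(40), 20)
  expect_error(fit_mle(X, rep(1, 20)), "both classes")
  expect_error(fit_mle(X[1:2, ], c(0, 1)), "samples")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(fit_mle(Xna, rep(c(0, 1), 10)), "undefined")
})

test_that("separable data produce a finite stabilized fit with a warning", {
  X <- matrix(c(seq(-2, -0.1, length.out = 10),
                seq(0.1, 2, length.out = 10)), ncol = 1)
  y <- rep(c(0, 1), each = 10)
  expect_warning(fit <- fit_mle(X, y, max_iter = 60), "separable")
  expect_true(all(is.finite(fit$model$weights)))
  expect_equal(unname(classify(fit$model, X)), y)
})

test_that("classification thresholds follow the >= convention", {
  model <- structure(
    list(weights = c(0, 0), raw_weights = c(0, 0), feature_names = "a",
         scaler = list(center = 0, scale = 1), threshold = 0.5),
    class = "logit_model")
  expect_equal(classify(model, matrix(rnorm(5))), rep(1L, 5)) # p = 0.5 >= v
  expect_equal(classify(model, 0, threshold = 0.99), 0L)
  model$weights <- c(1, 0)
  expect_equal(classify(model, 0.4055, threshold = 0.99), 0L) # p = 0.6
})

test_that("evaluation report follows the per-group verification layout", {
  model <- structure(
    list(weights = c(5, 0), raw_weights = c(5, 0), feature_names = "xi",
         scaler = list(center = 0, scale = 1), threshold = 0.5),
    class = "logit_model")
  X <- matrix(c(2, 2, 2, 2, -2, -2, -2, -2, 2, -2), ncol = 1)
  y <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0) # one apnea missed, one false alarm
  rep_ <- evaluate(model, X, y, group = rep(c("g1", "g2"), each = 5))
  expect_equal(rep_$actual_apnea[rep_$group == "total"], 5)
  expect_equal(rep_$identified_apnea[rep_$group == "total"], 4)
  expect_equal(rep_$missed[rep_$group == "total"], 1)
  expect_equal(rep_$accuracy_pct[rep_$group == "total"], 80)
  # totals equal the sum of the group rows
  grp <- rep_[rep_$group != "total", ]
  expect_equal(sum(grp$actual_apnea), 5)
  expect_equal(sum(grp$identified_apnea), 4)
  expect_error(evaluate(model, X[0, , drop = FALSE], integer(0)), "empty")
})

test_that("perfect predictions give a 100% report", {
  model <- structure(
    list(weights = c(10, 0), raw_weights = c(10, 0), feature_names = "xi",
         scaler = list(center = 0, scale = 1), threshold = 0.5),
    class = "logit_model")
  X <- matrix(c(1, 1, -1, -1), ncol = 1)
  y <- c(1, 1, 0, 0)
  rep_ <- evaluate(model, X, y)
  expect_equal(rep_$accuracy_pct[rep_$group == "total"], 100)
  expect_equal(attr(rep_, "frame_accuracy"), 1)
})

test_that("models round-trip through JSON", {
  set.seed(79)
  X <- matrix(rnorm(200), 100)
  colnames(X) <- c("ti_s", "similarity_pct")
  y <- rbinom(100, 1, 1 / (1 + exp(-X[, 1])))
  fit <- fit_mle(X, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit$model, path)
  m2 <- read_model(path)
  expect_equal(m2$weights, fit$model$weights)
  expect_equal(m2$feature_names, fit$model$feature_names)
  expect_equal(predict_proba(m2, X), predict_proba(fit$model, X))
})
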