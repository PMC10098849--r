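# Binomial logistic regression fitted by maximum likelihood, written out
# explicitly: the log-likelihood l(w) = sum_i [ y_i w.x_i - ln(1 + e^{w.x_i}) ]
# over intercept-augmented feature vectors, maximized by Newton iteration
# (Hessian solve with ridge jitter near singularity, step halving to keep
# l(w) non-decreasing) or by gradient ascent with backtracking.

.sigmoid <- function(eta) {
  ifelse(eta >= 0, 1 / (1 + exp(-eta)), exp(eta) / (1 + exp(eta)))
}

# log(1 + e^eta) without overflow
.log1pexp <- function(eta) {
  ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
}

#' Log-likelihood of a logistic model
#'
#' \eqn{l(w) = \sum_i [\, y_i\, w \cdot x_i - \ln(1 + e^{w \cdot x_i}) \,]}
#' with \eqn{x_i} including the appended intercept column.
#'
#' @param weights Coefficient vector (intercept last).
#' @param X Design matrix with intercept column appended, one row per
#'   sample.
#' @param y Binary labels in `{0, 1}`.
#' @return Scalar log-likelihood (finite for finite inputs).
#' @export
log_likelihood <- function(weights, X, y) {
  X <- as.matrix(X)
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1", call. = FALSE)
  if (ncol(X) != length(weights)) stop("weight/design mismatch", call. = FALSE)
  eta <- drop(X %*% weights)
  sum(y * eta - .log1pexp(eta))
}

#' Fit a binomial logistic regression by maximum likelihood
#'
#' Features are centered and scaled internally (the fitted weights are
#' reported on both the scaled and the raw scale; predictions are
#' identical). Newton iteration is the default; `method = "gradient"` uses
#' gradient ascent with backtracking line search. Convergence is declared
#' when the max-norm weight update falls below `tol`.
#'
#' @param X Numeric matrix or data frame of raw features (no intercept
#'   column), one row per frame.
#' @param y Binary labels in `{0, 1}` (1 = apnea).
#' @param method `"newton"` or `"gradient"`.
#' @param tol Convergence tolerance on the weight update (default 1e-8).
#' @param max_iter Iteration cap (default 100; gradient ascent typically
#'   needs more, default 5000 for that method).
#' @param threshold Decision threshold \eqn{v \in (0,1)} stored in the
#'   model (default 0.5).
#' @param ridge Ridge jitter added to the Hessian diagonal near
#'   singularity or separation (default 1e-8).
#' @return List with `model` (class `logit_model`: `weights` on the scaled
#'   feature space with intercept last, `raw_weights` on the original
#'   feature scale, `feature_names`, `scaler`, `threshold`) and `report`
#'   (class `train_report`: `n_samples`, `iterations`, `loglik_trace`,
#'   `converged`, `method`).
#' @export
fit_mle <- function(X, y, method = c("newton", "gradient"), tol = 1e-8,
                    max_iter = NULL, threshold = 0.5, ridge = 1e-8) {
  method <- match.arg(method)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1", call. = FALSE)
  if (anyNA(X)) stop("undefined features in the training matrix", call. = FALSE)
  n <- nrow(X); m <- ncol(X)
  if (n < m + 1) stop("need at least m + 1 samples", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  if (is.null(max_iter)) max_iter <- if (method == "newton") 100L else 5000L
  feature_names <- colnames(X) %||% paste0("x", seq_len(m))

  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale_, "/")
  Zi <- cbind(Z, intercept = 1)

  w <- numeric(m + 1)
  ll <- log_likelihood(w, Zi, y)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  step0 <- 1 / n # gradient ascent base step on standardized features

  for (iter in seq_len(max_iter)) {
    eta <- drop(Zi %*% w)
    p <- .sigmoid(eta)
    grad <- drop(crossprod(Zi, y - p))
    if (method == "newton") {
      wgt <- pmax(p * (1 - p), 1e-12)
      H <- crossprod(Zi * wgt, Zi)
      delta <- tryCatch(solve(H + diag(ridge, m + 1), grad),
                        error = function(e) {
                          solve(H + diag(max(ridge, 1e-4), m + 1), grad)
                        })
    } else {
      delta <- step0 * grad
    }
    # step halving: accept the largest step that does not decrease l(w)
    step <- 1
    repeat {
      w_new <- w + step * delta
      ll_new <- log_likelihood(w_new, Zi, y)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-12) { w_new <- w; ll_new <- ll; break }
    }
    upd <- max(abs(w_new - w))
    w <- w_new
    ll <- ll_new
    trace <- c(trace, ll)
    if (upd < tol) { converged <- TRUE; break }
  }

  p_fit <- .sigmoid(drop(Zi %*% w))
  if (!converged && all(abs(p_fit - y) < 1e-6)) {
    warning("training data are (near-)separable; weights are a ",
            "ridge-stabilized finite solution", call. = FALSE)
  }

  raw_w <- numeric(m + 1)
  raw_w[seq_len(m)] <- w[seq_len(m)] / scale_
  raw_w[m + 1] <- w[m + 1] - sum(w[seq_len(m)] * center / scale_)

  model <- structure(
    list(weights = unname(w), raw_weights = unname(raw_w),
         feature_names = feature_names,
         scaler = list(center = center, scale = scale_),
         threshold = threshold),
    class = "logit_model")
  report <- structure(
    list(n_samples = n, iterations = iter, loglik_trace = trace,
         converged = converged, method = method),
    class = "train_report")
  list(model = model, report = report)
}

#' @export
print.logit_model <- function(x, ...) {
  cat("<logit_model> ", length(x$feature_names), " features, threshold v = ",
      x$threshold, "\n", sep = "")
  w <- x$raw_weights
  names(w) <- c(x$feature_names, "(intercept)")
  print(round(w, 4))
  invisible(x)
}

#' @export
print.train_report <- function(x, ...) {
  cat("<train_report> n =", x$n_samples, "| method", x$method, "|",
      x$iterations, "iterations |",
      if (x$converged) "converged" else "not converged",
      "| l(w) =", sprintf("%.4f", utils::tail(x$loglik_trace, 1)), "\n")
  invisible(x)
}

# Scale a raw feature matrix with the model's stored scaler and append the
# intercept column.
.design <- function(model, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  m <- length(model$feature_names)
  if (ncol(X) != m) stop("feature vector length mismatch", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite feature value", call. = FALSE)
  Z <- sweep(sweep(X, 2, model$scaler$center), 2, model$scaler$scale, "/")
  cbind(Z, 1)
}

#' Apnea probability under a fitted logistic model
#'
#' \eqn{P(Y=1 \mid x) = e^{w \cdot x} / (1 + e^{w \cdot x})}, computed with
#' an overflow-safe sigmoid.
#'
#' @param model A `logit_model`.
#' @param x Feature vector (length m) or matrix (rows are frames), on the
#'   raw feature scale.
#' @return Probability (or vector of probabilities) in `(0, 1)`.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "logit_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  drop(.sigmoid(.design(model, x) %*% model$weights))
}

#' Classify feature vectors as apnea (1) or normal (0)
#'
#' Label 1 is assigned when \eqn{P(Y=1\mid x) \ge v} (ties at the
#' threshold resolve to 1).
#'
#' @inheritParams predict_proba
#' @param threshold Decision cut; defaults to the model's stored value.
#' @return Integer labels in `{0, 1}`.
#' @export
classify <- function(model, x, threshold = model$threshold) {
  stopifnot(threshold > 0, threshold < 1)
  as.integer(predict_proba(model, x) >= threshold)
}

#' Accuracy report in the per-group verification layout
#'
#' For each group: the number of actual apnea frames, how many of them the
#' model identified, how many were missed, and the percentage accuracy
#' (identified / actual). Frame-level overall accuracy, sensitivity and
#' specificity are appended as attributes, and a `total` row sums the
#' groups.
#'
#' @param model A `logit_model`.
#' @param X Feature matrix (raw scale).
#' @param y True labels in `{0, 1}`.
#' @param group Optional group id per row (e.g. subject); a single group
#'   when omitted.
#' @return Data frame with columns `group`, `actual_apnea`,
#'   `identified_apnea`, `missed`, `accuracy_pct`; attributes
#'   `frame_accuracy`, `sensitivity`, `specificity`.
#' @export
evaluate <- function(model, X, y, group = NULL) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty evaluation set", call. = FALSE)
  y <- as.integer(y)
  if (is.null(group)) group <- rep("all", nrow(X))
  pred <- classify(model, X)
  per <- lapply(split(seq_along(y), group), function(i) {
    actual <- sum(y[i] == 1)
    ident <- sum(y[i] == 1 & pred[i] == 1)
    data.frame(actual_apnea = actual, identified_apnea = ident,
               missed = actual - ident,
               accuracy_pct = if (actual > 0) 100 * ident / actual else NA_real_)
  })
  out <- do.call(rbind, per)
  out <- cbind(group = names(per), out)
  rownames(out) <- NULL
  tot <- data.frame(group = "total",
                    actual_apnea = sum(out$actual_apnea),
                    identified_apnea = sum(out$identified_apnea),
                    missed = sum(out$missed),
                    accuracy_pct = if (sum(out$actual_apnea) > 0) {
                      100 * sum(out$identified_apnea) / sum(out$actual_apnea)
                    } else NA_real_)
  out <- rbind(out, tot)
  attr(out, "frame_accuracy") <- mean(pred == y)
  attr(out, "sensitivity") <- if (any(y == 1)) {
    mean(pred[y == 1] == 1)
  } else NA_real_
  attr(out, "specificity") <- if (any(y == 0)) {
    mean(pred[y == 0] == 0)
  } else NA_real_
  out
}

#' Save or load a fitted logistic model as JSON
#'
#' @param model A `logit_model`.
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   `logit_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "logit_model"))
  obj <- list(feature_names = model$feature_names,
              weights = model$weights,
              raw_weights = model$raw_weights,
              scaler = list(center = as.numeric(model$scaler$center),
                            scale = as.numeric(model$scaler$scale)),
              threshold = model$threshold,
              provenance = list(package = "bcgsleep",
                                written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(weights = as.numeric(obj$weights),
         raw_weights = as.numeric(obj$raw_weights),
         feature_names = as.character(obj$feature_names),
         scaler = list(center = as.numeric(obj$scaler$center),
                       scale = as.numeric(obj$scaler$scale)),
         threshold = as.numeric(obj$threshold)),
    class = "logit_model")
}
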