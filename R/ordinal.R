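# Cumulative-link (proportional-odds, logistic) ordinal machinery.
# The model emits a continuous "z-score"; strictly increasing learned
# thresholds theta_1 < ... < theta_5 partition it into the six RASS
# levels -5..0. Orientation: larger z = more awake (higher RASS).
# Monotonicity is guaranteed by parameterizing the thresholds as
# theta_1 plus positive (exponentiated) increments.

.rass_levels <- -5:0

# level (-5..0) <-> class index (1..6)
.rass_to_idx <- function(y) as.integer(y) + 6L
.idx_to_rass <- function(k) as.integer(k) - 6L

.theta_from_raw <- function(raw) {
  # raw = c(theta1, log_gap_1..log_gap_4)
  raw[1L] + c(0, cumsum(exp(raw[-1L])))
}

.raw_from_theta <- function(theta) {
  c(theta[1L], log(diff(theta)))
}

#' Cumulative-link ordinal negative log-likelihood
#'
#' `P(level <= k | z) = logistic(theta_k - z)`; the likelihood of the
#' observed level is the difference of adjacent cumulative
#' probabilities. Per-sample losses are combined as a weighted mean.
#'
#' @param z numeric scores.
#' @param y RASS levels in -5..0 (same length as `z`).
#' @param thresholds strictly increasing numeric vector (length =
#'   number of levels - 1).
#' @param weights per-sample weights (default 1).
#' @return list: `loss` (scalar), `dz` (d loss / d z), `dtheta`
#'   (d loss / d thresholds), `prob` (N x K matrix of level
#'   probabilities).
#' @export
ordinal_nll <- function(z, y, thresholds, weights = NULL) {
  K <- length(thresholds) + 1L
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  idx <- .rass_to_idx(y)
  stopifnot(all(idx >= 1L & idx <= K))
  n <- length(z)
  if (is.null(weights)) weights <- rep(1, n)
  wsum <- sum(weights)
  # cumulative probs at each threshold for each sample
  A <- .sigmoid(outer(-z, thresholds, `+`))     # N x (K-1): sigma(theta_k - z)
  Afull <- cbind(0, A, 1)
  p_y <- Afull[cbind(seq_len(n), idx + 1L)] - Afull[cbind(seq_len(n), idx)]
  p_y <- pmax(p_y, 1e-12)
  loss <- sum(weights * (-log(p_y))) / wsum
  # derivatives of sigma: s(1-s)
  dA <- A * (1 - A)
  dAfull <- cbind(0, dA, 0)
  s_hi <- dAfull[cbind(seq_len(n), idx + 1L)]
  s_lo <- dAfull[cbind(seq_len(n), idx)]
  # dp/dz = -s_hi + s_lo  (theta_k - z decreasing in z)
  dz <- -weights / (wsum * p_y) * (s_lo - s_hi)
  dtheta <- numeric(K - 1L)
  for (k in seq_len(K - 1L)) {
    # p gains +s at theta_{idx}, -s at theta_{idx-1}
    contrib <- numeric(n)
    contrib[idx == k] <- s_hi[idx == k]
    contrib[idx == k + 1L] <- contrib[idx == k + 1L] - s_lo[idx == k + 1L]
    dtheta[k] <- sum(-weights / (wsum * p_y) * contrib)
  }
  probs <- Afull[, 2:(K + 1L), drop = FALSE] - Afull[, 1:K, drop = FALSE]
  list(loss = loss, dz = dz, dtheta = dtheta, prob = probs)
}

# map d loss/d thresholds to the unconstrained raw parameterization
.dtheta_to_draw <- function(dtheta, raw) {
  gaps <- exp(raw[-1L])
  draw <- numeric(length(raw))
  draw[1L] <- sum(dtheta)
  for (j in seq_along(gaps)) {
    draw[j + 1L] <- sum(dtheta[(j + 1L):length(dtheta)]) * gaps[j]
  }
  draw
}

#' Discretize a z-score into a RASS level
#'
#' The predicted level is the number of thresholds at or below `z`,
#' shifted onto the -5..0 scale; non-decreasing in `z` by construction.
#' A score exactly at a threshold is assigned to the level above it.
#'
#' @param z numeric scores.
#' @param thresholds strictly increasing thresholds.
#' @return integer RASS levels.
#' @export
discretize <- function(z, thresholds) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  counts <- vapply(z, function(zi) sum(zi >= thresholds), integer(1L))
  .idx_to_rass(counts + 1L)
}

#' Inverse-frequency class weights
#'
#' One weight per observed class, proportional to 1/n_c and normalized
#' to mean 1 over the samples' classes.
#'
#' @param y vector of class labels.
#' @return named numeric vector of per-class weights.
#' @export
class_weights <- function(y) {
  tab <- table(y)
  w <- 1 / as.numeric(tab)
  names(w) <- names(tab)
  per_sample <- w[as.character(y)]
  w * length(y) / sum(per_sample)
}

#' Fit a 1-D cumulative-link ordinal regression
#'
#' Maximum-likelihood fit of `z = a*x + b` with learned thresholds, by
#' BFGS on the exact analytic gradient. Used for the non-deep baseline
#' (band powers + BSR via a linear score) and for threshold-recovery
#' validation.
#'
#' @param x numeric predictor matrix (n x d) or vector.
#' @param y RASS levels in -5..0.
#' @param weights optional per-sample weights (default: unweighted
#'   maximum likelihood; pass inverse-frequency weights explicitly for
#'   a class-balanced fit).
#' @param fix_slope if `TRUE`, fixes `z = x` (vector input only) and
#'   fits thresholds alone.
#' @return list of class `ordinal_fit`: `coef`, `intercept`,
#'   `thresholds`, `logLik`.
#' @export
fit_ordinal <- function(x, y, weights = NULL, fix_slope = FALSE) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x); d <- ncol(x)
  if (is.null(weights)) weights <- rep(1, n)
  K <- length(.rass_levels)
  theta0 <- stats::qlogis(seq_len(K - 1L) / K) * 2
  if (fix_slope) {
    stopifnot(d == 1L)
    par0 <- .raw_from_theta(theta0)
    fn <- function(par) ordinal_nll(x[, 1L], y, .theta_from_raw(par),
                                    weights)$loss
    gr <- function(par) {
      o <- ordinal_nll(x[, 1L], y, .theta_from_raw(par), weights)
      .dtheta_to_draw(o$dtheta, par)
    }
    fit <- stats::optim(par0, fn, gr, method = "BFGS",
                        control = list(maxit = 500))
    return(structure(list(coef = 1, intercept = 0,
                          thresholds = .theta_from_raw(fit$par),
                          logLik = -fit$value * n),
                     class = "ordinal_fit"))
  }
  xs <- scale(x)
  ctr <- attr(xs, "scaled:center"); scl <- attr(xs, "scaled:scale")
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
  par0 <- c(numeric(d), .raw_from_theta(theta0))
  fn <- function(par) {
    z <- as.numeric(xs %*% par[seq_len(d)])
    ordinal_nll(z, y, .theta_from_raw(par[-seq_len(d)]), weights)$loss
  }
  gr <- function(par) {
    z <- as.numeric(xs %*% par[seq_len(d)])
    o <- ordinal_nll(z, y, .theta_from_raw(par[-seq_len(d)]), weights)
    c(as.numeric(crossprod(xs, o$dz)),
      .dtheta_to_draw(o$dtheta, par[-seq_len(d)]))
  }
  fit <- stats::optim(par0, fn, gr, method = "BFGS",
                      control = list(maxit = 1000))
  beta <- fit$par[seq_len(d)] / scl
  structure(list(coef = beta, intercept = -sum(ctr * beta),
                 thresholds = .theta_from_raw(fit$par[-seq_len(d)]),
                 logLik = -fit$value * n),
            class = "ordinal_fit")
}

#' Predict from an `ordinal_fit`
#' @param object an `ordinal_fit`.
#' @param newdata matrix or vector of predictors.
#' @param type `"level"` (discretized RASS) or `"z"`.
#' @param ... unused.
#' @export
predict.ordinal_fit <- function(object, newdata, type = c("level", "z"), ...) {
  type <- match.arg(type)
  if (is.vector(newdata)) newdata <- matrix(newdata, ncol = 1L)
  z <- as.numeric(newdata %*% object$coef) + object$intercept
  if (type == "z") z else discretize(z, object$thresholds)
}
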