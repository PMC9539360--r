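#' Matern 5/2 covariance with per-dimension (ARD) length scales
#'
#' The surrogate kernel:
#' \deqn{k(x, x') = \sigma_f^2 (1 + \sqrt{5} r + \tfrac{5}{3} r^2)
#'   \exp(-\sqrt{5} r), \quad
#'   r^2 = \sum_d (x_d - x'_d)^2 / \ell_d^2.}
#' Sample paths are twice differentiable: smooth enough for gradient-guided
#' reasoning about the response surface without the unrealistic infinite
#' smoothness of the squared-exponential kernel.
#'
#' @param x,xp Numeric matrices of encoded points (rows are points) or vectors
#'   for a single point; must have the same number of columns.
#' @param length_scales Positive length scale per column; a single value is
#'   recycled (isotropic kernel).
#' @param amplitude Covariance amplitude \eqn{\sigma_f^2} (> 0).
#' @return The `nrow(x)` by `nrow(xp)` covariance matrix.
#' @examples
#' matern52(0, 1, length_scales = 1) # (1 + sqrt(5) + 5/3) * exp(-sqrt(5))
#' @export
matern52 <- function(x, xp, length_scales, amplitude = 1) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(xp))) xp <- matrix(xp, nrow = 1)
  if (ncol(x) != ncol(xp)) stop("points have mismatched dimension")
  if (any(length_scales <= 0)) stop("length scales must be strictly positive")
  ls <- rep_len(length_scales, ncol(x))
  xs <- sweep(x, 2, ls, "/")
  xps <- sweep(xp, 2, ls, "/")
  r2 <- outer(rowSums(xs^2), rowSums(xps^2), "+") - 2 * tcrossprod(xs, xps)
  r <- sqrt(pmax(r2, 0))
  amplitude * (1 + sqrt(5) * r + (5 / 3) * r^2) * exp(-sqrt(5) * r)
}

# Per-dimension squared scaled-difference matrices for one training set,
# computed once per fit and reused across hyperparameter evaluations.
sq_diff_tensor <- function(X) {
  d <- ncol(X)
  lapply(seq_len(d), function(j) {
    dj <- outer(X[, j], X[, j], "-")
    dj * dj
  })
}

# Gram matrix (plus gradient pieces) from precomputed squared differences.
matern52_gram <- function(D2, length_scales, amplitude) {
  r2 <- 0
  for (j in seq_along(D2)) r2 <- r2 + D2[[j]] / length_scales[j]^2
  r <- sqrt(pmax(r2, 0))
  e <- exp(-sqrt(5) * r)
  K <- amplitude * (1 + sqrt(5) * r + (5 / 3) * r2) * e
  list(K = K, r = r, e = e)
}

nll_constants <- function(n) 0.5 * n * log(2 * pi)

# Negative log marginal likelihood and gradient in the parameterization
# theta = (log l_1..log l_d, log sf2, log sn2, c).
gp_objective <- function(theta, D2, y, jitter_rel = 1e-8) {
  d <- length(D2)
  n <- length(y)
  ls <- exp(theta[seq_len(d)])
  sf2 <- exp(theta[d + 1])
  sn2 <- exp(theta[d + 2])
  cmean <- theta[d + 3]
  g <- matern52_gram(D2, ls, sf2)
  K <- g$K
  diag(K) <- diag(K) + sn2 + jitter_rel * sf2
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) {
    return(list(value = 1e10, gradient = rep(0, d + 3)))
  }
  resid <- y - cmean
  alpha <- backsolve(L, forwardsolve(t(L), resid))
  nll <- 0.5 * sum(resid * alpha) + sum(log(diag(L))) + nll_constants(n)
  # gradient: dnll/dtheta_k = -1/2 tr((alpha alpha' - K^-1) dK/dtheta_k)
  Kinv <- chol2inv(L)
  A <- tcrossprod(alpha) - Kinv
  # dK/dr2 = -(5/6) sf2 (1 + sqrt5 r) e; dr2/dlog l_j = -2 D2_j / l_j^2
  base <- (5 / 3) * sf2 * (1 + sqrt(5) * g$r) * g$e
  grad <- numeric(d + 3)
  for (j in seq_len(d)) {
    dK <- base * (D2[[j]] / ls[j]^2)
    grad[j] <- -0.5 * sum(A * dK)
  }
  Kf <- g$K
  diag(Kf) <- diag(Kf) + jitter_rel * sf2
  grad[d + 1] <- -0.5 * sum(A * Kf)          # d K/d log sf2 = Kf
  grad[d + 2] <- -0.5 * sum(diag(A)) * sn2   # d K/d log sn2 = sn2 I
  grad[d + 3] <- -sum(alpha)                 # d nll/d c
  list(value = nll, gradient = grad)
}

#' Fit a Gaussian-process surrogate to encoded observations
#'
#' Hyperparameters (per-dimension length scales, covariance amplitude,
#' observation-noise variance and a constant mean in yield units) are point
#' estimates obtained by maximizing the log marginal likelihood with L-BFGS-B
#' in log-space from several random restarts. Restart starting points are
#' drawn from a fixed prior box: length scales in `[0.05, 5]` (log-uniform),
#' amplitude in `[0.1, 10] * var(y)`, noise in `[1e-4, 1] * var(y)`. The
#' returned model caches the Cholesky factorization of the Gram matrix, so
#' prediction is a pair of triangular solves.
#'
#' @param data A data frame of reaction conditions plus a response column, or a
#'   numeric matrix of encoded points in the unit cube (then `y` is required).
#' @param y Response vector (mRNA yield, g/L) when `data` is a matrix or when
#'   the response is supplied separately.
#' @param space The [param_space()] used to encode condition data frames.
#' @param response Name of the response column when `data` is a data frame
#'   (default `"yield_gL"`).
#' @param restarts Number of random restarts for the marginal-likelihood
#'   search (default 8).
#' @param seed Integer seed making the restarts (hence the fit) reproducible.
#' @param noise_floor Lower bound on the noise variance (default `1e-6`),
#'   keeping the Gram matrix invertible under duplicated inputs.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @return An object of class `ivt_gp`: hyperparameters, training data and the
#'   cached solve. Supports [predict()][predict.ivt_gp],
#'   [generics::tidy()] and [generics::glance()].
#' @examples
#' X <- matrix(runif(20), ncol = 2)
#' y <- sin(2 * pi * X[, 1]) + 0.1 * X[, 2]
#' m <- gp_fit(X, y, restarts = 2, seed = 1)
#' glance(m)
#' @export
gp_fit <- function(data, y = NULL, space = ivt_space(), response = "yield_gL",
                   restarts = 8, seed = NULL, noise_floor = 1e-6,
                   maxit = 100) {
  if (is.data.frame(data)) {
    if (is.null(y)) {
      if (!response %in% names(data)) {
        stop("response column '", response, "' not found")
      }
      y <- data[[response]]
      data <- data[setdiff(names(data), response)]
    }
    X <- encode_conditions(data[space$specs$name], space)
  } else {
    X <- as.matrix(data)
    space <- NULL
  }
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("y length does not match rows of data")
  if (nrow(X) < 2) stop("need at least 2 observations to fit the surrogate")
  if (any(X < -1e-9) || any(X > 1 + 1e-9)) {
    stop("encoded inputs must lie in the unit cube")
  }

  d <- ncol(X)
  D2 <- sq_diff_tensor(X)
  vy <- max(stats::var(y), 1e-12)

  run_restarts <- function() {
    starts <- lapply(seq_len(restarts), function(i) {
      c(stats::runif(d, log(0.05), log(5)),
        log(vy) + stats::runif(1, log(0.1), log(10)),
        log(vy) + stats::runif(1, log(1e-4), log(1)),
        mean(y) + stats::rnorm(1, 0, stats::sd(y) / 4))
    })
    starts[[1]][seq_len(d)] <- rep(log(0.5), d)  # one deterministic start
    best <- NULL
    for (s in starts) {
      fit <- tryCatch(
        stats::optim(
          s,
          fn = function(th) gp_objective(th, D2, y)$value,
          gr = function(th) gp_objective(th, D2, y)$gradient,
          method = "L-BFGS-B",
          lower = c(rep(log(0.03), d), log(vy) + log(1e-3),
                    log(max(noise_floor, 1e-12)), min(y) - 10 * sqrt(vy)),
          upper = c(rep(log(50), d), log(vy) + log(1e3),
                    log(10 * vy + 1), max(y) + 10 * sqrt(vy)),
          control = list(maxit = maxit)
        ),
        error = function(e) NULL
      )
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
        best <- fit
      }
    }
    if (is.null(best)) stop("marginal-likelihood optimization failed")
    best
  }
  best <- if (is.null(seed)) run_restarts() else {
    withr::with_seed(seed, run_restarts())
  }

  th <- best$par
  hp <- list(
    length_scales = exp(th[seq_len(d)]),
    amplitude = exp(th[d + 1]),
    noise = max(exp(th[d + 2]), noise_floor),
    mean = th[d + 3]
  )
  g <- matern52_gram(D2, hp$length_scales, hp$amplitude)
  K <- g$K
  diag(K) <- diag(K) + hp$noise + 1e-8 * hp$amplitude
  L <- tryCatch(chol(K), error = function(e) {
    stop("Gram matrix not positive definite after jitter; ",
         "increase noise_floor")
  })
  resid <- y - hp$mean
  alpha <- backsolve(L, forwardsolve(t(L), resid))
  structure(
    list(
      X = X, y = y, space = space, hyperparams = hp,
      L = L, alpha = alpha,
      log_marginal = -(0.5 * sum(resid * alpha) + sum(log(diag(L))) +
                         nll_constants(length(y)))
    ),
    class = "ivt_gp"
  )
}

#' @export
print.ivt_gp <- function(x, ...) {
  cat("<ivt_gp> Matern 5/2 ARD Gaussian process\n",
      "  n = ", length(x$y), ", encoded dim = ", ncol(x$X), "\n",
      "  amplitude = ", signif(x$hyperparams$amplitude, 4),
      ", noise = ", signif(x$hyperparams$noise, 4),
      ", mean = ", signif(x$hyperparams$mean, 4), " g/L\n",
      "  log marginal likelihood = ", signif(x$log_marginal, 6), "\n",
      sep = "")
  invisible(x)
}

encode_newdata <- function(object, newdata) {
  if (is.data.frame(newdata)) {
    if (is.null(object$space)) {
      stop("model was fitted on a raw matrix; supply encoded points")
    }
    encode_conditions(newdata[object$space$specs$name], object$space)
  } else {
    X <- as.matrix(newdata)
    if (is.null(dim(newdata)) && length(newdata) == ncol(object$X)) {
      X <- matrix(newdata, nrow = 1)
    }
    if (ncol(X) != ncol(object$X)) {
      stop("newdata has ", ncol(X), " coordinates; model expects ",
           ncol(object$X))
    }
    X
  }
}

#' Posterior mean and standard deviation of the GP surrogate
#'
#' Standard Gaussian-process regression posterior with constant prior mean
#' `c`: `mu(x) = c + k(x)' K^-1 (y - c)` and latent variance
#' `k(x,x) - k(x)' K^-1 k(x)`. Far from all training points the prediction
#' reverts to the prior `(c, sqrt(sf2 + sn2))`; as the fitted noise goes to
#' zero the posterior mean interpolates the data.
#'
#' @param object An `ivt_gp` model.
#' @param newdata A data frame of reaction conditions or a matrix of encoded
#'   points.
#' @param ... Unused.
#' @return A tibble with columns `mean` and `sd` (g/L), one row per point.
#' @export
predict.ivt_gp <- function(object, newdata, ...) {
  Xs <- encode_newdata(object, newdata)
  hp <- object$hyperparams
  Ks <- matern52(Xs, object$X, hp$length_scales, hp$amplitude)
  mu <- hp$mean + as.numeric(Ks %*% object$alpha)
  V <- forwardsolve(t(object$L), t(Ks))
  var_lat <- pmax(hp$amplitude - colSums(V^2), 0)
  tibble::tibble(mean = mu, sd = sqrt(var_lat))
}

#' Exact Gaussian log marginal likelihood of a fitted model
#'
#' @param model An `ivt_gp` model, or a list with elements `X`, `y` and
#'   `hyperparams` (candidate hyperparameters not yet optimized).
#' @return The log marginal likelihood of `y` given `X` and the
#'   hyperparameters.
#' @export
log_marginal_likelihood <- function(model) {
  if (inherits(model, "ivt_gp") && !is.null(model$log_marginal)) {
    return(model$log_marginal)
  }
  hp <- model$hyperparams
  D2 <- sq_diff_tensor(model$X)
  g <- matern52_gram(D2, rep_len(hp$length_scales, ncol(model$X)),
                     hp$amplitude)
  K <- g$K
  diag(K) <- diag(K) + hp$noise + 1e-8 * hp$amplitude
  L <- tryCatch(chol(K), error = function(e) {
    stop("Gram matrix is not positive definite")
  })
  resid <- model$y - hp$mean
  alpha <- backsolve(L, forwardsolve(t(L), resid))
  -(0.5 * sum(resid * alpha) + sum(log(diag(L))) +
      nll_constants(length(model$y)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the hyperparameters of a fitted GP surrogate
#'
#' @param x An `ivt_gp` model.
#' @param ... Unused.
#' @return A tibble with one row per hyperparameter (`term`, `estimate`):
#'   one length scale per encoded coordinate, the amplitude, the noise
#'   variance and the constant mean.
#' @export
tidy.ivt_gp <- function(x, ...) {
  nms <- colnames(x$X)
  if (is.null(nms)) nms <- paste0("x", seq_len(ncol(x$X)))
  tibble::tibble(
    term = c(paste0("length_scale.", nms), "amplitude", "noise", "mean"),
    estimate = c(x$hyperparams$length_scales, x$hyperparams$amplitude,
                 x$hyperparams$noise, x$hyperparams$mean)
  )
}

#' One-row model summary of a fitted GP surrogate
#'
#' @inheritParams tidy.ivt_gp
#' @return A one-row tibble: `nobs`, `logLik` (log marginal likelihood),
#'   `amplitude`, `noise`, `mean`.
#' @export
glance.ivt_gp <- function(x, ...) {
  tibble::tibble(
    nobs = length(x$y),
    logLik = x$log_marginal,
    amplitude = x$hyperparams$amplitude,
    noise = x$hyperparams$noise,
    mean = x$hyperparams$mean
  )
}

#' Save / restore a fitted surrogate as a JSON checkpoint
#'
#' The checkpoint stores hyperparameters plus the training data, so the
#' restored model reproduces predictions exactly (the Gram factorization is
#' rebuilt on load).
#'
#' @param model An `ivt_gp` fitted on encoded inputs or conditions.
#' @param path Output path.
#' @export
write_gp_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ivt_gp"))
  obj <- list(
    hyperparams = model$hyperparams,
    X = unname(apply(model$X, 1, as.numeric, simplify = FALSE)),
    encoded_names = colnames(model$X),
    y = model$y
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gp_checkpoint
#' @param path Path of a checkpoint written by [write_gp_checkpoint()].
#' @param space Optional [param_space()] to re-attach for data-frame
#'   prediction.
#' @export
read_gp_checkpoint <- function(path, space = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- if (is.matrix(obj$X)) obj$X else {
    matrix(unlist(obj$X), nrow = length(obj$y), byrow = TRUE)
  }
  colnames(X) <- obj$encoded_names
  hp <- obj$hyperparams
  hp$length_scales <- as.numeric(hp$length_scales)
  D2 <- sq_diff_tensor(X)
  g <- matern52_gram(D2, hp$length_scales, hp$amplitude)
  K <- g$K
  diag(K) <- diag(K) + hp$noise + 1e-8 * hp$amplitude
  L <- chol(K)
  resid <- obj$y - hp$mean
  alpha <- backsolve(L, forwardsolve(t(L), resid))
  structure(
    list(X = X, y = obj$y, space = space, hyperparams = hp, L = L,
         alpha = alpha,
         log_marginal = -(0.5 * sum(resid * alpha) + sum(log(diag(L))) +
                            nll_constants(length(obj$y)))),
    class = "ivt_gp"
  )
}
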