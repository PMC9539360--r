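# Shared fixtures and independent oracles used across the suite.

# small all-real spaces for math-level tests
real_space_1d <- function() {
  param_space(tibble::tibble(
    name = "x", kind = "real", units = "", lo = 0, hi = 1,
    levels = list(NULL)
  ))
}

real_space_kd <- function(k, lo = 0, hi = 1) {
  param_space(tibble::tibble(
    name = paste0("x", seq_len(k)), kind = "real", units = "",
    lo = lo, hi = hi, levels = replicate(k, NULL, simplify = FALSE)
  ))
}

# random valid conditions for the default space, for round-trip properties
random_conditions <- function(space, n, seed) {
  withr::with_seed(seed, {
    out <- purrr::map(seq_len(nrow(space$specs)), function(i) {
      if (space$specs$kind[i] == "categorical") {
        sample(space$specs$levels[[i]], n, replace = TRUE)
      } else {
        x <- stats::runif(n, space$specs$lo[i], space$specs$hi[i])
        if (space$specs$kind[i] == "integer") x <- round(x)
        x
      }
    })
    names(out) <- space$specs$name
    tibble::as_tibble(out)
  })
}

# dense-linear-algebra GP posterior, independent of the package's cached
# Cholesky path: plain solve() on the full Gram matrix
dense_gp_oracle <- function(X, y, hp, Xs, jitter = 1e-8) {
  K <- matern52(X, X, hp$length_scales, hp$amplitude)
  diag(K) <- diag(K) + hp$noise + jitter * hp$amplitude
  Ki <- solve(K)
  Ks <- matern52(Xs, X, hp$length_scales, hp$amplitude)
  mu <- hp$mean + Ks %*% Ki %*% (y - hp$mean)
  v <- hp$amplitude - rowSums((Ks %*% Ki) * Ks)
  list(mean = as.numeric(mu), sd = sqrt(pmax(v, 0)))
}

# log marginal likelihood by brute-force multivariate-normal density
dense_lml_oracle <- function(X, y, hp, jitter = 1e-8) {
  K <- matern52(X, X, hp$length_scales, hp$amplitude)
  diag(K) <- diag(K) + hp$noise + jitter * hp$amplitude
  r <- y - hp$mean
  as.numeric(-0.5 * t(r) %*% solve(K, r) - 0.5 * determinant(K)$modulus -
               length(y) / 2 * log(2 * pi))
}

# expected improvement by numerical integration of E[max(0, Y - f_max)];
# finite upper limit far in the tail keeps the quadrature from missing a
# narrow density bump on [f_max, Inf)
ei_numeric <- function(mu, s, f_max) {
  stats::integrate(function(y) (y - f_max) * stats::dnorm(y, mu, s),
                   lower = f_max, upper = max(f_max, mu) + 20 * s,
                   rel.tol = 1e-13, abs.tol = 1e-14,
                   subdivisions = 500L)$value
}

# exact Shapley values by enumeration of all 2^M coalitions
exact_shapley <- function(f, background, x, features) {
  m <- length(features)
  v <- function(S) {
    z <- background[, features, drop = FALSE]
    if (length(S) > 0) {
      z[, features[S]] <- x[rep(1, nrow(z)), features[S], drop = FALSE]
    }
    mean(f(z))
  }
  phi <- numeric(m)
  subsets <- unlist(lapply(0:(m - 1), function(k) {
    utils::combn(m, k, simplify = FALSE)
  }), recursive = FALSE)
  for (j in seq_len(m)) {
    for (S in subsets) {
      if (j %in% S) next
      w <- factorial(length(S)) * factorial(m - length(S) - 1) / factorial(m)
      phi[j] <- phi[j] + w * (v(c(S, j)) - v(S))
    }
  }
  names(phi) <- features
  phi
}

# build an ivt_gp with chosen hyperparameters through the public
# checkpoint-file interface (no optimization involved)
gp_with_hyperparams <- function(X, y, hp, space = NULL) {
  path <- withr::local_tempfile(fileext = ".json",
                                .local_envir = parent.frame())
  obj <- list(
    hyperparams = hp,
    X = unname(apply(as.matrix(X), 1, as.numeric, simplify = FALSE)),
    encoded_names = colnames(X),
    y = y
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  read_gp_checkpoint(path, space)
}
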