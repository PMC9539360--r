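#' Expected improvement over the best observed yield
#'
#' For a candidate whose surrogate prediction is Normal(`mean`, `sd`^2) and a
#' current best observation `f_max`, the expected improvement is
#' \deqn{EI = (\hat y - f_{max})\,\Phi(z) + s\,\phi(z), \quad
#'   z = (\hat y - f_{max})/s,}
#' i.e. `E[max(0, Y - f_max)]`, the mass of the predictive density beyond the
#' incumbent weighted by how far beyond it lies. At `sd = 0` it degenerates to
#' `max(0, mean - f_max)`.
#'
#' @param mean Surrogate posterior mean(s), g/L.
#' @param sd Surrogate posterior standard deviation(s), g/L; must be >= 0.
#' @param f_max Best observed yield so far, g/L.
#' @return Expected improvement, same length as `mean`; always >= 0.
#' @examples
#' expected_improvement(5, 1, 5) # = dnorm(0) ~ 0.39894
#' @export
expected_improvement <- function(mean, sd, f_max) {
  if (any(sd < 0)) stop("sd must be non-negative")
  z <- (mean - f_max) / sd
  ei <- ifelse(
    sd == 0,
    pmax(0, mean - f_max),
    (mean - f_max) * stats::pnorm(z) + sd * stats::dnorm(z)
  )
  pmax(ei, 0)
}

#' Propose the next batch of reaction conditions
#'
#' Scores a large candidate pool with [expected_improvement()] and assembles a
#' batch of `batch_size` (3-5) conditions balancing exploitation and
#' exploration: the first member is the pool EI maximizer; the remaining
#' members are drawn at random from near-optimal candidates (EI at least
#' `ei_frac` of the maximum) subject to a minimum pairwise distance in encoded
#' space, falling back to the next-best EI candidates when the diverse set is
#' exhausted. The pool is a fresh Latin hypercube over the space plus local
#' Gaussian refinements around the incumbent best conditions, so the search
#' can both jump globally and polish locally.
#'
#' @param model A fitted `ivt_gp` surrogate.
#' @param space The [param_space()] to propose in.
#' @param f_max Best observed yield so far (g/L). Supply the maximum of the
#'   experiment log.
#' @param batch_size Number of conditions to return, between 3 and 5 (the
#'   per-cycle batch the wet lab evaluates); values 1-2 are accepted for
#'   programmatic use.
#' @param seed Integer seed; fixed seed gives identical proposals.
#' @param pool_size Size of the Latin-hypercube candidate pool (default
#'   20000).
#' @param incumbent Optional encoded point (or conditions data frame of one
#'   row) around which local refinements are sampled; defaults to the training
#'   point of `model` with the highest target.
#' @param n_local Number of local refinement candidates (default 2000, split
#'   over two perturbation scales).
#' @param ei_frac Members 2..k are drawn from candidates with
#'   `ei >= ei_frac * max(ei)` (default 0.5).
#' @param min_dist Minimum pairwise normalized distance between batch members
#'   in encoded space (default 0.05). The distance is the root-mean-square
#'   per-coordinate difference (Euclidean distance divided by the square root
#'   of the encoded dimension), so the threshold has the same meaning
#'   regardless of dimensionality.
#' @return A tibble of `batch_size` reaction conditions with columns for every
#'   parameter plus `ei` (g/L) and `provenance` (`"maximizer"`, `"diversity"`
#'   or `"fallback"`).
#' @export
propose_batch <- function(model, space = ivt_space(), f_max = max(model$y),
                          batch_size = 4, seed = NULL, pool_size = 20000,
                          incumbent = NULL, n_local = 2000, ei_frac = 0.5,
                          min_dist = 0.05) {
  if (!inherits(model, "ivt_gp")) stop("model must be a fitted ivt_gp")
  assert_space(space)
  if (batch_size < 1 || batch_size > 5) {
    stop("batch_size must be between 1 and 5")
  }
  build <- function() {
    d <- space$encoded_dim
    pool_cond <- lhs_design(space, pool_size)
    pool <- encode_conditions(pool_cond, space)
    if (is.null(incumbent)) {
      top <- order(model$y, decreasing = TRUE)
      top <- top[!duplicated(model$X[top, , drop = FALSE])]
      inc <- model$X[top[seq_len(min(3, length(top)))], , drop = FALSE]
    } else if (is.data.frame(incumbent)) {
      inc <- encode_conditions(incumbent, space)
    } else {
      inc <- matrix(incumbent, ncol = d)
    }
    if (ncol(inc) == d && n_local > 0) {
      local <- do.call(rbind, lapply(c(0.1, 0.03), function(sdl) {
        P <- matrix(stats::rnorm(ceiling(n_local / 2) * d, 0, sdl),
                    ncol = d, byrow = TRUE)
        sweep(P, 2, as.numeric(inc[1, ]), "+")
      }))
      # axis-aligned line scans through the best points seen: cheap
      # coordinate refinement suiting near-separable response surfaces
      grid <- seq(0, 1, length.out = 21)
      offsets <- seq(-0.06, 0.06, length.out = 11)
      lines <- do.call(rbind, lapply(seq_len(nrow(inc)), function(b) {
        do.call(rbind, lapply(seq_len(d), function(j) {
          vals <- unique(c(grid, inc[b, j] + offsets))
          L <- matrix(rep(inc[b, ], each = length(vals)),
                      nrow = length(vals))
          L[, j] <- vals
          L
        }))
      }))
      local <- pmin(pmax(rbind(local, lines), 0), 1)
      colnames(local) <- colnames(pool)
      pool <- rbind(pool, local)
    }
    # snap to representable conditions before scoring so EI is evaluated at
    # the points that would actually be run (integers rounded, one-hot)
    cond <- decode_conditions(pool, space)
    enc <- encode_conditions(cond, space)
    pred <- stats::predict(model, enc)
    ei <- expected_improvement(pred$mean, pred$sd, f_max)

    ord <- order(ei, decreasing = TRUE)
    # drop duplicated decoded conditions (integer rounding can collapse)
    dup <- duplicated(enc[ord, , drop = FALSE])
    ord <- ord[!dup]

    chosen <- ord[1]
    provenance <- "maximizer"
    ei_max <- ei[ord[1]]
    good <- ord[ei[ord] >= ei_frac * ei_max]
    good <- setdiff(good, chosen)
    shuffled <- if (length(good) > 1) sample(good) else good
    k <- 1
    for (cand in shuffled) {
      if (length(chosen) >= batch_size) break
      dists <- sqrt(rowMeans(
        (enc[chosen, , drop = FALSE] -
           matrix(enc[cand, ], length(chosen), ncol(enc), byrow = TRUE))^2
      ))
      if (all(dists >= min_dist)) {
        chosen <- c(chosen, cand)
        provenance <- c(provenance, "diversity")
      }
    }
    if (length(chosen) < batch_size) {
      for (cand in setdiff(ord, chosen)) {
        if (length(chosen) >= batch_size) break
        chosen <- c(chosen, cand)
        provenance <- c(provenance, "fallback")
      }
    }
    out <- cond[chosen, , drop = FALSE]
    out$ei <- ei[chosen]
    out$provenance <- provenance
    out
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
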