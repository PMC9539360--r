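#' Shapley sampling-value attribution for one prediction
#'
#' Model-agnostic additive explanation `g(z') = phi0 + sum_j phi_j z'_j` of a
#' surrogate prediction at `x`: features are treated as players in a
#' cooperative game and each parameter receives its average marginal
#' contribution over sampled feature orderings (the Shapley sampling-values
#' approximation). For each sampled permutation, features enter in permutation
#' order; features not yet entered are imputed from a background draw;
#' antithetic (forward + reversed) permutations are paired for variance
#' reduction. Categorical parameters are imputed at the raw-label level, so
#' the attribution is per reaction parameter, not per one-hot column.
#'
#' @param predict_fn A function mapping a data frame of conditions to numeric
#'   predictions, e.g. `function(d) predict(model, d)$mean`.
#' @param background A non-empty data frame of background conditions (the
#'   experiment log is the natural choice).
#' @param x A single-row data frame: the conditions whose prediction is
#'   explained.
#' @param n_permutations Number of sampled orderings (default 256, counting
#'   both members of each antithetic pair).
#' @param seed Integer seed for permutation and background sampling.
#' @param features Character vector of feature columns (default: all columns
#'   of `background` that `x` also has).
#' @return A tibble of class `ivt_shap` with columns `parameter`, `value`
#'   (the raw parameter value at `x`), `phi` (effect, g/L) and `mc_sd`
#'   (Monte-Carlo standard error), plus attributes `base` (`phi0`, the mean
#'   background prediction) and `prediction` (`f(x)`). Local accuracy holds
#'   within Monte-Carlo error: `phi0 + sum(phi) ~ f(x)`.
#' @examples
#' f <- function(d) 2 * d$a
#' bg <- data.frame(a = c(-1, 1), b = c(0, 1)) # mean(a) = 0
#' shap_values(f, bg, data.frame(a = 1, b = 0), n_permutations = 8, seed = 1)
#' @export
shap_values <- function(predict_fn, background, x, n_permutations = 256,
                        seed = NULL, features = NULL) {
  background <- tibble::as_tibble(background)
  x <- tibble::as_tibble(x)[1, , drop = FALSE]
  if (nrow(background) == 0) stop("background must be non-empty")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (is.null(features)) features <- intersect(names(background), names(x))
  m <- length(features)
  if (m == 0) stop("no shared feature columns between background and x")

  run <- function() {
    n_pairs <- ceiling(n_permutations / 2)
    perms <- vector("list", 2 * n_pairs)
    bg_idx <- integer(2 * n_pairs)
    for (i in seq_len(n_pairs)) {
      p <- sample.int(m)
      b <- sample.int(nrow(background), 1)
      perms[[2 * i - 1]] <- p
      perms[[2 * i]] <- rev(p)
      bg_idx[c(2 * i - 1, 2 * i)] <- b
    }
    perms <- perms[seq_len(n_permutations)]
    bg_idx <- bg_idx[seq_len(n_permutations)]

    # build every chain state (m + 1 per permutation) and predict in one call
    chains <- vector("list", length(perms))
    for (pi in seq_along(perms)) {
      z <- background[rep(bg_idx[pi], m + 1), features, drop = FALSE]
      on <- logical(m)
      for (k in seq_len(m)) {
        on[perms[[pi]][k]] <- TRUE
        z[k + 1, features[on]] <- x[1, features[on]]
      }
      chains[[pi]] <- z
    }
    big <- dplyr::bind_rows(chains)
    preds <- predict_fn(big)
    contrib <- matrix(0, length(perms), m, dimnames = list(NULL, features))
    for (pi in seq_along(perms)) {
      f_chain <- preds[((pi - 1) * (m + 1) + 1):(pi * (m + 1))]
      contrib[pi, perms[[pi]]] <- diff(f_chain)
    }
    contrib
  }
  contrib <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  phi <- colMeans(contrib)
  mc_sd <- apply(contrib, 2, stats::sd) / sqrt(nrow(contrib))
  if (nrow(contrib) == 1) mc_sd <- rep(0, m)
  out <- tibble::tibble(
    parameter = features,
    value = as.character(unlist(x[1, features])),
    phi = unname(phi),
    mc_sd = unname(mc_sd)
  )
  attr(out, "base") <- mean(predict_fn(background))
  attr(out, "prediction") <- predict_fn(x)
  class(out) <- c("ivt_shap", class(out))
  out
}

#' Explain every observation of an experiment log
#'
#' Applies [shap_values()] to each row of `data` against a common background
#' (by default the data itself, i.e. the full log) using the GP posterior mean
#' as the function being explained.
#'
#' @param model A fitted `ivt_gp` surrogate (or any object with a `predict`
#'   method returning a `mean` column).
#' @param data Data frame of conditions to explain, one attribution per row.
#' @param background Background conditions (default `data`).
#' @param space The [param_space()]; its parameter names define the features.
#' @inheritParams shap_values
#' @return A long tibble `(observation, parameter, value, phi, mc_sd, base,
#'   prediction)`, suitable for [importance_summary()] and
#'   [dependence_table()].
#' @export
shap_explain <- function(model, data, background = data,
                         n_permutations = 256, seed = NULL,
                         space = ivt_space()) {
  predict_fn <- function(d) stats::predict(model, d)$mean
  features <- space$specs$name
  seeds <- derive_seeds(seed, nrow(data))
  purrr::map_dfr(seq_len(nrow(data)), function(i) {
    s <- shap_values(predict_fn, background[features],
                     data[i, features, drop = FALSE],
                     n_permutations = n_permutations, seed = seeds[[i]],
                     features = features)
    tibble::tibble(
      observation = i,
      parameter = s$parameter,
      value = s$value,
      phi = s$phi,
      mc_sd = s$mc_sd,
      base = attr(s, "base"),
      prediction = attr(s, "prediction")
    )
  })
}

#' Rank parameters by mean absolute Shapley effect
#'
#' @param attributions A long attribution tibble from [shap_explain()] (or a
#'   single [shap_values()] result).
#' @return A tibble `(parameter, mean_abs_phi)` sorted by decreasing effect;
#'   ties broken by parameter order in the attribution table.
#' @export
importance_summary <- function(attributions) {
  if (nrow(attributions) == 0) stop("attributions are empty")
  attributions |>
    dplyr::mutate(.order = match(.data$parameter,
                                 unique(.data$parameter))) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(mean_abs_phi = mean(abs(.data$phi)),
                     .order = dplyr::first(.data$.order)) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_phi), .data$.order) |>
    dplyr::select("parameter", "mean_abs_phi")
}

#' Per-observation (value, effect) pairs for one parameter
#'
#' The data behind a SHAP dependence (or beeswarm) panel: how a parameter's
#' raw value relates to its attributed effect across the log.
#'
#' @inheritParams importance_summary
#' @param parameter Name of one reaction parameter.
#' @return A tibble `(observation, value, phi)` in log order; `value` stays
#'   character for categorical parameters and is numeric otherwise.
#' @export
dependence_table <- function(attributions, parameter) {
  hit <- attributions$parameter == parameter
  if (!any(hit)) stop("unknown parameter: ", parameter)
  out <- attributions[hit, , drop = FALSE]
  value <- out$value
  num <- suppressWarnings(as.numeric(value))
  if (!anyNA(num)) value <- num
  tibble::tibble(
    observation = if ("observation" %in% names(out)) {
      out$observation
    } else {
      seq_len(nrow(out))
    },
    value = value,
    phi = out$phi
  )
}
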