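#' Surrogate factories for cross-validated comparison
#'
#' A surrogate factory is a function `(data, space) -> predict_fn` where
#' `data` holds reaction-parameter columns plus `yield_gL` and the returned
#' `predict_fn` maps a conditions data frame to numeric yield predictions.
#' Three factories are provided: the in-package GP surrogate, a random forest
#' ([ranger::ranger()]) and a gradient-boosting machine
#' ([xgboost::xgboost()]), the latter two operating on the one-hot encoded
#' representation. The tree learners are pluggable comparators; the GP is the
#' reference surrogate used by the optimization loop.
#'
#' @param restarts,maxit GP marginal-likelihood search controls.
#' @param seed Integer seed fixing each factory's fit.
#' @return A factory function.
#' @export
gp_surrogate <- function(restarts = 4, maxit = 60, seed = 1) {
  function(data, space = ivt_space()) {
    model <- gp_fit(data[space$specs$name], y = data$yield_gL, space = space,
                    restarts = restarts, seed = seed, maxit = maxit)
    function(newdata) stats::predict(model, newdata)$mean
  }
}

#' @rdname gp_surrogate
#' @param num_trees Number of random-forest trees.
#' @export
rf_surrogate <- function(num_trees = 500, seed = 1) {
  function(data, space = ivt_space()) {
    if (!requireNamespace("ranger", quietly = TRUE)) {
      stop("the ranger package is required for the random-forest comparator")
    }
    X <- as.data.frame(encode_conditions(data[space$specs$name], space))
    names(X) <- make.names(names(X))
    X$yield_gL <- data$yield_gL
    model <- ranger::ranger(yield_gL ~ ., data = X, num.trees = num_trees,
                            seed = seed)
    function(newdata) {
      Xn <- as.data.frame(encode_conditions(newdata[space$specs$name], space))
      names(Xn) <- make.names(names(Xn))
      stats::predict(model, Xn)$predictions
    }
  }
}

#' @rdname gp_surrogate
#' @param nrounds,eta Boosting rounds and learning rate.
#' @export
gbm_surrogate <- function(nrounds = 200, eta = 0.1, seed = 1) {
  function(data, space = ivt_space()) {
    if (!requireNamespace("xgboost", quietly = TRUE)) {
      stop("the xgboost package is required for the GBM comparator")
    }
    X <- encode_conditions(data[space$specs$name], space)
    model <- withr::with_seed(seed, xgboost::xgboost(
      X, data$yield_gL, nrounds = nrounds, learning_rate = eta,
      max_depth = 4, nthreads = 1, verbosity = 0
    ))
    function(newdata) {
      stats::predict(model, encode_conditions(newdata[space$specs$name],
                                              space))
    }
  }
}

#' Leave-one-out cross-validation errors of a surrogate
#'
#' Each observation is held out exactly once: the factory trains a fresh
#' surrogate on the other `n - 1` rows and the absolute prediction error
#' `|y_i - yhat_{-i}(x_i)|` is recorded. Folds run in log order; the held-out
#' target never reaches the training call.
#'
#' @param factory A surrogate factory, e.g. [gp_surrogate()].
#' @param log An experiment log (or any tibble with the parameter columns and
#'   `yield_gL`) with at least 3 rows.
#' @param space The [param_space()].
#' @return A tibble `(fold, yield_gL, pred_gL, abs_error)` of `nrow(log)`
#'   rows.
#' @export
loo_errors <- function(factory, log, space = ivt_space()) {
  if (nrow(log) < 3) stop("need at least 3 observations for LOO-CV")
  purrr::map_dfr(seq_len(nrow(log)), function(i) {
    train <- log[-i, , drop = FALSE]
    predict_fn <- tryCatch(
      factory(train, space),
      error = function(e) stop("surrogate factory failed on fold ", i, ": ",
                               conditionMessage(e))
    )
    pred <- predict_fn(log[i, , drop = FALSE])
    tibble::tibble(
      fold = i,
      yield_gL = log$yield_gL[i],
      pred_gL = as.numeric(pred)[1],
      abs_error = abs(log$yield_gL[i] - as.numeric(pred)[1])
    )
  })
}

#' Compare surrogate families by LOO-CV on one experiment log
#'
#' @param factories A named list of surrogate factories, e.g.
#'   `list(gp = gp_surrogate(), rf = rf_surrogate(), gbm = gbm_surrogate())`.
#' @inheritParams loo_errors
#' @return A long tibble `(model, fold, yield_gL, pred_gL, abs_error)`,
#'   box-plot ready. Summarize with [loo_summary()] and
#'   [paired_loo_differences()].
#' @export
compare_surrogates <- function(factories, log, space = ivt_space()) {
  if (length(factories) < 1) stop("supply at least one factory")
  if (is.null(names(factories)) || any(names(factories) == "")) {
    stop("factories must be named")
  }
  purrr::imap_dfr(factories, function(f, nm) {
    dplyr::mutate(loo_errors(f, log, space), model = nm, .before = 1)
  })
}

#' @rdname compare_surrogates
#' @param errors The long error tibble from [compare_surrogates()].
#' @return `loo_summary()`: one row per model with `median`, `iqr` and `mean`
#'   absolute error.
#' @export
loo_summary <- function(errors) {
  errors |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$abs_error),
      iqr = stats::IQR(.data$abs_error),
      mean = mean(.data$abs_error)
    )
}

#' @rdname compare_surrogates
#' @return `paired_loo_differences()`: per-fold differences in absolute error
#'   for every model pair (`model_a`, `model_b`, `fold`, `difference` =
#'   a minus b).
#' @export
paired_loo_differences <- function(errors) {
  wide <- tidyr::pivot_wider(errors[c("model", "fold", "abs_error")],
                             names_from = "model",
                             values_from = "abs_error")
  models <- setdiff(names(wide), "fold")
  if (length(models) < 2) {
    return(tibble::tibble(model_a = character(), model_b = character(),
                          fold = integer(), difference = numeric()))
  }
  pairs <- utils::combn(models, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    tibble::tibble(model_a = pr[1], model_b = pr[2], fold = wide$fold,
                   difference = wide[[pr[1]]] - wide[[pr[2]]])
  })
}
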