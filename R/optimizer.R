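log_columns <- function(space) {
  c("batch_id", "source", space$specs$name, "yield_gL", "replicate_sd_gL")
}

#' Create an empty experiment log
#'
#' The experiment log is the single source of truth for the optimization loop:
#' an append-only tibble with one row per evaluated reaction, columns
#' `batch_id` (cycle index, 0 for the seeding design), `source` (`"lhs"`,
#' `"bo"` or `"manual"`), one column per reaction parameter, the measured
#' `yield_gL` and an optional `replicate_sd_gL`.
#'
#' @param space The [param_space()] the log belongs to.
#' @return A zero-row tibble with the canonical column order.
#' @export
empty_experiment_log <- function(space = ivt_space()) {
  cols <- c(
    list(batch_id = integer(), source = character()),
    stats::setNames(
      purrr::map(seq_len(nrow(space$specs)), function(i) {
        if (space$specs$kind[i] == "categorical") character() else numeric()
      }),
      space$specs$name
    ),
    list(yield_gL = numeric(), replicate_sd_gL = numeric())
  )
  tibble::as_tibble(cols)
}

#' Read / write an experiment log CSV
#'
#' The on-disk format is a UTF-8 CSV with '.' decimal separator and the exact
#' header `batch_id,source,cofactor,cofactor_mM,DTT_mM,RNaseInh_UmL,NTPs_mM,`
#' `DNA_nM,PPase_UmL,spermidine_mM,T7_UmL,temperature_C,time_min,pH,yield_gL,`
#' `replicate_sd_gL` (for the default space; column names track the space).
#' Reading validates every row's conditions against the space.
#'
#' @param path CSV file path.
#' @param space The [param_space()] of the log.
#' @return `read_experiment_log()` returns the log tibble;
#'   `write_experiment_log()` returns `path` invisibly.
#' @export
read_experiment_log <- function(path, space = ivt_space()) {
  log <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(log_columns(space), names(log))
  if (length(missing) > 0) {
    stop("experiment log lacks column(s): ", paste(missing, collapse = ", "))
  }
  log <- log[log_columns(space)]
  stop_if_invalid(log[space$specs$name], space)
  if (any(log$yield_gL < 0)) stop("yields must be non-negative")
  log
}

#' @rdname read_experiment_log
#' @param log An experiment-log tibble.
#' @export
write_experiment_log <- function(log, path, space = ivt_space()) {
  readr::write_csv(log[log_columns(space)], path)
  invisible(path)
}

#' Seed the loop with a Latin hypercube design
#'
#' Thin wrapper over [lhs_design()] returning proposals tagged with
#' `source = "lhs"` and `batch_id = 0`, ready for [record_results()].
#'
#' @inheritParams lhs_design
#' @param n_init Number of seeding conditions (default 16).
#' @return A tibble of `n_init` proposals.
#' @export
initialize_design <- function(space = ivt_space(), n_init = 16, seed = NULL) {
  d <- lhs_design(space, n_init, seed)
  dplyr::mutate(d, batch_id = 0L, source = "lhs", .before = 1)
}

#' One optimization cycle: refit the surrogate and propose a batch
#'
#' Refits the GP on the full log, takes `f_max` as the best observed yield,
#' and delegates to [propose_batch()]. The log itself is not modified; feed
#' measured yields back with [record_results()].
#'
#' @param log An experiment log with at least 2 observations.
#' @param space The [param_space()].
#' @param batch_size Batch size, 3-5 conventionally (default 4).
#' @param seed Integer seed controlling both the refit restarts and the
#'   proposal pool.
#' @param restarts,maxit Passed to [gp_fit()].
#' @param noise_floor Lower bound on the GP noise variance (g/L squared).
#'   The default 0.04 corresponds to the low end of the assay's replicate
#'   standard deviation (about 0.2 g/L) and stops the refit from degenerating
#'   into a noise-free interpolation of replicate scatter.
#' @param ... Passed on to [propose_batch()] (pool size, diversity knobs).
#' @return A tibble of proposals tagged `source = "bo"` and the next
#'   `batch_id`, with `ei` and `provenance` columns.
#' @export
bo_step <- function(log, space = ivt_space(), batch_size = 4, seed = NULL,
                    restarts = 8, maxit = 100, noise_floor = 0.04, ...) {
  if (nrow(log) < 2) {
    stop("need at least 2 recorded observations; run initialize_design() ",
         "and record_results() first")
  }
  seeds <- derive_seeds(seed, 2)
  model <- gp_fit(log[space$specs$name], y = log$yield_gL, space = space,
                  restarts = restarts, seed = seeds[[1]], maxit = maxit,
                  noise_floor = noise_floor)
  prop <- propose_batch(model, space, f_max = max(log$yield_gL),
                        batch_size = batch_size, seed = seeds[[2]], ...)
  dplyr::mutate(prop,
                batch_id = max(log$batch_id) + 1L, source = "bo",
                .before = 1)
}

derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  # keep derived seeds inside 32-bit integer range
  as.list((as.numeric(seed) * 1000 + seq_len(k)) %% .Machine$integer.max)
}

#' Append measured yields to the experiment log
#'
#' @param log The current experiment log.
#' @param proposals A proposals tibble (from [initialize_design()] or
#'   [bo_step()]); extra columns such as `ei` are dropped.
#' @param yields Measured mRNA concentrations, g/L, aligned with
#'   `proposals`; all must be >= 0. `NA` entries mark reactions not (yet)
#'   performed and are skipped, supporting partial batch results.
#' @param replicate_sd Optional replicate standard deviations, g/L.
#' @param space The [param_space()].
#' @return The extended log; previously recorded rows are untouched.
#' @export
record_results <- function(log, proposals, yields, replicate_sd = NA_real_,
                           space = ivt_space()) {
  if (nrow(proposals) != length(yields)) {
    stop("got ", length(yields), " yields for ", nrow(proposals),
         " proposals")
  }
  if (any(yields < 0, na.rm = TRUE)) stop("yields must be non-negative")
  replicate_sd <- rep_len(replicate_sd, length(yields))
  keep <- !is.na(yields)
  new <- proposals[keep, , drop = FALSE]
  stop_if_invalid(new[space$specs$name], space)
  if (!"batch_id" %in% names(new)) {
    new$batch_id <- if (nrow(log) == 0) 0L else max(log$batch_id) + 1L
  }
  if (!"source" %in% names(new)) new$source <- "manual"
  new$yield_gL <- yields[keep]
  new$replicate_sd_gL <- replicate_sd[keep]
  dplyr::bind_rows(log, new[log_columns(space)])
}

#' Stopping rule for the optimization loop
#'
#' The loop stops when the total evaluation budget is exhausted, or when the
#' best-so-far yield has improved by less than `min_improvement` over the last
#' `patience` evaluations (a plateau).
#'
#' @param max_budget Total evaluation cap (default 150 reactions).
#' @param patience Plateau window, in evaluations (default 30).
#' @param min_improvement Smallest improvement in best-so-far, g/L, counted as
#'   progress (default 0.5, about one replicate standard deviation).
#' @return A `stopping_rule` list.
#' @export
stopping_rule <- function(max_budget = 150, patience = 30,
                          min_improvement = 0.5) {
  stopifnot(max_budget > 0, patience > 0, min_improvement > 0)
  structure(list(max_budget = max_budget, patience = patience,
                 min_improvement = min_improvement),
            class = "stopping_rule")
}

#' Should the optimization stop?
#'
#' @param log The experiment log.
#' @param rule A [stopping_rule()].
#' @return A list with `stop` (logical) and `reason` (`"budget"`,
#'   `"plateau"` or `"continue"`).
#' @export
stopped <- function(log, rule = stopping_rule()) {
  n <- nrow(log)
  if (n >= rule$max_budget) {
    return(list(stop = TRUE, reason = "budget"))
  }
  if (n > rule$patience) {
    best <- cummax(log$yield_gL)
    gain <- best[n] - best[n - rule$patience]
    if (gain < rule$min_improvement) {
      return(list(stop = TRUE, reason = "plateau"))
    }
  }
  list(stop = FALSE, reason = "continue")
}

#' Best-so-far convergence trace
#'
#' @param log A non-empty experiment log (or any tibble with `yield_gL`).
#' @return A tibble `(evaluation, yield_gL, best_gL)` where `best_gL` is the
#'   running maximum (non-decreasing; its last entry is the overall best).
#' @export
best_so_far_trace <- function(log) {
  if (nrow(log) == 0) stop("experiment log is empty")
  tibble::tibble(
    evaluation = seq_len(nrow(log)),
    yield_gL = log$yield_gL,
    best_gL = cummax(log$yield_gL)
  )
}

#' Long-format data for a parallel-coordinates view of the log
#'
#' Numeric parameters are min-max scaled to `[0, 1]` using the space bounds;
#' categorical parameters map levels to equally spaced positions. One row per
#' (observation, parameter) pair plus the yield, ready for plotting or export.
#'
#' @param log The experiment log.
#' @param space The [param_space()].
#' @return A tibble `(evaluation, parameter, value, position, yield_gL)`.
#' @export
parallel_coordinates_data <- function(log, space = ivt_space()) {
  purrr::map_dfr(seq_len(nrow(space$specs)), function(i) {
    nm <- space$specs$name[i]
    v <- log[[nm]]
    pos <- if (space$specs$kind[i] == "categorical") {
      lv <- space$specs$levels[[i]]
      (match(v, lv) - 1) / max(length(lv) - 1, 1)
    } else {
      (as.numeric(v) - space$specs$lo[i]) /
        (space$specs$hi[i] - space$specs$lo[i])
    }
    tibble::tibble(
      evaluation = seq_len(nrow(log)),
      parameter = factor(nm, levels = space$specs$name),
      value = as.character(v),
      position = pos,
      yield_gL = log$yield_gL
    )
  })
}

#' Run the closed optimization loop against a simulator
#'
#' Executes the full in-silico cycle: Latin hypercube seeding, noisy
#' measurement through the simulator, then repeated refit-propose-measure
#' cycles until the evaluation budget is spent. With the defaults (16 seeding
#' reactions plus batches of 4 up to 60 evaluations) this mirrors a campaign
#' in which the best conditions emerge within the first 60 runs.
#'
#' @param sim Simulator parameters from [sim_params()] (or any object
#'   accepted by [ivt_measure()]).
#' @param budget Total number of evaluations (default 60).
#' @param batch_size Proposals per cycle (default 4).
#' @param n_init Seeding design size (default 16).
#' @param seed Integer seed; the whole trajectory is reproducible.
#' @param space The [param_space()].
#' @param noise_sd Measurement noise passed to [ivt_measure()] (default the
#'   simulator's calibrated replicate noise). Use 0 for noise-free runs.
#' @param restarts,maxit GP refit controls per cycle, see [gp_fit()].
#' @param ... Extra arguments for [propose_batch()].
#' @return The final experiment log (`budget` rows).
#' @export
run_closed_loop <- function(sim = sim_params(), budget = 60, batch_size = 4,
                            n_init = 16, seed = NULL, space = ivt_space(),
                            noise_sd = NULL, restarts = 8, maxit = 100, ...) {
  stopifnot(budget >= n_init)
  seeds <- derive_seeds(seed, 2 * ceiling((budget - n_init) / batch_size) + 2)
  si <- 1
  design <- initialize_design(space, n_init, seed = seeds[[si]]); si <- si + 1
  obs <- ivt_measure(design, sim, seed = seeds[[si]], noise_sd = noise_sd)
  si <- si + 1
  log <- record_results(empty_experiment_log(space), design, obs$yield_gL,
                        space = space)
  cycle <- 1
  while (nrow(log) < budget) {
    bs <- min(batch_size, budget - nrow(log))
    prop <- tryCatch(
      bo_step(log, space, batch_size = max(bs, 1), seed = seeds[[si]],
              restarts = restarts, maxit = maxit, ...),
      error = function(e) {
        stop("closed-loop cycle ", cycle, " failed: ", conditionMessage(e))
      }
    )
    si <- si + 1
    prop <- prop[seq_len(bs), , drop = FALSE]
    obs <- ivt_measure(prop[space$specs$name], sim, seed = seeds[[si]],
                       noise_sd = noise_sd)
    si <- si + 1
    log <- record_results(log, prop, obs$yield_gL, space = space)
    cycle <- cycle + 1
  }
  log
}

#' Random-search baseline at the same budget
#'
#' Draws `budget` uniform conditions (each parameter independently uniform on
#' its domain) and measures them through the simulator, as a paired baseline
#' for [run_closed_loop()].
#'
#' @inheritParams run_closed_loop
#' @return An experiment log of `budget` rows, `source = "manual"`.
#' @export
run_random_search <- function(sim = sim_params(), budget = 60, seed = NULL,
                              space = ivt_space(), noise_sd = NULL) {
  seeds <- derive_seeds(seed, 2)
  draw <- function() {
    out <- purrr::map(seq_len(nrow(space$specs)), function(i) {
      if (space$specs$kind[i] == "categorical") {
        sample(space$specs$levels[[i]], budget, replace = TRUE)
      } else {
        x <- stats::runif(budget, space$specs$lo[i], space$specs$hi[i])
        if (space$specs$kind[i] == "integer") x <- round(x)
        x
      }
    })
    names(out) <- space$specs$name
    tibble::as_tibble(out)
  }
  cond <- if (is.null(seeds[[1]])) draw() else {
    withr::with_seed(seeds[[1]], draw())
  }
  obs <- ivt_measure(cond, sim, seed = seeds[[2]], noise_sd = noise_sd)
  record_results(empty_experiment_log(space), cond, obs$yield_gL,
                 space = space)
}
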