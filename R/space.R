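#' Define a mixed categorical/integer/real reaction-parameter space
#'
#' A parameter space is an ordered collection of parameter specifications, one
#' per reaction parameter. Each specification has a `kind` (`"categorical"`,
#' `"integer"` or `"real"`), a domain (a label set for categorical parameters,
#' a closed interval `[lo, hi]` otherwise) and free-text units. The space also
#' carries the dimensionality of its numeric encoding: every numeric parameter
#' contributes one min-max-scaled coordinate and every categorical parameter a
#' one-hot block with one coordinate per level.
#'
#' @param specs A data frame with columns `name` (unique identifiers), `kind`,
#'   `units`, `lo`, `hi` (numeric bounds, `NA` for categorical) and `levels`
#'   (list column of character vectors, `NULL` for numeric parameters).
#' @return An object of class `ivt_param_space` with elements `specs` (tibble),
#'   `encoded_dim` and `encoded_names`.
#' @seealso [ivt_space()] for the default 12-parameter IVT space.
#' @export
param_space <- function(specs) {
  specs <- tibble::as_tibble(specs)
  required <- c("name", "kind", "units", "lo", "hi", "levels")
  missing <- setdiff(required, names(specs))
  if (length(missing) > 0) {
    stop("param_space specs lack column(s): ", paste(missing, collapse = ", "))
  }
  specs <- specs[required]
  if (anyDuplicated(specs$name)) {
    stop("parameter names must be unique within a space")
  }
  bad_kind <- setdiff(unique(specs$kind), c("categorical", "integer", "real"))
  if (length(bad_kind) > 0) {
    stop("unknown parameter kind(s): ", paste(bad_kind, collapse = ", "))
  }
  for (i in seq_len(nrow(specs))) {
    if (specs$kind[i] == "categorical") {
      lv <- specs$levels[[i]]
      if (length(lv) == 0 || anyDuplicated(lv)) {
        stop("categorical parameter '", specs$name[i],
             "' needs a non-empty, duplicate-free level set")
      }
    } else {
      if (!is.finite(specs$lo[i]) || !is.finite(specs$hi[i]) ||
          specs$lo[i] >= specs$hi[i]) {
        stop("numeric parameter '", specs$name[i], "' needs finite lo < hi")
      }
    }
  }
  encoded_names <- unlist(purrr::map(seq_len(nrow(specs)), function(i) {
    if (specs$kind[i] == "categorical") {
      paste(specs$name[i], specs$levels[[i]], sep = ".")
    } else {
      specs$name[i]
    }
  }))
  structure(
    list(
      specs = specs,
      encoded_dim = length(encoded_names),
      encoded_names = encoded_names
    ),
    class = "ivt_param_space"
  )
}

#' @export
print.ivt_param_space <- function(x, ...) {
  cat("<ivt_param_space> ", nrow(x$specs), " parameters, encoded dimension ",
      x$encoded_dim, "\n", sep = "")
  print(dplyr::mutate(
    x$specs,
    domain = purrr::map_chr(seq_len(nrow(x$specs)), function(i) {
      if (x$specs$kind[i] == "categorical") {
        paste(x$specs$levels[[i]], collapse = ", ")
      } else {
        paste0("[", x$specs$lo[i], ", ", x$specs$hi[i], "]")
      }
    }),
    levels = NULL, lo = NULL, hi = NULL
  ))
  invisible(x)
}

spec_row <- function(name, kind, units, lo = NA_real_, hi = NA_real_,
                     levels = NULL) {
  tibble::tibble(name = name, kind = kind, units = units,
                 lo = lo, hi = hi, levels = list(levels))
}

#' The default 12-parameter IVT reaction space
#'
#' Builds the search domain for in vitro transcription optimization: the
#' magnesium cofactor salt and its concentration, DTT, RNase inhibitor, NTP
#' substrate, DNA template, inorganic pyrophosphatase, spermidine, T7 RNA
#' polymerase activity, temperature, reaction time and initial pH. Parameter
#' names double as the columns of the experiment-log CSV (see
#' [read_experiment_log()]).
#'
#' @return An [param_space()] object with 12 parameters (encoded dimension 13:
#'   11 scaled numeric coordinates plus a 2-level one-hot cofactor block).
#' @examples
#' s <- ivt_space()
#' s$encoded_dim
#' @export
ivt_space <- function() {
  param_space(dplyr::bind_rows(
    spec_row("cofactor", "categorical", "cofactor choice",
             levels = c("MgAcetate", "MgCl2")),
    spec_row("cofactor_mM", "real", "mM", 0, 100),
    spec_row("DTT_mM", "real", "mM", 0, 10),
    spec_row("RNaseInh_UmL", "integer", "U/mL", 0, 2000),
    spec_row("NTPs_mM", "real", "mM", 1, 10),
    spec_row("DNA_nM", "integer", "nM", 10, 100),
    spec_row("PPase_UmL", "integer", "U/mL", 0, 10),
    spec_row("spermidine_mM", "real", "mM", 0, 10),
    spec_row("T7_UmL", "integer", "U/mL", 1000, 50000),
    spec_row("temperature_C", "integer", "degC", 20, 50),
    spec_row("time_min", "integer", "min", 10, 300),
    spec_row("pH", "real", "", 6.5, 8)
  ))
}

assert_space <- function(space) {
  if (!inherits(space, "ivt_param_space")) {
    stop("expected an ivt_param_space; see param_space() / ivt_space()")
  }
  invisible(space)
}

#' Validate reaction conditions against a parameter space
#'
#' Violations are returned as data, one row each, rather than raised: a missing
#' parameter, a value outside its interval, or an unknown categorical label.
#'
#' @param conditions A data frame with one column per parameter and one row per
#'   candidate reaction condition.
#' @param space An [param_space()] object (default [ivt_space()]).
#' @return A tibble with columns `row`, `parameter`, `value`, `problem`; zero
#'   rows iff every condition is valid.
#' @examples
#' validate_conditions(tibble::tibble(pH = 9), ivt_space())
#' @export
validate_conditions <- function(conditions, space = ivt_space()) {
  assert_space(space)
  conditions <- tibble::as_tibble(conditions)
  out <- list()
  push <- function(row, parameter, value, problem) {
    if (length(row) == 0) return(invisible(NULL))
    out[[length(out) + 1]] <<- tibble::tibble(
      row = row, parameter = parameter, value = as.character(value),
      problem = problem
    )
  }
  for (i in seq_len(nrow(space$specs))) {
    nm <- space$specs$name[i]
    if (!nm %in% names(conditions)) {
      push(NA_integer_, nm, NA_character_, "missing parameter")
      next
    }
    v <- conditions[[nm]]
    miss <- which(is.na(v))
    push(miss, nm, v[miss], "missing value")
    ok <- which(!is.na(v))
    if (space$specs$kind[i] == "categorical") {
      bad <- ok[!(v[ok] %in% space$specs$levels[[i]])]
      push(bad, nm, v[bad],
           paste0("label not in {",
                  paste(space$specs$levels[[i]], collapse = ", "), "}"))
    } else {
      x <- suppressWarnings(as.numeric(v))
      nonnum <- ok[is.na(x[ok])]
      push(nonnum, nm, v[nonnum], "not numeric")
      num <- setdiff(ok, nonnum)
      oob <- num[x[num] < space$specs$lo[i] | x[num] > space$specs$hi[i]]
      push(oob, nm, v[oob],
           paste0("outside [", space$specs$lo[i], ", ", space$specs$hi[i],
                  "] ", space$specs$units[i]))
      if (space$specs$kind[i] == "integer") {
        frac <- setdiff(num, oob)[x[setdiff(num, oob)] !=
                                    round(x[setdiff(num, oob)])]
        push(frac, nm, v[frac], "not an integer")
      }
    }
  }
  if (length(out) == 0) {
    tibble::tibble(row = integer(), parameter = character(),
                   value = character(), problem = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(out), .data$row)
  }
}

stop_if_invalid <- function(conditions, space) {
  v <- validate_conditions(conditions, space)
  if (nrow(v) > 0) {
    stop("invalid reaction conditions: ",
         paste(unique(paste0(v$parameter, " (", v$problem, ")")),
               collapse = "; "))
  }
  invisible(conditions)
}

#' Encode reaction conditions on the unit hypercube
#'
#' Numeric parameters are min-max scaled to `[0, 1]`; each categorical
#' parameter becomes a one-hot block in declared level order. This is the
#' representation the Gaussian-process kernel and the acquisition search
#' operate on.
#'
#' @inheritParams validate_conditions
#' @return A numeric matrix with `nrow(conditions)` rows, `space$encoded_dim`
#'   columns and column names `space$encoded_names`.
#' @export
encode_conditions <- function(conditions, space = ivt_space()) {
  assert_space(space)
  conditions <- tibble::as_tibble(conditions)
  stop_if_invalid(conditions, space)
  n <- nrow(conditions)
  cols <- list()
  for (i in seq_len(nrow(space$specs))) {
    nm <- space$specs$name[i]
    if (space$specs$kind[i] == "categorical") {
      lv <- space$specs$levels[[i]]
      block <- matrix(0, n, length(lv))
      block[cbind(seq_len(n), match(conditions[[nm]], lv))] <- 1
      cols[[i]] <- block
    } else {
      x <- as.numeric(conditions[[nm]])
      cols[[i]] <- matrix(
        (x - space$specs$lo[i]) / (space$specs$hi[i] - space$specs$lo[i]),
        ncol = 1
      )
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- space$encoded_names
  m
}

#' Decode unit-hypercube points back to reaction conditions
#'
#' The inverse of [encode_conditions()], tolerant of relaxed points coming out
#' of the acquisition search: numeric coordinates are un-scaled and clipped to
#' their bounds, integer parameters rounded to the nearest whole number, and a
#' categorical block decoded by the argmax of its coordinates (so the block
#' need not be exactly one-hot). `decode_conditions(encode_conditions(c))`
#' recovers `c` for every valid `c`.
#'
#' @param points A numeric matrix (or vector for a single point) of encoded
#'   coordinates, `space$encoded_dim` columns.
#' @inheritParams validate_conditions
#' @return A tibble of reaction conditions, one row per point.
#' @export
decode_conditions <- function(points, space = ivt_space()) {
  assert_space(space)
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  if (ncol(points) != space$encoded_dim) {
    stop("encoded points have ", ncol(points), " coordinates; expected ",
         space$encoded_dim)
  }
  n <- nrow(points)
  out <- vector("list", nrow(space$specs))
  names(out) <- space$specs$name
  j <- 1
  for (i in seq_len(nrow(space$specs))) {
    if (space$specs$kind[i] == "categorical") {
      lv <- space$specs$levels[[i]]
      block <- points[, j:(j + length(lv) - 1), drop = FALSE]
      out[[i]] <- lv[max.col(block, ties.method = "first")]
      j <- j + length(lv)
    } else {
      lo <- space$specs$lo[i]
      hi <- space$specs$hi[i]
      x <- pmin(pmax(points[, j], 0), 1) * (hi - lo) + lo
      if (space$specs$kind[i] == "integer") {
        x <- pmin(pmax(round(x), lo), hi)
      }
      out[[i]] <- unname(x)
      j <- j + 1
    }
  }
  tibble::as_tibble(out)
}

#' Read / write a parameter-space definition as JSON
#'
#' The file is a JSON array of objects `{name, kind, domain, units}` where
#' `domain` is either `[lo, hi]` or the categorical label list. The package
#' bundles `ivt_space.json`, which reproduces the default IVT space.
#'
#' @param path File path.
#' @return `read_param_space()` returns an [param_space()];
#'   `write_param_space()` returns `path` invisibly.
#' @examples
#' read_param_space(system.file("extdata", "ivt_space.json", package = "ivtbo"))
#' @export
read_param_space <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::map(raw, function(p) {
    if (p$kind == "categorical") {
      spec_row(p$name, p$kind, p$units, levels = unlist(p$domain))
    } else {
      dom <- unlist(p$domain)
      spec_row(p$name, p$kind, p$units, dom[1], dom[2])
    }
  })
  param_space(dplyr::bind_rows(rows))
}

#' @rdname read_param_space
#' @param space An [param_space()] to serialize.
#' @export
write_param_space <- function(space, path) {
  assert_space(space)
  objs <- purrr::map(seq_len(nrow(space$specs)), function(i) {
    dom <- if (space$specs$kind[i] == "categorical") {
      as.list(space$specs$levels[[i]])
    } else {
      list(space$specs$lo[i], space$specs$hi[i])
    }
    list(name = space$specs$name[i], kind = space$specs$kind[i],
         domain = dom, units = space$specs$units[i])
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
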