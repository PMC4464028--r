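#' Declare how one parameter is sampled
#'
#' A `parameterSpec` carries a baseline value and either a symmetric
#' variation percentage (`var_pct = 25` means +/-25% around the baseline)
#' or explicit `(min, max)` bounds, plus the sampling distribution.
#'
#' @param name Parameter name (must match a model parameter / design
#'   column).
#' @param baseline Baseline value; required when `var_pct` is used, or for
#'   a normal distribution (the mean).
#' @param dist `"uniform"` or `"normal"`.
#' @param var_pct Variation percentage, `>= 0`; mutually exclusive with
#'   explicit bounds.
#' @param min,max Explicit bounds; used verbatim.
#' @param sd Standard deviation for `dist = "normal"`.
#' @param nonnegative If `TRUE`, a negative resolved lower bound (from a
#'   large `var_pct` on a small baseline) is clipped to 0 with a message.
#' @return An object of class `parameterSpec`.
#' @export
#' @examples
#' resolveInterval(parameterSpec("omega_CSC", baseline = 1, var_pct = 25))
parameterSpec <- function(name, baseline = NULL,
                          dist = c("uniform", "normal"),
                          var_pct = NULL, min = NULL, max = NULL, sd = NULL,
                          nonnegative = FALSE) {
  dist <- match.arg(dist)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  has_bounds <- !is.null(min) || !is.null(max)
  if (has_bounds && (is.null(min) || is.null(max))) {
    stop("spec '", name, "': both 'min' and 'max' are required for explicit ",
         "bounds", call. = FALSE)
  }
  if (!has_bounds && is.null(var_pct) && !(dist == "normal" && !is.null(sd))) {
    stop("spec '", name, "': give either var_pct or explicit (min, max)",
         call. = FALSE)
  }
  if (!has_bounds && is.null(baseline)) {
    stop("spec '", name, "': 'baseline' is required without explicit bounds",
         call. = FALSE)
  }
  if (!is.null(var_pct) && var_pct < 0) {
    stop("spec '", name, "': var_pct must be >= 0", call. = FALSE)
  }
  if (dist == "normal" && is.null(sd) && is.null(var_pct)) {
    stop("spec '", name, "': normal distribution needs 'sd' (or var_pct to ",
         "derive bounds)", call. = FALSE)
  }
  structure(list(name = name, baseline = baseline, dist = dist,
                 var_pct = var_pct, min = min, max = max, sd = sd,
                 nonnegative = isTRUE(nonnegative)),
            class = "parameterSpec")
}

#' Resolve a spec's sampling interval
#'
#' @param spec A [parameterSpec()].
#' @return Numeric `c(min, max)`. For `var_pct` = v the interval is
#'   `baseline * (1 -/+ v/100)`; explicit bounds pass through unchanged.
#'   A negative lower bound is clipped to 0 (with a message) when the spec
#'   is flagged `nonnegative`.
#' @export
resolveInterval <- function(spec) {
  stopifnot(inherits(spec, "parameterSpec"))
  if (!is.null(spec$min)) {
    lo <- spec$min; hi <- spec$max
    if (lo >= hi) {
      stop("spec '", spec$name, "': explicit min >= max", call. = FALSE)
    }
  } else if (is.null(spec$var_pct)) {
    # unbounded normal: strata are defined by probability mass, not range
    lo <- -Inf; hi <- Inf
  } else {
    v <- spec$var_pct / 100
    lo <- spec$baseline * (1 - v)
    hi <- spec$baseline * (1 + v)
    if (spec$nonnegative && lo < 0) {
      message("spec '", spec$name, "': lower bound ", lo,
              " clipped to 0 (non-negative parameter)")
      lo <- 0
    }
    if (lo >= hi) {
      stop("spec '", spec$name, "': degenerate interval (baseline ",
           spec$baseline, ", var_pct ", spec$var_pct, ")", call. = FALSE)
    }
    if (spec$baseline < lo || spec$baseline > hi) {
      stop("spec '", spec$name, "': baseline outside resolved interval",
           call. = FALSE)
    }
  }
  c(min = lo, max = hi)
}

# Deterministic per-column RNG substream: a small string hash mixed with the
# master seed, so adding or reordering specs never perturbs other columns.
columnSeed <- function(seed, name) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 2147483563
  as.integer((seed + h) %% 2147483563 + 1)
}

#' Latin hypercube sample of a parameter space
#'
#' For each parameter, the distribution's support is divided into `n`
#' equal-probability strata and each stratum is sampled exactly once
#' (uniform within the stratum, via the inverse CDF), then the column is
#' independently permuted. Uniform columns use equal-width strata on the
#' resolved interval; normal columns use equal probability mass (values are
#' not truncated unless explicit bounds are given, in which case the normal
#' is truncated to them).
#'
#' Each column draws from its own RNG substream derived from `seed` and the
#' parameter name, so designs are reproducible and adding a parameter does
#' not perturb the other columns.
#'
#' @param specs List of [parameterSpec()] objects (k of them).
#' @param n Sample size, `>= 2`. A warning is issued when `n <= k + 1`.
#' @param seed Integer master seed.
#' @return An object of class `sampleDesign` with elements `specs`, `n`,
#'   `seed` and `matrix` (an `n x k` data frame with parameter-named
#'   columns).
#' @export
#' @examples
#' d <- lhsSample(list(parameterSpec("a", min = 0, max = 1)), n = 4, seed = 1)
#' sort(d$matrix$a) # one value per quarter of [0, 1]
lhsSample <- function(specs, n, seed) {
  if (inherits(specs, "parameterSpec")) specs <- list(specs)
  stopifnot(is.list(specs), length(specs) >= 1L)
  ok <- vapply(specs, inherits, logical(1), "parameterSpec")
  if (!all(ok)) stop("'specs' must be a list of parameterSpec", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop("'n' must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    stop("'seed' must be an integer", call. = FALSE)
  }
  n <- as.integer(n)
  k <- length(specs)
  nms <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nms)) {
    stop("duplicated parameter names in specs: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  if (n <= k + 1) {
    warning("sample size n = ", n, " should be greater than k + 1 = ", k + 1,
            call. = FALSE)
  }
  cols <- vector("list", k)
  for (j in seq_len(k)) {
    spec <- specs[[j]]
    iv <- resolveInterval(spec)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(columnSeed(seed, spec$name))
    strata <- sample.int(n)               # which stratum each row receives
    u <- stats::runif(n)                  # position within the stratum
    prob <- (strata - 1 + u) / n
    cols[[j]] <- if (spec$dist == "uniform") {
      iv[["min"]] + (iv[["max"]] - iv[["min"]]) * prob
    } else {
      mean <- spec$baseline
      sd <- if (!is.null(spec$sd)) spec$sd else
        (iv[["max"]] - iv[["min"]]) / 4   # derived spread when only var_pct given
      if (!is.finite(sd)) {
        stop("spec '", spec$name, "': normal sampling needs 'sd' or bounds",
             call. = FALSE)
      }
      if (!is.null(spec$min)) {
        plo <- stats::pnorm(iv[["min"]], mean, sd)
        phi <- stats::pnorm(iv[["max"]], mean, sd)
        stats::qnorm(plo + (phi - plo) * prob, mean, sd)
      } else {
        stats::qnorm(prob, mean, sd)
      }
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  m <- as.data.frame(stats::setNames(cols, nms))
  structure(list(specs = specs, n = n, seed = as.integer(seed), matrix = m),
            class = "sampleDesign")
}

#' @export
print.sampleDesign <- function(x, ...) {
  cat("<sampleDesign> n = ", x$n, ", k = ", ncol(x$matrix),
      ", seed = ", x$seed, "\n", sep = "")
  for (s in x$specs) {
    iv <- resolveInterval(s)
    cat(sprintf("  %-12s %s on [%g, %g]\n", s$name, s$dist,
                iv[["min"]], iv[["max"]]))
  }
  invisible(x)
}

#' Write / read a design matrix as CSV
#'
#' Full-precision (17 significant digits) CSV with one column per parameter
#' and one row per sample, so that `readDesign(writeDesign(d, f))`
#' reproduces the matrix bit-exactly.
#'
#' @param design A [lhsSample()] design.
#' @param path File path.
#' @return `writeDesign` returns `path` invisibly; `readDesign` returns the
#'   design matrix as a data frame.
#' @export
writeDesign <- function(design, path) {
  stopifnot(inherits(design, "sampleDesign"))
  m <- design$matrix
  lines <- c(paste(colnames(m), collapse = ","),
             apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @param expected_names Optional character vector of required column
#'   names; a missing column is a format error naming it.
#' @rdname writeDesign
#' @export
readDesign <- function(path, expected_names = NULL) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) == 0L) {
    stop("design file '", path, "' has no sample rows", call. = FALSE)
  }
  if (!is.null(expected_names)) {
    missing <- setdiff(expected_names, colnames(raw))
    if (length(missing)) {
      stop("design file '", path, "' is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  for (j in seq_along(raw)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad)) {
      stop("non-numeric value in column '", colnames(raw)[j], "', row ",
           bad[1], call. = FALSE)
    }
    raw[[j]] <- v
  }
  raw
}

#' Parameter specs for the CSC model's standard experiment
#'
#' The shipped study design: every rate parameter varies +/-50% uniformly
#' around its [cscParameters()] baseline, while the symmetric-division
#' probability `P_sy` spans its full range `[0, 1]`.
#'
#' @param params Baseline parameters, default [cscParameters()].
#' @param var_pct Variation percentage for the rate parameters, default 50.
#' @return List of 13 [parameterSpec()] objects.
#' @export
cscParameterSpecs <- function(params = cscParameters(), var_pct = 50) {
  p <- checkNamedNumeric(unclass(params), cscParameterNames, "CSC parameters")
  specs <- list(parameterSpec("P_sy", baseline = p[["P_sy"]], min = 0, max = 1))
  for (nm in setdiff(cscParameterNames, "P_sy")) {
    specs <- c(specs, list(parameterSpec(nm, baseline = p[[nm]],
                                         var_pct = var_pct,
                                         nonnegative = TRUE)))
  }
  specs
}
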