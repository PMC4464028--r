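defaultLevelColors <- function(r) {
  if (r == 4L) c("black", "blue", "red", "green") else
    grDevices::hcl.colors(r, "Dark 3")
}

# Round half up (not banker's rounding); legends print 2 decimals while the
# internal boundaries keep full precision.
roundHalfUp <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Partition a parameter range into equal color-coded levels
#'
#' Divides `[min, max]` into `r` equal-width subintervals (levels). The
#' first level is closed on both ends, the others are left-open
#' right-closed, matching the bracket convention
#' `[0.00, 0.25] (0.25, 0.50] (0.50, 0.75] (0.75, 1.00]`. The default
#' color order for `r = 4` is black, blue, red, green (lowest to highest
#' level).
#'
#' @param min,max Range endpoints, `min < max`.
#' @param r Number of levels, `>= 2` (default 4).
#' @param parameter Optional parameter name (or combination expression)
#'   the partition refers to.
#' @param colors Optional vector of `r` colors.
#' @return Object of class `levelPartition` with elements `parameter`,
#'   `min`, `max`, `r`, `boundaries` (the `r - 1` interior cut points, full
#'   precision) and `colors`.
#' @export
#' @examples
#' partitionRange(0, 1, 4)$boundaries      # 0.25 0.50 0.75
#' partitionRange(0.01, 5.99, 4)$boundaries
partitionRange <- function(min, max, r = 4L, parameter = NULL,
                           colors = NULL) {
  if (!is.numeric(min) || !is.numeric(max) || min >= max) {
    stop("need min < max for a level partition", call. = FALSE)
  }
  if (r < 2) stop("need at least r = 2 levels", call. = FALSE)
  r <- as.integer(r)
  boundaries <- min + (max - min) * seq_len(r - 1) / r
  if (is.null(colors)) colors <- defaultLevelColors(r)
  if (length(colors) != r) stop("'colors' must have length r", call. = FALSE)
  structure(list(parameter = parameter, min = min, max = max, r = r,
                 boundaries = boundaries, colors = colors),
            class = "levelPartition")
}

#' Legend labels of a partition, 2-decimal bounds
#'
#' @param partition A [levelPartition()].
#' @param digits Printed decimals (default 2, rounded half-up).
#' @return Character vector of `r` interval labels.
#' @export
levelLabels <- function(partition, digits = 2) {
  b <- roundHalfUp(c(partition$min, partition$boundaries, partition$max),
                   digits)
  fmt <- paste0("%.", digits, "f")
  vapply(seq_len(partition$r), function(i) {
    lb <- if (i == 1) "[" else "("
    sprintf("%s%s, %s]", lb, sprintf(fmt, b[i]), sprintf(fmt, b[i + 1]))
  }, character(1))
}

#' @export
print.levelPartition <- function(x, ...) {
  cat("<levelPartition>", if (!is.null(x$parameter)) x$parameter else "",
      " r = ", x$r, "\n", sep = "")
  lab <- levelLabels(x)
  for (i in seq_len(x$r)) {
    cat(sprintf("  level %d (%s): %s\n", i, x$colors[i], lab[i]))
  }
  invisible(x)
}

#' Assign values to partition levels
#'
#' @param value Numeric vector of values within `[min, max]`.
#' @param partition A [levelPartition()].
#' @return Integer vector of level indices in `1..r`, under the convention
#'   that the first interval is closed and the rest are `(lo, hi]`. Values
#'   outside the range are an error: the caller decides whether to clip or
#'   extend the partition.
#' @export
#' @examples
#' p <- partitionRange(0, 1, 4)
#' assignLevel(c(0.25, 0.250001, 1), p) # 1 2 4
assignLevel <- function(value, partition) {
  stopifnot(inherits(partition, "levelPartition"))
  if (any(value < partition$min | value > partition$max)) {
    bad <- value[value < partition$min | value > partition$max][1]
    stop("value ", bad, " outside the partition range [", partition$min,
         ", ", partition$max, "]", call. = FALSE)
  }
  idx <- vapply(value, function(v) sum(v > partition$boundaries), numeric(1))
  as.integer(idx) + 1L
}

#' Evaluate a parameter-combination expression over a design
#'
#' Derived quantities such as `P_sy * omega_CSC` or
#' `P_sy * omega_CSC - eta_1` are first-class partition/scatter axes. The
#' expression grammar is restricted to design column names, numeric
#' literals, `+`, `-`, `*` and parentheses; division and powers are
#' rejected.
#'
#' @param expression Character scalar, e.g. `"P_sy*omega_CSC-eta_1"`.
#' @param design A [lhsSample()] design or a data frame of columns.
#' @return Numeric vector of length n (row-wise evaluation).
#' @export
combineColumns <- function(expression, design) {
  m <- if (inherits(design, "sampleDesign")) design$matrix else design
  stopifnot(is.data.frame(m), is.character(expression),
            length(expression) == 1L)
  expr <- tryCatch(str2lang(expression),
                   error = function(e) stop("cannot parse expression '",
                                            expression, "'", call. = FALSE))
  checkNode <- function(node) {
    if (is.name(node)) {
      nm <- as.character(node)
      if (!nm %in% colnames(m)) {
        stop("unknown identifier '", nm, "' (not a design column)",
             call. = FALSE)
      }
    } else if (is.call(node)) {
      op <- as.character(node[[1]])
      if (!op %in% c("+", "-", "*", "(")) {
        stop("operator '", op, "' not allowed; grammar is identifiers, ",
             "numbers, +, -, * and parentheses", call. = FALSE)
      }
      for (arg in as.list(node)[-1]) checkNode(arg)
    } else if (!is.numeric(node)) {
      stop("disallowed token in expression '", expression, "'",
           call. = FALSE)
    }
  }
  checkNode(expr)
  eval(expr, envir = m, enclos = baseenv())
}

#' Color-coded trajectory plot
#'
#' Draws every sample's trajectory for one output variable, colored by the
#' level its key-parameter value falls in, with the partition intervals in
#' the legend (2-decimal bounds). On a log scale, values at or below zero
#' are clipped to `log_floor` and the clipped count is reported in the
#' plot's sidecar metadata.
#'
#' @param Y An [simulateEnsemble()] output.
#' @param key_column Numeric vector (length n) of key-parameter values,
#'   e.g. a design column or a [combineColumns()] result.
#' @param partition A [levelPartition()] covering `key_column`'s range.
#' @param variable Output variable to draw.
#' @param scale `"linear"` or `"log"` (log10 y axis).
#' @param log_floor Positive floor replacing values `<= 0` on a log scale.
#' @return A ggplot object; attribute `"sidecar"` carries the partition
#'   bounds, per-level counts and clipped-point count.
#' @export
coloredTraces <- function(Y, key_column, partition, variable,
                          scale = c("linear", "log"), log_floor = 1e-3) {
  scale <- match.arg(scale)
  stopifnot(inherits(Y, "ensembleOutput"),
            inherits(partition, "levelPartition"))
  if (!variable %in% Y$variable_names) {
    stop("unknown variable '", variable, "'", call. = FALSE)
  }
  n <- dim(Y$values)[1]
  if (length(key_column) != n) {
    stop("key_column length must equal the number of samples", call. = FALSE)
  }
  lv <- assignLevel(key_column, partition)
  keep <- which(Y$success)
  m <- Y$values[keep, , variable, drop = FALSE]
  dim(m) <- c(length(keep), length(Y$grid$times))
  clipped <- 0L
  if (scale == "log") {
    clipped <- sum(m <= 0)
    m[m <= 0] <- log_floor
  }
  labs <- levelLabels(partition)
  d <- data.frame(
    time = rep(Y$grid$times, each = length(keep)),
    value = as.vector(m),
    sample = rep(keep, times = length(Y$grid$times)),
    level = factor(rep(labs[lv[keep]], times = length(Y$grid$times)),
                   levels = labs))
  pal <- stats::setNames(partition$colors, labs)
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value,
                                       group = .data$sample,
                                       color = .data$level)) +
    ggplot2::geom_line(linewidth = 0.25, alpha = 0.8) +
    ggplot2::scale_color_manual(values = pal, drop = FALSE,
                                name = partition$parameter %||% "level") +
    ggplot2::labs(x = "time", y = variable) +
    ggplot2::theme_minimal()
  if (scale == "log") g <- g + ggplot2::scale_y_log10()
  attr(g, "sidecar") <- list(
    parameter = partition$parameter, variable = variable, scale = scale,
    bounds = c(partition$min, partition$boundaries, partition$max),
    counts_per_level = as.vector(table(factor(lv[keep],
                                              levels = seq_len(partition$r)))),
    clipped_points = clipped)
  g
}

#' Color-coded scatter plot at one time point
#'
#' One point per surviving sample at (key value, output value), colored by
#' partition level; typically used on an [outputsAtTime()] slice at the
#' final time.
#'
#' @param outputs_t An `n x v` slice from [outputsAtTime()] (its `"time"`
#'   attribute labels the plot).
#' @param x_column Numeric vector (length n): a design column or
#'   [combineColumns()] result for the x axis.
#' @param partition A [levelPartition()]; levels are assigned from
#'   `color_column`.
#' @param variable Output variable for the y axis.
#' @param color_column Values driving the color code (default `x_column`,
#'   i.e. the scatter is colored by its own x axis; pass a different
#'   column to cross-color, as in the combination analyses).
#' @param success Optional logical vector of surviving rows.
#' @param scale `"linear"` or `"log"` y axis; `log_floor` as in
#'   [coloredTraces()].
#' @param log_floor Positive floor replacing values `<= 0` on a log scale.
#' @return A ggplot object with a `"sidecar"` attribute.
#' @export
coloredScatter <- function(outputs_t, x_column, partition, variable,
                           color_column = x_column, success = NULL,
                           scale = c("linear", "log"), log_floor = 1e-3) {
  scale <- match.arg(scale)
  stopifnot(inherits(partition, "levelPartition"))
  if (!variable %in% colnames(outputs_t)) {
    stop("unknown variable '", variable, "'", call. = FALSE)
  }
  n <- nrow(outputs_t)
  stopifnot(length(x_column) == n, length(color_column) == n)
  if (is.null(success)) success <- rep(TRUE, n)
  lv <- assignLevel(color_column, partition)
  keep <- which(success)
  y <- outputs_t[keep, variable]
  clipped <- 0L
  if (scale == "log") {
    clipped <- sum(y <= 0)
    y[y <= 0] <- log_floor
  }
  labs <- levelLabels(partition)
  d <- data.frame(x = x_column[keep], y = y,
                  level = factor(labs[lv[keep]], levels = labs))
  pal <- stats::setNames(partition$colors, labs)
  tlab <- attr(outputs_t, "time")
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                       color = .data$level)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::scale_color_manual(values = pal, drop = FALSE,
                                name = partition$parameter %||% "level") +
    ggplot2::labs(x = partition$parameter %||% "parameter", y = variable,
                  title = if (!is.null(tlab)) paste0(variable, " at t = ", tlab)) +
    ggplot2::theme_minimal()
  if (scale == "log") g <- g + ggplot2::scale_y_log10()
  attr(g, "sidecar") <- list(
    parameter = partition$parameter, variable = variable, scale = scale,
    time = tlab,
    bounds = c(partition$min, partition$boundaries, partition$max),
    counts_per_level = as.vector(table(factor(lv[keep],
                                              levels = seq_len(partition$r)))),
    clipped_points = clipped)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a figure with its machine-readable sidecar
#'
#' Writes the plot as PNG (and optionally SVG) plus a JSON sidecar with the
#' partition bounds, per-level counts and clipped-point counts, so figures
#' are checkable without image parsing.
#'
#' @param plot A plot from [coloredTraces()], [coloredScatter()] or
#'   [plotPrcc()].
#' @param path Output path without extension.
#' @param formats Subset of `c("png", "svg")`.
#' @param width,height,dpi Device settings.
#' @return Invisibly, the files written.
#' @export
saveFigure <- function(plot, path, formats = "png",
                       width = 7, height = 5, dpi = 150) {
  files <- character(0)
  for (fmt in formats) {
    f <- paste0(path, ".", fmt)
    ggplot2::ggsave(f, plot, width = width, height = height, dpi = dpi)
    files <- c(files, f)
  }
  sidecar <- attr(plot, "sidecar")
  if (!is.null(sidecar)) {
    f <- paste0(path, ".json")
    jsonlite::write_json(sidecar, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  invisible(files)
}
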