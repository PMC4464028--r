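#' Generic ODE model definition
#'
#' A `modelDefinition` bundles everything the workflow needs to simulate and
#' analyse an autonomous ODE system: state and parameter names, the
#' right-hand side, an optional analytic Jacobian, and defaults. User models
#' registered through this constructor are usable anywhere the built-in
#' models are (sampling, ensembles, PRCC, level plots, bifurcation scans).
#'
#' @param name Identifier for the model.
#' @param state_names Ordered character vector of state variable names.
#' @param parameter_names Ordered character vector of parameter names.
#' @param rhs Function `(state, params, t)` returning the derivative vector,
#'   same length and order as `state_names`. The system is treated as
#'   autonomous; `t` is accepted for solver compatibility only.
#' @param jacobian Optional function `(state, params)` returning the square
#'   Jacobian matrix of `rhs` with respect to the state. When `NULL`, a
#'   central finite-difference fallback is used.
#' @param default_parameters Named numeric vector of baseline parameters.
#' @param default_initial_state Named numeric vector of initial conditions.
#'
#' @return An object of class `modelDefinition`.
#' @export
modelDefinition <- function(name, state_names, parameter_names, rhs,
                            jacobian = NULL,
                            default_parameters, default_initial_state) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(state_names), length(state_names) >= 1L,
            is.character(parameter_names), is.function(rhs))
  if (!is.null(jacobian) && !is.function(jacobian)) {
    stop("'jacobian' must be a function or NULL", call. = FALSE)
  }
  default_parameters <- checkNamedNumeric(default_parameters, parameter_names,
                                          "default_parameters")
  default_initial_state <- checkNamedNumeric(default_initial_state, state_names,
                                             "default_initial_state")
  d0 <- rhs(default_initial_state, default_parameters, 0)
  if (length(d0) != length(state_names)) {
    stop("rhs output length (", length(d0), ") does not match the number of ",
         "state variables (", length(state_names), ")", call. = FALSE)
  }
  structure(list(name = name,
                 state_names = state_names,
                 parameter_names = parameter_names,
                 rhs = rhs,
                 jacobian = jacobian,
                 default_parameters = default_parameters,
                 default_initial_state = default_initial_state),
            class = "modelDefinition")
}

checkNamedNumeric <- function(x, expected_names, what) {
  x <- unlist(x)
  if (!is.numeric(x) || length(x) != length(expected_names)) {
    stop("'", what, "' must be a numeric vector of length ",
         length(expected_names), call. = FALSE)
  }
  if (is.null(names(x))) {
    names(x) <- expected_names
  } else if (!setequal(names(x), expected_names)) {
    stop("'", what, "' names do not match: expected {",
         paste(expected_names, collapse = ", "), "}", call. = FALSE)
  }
  x[expected_names]
}

#' @export
print.modelDefinition <- function(x, ...) {
  cat("<modelDefinition> ", x$name, "\n", sep = "")
  cat("  states    : ", paste(x$state_names, collapse = ", "), "\n", sep = "")
  cat("  parameters: ", paste(x$parameter_names, collapse = ", "), "\n", sep = "")
  cat("  jacobian  : ", if (is.null(x$jacobian)) "finite-difference fallback"
      else "analytic", "\n", sep = "")
  invisible(x)
}

#' Jacobian of a model's right-hand side
#'
#' Evaluates the analytic Jacobian when the model provides one, otherwise a
#' central finite-difference approximation of `rhs` (step `1e-6 * max(1,
#' |state_i|)` per component).
#'
#' @param model A [modelDefinition()].
#' @param state Numeric state vector.
#' @param params Numeric parameter vector.
#' @return Square numeric matrix, one row/column per state variable.
#' @export
modelJacobian <- function(model, state, params) {
  if (!is.null(model$jacobian)) {
    J <- model$jacobian(state, params)
  } else {
    J <- fdJacobian(function(s) model$rhs(s, params, 0), state)
  }
  J <- as.matrix(J)
  dimnames(J) <- list(model$state_names, model$state_names)
  J
}

# Central finite differences; step scaled per component.
fdJacobian <- function(f, x, h = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (i in seq_len(n)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    J[, i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  J
}

# ---------------------------------------------------------------------------
# CSC population model
# ---------------------------------------------------------------------------

cscParameterNames <- c("P_sy", "omega_CSC", "omega_PC", "eta_1", "eta_2",
                       "eta_3", "gamma_PC", "delta_1", "delta_2", "delta_3",
                       "delta_4", "h_CSC", "h_PC")

cscStateNames <- c("N_CSC", "N_PC1", "N_PC2", "N_TC", "N_DC")

#' Phenotypic parameters of the CSC population model
#'
#' Builds and validates the 13-parameter vector of the cancer stem cell
#' (CSC) tumor growth model. Rates are per unit time (day^-1 at the default
#' time scale); feedback intensities are per cell.
#'
#' The defaults are a documented package choice, not ground truth from any
#' particular experiment. They are constructed so that (i) the closed-form
#' invasion boundary `(eta_1 + delta_1) / omega_CSC` equals 0.025, (ii) the
#' default initial tumor of 1e5 cells has terminal cells as the largest and
#' CSCs as the smallest subpopulation, and (iii) under wide (+/-50%) uniform
#' parameter variation over `[0, 200]` the symmetric-division probability
#' `P_sy` produces the characteristic switch between tumor extinction and
#' sustained growth.
#'
#' @param ... Named parameter overrides; unnamed arguments are rejected.
#'   Valid names: `P_sy` (probability of symmetric CSC division, in
#'   `[0, 1]`), `omega_CSC`, `omega_PC` (CSC and PC1 proliferation rates),
#'   `eta_1`, `eta_2`, `eta_3` (CSC, PC1, PC2 differentiation rates),
#'   `gamma_PC` (PC1 de-differentiation rate), `delta_1`, `delta_2`,
#'   `delta_3` (CSC, PC, TC death rates), `delta_4` (dead-cell lysis rate),
#'   `h_CSC`, `h_PC` (feedback intensities, 1/cells).
#' @return Named numeric vector of length 13, class `cscParameters`.
#' @export
#' @examples
#' p <- cscParameters(P_sy = 0.1)
#' invasionThreshold(p)
cscParameters <- function(...) {
  defaults <- c(P_sy = 0.5, omega_CSC = 1.0, omega_PC = 0.8,
                eta_1 = 0.01, eta_2 = 0.2, eta_3 = 0.3,
                gamma_PC = 0.01,
                delta_1 = 0.015, delta_2 = 0.05, delta_3 = 0.01,
                delta_4 = 0.2,
                h_CSC = 1.5e-4, h_PC = 1.5e-4)
  overrides <- c(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      stop("unknown CSC parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    defaults[names(overrides)] <- overrides
  }
  validateCscParameters(defaults)
  structure(defaults, class = "cscParameters")
}

validateCscParameters <- function(p) {
  p <- checkNamedNumeric(unclass(p), cscParameterNames, "CSC parameters")
  if (any(!is.finite(p))) stop("CSC parameters must be finite", call. = FALSE)
  if (any(p < 0)) {
    stop("CSC parameters must be non-negative; offending: ",
         paste(names(p)[p < 0], collapse = ", "), call. = FALSE)
  }
  if (p[["P_sy"]] > 1) stop("P_sy must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

#' Default initial state of the CSC model
#'
#' A tumor of 1e5 cells (the subcutaneous-injection order of magnitude) with
#' terminal cells as the largest and CSCs as the smallest subpopulation.
#'
#' @return Named numeric vector of the five compartment sizes (cells).
#' @export
cscInitialState <- function() {
  c(N_CSC = 100, N_PC1 = 900, N_PC2 = 9000, N_TC = 85000, N_DC = 5000)
}

#' Feedback-limited proliferation rate
#'
#' The tumor microenvironment limits proliferation through the density of
#' terminal cells: an intrinsic rate `omega` is reduced to
#' `omega / (1 + h * N_TC)`, where `h` is the feedback intensity.
#'
#' @param omega Intrinsic proliferation rate (1/time), `>= 0`.
#' @param h Feedback intensity (1/cells), `>= 0`.
#' @param N_TC Terminal-cell count, `>= 0`.
#' @return Effective rate, `<= omega`, equal to `omega` when `h = 0`.
#' @export
#' @examples
#' effectiveRate(2, 1, 1)   # 1
#' effectiveRate(3, 0.5, 4) # 1
effectiveRate <- function(omega, h, N_TC) {
  if (any(omega < 0) || any(h < 0) || any(N_TC < 0)) {
    stop("effectiveRate: all inputs must be non-negative", call. = FALSE)
  }
  omega / (1 + h * N_TC)
}

#' Right-hand side of the CSC population model
#'
#' Five-compartment balance for cancer stem cells (CSC), two progenitor
#' levels (PC1, PC2), terminal cells (TC) and dead cells (DC). A CSC divides
#' symmetrically (two CSCs) with probability `P_sy` and asymmetrically
#' otherwise; PC1 divisions produce two PC2 cells; both proliferation rates
#' are feedback-limited by the TC count via [effectiveRate()]. All death
#' fluxes accumulate in DC, which is cleared by lysis.
#'
#' @param state Numeric vector `(N_CSC, N_PC1, N_PC2, N_TC, N_DC)`.
#' @param params A [cscParameters()] vector (or any named numeric vector
#'   with the same 13 names).
#' @param t Time; unused (the system is autonomous) but accepted for solver
#'   compatibility.
#' @return Numeric vector of the five derivatives (cells/time), in state
#'   order.
#' @export
cscRhs <- function(state, params, t = 0) {
  if (length(state) != 5L) {
    stop("CSC state must have length 5", call. = FALSE)
  }
  p <- checkNamedNumeric(unclass(params), cscParameterNames, "CSC parameters")
  N_CSC <- state[[1]]; N_PC1 <- state[[2]]; N_PC2 <- state[[3]]
  N_TC <- state[[4]]; N_DC <- state[[5]]
  W_C <- p[["omega_CSC"]] / (1 + p[["h_CSC"]] * N_TC)
  W_P <- p[["omega_PC"]] / (1 + p[["h_PC"]] * N_TC)
  c(p[["P_sy"]] * W_C * N_CSC + p[["gamma_PC"]] * N_PC1 -
      (p[["eta_1"]] + p[["delta_1"]]) * N_CSC,
    (1 - p[["P_sy"]]) * W_C * N_CSC - W_P * N_PC1 - p[["gamma_PC"]] * N_PC1 +
      p[["eta_1"]] * N_CSC - (p[["eta_2"]] + p[["delta_2"]]) * N_PC1,
    2 * W_P * N_PC1 + p[["eta_2"]] * N_PC1 -
      (p[["eta_3"]] + p[["delta_2"]]) * N_PC2,
    p[["eta_3"]] * N_PC2 - p[["delta_3"]] * N_TC,
    p[["delta_1"]] * N_CSC + p[["delta_2"]] * (N_PC1 + N_PC2) +
      p[["delta_3"]] * N_TC - p[["delta_4"]] * N_DC)
}

#' Analytic Jacobian of the CSC population model
#'
#' Partial derivatives of [cscRhs()] with respect to the state, including
#' the dependence of the feedback-limited rates on the terminal-cell count.
#'
#' @inheritParams cscRhs
#' @return 5x5 numeric matrix (1/time) with state names on both dimensions.
#' @export
cscJacobian <- function(state, params) {
  if (length(state) != 5L) {
    stop("CSC state must have length 5", call. = FALSE)
  }
  p <- checkNamedNumeric(unclass(params), cscParameterNames, "CSC parameters")
  N_CSC <- state[[1]]; N_PC1 <- state[[2]]; N_TC <- state[[4]]
  denC <- 1 + p[["h_CSC"]] * N_TC
  denP <- 1 + p[["h_PC"]] * N_TC
  W_C <- p[["omega_CSC"]] / denC
  W_P <- p[["omega_PC"]] / denP
  dWC <- -p[["omega_CSC"]] * p[["h_CSC"]] / denC^2  # dW_C / dN_TC
  dWP <- -p[["omega_PC"]] * p[["h_PC"]] / denP^2
  J <- matrix(0, 5, 5, dimnames = list(cscStateNames, cscStateNames))
  J[1, 1] <- p[["P_sy"]] * W_C - p[["eta_1"]] - p[["delta_1"]]
  J[1, 2] <- p[["gamma_PC"]]
  J[1, 4] <- p[["P_sy"]] * N_CSC * dWC
  J[2, 1] <- (1 - p[["P_sy"]]) * W_C + p[["eta_1"]]
  J[2, 2] <- -(W_P + p[["gamma_PC"]] + p[["eta_2"]] + p[["delta_2"]])
  J[2, 4] <- (1 - p[["P_sy"]]) * N_CSC * dWC - N_PC1 * dWP
  J[3, 2] <- 2 * W_P + p[["eta_2"]]
  J[3, 3] <- -(p[["eta_3"]] + p[["delta_2"]])
  J[3, 4] <- 2 * N_PC1 * dWP
  J[4, 3] <- p[["eta_3"]]
  J[4, 4] <- -p[["delta_3"]]
  J[5, 1] <- p[["delta_1"]]
  J[5, 2] <- p[["delta_2"]]
  J[5, 3] <- p[["delta_2"]]
  J[5, 4] <- p[["delta_3"]]
  J[5, 5] <- -p[["delta_4"]]
  J
}

#' The CSC population model as a model definition
#'
#' @param params Baseline parameters, default [cscParameters()].
#' @param initial_state Initial compartment sizes, default
#'   [cscInitialState()].
#' @return A [modelDefinition()] named `"csc"` with analytic Jacobian.
#' @export
cscModel <- function(params = cscParameters(),
                     initial_state = cscInitialState()) {
  validateCscParameters(params)
  modelDefinition(
    name = "csc",
    state_names = cscStateNames,
    parameter_names = cscParameterNames,
    rhs = cscRhs,
    jacobian = cscJacobian,
    default_parameters = unclass(params),
    default_initial_state = initial_state)
}

# ---------------------------------------------------------------------------
# Fixture models
# ---------------------------------------------------------------------------

#' Small fixture models for testing the workflow
#'
#' Three fully specified toy models exercise the statistical and dynamical
#' machinery on systems with known behavior:
#' \describe{
#'   \item{`logistic`}{`dN/dt = r N (1 - N/K)`; closed-form solution and
#'     known carrying-capacity equilibrium.}
#'   \item{`monotone_linear`}{a relaxation `dy/dt = a1 x1 + a2 x2 + a3 x3 - y`
#'     from `y(0) = 0`, so at every `t > 0` the output is a strictly
#'     monotone transform of the static response `sum(a_j x_j)`; used to
#'     validate the rank-statistics path.}
#'   \item{`bistable_toy`}{`dx/dt = x (p - x)(x - 1)` with equilibria
#'     `{0, p, 1}` for `0 < p < 1`, exchanging stability in `p`.}
#' }
#'
#' @param name One of `"logistic"`, `"monotone_linear"`, `"bistable_toy"`.
#' @return A [modelDefinition()].
#' @export
fixtureModel <- function(name) {
  switch(name,
    logistic = modelDefinition(
      name = "logistic",
      state_names = "N",
      parameter_names = c("r", "K"),
      rhs = function(state, params, t = 0) {
        params[["r"]] * state[[1]] * (1 - state[[1]] / params[["K"]])
      },
      jacobian = function(state, params) {
        matrix(params[["r"]] * (1 - 2 * state[[1]] / params[["K"]]), 1, 1)
      },
      default_parameters = c(r = 1, K = 100),
      default_initial_state = c(N = 1)),
    monotone_linear = modelDefinition(
      name = "monotone_linear",
      state_names = "y",
      parameter_names = c("x1", "x2", "x3", "a1", "a2", "a3"),
      rhs = function(state, params, t = 0) {
        params[["a1"]] * params[["x1"]] + params[["a2"]] * params[["x2"]] +
          params[["a3"]] * params[["x3"]] - state[[1]]
      },
      jacobian = function(state, params) matrix(-1, 1, 1),
      default_parameters = c(x1 = 0.5, x2 = 0.5, x3 = 0.5,
                             a1 = 1, a2 = 0.1, a3 = 0),
      default_initial_state = c(y = 0)),
    bistable_toy = modelDefinition(
      name = "bistable_toy",
      state_names = "x",
      parameter_names = "p",
      rhs = function(state, params, t = 0) {
        x <- state[[1]]
        x * (params[["p"]] - x) * (x - 1)
      },
      jacobian = function(state, params) {
        x <- state[[1]]; p <- params[["p"]]
        matrix((p - x) * (x - 1) - x * (x - 1) + x * (p - x), 1, 1)
      },
      default_parameters = c(p = 0.5),
      default_initial_state = c(x = 0.5)),
    stop("unknown fixture model '", name, "'; available: ",
         "logistic, monotone_linear, bistable_toy", call. = FALSE)
  )
}

#' Look up a model by name
#'
#' Resolves the built-in CSC model or a fixture model; a
#' [modelDefinition()] object is passed through unchanged, which is the
#' plug-in path for user models.
#'
#' @param model Model name (`"csc"`, `"logistic"`, `"monotone_linear"`,
#'   `"bistable_toy"`) or a [modelDefinition()].
#' @return A [modelDefinition()].
#' @export
getModel <- function(model) {
  if (inherits(model, "modelDefinition")) return(model)
  if (!is.character(model) || length(model) != 1L) {
    stop("'model' must be a model name or a modelDefinition", call. = FALSE)
  }
  if (model == "csc") return(cscModel())
  fixtureModel(model)
}
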