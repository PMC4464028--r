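knownConfigKeys <- c("model", "seed", "n", "r", "alpha", "var_pct", "time",
                     "initial_state", "parameters", "sample_parameters",
                     "key_parameters", "combinations", "bifurcation", "plots",
                     "output_dir")

#' Load and validate an experiment configuration
#'
#' Reads a YAML experiment description (model, parameter specs, time grid,
#' sample size, seed, partition level count, significance level, key
#' parameters, plot options) and validates it in one pass, reporting every
#' problem at once. Unknown keys are rejected. `seed` and `n` are
#' mandatory: runs must be reproducible.
#'
#' @param path YAML file path.
#' @return Object of class `experimentConfig`: the validated settings with
#'   all defaults filled in.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  # YAML 1.1 resolves bare y/n/yes/no/on/off keys to booleans, which would
  # swallow the sample-size key 'n'; quote such keys before parsing
  lines <- readLines(path, warn = FALSE)
  lines <- gsub("^(\\s*)(y|n|yes|no|on|off|true|false)(\\s*:)",
                '\\1"\\2"\\3', lines, ignore.case = TRUE)
  raw <- yaml::yaml.load(paste(lines, collapse = "\n"))
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  unknown <- setdiff(names(raw), knownConfigKeys)
  if (length(unknown)) {
    note(paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  model_name <- raw$model %||% note("missing required key 'model'")
  if (is.null(raw$seed)) note("missing required key 'seed' (mandatory for reproducibility)")
  else if (!is.numeric(raw$seed) || raw$seed != round(raw$seed)) {
    note("'seed' must be an integer")
  }
  if (is.null(raw$n)) note("missing required key 'n'")
  else if (!is.numeric(raw$n) || raw$n < 2) note("'n' must be an integer >= 2")
  r <- raw$r %||% 4
  if (!is.numeric(r) || r < 2) note("'r' must be an integer >= 2")
  alpha <- raw$alpha %||% 0.01
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    note("'alpha' must be in (0, 1)")
  }
  if (is.null(raw$time) || !all(c("t_ini", "t_end") %in% names(raw$time))) {
    note("'time' must contain t_ini and t_end")
  }
  var_pct <- raw$var_pct %||% 50
  if (!is.numeric(var_pct) || var_pct < 0) note("'var_pct' must be >= 0")
  scale <- (raw$plots %||% list())$scale %||% "linear"
  if (!scale %in% c("linear", "log")) note("plots$scale must be linear or log")

  if (length(problems)) {
    stop("invalid configuration '", path, "':\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }

  model <- getModel(model_name)
  grid <- timeGrid(raw$time$t_ini, raw$time$t_end,
                   points = raw$time$points %||% 100,
                   times = raw$time$times)

  y0 <- model$default_initial_state
  if (!is.null(raw$initial_state)) {
    bad <- setdiff(names(raw$initial_state), model$state_names)
    if (length(bad)) {
      stop("initial_state name(s) not in model: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    y0[names(raw$initial_state)] <- unlist(raw$initial_state)
  }

  # per-parameter spec overrides on top of model defaults + var_pct
  specs <- list()
  overrides <- raw$parameters %||% list()
  bad <- setdiff(names(overrides), model$parameter_names)
  if (length(bad)) {
    stop("parameters section names unknown parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sampled <- raw$sample_parameters %||% model$parameter_names
  bad <- setdiff(sampled, model$parameter_names)
  if (length(bad)) {
    stop("sample_parameters names unknown parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (nm in sampled) {
    o <- overrides[[nm]]
    specs[[nm]] <- if (!is.null(o) && !is.null(o$min)) {
      parameterSpec(nm, baseline = o$baseline, min = o$min, max = o$max,
                    dist = o$dist %||% "uniform", sd = o$sd)
    } else {
      parameterSpec(nm,
                    baseline = (o$baseline %||% model$default_parameters[[nm]]),
                    var_pct = o$var_pct %||% var_pct,
                    dist = o$dist %||% "uniform", sd = o$sd,
                    nonnegative = TRUE)
    }
  }
  # the CSC model's P_sy is a probability: full range by convention unless
  # the config overrides it
  if (model$name == "csc" && is.null(overrides[["P_sy"]]) &&
      "P_sy" %in% sampled) {
    specs[["P_sy"]] <- parameterSpec("P_sy", baseline = 0.5, min = 0, max = 1)
  }

  structure(list(model = model,
                 seed = as.integer(raw$seed),
                 n = as.integer(raw$n),
                 r = as.integer(r),
                 alpha = alpha,
                 grid = grid,
                 initial_state = y0,
                 specs = unname(specs),
                 key_parameters = raw$key_parameters %||% character(0),
                 combinations = raw$combinations %||% character(0),
                 bifurcation = raw$bifurcation,
                 plot_scale = scale,
                 plot_formats = (raw$plots %||% list())$formats %||% "png",
                 output_dir = raw$output_dir %||% "results"),
            class = "experimentConfig")
}

#' Tumor outcome classification at the end of an ensemble
#'
#' A sample counts as an extinction (unsustainable tumor growth) when its
#' final value of `variable` lies below the band; by default the band is
#' the variable's shared initial value, i.e. a tumor whose CSC pool has
#' not grown over the simulated horizon.
#'
#' @param Y An [simulateEnsemble()] output.
#' @param variable Variable inspected (default `"N_CSC"` when present,
#'   else the first variable).
#' @param band Extinction band; default the variable's value at the first
#'   grid time of the first successful run.
#' @return Logical vector (length n): `TRUE` = extinct; `NA` for failed
#'   runs. Attribute `"band"` records the band used.
#' @export
extinctAtEnd <- function(Y, variable = NULL, band = NULL) {
  stopifnot(inherits(Y, "ensembleOutput"))
  if (is.null(variable)) {
    variable <- if ("N_CSC" %in% Y$variable_names) "N_CSC"
                else Y$variable_names[1]
  }
  if (is.null(band)) {
    i0 <- which(Y$success)[1]
    band <- as.numeric(Y$values[i0, 1, variable])
  }
  fin <- Y$values[, dim(Y$values)[2], variable]
  out <- fin < band
  out[!Y$success] <- NA
  attr(out, "band") <- band
  out
}

#' Run the full exploration workflow
#'
#' Executes the three phases end to end: LHS sampling, ensemble
#' simulation, time-course PRCC with significance tests, color-coded
#' trace/scatter visualization for each key parameter (and each declared
#' parameter combination), and a bifurcation scan when configured. All
#' artifacts (design CSV, ensemble container, PRCC tables, figures with
#' JSON sidecars, diagram CSV, run manifest) are written under the
#' configured output directory.
#'
#' @param config An [loadConfig()] result (or a path to a YAML config).
#' @param output_dir Overrides the config's output directory.
#' @return Invisibly, a list with the in-memory stage results (`design`,
#'   `ensemble`, `sensitivity`, `partitions`, `diagrams`, `manifest`).
#' @export
runWorkflow <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- loadConfig(config)
  stopifnot(inherits(config, "experimentConfig"))
  out <- output_dir %||% config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  timings <- list()
  tick <- function(stage, t0) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  # phase 1.1: sampling
  t0 <- Sys.time()
  design <- lhsSample(config$specs, n = config$n, seed = config$seed)
  writeDesign(design, file.path(out, "design.csv"))
  tick("sample", t0)

  # phase 1.2: ensemble simulation
  t0 <- Sys.time()
  Y <- simulateEnsemble(config$model, design, y0 = config$initial_state,
                        grid = config$grid)
  writeEnsemble(Y, file.path(out, "ensemble"))
  tick("simulate", t0)

  Yrep <- if (config$model$name == "csc") collapseProgenitors(Y) else Y

  # phase 2: key parameter identification
  t0 <- Sys.time()
  sens <- prccOverTime(design, Yrep, alpha = config$alpha)
  writeSensitivity(sens, file.path(out, "sensitivity"))
  for (v in sens$variables) {
    saveFigure(plotPrcc(sens, v), file.path(out, paste0("prcc_", v)),
               formats = config$plot_formats)
  }
  tick("prcc", t0)

  # phase 3.1-3.2: level partitions, colored traces and scatters
  t0 <- Sys.time()
  keys <- config$key_parameters
  combos <- config$combinations
  partitions <- list()
  fin <- outputsAtTime(Yrep, config$grid$t_end)
  for (key in c(keys, combos)) {
    vals <- if (key %in% colnames(design$matrix)) design$matrix[[key]]
            else combineColumns(key, design)
    part <- partitionRange(min(vals), max(vals), r = config$r,
                           parameter = key)
    partitions[[key]] <- part
    safe <- gsub("[^A-Za-z0-9_.-]", "_", key)
    for (v in Yrep$variable_names) {
      saveFigure(coloredTraces(Yrep, vals, part, v,
                               scale = config$plot_scale),
                 file.path(out, paste0("traces_", safe, "_", v)),
                 formats = config$plot_formats)
      saveFigure(coloredScatter(fin, vals, part, v, success = Yrep$success,
                                scale = config$plot_scale),
                 file.path(out, paste0("scatter_", safe, "_", v)),
                 formats = config$plot_formats)
    }
  }
  tick("levels", t0)

  # phase 3.3: bifurcation scan
  diagrams <- list()
  if (!is.null(config$bifurcation)) {
    t0 <- Sys.time()
    b <- config$bifurcation
    diag <- scanParameter(config$model, name = b$parameter,
                          range = as.numeric(b$range),
                          n_points = b$points %||% 51L,
                          y0 = config$initial_state)
    diagrams[[b$parameter]] <- diag
    writeDiagram(diag, file.path(out, paste0("diagram_", b$parameter, ".csv")))
    saveFigure(plotDiagram(diag),
               file.path(out, paste0("diagram_", b$parameter)),
               formats = config$plot_formats)
    tick("bifurcate", t0)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cscsense")),
    model = config$model$name,
    seed = config$seed, n = config$n, r = config$r, alpha = config$alpha,
    t_ini = config$grid$t_ini, t_end = config$grid$t_end,
    n_failures = sum(!Y$success),
    timings_sec = timings,
    total_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(design = design, ensemble = Y, sensitivity = sens,
                 partitions = partitions, diagrams = diagrams,
                 manifest = manifest))
}
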