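#' Relative-risk parameter sets
#'
#' A `brisk_params` object holds the component relative-risk tables of the
#' multiplicative model: a family-history category table with prevalence
#' weights, density parameters (continuous log-linear or categorical with
#' prevalence weights), and per-menopause-stratum BMI log-linear slopes.
#' Categorical components are *centered*: raw RRs are divided by the
#' prevalence-weighted mean so the population-average relative risk is 1.
#'
#' @param family_history data.frame with columns `n_fdr`, `age_dx`, `n_sdr`
#'   (band labels, `"any"` for a wildcard), `rr` (raw relative risk > 0) and
#'   `weight` (category prevalence; must sum to 1).
#' @param density list with `mode` (`"continuous"` or `"categorical"`),
#'   `continuous` (list with `slope` per percent and `reference` percent) and
#'   `categorical` (data.frame with `label`, `rr`, `weight`).
#' @param bmi list with elements `pre` and `post`, each a list with `slope`
#'   (log-RR per kg/m^2) and `reference` (kg/m^2).
#' @param lifetime_max_age horizon age for remaining lifetime risk (years).
#' @param disabled character vector of component names (`"family_history"`,
#'   `"density"`, `"bmi"`, `"prs"`) that contribute a factor of 1.
#' @return object of class `brisk_params`.
#' @seealso [read_params()], [default_params()], [centering_constant()]
#' @export
rr_parameters <- function(family_history, density, bmi,
                          lifetime_max_age = 85, disabled = character()) {
  stopifnot(is.data.frame(family_history))
  req <- c("n_fdr", "age_dx", "n_sdr", "rr", "weight")
  miss <- setdiff(req, names(family_history))
  if (length(miss) > 0)
    stop("family_history table missing column(s): ", paste(miss, collapse = ", "))
  if (any(family_history$rr <= 0))
    stop("family_history raw RRs must be > 0")
  .check_weights(family_history$weight, "family_history")

  if (!is.list(density) || is.null(density$mode) ||
      !density$mode %in% c("continuous", "categorical"))
    stop("density$mode must be 'continuous' or 'categorical'")
  if (density$mode == "continuous") {
    cc <- density$continuous
    if (is.null(cc$slope) || is.null(cc$reference))
      stop("continuous density requires 'slope' and 'reference'")
  } else {
    ct <- density$categorical
    if (is.null(ct) || !all(c("rr", "weight") %in% names(ct)))
      stop("categorical density requires a table with 'rr' and 'weight'")
    if (any(ct$rr <= 0)) stop("density raw RRs must be > 0")
    .check_weights(ct$weight, "density")
  }

  for (st in c("pre", "post")) {
    if (is.null(bmi[[st]]) || is.null(bmi[[st]]$slope) || is.null(bmi[[st]]$reference))
      stop("bmi parameters missing for stratum '", st, "'")
  }

  bad <- setdiff(disabled, c("family_history", "density", "bmi", "prs"))
  if (length(bad) > 0) stop("unknown component(s) in 'disabled': ",
                            paste(bad, collapse = ", "))

  structure(list(family_history = family_history, density = density, bmi = bmi,
                 lifetime_max_age = lifetime_max_age, disabled = disabled),
            class = "brisk_params")
}

.check_weights <- function(w, what) {
  if (any(w < 0)) stop(what, " prevalence weights must be >= 0")
  if (abs(sum(w) - 1) > 1e-9)
    stop(what, " prevalence weights must sum to 1 (got ", format(sum(w)), ")")
  invisible(TRUE)
}

#' Centering constant of a categorical component
#'
#' The prevalence-weighted mean of the raw relative risks, i.e. the divisor
#' that makes the centered component average 1 in the population.
#'
#' @param params a `brisk_params` object.
#' @param component `"family_history"` or `"density"` (categorical mode only).
#' @return positive scalar.
#' @export
centering_constant <- function(params, component = c("family_history", "density")) {
  component <- match.arg(component)
  if (component == "family_history") {
    tab <- params$family_history
  } else {
    if (params$density$mode != "categorical")
      stop("density centering constant is defined for categorical mode only")
    tab <- params$density$categorical
  }
  sum(tab$weight * tab$rr)
}

#' Read a parameter set from a YAML configuration file
#'
#' Validates the configuration on load and raises errors that name the
#' offending key.
#'
#' @param path path to a YAML file following the schema of the packaged
#'   `default_params.yaml`.
#' @return a `brisk_params` object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (key in c("family_history", "density", "bmi")) {
    if (is.null(cfg[[key]])) stop("parameter file ", path, ": missing section '", key, "'")
  }
  fh <- cfg$family_history$categories
  if (is.null(fh)) stop("parameter file ", path, ": missing 'family_history: categories'")
  fh <- do.call(rbind, lapply(fh, function(r) {
    for (k in c("n_fdr", "age_dx", "n_sdr", "rr", "weight"))
      if (is.null(r[[k]])) stop("parameter file ", path,
                                ": family_history category missing field '", k, "'")
    data.frame(n_fdr = as.character(r$n_fdr), age_dx = as.character(r$age_dx),
               n_sdr = as.character(r$n_sdr), rr = as.numeric(r$rr),
               weight = as.numeric(r$weight), stringsAsFactors = FALSE)
  }))
  dens <- cfg$density
  if (!is.null(dens$categorical)) {
    dens$categorical <- do.call(rbind, lapply(dens$categorical, function(r)
      data.frame(label = as.character(r$label), rr = as.numeric(r$rr),
                 weight = as.numeric(r$weight), stringsAsFactors = FALSE)))
  }
  max_age <- if (!is.null(cfg$model$lifetime_max_age)) cfg$model$lifetime_max_age else 85
  disabled <- if (!is.null(cfg$model$disabled)) as.character(cfg$model$disabled) else character()
  rr_parameters(fh, dens, cfg$bmi, lifetime_max_age = max_age, disabled = disabled)
}

#' Packaged default parameter set
#'
#' Loads the shipped illustrative parameter tables.  These defaults are
#' documented approximations (family-history RRs in the flavor of the large
#' pooled familial-risk analyses, plausible density and BMI slopes); they are
#' configuration, not canonical fitted values.
#'
#' @return a `brisk_params` object.
#' @export
default_params <- function() {
  read_params(system.file("extdata", "default_params.yaml", package = "brisk",
                          mustWork = TRUE))
}

#' @export
print.brisk_params <- function(x, ...) {
  cat("Relative-risk parameter set\n")
  cat("  family history: ", nrow(x$family_history), " categories, c_fh = ",
      format(centering_constant(x, "family_history"), digits = 6), "\n", sep = "")
  cat("  density mode:   ", x$density$mode, "\n", sep = "")
  cat("  BMI slopes:     pre ", x$bmi$pre$slope, ", post ", x$bmi$post$slope,
      " per kg/m^2\n", sep = "")
  cat("  lifetime horizon age: ", x$lifetime_max_age, "\n", sep = "")
  if (length(x$disabled) > 0)
    cat("  disabled components: ", paste(x$disabled, collapse = ", "), "\n", sep = "")
  invisible(x)
}
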