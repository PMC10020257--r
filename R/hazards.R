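#' Age-specific hazard tables
#'
#' A `brisk_hazards` object holds piecewise-constant annual rates: the
#' population breast-cancer incidence rate `h1(t)` and the competing
#' (non-breast-cancer) mortality rate `h2(t)` per woman-year, for contiguous
#' integer ages.
#'
#' @param age integer vector of contiguous ages (years).
#' @param incidence breast-cancer incidence rate per woman-year, same length.
#' @param mortality competing mortality rate per woman-year, same length.
#' @return object of class `brisk_hazards`.
#' @export
hazard_table <- function(age, incidence, mortality) {
  age <- as.integer(age)
  if (length(age) == 0) stop("empty hazard table")
  if (any(diff(age) != 1L)) stop("hazard table ages must be contiguous integers")
  if (length(incidence) != length(age) || length(mortality) != length(age))
    stop("incidence/mortality must match the age vector in length")
  if (any(!is.finite(incidence)) || any(incidence < 0))
    stop("incidence rates must be finite and >= 0")
  if (any(!is.finite(mortality)) || any(mortality < 0))
    stop("mortality rates must be finite and >= 0")
  structure(list(age = age, incidence = as.numeric(incidence),
                 mortality = as.numeric(mortality),
                 age_min = age[1], age_max = age[length(age)]),
            class = "brisk_hazards")
}

#' Read a hazard table from CSV
#'
#' Expects header `age,incidence,mortality`, one row per year of age, rates
#' per woman-year.
#'
#' @param path CSV file path.
#' @return a `brisk_hazards` object.
#' @export
read_hazards <- function(path) {
  if (!file.exists(path)) stop("hazard file not found: ", path)
  d <- utils::read.csv(path)
  miss <- setdiff(c("age", "incidence", "mortality"), names(d))
  if (length(miss) > 0)
    stop("hazard file ", path, " missing column(s): ", paste(miss, collapse = ", "))
  d <- d[order(d$age), ]
  hazard_table(d$age, d$incidence, d$mortality)
}

#' Packaged synthetic hazard table
#'
#' Smooth parametric rates (logistic-in-age incidence, Gompertz competing
#' mortality) chosen to resemble contemporary US female rates in overall
#' shape and magnitude; synthetic and illustrative, not a published life
#' table.  Covers ages 20-89.
#'
#' @return a `brisk_hazards` object.
#' @export
default_hazards <- function() {
  read_hazards(system.file("extdata", "hazards_synthetic_us.csv",
                           package = "brisk", mustWork = TRUE))
}

# rate lookup for integer ages; errors on coverage gaps
.hazard_at <- function(hz, ages) {
  idx <- ages - hz$age_min + 1L
  if (any(idx < 1L | idx > length(hz$age)))
    stop("hazard table covers ages ", hz$age_min, "-", hz$age_max,
         "; requested age out of range")
  list(h1 = hz$incidence[idx], h2 = hz$mortality[idx])
}

#' @export
print.brisk_hazards <- function(x, ...) {
  cat("Hazard table: ages ", x$age_min, "-", x$age_max,
      " (rates per woman-year)\n", sep = "")
  invisible(x)
}
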