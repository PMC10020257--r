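#' Packaged published count tables
#'
#' The package ships, as plain-text CSV, the cross-classification count
#' matrices and per-age-band calibration columns of a published validation
#' of the model on nested case-control data: reclassification tables for
#' 5-year risk (new model vs a clinical 5-year model; overall and by ER/PR
#' subtype) and for remaining lifetime risk (vs a pedigree-based clinical
#' model; overall, by ER/PR subtype and by stage), and the calibration
#' expected/observed columns.  Every matrix is validated against its
#' embedded row and column totals at load time.
#'
#' Available names: `"table4"` (5-year reclassification, cases + controls),
#' `"table5"`/`"table6"` (5-year, ER+/PR+ and ER-/PR- cases),
#' `"table7"` (lifetime, cases + controls), `"table8"`/`"table9"` (lifetime
#' by ER/PR), `"table10"`/`"table11"` (lifetime by stage 1 / stage 2+),
#' `"table3_5year"` and `"table3_lifetime"` (calibration columns).
#'
#' @return `brisk_fixtures()`: character vector of fixture names.
#' @export
brisk_fixtures <- function() {
  c("table3_5year", "table3_lifetime", paste0("table", 4:11))
}

.fixture_scheme <- function(name) {
  if (name %in% c("table4", "table5", "table6")) scheme_5year() else scheme_lifetime()
}

.fixture_models <- function(name) {
  if (name %in% c("table4", "table5", "table6"))
    c(old = "gail_5year", new = "brisk_5year")
  else c(old = "ibis_lifetime", new = "brisk_lifetime")
}

#' Load a packaged fixture
#'
#' Reclassification fixtures return a `brisk_reclass` object; calibration
#' fixtures return the per-band data.frame (with the `Total` row removed but
#' checked).  A mismatch between cell counts and the embedded totals is a
#' packaging error and fails loudly.
#'
#' @param name one of [brisk_fixtures()].
#' @return a `brisk_reclass` object or a data.frame.
#' @export
load_fixture <- function(name) {
  if (!name %in% brisk_fixtures())
    stop("unknown fixture '", name, "'; available: ",
         paste(brisk_fixtures(), collapse = ", "))
  path <- system.file("extdata", "fixtures", paste0(name, ".csv"),
                      package = "brisk", mustWork = TRUE)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)

  if (startsWith(name, "table3")) {
    tot <- d[d$age_band == "Total", ]
    body <- d[d$age_band != "Total", ]
    for (cl in names(d)[-1]) {
      tolerance <- if (cl == "n") 0 else 0.02   # printed totals are rounded
      if (abs(sum(body[[cl]]) - tot[[cl]]) > tolerance)
        stop("fixture ", name, ": column '", cl, "' sums to ",
             sum(body[[cl]]), " but the printed total is ", tot[[cl]])
    }
    attr(body, "printed_totals") <- tot
    return(body)
  }

  scheme <- .fixture_scheme(name)
  k <- length(scheme$labels)
  cols <- names(d)[3:(2 + k)]
  arms <- list()
  for (arm in unique(d$arm)) {
    a <- d[d$arm == arm, ]
    tot <- a[a$old_category == "Total", ]
    body <- a[a$old_category != "Total", ]
    m <- as.matrix(body[, cols])
    if (any(rowSums(m) != body$total))
      stop("fixture ", name, " (", arm, "): row totals do not match")
    if (any(colSums(m) != as.integer(tot[, cols])) ||
        sum(m) != tot$total)
      stop("fixture ", name, " (", arm, "): column totals do not match")
    arms[[arm]] <- m
  }
  models <- .fixture_models(name)
  reclass_from_counts(arms$case, arms$control, scheme,
                      old_name = models[["old"]], new_name = models[["new"]])
}

#' Calibration summary from a packaged calibration fixture
#'
#' Sums the per-band expected and observed columns of a calibration fixture
#' and returns the E/O ratio with its log-scale confidence interval.
#'
#' @param name `"table3_5year"` or `"table3_lifetime"`.
#' @param model column prefix: `"brisk"`, `"gail"` (5-year) or `"ibis"`
#'   (lifetime).
#' @return a `brisk_calibration` object.
#' @export
calibration_from_fixture <- function(name, model = "brisk") {
  d <- load_fixture(name)
  ec <- paste0(model, "_expected"); oc <- paste0(model, "_observed")
  if (!ec %in% names(d)) stop("fixture ", name, " has no model '", model, "'")
  eo_result(d[[ec]], d[[oc]], n = d$n, labels = d$age_band)
}
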