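#' Risk-factor profiles
#'
#' A cohort is an ordinary data.frame with one row per woman and the columns
#' below.  [risk_profile()] builds a one-row cohort for interactive use.
#'
#' Columns: `age` (years, within the hazard table's coverage), `n_fdr`
#' (affected first-degree relatives), `age_youngest_fdr` (years at diagnosis
#' of the youngest affected first-degree relative; `NA` when `n_fdr = 0`),
#' `n_sdr` (affected second-degree relatives), `percent_density` (0-100,
#' optional), `density_category` (1-based index into the categorical density
#' table, optional), `bmi` (kg/m^2), `menopausal_status` (`"pre"`/`"post"`),
#' `prs` (positive, population mean about 1; optional).
#'
#' @param age,n_fdr,age_youngest_fdr,n_sdr,percent_density,density_category,bmi,menopausal_status,prs
#'   see above.
#' @return one-row data.frame.
#' @export
risk_profile <- function(age, n_fdr = 0, age_youngest_fdr = NA_real_, n_sdr = 0,
                         percent_density = NA_real_, density_category = NA_integer_,
                         bmi = NA_real_, menopausal_status = "post", prs = NA_real_) {
  data.frame(age = age, n_fdr = n_fdr, age_youngest_fdr = age_youngest_fdr,
             n_sdr = n_sdr, percent_density = percent_density,
             density_category = density_category, bmi = bmi,
             menopausal_status = menopausal_status, prs = prs,
             stringsAsFactors = FALSE)
}

# Band label DSL used by the family-history table:
#   "any"  matches everything (including NA values)
#   "<X"   value < X          ">=X"  value >= X
#   "N+"   value >= N         "N"    value == N
.band_match <- function(value, label) {
  if (label == "any") return(rep(TRUE, length(value)))
  out <- rep(FALSE, length(value))
  ok <- !is.na(value)
  if (startsWith(label, "<")) {
    out[ok] <- value[ok] < as.numeric(substring(label, 2))
  } else if (startsWith(label, ">=")) {
    out[ok] <- value[ok] >= as.numeric(substring(label, 3))
  } else if (endsWith(label, "+")) {
    out[ok] <- value[ok] >= as.numeric(substring(label, 1, nchar(label) - 1))
  } else {
    out[ok] <- value[ok] == as.numeric(label)
  }
  out
}

#' Centered family-history relative risk
#'
#' Looks up the raw relative risk for each woman's family-history category
#' (counts of affected first- and second-degree relatives and age at
#' diagnosis of the youngest affected first-degree relative) and divides by
#' the centering constant so the prevalence-weighted population mean is 1.
#'
#' @param profile cohort data.frame (see [risk_profile()]).
#' @param params a `brisk_params` object.
#' @return numeric vector of centered relative risks.
#' @export
family_history_rr <- function(profile, params) {
  tab <- params$family_history
  n <- nrow(profile)
  n_fdr <- if (!is.null(profile$n_fdr)) profile$n_fdr else rep(0, n)
  n_sdr <- if (!is.null(profile$n_sdr)) profile$n_sdr else rep(0, n)
  age_dx <- if (!is.null(profile$age_youngest_fdr)) profile$age_youngest_fdr
            else rep(NA_real_, n)
  raw <- rep(NA_real_, n)
  for (i in seq_len(nrow(tab))) {
    hit <- .band_match(n_fdr, tab$n_fdr[i]) &
           .band_match(age_dx, tab$age_dx[i]) &
           .band_match(n_sdr, tab$n_sdr[i]) & is.na(raw)
    raw[hit] <- tab$rr[i]
  }
  if (anyNA(raw)) {
    bad <- which(is.na(raw))[1]
    stop("family-history table does not cover band (n_fdr=", n_fdr[bad],
         ", age_dx=", age_dx[bad], ", n_sdr=", n_sdr[bad], ") at row ", bad)
  }
  raw / centering_constant(params, "family_history")
}

#' Mammographic density relative risk
#'
#' In continuous mode, `exp(slope * (percent_density - reference))`; in
#' categorical mode, the raw category RR divided by the prevalence-weighted
#' centering constant.
#'
#' @inheritParams family_history_rr
#' @return numeric vector of relative risks.
#' @export
density_rr <- function(profile, params) {
  dens <- params$density
  if (dens$mode == "continuous") {
    pd <- profile$percent_density
    if (is.null(pd) || anyNA(pd))
      stop("percent_density required (continuous density mode) but absent",
           if (!is.null(pd)) paste0(" at row ", which(is.na(pd))[1]) else "")
    if (any(pd < 0 | pd > 100)) stop("percent_density must be in [0, 100]")
    exp(dens$continuous$slope * (pd - dens$continuous$reference))
  } else {
    ct <- dens$categorical
    cat_idx <- profile$density_category
    if (is.null(cat_idx) || anyNA(cat_idx))
      stop("density_category required (categorical density mode) but absent",
           if (!is.null(cat_idx)) paste0(" at row ", which(is.na(cat_idx))[1]) else "")
    if (any(cat_idx < 1 | cat_idx > nrow(ct)))
      stop("density_category out of range 1-", nrow(ct))
    ct$rr[cat_idx] / centering_constant(params, "density")
  }
}

#' Body-mass-index relative risk
#'
#' Log-linear in BMI with separate slopes for pre- and postmenopausal women:
#' `exp(slope_stratum * (bmi - reference_stratum))`.
#'
#' @inheritParams family_history_rr
#' @return numeric vector of relative risks.
#' @export
bmi_rr <- function(profile, params) {
  st <- profile$menopausal_status
  if (is.null(st) || anyNA(st) || !all(st %in% c("pre", "post")))
    stop("menopausal_status must be 'pre' or 'post' for every row")
  if (is.null(profile$bmi) || anyNA(profile$bmi))
    stop("bmi required but absent")
  slope <- ifelse(st == "post", params$bmi$post$slope, params$bmi$pre$slope)
  ref   <- ifelse(st == "post", params$bmi$post$reference, params$bmi$pre$reference)
  exp(slope * (profile$bmi - ref))
}

#' Combined multiplicative relative risk
#'
#' Product of component relative risks; order-invariant.  Components may be
#' passed as several vectors (recycled) or a single list of vectors.
#'
#' @param ... positive numeric vectors, or one list of them.
#' @return numeric vector.
#' @export
combined_rr <- function(...) {
  comps <- list(...)
  if (length(comps) == 1 && is.list(comps[[1]]) && !is.data.frame(comps[[1]]))
    comps <- comps[[1]]
  if (length(comps) == 0) stop("no components supplied")
  for (x in comps) {
    if (any(!is.finite(x)) || any(x <= 0))
      stop("all relative-risk components must be finite and > 0")
  }
  Reduce(`*`, comps)
}

#' Absolute risk under competing mortality
#'
#' Projects a combined relative risk `rr` applied to the baseline incidence
#' onto the cumulative probability of breast cancer over `horizon` whole
#' years from `age`, with piecewise-constant annual hazards and competing
#' mortality.  Within each year the cause-specific probability is the exact
#' closed form for constant competing rates:
#' `[rr*h1/(rr*h1+h2)] * (1 - exp(-(rr*h1+h2)))`, discounted by all-cause
#' survival to the start of the year.
#'
#' @param age starting age(s), years; real values are floored to index the
#'   hazard table.
#' @param horizon projection length in whole years (scalar, >= 0).
#' @param rr combined relative risk(s), > 0; recycled against `age`.
#' @param hazards a `brisk_hazards` object covering `[age, age+horizon-1]`.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
absolute_risk <- function(age, horizon, rr, hazards) {
  if (length(horizon) != 1 || !is.finite(horizon) || horizon < 0)
    stop("horizon must be a single nonnegative number of years")
  if (abs(horizon - round(horizon)) > 1e-8)
    stop("horizon must be a whole number of years")
  horizon <- as.integer(round(horizon))
  if (any(!is.finite(rr)) || any(rr <= 0)) stop("rr must be finite and > 0")
  n <- max(length(age), length(rr))
  age <- rep_len(as.integer(floor(age)), n)
  rr <- rep_len(rr, n)
  if (horizon == 0) return(numeric(n) + 0)
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- .hazard_at(hazards, age[i]:(age[i] + horizon - 1L))
    lam <- rr[i] * h$h1 + h$h2
    frac <- ifelse(lam > 0, rr[i] * h$h1 / lam, 0)
    surv <- c(1, exp(-cumsum(lam))[-horizon])
    out[i] <- sum(frac * (1 - exp(-lam)) * surv)
  }
  out
}

#' Remaining lifetime risk
#'
#' Absolute risk from the current age to a horizon age (default 85),
#' accounting for competing mortality.
#'
#' @inheritParams absolute_risk
#' @param max_age horizon age, years.
#' @return numeric vector of probabilities.
#' @export
remaining_lifetime_risk <- function(age, rr, hazards, max_age = 85) {
  n <- max(length(age), length(rr))
  age_i <- rep_len(as.integer(floor(age)), n)
  rr <- rep_len(rr, n)
  if (any(age_i > max_age)) stop("age exceeds max_age (", max_age, ")")
  out <- numeric(n)
  for (tau in unique(max_age - age_i)) {
    sel <- (max_age - age_i) == tau
    out[sel] <- absolute_risk(age_i[sel], tau, rr[sel], hazards)
  }
  out
}

#' Validate a cohort of risk-factor profiles
#'
#' @param cohort cohort data.frame.
#' @param params a `brisk_params` object.
#' @param hazards a `brisk_hazards` object.
#' @return character vector of row-indexed problem descriptions (empty when
#'   the cohort is valid).
#' @export
validate_profiles <- function(cohort, params, hazards) {
  probs <- character()
  add <- function(rows, msg) {
    if (length(rows) > 0)
      probs <<- c(probs, paste0("row ", rows, ": ", msg))
  }
  n <- nrow(cohort)
  if (is.null(cohort$age)) return("column 'age' is required")
  add(which(is.na(cohort$age) | cohort$age < hazards$age_min |
              cohort$age > hazards$age_max),
      paste0("age outside hazard coverage ", hazards$age_min, "-", hazards$age_max))
  if (!"family_history" %in% params$disabled) {
    nf <- if (!is.null(cohort$n_fdr)) cohort$n_fdr else rep(0, n)
    add(which(!is.na(nf) & nf < 0), "n_fdr must be >= 0")
    if (!is.null(cohort$age_youngest_fdr))
      add(which(!is.na(nf) & nf == 0 & !is.na(cohort$age_youngest_fdr)),
          "age_youngest_fdr present with n_fdr = 0")
  }
  if (!"density" %in% params$disabled) {
    if (params$density$mode == "continuous") {
      pd <- cohort$percent_density
      if (is.null(pd)) probs <- c(probs, "column 'percent_density' is required")
      else add(which(is.na(pd) | pd < 0 | pd > 100),
               "percent_density missing or outside [0, 100]")
    } else {
      dc <- cohort$density_category
      if (is.null(dc)) probs <- c(probs, "column 'density_category' is required")
      else add(which(is.na(dc) | dc < 1 | dc > nrow(params$density$categorical)),
               "density_category missing or out of range")
    }
  }
  if (!"bmi" %in% params$disabled) {
    if (is.null(cohort$bmi)) probs <- c(probs, "column 'bmi' is required")
    else add(which(is.na(cohort$bmi) | cohort$bmi <= 10 | cohort$bmi >= 70),
             "bmi missing or outside (10, 70) kg/m^2")
    st <- cohort$menopausal_status
    if (is.null(st)) probs <- c(probs, "column 'menopausal_status' is required")
    else add(which(is.na(st) | !st %in% c("pre", "post")),
             "menopausal_status must be 'pre' or 'post'")
  }
  if (!is.null(cohort$prs) && !"prs" %in% params$disabled)
    add(which(!is.na(cohort$prs) & cohort$prs <= 0), "prs must be > 0")
  probs
}

#' Score a cohort: combined relative risk and absolute risk projections
#'
#' Computes each woman's combined relative risk as the product of the enabled
#' centered components (family history, density, BMI, and the `prs` column if
#' present; disabled or absent components contribute 1), then projects it to
#' 5-year and remaining lifetime absolute risk.
#'
#' @param cohort cohort data.frame (see [risk_profile()] for columns).
#' @param params a `brisk_params` object.
#' @param hazards a `brisk_hazards` object.
#' @param skip_invalid drop invalid rows with a warning instead of aborting.
#' @return the cohort with columns `combined_rr`, `score_brisk5` and
#'   `score_brisklt` appended; row order preserved.
#' @export
score_cohort <- function(cohort, params = default_params(),
                         hazards = default_hazards(), skip_invalid = FALSE) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0) {
    cohort$combined_rr <- numeric(0)
    cohort$score_brisk5 <- numeric(0)
    cohort$score_brisklt <- numeric(0)
    return(cohort)
  }
  probs <- validate_profiles(cohort, params, hazards)
  if (length(probs) > 0) {
    if (!skip_invalid)
      stop("invalid cohort rows:\n", paste(utils::head(probs, 20), collapse = "\n"),
           if (length(probs) > 20) paste0("\n... and ", length(probs) - 20, " more"))
    bad <- unique(as.integer(sub("^row ([0-9]+):.*$", "\\1",
                                 grep("^row ", probs, value = TRUE))))
    warning("dropping ", length(bad), " invalid row(s)")
    cohort <- cohort[setdiff(seq_len(nrow(cohort)), bad), , drop = FALSE]
    if (nrow(cohort) == 0) stop("no valid rows remain after skipping")
  }
  comps <- list()
  if (!"family_history" %in% params$disabled)
    comps$fh <- family_history_rr(cohort, params)
  if (!"density" %in% params$disabled)
    comps$density <- density_rr(cohort, params)
  if (!"bmi" %in% params$disabled)
    comps$bmi <- bmi_rr(cohort, params)
  if (!is.null(cohort$prs) && !"prs" %in% params$disabled) {
    prs <- cohort$prs
    prs[is.na(prs)] <- 1
    comps$prs <- prs
  }
  rr <- if (length(comps) > 0) combined_rr(comps) else rep(1, nrow(cohort))
  cohort$combined_rr <- rr
  cohort$score_brisk5 <- absolute_risk(cohort$age, 5, rr, hazards)
  cohort$score_brisklt <- remaining_lifetime_risk(cohort$age, rr, hazards,
                                                  max_age = params$lifetime_max_age)
  cohort
}
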