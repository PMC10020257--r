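#' Clinical risk category schemes
#'
#' A category scheme is an ordered set of probability cut points defining
#' left-closed, right-open intervals.  [scheme_5year()] gives the 5-year-risk
#' categories used around the 1.67% chemoprevention and 3% endocrine-therapy
#' thresholds; [scheme_lifetime()] gives the lifetime-risk categories around
#' the 20% and 25% enhanced-screening thresholds.
#'
#' @param edges strictly increasing interior cut points, probabilities.
#' @param labels optional labels, one more than `length(edges)`.
#' @return object of class `brisk_scheme`.
#' @export
category_scheme <- function(edges, labels = NULL) {
  if (length(edges) < 1 || any(diff(edges) <= 0))
    stop("edges must be strictly increasing")
  if (any(edges < 0 | edges > 1)) stop("edges must be probabilities")
  if (is.null(labels)) {
    pct <- function(x) sub("\\.?0+$", "", format(100 * x))
    labels <- c(paste0("<", pct(edges[1]), "%"),
                if (length(edges) > 1)
                  paste0(">=", pct(edges[-length(edges)]), " to <", pct(edges[-1]), "%"),
                paste0(">=", pct(edges[length(edges)]), "%"))
  }
  if (length(labels) != length(edges) + 1)
    stop("need length(edges) + 1 labels")
  structure(list(edges = edges, labels = labels), class = "brisk_scheme")
}

#' @rdname category_scheme
#' @export
scheme_5year <- function() {
  category_scheme(c(0.01, 0.0167, 0.03),
                  c("<1%", ">=1 to <1.67%", ">=1.67 to <3%", ">=3%"))
}

#' @rdname category_scheme
#' @export
scheme_lifetime <- function() {
  category_scheme(c(0.06, 0.12, 0.20, 0.25),
                  c("<6%", ">=6 to <12%", ">=12 to <20%", ">=20 to <25%", ">=25%"))
}

#' Assign risks to categories
#'
#' Intervals are left-closed: a risk exactly on a cut point belongs to the
#' upper category.
#'
#' @param risk numeric vector of probabilities in `[0, 1]`.
#' @param scheme a `brisk_scheme`.
#' @return integer category indices (1 = lowest).
#' @export
categorize <- function(risk, scheme) {
  if (any(!is.na(risk) & (risk < 0 | risk > 1)))
    stop("risk values must lie in [0, 1]")
  findInterval(risk, scheme$edges) + 1L
}

.as_case <- function(case_status) {
  if (is.logical(case_status)) return(case_status)
  if (is.numeric(case_status)) return(case_status != 0)
  tolower(as.character(case_status)) %in% c("case", "1", "true", "yes")
}

#' Cross-classification (reclassification) table for two risk models
#'
#' Tabulates subjects by their risk category under an old and a new model,
#' separately for cases and controls.
#'
#' @param subjects data.frame with a case-status column and the two score
#'   columns.
#' @param old_model,new_model names of the score columns (probabilities).
#' @param scheme a `brisk_scheme`.
#' @param status_col name of the case-status column (values `"case"` /
#'   `"control"`, logical, or 0/1).
#' @param drop_missing drop subjects missing either score (with a warning)
#'   instead of raising an error; mirrors validation on the subset of a
#'   cohort for which a comparator model is available.
#' @return object of class `brisk_reclass` with integer matrices `cases` and
#'   `controls` (old categories in rows, new in columns).
#' @export
build_reclass_table <- function(subjects, old_model, new_model, scheme,
                                status_col = "case_status", drop_missing = FALSE) {
  for (cl in c(status_col, old_model, new_model))
    if (!cl %in% names(subjects)) stop("missing column '", cl, "'")
  old <- subjects[[old_model]]; new <- subjects[[new_model]]
  bad <- which(is.na(old) | is.na(new))
  if (length(bad) > 0) {
    if (!drop_missing)
      stop("missing score at row(s): ", paste(utils::head(bad, 10), collapse = ", "),
           if (length(bad) > 10) " ...", "; set drop_missing = TRUE to exclude")
    warning("excluding ", length(bad), " subject(s) with a missing score")
    subjects <- subjects[-bad, , drop = FALSE]
    old <- subjects[[old_model]]; new <- subjects[[new_model]]
  }
  k <- length(scheme$labels)
  is_case <- .as_case(subjects[[status_col]])
  tab_arm <- function(sel) {
    m <- table(factor(categorize(old[sel], scheme), levels = seq_len(k)),
               factor(categorize(new[sel], scheme), levels = seq_len(k)))
    m <- matrix(as.integer(m), k, k, dimnames = list(scheme$labels, scheme$labels))
    m
  }
  reclass_from_counts(tab_arm(is_case), tab_arm(!is_case), scheme,
                      old_name = old_model, new_name = new_model)
}

#' Build a reclassification table from count matrices
#'
#' @param cases K x K integer matrix (old model in rows, new in columns).
#' @param controls optional K x K matrix for controls.
#' @param scheme a `brisk_scheme` with K labels.
#' @param old_name,new_name model names for display.
#' @return a `brisk_reclass` object.
#' @export
reclass_from_counts <- function(cases, controls = NULL, scheme,
                                old_name = "old", new_name = "new") {
  k <- length(scheme$labels)
  chk <- function(m, what) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(k, k))) stop(what, " matrix must be ", k, "x", k)
    if (any(m < 0) || any(m != round(m))) stop(what, " counts must be nonnegative integers")
    storage.mode(m) <- "integer"
    dimnames(m) <- list(scheme$labels, scheme$labels)
    m
  }
  structure(list(cases = chk(cases, "case"),
                 controls = if (!is.null(controls)) chk(controls, "control"),
                 scheme = scheme, old_name = old_name, new_name = new_name),
            class = "brisk_reclass")
}

#' @export
print.brisk_reclass <- function(x, ...) {
  cat("Reclassification: ", x$old_name, " (rows) vs ", x$new_name,
      " (columns)\nCases:\n", sep = "")
  print(x$cases)
  if (!is.null(x$controls)) { cat("Controls:\n"); print(x$controls) }
  invisible(x)
}

.arm_movement <- function(m) {
  k <- nrow(m)
  up <- sum(m[upper.tri(m)])
  down <- sum(m[lower.tri(m)])
  n <- sum(m)
  p_up <- up / n; p_down <- down / n
  list(up = up, down = down, n = n,
       improvement = p_up - p_down,
       se = sqrt((p_up + p_down - (p_up - p_down)^2) / n))
}

#' Categorical net reclassification improvement
#'
#' Computes, per arm, the net proportion of movers across categories
#' (up-movers minus down-movers over the arm size), with the
#' Pencina-Steyerberg standard error
#' `sqrt((p_up + p_down - (p_up - p_down)^2) / n)`.  The control term enters
#' the overall NRI with a negative sign (controls moving down is an
#' improvement); the overall SE is the root-sum-square of the arm SEs.
#' With a cases-only table, only the case improvement is returned.
#'
#' @param table a `brisk_reclass` object.
#' @return object of class `brisk_nri`: `case_improvement`, `se_case`,
#'   `control_improvement`, `se_control`, `overall`, `se_overall`, and the
#'   mover counts per arm.
#' @export
nri <- function(table) {
  stopifnot(inherits(table, "brisk_reclass"))
  if (sum(table$cases) == 0) stop("NRI undefined: no cases")
  cs <- .arm_movement(table$cases)
  out <- list(case_improvement = cs$improvement, se_case = cs$se,
              movers = list(cases = cs[c("up", "down", "n")]))
  if (!is.null(table$controls)) {
    if (sum(table$controls) == 0) stop("NRI undefined: no controls")
    ct <- .arm_movement(table$controls)
    out$control_improvement <- -ct$improvement
    out$se_control <- ct$se
    out$overall <- out$case_improvement + out$control_improvement
    out$se_overall <- sqrt(cs$se^2 + ct$se^2)
    out$movers$controls <- ct[c("up", "down", "n")]
  }
  structure(out, class = "brisk_nri")
}

#' @export
print.brisk_nri <- function(x, digits = 3, ...) {
  f <- function(v, s) sprintf("%.*f (SE %.*f)", digits, v, digits, s)
  cat("Classification improvement, cases:   ", f(x$case_improvement, x$se_case), "\n")
  if (!is.null(x$overall)) {
    cat("Classification improvement, controls:", f(x$control_improvement, x$se_control), "\n")
    cat("Overall NRI:                         ", f(x$overall, x$se_overall), "\n")
  }
  invisible(x)
}

# ---- discrimination -------------------------------------------------------

# Placement values: for each case, the fraction of controls it beats
# (ties 1/2), and vice versa.  Midrank formulation.
.placements <- function(cases, controls) {
  m <- length(cases); n <- length(controls)
  r_all <- rank(c(cases, controls), ties.method = "average")
  r_cases <- rank(cases, ties.method = "average")
  r_controls <- rank(controls, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_cases) / n            # per-case placements
  v01 <- 1 - (r_all[m + seq_len(n)] - r_controls) / m # per-control placements
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Area under the ROC curve with DeLong confidence interval
#'
#' Mann-Whitney AUC (probability a random case outscores a random control,
#' ties counted one half) with the DeLong variance from placement-value
#' dispersion.
#'
#' @param case_scores,control_scores numeric score vectors, both nonempty.
#' @param conf confidence level for the Wald interval.
#' @return list with `auc`, `se`, `ci` (clamped to `[0, 1]`), `n_cases`,
#'   `n_controls`.
#' @export
auc <- function(case_scores, control_scores, conf = 0.95) {
  if (length(case_scores) == 0 || length(control_scores) == 0)
    stop("AUC undefined: an arm is empty")
  pl <- .placements(case_scores, control_scores)
  v <- stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
  if (length(pl$v10) < 2 || length(pl$v01) < 2) v <- NA_real_
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(auc = pl$auc, se = se,
       ci = c(max(0, pl$auc - z * se), min(1, pl$auc + z * se)),
       n_cases = length(case_scores), n_controls = length(control_scores))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two risk scores measured on the same subjects using
#' the DeLong covariance of the paired placement values; returns a 1-d.f.
#' chi-square statistic `(AUC1 - AUC2)^2 / var(AUC1 - AUC2)` and a two-sided
#' p-value.
#'
#' @param subjects data.frame with the two score columns and a case-status
#'   column.
#' @param model1,model2 score column names.
#' @param status_col case-status column name.
#' @param drop_missing drop subjects missing either score.
#' @return list with `auc1`, `auc2`, `diff`, `var_diff`, `chi_sq`, `df`,
#'   `p_value`.
#' @export
delong_compare <- function(subjects, model1, model2,
                           status_col = "case_status", drop_missing = FALSE) {
  for (cl in c(status_col, model1, model2))
    if (!cl %in% names(subjects)) stop("missing column '", cl, "'")
  keep <- !(is.na(subjects[[model1]]) | is.na(subjects[[model2]]))
  if (any(!keep)) {
    if (!drop_missing) stop("missing scores; set drop_missing = TRUE to exclude")
    subjects <- subjects[keep, , drop = FALSE]
  }
  is_case <- .as_case(subjects[[status_col]])
  if (!any(is_case) || all(is_case)) stop("need both cases and controls")
  p1 <- .placements(subjects[[model1]][is_case], subjects[[model1]][!is_case])
  p2 <- .placements(subjects[[model2]][is_case], subjects[[model2]][!is_case])
  m <- sum(is_case); n <- sum(!is_case)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- p1$auc - p2$auc
  if (var_diff <= 0) {
    if (abs(d) < 1e-12) {
      chi <- 0; p <- 1
    } else {
      warning("zero DeLong variance with nonzero AUC difference")
      chi <- Inf; p <- 0
    }
  } else {
    chi <- d^2 / var_diff
    p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  }
  list(auc1 = p1$auc, auc2 = p2$auc, diff = d, var_diff = var_diff,
       chi_sq = chi, df = 1, p_value = p)
}

#' Odds ratio per control standard deviation
#'
#' Univariable logistic regression of case status on the score divided by
#' the control-arm standard deviation (denominator n - 1), with Wald
#' confidence limits on the exponentiated coefficient.
#'
#' @param scores numeric score vector.
#' @param case_status case indicator (`"case"`/`"control"`, logical, or 0/1).
#' @param conf confidence level.
#' @return list with `or`, `ci`, `se_log_or`, `p_value`, `sd_controls`.
#' @export
or_per_sd <- function(scores, case_status, conf = 0.95) {
  is_case <- .as_case(case_status)
  if (!any(is_case) || all(is_case)) stop("need both cases and controls")
  s <- stats::sd(scores[!is_case])
  if (!is.finite(s) || s == 0) stop("control-arm SD is zero; OR per SD undefined")
  fit <- stats::glm(is_case ~ I(scores / s), family = stats::binomial())
  co <- summary(fit)$coefficients[2, ]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = exp(co[["Estimate"]]),
       ci = exp(co[["Estimate"]] + c(-1, 1) * z * co[["Std. Error"]]),
       se_log_or = co[["Std. Error"]],
       p_value = co[["Pr(>|z|)"]],
       sd_controls = s)
}

# ---- calibration ----------------------------------------------------------

#' Age bands used for calibration summaries
#'
#' Under-45, then 5-year bands to 75 and over.
#'
#' @return list with `breaks` (left-closed) and `labels`.
#' @export
calibration_age_bands <- function() {
  list(breaks = c(-Inf, 45, 50, 55, 60, 65, 70, 75, Inf),
       labels = c("<45", "45-49", "50-54", "55-59", "60-64", "65-69",
                  "70-74", "75+"))
}

.eo_ci <- function(ratio, E, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ratio * exp(c(-1, 1) * z / sqrt(E))
}

#' Expected/observed calibration from per-band totals
#'
#' @param expected,observed per-band expected and observed incident counts.
#' @param n optional per-band sizes.
#' @param labels optional band labels.
#' @param conf confidence level.
#' @return object of class `brisk_calibration`: per-band table, totals `E`
#'   and `O`, `ratio = E/O` and its log-scale confidence interval
#'   `ratio * exp(-/+ z / sqrt(E))`.
#' @export
eo_result <- function(expected, observed, n = NULL, labels = NULL, conf = 0.95) {
  stopifnot(length(expected) == length(observed))
  E <- sum(expected); O <- sum(observed)
  if (E <= 0 || O <= 0) stop("E and O totals must be positive")
  tab <- data.frame(band = if (!is.null(labels)) labels else seq_along(expected),
                    n = if (!is.null(n)) n else NA_integer_,
                    expected = expected, observed = observed)
  structure(list(table = tab, E = E, O = O, ratio = E / O,
                 ci = .eo_ci(E / O, E, conf), conf = conf),
            class = "brisk_calibration")
}

#' Median-based expected/observed calibration on controls
#'
#' Per age band, the expected count is the *median* model risk in the band
#' times the number of women (the median because the age-specific score
#' distributions are strongly right-skewed); the observed count is the
#' population-rate-based risk summed over the same women.  Controls are used
#' because they represent the general population.
#'
#' @param controls data.frame of control subjects with an `age` column.
#' @param score column name of the model risk (probability over the horizon).
#' @param population_risk either a numeric vector of per-band population
#'   risks over the same horizon, or `NULL` to derive per-woman baseline
#'   risks from `hazards` (relative risk 1).
#' @param hazards a `brisk_hazards` object (used when `population_risk` is
#'   `NULL`).
#' @param horizon projection length in years, or `"lifetime"`.
#' @param max_age lifetime horizon age when `horizon = "lifetime"`.
#' @param bands band definition as from [calibration_age_bands()].
#' @param conf confidence level.
#' @return a `brisk_calibration` object.
#' @export
calibration_eo <- function(controls, score, population_risk = NULL,
                           hazards = NULL, horizon = 5, max_age = 85,
                           bands = calibration_age_bands(), conf = 0.95) {
  if (!score %in% names(controls)) stop("missing score column '", score, "'")
  band_idx <- findInterval(controls$age, bands$breaks[-1]) + 1L
  k <- length(bands$labels)
  expected <- observed <- numeric(k)
  nn <- integer(k)
  if (is.null(population_risk)) {
    if (is.null(hazards)) stop("supply population_risk or hazards")
    base <- if (identical(horizon, "lifetime"))
      remaining_lifetime_risk(controls$age, 1, hazards, max_age = max_age)
    else absolute_risk(controls$age, horizon, 1, hazards)
  }
  for (b in seq_len(k)) {
    sel <- band_idx == b
    nn[b] <- sum(sel)
    if (nn[b] == 0) { warning("empty age band '", bands$labels[b], "' skipped"); next }
    expected[b] <- stats::median(controls[[score]][sel]) * nn[b]
    observed[b] <- if (is.null(population_risk)) sum(base[sel])
                   else population_risk[b] * nn[b]
  }
  eo_result(expected, observed, n = nn, labels = bands$labels, conf = conf)
}

#' @export
print.brisk_calibration <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("E = %.2f, O = %.2f, E/O = %.2f (%.0f%% CI %.2f, %.2f)\n",
              x$E, x$O, x$ratio, 100 * x$conf, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Fraction of an arm at or above a risk threshold
#'
#' For a numeric score vector, the fraction at or above `threshold`.  For a
#' `brisk_reclass` table, the threshold must coincide with a category edge;
#' the fraction is computed from the requested arm's margin under the
#' requested model.
#'
#' @param x numeric scores or a `brisk_reclass` object.
#' @param threshold probability threshold.
#' @param arm `"case"` or `"control"` (table input).
#' @param model `"new"` or `"old"` (table input).
#' @param ... unused.
#' @return fraction in `[0, 1]`.
#' @export
proportion_above <- function(x, threshold, ...) UseMethod("proportion_above")

#' @rdname proportion_above
#' @export
proportion_above.numeric <- function(x, threshold, ...) mean(x >= threshold)

#' @rdname proportion_above
#' @export
proportion_above.brisk_reclass <- function(x, threshold, arm = "case",
                                           model = c("new", "old"), ...) {
  model <- match.arg(model)
  edges <- x$scheme$edges
  j <- which(abs(edges - threshold) < 1e-12)
  if (length(j) == 0) {
    if (threshold > max(edges)) return(0)
    stop("threshold ", threshold, " is not a category edge of the scheme")
  }
  m <- if (arm == "case") x$cases else x$controls
  if (is.null(m)) stop("table has no ", arm, " arm")
  keep <- (j + 1):ncol(m)
  if (model == "new") sum(m[, keep]) / sum(m) else sum(m[keep, ]) / sum(m)
}
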