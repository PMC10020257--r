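test_that("categorization is left-closed and monotone", {
  s5 <- scheme_5year(); slt <- scheme_lifetime()
  expect_equal(s5$labels[categorize(0.0167, s5)], ">=1.67 to <3%")
  expect_equal(s5$labels[categorize(0.0099, s5)], "<1%")
  expect_equal(slt$labels[categorize(0.20, slt)], ">=20 to <25%")
  expect_equal(categorize(c(0, 0.01, 0.03, 1), s5), c(1L, 2L, 4L, 4L))
  set.seed(5)
  x <- sort(runif(100))
  expect_true(all(diff(categorize(x, slt)) >= 0))
  expect_error(categorize(1.2, s5), "\\[0, 1\\]")
  expect_error(category_scheme(c(0.2, 0.1)), "increasing")
})

test_that("reclassification tables match brute-force tabulation", {
  s <- scheme_5year()
  # three controls in one cell
  d <- data.frame(case_status = "control", old = 0.012, new = 0.02)
  d <- d[rep(1, 3), ]
  d$case_status <- "control"
  tab <- build_reclass_table(rbind(d, data.frame(case_status = "case",
                                                 old = 0.001, new = 0.001)),
                             "old", "new", s)
  expect_equal(tab$controls[2, 3], 3L)
  expect_equal(sum(tab$controls), 3L)

  set.seed(13)
  n <- 50
  d <- data.frame(case_status = sample(c("case", "control"), n, TRUE),
                  old = runif(n, 0, 0.06), new = runif(n, 0, 0.06))
  tab <- build_reclass_table(d, "old", "new", s)
  expect_equal(sum(tab$cases), sum(d$case_status == "case"))
  # double-loop oracle
  for (arm in c("case", "control")) {
    m <- matrix(0L, 4, 4)
    for (r in which(d$case_status == arm))
      m[categorize(d$old[r], s), categorize(d$new[r], s)] <-
        m[categorize(d$old[r], s), categorize(d$new[r], s)] + 1L
    expect_equal(unname(if (arm == "case") tab$cases else tab$controls), m)
  }

  d$new[3] <- NA
  expect_error(build_reclass_table(d, "old", "new", s), "missing score")
  expect_warning(t2 <- build_reclass_table(d, "old", "new", s, drop_missing = TRUE),
                 "excluding 1")
  expect_equal(sum(t2$cases) + sum(t2$controls), n - 1)
})

test_that("NRI equals brute-force mover enumeration with Pencina errors", {
  s <- scheme_lifetime()
  diag_tab <- reclass_from_counts(diag(5) * 7, diag(5) * 3, s)
  r0 <- nri(diag_tab)
  expect_equal(r0$case_improvement, 0)
  expect_equal(r0$overall, 0)

  set.seed(17)
  for (rep in 1:10) {
    cm <- matrix(rpois(25, 8), 5, 5)
    km <- matrix(rpois(25, 12), 5, 5)
    res <- nri(reclass_from_counts(cm, km, s))
    mc <- bf_movement(cm); mk <- bf_movement(km)
    nc <- sum(cm); nk <- sum(km)
    expect_equal(res$case_improvement, (mc["up"] - mc["down"]) / nc,
                 ignore_attr = TRUE)
    expect_equal(res$control_improvement, -(mk["up"] - mk["down"]) / nk,
                 ignore_attr = TRUE)
    expect_equal(res$overall, res$case_improvement + res$control_improvement,
                 tolerance = 1e-12)
    pu <- mc[["up"]] / nc; pd <- mc[["down"]] / nc
    expect_equal(res$se_case, sqrt((pu + pd - (pu - pd)^2) / nc), tolerance = 1e-12)
    expect_equal(res$se_overall^2, res$se_case^2 + res$se_control^2,
                 tolerance = 1e-12)
  }
  expect_error(nri(reclass_from_counts(matrix(0, 5, 5), km, s)), "no cases")
})

test_that("AUC equals exhaustive pair counting and agrees with pROC", {
  expect_equal(auc(c(2, 3), 1)$auc, 1.0)
  expect_equal(auc(c(1, 2, 2, 5), c(1, 2, 2, 5))$auc, 0.5)
  expect_equal(auc(c(1, 3), c(2, 4))$auc, 0.25)

  set.seed(19)
  for (rep in 1:5) {
    m <- sample(5:100, 1); n <- sample(5:100, 1)
    cs <- sample(round(rnorm(m, 1, 1), 1))   # rounding induces ties
    ks <- round(rnorm(n, 0, 1), 1)
    got <- auc(cs, ks)
    expect_equal(got$auc, bf_auc(cs, ks), tolerance = 1e-12)
    ref <- pROC::roc(response = c(rep(1, m), rep(0, n)), predictor = c(cs, ks),
                     quiet = TRUE, direction = "<")
    expect_equal(got$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    expect_equal(got$ci,
                 as.numeric(pROC::ci.auc(ref, method = "delong"))[c(1, 3)],
                 tolerance = 1e-9)
  }
  expect_error(auc(numeric(0), c(1, 2)), "empty")
})

test_that("DeLong comparison matches placement-value brute force and pROC", {
  set.seed(23)
  d <- data.frame(case_status = rep(c("case", "control"), c(10, 12)))
  d$a <- rnorm(22) + (d$case_status == "case")
  d$b <- 0.6 * d$a + rnorm(22)

  same <- delong_compare(transform(d, b = a), "a", "b")
  expect_equal(same$chi_sq, 0)
  expect_equal(same$p_value, 1)

  got <- delong_compare(d, "a", "b")
  is_case <- d$case_status == "case"
  pa <- bf_placements(d$a[is_case], d$a[!is_case])
  pb <- bf_placements(d$b[is_case], d$b[!is_case])
  v <- var(pa$v10 - pb$v10) / sum(is_case) + var(pa$v01 - pb$v01) / sum(!is_case)
  expect_equal(got$var_diff, v, tolerance = 1e-10)
  expect_equal(got$auc1, auc(d$a[is_case], d$a[!is_case])$auc)

  # invariant under strictly monotone transforms of either score
  tr <- delong_compare(transform(d, a = exp(a), b = atan(b)), "a", "b")
  expect_equal(tr$chi_sq, got$chi_sq, tolerance = 1e-12)

  rt <- pROC::roc.test(pROC::roc(is_case, d$a, quiet = TRUE, direction = "<"),
                       pROC::roc(is_case, d$b, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(got$p_value, as.numeric(rt$p.value), tolerance = 1e-9)
})

test_that("OR per control SD is scale-invariant and recovers designed effects", {
  set.seed(29)
  n <- 3000
  status <- rep(c(1, 0), each = n / 2)
  null_scores <- rnorm(n)
  o0 <- or_per_sd(null_scores, status)
  expect_gt(o0$ci[1], 0.8); expect_lt(o0$ci[2], 1.25)
  expect_true(o0$ci[1] < 1 && 1 < o0$ci[2])

  x <- rnorm(n, mean = 0.4 * status)   # per-unit log-OR 0.4 given unit variance
  o1 <- or_per_sd(x, status)
  o10 <- or_per_sd(10 * x, status)
  expect_equal(o1$or, o10$or, tolerance = 1e-9)
  s <- sd(x[status == 0])
  expect_lt(abs(log(o1$or) - 0.4 * s), 2 * o1$se_log_or)
  expect_error(or_per_sd(rep(1, n), status), "SD is zero")
})

test_that("E/O calibration is median-based with log-symmetric intervals", {
  r <- eo_result(c(2, 3, 5), c(2, 3, 5))
  expect_equal(r$ratio, 1.0)
  expect_equal(log(r$ci[2] / r$ratio), log(r$ratio / r$ci[1]), tolerance = 1e-12)

  hz <- default_hazards()
  set.seed(31)
  d <- data.frame(age = runif(400, 40, 79))
  d$score <- absolute_risk(d$age, 5, 1, hz) * exp(rnorm(400, 0, 0.3))
  cal <- calibration_eo(d, "score", hazards = hz, horizon = 5)
  perm <- calibration_eo(d[sample(400), ], "score", hazards = hz, horizon = 5)
  expect_equal(cal$E, perm$E, tolerance = 1e-12)
  expect_equal(cal$ratio, perm$ratio, tolerance = 1e-12)
  # per-band expected is median score times band size
  b <- calibration_age_bands()
  sel <- d$age >= 60 & d$age < 65
  expect_equal(cal$table$expected[cal$table$band == "60-64"],
               median(d$score[sel]) * sum(sel))
  w <- capture_warnings(calibration_eo(d[d$age < 45, , drop = FALSE], "score",
                                       hazards = hz))
  expect_true(any(grepl("empty age band", w)))
})

test_that("threshold-exceedance proportions respect category edges", {
  expect_equal(proportion_above(c(0.1, 0.2, 0.3, 0.4), 0.25), 0.5)
  tab <- reclass_from_counts(matrix(c(5, 0, 0, 5, 5, 0, 0, 5, 10), 3, 3,
                                    byrow = TRUE),
                             NULL, category_scheme(c(0.1, 0.2)))
  expect_equal(proportion_above(tab, 0.2, "case", "new"), 10 / 30)
  expect_equal(proportion_above(tab, 0.1, "case", "old"), 25 / 30)
  expect_equal(proportion_above(tab, 0.9, "case", "new"), 0)
  expect_error(proportion_above(tab, 0.15, "case", "new"), "category edge")
})
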