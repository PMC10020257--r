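#' Specification for a synthetic case-control cohort
#'
#' Defaults emulate the marginal risk-factor distributions reported for the
#' control arm of the nested case-control cohort the model was validated on:
#' control age mean 59.3 (SD 7.5), percent density mean 24.7 (SD 18.1)
#' (logit-normal family), BMI mean 25.9 (SD 4.7), about 14% with an affected
#' first-degree relative, 85% postmenopausal.  The polygenic score is
#' lognormal with population mean 1; its default log-SD of `log(1.61)`
#' corresponds to an odds ratio per SD of 1.61 for the genome-wide score the
#' model uses.
#'
#' @param n_cases,n_controls arm sizes (> 0).
#' @param seed integer RNG seed; cohorts are reproducible from (spec, seed).
#' @param age_mean,age_sd,age_range age distribution (truncated normal).
#' @param density_logit_mu,density_logit_sd logit-normal percent-density
#'   parameters (`100 * plogis(mu + sd * Z)`); the defaults moment-match
#'   mean 24.7, SD 18.1.
#' @param bmi_mean,bmi_sd,bmi_range BMI distribution (truncated normal).
#' @param menopause_age50,menopause_scale logistic model for
#'   `P(post) = plogis((age - age50) / scale)`.
#' @param prs_log_sd SD of log(PRS); 0 disables the polygenic component.
#' @param pool_factor case pool size as a multiple of `n_cases` for
#'   relative-risk-weighted case sampling.
#' @return object of class `brisk_cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls, seed,
                        age_mean = 59.3, age_sd = 7.5, age_range = c(40, 75),
                        density_logit_mu = -1.3856, density_logit_sd = 1.1314,
                        bmi_mean = 25.9, bmi_sd = 4.7, bmi_range = c(16, 60),
                        menopause_age50 = 51, menopause_scale = 2.5,
                        prs_log_sd = log(1.61), pool_factor = 50) {
  if (n_cases <= 0 || n_controls <= 0) stop("arm sizes must be > 0")
  if (age_sd <= 0 || bmi_sd <= 0 || density_logit_sd < 0)
    stop("distribution SDs must be positive")
  if (prs_log_sd < 0) stop("prs_log_sd must be >= 0")
  structure(as.list(environment()), class = "brisk_cohort_spec")
}

.rtrunc_norm <- function(n, mean, sd, range) {
  lo <- stats::pnorm(range[1], mean, sd); hi <- stats::pnorm(range[2], mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

# sample m values consistent with a family-history band label
.band_values <- function(label, m, kind) {
  if (label == "any") {
    if (kind == "age_dx") return(stats::runif(m, 35, 70))  # caller NA-masks n_fdr=0
    return(rep(0, m))
  }
  if (startsWith(label, "<"))
    return(stats::runif(m, 30, as.numeric(substring(label, 2))))
  if (startsWith(label, ">="))
    return(stats::runif(m, as.numeric(substring(label, 3)), 75))
  if (endsWith(label, "+"))
    return(rep(as.numeric(substring(label, 1, nchar(label) - 1)), m))
  rep(as.numeric(label), m)
}

# cut points implied by a categorical density table with labels "<X%", ">=X%"...
.density_edges <- function(ct) {
  v <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", ct$label[-1])))
  if (anyNA(v)) stop("cannot parse categorical density labels into cut points")
  v
}

.draw_population <- function(n, spec, params) {
  age <- .rtrunc_norm(n, spec$age_mean, spec$age_sd, spec$age_range)
  pd <- 100 * stats::plogis(spec$density_logit_mu +
                            spec$density_logit_sd * stats::rnorm(n))
  bmi <- .rtrunc_norm(n, spec$bmi_mean, spec$bmi_sd, spec$bmi_range)
  meno <- ifelse(stats::runif(n) <
                   stats::plogis((age - spec$menopause_age50) / spec$menopause_scale),
                 "post", "pre")
  fh <- params$family_history
  cat_idx <- sample.int(nrow(fh), n, replace = TRUE, prob = fh$weight)
  n_fdr <- n_sdr <- age_dx <- numeric(n)
  for (i in seq_len(nrow(fh))) {
    rows <- which(cat_idx == i)
    if (length(rows) == 0) next
    n_fdr[rows] <- .band_values(fh$n_fdr[i], length(rows), "n_fdr")
    n_sdr[rows] <- .band_values(fh$n_sdr[i], length(rows), "n_sdr")
    age_dx[rows] <- .band_values(fh$age_dx[i], length(rows), "age_dx")
  }
  age_dx[n_fdr == 0] <- NA_real_
  dens_cat <- NA_integer_
  if (!is.null(params$density$categorical)) {
    edges <- .density_edges(params$density$categorical)
    dens_cat <- findInterval(pd, edges) + 1L
  }
  prs <- if (spec$prs_log_sd > 0)
    exp(stats::rnorm(n, -spec$prs_log_sd^2 / 2, spec$prs_log_sd))
  else rep(1, n)
  data.frame(age = age, n_fdr = n_fdr, age_youngest_fdr = age_dx, n_sdr = n_sdr,
             percent_density = pd, density_category = dens_cat, bmi = bmi,
             menopausal_status = meno, prs = prs, stringsAsFactors = FALSE)
}

#' Generate a synthetic case-control cohort
#'
#' Controls are drawn from the population model of the spec; cases are drawn
#' from a large population pool (`pool_factor * n_cases` women) by weighted
#' sampling with probability proportional to each woman's combined relative
#' risk under `params` — the retrospective analogue of risk-proportional
#' case occurrence in a nested case-control design.  Output is byte-identical
#' for a fixed (spec, seed).
#'
#' @param spec a `brisk_cohort_spec`.
#' @param params a `brisk_params` object; disabled components do not
#'   contribute to the case-sampling relative risk.
#' @return data.frame: profile columns plus `case_status` (`"case"` /
#'   `"control"`) and `true_rr` (the combined relative risk used for
#'   sampling).
#' @export
generate_cohort <- function(spec, params = default_params()) {
  stopifnot(inherits(spec, "brisk_cohort_spec"))
  set.seed(spec$seed)
  controls <- .draw_population(spec$n_controls, spec, params)
  pool <- .draw_population(spec$pool_factor * spec$n_cases, spec, params)
  rr_of <- function(df) {
    comps <- list()
    if (!"family_history" %in% params$disabled)
      comps$fh <- family_history_rr(df, params)
    if (!"density" %in% params$disabled)
      comps$density <- density_rr(df, params)
    if (!"bmi" %in% params$disabled)
      comps$bmi <- bmi_rr(df, params)
    if (!"prs" %in% params$disabled) comps$prs <- df$prs
    if (length(comps) == 0) rep(1, nrow(df)) else combined_rr(comps)
  }
  rr_pool <- rr_of(pool)
  idx <- sample.int(nrow(pool), spec$n_cases, replace = FALSE, prob = rr_pool)
  cases <- pool[idx, , drop = FALSE]
  out <- rbind(
    cbind(cases, case_status = "case", true_rr = rr_pool[idx]),
    cbind(controls, case_status = "control", true_rr = rr_of(controls))
  )
  rownames(out) <- NULL
  out$id <- sprintf("S%05d", seq_len(nrow(out)))
  out[, c("id", setdiff(names(out), "id"))]
}

#' Simulate a SNP weight table
#'
#' Independent loci with risk-allele frequencies uniform on (0.05, 0.95) and
#' per-allele odds ratios lognormal around 1 (|log OR| mostly < 0.1,
#' matching the small per-allele effects of genome-wide significant breast
#' cancer loci).
#'
#' @param n_snps number of variants.
#' @param seed RNG seed.
#' @param log_or_sd SD of per-allele log odds ratios.
#' @return a `brisk_snp_weights` data.frame.
#' @export
simulate_snp_weights <- function(n_snps, seed = 1, log_or_sd = 0.05) {
  set.seed(seed)
  alleles <- c("A", "C", "G", "T")
  ra <- sample(alleles, n_snps, replace = TRUE)
  oa <- vapply(ra, function(a) sample(setdiff(alleles, c(a, .complement(a))), 1),
               character(1))
  snp_weights(data.frame(
    variant_id = sprintf("rs%06d", seq_len(n_snps)),
    chrom = sample(1:22, n_snps, replace = TRUE),
    pos = sample.int(1e8, n_snps),
    risk_allele = ra, other_allele = oa,
    freq = stats::runif(n_snps, 0.05, 0.95),
    or = exp(stats::rnorm(n_snps, 0, log_or_sd)),
    stringsAsFactors = FALSE))
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Independent loci; risk-allele counts are Binomial(2, freq) per variant.
#'
#' @param n_samples number of women.
#' @param weights a `brisk_snp_weights` table.
#' @param seed RNG seed.
#' @return samples x variants integer matrix of risk-allele counts.
#' @export
simulate_genotypes <- function(n_samples, weights, seed = 1) {
  weights <- snp_weights(weights)
  set.seed(seed)
  m <- vapply(weights$freq,
              function(p) stats::rbinom(n_samples, 2, p),
              integer(n_samples))
  dimnames(m) <- list(sprintf("S%05d", seq_len(n_samples)), weights$variant_id)
  m
}
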