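# Shared fixtures and independent brute-force oracles.

# 4-category demo family-history table: raw RRs and prevalence weights with
# hand-computed centering constant 1.202.
demo_params <- function(density_mode = "continuous") {
  fh <- data.frame(
    n_fdr = c("0", "1", "2+", "0"),
    age_dx = c("any", "any", "any", "any"),
    n_sdr = c("0", "any", "any", "1+"),
    rr = c(1.0, 1.8, 2.9, 1.3),
    weight = c(0.65, 0.13, 0.02, 0.20),
    stringsAsFactors = FALSE)
  rr_parameters(
    fh,
    density = list(mode = density_mode,
                   continuous = list(slope = 0.02, reference = 25),
                   categorical = data.frame(label = c("<25%", ">=25%"),
                                            rr = c(0.8, 1.5),
                                            weight = c(0.6, 0.4))),
    bmi = list(pre = list(slope = -0.02, reference = 25),
               post = list(slope = 0.03, reference = 25)))
}

const_hazards <- function(h1, h2, ages = 20:99) {
  hazard_table(ages, rep(h1, length(ages)), rep(h2, length(ages)))
}

random_hazards <- function(ages = 20:99) {
  hazard_table(ages, runif(length(ages), 0, 0.05), runif(length(ages), 0, 0.05))
}

# day-step Euler integration of the competing-risk cumulative incidence;
# numerically independent of the per-year closed form
euler_absolute_risk <- function(age, horizon, rr, hz, dt = 1 / 365) {
  risk <- 0; surv <- 1
  for (t in age:(age + horizon - 1)) {
    h <- brisk:::.hazard_at(hz, t)
    lam <- rr * h$h1 + h$h2
    for (s in seq_len(round(1 / dt))) {
      risk <- risk + surv * rr * h$h1 * dt
      surv <- surv * (1 - lam * dt)
    }
  }
  risk
}

# exhaustive pair-counting AUC with half credit for ties
bf_auc <- function(cases, controls) {
  tot <- 0
  for (x in cases) for (y in controls)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(cases) * length(controls))
}

# direct placement values by double loop
bf_placements <- function(cases, controls) {
  v10 <- vapply(cases, function(x) mean((x > controls) + 0.5 * (x == controls)),
                numeric(1))
  v01 <- vapply(controls, function(y) mean((cases > y) + 0.5 * (cases == y)),
                numeric(1))
  list(v10 = v10, v01 = v01)
}

# up/down mover enumeration over every cell of a K x K matrix
bf_movement <- function(m) {
  up <- down <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (j > i) up <- up + m[i, j]
    if (j < i) down <- down + m[i, j]
  }
  c(up = up, down = down)
}

write_tiny_vcf <- function(path, samples = c("S1", "S2")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rec <- function(chrom, pos, id, ref, alt, ...)
    paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", ...), collapse = "\t")
  writeLines(c(hdr,
               rec(1, 100, "rs1", "A", "G", "1/1", "0/1"),   # risk = ALT
               rec(1, 200, "rs2", "C", "T", "0/0", "0/1"),   # risk = REF
               rec(1, 300, "rs3", "A", "T", "0/1", "1/1"),   # palindromic
               rec(1, 400, "rs4", "G", "C", "0/0", "./.")),  # palindromic C/G
             path)
}
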