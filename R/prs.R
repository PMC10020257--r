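#' Read a SNP weight table
#'
#' Tab-separated with header
#' `variant_id  chrom  pos  risk_allele  other_allele  freq  or`:
#' risk-allele frequency `freq` in (0,1) and per-allele odds ratio `or` > 0.
#'
#' @param path TSV file path.
#' @return data.frame of class `brisk_snp_weights`.
#' @export
read_snp_weights <- function(path) {
  if (!file.exists(path)) stop("SNP weight file not found: ", path)
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("variant_id", "chrom", "pos", "risk_allele", "other_allele", "freq", "or")
  miss <- setdiff(req, names(w))
  if (length(miss) > 0)
    stop("SNP weight file missing column(s): ", paste(miss, collapse = ", "))
  snp_weights(w)
}

#' Construct/validate a SNP weight table
#'
#' @param w data.frame with at least `variant_id`, `risk_allele`, `freq`, `or`.
#' @return the validated data.frame, classed `brisk_snp_weights`.
#' @export
snp_weights <- function(w) {
  stopifnot(is.data.frame(w))
  if (nrow(w) == 0) stop("empty SNP weight table")
  miss <- setdiff(c("variant_id", "risk_allele", "freq", "or"), names(w))
  if (length(miss) > 0)
    stop("SNP weight table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(w$variant_id))
    stop("duplicate variant_id in SNP weight table: ",
         w$variant_id[duplicated(w$variant_id)][1])
  if (any(w$freq <= 0 | w$freq >= 1))
    stop("risk-allele frequencies must lie strictly in (0, 1)")
  if (any(w$or <= 0)) stop("per-allele odds ratios must be > 0")
  class(w) <- c("brisk_snp_weights", "data.frame")
  w
}

#' Population mean genotype relative risk under Hardy-Weinberg equilibrium
#'
#' For risk-allele frequency `p` and per-allele odds ratio `r`, the mean of
#' `r^g` over HWE genotype frequencies:
#' `mu = (1-p)^2 + 2p(1-p) r + p^2 r^2`.  Dividing each genotype's `r^g` by
#' `mu` centers the per-SNP factor to population mean 1.
#'
#' @param p risk-allele frequency in (0, 1); vectorized.
#' @param r per-allele odds ratio > 0; vectorized.
#' @return numeric vector of means (>= 1 when `r >= 1`).
#' @export
hwe_mean_factor <- function(p, r) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  if (any(r <= 0)) stop("r must be > 0")
  (1 - p)^2 + 2 * p * (1 - p) * r + p^2 * r^2
}

#' Per-SNP normalized risk factor
#'
#' `r^g / mu(p, r)` for risk-allele count `g`; missing genotypes contribute
#' exactly 1 (the population mean), keeping scores centered without dropping
#' samples.
#'
#' @param g risk-allele count in `{0, 1, 2}` or `NA`; vectorized.
#' @param p,r risk-allele frequency and per-allele odds ratio (recycled).
#' @return numeric vector of positive factors.
#' @export
snp_factor <- function(g, p, r) {
  ok <- is.na(g) | g %in% c(0, 1, 2)
  if (!all(ok)) stop("genotype counts must be in {0, 1, 2} or NA (got ",
                     g[!ok][1], ")")
  out <- r^ifelse(is.na(g), 0, g) / hwe_mean_factor(p, r)
  out[is.na(g)] <- 1
  out
}

#' Multiplicative polygenic risk score
#'
#' The product over the weight table of per-SNP normalized factors
#' `r^g / mu(p, r)`; under Hardy-Weinberg sampling the population mean score
#' is 1.  Genotypes are matched to weights by `variant_id`; genotyped
#' variants absent from the weight table are ignored (with a message),
#' weight-table variants absent from the genotypes count as missing and
#' contribute 1.
#'
#' @param genotypes named numeric vector (one sample; names are variant ids,
#'   values risk-allele counts 0/1/2 or `NA`) or a samples x variants matrix
#'   or data.frame with variant ids as column names.
#' @param weights a `brisk_snp_weights` table.
#' @return for a vector: list with `score`, `n_used`, `n_missing`; for a
#'   matrix: data.frame with those columns, one row per sample.
#' @export
prs_score <- function(genotypes, weights) {
  weights <- snp_weights(weights)
  if (is.matrix(genotypes) || is.data.frame(genotypes)) {
    gm <- as.matrix(genotypes)
    extra <- setdiff(colnames(gm), weights$variant_id)
    if (length(extra) > 0)
      message(length(extra), " genotyped variant(s) not in the weight table; ignored")
    res <- lapply(seq_len(nrow(gm)), function(i) {
      r <- prs_score(setNames(gm[i, ], colnames(gm)), weights)
      data.frame(score = r$score, n_used = r$n_used, n_missing = r$n_missing)
    })
    out <- do.call(rbind, res)
    rownames(out) <- rownames(gm)
    return(out)
  }
  g <- genotypes[match(weights$variant_id, names(genotypes))]
  factors <- snp_factor(as.numeric(g), weights$freq, weights$or)
  list(score = prod(factors),
       n_used = sum(!is.na(g)),
       n_missing = sum(is.na(g)))
}

#' Rescale log-scores to a target standard deviation
#'
#' Optional post-hoc rescaling of a mean-1 multiplicative score so the
#' standard deviation of its logarithm matches `log(target_or_per_sd)`
#' (under the multiplicative hazard model the odds ratio per standard
#' deviation of a lognormal score with log-SD sigma is `exp(sigma)`).
#' Off by default in all pipelines.
#'
#' @param scores positive numeric vector, population mean about 1.
#' @param target_or_per_sd desired odds ratio per SD (> 1 scales up).
#' @return rescaled scores, re-centered to mean 1 on the natural scale.
#' @export
rescale_prs <- function(scores, target_or_per_sd) {
  if (any(scores <= 0)) stop("scores must be > 0")
  if (target_or_per_sd <= 0) stop("target_or_per_sd must be > 0")
  ls <- log(scores)
  s <- stats::sd(ls)
  if (s == 0) stop("cannot rescale a zero-variance score")
  ls2 <- (ls - mean(ls)) * log(target_or_per_sd) / s
  out <- exp(ls2)
  out / mean(out)
}

# ---- genotype input -------------------------------------------------------

#' Read a dosage matrix (samples x variants CSV)
#'
#' First column `sample_id`, remaining columns named by variant id with
#' risk-allele counts 0/1/2 (blank/NA for missing).
#'
#' @param path CSV path.
#' @return numeric matrix with sample ids as rownames.
#' @export
read_dosage <- function(path) {
  if (!file.exists(path)) stop("dosage file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "sample_id") stop("dosage file must start with 'sample_id'")
  m <- as.matrix(d[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- d$sample_id
  bad <- !(is.na(m) | m %in% c(0, 1, 2))
  if (any(bad)) stop("dosage values must be 0/1/2 or missing")
  m
}

.complement <- function(a) chartr("ACGT", "TGCA", toupper(a))

#' Extract risk-allele counts from a VCF
#'
#' Matches weight-table variants to VCF records by `variant_id` (falling back
#' to chrom+pos when ids are missing), resolves allele orientation (the risk
#' allele may be REF or ALT; ALT counts are complemented when the risk allele
#' is REF), and treats unmatched or ambiguous variants as missing.
#' Palindromic (A/T, C/G) variants are resolved via strand complement only
#' when the allele frequency is informative (`|freq - 0.5| > 0.1`); otherwise
#' they are set missing with a warning.  Requires the `vcfR` package.
#'
#' @param path VCF file path (uncompressed or gzipped).
#' @param weights a `brisk_snp_weights` table.
#' @return samples x variants numeric matrix of risk-allele counts (`NA` for
#'   missing), columns in weight-table order.
#' @export
genotypes_from_vcf <- function(path, weights) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("genotypes_from_vcf requires the 'vcfR' package")
  if (!file.exists(path)) stop("VCF not found: ", path)
  weights <- snp_weights(weights)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # alt-allele dosage per record x sample
  alt_count <- function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
  }
  n_samp <- ncol(gt)
  out <- matrix(NA_real_, nrow = n_samp, ncol = nrow(weights),
                dimnames = list(colnames(gt), weights$variant_id))
  ids <- fix[, "ID"]
  key <- paste(fix[, "CHROM"], fix[, "POS"], sep = ":")
  for (j in seq_len(nrow(weights))) {
    w <- weights[j, ]
    rec <- which(ids == w$variant_id)
    if (length(rec) == 0 && all(c("chrom", "pos") %in% names(weights)))
      rec <- which(key == paste(w$chrom, w$pos, sep = ":"))
    if (length(rec) == 0) next                      # absent -> missing
    rec <- rec[1]
    ref <- toupper(fix[rec, "REF"]); alt <- toupper(fix[rec, "ALT"])
    ra <- toupper(w$risk_allele)
    oa <- if ("other_allele" %in% names(weights)) toupper(w$other_allele) else NA
    palindromic <- !is.na(oa) && ra == .complement(oa)
    orient <- NA_character_
    if (ra == alt) orient <- "alt"
    else if (ra == ref) orient <- "ref"
    else if (.complement(ra) == alt) orient <- "alt"   # strand flip
    else if (.complement(ra) == ref) orient <- "ref"
    if (palindromic && abs(w$freq - 0.5) <= 0.1) {
      warning("palindromic variant ", w$variant_id,
              " with uninformative frequency; treated as missing")
      next
    }
    if (is.na(orient)) {
      warning("alleles of ", w$variant_id, " do not match the VCF record; ",
              "treated as missing")
      next
    }
    ac <- vapply(gt[rec, ], alt_count, numeric(1))
    out[, j] <- if (orient == "alt") ac else 2 - ac
  }
  out
}
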