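## Synthetic family phenotype tables with known ground truth.
##
## The generator emulates a multicentre affected-full-sibling sample of
## recurrent depression: families of 2-5 affected siblings nested within
## study centres, a positively skewed age at onset modelled on the
## square-root scale with centre and family random intercepts, and an
## overdispersed lifetime episode count generated from a negative-binomial
## mixed model with illness duration as exposure.

#' Ground-truth parameters for the family simulator
#'
#' Collects the generative parameters for both phenotype tracks together with
#' the implied true intraclass correlations, so recovery tests can compare
#' estimates against known truth.
#'
#' @param sigma2_family,sigma2_center,sigma2_e Variance components of
#'   sqrt(age at onset): family, centre and residual variance on the
#'   square-root-years scale.  Defaults give a family-level residual ICC of
#'   0.278 conditional on centre.
#' @param beta0_aao Intercept of sqrt(age at onset) (default 5.1, i.e. onset
#'   near 26 years).
#' @param beta_sex_aao Fixed effect of sex on sqrt(age at onset).
#' @param nb_beta0 Intercept of the log episode rate per year of illness.
#' @param nb_beta_sex,nb_beta_age Fixed effects of sex and age on the log
#'   episode rate.
#' @param alpha Negative-binomial overdispersion (conditional variance
#'   `m + alpha * m^2`).
#' @param nb_sigma2_family Family random-intercept variance on the log-rate
#'   scale.
#' @param h2_snp True SNP heritability for genotype simulations (unused by
#'   the family table generator).
#' @return A `famvar_truth` list.  `icc_aao` is
#'   `sigma2_family / (sigma2_family + sigma2_e)`; `icc_count` is the
#'   closed-form count ICC at the per-year rate scale (see
#'   [carrasco_icc_value()]).
#' @export
sim_truth <- function(sigma2_family = 0.278, sigma2_center = 0.05,
                      sigma2_e = 0.722, beta0_aao = 5.1, beta_sex_aao = -0.1,
                      nb_beta0 = log(0.3), nb_beta_sex = 0.1,
                      nb_beta_age = 0, alpha = 0.5, nb_sigma2_family = 0.25,
                      h2_snp = 0.5) {
  vars <- c(sigma2_family, sigma2_center, sigma2_e, alpha, nb_sigma2_family)
  if (any(vars < 0)) stop("variances and overdispersion must be non-negative")
  if (h2_snp < 0 || h2_snp >= 1) stop("h2_snp must lie in [0, 1)")
  truth <- list(
    sigma2_family = sigma2_family, sigma2_center = sigma2_center,
    sigma2_e = sigma2_e, beta0_aao = beta0_aao, beta_sex_aao = beta_sex_aao,
    nb_beta0 = nb_beta0, nb_beta_sex = nb_beta_sex, nb_beta_age = nb_beta_age,
    alpha = alpha, nb_sigma2_family = nb_sigma2_family, h2_snp = h2_snp)
  truth$icc_aao <- if (sigma2_family + sigma2_e > 0)
    sigma2_family / (sigma2_family + sigma2_e) else 0
  truth$icc_count <- carrasco_icc_value(
    mu = exp(nb_beta0 + nb_sigma2_family / 2),
    sigma2 = nb_sigma2_family, alpha = alpha)
  class(truth) <- "famvar_truth"
  truth
}

#' Simulate an affected-sibling family phenotype table
#'
#' Generates `n_families` sibships of affected full siblings nested within
#' study centres.  sqrt(age at onset) follows a three-level Gaussian model
#' (centre + family random intercepts); onsets are floored at 5 years.  Age
#' equals onset plus a gamma-distributed illness duration (mean 19 y, sd
#' 10 y, floored at 0.5 y), which guarantees `aao <= age`, yields adult ages
#' centred near 45, and induces the sibling age-onset correlation seen in
#' affected-sibling data.  Lifetime episode counts are negative-binomial with
#' log-mean `nb_beta0 + nb_beta_sex*sex + nb_beta_age*age + log(duration) +
#' family effect`; under recurrent-case ascertainment counts are
#' zero-truncated by resampling.
#'
#' @param n_families Number of families (>= 2; default 691).
#' @param size_weights Probabilities of sibship sizes 2..5 (must sum to 1).
#' @param n_centers Number of study centres (default 8).
#' @param truth A [sim_truth()] object.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param truncate_counts Resample episode counts until >= 1 (default TRUE,
#'   mimicking recurrent-MDD ascertainment).
#' @param unit_exposure If TRUE, episode counts are generated with unit
#'   exposure (offset 0) instead of `log(duration)`; useful for calibration
#'   studies on the rate scale.
#' @return List with `table` (a data.frame with columns `subject_id`,
#'   `family_id`, `center_id`, `sex`, `age`, `aao`, `episode_count`,
#'   `duration`) and `truth`.
#' @export
simulate_family_phenotypes <- function(n_families = 691,
                                       size_weights = c(0.62, 0.25, 0.09, 0.04),
                                       n_centers = 8,
                                       truth = sim_truth(),
                                       seed = 1,
                                       truncate_counts = TRUE,
                                       unit_exposure = FALSE) {
  stopifnot(inherits(truth, "famvar_truth"))
  if (n_families < 2) stop("need at least 2 families")
  if (length(size_weights) != 4L || any(size_weights < 0))
    stop("size_weights must be 4 non-negative probabilities for sizes 2..5")
  if (abs(sum(size_weights) - 1) > 1e-8) stop("size_weights must sum to 1")
  if (n_centers < 1) stop("need at least one centre")

  set.seed(child_seed(seed, "family-phenotypes"))
  sizes <- sample(2:5, n_families, replace = TRUE, prob = size_weights)
  center_of_family <- sample.int(n_centers, n_families, replace = TRUE)
  fam <- rep(seq_len(n_families), sizes)
  n <- length(fam)

  u_center <- stats::rnorm(n_centers, 0, sqrt(truth$sigma2_center))
  u_family <- stats::rnorm(n_families, 0, sqrt(truth$sigma2_family))
  b_family <- stats::rnorm(n_families, 0, sqrt(truth$nb_sigma2_family))

  sex <- stats::rbinom(n, 1, 0.65)  # female-majority, typical of MDD samples
  sqrt_onset <- truth$beta0_aao + truth$beta_sex_aao * sex +
    u_center[center_of_family[fam]] + u_family[fam] +
    stats::rnorm(n, 0, sqrt(truth$sigma2_e))
  aao <- pmax(5, sqrt_onset^2)
  duration <- pmax(0.5, stats::rgamma(n, shape = 19^2 / 100, scale = 100 / 19))
  age <- aao + duration

  off <- if (unit_exposure) rep(0, n) else log_duration_offset(duration)
  eta <- truth$nb_beta0 + truth$nb_beta_sex * sex + truth$nb_beta_age * age +
    off + b_family[fam]
  episode_count <- draw_nb_counts(exp(eta), truth$alpha,
                                  truncate = truncate_counts)

  tab <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    family_id = sprintf("F%04d", fam),
    center_id = sprintf("C%02d", center_of_family[fam]),
    sex = sex,
    age = round(age, 1),
    aao = round(aao, 1),
    episode_count = episode_count,
    duration = round(age - aao, 1),
    stringsAsFactors = FALSE)
  # rounding age and onset to 0.1 y can leave duration marginally below the
  # generated floor; the analysis-side offset floor handles that
  list(table = tab, truth = truth)
}

# Conditional NB2 draw with optional zero truncation by resampling.
draw_nb_counts <- function(mu, alpha, truncate = TRUE) {
  y <- if (alpha <= 0) stats::rpois(length(mu), mu)
       else stats::rnbinom(length(mu), size = 1 / alpha, mu = mu)
  if (truncate) {
    for (it in 1:1000) {
      z <- which(y < 1L)
      if (!length(z)) break
      y[z] <- if (alpha <= 0) stats::rpois(length(z), mu[z])
              else stats::rnbinom(length(z), size = 1 / alpha, mu = mu[z])
    }
    y[y < 1L] <- 1L
  }
  y
}

#' Simulate sibling count data from the NB mixed model
#'
#' Low-level generator used for calibration and oracle studies: families of a
#' given size share one Gaussian log-rate intercept and counts are
#' conditionally NB2.  No covariates, no truncation.
#'
#' @param n_families Number of families.
#' @param size Siblings per family (scalar or vector of length `n_families`).
#' @param beta0 Log-mean intercept.
#' @param alpha NB2 overdispersion (0 gives Poisson).
#' @param sigma2 Family random-intercept variance.
#' @param offset_log Per-subject log-exposure (default 0).
#' @param seed Integer seed.
#' @return data.frame with `family_id`, `y`, `offset_log`.
#' @export
simulate_nb_families <- function(n_families, size = 2, beta0 = 0, alpha = 0.5,
                                 sigma2 = 0.1, offset_log = 0, seed = 1) {
  set.seed(child_seed(seed, "nb-families"))
  sizes <- rep_len(size, n_families)
  fam <- rep(seq_len(n_families), sizes)
  b <- stats::rnorm(n_families, 0, sqrt(sigma2))
  off <- rep_len(offset_log, length(fam))
  mu <- exp(beta0 + off + b[fam])
  data.frame(family_id = fam,
             y = draw_nb_counts(mu, alpha, truncate = FALSE),
             offset_log = off)
}

#' Write / read a family phenotype table
#'
#' Tab-separated text with a fixed header (`subject_id`, `family_id`,
#' `center_id`, `sex`, `age`, `aao`, `episode_count`, `duration`); missing
#' values are written as `NA`.
#'
#' @param table A family phenotype data.frame.
#' @param path File path.
#' @return `read_phenotype_table` returns the data.frame.
#' @export
write_phenotype_table <- function(table, path) {
  cols <- c("subject_id", "family_id", "center_id", "sex", "age", "aao",
            "episode_count", "duration")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  utils::write.table(table[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_phenotype_table
#' @export
read_phenotype_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA")
  check_phenotype_table(tab)
  tab
}

# Validates the structural invariants of a family phenotype table.
check_phenotype_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  need <- c("subject_id", "family_id", "center_id", "sex", "age", "aao")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  ok <- !is.na(tab$aao) & !is.na(tab$age)
  if (any(tab$aao[ok] > tab$age[ok] + 1e-8))
    stop("found rows with aao > age")
  centers_per_family <- tapply(tab$center_id, tab$family_id,
                               function(x) length(unique(x)))
  if (any(centers_per_family > 1L))
    stop("families must be nested within a single centre")
  invisible(tab)
}
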