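## End-to-end orchestration of the two analysis tracks, with structured
## report fragments suitable for JSON export.

famvar_default_config <- function() {
  list(maf_min = 0.01, grm_cutoff = 0.025, n_pcs = 10, n_quad = 7,
       duration_floor = 0.5, conf = 0.95, include_center_icc = FALSE)
}

# Merge user overrides into the default configuration.
resolve_config <- function(config = list()) {
  cfg <- famvar_default_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  cfg
}

icc_block <- function(icc, lrt = NULL, model = "", n = NA_integer_) {
  h2 <- maximal_heritability(icc)
  list(model = model, n = n,
       icc = icc$icc, se = icc$se,
       ci_low = icc$ci_low, ci_high = icc$ci_high,
       icc_method = icc$method,
       lrt_statistic = if (is.null(lrt)) NULL else lrt$statistic,
       lrt_p = if (is.null(lrt)) NULL else lrt$p_value,
       h2_max = h2$h2_max, h2_max_ci_low = h2$ci_low,
       h2_max_ci_high = h2$ci_high)
}

#' Run the familiality track on a family phenotype table
#'
#' Fits, per phenotype: the sqrt(age-at-onset) linear mixed model with sex
#' only and with sex + age (centre and family random intercepts); the
#' negative-binomial mixed model for episode counts with a log-duration
#' offset (full model: sex + age + centre dummies; reduced model: centre
#' dummies only, on which the count ICC is computed) together with its
#' Poisson comparison; and the log episode-frequency linear mixed model.
#' Each ICC is converted to a maximal-heritability bound.  Track failures
#' are caught and reported; the run continues.
#'
#' @param table A family phenotype data.frame (see
#'   [simulate_family_phenotypes()]).
#' @param config Named list of overrides of the defaults
#'   (`duration_floor = 0.5`, `n_quad = 7`, `conf = 0.95`,
#'   `include_center_icc = FALSE`).
#' @return List of report fragments: `aao_sex`, `aao_sex_age`,
#'   `episodicity_nb` (with `poisson_lrt_p`, `alpha`), `episodicity_lnfreq`,
#'   plus `n_input`.
#' @export
run_familiality <- function(table, config = list()) {
  cfg <- resolve_config(config)
  check_phenotype_table(table)
  out <- list(n_input = nrow(table))

  fit_aao <- function(with_age) {
    ok <- stats::complete.cases(table[c("aao", "sex", "age", "family_id",
                                        "center_id")])
    d <- table[ok, ]
    X <- cbind(intercept = 1, sex = d$sex)
    if (with_age) X <- cbind(X, age = d$age)
    fit <- fit_lmm_nested(sqrt_aao(d$aao), X, d$family_id, d$center_id)
    red <- drop_family_refit(fit)
    icc <- residual_icc(fit, include_center = cfg$include_center_icc,
                        conf = cfg$conf)
    icc_block(icc, lrt_family_variance(fit, red),
              model = if (with_age) "sqrtAAO ~ sex + age | center/family"
                      else "sqrtAAO ~ sex | center/family",
              n = nrow(d))
  }
  out$aao_sex <- tryCatch(fit_aao(FALSE), error = function(e)
    list(error = conditionMessage(e)))
  out$aao_sex_age <- tryCatch(fit_aao(TRUE), error = function(e)
    list(error = conditionMessage(e)))

  out$episodicity_nb <- tryCatch({
    ok <- stats::complete.cases(table[c("episode_count", "sex", "age",
                                        "family_id", "center_id")]) &
      !is.na(table$aao)
    d <- table[ok, ]
    if (!nrow(d) || all(is.na(d$episode_count)))
      stop("no usable episode counts")
    off <- log_duration_offset(d$age - d$aao, floor = cfg$duration_floor)
    cen <- stats::model.matrix(~ factor(center_id), d)  # intercept + dummies
    Xfull <- cbind(cen, sex = d$sex, age = d$age)
    colnames(Xfull)[1] <- "intercept"
    full <- fit_nb_glmm(d$episode_count, Xfull, off, d$family_id,
                        n_quad = cfg$n_quad, varpar_cov = FALSE)
    full0 <- fit_nb_glmm(d$episode_count, Xfull, off, d$family_id,
                         n_quad = cfg$n_quad, no_random = TRUE,
                         varpar_cov = FALSE)
    lrt_full <- list(statistic = max(0, 2 * (full$loglik - full0$loglik)))
    lrt_full$p_value <- 0.5 * stats::pchisq(lrt_full$statistic, 1,
                                            lower.tail = FALSE)
    pois <- poisson_vs_nb_comparison(d$episode_count, Xfull, off,
                                     d$family_id, n_quad = cfg$n_quad)
    Xred <- cen
    colnames(Xred)[1] <- "intercept"
    red <- fit_nb_glmm(d$episode_count, Xred, off, d$family_id,
                       n_quad = cfg$n_quad)
    icc <- carrasco_icc(red, conf = cfg$conf)
    blk <- icc_block(icc, lrt_full,
                     model = "episode_count ~ center + sex + age, offset ln(duration) | family (ICC on reduced model)",
                     n = nrow(d))
    blk$alpha <- red$alpha
    blk$sigma2_family <- red$sigma2_family
    blk$mu_marginal <- icc$mu_marginal
    blk$poisson_lrt_p <- pois$lrt_overdispersion$p_value
    blk
  }, error = function(e) list(error = conditionMessage(e)))

  out$episodicity_lnfreq <- tryCatch({
    ok <- stats::complete.cases(table[c("episode_count", "sex", "age",
                                        "family_id", "center_id")]) &
      !is.na(table$aao) & table$episode_count >= 1
    d <- table[ok, ]
    if (!nrow(d)) stop("no usable episode counts")
    y <- ln_episode_frequency(d$episode_count, d$age - d$aao,
                              floor = cfg$duration_floor)
    X <- cbind(intercept = 1, sex = d$sex, age = d$age)
    fit <- fit_lmm_nested(y, X, d$family_id, d$center_id)
    red <- drop_family_refit(fit)
    icc <- residual_icc(fit, include_center = cfg$include_center_icc,
                        conf = cfg$conf)
    icc_block(icc, lrt_family_variance(fit, red),
              model = "ln(episode frequency) ~ sex + age | center/family",
              n = nrow(d))
  }, error = function(e) list(error = conditionMessage(e)))
  out
}

#' Run the SNP-heritability track
#'
#' Full GREML chain on a genotype panel: MAF-filtered GRM, greedy
#' relatedness pruning, principal-component covariates, then AI-REML per
#' phenotype.  Phenotypes are residualised on any supplied covariate columns
#' (fixed-effects regression) and optionally rank-normalised with Blom
#' scores before GREML.  Per-stage filter counts are recorded, with exact
#' bookkeeping (`individuals_in = individuals_pruned + individuals_used`).
#'
#' @param genotypes A `famvar_genotypes` object, or a PLINK path prefix to
#'   read with [read_plink_bed()].
#' @param phenotypes data.frame with an `id` column and one numeric column
#'   per trait (ids must intersect the genotype ids).
#' @param rank_normalize Character vector of trait columns to Blom-transform
#'   after residualisation (default none).
#' @param covariate_cols Character vector of columns of `phenotypes` used to
#'   residualise every trait (default none).
#' @param config Named list of overrides (`maf_min = 0.01`,
#'   `grm_cutoff = 0.025`, `n_pcs = 10`).
#' @return List with `counts` (filter bookkeeping) and one fragment per
#'   trait: `h2`, `se`, `p`, `lrt`, `sigma2_g`, `sigma2_e`, `n_used`,
#'   `converged`.
#' @export
run_snp_h2 <- function(genotypes, phenotypes, rank_normalize = character(),
                       covariate_cols = character(), config = list()) {
  cfg <- resolve_config(config)
  if (is.character(genotypes)) genotypes <- read_plink_bed(genotypes)
  stopifnot(inherits(genotypes, "famvar_genotypes"),
            is.data.frame(phenotypes), "id" %in% names(phenotypes))
  ids <- intersect(genotypes$ids, phenotypes$id)
  if (!length(ids)) stop("no overlap between genotype and phenotype ids")

  grm <- compute_grm(genotypes, maf_min = cfg$maf_min)
  kept <- prune_relatedness(grm, cutoff = cfg$grm_cutoff)
  used_ids <- intersect(kept, ids)
  grm_used <- subset_grm(grm, used_ids)
  pcs <- grm_pca(grm_used, k = min(cfg$n_pcs, length(used_ids) - 1L))

  counts <- list(
    snps_in = nrow(genotypes$snps),
    snps_maf_filtered = grm$n_snps_excluded,
    snps_used = grm$n_snps_used,
    individuals_in = length(grm$ids),
    individuals_pruned = length(grm$ids) - length(kept),
    individuals_used = length(kept),
    individuals_analyzed = length(used_ids))

  ph <- phenotypes[match(used_ids, phenotypes$id), , drop = FALSE]
  traits <- setdiff(names(phenotypes), c("id", covariate_cols))
  out <- list(counts = counts)
  for (tr in traits) {
    out[[tr]] <- tryCatch({
      y <- ph[[tr]]
      ok <- !is.na(y)
      if (length(covariate_cols)) {
        C <- as.matrix(ph[covariate_cols])
        ok <- ok & stats::complete.cases(C)
        y <- stats::lm.fit(cbind(1, C[ok, , drop = FALSE]),
                           y[ok])$residuals
      } else y <- y[ok]
      if (tr %in% rank_normalize) y <- blom_rank_normalize(y)
      g2 <- subset_grm(grm_used, used_ids[ok])
      fit <- fit_greml(y, covariates = pcs[ok, , drop = FALSE], grm = g2)
      list(h2 = fit$h2, se = fit$se_h2, p = fit$p, lrt = fit$lrt,
           sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
           n_used = fit$n_used, converged = fit$converged,
           rank_normalized = tr %in% rank_normalize)
    }, error = function(e) list(error = conditionMessage(e)))
  }
  out
}

#' Assemble and validate an analysis report
#'
#' Collects fragments from the two tracks together with power calculations
#' and provenance, checks that every reported ICC/heritability lies in
#' \[0, 1\] and that all numeric leaves are finite, and (optionally) writes
#' the report as JSON text.
#'
#' @param familiality Output of [run_familiality()].
#' @param snp Output of [run_snp_h2()] (optional).
#' @param power Named list of power results (optional).
#' @param seed Root seed used for the run.
#' @param config Configuration used (defaults recorded when omitted).
#' @param path Optional path; when given the report is written as pretty
#'   JSON.
#' @return The report list, invisibly when written.
#' @export
assemble_report <- function(familiality = NULL, snp = NULL, power = NULL,
                            seed = NA_integer_, config = list(), path = NULL) {
  report <- list(
    familiality = familiality, snp = snp, power = power,
    provenance = list(
      seed = seed, config = resolve_config(config),
      package_version = as.character(utils::packageVersion("famvar")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  validate_report(report)
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    return(invisible(report))
  }
  report
}

#' @rdname assemble_report
#' @param report A report list.
#' @export
validate_report <- function(report) {
  walk <- function(x, path) {
    if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], paste(path, nm, sep = "/"))
    } else if (is.numeric(x) && !grepl("timestamp", path)) {
      if (any(!is.finite(x) & !is.na(x)))
        stop("non-finite numeric at ", path)
      if (grepl("(^|/)(icc|h2|h2_max)$", path) &&
          any(x < 0 | x > 1, na.rm = TRUE))
        stop("proportion out of [0, 1] at ", path)
    }
  }
  walk(report, "")
  invisible(TRUE)
}
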