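#' Mann-Whitney U test (exact or tie-corrected normal approximation)
#'
#' Two-sided rank-sum test. `U` is computed from midrank summation,
#' `U = R1 - n1 (n1 + 1) / 2` with `R1` the rank sum of `x`. When
#' `n1 + n2 <= exact_threshold` and there are no ties, the two-sided p-value
#' is exact: twice the smaller tail of the exact null distribution of `U`
#' (capped at 1). Otherwise a normal approximation is used with the usual
#' tie correction of the variance and a 0.5 continuity correction. The two
#' regimes agree closely near the threshold, which sits just above the
#' study-scale comparison of 11 vs 11 subjects.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact_threshold switch to the normal approximation above this
#'   combined sample size (default 16).
#' @return an object of class `mw_test`: list with `statistic` (U of `x`),
#'   `p_value`, `n1`, `n2`, `method` (`"exact"` or
#'   `"normal_approx_tie_corrected"`).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(x, y, exact_threshold = 16) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (n1 + n2 <= exact_threshold && !ties) {
    p_lo <- stats::pwilcox(U, n1, n2)
    p_hi <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    tt <- table(c(x, y))
    tie_term <- sum(tt^3 - tt) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1  # all observations identical
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx_tie_corrected"
  }
  structure(list(statistic = U, p_value = p, n1 = n1, n2 = n2,
                 method = method),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.4g (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$statistic, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Simple linear regression of a tortuosity index on a covariate
#'
#' Ordinary least squares `y ~ x` with the usual t-test on the slope.
#'
#' @param x covariate values (non-constant, `n >= 3` complete pairs).
#' @param y response values.
#' @return an object of class `ols_result`: `slope`, `intercept`,
#'   `slope_se`, `t_statistic`, `p_value`, `r_squared`, `n`.
#' @export
ols_regression <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x)[ok]; y <- as.numeric(y)[ok]
  n <- length(x)
  if (n < 3L) stop("regression needs at least 3 complete pairs")
  if (stats::var(x) == 0) stop("covariate is constant")
  if (stats::var(y) == 0) {
    # flat response: slope 0 with no explained variance
    return(structure(list(slope = 0, intercept = mean(y), slope_se = 0,
                          t_statistic = 0, p_value = 1, r_squared = 0,
                          n = n),
                     class = "ols_result"))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(slope = unname(co["x", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 slope_se = unname(co["x", "Std. Error"]),
                 t_statistic = unname(co["x", "t value"]),
                 p_value = unname(co["x", "Pr(>|t|)"]),
                 r_squared = sm$r.squared, n = n),
            class = "ols_result")
}

#' @export
print.ols_result <- function(x, ...) {
  cat(sprintf(
    "OLS: slope %.4g (SE %.3g), t = %.3g, p = %.4g, r^2 = %.3f, n = %d\n",
    x$slope, x$slope_se, x$t_statistic, x$p_value, x$r_squared, x$n))
  invisible(x)
}

#' Read a subjects table
#'
#' Reads the cohort CSV (`subject_id, group, sex, age` plus optional
#' systemic covariates `gfr`, `mwt`, `nyha`, `stroke` and free-text columns)
#' and validates it.
#'
#' @param path CSV file path.
#' @return a data frame of subject records.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("no such subjects file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "sex", "age")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("subjects table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in subjects table")
  if (any(!df$group %in% c("FD", "control")))
    stop("group must be 'FD' or 'control'")
  if (any(!df$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (any(df$age <= 0)) stop("ages must be positive")
  if ("gfr" %in% names(df) && any(df$gfr <= 0, na.rm = TRUE))
    stop("gfr must be positive when present")
  if ("nyha" %in% names(df) && any(!df$nyha %in% c(1:4, NA)))
    stop("nyha must be in 1..4 when present")
  df
}

#' The packaged case-series clinical table
#'
#' Returns the packaged fixture reproducing the published clinical table of
#' the 11 Fabry-disease patients (sex, age, NYHA class, interventricular
#' maximum wall thickness, GFR, stroke history, phenotype, cornea
#' verticillata, GLA mutation, therapy), transcribed verbatim.
#'
#' @return a data frame with one row per patient.
#' @export
fabry_table1 <- function() {
  read_subjects(system.file("extdata", "table1_subjects.csv",
                            package = "ocutort", mustWork = TRUE))
}

#' Demographic summary per group
#'
#' @param records subject records (data frame as from [read_subjects()]).
#' @return a data frame, one row per group: `n`, `n_male`, `n_female`,
#'   `age_mean`, `age_sd` (sample SD, `n - 1` denominator; `NA` for a single
#'   subject), `age_min`, `age_max`.
#' @examples
#' summarize_demographics(fabry_table1())
#' @export
summarize_demographics <- function(records) {
  if (nrow(records) < 1L) stop("need at least one record")
  out <- do.call(rbind, lapply(split(records, records$group), function(g) {
    data.frame(group = g$group[1L], n = nrow(g),
               n_male = sum(g$sex == "M"), n_female = sum(g$sex == "F"),
               age_mean = mean(g$age),
               age_sd = if (nrow(g) >= 2L) stats::sd(g$age) else NA_real_,
               age_min = min(g$age), age_max = max(g$age),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate segment-level metrics to the unit of analysis
#'
#' Averages metric values over the segments within each eye, then over the
#' two eyes, yielding one value per subject, site and metric (the default
#' unit of analysis, chosen so that the two correlated eyes of a subject do
#' not count as independent observations). With `unit = "eye"` the
#' aggregation stops at eye level. Subjects contributing a single eye at a
#' site are kept with a warning; sites with no segments for a subject are
#' simply absent from the output.
#'
#' @param metrics a metrics table as from [tortuosity_table()].
#' @param unit `"subject"` (default) or `"eye"`.
#' @param values metric columns to aggregate.
#' @return a data frame with one row per subject (x eye) x site and one
#'   column per metric.
#' @export
aggregate_to_subject <- function(metrics, unit = c("subject", "eye"),
                                 values = c("soam", "pad", "i2e")) {
  unit <- match.arg(unit)
  need <- c("subject_id", "eye", "site", values)
  miss <- setdiff(need, names(metrics))
  if (length(miss))
    stop("metrics table is missing columns: ", paste(miss, collapse = ", "))
  by_eye <- stats::aggregate(metrics[values],
                             by = metrics[c("subject_id", "eye", "site")],
                             FUN = mean)
  if (unit == "eye") return(by_eye)
  n_eyes <- stats::aggregate(list(n_eyes = by_eye$eye),
                             by = by_eye[c("subject_id", "site")],
                             FUN = function(e) length(unique(e)))
  single <- n_eyes[n_eyes$n_eyes < 2L, , drop = FALSE]
  if (nrow(single) > 0L)
    warning("single-eye aggregation for: ",
            paste(sprintf("%s/%s", single$subject_id, single$site),
                  collapse = ", "), call. = FALSE)
  out <- stats::aggregate(by_eye[values],
                          by = by_eye[c("subject_id", "site")], FUN = mean)
  out
}

#' Statistical-analysis configuration
#'
#' @param alpha significance level (default 0.05; no multiplicity
#'   correction is applied anywhere, since every test compares two groups).
#' @param aggregation unit of analysis, `"subject"` or `"eye"`.
#' @param exact_threshold see [mann_whitney()].
#' @return an object of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, aggregation = c("subject", "eye"),
                         exact_threshold = 16) {
  aggregation <- match.arg(aggregation)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(alpha = alpha, aggregation = aggregation,
                 exact_threshold = exact_threshold),
            class = "stats_config")
}

#' Run the full case-control tortuosity analysis
#'
#' Executes, per tortuosity index and ocular site: the FD-vs-control
#' Mann-Whitney comparison; the male-vs-female comparison within each group;
#' OLS regressions of the index on age (within each group) and on the
#' systemic covariates GFR, MWT (and MSSI when a column of that name is
#' present) within the FD group; and, per index, the regression of the
#' mean conjunctival value on the retinal value across all subjects.
#' Comparisons that cannot be run (missing covariate, too few observations,
#' constant covariate) are recorded in `skipped` with a reason, never
#' silently dropped. p-values below `alpha` are flagged significant; no
#' multiple-testing correction is applied.
#'
#' @param metrics segment-level metrics table ([tortuosity_table()]).
#' @param subjects subject records ([read_subjects()] or
#'   `gen_cohort()$subjects`).
#' @param config a [stats_config()].
#' @return an object of class `study_report`: list with data frames `tests`
#'   (`comparison, site, metric, n1, n2, statistic, p_value, method,
#'   significant`), `regressions` (`comparison, site, metric, covariate,
#'   slope, intercept, slope_se, t_statistic, p_value, r_squared, n,
#'   significant`), `skipped` (`comparison, site, metric, reason`),
#'   `demographics`, plus the aggregated per-subject table and the
#'   configuration.
#' @export
run_study <- function(metrics, subjects, config = stats_config()) {
  stopifnot(inherits(config, "stats_config"))
  if (!all(metrics$subject_id %in% subjects$subject_id))
    stop("metrics table contains subject_ids absent from the subjects table")
  values <- c("soam", "pad", "i2e")
  agg <- aggregate_to_subject(metrics, unit = config$aggregation,
                              values = values)
  agg <- merge(agg, subjects, by = "subject_id")
  sites <- sort(unique(agg$site))
  tests <- list(); regs <- list(); skipped <- list()
  note_skip <- function(comparison, site, metric, reason)
    data.frame(comparison = comparison, site = site, metric = metric,
               reason = reason, stringsAsFactors = FALSE)
  add_test <- function(comparison, site, metric, x, y) {
    if (length(x) < 1L || length(y) < 1L)
      return(note_skip(comparison, site, metric, "empty group"))
    tt <- mann_whitney(x, y, config$exact_threshold)
    data.frame(comparison = comparison, site = site, metric = metric,
               n1 = tt$n1, n2 = tt$n2, statistic = tt$statistic,
               p_value = tt$p_value, method = tt$method,
               significant = tt$p_value < config$alpha,
               stringsAsFactors = FALSE)
  }
  add_reg <- function(comparison, site, metric, covariate, x, y) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L)
      return(note_skip(comparison, site, metric,
                       sprintf("fewer than 3 complete pairs for %s",
                               covariate)))
    if (stats::var(x[ok]) == 0)
      return(note_skip(comparison, site, metric,
                       sprintf("covariate %s is constant", covariate)))
    rr <- ols_regression(x, y)
    data.frame(comparison = comparison, site = site, metric = metric,
               covariate = covariate, slope = rr$slope,
               intercept = rr$intercept, slope_se = rr$slope_se,
               t_statistic = rr$t_statistic, p_value = rr$p_value,
               r_squared = rr$r_squared, n = rr$n,
               significant = rr$p_value < config$alpha,
               stringsAsFactors = FALSE)
  }
  push <- function(lst, el) c(lst, list(el))
  for (site in sites) {
    a <- agg[agg$site == site, , drop = FALSE]
    for (metric in values) {
      res <- add_test("FD_vs_control", site, metric,
                      a[[metric]][a$group == "FD"],
                      a[[metric]][a$group == "control"])
      if ("reason" %in% names(res)) skipped <- push(skipped, res)
      else tests <- push(tests, res)
      for (grp in c("FD", "control")) {
        g <- a[a$group == grp, , drop = FALSE]
        res <- add_test(paste0("M_vs_F_", grp), site, metric,
                        g[[metric]][g$sex == "M"],
                        g[[metric]][g$sex == "F"])
        if ("reason" %in% names(res)) skipped <- push(skipped, res)
        else tests <- push(tests, res)
        res <- add_reg(paste0("age_", grp), site, metric, "age",
                       g$age, g[[metric]])
        if ("reason" %in% names(res)) skipped <- push(skipped, res)
        else regs <- push(regs, res)
      }
      fd <- a[a$group == "FD", , drop = FALSE]
      for (cov in c("gfr", "mwt", "mssi")) {
        if (!cov %in% names(fd)) {
          if (cov != "mssi")  # mssi is an optional extra column
            skipped <- push(skipped, note_skip(
              "systemic_FD", site, metric,
              sprintf("covariate %s not available", cov)))
          next
        }
        res <- add_reg("systemic_FD", site, metric, cov, fd[[cov]],
                       fd[[metric]])
        if ("reason" %in% names(res)) skipped <- push(skipped, res)
        else regs <- push(regs, res)
      }
    }
  }
  # retina vs mean-conjunctival association, per metric, across subjects
  conj_sites <- grep("^conj_", sites, value = TRUE)
  if ("retina" %in% sites && length(conj_sites) > 0L) {
    for (metric in values) {
      ret <- agg[agg$site == "retina", c("subject_id", metric)]
      conj <- stats::aggregate(agg[agg$site %in% conj_sites, metric,
                                   drop = FALSE],
                               by = agg[agg$site %in% conj_sites,
                                        "subject_id", drop = FALSE],
                               FUN = mean)
      both <- merge(ret, conj, by = "subject_id",
                    suffixes = c("_retina", "_conj"))
      res <- add_reg("retina_vs_conjunctiva", "all", metric, "retina",
                     both[[paste0(metric, "_retina")]],
                     both[[paste0(metric, "_conj")]])
      if ("reason" %in% names(res)) skipped <- push(skipped, res)
      else regs <- push(regs, res)
    }
  } else {
    skipped <- push(skipped, note_skip(
      "retina_vs_conjunctiva", "all", "all",
      "needs both retinal and conjunctival sites"))
  }
  bind <- function(lst) if (length(lst)) do.call(rbind, lst) else NULL
  structure(list(tests = bind(tests), regressions = bind(regs),
                 skipped = bind(skipped),
                 demographics = summarize_demographics(subjects),
                 aggregated = agg, config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Case-control vessel tortuosity study\n")
  d <- x$demographics
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %s: n = %d (%dM/%dF), age %.1f +/- %s [%g-%g]\n",
                d$group[i], d$n[i], d$n_male[i], d$n_female[i],
                d$age_mean[i],
                if (is.na(d$age_sd[i])) "NA" else sprintf("%.1f",
                                                          d$age_sd[i]),
                d$age_min[i], d$age_max[i]))
  nt <- if (is.null(x$tests)) 0L else nrow(x$tests)
  nr <- if (is.null(x$regressions)) 0L else nrow(x$regressions)
  ns <- if (is.null(x$skipped)) 0L else nrow(x$skipped)
  cat(sprintf("  %d rank tests, %d regressions, %d skipped\n", nt, nr, ns))
  sig <- x$tests[x$tests$significant, , drop = FALSE]
  if (!is.null(sig) && nrow(sig)) {
    cat(sprintf("  significant at alpha = %g:\n", x$config$alpha))
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    %-16s %-14s %-5s p = %.4g\n", sig$comparison[i],
                  sig$site[i], sig$metric[i], sig$p_value[i]))
  } else {
    cat(sprintf("  nothing significant at alpha = %g\n", x$config$alpha))
  }
  invisible(x)
}

#' @export
summary.study_report <- function(object, ...) {
  print(object)
  if (!is.null(object$skipped) && nrow(object$skipped)) {
    cat("skipped comparisons:\n")
    print(object$skipped, row.names = FALSE)
  }
  invisible(object)
}

#' @export
as.data.frame.study_report <- function(x, ...) {
  tests <- x$tests
  regs <- x$regressions
  out <- list()
  if (!is.null(tests)) out <- c(out, list(tests[c(
    "comparison", "site", "metric", "n1", "n2", "statistic", "p_value",
    "method", "significant")]))
  if (!is.null(regs)) {
    rr <- data.frame(comparison = paste(regs$comparison, regs$covariate,
                                        sep = ":"),
                     site = regs$site, metric = regs$metric,
                     n1 = regs$n, n2 = NA_integer_,
                     statistic = regs$t_statistic, p_value = regs$p_value,
                     method = "ols_t", significant = regs$significant,
                     stringsAsFactors = FALSE)
    out <- c(out, list(rr))
  }
  do.call(rbind, out)
}

#' @export
plot.study_report <- function(x, ...) {
  df <- as.data.frame(x)
  df <- df[order(df$p_value), , drop = FALSE]
  lab <- sprintf("%s %s %s", df$comparison, df$site, df$metric)
  graphics::dotchart(-log10(df$p_value), labels = lab,
                     xlab = "-log10 p", pch = ifelse(df$significant, 19, 1),
                     cex = 0.6, ...)
  graphics::abline(v = -log10(x$config$alpha), lty = 2)
  invisible(x)
}

#' Rejection rate of the pipeline statistic over simulated cohorts
#'
#' Repeatedly simulates a cohort, runs the measurement pipeline (centerline
#' generation, tortuosity metrics, subject-level aggregation) and the
#' FD-vs-control Mann-Whitney test for one index at one site, and returns
#' the fraction of replicates with `p < alpha`. With
#' `effect_multiplier = 1` this estimates the type-I error of the whole
#' pipeline; with an injected effect it estimates power.
#'
#' @param cp a [cohort_params()]; its `rng_seed` is ignored (per-replicate
#'   seeds are derived from `rng_seed` below).
#' @param n_reps number of simulated cohorts.
#' @param metric index tested (default `"soam"`).
#' @param site site tested (default `"retina"`; must be in `cp$sites`).
#' @param alpha significance level.
#' @param rng_seed base seed; replicate `i` uses `rng_seed + i`.
#' @param return_pvalues return the p-values instead of the rate.
#' @return the rejection rate (or the vector of p-values).
#' @export
simulate_rejection_rate <- function(cp, n_reps = 200, metric = "soam",
                                    site = "retina", alpha = 0.05,
                                    rng_seed = 1, return_pvalues = FALSE) {
  stopifnot(inherits(cp, "cohort_params"), site %in% cp$sites)
  mc <- metric_config(resample_spacing_px = cp$sample_spacing_px)
  pvals <- vapply(seq_len(n_reps), function(i) {
    cp$rng_seed <- rng_seed + i
    co <- gen_cohort(cp)
    keep <- vapply(co$traces, function(tr) tr$site == site, logical(1L))
    mt <- tortuosity_table(co$traces[keep], mc)
    agg <- suppressWarnings(aggregate_to_subject(mt, values = metric))
    agg <- merge(agg, co$subjects[c("subject_id", "group")],
                 by = "subject_id")
    mann_whitney(agg[[metric]][agg$group == "FD"],
                 agg[[metric]][agg$group == "control"])$p_value
  }, numeric(1L))
  if (return_pvalues) pvals else mean(pvals < alpha)
}
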