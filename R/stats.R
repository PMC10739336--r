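## Statistical layer: normality screening, Poisson GLMs on log-scaled
## predictors, and habitat-group comparisons (Kruskal-Wallis + Dunn).

#' Normality screen for a summary variable
#'
#' Shapiro-Wilk test plus adjusted Fisher-Pearson sample skewness, used to
#' justify the switch from Gaussian to count models for the genus-level
#' MDC summaries.
#'
#' @param values Numeric vector, `n >= 3`.
#' @return A one-row tibble: `n`, `shapiro_w`, `shapiro_p`, `skewness`.
#' @importFrom stats shapiro.test
#' @export
normality_gate <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) abort("normality_gate needs n >= 3")
  if (length(unique(values)) == 1) {
    abort("values are constant; normality test is degenerate")
  }
  sw <- shapiro.test(values)
  tibble(
    n = length(values),
    shapiro_w = unname(sw$statistic),
    shapiro_p = sw$p.value,
    skewness = e1071::skewness(values, type = 2)
  )
}

#' Poisson regression of a count summary on a log-scaled predictor
#'
#' Fits a log-link Poisson GLM `response ~ log(predictor)` (base 10 by
#' default). The slope is reported on the log10-predictor scale along with
#' its natural-log equivalent, the Wald chi-square statistic
#' `(slope / se)^2`, the model log-likelihood and the likelihood-ratio
#' chi-square against the intercept-only model.
#'
#' @param data A data frame.
#' @param response Count outcome column (tidy-eval). Non-integer values are
#'   rounded to the nearest integer when `round = TRUE` (the default, for
#'   mean-type summaries); with `round = FALSE` non-integer counts are an
#'   error.
#' @param predictor Positive predictor column (tidy-eval), log-scaled
#'   internally.
#' @param log_base Base for the predictor log scale (default 10).
#' @param round Round the response to integers before fitting.
#' @return An object of class `mdc_glm`; see [tidy.mdc_glm()] and
#'   [glance.mdc_glm()].
#' @importFrom stats glm poisson pchisq logLik coef
#' @export
poisson_glm <- function(data, response, predictor, log_base = 10,
                        round = TRUE) {
  y <- dplyr::pull(data, {{ response }})
  x <- dplyr::pull(data, {{ predictor }})
  if (any(is.na(y)) || any(is.na(x))) abort("NA in response or predictor")
  if (any(y < 0)) abort("response must be non-negative counts")
  if (round) {
    y <- round(y)
  } else if (any(y != floor(y))) {
    abort("response contains non-integer counts (set round = TRUE)")
  }
  if (any(x <= 0)) abort("predictor must be strictly positive (log scale)")
  lx <- log(x, base = log_base)
  fit <- glm(y ~ lx, family = poisson())
  if (!fit$converged) abort("Poisson GLM did not converge")
  sm <- summary(fit)$coefficients
  slope <- sm["lx", "Estimate"]
  se <- sm["lx", "Std. Error"]
  wald <- (slope / se)^2
  chi2 <- fit$null.deviance - fit$deviance
  structure(
    list(fit = fit,
         response = as_name(enquo(response)),
         predictor = as_name(enquo(predictor)),
         log_base = log_base,
         n = length(y),
         intercept = unname(coef(fit)[1]),
         slope = slope,
         slope_se = se,
         slope_ln = slope / log(log_base),
         wald_stat = wald,
         p_value = pchisq(wald, df = 1, lower.tail = FALSE),
         loglik = as.numeric(logLik(fit)),
         chi2 = chi2,
         chi2_p = pchisq(chi2, df = 1, lower.tail = FALSE)),
    class = "mdc_glm"
  )
}

#' @export
print.mdc_glm <- function(x, ...) {
  cat("Poisson GLM:", x$response, "~ log", x$log_base, "(",
      x$predictor, "), n =", x$n, "\n")
  cat(sprintf("  slope = %.4g +/- %.2g (SE), Wald chi2 = %.4g, p = %.3g\n",
              x$slope, x$slope_se, x$wald_stat, x$p_value))
  cat(sprintf("  log-likelihood = %.4f, LR chi2 = %.4g, p = %.3g\n",
              x$loglik, x$chi2, x$chi2_p))
  invisible(x)
}

#' Tidy a Poisson MDC model
#'
#' @param x An `mdc_glm` object.
#' @param ... Unused.
#' @return One row per model term with estimate, SE, Wald statistic and p.
#' @export
tidy.mdc_glm <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = c("(Intercept)", paste0("log", x$log_base, "(", x$predictor, ")")),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname((sm[, "Estimate"] / sm[, "Std. Error"])^2),
    p.value = pchisq((sm[, "Estimate"] / sm[, "Std. Error"])^2, 1,
                     lower.tail = FALSE) |> unname()
  )
}

#' Model-level summary of a Poisson MDC model
#'
#' @param x An `mdc_glm` object.
#' @param ... Unused.
#' @return A one-row tibble with log-likelihood, LR chi-square vs the
#'   intercept-only model, and sample size.
#' @export
glance.mdc_glm <- function(x, ...) {
  tibble(
    logLik = x$loglik,
    chi2 = x$chi2,
    chi2_p = x$chi2_p,
    deviance = x$fit$deviance,
    null.deviance = x$fit$null.deviance,
    nobs = x$n
  )
}

#' Habitat-group comparison of a genus-level variable
#'
#' Kruskal-Wallis test (tie-corrected) across habitat groups, followed by
#' Dunn's pairwise z tests with Bonferroni-adjusted p values (capped at 1).
#' Groups with fewer than 2 observations are excluded with a warning.
#'
#' @param data A data frame.
#' @param values Numeric column (tidy-eval), e.g. mean pairwise identity.
#' @param groups Grouping column (tidy-eval), e.g. habitat category.
#' @return An object of class `habitat_test` with `h_stat`, `df`,
#'   `p_value` and a `dunn` tibble (`group1`, `group2`, `z`, `p_value`,
#'   `p_adj`).
#' @importFrom stats kruskal.test pnorm
#' @export
habitat_comparison <- function(data, values, groups) {
  v <- dplyr::pull(data, {{ values }})
  g <- as.character(dplyr::pull(data, {{ groups }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(paste0("excluding group(s) with < 2 observations: ",
                paste(small, collapse = ", ")))
    keep <- !(g %in% small)
    v <- v[keep]; g <- g[keep]
  }
  lv <- unique(g)
  if (length(lv) < 2) abort("need at least 2 groups with >= 2 observations")
  kw <- kruskal.test(v, factor(g))
  dunn <- .dunn_test(v, g)
  structure(
    list(h_stat = unname(kw$statistic),
         df = unname(kw$parameter),
         p_value = kw$p.value,
         n = length(v),
         groups = sort(lv),
         dunn = dunn),
    class = "habitat_test"
  )
}

## Dunn's test: pairwise z on mean ranks with tie correction; Bonferroni
## over the number of pairs.
.dunn_test <- function(v, g) {
  r <- rank(v)
  N <- length(v)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- sort(unique(g))
  m <- length(lv) * (length(lv) - 1) / 2
  pairs <- combn(lv, 2)
  map_dfr(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    n1 <- sum(g == g1); n2 <- sum(g == g2)
    rb1 <- mean(r[g == g1]); rb2 <- mean(r[g == g2])
    sigma <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n1 + 1 / n2))
    z <- (rb1 - rb2) / sigma
    p <- 2 * pnorm(-abs(z))
    tibble(group1 = g1, group2 = g2, z = z,
           p_value = p, p_adj = pmin(1, m * p))
  })
}

#' @export
print.habitat_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H(%d, N = %d) = %.3f; p = %.3f\n",
              x$df, x$n, x$h_stat, x$p_value))
  cat("Dunn pairwise comparisons (Bonferroni-adjusted):\n")
  print(x$dunn)
  invisible(x)
}

#' @rdname habitat_comparison
#' @param x A `habitat_test` object.
#' @param ... Unused.
#' @export
tidy.habitat_test <- function(x, ...) x$dunn

#' @rdname habitat_comparison
#' @export
glance.habitat_test <- function(x, ...) {
  tibble(statistic = x$h_stat, df = x$df, p.value = x$p_value, nobs = x$n)
}
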