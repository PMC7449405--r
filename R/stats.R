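# Phenotype statistics: rank inverse normal transformation, per-cohort linear
# models, inverse-variance fixed-effects and DerSimonian-Laird random-effects
# meta-analysis with I^2 heterogeneity, and Bonferroni thresholds.

#' Rank inverse normal transformation (Blom offset)
#'
#' Maps values to normal quantiles of their ranks:
#' `qnorm((rank - 3/8) / (n + 1/4))`, ties receiving average ranks. The
#' transform is monotone, so output rank order equals input rank order.
#'
#' @param values Numeric vector with at least 3 finite values; must not be
#'   constant.
#' @return Transformed vector in standard-deviation units.
#' @export
rank_inverse_normal <- function(values) {
  if (length(values) < 3L || any(!is.finite(values)))
    stop("need at least 3 finite values", call. = FALSE)
  if (length(unique(values)) == 1L)
    stop("all values are identical; the transformation is undefined",
         call. = FALSE)
  r <- rank(values, ties.method = "average")
  qnorm((r - 3 / 8) / (length(values) + 1 / 4))
}

#' Ordinary least-squares fit with per-term tests
#'
#' @param response Numeric response vector, or a formula (then `design` is the
#'   data).
#' @param design Data.frame of covariates (an intercept is added), or the data
#'   for the formula interface.
#' @return A data.frame (term, beta, se, t, p) with two-sided p-values from
#'   the t distribution on the residual degrees of freedom.
#' @export
fit_linear_model <- function(response, design) {
  if (inherits(response, "formula")) {
    fit <- lm(response, data = design)
  } else {
    design <- as.data.frame(design)
    if (ncol(design) > 0L && nrow(design) != length(response))
      stop("response and design have different lengths", call. = FALSE)
    if (ncol(design) == 0L) {
      fit <- lm(response ~ 1)
    } else {
      dat <- cbind(.response = response, design)
      fit <- lm(.response ~ ., data = dat)
    }
  }
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (fit$df.residual < 1L)
    stop("more model terms than observations", call. = FALSE)
  s <- summary(fit)$coefficients
  data.frame(term = rownames(s), beta = s[, 1], se = s[, 2], t = s[, 3],
             p = s[, 4], row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-cohort effect estimates
#'
#' Convenience container for meta-analysis input.
#'
#' @param cohort Identifier.
#' @param beta Effect estimate.
#' @param se Standard error (> 0).
#' @param n Sample size.
#' @return A one-row data.frame of class `effect_estimate`.
#' @export
effect_estimate <- function(cohort, beta, se, n = NA_integer_) {
  if (!is.finite(se) || se <= 0) stop("`se` must be positive", call. = FALSE)
  structure(data.frame(cohort = cohort, beta = beta, se = se, n = n,
                       stringsAsFactors = FALSE),
            class = c("effect_estimate", "data.frame"))
}

check_estimates <- function(estimates, min_k) {
  est <- as.data.frame(estimates)
  stopifnot(all(c("beta", "se") %in% names(est)))
  if (any(!is.finite(est$se) | est$se <= 0))
    stop("every study standard error must be positive", call. = FALSE)
  if (nrow(est) < min_k)
    stop("need at least ", min_k, " studies", call. = FALSE)
  est
}

meta_result <- function(beta, se, tau2, q, k, model) {
  z <- beta / se
  structure(list(beta_pooled = beta, se_pooled = se,
                 p_value = 2 * pnorm(-abs(z)),
                 tau2 = tau2,
                 i2_percent = if (k >= 2L) i_squared(q, k - 1L) else 0,
                 q_stat = q, k_studies = k, model = model),
            class = "meta_result")
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Weights `w_i = 1/se_i^2`; pooled beta is the weighted mean and
#' `se_pooled = 1/sqrt(sum w_i)`; two-sided p from the normal approximation.
#'
#' @param estimates Data.frame with columns cohort, beta, se (one row per
#'   study; k >= 1).
#' @return A `meta_result` with `tau2 = 0`.
#' @export
fixed_effects_meta <- function(estimates) {
  est <- check_estimates(estimates, 1L)
  w <- 1 / est$se^2
  beta <- sum(w * est$beta) / sum(w)
  q <- sum(w * (est$beta - beta)^2)
  meta_result(beta, sqrt(1 / sum(w)), tau2 = 0, q = q, k = nrow(est),
              model = "fixed")
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Computes `Q = sum w_i (beta_i - beta_FE)^2` with fixed-effects weights,
#' estimates the between-study variance
#' `tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`, re-weights with
#' `w*_i = 1/(se_i^2 + tau^2)` and pools. When `Q <= k-1` the estimate
#' truncates to zero and the result coincides with fixed effects.
#'
#' @param estimates Data.frame with columns cohort, beta, se (k >= 2).
#' @return A `meta_result`.
#' @export
random_effects_meta <- function(estimates) {
  est <- check_estimates(estimates, 2L)
  k <- nrow(est)
  w <- 1 / est$se^2
  beta_fe <- sum(w * est$beta) / sum(w)
  q <- sum(w * (est$beta - beta_fe)^2)
  c_denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (c_denom > 0) max(0, (q - (k - 1)) / c_denom) else 0
  ws <- 1 / (est$se^2 + tau2)
  beta <- sum(ws * est$beta) / sum(ws)
  meta_result(beta, sqrt(1 / sum(ws)), tau2 = tau2, q = q, k = k,
              model = "random")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %s-effects over %d studies\n", x$model, x$k_studies))
  cat(sprintf("  beta %.4f (se %.4f), p = %.3g\n", x$beta_pooled, x$se_pooled,
              x$p_value))
  cat(sprintf("  Q = %.3f, tau^2 = %.4f, I^2 = %.1f%%\n", x$q_stat, x$tau2,
              x$i2_percent))
  invisible(x)
}

#' @export
summary.meta_result <- function(object, ...) {
  data.frame(model = object$model, k = object$k_studies,
             beta_pooled = object$beta_pooled, se_pooled = object$se_pooled,
             p_value = object$p_value, tau2 = object$tau2,
             i2_percent = object$i2_percent, q_stat = object$q_stat)
}

#' Heterogeneity I-squared
#'
#' Proportion of meta-analysis variance attributable to between-study
#' heterogeneity: `I^2 = max(0, (Q - df)/Q) * 100` (percent, truncated at 0).
#'
#' @param q_stat Cochran's Q (non-negative).
#' @param df Degrees of freedom (k - 1, at least 1).
#' @return Percent in \[0, 100\].
#' @export
i_squared <- function(q_stat, df) {
  if (df < 1) stop("df must be at least 1", call. = FALSE)
  if (q_stat < 0) stop("q_stat must be non-negative", call. = FALSE)
  if (q_stat == 0) return(0)
  max(0, (q_stat - df) / q_stat) * 100
}

#' Bonferroni per-test threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m_tests Number of tests (>= 1).
#' @param signif_digits Optional rounding for presentation (e.g. 2 reproduces
#'   printed thresholds like 2.6e-3).
#' @return `alpha / m_tests`, optionally rounded to significant figures.
#' @export
bonferroni_threshold <- function(alpha, m_tests, signif_digits = NULL) {
  assert_scalar_number(alpha, "alpha", 0, 1, strict_lower = TRUE,
                       strict_upper = TRUE)
  m_tests <- assert_count(m_tests, "m_tests", min = 1L)
  out <- alpha / m_tests
  if (!is.null(signif_digits)) out <- signif(out, signif_digits)
  out
}

#' Per-cohort association then random-effects meta-analysis
#'
#' Fits, within each cohort, a linear model of the (optionally RINT-
#' standardized) response on the term of interest plus covariates, and pools
#' the per-cohort coefficients with [random_effects_meta()] (or
#' [fixed_effects_meta()]).
#'
#' @param data Phenotype table with a `cohort` column.
#' @param response Name of the response column.
#' @param term Name of the coefficient of interest (e.g. "depotvisc" for the
#'   depot contrast); matched against the fitted term names.
#' @param covariates Character vector of covariate column names (the term's
#'   own column is added automatically).
#' @param rint Apply [rank_inverse_normal()] to the response within cohort.
#' @param model "random" (default) or "fixed".
#' @param standardize_bmi Standardize a `BMI` covariate within cohort so its
#'   slope is per SD of BMI.
#' @return A list with `per_cohort` (data.frame of class effect rows) and
#'   `meta` (a `meta_result`).
#' @export
meta_association <- function(data, response, term, covariates = character(0),
                             rint = FALSE, model = c("random", "fixed"),
                             standardize_bmi = TRUE) {
  model <- match.arg(model)
  rows <- lapply(split(data, data$cohort), function(d) {
    y <- d[[response]]
    if (rint) y <- rank_inverse_normal(y)
    columns <- unique(c(term_column(term, d), covariates))
    design <- d[, columns, drop = FALSE]
    if (standardize_bmi && "BMI" %in% names(design))
      design$BMI <- as.numeric(scale(design$BMI))
    fit <- fit_linear_model(y, design)
    hit <- fit[fit$term == term | make.names(fit$term) == make.names(term), ,
               drop = FALSE]
    if (nrow(hit) != 1L)
      stop("term `", term, "` not found among: ",
           paste(fit$term, collapse = ", "), call. = FALSE)
    data.frame(cohort = d$cohort[1], beta = hit$beta, se = hit$se,
               n = nrow(d), stringsAsFactors = FALSE)
  })
  per_cohort <- do.call(rbind, rows)
  rownames(per_cohort) <- NULL
  meta <- if (model == "random" && nrow(per_cohort) >= 2L)
    random_effects_meta(per_cohort) else fixed_effects_meta(per_cohort)
  list(per_cohort = per_cohort, meta = meta)
}

# find the data column generating a model term (e.g. depotvisc <- depot)
term_column <- function(term, data) {
  hit <- names(data)[vapply(names(data), function(nm) startsWith(term, nm),
                            logical(1))]
  if (!length(hit)) stop("no data column generates term `", term, "`",
                         call. = FALSE)
  hit[which.max(nchar(hit))]
}
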