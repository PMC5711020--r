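#' Ordinary least squares with sequential (Type-1) sums of squares
#'
#' Fits `response ~ term1 + term2 + ...` by OLS with the terms entering in
#' the stated order, and reports the sequential ANOVA decomposition: each
#' term's sum of squares is the reduction in residual SS when it enters
#' after the preceding terms, F = (delta SS / delta df) / residual MSE, and p
#' from the F distribution. Factor terms with fewer than two observed levels
#' are dropped with a warning; rank-deficient designs are handled by
#' pivoting (aliased coefficients are flagged).
#'
#' @param data data.frame holding the response and all terms.
#' @param response name of the response column.
#' @param terms character vector of column names, in entry order.
#' @return An object of class `glm_fit`: the underlying `lm` fit plus the
#'   sequential ANOVA table (`anova`), residual `mse` and `df_residual`,
#'   coefficient vector, and bookkeeping of dropped/aliased terms.
#' @export
fit_glm <- function(data, response, terms) {
  data <- as.data.frame(data)
  stopifnot(response %in% names(data), all(terms %in% names(data)))
  dropped <- character()
  keep <- character()
  for (t in terms) {
    v <- data[[t]]
    if (is.character(v)) data[[t]] <- v <- factor(v)
    if (is.factor(v)) {
      data[[t]] <- v <- droplevels(v)
      if (nlevels(v) < 2) {
        warning("dropping term '", t, "': fewer than 2 observed levels")
        dropped <- c(dropped, t)
        next
      }
    }
    keep <- c(keep, t)
  }
  if (length(keep) == 0) stop("no usable model terms")
  fml <- stats::reformulate(keep, response = response)
  fit <- stats::lm(fml, data = data)
  if (stats::df.residual(fit) <= 0) {
    stop("no residual degrees of freedom (n <= model df)")
  }
  an <- stats::anova(fit)
  aliased <- any(is.na(stats::coef(fit)))
  if (aliased) {
    warning("rank-deficient design: aliased coefficients set by pivoting")
  }
  structure(list(fit = fit, anova = an,
                 mse = an["Residuals", "Mean Sq"],
                 df_residual = stats::df.residual(fit),
                 coefficients = stats::coef(fit),
                 terms = keep, dropped = dropped, aliased = aliased,
                 data = data, response = response),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("<glm_fit> ", deparse(stats::formula(x$fit)), "\n", sep = "")
  print(x$anova)
  invisible(x)
}

#' Term p-value from the sequential ANOVA table
#'
#' @param fit a [fit_glm()] result.
#' @param term term name.
#' @return The p-value of that term's sequential F test.
#' @export
term_p <- function(fit, term) {
  if (!term %in% rownames(fit$anova)) return(NA_real_)
  fit$anova[term, "Pr(>F)"]
}

#' Least-squares (adjusted) means of a factor term
#'
#' Predicted means per level of `factor_name`, with numeric covariates held
#' at their observed mean and every other factor averaged with equal weight
#' over its levels.
#'
#' @param fit a [fit_glm()] result.
#' @param factor_name name of a factor term in the model.
#' @return Named numeric vector of adjusted means, one per level.
#' @export
adjusted_means <- function(fit, factor_name) {
  stopifnot(factor_name %in% fit$terms)
  dat <- fit$data
  lv <- levels(dat[[factor_name]])
  others <- setdiff(fit$terms, factor_name)
  grid <- list()
  grid[[factor_name]] <- lv
  for (t in others) {
    v <- dat[[t]]
    grid[[t]] <- if (is.factor(v)) levels(v) else mean(v)
  }
  g <- expand.grid(grid, stringsAsFactors = FALSE)
  for (t in fit$terms) {
    if (is.factor(dat[[t]])) g[[t]] <- factor(g[[t]], levels = levels(dat[[t]]))
  }
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit$fit)), g,
                           contrasts.arg = fit$fit$contrasts)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  pred <- drop(X %*% beta)
  tapply(pred, g[[factor_name]], mean)[lv]
}

#' Fisher's least-significant-difference contrast
#'
#' Classical LSD test between two groups of a joint model: the difference of
#' adjusted means is referred to t = diff / sqrt(MSE * (1/n1 + 1/n2)) on the
#' joint model's residual degrees of freedom. No multiplicity adjustment is
#' applied, as is conventional for LSD post hocs.
#'
#' @param mean1,mean2 adjusted group means (contrast is mean1 - mean2).
#' @param n1,n2 group sizes.
#' @param mse,df_residual residual mean square and df of the joint model.
#' @return list: `diff`, `se`, `t`, `p` (two-sided), `df`.
#' @export
lsd_contrast <- function(mean1, mean2, n1, n2, mse, df_residual) {
  if (n1 < 2 || n2 < 2) stop("LSD contrast needs at least 2 mice per group")
  se <- sqrt(mse * (1 / n1 + 1 / n2))
  d <- mean1 - mean2
  if (se == 0) {
    t <- if (d == 0) 0 else sign(d) * Inf
  } else {
    t <- d / se
  }
  list(diff = d, se = se, t = t,
       p = 2 * stats::pt(-abs(t), df_residual), df = df_residual)
}

#' Cohen's D standardized mean difference
#'
#' Signed effect size `(mean(group_h) - mean(group_a)) / pooled SD`, with
#' the pooled SD computed from the two group variances weighted by their
#' degrees of freedom. Positive values mean the donor (heterozygous) group
#' has the larger trait value.
#'
#' @param group_a,group_h numeric vectors (host and donor genotype groups),
#'   each of length >= 2.
#' @return A single number; `NA` with a warning if the pooled SD is zero.
#' @export
cohens_d <- function(group_a, group_h) {
  n_a <- length(group_a); n_h <- length(group_h)
  if (n_a < 2 || n_h < 2) stop("both groups need n >= 2")
  sp2 <- ((n_a - 1) * stats::var(group_a) + (n_h - 1) * stats::var(group_h)) /
    (n_a + n_h - 2)
  if (sp2 == 0) {
    warning("zero pooled SD; Cohen's D undefined")
    return(NA_real_)
  }
  (mean(group_h) - mean(group_a)) / sqrt(sp2)
}
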