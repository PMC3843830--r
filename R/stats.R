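#' @include utils.R
NULL

#' Group summaries of a per-species metric
#'
#' @param table a species data.frame (e.g. [speciesTable1()]).
#' @param by grouping column name (e.g. `"pigment_class"` or `"group_label"`).
#' @param value value column name (default `"lambda_t50"`).
#' @param groups optional subset of group labels to keep, in this order.
#' @return A data.frame with one row per group: `group`, `n`, `mean`, `sd`
#'   (sample sd, 0 for single-member groups), `min`, `max`.
#' @examples
#' summarizeGroups(speciesTable1(), by = "pigment_class")
#' @export
summarizeGroups <- function(table, by, value = "lambda_t50", groups = NULL) {
  if (!all(c(by, value) %in% names(table))) {
    stop("columns not found: ", by, " / ", value, call. = FALSE)
  }
  g <- as.character(table[[by]])
  x <- table[[value]]
  keep <- !is.na(g) & !is.na(x)
  g <- g[keep]; x <- x[keep]
  labs <- if (is.null(groups)) sort(unique(g)) else groups
  if (!all(labs %in% g)) {
    stop("empty group(s): ", paste(setdiff(labs, g), collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(labs, function(lab) {
    xi <- x[g == lab]
    data.frame(group = lab, n = length(xi), mean = mean(xi),
               sd = if (length(xi) > 1L) sd(xi) else 0,
               min = min(xi), max = max(xi), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Dunn-Šidák corrected significance level
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param familySize number of comparisons in the family.
#' @return Per-comparison level \eqn{\alpha' = 1 - (1 - \alpha)^{1/n}}.
#' @export
dunnSidakAlpha <- function(alpha = 0.05, familySize = 1L) {
  stopifnot(familySize >= 1)
  1 - (1 - alpha)^(1 / familySize)
}

#' Two-group comparison with a normality gate
#'
#' Compares two samples the way the comparative analysis treats group
#' \eqn{\lambda_{T0.5}} and slope values: a Shapiro–Wilk test at
#' \eqn{\alpha = 0.05} on each group decides between a two-tailed unpaired
#' Student t-test (both groups consistent with normality) and a two-tailed
#' Wilcoxon rank-sum test. When a group is too small for the normality gate
#' (n < 3), the rank-sum test is used. For slope-interval families the
#' per-comparison level is Dunn-Šidák corrected.
#'
#' @param a,b numeric samples, each with at least 2 values.
#' @param familySize number of comparisons in the family (Dunn-Šidák
#'   correction; 1 = no correction).
#' @param alpha family-wise significance level.
#' @return An object of class `"GroupComparison"`: a list with `n`, `mean`,
#'   `sd` (each length 2), `test` (`"t"` or `"wilcoxon"`), `statistic`,
#'   `p_value`, `alpha_corrected` and `significant`.
#' @export
compareGroups <- function(a, b, familySize = 1L, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  normal <- function(x) {
    length(x) >= 3L && length(unique(x)) > 1L && shapiro.test(x)$p.value > 0.05
  }
  useT <- normal(a) && normal(b)
  if (useT) {
    ht <- t.test(a, b, var.equal = TRUE)
    test <- "t"
  } else {
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- !ties && length(a) < 8L && length(b) < 8L
    ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
    test <- "wilcoxon"
  }
  ac <- dunnSidakAlpha(alpha, familySize)
  structure(list(n = c(length(a), length(b)), mean = c(mean(a), mean(b)),
                 sd = c(sd(a), sd(b)), test = test,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 alpha_corrected = ac, significant = ht$p.value < ac),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("GroupComparison (%s test): n = %d vs %d\n",
              x$test, x$n[1], x$n[2]))
  cat(sprintf("  means %.4g vs %.4g (sd %.4g / %.4g)\n",
              x$mean[1], x$mean[2], x$sd[1], x$sd[2]))
  cat(sprintf("  statistic %.4g, p = %.4g, alpha' = %.4g (%ssignificant)\n",
              x$statistic, x$p_value, x$alpha_corrected,
              if (x$significant) "" else "not "))
  invisible(x)
}

#' Spearman rank correlation with pairwise-complete data
#'
#' Tie-corrected Spearman correlation with a two-sided p-value; incomplete
#' pairs are dropped and the remaining pair count reported.
#'
#' @param x,y paired numeric vectors.
#' @return A list with `rho`, `p_value`, `n` (complete pairs used).
#' @export
correlateSpearman <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("constant input; correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

# deterministic start list for the two-term exponential: all ordered pairs of
# candidate rates, amplitudes seeded by a linear solve at fixed rates
.ttexpStarts <- function(x, y) {
  rates <- c(-0.2, -0.05, -0.01, -0.001, 0.001, 0.01, 0.05)
  pairs <- expand.grid(b = rates, d = rates)
  pairs <- pairs[pairs$b < pairs$d, , drop = FALSE]
  starts <- list()
  for (i in seq_len(nrow(pairs))) {
    b0 <- pairs$b[i]; d0 <- pairs$d[i]
    X <- cbind(exp(b0 * x), exp(d0 * x))
    ac <- tryCatch(qr.solve(crossprod(X), crossprod(X, y)),
                   error = function(e) NULL)
    if (is.null(ac) || any(!is.finite(ac))) ac <- c(mean(y), 0)
    starts[[length(starts) + 1L]] <-
      list(a = ac[1], b = b0, c = ac[2], d = d0)
  }
  starts
}

#' Least-squares curve fits for spectral/eye-size relationships
#'
#' Fits one of the three curve families used in the comparative analysis:
#' `"linear"` (\eqn{y = p_1 + p_2 x}), `"poly2"` (second-order polynomial,
#' the shape of the retinal-UV-irradiance vs \eqn{\lambda_{T0.5}} relation)
#' and `"two_term_exponential"`
#' (\eqn{y = a e^{bx} + c e^{dx}}, the eye-size relation after outlier
#' exclusion). The two-term exponential is fitted by Levenberg–Marquardt
#' nonlinear least squares from a deterministic multi-start list covering
#' both sign patterns of the rates, and the best converged fit by residual
#' sum of squares is returned.
#'
#' @param x,y numeric vectors (incomplete pairs dropped).
#' @param family `"linear"`, `"poly2"` or `"two_term_exponential"`.
#' @return An object of class `"FitResult"`: list with `family`,
#'   `coefficients` (named), `rss`, `n` and `predict` (a function of x).
#' @examples
#' f <- fitCurve(1:10, 2 + 3 * (1:10), "linear")
#' f$coefficients
#' @export
fitCurve <- function(x, y, family = c("linear", "poly2",
                                      "two_term_exponential")) {
  family <- match.arg(family)
  keep <- complete.cases(x, y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  npar <- switch(family, linear = 2L, poly2 = 3L, two_term_exponential = 4L)
  if (length(x) <= npar) {
    stop("need more points than coefficients", call. = FALSE)
  }
  if (family == "linear") {
    fit <- lm(y ~ x)
    cf <- setNames(coef(fit), c("intercept", "slope"))
    pred <- function(xx) cf[1] + cf[2] * xx
    rss <- sum(fit$residuals^2)
  } else if (family == "poly2") {
    fit <- lm(y ~ x + I(x^2))
    cf <- setNames(coef(fit), c("c0", "c1", "c2"))
    pred <- function(xx) cf[1] + cf[2] * xx + cf[3] * xx^2
    rss <- sum(fit$residuals^2)
  } else {
    best <- NULL
    for (st in .ttexpStarts(x, y)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a * exp(b * x) + c * exp(d * x), start = st,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rssi <- sum(residuals(fit)^2)
      if (is.null(best) || rssi < best$rss) {
        best <- list(fit = fit, rss = rssi)
      }
    }
    if (is.null(best)) {
      stop("two-term exponential fit failed to converge from any start",
           call. = FALSE)
    }
    cf <- coef(best$fit)[c("a", "b", "c", "d")]
    pred <- function(xx) cf["a"] * exp(cf["b"] * xx) + cf["c"] * exp(cf["d"] * xx)
    rss <- best$rss
  }
  structure(list(family = family, coefficients = cf, rss = rss,
                 n = length(x), predict = pred), class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult (%s), n = %d, RSS = %.6g\n", x$family, x$n, x$rss))
  print(x$coefficients)
  invisible(x)
}
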