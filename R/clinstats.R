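#' Remission and response classification from HAM-D scores
#'
#' Remission: week-8 HAM-D total of 7 or less. Response: a decrease of 50%
#' or more from baseline to week 8.
#'
#' @param hamd_w0,hamd_w8 baseline and week-8 totals (vectors allowed).
#' @return data.frame with logical columns `remission`, `response`.
#' @export
classify_outcomes <- function(hamd_w0, hamd_w8) {
  if (any(hamd_w0 < 0 | hamd_w8 < 0, na.rm = TRUE))
    stop("HAM-D scores must be nonnegative")
  if (any(hamd_w0 == 0, na.rm = TRUE))
    stop("response undefined for baseline HAM-D of 0")
  data.frame(remission = hamd_w8 <= 7,
             response = (hamd_w0 - hamd_w8) / hamd_w0 >= 0.5)
}

#' Median split of a biomarker into low and high groups
#'
#' Values strictly below the median go to "low", strictly above to
#' "high"; values equal to the median are assigned to "low"
#' (deterministic tie rule). With even n and no exact ties the groups are
#' equal-sized.
#'
#' @param values numeric biomarker values (>= 4 non-missing).
#' @param index_name label for provenance.
#' @return list: index, median, group (factor low/high aligned to values;
#'   NA values stay NA).
#' @export
median_split <- function(values, index_name = "index") {
  ok <- !is.na(values)
  if (sum(ok) < 4) stop("median split needs at least 4 non-missing values")
  if (length(unique(values[ok])) == 1)
    stop("median split undefined: all values identical")
  med <- stats::median(values[ok])
  grp <- ifelse(values <= med, "low", "high")
  grp[!ok] <- NA
  list(index = index_name, median = med,
       group = factor(grp, levels = c("low", "high")))
}

#' Two-by-two contingency table of group versus outcome
#'
#' Rows are the low/high biomarker groups, columns the positive/negative
#' outcome; counts sum to the number of complete cases.
#'
#' @param group factor low/high.
#' @param flag logical outcome (TRUE = positive: remitted / responded).
#' @return 2x2 integer matrix, rows c("low","high"), cols c("yes","no").
#' @export
contingency <- function(group, flag) {
  ok <- !is.na(group) & !is.na(flag)
  tab <- table(factor(group[ok], levels = c("low", "high")),
               factor(ifelse(flag[ok], "yes", "no"),
                      levels = c("yes", "no")))
  m <- matrix(as.integer(tab), 2, 2,
              dimnames = list(c("low", "high"), c("yes", "no")))
  m
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson statistic (no Yates continuity correction) with
#' df = 1 and a two-sided p from the chi-square distribution.
#'
#' @param tab 2x2 nonnegative integer matrix with all margins positive.
#' @return list: statistic, df, p.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square undefined: a table margin is zero")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

# Orthonormal polynomial-free contrast basis for k repeated measures:
# k x (k-1) matrix C with C'C = I and columns orthogonal to the unit
# vector (normalized Helmert contrasts).
within_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Mauchly's sphericity test and Greenhouse-Geisser epsilon
#'
#' Both are computed from the error covariance of the orthonormalized
#' within-subject contrasts, after removing the between-subject model
#' (default: intercept only). Mauchly's W uses the chi-square
#' approximation; the Greenhouse-Geisser epsilon is
#' (sum lambda)^2 / ((k-1) sum lambda^2) from the eigenvalues of the
#' contrast covariance, bounded in (1/(k-1), 1].
#'
#' @param y n x k matrix of repeated measures (k >= 3).
#' @param x optional between-subject design matrix (without intercept;
#'   one is added).
#' @return list: mauchly_w, mauchly_p, epsilon, df_error.
#' @export
mauchly_and_epsilon <- function(y, x = NULL) {
  y <- as.matrix(y)
  n <- nrow(y); k <- ncol(y)
  if (k < 3) stop("need at least 3 repeated measures")
  X <- cbind(`(Intercept)` = rep(1, n), x)
  if (n <= ncol(X) + k - 1)
    stop("too few subjects for the within-subject covariance")
  C <- within_contrasts(k)
  Z <- y %*% C
  fit <- stats::lm.fit(X, Z)
  E <- crossprod(as.matrix(fit$residuals))
  df_e <- n - ncol(X)
  S <- E / df_e
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) < 1e-12 || min(ev) <= 1e-10 * max(ev))
    stop("singular within-subject covariance")
  p <- k - 1
  W <- prod(ev) / (sum(ev) / p)^p
  f <- 1 - (2 * p^2 + p + 2) / (6 * p * df_e)
  chi <- -f * df_e * log(W)
  df_chi <- p * (p + 1) / 2 - 1
  eps <- sum(ev)^2 / (p * sum(ev^2))
  list(mauchly_w = W,
       mauchly_p = stats::pchisq(chi, df_chi, lower.tail = FALSE),
       epsilon = eps, df_error = df_e)
}

#' Greenhouse-Geisser-adjusted degrees of freedom
#'
#' df1 = epsilon x (k-1) x df_effect and df2 = epsilon x (k-1) x df_error.
#'
#' @param epsilon Greenhouse-Geisser epsilon.
#' @param k number of repeated-measure levels.
#' @param df_error between-model residual df (n - parameters).
#' @param df_effect hypothesis df of the between term (default 1).
#' @return c(df1, df2), fractional.
#' @export
gg_adjust_df <- function(epsilon, k, df_error, df_effect = 1) {
  c(df1 = epsilon * (k - 1) * df_effect,
    df2 = epsilon * (k - 1) * df_error)
}

# 0/1 coding for the two-level clinical covariates, declared once.
# Constant covariates are uninformative (aliased with the intercept) and
# are dropped; reported dfs reflect the retained set.
code_covariates <- function(covariates) {
  cv <- as.data.frame(covariates)
  for (nm in names(cv)) {
    v <- cv[[nm]]
    if (is.character(v) || is.factor(v)) {
      lev <- sort(unique(as.character(v)))
      if (length(lev) > 2)
        stop("covariate ", nm, " must be numeric or two-level")
      cv[[nm]] <- as.numeric(as.character(v) == lev[length(lev)])
    }
  }
  m <- as.matrix(cv)
  keep <- apply(m, 2, function(col) stats::sd(col) > 0)
  m[, keep, drop = FALSE]
}

#' Repeated-measures ANCOVA for the week-by-group interaction
#'
#' HAM-D scores at the four weeks are the within-subject factor; the
#' biomarker group (low/high) is the between factor; age, sex, baseline
#' HAM-D and medication type enter as between-subject covariates (0/1
#' coding for the two-level ones). The univariate interaction F is
#' computed from the orthonormal within-contrast scores; when Mauchly's
#' test rejects sphericity at `gg_alpha`, degrees of freedom are
#' Greenhouse-Geisser adjusted.
#'
#' @param y n x k matrix of repeated measures (weeks 0/2/4/8).
#' @param group factor with two levels (low/high).
#' @param covariates data.frame of covariates (numeric or two-level).
#' @param gg_alpha Mauchly threshold for applying the GG correction
#'   (default 0.05).
#' @return list: F, df1, df2 (possibly adjusted), p, epsilon, mauchly_w,
#'   mauchly_p, gg_applied, df1_unadj, df2_unadj.
#' @export
rm_ancova <- function(y, group, covariates = NULL, gg_alpha = 0.05) {
  y <- as.matrix(y)
  n <- nrow(y); k <- ncol(y)
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (min(table(group)) < 2) stop("fewer than 2 subjects in a group")
  g <- as.numeric(group == levels(group)[2])
  X <- cbind(1, g)
  colnames(X) <- c("(Intercept)", "group")
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0)
    X <- cbind(X, code_covariates(covariates))
  if (qr(X)$rank < ncol(X)) stop("singular between-subject design")

  C <- within_contrasts(k)
  Z <- y %*% C
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Z)
  E <- crossprod(Z - X %*% B)
  df_e <- n - ncol(X)

  # hypothesis SSCP for the group row of B
  j <- match("group", colnames(X))
  L <- matrix(0, 1, ncol(X)); L[1, j] <- 1
  H <- crossprod(L %*% B, solve(L %*% XtXi %*% t(L))) %*% (L %*% B)

  Fstat <- (sum(diag(H)) / (k - 1)) / (sum(diag(E)) / ((k - 1) * df_e))
  sph <- mauchly_and_epsilon(y, X[, -1, drop = FALSE])
  df1_u <- k - 1
  df2_u <- (k - 1) * df_e
  gg <- sph$mauchly_p < gg_alpha
  dfs <- if (gg) gg_adjust_df(sph$epsilon, k, df_e) else c(df1_u, df2_u)
  list(F = Fstat, df1 = unname(dfs[1]), df2 = unname(dfs[2]),
       p = stats::pf(Fstat, dfs[1], dfs[2], lower.tail = FALSE),
       epsilon = sph$epsilon, mauchly_w = sph$mauchly_w,
       mauchly_p = sph$mauchly_p, gg_applied = gg,
       df1_unadj = df1_u, df2_unadj = df2_u)
}

#' One-way ANCOVA on the HAM-D score of a single week
#'
#' Group effect on one week's score, adjusting for the covariates; raw
#' (unadjusted) group means and SDs are reported alongside.
#'
#' @param score numeric outcome (one week's HAM-D).
#' @param group two-level factor.
#' @param covariates data.frame of covariates.
#' @return list: F, df1, df2, p, means (low/high), sds.
#' @export
ancova_at_week <- function(score, group, covariates = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (min(table(group)) < 2) stop("fewer than 2 subjects in a group")
  df <- data.frame(score = score, group = group)
  cv <- if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0)
    as.data.frame(code_covariates(covariates)) else NULL
  full <- if (is.null(cv)) stats::lm(score ~ group, df) else
    stats::lm(score ~ ., cbind(df, cv))
  red <- if (is.null(cv)) stats::lm(score ~ 1, df) else
    stats::lm(score ~ ., cbind(df[, "score", drop = FALSE], cv))
  av <- stats::anova(red, full)
  ms <- tapply(score, group, mean)
  ss <- tapply(score, group, stats::sd)
  list(F = av$F[2], df1 = av$Df[2], df2 = av$Res.Df[2],
       p = av$`Pr(>F)`[2],
       means = c(low = unname(ms["low"]), high = unname(ms["high"])),
       sds = c(low = unname(ss["low"]), high = unname(ss["high"])))
}

#' Partial correlation controlling for covariates
#'
#' Correlation of the residuals of x and y after regressing each on the
#' covariate set (with intercept); df = n - 2 - #covariates and the
#' two-sided p comes from the t transform. With no covariates this is the
#' ordinary product-moment correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame/matrix of covariates or NULL.
#' @return list: r, df, p, n, covariates (names).
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  ok <- !is.na(x) & !is.na(y)
  cv <- NULL
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    cv <- code_covariates(covariates)
    ok <- ok & stats::complete.cases(cv)
    cv <- cv[ok, , drop = FALSE]
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  q <- if (is.null(cv)) 0 else ncol(cv)
  if (n <= q + 2) stop("need more observations than covariates + 2")
  if (!is.null(cv)) {
    X <- cbind(1, cv)
    x <- stats::lm.fit(X, x)$residuals
    y <- stats::lm.fit(X, y)$residuals
  }
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stop("constant variable after residualization")
  r <- stats::cor(x, y)
  df <- n - 2 - q
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(abs(tt), df, lower.tail = FALSE),
       n = n, covariates = colnames(cv))
}
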