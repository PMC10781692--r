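#' Clinical scale definitions
#'
#' Registered response and remission rules: response is a reduction of at
#' least 50 percent from baseline (boundary inclusive) on the scales for
#' which it is defined; remission is scale-specific — BSI-CV: reduction of
#' at least 50 percent AND score < 6; HAMD-17: score < 8; MADRS: score < 11;
#' HAMD-6: score < 5; BDI: score < 13. The neurocognitive scales (PDQ-D,
#' DST, DSST) carry no response/remission rule.
#'
#' @return data.frame: scale, hasResponse, remissionThreshold,
#'   remissionNeedsReduction.
#' @export
scaleDefinitions <- function() {
  data.frame(
    scale = c("BSI-CV", "HAMD-17", "HAMD-6", "MADRS", "BDI",
              "PDQ-D", "DST", "DSST"),
    hasResponse = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    remissionThreshold = c(6, 8, 5, 11, 13, NA, NA, NA),
    remissionNeedsReduction = c(TRUE, FALSE, FALSE, FALSE, FALSE, NA, NA, NA),
    stringsAsFactors = FALSE)
}

#' Percent reduction from baseline
#'
#' \code{(baseline - follow) / baseline}, as an unrounded fraction; may be
#' negative when a score worsens. Rounding to two decimals happens only at
#' the reporting layer.
#'
#' @param baseline,follow scores (vectorized).
#' @export
percentReduction <- function(baseline, follow) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  (baseline - follow) / baseline
}

#' Format a fraction as a percent string
#'
#' Half-up rounding to two decimals, e.g. 0.6523 -> "65.23%".
#'
#' @param frac numeric fraction.
#' @export
formatPercent <- function(frac) {
  sprintf("%.2f%%", floor(frac * 10000 + 0.5) / 100)
}

#' Response and remission classification
#'
#' @param scale scale name (see \code{scaleDefinitions}).
#' @param baseline,follow scores (vectorized).
#' @return data.frame(reduction, response, remission).
#' @export
classifyOutcome <- function(scale, baseline, follow) {
  defs <- scaleDefinitions()
  d <- defs[defs$scale == scale, ]
  if (!nrow(d)) stop("unknown scale: ", scale)
  red <- percentReduction(baseline, follow)
  resp <- if (d$hasResponse) red >= 0.5 else rep(NA, length(red))
  rem <- if (!is.na(d$remissionThreshold)) {
    ok <- follow < d$remissionThreshold
    if (isTRUE(d$remissionNeedsReduction)) ok & red >= 0.5 else ok
  } else rep(NA, length(red))
  data.frame(reduction = red, response = resp, remission = rem)
}

#' Mean-impute missing scores at a timepoint
#'
#' Replaces each missing value by the mean of the observed values for the
#' same scale and timepoint, recording an audit entry; observed values are
#' never changed. More than one missing value per scale-timepoint triggers
#' a warning (the registered procedure anticipated a single missed visit);
#' a fully missing scale-timepoint is an error.
#'
#' @param scores long data.frame: subject, scale, timepoint, value.
#' @return list(scores, audit) where audit lists the imputed cells.
#' @export
imputeMissing <- function(scores) {
  audit <- scores[0, c("subject", "scale", "timepoint")]
  audit$imputed <- numeric(0)
  key <- interaction(scores$scale, scores$timepoint, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    v <- scores$value[idx]
    if (!any(is.na(v))) next
    if (all(is.na(v)))
      stop("all values missing for ", k)
    if (sum(is.na(v)) > 1)
      warning("more than one missing value for ", k)
    m <- mean(v, na.rm = TRUE)
    miss <- idx[is.na(v)]
    scores$value[miss] <- m
    audit <- rbind(audit, data.frame(subject = scores$subject[miss],
                                     scale = scores$scale[miss],
                                     timepoint = scores$timepoint[miss],
                                     imputed = m))
  }
  list(scores = scores, audit = audit)
}

#' Response and remission rates
#'
#' @param scale scale name.
#' @param baseline,follow aligned per-subject scores (post imputation).
#' @return list(n, response = list(count, pct), remission = list(count,
#'   pct)); percentages half-up rounded to two decimals.
#' @export
summarizeRates <- function(scale, baseline, follow) {
  if (!length(baseline)) stop("empty cohort")
  cl <- classifyOutcome(scale, baseline, follow)
  pct <- function(k) floor(100 * k / length(baseline) * 100 + 0.5) / 100
  list(n = length(baseline),
       response = list(count = sum(cl$response), pct = pct(sum(cl$response))),
       remission = list(count = sum(cl$remission), pct = pct(sum(cl$remission))))
}

# Greenhouse-Geisser epsilon from the subjects x timepoints data matrix.
.ggEpsilon <- function(M) {
  S <- cov(M)
  k <- ncol(S)
  Sc <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  (sum(diag(Sc)))^2 / ((k - 1) * sum(Sc^2))
}

#' Longitudinal tests on repeated clinical scores
#'
#' One-way within-subject (repeated measures) ANOVA with optional
#' Greenhouse-Geisser correction of the degrees of freedom, plus
#' Bonferroni-corrected paired pairwise comparisons. For two timepoints
#' the ANOVA F equals the squared paired t statistic.
#'
#' @param M subjects x timepoints numeric matrix (complete data).
#' @param ggCorrect apply Greenhouse-Geisser correction to the reported p.
#' @return list(F, df, p, epsilon, pGG, pairwise).
#' @export
longitudinalTests <- function(M, ggCorrect = TRUE) {
  M <- as.matrix(M)
  n <- nrow(M); k <- ncol(M)
  if (n < 3) stop("need at least 3 subjects")
  if (k < 2) stop("need at least 2 timepoints")
  if (any(is.na(M))) stop("complete (post-imputation) data required")
  if (is.null(colnames(M))) colnames(M) <- paste0("t", seq_len(k))
  d <- data.frame(value = as.vector(M),
                  tp = factor(rep(colnames(M), each = n)),
                  subj = factor(rep(seq_len(n), k)))
  fit <- aov(value ~ tp + Error(subj), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fv <- tab["tp", "F value"]
  df1 <- tab["tp", "Df"]; df2 <- tab["Residuals", "Df"]
  pv <- tab["tp", "Pr(>F)"]
  if (tab["tp", "Sum Sq"] < 1e-12 * max(1, sum(tab[, "Sum Sq"]))) {
    Fv <- 0; pv <- 1       # no timepoint effect at all (0/0 in aov)
  }
  eps <- .ggEpsilon(M)
  if (!is.finite(eps)) eps <- 1
  pGG <- pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
  pw <- NULL
  if (k > 2) {
    pairs <- combn(k, 2)
    praw <- apply(pairs, 2, function(ij)
      stats::t.test(M[, ij[1]], M[, ij[2]], paired = TRUE)$p.value)
    pw <- data.frame(a = colnames(M)[pairs[1, ]], b = colnames(M)[pairs[2, ]],
                     p = stats::p.adjust(praw, method = "bonferroni"))
  }
  list(F = unname(Fv), df = c(df1, df2), p = unname(pv),
       epsilon = eps, pGG = if (ggCorrect) unname(pGG) else NA_real_,
       pairwise = pw)
}

#' Paired t test wrapper for two-timepoint scales
#'
#' @param pre,post aligned scores.
#' @export
pairedT <- function(pre, post) {
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanDiff = unname(tt$estimate))
}

#' Correlation between connectivity estimates and score changes
#'
#' Pearson correlation with a two-sided p value; when covariates are
#' supplied, the partial correlation of the residuals after regressing
#' both variables on the covariates, with degrees of freedom n - 2 - k.
#' No multiple-testing correction is applied.
#'
#' @param x,y aligned numeric vectors (n >= 4).
#' @param covariates optional numeric matrix/vector of covariates.
#' @return list(r, p, df, partial).
#' @export
correlateOutcomes <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (n < 4 || length(y) != n) stop("need aligned vectors with n >= 4")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  if (is.null(covariates)) {
    ct <- stats::cor.test(x, y)
    return(list(r = unname(ct$estimate), p = ct$p.value,
                df = unname(ct$parameter), partial = FALSE))
  }
  Z <- cbind(1, as.matrix(covariates))
  k <- ncol(Z) - 1
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12)
    stop("zero residual variance after covariate adjustment")
  r <- cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df), df = df, partial = TRUE)
}
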