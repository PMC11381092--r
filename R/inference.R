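#' @include AllClasses.R
NULL

#' Small-sample corrected AIC
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1).
#'
#' @param loglik log-likelihood (nats).
#' @param k parameter count (fixed effects plus variance components).
#' @param n observations.
#' @return AICc; error when n <= k + 1 (correction undefined).
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' @param aiccValues vector of AICc values for one candidate set.
#' @return weights summing to 1.
#' @export
akaikeWeights <- function(aiccValues) {
  d <- aiccValues - min(aiccValues)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Iterative VIF/GVIF collinearity screen
#'
#' Fits the design, computes variance inflation factors (GVIF for
#' multi-df terms), and removes offending terms one at a time --
#' interactions before main effects, worst first -- until every term
#' passes. A 1-df term fails when VIF exceeds \code{vifThr} (default
#' 5); a multi-df term fails when GVIF^(1/(2 df)) exceeds
#' \code{gvifThr} (default 2.2). Perfectly collinear (aliased) terms
#' are removed first with an infinite-VIF report line.
#'
#' @param data data.frame of predictors.
#' @param terms character vector of model terms (may include
#'   interactions like \code{"a:b"}).
#' @param vifThr,gvifThr thresholds.
#' @return list with \code{retained}, \code{removed}, and \code{report}
#'   (term, vif, measure, threshold, action per round).
#' @export
vifScreen <- function(data, terms, vifThr = 5, gvifThr = 2.2) {
  retained <- terms
  removed <- character(0)
  report <- list()
  repeat {
    if (length(retained) < 2) break
    f <- stats::as.formula(paste(".vify ~", paste(retained, collapse = "+")))
    df <- data
    df$.vify <- seq_len(nrow(df))           # VIF ignores the response
    fit <- stats::lm(f, data = df)
    al <- stats::alias(fit)$Complete
    if (!is.null(al)) {
      ## perfectly collinear: drop the aliased term (interactions first)
      aliased <- rownames(al)
      bad <- retained[vapply(retained, function(tm) any(grepl(
        gsub(":", ".*", tm, fixed = FALSE), aliased)), logical(1))]
      bad <- if (length(bad)) bad[order(!grepl(":", bad))][1] else
        retained[length(retained)]
      report[[length(report) + 1L]] <- data.frame(
        term = bad, measure = Inf, threshold = vifThr,
        action = "removed (aliased)")
      removed <- c(removed, bad)
      retained <- setdiff(retained, bad)
      next
    }
    v <- withCallingHandlers(
      car::vif(fit),
      warning = function(w) {
        if (grepl("higher-order terms", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (is.matrix(v)) {
      dfree <- v[, "Df"]
      meas <- ifelse(dfree == 1, v[, "GVIF"],
                     v[, "GVIF^(1/(2*Df))"])
      thr <- ifelse(dfree == 1, vifThr, gvifThr)
    } else {
      meas <- v
      thr <- rep(vifThr, length(v))
    }
    fail <- meas > thr
    if (!any(fail)) {
      report[[length(report) + 1L]] <- data.frame(
        term = names(meas), measure = unname(meas),
        threshold = unname(thr), action = "retained")
      break
    }
    cand <- names(meas)[fail]
    inter <- grepl(":", cand)
    pool <- if (any(inter)) cand[inter] else cand
    worst <- pool[which.max(meas[pool])]
    report[[length(report) + 1L]] <- data.frame(
      term = worst, measure = unname(meas[worst]),
      threshold = unname(thr[names(meas) == worst][1]),
      action = "removed")
    removed <- c(removed, worst)
    retained <- setdiff(retained, worst)
  }
  list(retained = retained, removed = removed,
       report = if (length(report)) do.call(rbind, report) else
         data.frame(term = character(0), measure = numeric(0),
                    threshold = numeric(0), action = character(0)))
}

#' Fit and AICc-rank a candidate model set
#'
#' Fits every candidate fixed-effect structure by maximum likelihood --
#' as a linear mixed model with a random intercept for bird identity
#' when repeats exist (and \code{random = "BIRD_ID"}), otherwise as a
#' linear model -- and ranks them by AICc. The parameter count k
#' includes fixed effects plus variance components (random-intercept SD
#' and residual SD). Candidates with fewer observations than
#' parameters + 2 are skipped with a message.
#'
#' @param data data.frame holding the response and covariates.
#' @param response response column name.
#' @param candidates character vector of fixed-effect right-hand sides
#'   (include \code{"1"} or the mandatory-covariate-only null model).
#' @param random "BIRD_ID" or "NONE".
#' @param birdCol grouping column for the random intercept.
#' @return list with \code{table} (one row per fitted candidate:
#'   formula, k, loglik, aicc, delta_aicc, weight, r2_marginal,
#'   r2_conditional, random_effect; sorted by AICc) and \code{fits}
#'   (named list of fitted models, ML).
#' @export
fitCandidates <- function(data, response, candidates,
                          random = c("BIRD_ID", "NONE"),
                          birdCol = "bird_id") {
  random <- match.arg(random)
  useLmm <- random == "BIRD_ID" && birdCol %in% names(data) &&
    any(duplicated(data[[birdCol]]))
  fits <- list()
  rows <- list()
  for (rhs in candidates) {
    fml <- if (useLmm)
      stats::as.formula(sprintf("%s ~ %s + (1 | %s)", response, rhs,
                                birdCol))
    else stats::as.formula(sprintf("%s ~ %s", response, rhs))
    fit <- tryCatch(
      if (useLmm) lme4::lmer(fml, data = data, REML = FALSE)
      else stats::lm(fml, data = data),
      error = function(e) NULL)
    if (is.null(fit)) {
      message("candidate skipped (fit failed): ", rhs)
      next
    }
    ll <- stats::logLik(fit)
    k <- attr(ll, "df")
    n <- stats::nobs(fit)
    if (n <= k + 1) {
      message("candidate skipped (too few rows for AICc): ", rhs)
      next
    }
    r2 <- r2Nakagawa(fit)
    fits[[rhs]] <- fit
    rows[[rhs]] <- data.frame(
      formula = rhs, k = k, loglik = as.numeric(ll),
      aicc = aicc(as.numeric(ll), k, n),
      r2_marginal = r2$r2m, r2_conditional = r2$r2c,
      random_effect = if (useLmm) "BIRD_ID" else "NONE",
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no candidate could be fitted")
  tab <- do.call(rbind, rows)
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab$weight <- akaikeWeights(tab$aicc)
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' Likelihood-ratio comparison of top and null model
#'
#' Chi-square likelihood-ratio test of the AICc-top model against the
#' nested null, both fitted by maximum likelihood. A numerically
#' negative statistic is clipped to zero with a warning.
#'
#' @param fitTop,fitNull fitted models (null nested in top).
#' @return list with statistic, df and p.
#' @export
compareToNull <- function(fitTop, fitNull) {
  kT <- attr(stats::logLik(fitTop), "df")
  kN <- attr(stats::logLik(fitNull), "df")
  if (kT < kN) stop("null model must be nested in the top model")
  stat <- 2 * (as.numeric(stats::logLik(fitTop)) -
                 as.numeric(stats::logLik(fitNull)))
  if (stat < 0) {
    if (stat < -1e-6)
      warning("negative likelihood-ratio statistic clipped to 0")
    stat <- 0
  }
  df <- kT - kN
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Nakagawa marginal and conditional R-squared
#'
#' r2m = var(fixed predictions) / (var(fixed) + var(random) +
#' var(residual)); r2c adds the random-intercept variance to the
#' numerator. For a plain linear model the random variance is zero and
#' the two coincide.
#'
#' @param fit an lmerMod or lm fit.
#' @return list with r2m and r2c.
#' @export
r2Nakagawa <- function(fit) {
  if (inherits(fit, "merMod")) {
    fixedPred <- as.vector(lme4::getME(fit, "X") %*% lme4::fixef(fit))
    varF <- stats::var(fixedPred)
    vc <- lme4::VarCorr(fit)
    varR <- sum(vapply(vc, function(m) m[1, 1], numeric(1)))
    varE <- attr(vc, "sc")^2
  } else {
    fixedPred <- stats::fitted(fit)
    varF <- stats::var(fixedPred)
    varR <- 0
    varE <- summary(fit)$sigma^2
  }
  denom <- varF + varR + varE
  list(r2m = varF / denom, r2c = (varF + varR) / denom)
}

#' REML refit of the selected model with t-statistics
#'
#' Refits the AICc-selected model by restricted maximum likelihood and
#' reports coefficient t-statistics: Satterthwaite denominator degrees
#' of freedom for mixed models (via lmerTest), classical t for linear
#' models. A singular refit (random-intercept variance collapsing to
#' zero) falls back to the fixed-effects-only linear model and is
#' flagged.
#'
#' @param fit an ML-fitted lmerMod or lm (as from
#'   \code{\link{fitCandidates}}).
#' @return list with \code{fit} (REML or lm), \code{coefficients}
#'   (estimate, SE, df, t, p per fixed effect) and \code{singular}.
#' @export
refitREML <- function(fit) {
  if (inherits(fit, "merMod")) {
    fml <- stats::formula(fit)
    dat <- stats::model.frame(fit)
    ## model.frame mangles the response/grouping names into columns
    refit <- lmerTest::lmer(fml, data = dat, REML = TRUE)
    if (lme4::isSingular(refit)) {
      fixedFml <- lme4::nobars(fml)
      lmFit <- stats::lm(fixedFml, data = dat)
      cf <- summary(lmFit)$coefficients
      return(list(fit = lmFit,
                  coefficients = data.frame(
                    term = rownames(cf), estimate = cf[, 1],
                    se = cf[, 2], df = lmFit$df.residual,
                    t = cf[, 3], p = cf[, 4], row.names = NULL),
                  singular = TRUE))
    }
    cf <- stats::coef(summary(refit))
    list(fit = refit,
         coefficients = data.frame(
           term = rownames(cf), estimate = cf[, "Estimate"],
           se = cf[, "Std. Error"], df = cf[, "df"],
           t = cf[, "t value"], p = cf[, "Pr(>|t|)"],
           row.names = NULL),
         singular = FALSE)
  } else {
    cf <- summary(fit)$coefficients
    list(fit = fit,
         coefficients = data.frame(
           term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
           df = fit$df.residual, t = cf[, 3], p = cf[, 4],
           row.names = NULL),
         singular = FALSE)
  }
}
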