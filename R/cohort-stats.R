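#' Normality-gated two-group comparison
#'
#' Compares a variable between the COPD and control groups. Shapiro-Wilk
#' normality is tested per group; if either group departs from normality
#' at `alphaNormality` the Mann-Whitney U (Wilcoxon rank-sum) test is
#' used, otherwise a t test (Welch by default; set `welch = FALSE` for
#' the classic equal-variance Student test). Summaries report the median
#' with 25th/75th percentiles alongside mean and SD.
#'
#' @param table cohort data.frame with a `group` column.
#' @param variable column name to compare.
#' @param alphaNormality significance level of the normality gate.
#' @param welch use the Welch (unequal-variance) t statistic.
#' @return list of class `GroupComparison`: per-group summaries, the
#'   normality p-values, the test used, its statistic and p-value.
#' @export
compareGroups <- function(table, variable, alphaNormality = 0.05,
                          welch = TRUE) {
  stopifnot(variable %in% names(table), "group" %in% names(table))
  x <- table[[variable]][table$group == "COPD"]
  y <- table[[variable]][table$group == "control"]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L)
    stop("both groups need at least 3 observations")

  summ <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    list(n = length(v), median = q[2], q25 = q[1], q75 = q[3],
         mean = mean(v), sd = stats::sd(v))
  }
  res <- list(variable = variable,
              copd = summ(x), control = summ(y))

  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    res$degenerate <- "both groups constant; no test performed"
    res$test <- "none"
    res$statistic <- if (mean(x) == mean(y)) 0 else NA_real_
    res$p.value <- if (mean(x) == mean(y)) 1 else NA_real_
    class(res) <- "GroupComparison"
    return(res)
  }

  shap <- function(v) {
    if (stats::sd(v) == 0 || length(v) < 3L || length(v) > 5000L)
      return(NA_real_)
    stats::shapiro.test(v)$p.value
  }
  res$normality <- c(copd = shap(x), control = shap(y))
  res$alphaNormality <- alphaNormality
  nonNormal <- any(res$normality < alphaNormality, na.rm = TRUE) ||
    any(is.na(res$normality))
  if (nonNormal) {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    res$test <- "Mann-Whitney"
  } else {
    ht <- stats::t.test(x, y, var.equal = !welch)
    res$test <- if (welch) "t (Welch)" else "t (Student)"
  }
  res$statistic <- unname(ht$statistic)
  res$p.value <- ht$p.value
  class(res) <- "GroupComparison"
  res
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("GroupComparison: %s\n", x$variable))
  fmt <- function(g, s) sprintf(
    "  %-8s n=%d  median %.3g (%.3g, %.3g)  mean %.3g +/- %.3g\n",
    g, s$n, s$median, s$q25, s$q75, s$mean, s$sd)
  cat(fmt("COPD", x$copd)); cat(fmt("control", x$control))
  cat(sprintf("  test: %s  statistic %.4g  p = %.4g\n",
              x$test, x$statistic, x$p.value))
  invisible(x)
}

#' Normality-gated bivariate correlation
#'
#' Pearson product-moment correlation by default; Spearman rank
#' correlation when either variable fails the per-variable Shapiro-Wilk
#' normality gate at `alphaNormality`.
#'
#' @param table data.frame.
#' @param x,y column names.
#' @param alphaNormality significance level of the normality gate.
#' @param method force `"pearson"` or `"spearman"` instead of gating.
#' @return list with `r`, `p.value`, `method`, `n`, and the normality
#'   p-values when the gate decided.
#' @export
correlateVars <- function(table, x, y, alphaNormality = 0.05,
                          method = NULL) {
  stopifnot(x %in% names(table), y %in% names(table))
  ok <- is.finite(table[[x]]) & is.finite(table[[y]])
  vx <- table[[x]][ok]; vy <- table[[y]][ok]
  if (length(vx) < 4L) stop("need at least 4 complete pairs")
  normP <- NULL
  if (is.null(method)) {
    shap <- function(v) if (stats::sd(v) == 0) 0 else
      stats::shapiro.test(v)$p.value
    normP <- c(shap(vx), shap(vy))
    names(normP) <- c(x, y)
    method <- if (any(normP < alphaNormality)) "spearman" else "pearson"
  }
  ct <- suppressWarnings(stats::cor.test(vx, vy, method = method,
                                         exact = FALSE))
  list(x = x, y = y, r = unname(ct$estimate), p.value = ct$p.value,
       method = method, n = length(vx), normality = normP)
}

#' Bidirectional stepwise regression with standardized coefficients
#'
#' Classic p-value stepwise selection on z-scored variables: at each
#' iteration the candidate with the smallest partial-F p-value below
#' `pEnter` is added, then any included term whose p-value exceeds
#' `pRemove` is dropped (largest first), until a fixed point. Because
#' every variable is standardized, the reported coefficients are
#' standardized betas; with a single selected predictor the beta equals
#' the Pearson correlation with the outcome. Candidates that are
#' near-collinear with the current model (squared multiple correlation
#' with included terms above 0.999) are skipped with a warning.
#'
#' @param table data.frame.
#' @param outcome outcome column name.
#' @param candidates character vector of candidate predictor columns.
#' @param pEnter forward inclusion threshold (default 0.05).
#' @param pRemove backward elimination threshold (default 0.10).
#' @return list of class `RegressionReport`: `selected` (data.frame of
#'   term, standardized beta, p-value), `r.squared` of the final model,
#'   `unselected` (last-considered p-value of each excluded candidate),
#'   and `trace` (the add/drop steps with cumulative R-squared).
#' @export
stepwiseRegression <- function(table, outcome, candidates,
                               pEnter = 0.05, pRemove = 0.10) {
  stopifnot(outcome %in% names(table), all(candidates %in% names(table)))
  dat <- table[c(outcome, candidates)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n <= length(candidates) + 2L)
    stop("need n > number of candidates + 2")
  zs <- as.data.frame(lapply(dat, function(v) {
    s <- stats::sd(v)
    if (s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }))

  included <- character()
  trace <- list()
  lastP <- stats::setNames(rep(NA_real_, length(candidates)), candidates)
  fit <- function(terms) {
    f <- if (length(terms))
      stats::reformulate(terms, response = outcome)
    else stats::as.formula(paste(outcome, "~ 1"))
    stats::lm(f, data = zs)
  }
  termP <- function(model) {
    cf <- summary(model)$coefficients
    rows <- setdiff(rownames(cf), "(Intercept)")
    stats::setNames(cf[rows, "Pr(>|t|)"], rows)
  }

  repeat {
    changed <- FALSE
    # forward step
    pool <- setdiff(candidates, included)
    if (length(pool)) {
      pvals <- vapply(pool, function(cand) {
        if (length(included)) {
          # aux R^2 only; a perfect fit here is exactly the case we guard
          aux <- suppressWarnings(summary(stats::lm(
            stats::reformulate(included, response = cand),
            data = zs))$r.squared)
          if (aux > 0.999) {
            warning(sprintf("candidate %s is collinear with the model; skipped",
                            cand))
            return(NA_real_)
          }
        }
        m <- fit(c(included, cand))
        p <- termP(m)
        unname(p[cand])
      }, numeric(1))
      lastP[names(pvals)] <- pvals
      best <- which.min(pvals)
      if (length(best) && !is.na(pvals[best]) && pvals[best] < pEnter) {
        included <- c(included, pool[best])
        m <- fit(included)
        trace[[length(trace) + 1L]] <- list(
          step = "add", term = pool[best], p = unname(pvals[best]),
          r.squared = summary(m)$r.squared)
        changed <- TRUE
      }
    }
    # backward step
    if (length(included)) {
      p <- termP(fit(included))
      worst <- which.max(p)
      if (p[worst] > pRemove) {
        dropped <- included[worst]
        lastP[dropped] <- unname(p[worst])
        included <- setdiff(included, dropped)
        trace[[length(trace) + 1L]] <- list(
          step = "drop", term = dropped, p = unname(p[worst]),
          r.squared = summary(fit(included))$r.squared)
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  final <- fit(included)
  sm <- summary(final)
  selected <- if (length(included)) {
    cf <- sm$coefficients
    data.frame(term = included,
               beta = unname(cf[included, "Estimate"]),
               p.value = unname(cf[included, "Pr(>|t|)"]),
               stringsAsFactors = FALSE)
  } else data.frame(term = character(), beta = numeric(),
                    p.value = numeric(), stringsAsFactors = FALSE)
  res <- list(outcome = outcome, candidates = candidates,
              selected = selected,
              r.squared = if (length(included)) sm$r.squared else 0,
              unselected = lastP[setdiff(candidates, included)],
              trace = trace, n = n,
              pEnter = pEnter, pRemove = pRemove)
  class(res) <- "RegressionReport"
  res
}

#' @export
print.RegressionReport <- function(x, ...) {
  cat(sprintf("RegressionReport: %s ~ stepwise(%s), n = %d\n",
              x$outcome, paste(x$candidates, collapse = ", "), x$n))
  if (nrow(x$selected)) {
    for (i in seq_len(nrow(x$selected)))
      cat(sprintf("  %-10s beta = %+.3f  p = %.4g\n",
                  x$selected$term[i], x$selected$beta[i],
                  x$selected$p.value[i]))
  } else cat("  (no variable selected; null model)\n")
  cat(sprintf("  cumulative R-squared = %.3f\n", x$r.squared))
  invisible(x)
}
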