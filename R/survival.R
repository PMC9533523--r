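# Survival validation layer: Kaplan-Meier, log-rank, Cox, C-index, iAUC.
#
# The estimators are delegated to the survival package (product-limit,
# log-rank via survdiff, Cox partial likelihood with Efron ties, Harrell's
# concordance); the time-dependent AUC and its 0-5 year integral are
# implemented here (Uno-style IPCW, cumulative cases / dynamic controls)
# because no pre-packaged R estimator is assumed.

#' Kaplan-Meier curve
#'
#' Product-limit estimate of the survival function.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators: 1 = death (any cause), 0 = censored.
#' @return An object of class `km_curve`: list with `time` (increasing unique
#'   times), `surv` (right-continuous step values), `n_risk`, `n_event`, `n`.
#' @export
km_curve <- function(times, events) {
  if (length(times) < 1L) stop("need at least one subject")
  if (any(times <= 0)) stop("times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n = length(times)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Evaluates the right-continuous step function; S(0) = 1, and the 5-year
#' rate is `survival_at(curve, 5)`.
#'
#' @param curve A [km_curve()].
#' @param t Non-negative time(s); vectorized.
#' @return S(t) value(s) in [0, 1].
#' @export
survival_at <- function(curve, t) {
  if (!inherits(curve, "km_curve")) stop("curve must be a km_curve")
  if (any(t < 0)) stop("t must be non-negative")
  c(1, curve$surv)[findInterval(t, curve$time) + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: n = %d, %d event times, S(max) = %.3f\n",
              x$n, sum(x$n_event > 0), min(x$surv)))
  invisible(x)
}

#' K-group log-rank test
#'
#' Standard observed-minus-expected log-rank statistic with a two-sided
#' p-value from the chi-square distribution on k - 1 degrees of freedom.
#'
#' @param times,events As in [km_curve()].
#' @param groups Group labels, at least two distinct values.
#' @return List with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("log-rank requires at least 2 groups")
  fit <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1L
  list(chi2 = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Harrell's concordance index
#'
#' Concordance between a risk score (higher = worse prognosis) and observed
#' survival, over all usable pairs; ties in the risk score count 0.5.
#'
#' @param risk Numeric risk scores.
#' @param times,events As in [km_curve()].
#' @return C-index in [0, 1].
#' @export
c_index <- function(risk, times, events) {
  if (length(risk) != length(times)) stop("risk and times lengths differ")
  fit <- survival::concordance(survival::Surv(times, events) ~ risk,
                               reverse = TRUE)
  counts <- fit$count
  if (sum(counts[c("concordant", "discordant", "tied.x")]) == 0)
    stop("no comparable pairs")
  unname(fit$concordance)
}

# IPCW weights 1/G(T-) from the Kaplan-Meier estimate of the censoring
# distribution (events and censorings swapped), evaluated just before each
# subject's time.
censoring_weights <- function(times, events) {
  cfit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  # left limit: G(t-) evaluated by stepping just below t
  G <- c(1, cfit$surv)[findInterval(times - 1e-12, cfit$time) + 1L]
  G[G <= 0] <- min(G[G > 0])
  1 / G
}

#' Time-dependent AUC and its 0-5 year integral
#'
#' Cumulative/dynamic time-dependent AUC with inverse-probability-of-censoring
#' weights (Uno-style): at time t, cases are subjects with an observed event
#' at or before t (weighted by 1/G(T-), G the censoring survival function) and
#' controls are subjects still at risk after t. `AUC(t)` is the weighted
#' probability that a case outranks a control, ties counting 0.5. The
#' integrated AUC is the trapezoid-rule integral of AUC(t) over a grid of
#' event times in (0, horizon], normalized by the grid span (for a single
#' usable grid point it is that point's AUC). Grids larger than `max_grid`
#' points are thinned to evenly spaced quantiles of the event times.
#'
#' @param risk Numeric risk scores (higher = worse prognosis).
#' @param times,events As in [km_curve()].
#' @param horizon Upper end of the integration window in the time unit of
#'   `times`; default 5 (years).
#' @param max_grid Maximum number of evaluation times, default 250.
#' @return List with `iauc`, `grid` (evaluation times) and `auc` (AUC(t)).
#' @export
iauc <- function(risk, times, events, horizon = 5, max_grid = 250L) {
  if (horizon <= 0) stop("horizon must be > 0")
  if (length(risk) != length(times)) stop("risk and times lengths differ")
  ev_times <- sort(unique(times[events == 1 & times <= horizon]))
  if (!length(ev_times)) stop("no events before the horizon")
  # need at least one control after t: drop grid points with none
  ev_times <- ev_times[vapply(ev_times, function(t) any(times > t), logical(1))]
  if (!length(ev_times)) stop("no usable evaluation times before the horizon")
  if (length(ev_times) > max_grid)
    ev_times <- unique(stats::quantile(ev_times, seq(0, 1, length.out = max_grid),
                                       type = 1, names = FALSE))
  w <- censoring_weights(times, events)
  auc_at <- function(t) {
    case <- which(times <= t & events == 1)
    ctrl <- which(times > t)
    rs <- sort(risk[ctrl])
    n_ctrl <- length(ctrl)
    # for each case: #controls strictly below + 0.5 * #ties, via sorted ranks
    lo <- findInterval(risk[case], rs, left.open = TRUE)   # strictly less
    hi <- findInterval(risk[case], rs)                     # less or equal
    num <- sum(w[case] * (lo + 0.5 * (hi - lo)))
    num / (sum(w[case]) * n_ctrl)
  }
  auc <- vapply(ev_times, auc_at, numeric(1))
  iauc_val <- if (length(ev_times) == 1L) {
    auc
  } else {
    span <- ev_times[length(ev_times)] - ev_times[1]
    sum(diff(ev_times) * (utils::head(auc, -1) + utils::tail(auc, -1)) / 2) / span
  }
  list(iauc = iauc_val, grid = ev_times, auc = auc)
}

#' Proportional-hazards fits in the style of a prognostic-factor table
#'
#' Fits Cox proportional-hazards models (partial likelihood, Efron tie
#' handling) for overall survival. In `"univariate"` mode each covariate is
#' fit alone; `"multivariate"` refits jointly the covariates with any
#' univariate Wald p below `select_p`; `"both"` returns the two tables
#' side by side. Categorical covariates are dummy-coded against their
#' reference level (first factor level, override via `reference_levels`);
#' hazard ratios are `exp(coef)` with 95% Wald confidence intervals on the
#' log scale. Model discrimination is summarized by Harrell's C-index and
#' the 0-5 year integrated AUC of the linear predictor (multivariate model
#' when fitted, otherwise the first univariate model).
#'
#' @param data data.frame with time/event columns and covariates.
#' @param covariates Character vector of covariate column names.
#' @param reference_levels Named character vector, e.g.
#'   `c(stage = "I", cea = "normal")`.
#' @param time_col,event_col Column names, defaults `os_years` / `os_event`.
#' @param mode `"univariate"`, `"multivariate"` or `"both"`.
#' @param select_p Univariate selection threshold for the multivariate fit.
#' @return Object of class `cox_fit`: list with `table` (analysis, variable,
#'   level, hr, ci_low, ci_high, p, n), `selected`, `c_index`, `iauc`.
#' @export
cox_fit <- function(data, covariates, reference_levels = NULL,
                    time_col = "os_years", event_col = "os_event",
                    mode = c("both", "univariate", "multivariate"),
                    select_p = 0.05) {
  mode <- match.arg(mode)
  if (!all(c(time_col, event_col) %in% names(data)))
    stop("data must contain columns ", time_col, " and ", event_col)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) stop("missing covariates: ", paste(missing_cov, collapse = ", "))
  dat <- data
  for (v in covariates) {
    if (is.character(dat[[v]]) || is.logical(dat[[v]])) dat[[v]] <- factor(dat[[v]])
    if (is.factor(dat[[v]]) && !is.null(reference_levels) && v %in% names(reference_levels)
        && reference_levels[[v]] %in% levels(dat[[v]]))
      dat[[v]] <- stats::relevel(dat[[v]], ref = reference_levels[[v]])
    vals <- dat[[v]]
    if (length(unique(vals[!is.na(vals)])) < 2L)
      stop("covariate '", v, "' is constant")
  }
  surv_obj <- sprintf("survival::Surv(%s, %s)", time_col, event_col)
  fit_one <- function(vars, analysis) {
    f <- stats::as.formula(paste(surv_obj, "~", paste(vars, collapse = " + ")))
    fit <- tryCatch(
      survival::coxph(f, data = dat, ties = "efron"),
      error = function(e) stop("Cox fit failed (", analysis, "): ", conditionMessage(e)),
      warning = function(w) {
        if (grepl("converge|infinite", conditionMessage(w)))
          stop("Cox fit did not converge (possible separation): ", conditionMessage(w))
        suppressWarnings(survival::coxph(f, data = dat, ties = "efron"))
      })
    if (any(!is.finite(fit$coefficients)))
      stop("Cox fit produced non-finite coefficients (separation?)")
    s <- summary(fit)
    co <- s$coefficients
    term_var <- rep(vars, vapply(vars, function(v)
      if (is.factor(dat[[v]])) nlevels(dat[[v]]) - 1L else 1L, integer(1)))
    lvl <- mapply(function(term, v) sub(paste0("^", v), "", term),
                  rownames(co), term_var)
    lvl[lvl == ""] <- "(continuous)"
    list(fit = fit,
         table = data.frame(analysis = analysis, variable = term_var,
                            level = unname(lvl),
                            hr = unname(co[, "exp(coef)"]),
                            ci_low = unname(s$conf.int[, "lower .95"]),
                            ci_high = unname(s$conf.int[, "upper .95"]),
                            p = unname(co[, "Pr(>|z|)"]),
                            n = s$n))
  }
  tables <- list(); uni_min_p <- NULL; last_fit <- NULL
  if (mode %in% c("univariate", "both")) {
    uni <- lapply(covariates, function(v) fit_one(v, "univariate"))
    tables <- c(tables, lapply(uni, `[[`, "table"))
    uni_min_p <- vapply(seq_along(covariates), function(i)
      min(uni[[i]]$table$p), numeric(1))
    names(uni_min_p) <- covariates
    last_fit <- uni[[1]]$fit
  }
  selected <- character(0)
  if (mode %in% c("multivariate", "both")) {
    selected <- if (is.null(uni_min_p)) {
      covariates
    } else {
      covariates[uni_min_p < select_p]
    }
    if (length(selected)) {
      multi <- fit_one(selected, "multivariate")
      tables <- c(tables, list(multi$table))
      last_fit <- multi$fit
    } else if (mode == "multivariate") {
      stop("no covariates pass the univariate selection threshold")
    }
  }
  lp <- stats::predict(last_fit, type = "lp")
  used <- as.integer(rownames(stats::model.frame(last_fit)))
  ci <- c_index(lp, dat[[time_col]][used], dat[[event_col]][used])
  ia <- tryCatch(iauc(lp, dat[[time_col]][used], dat[[event_col]][used])$iauc,
                 error = function(e) NA_real_)
  structure(list(table = do.call(rbind, tables), selected = selected,
                 c_index = ci, iauc = ia),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  tab <- x$table
  tab$hr <- sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$ci_low, tab$ci_high)
  tab$p <- format.pval(tab$p, digits = 2, eps = 1e-3)
  print(tab[, c("analysis", "variable", "level", "hr", "p", "n")],
        row.names = FALSE)
  cat(sprintf("C-index %.3f, iAUC(0-5y) %.3f\n", x$c_index, x$iauc))
  invisible(x)
}

#' Stage-stratified Kaplan-Meier analysis
#'
#' Restricts the data to one stratum (e.g. stage II), then computes per-group
#' Kaplan-Meier curves and the log-rank p-value across the grouping variable.
#' An empty stratum, or a stratum with a single group, is skipped with a
#' warning and returns `NULL`.
#'
#' @param data data.frame with time/event columns, the stratum column and the
#'   grouping column.
#' @param stratum_col,stratum_level Column and value defining the stratum.
#' @param group_col Grouping column (e.g. the immune score).
#' @param time_col,event_col As in [cox_fit()].
#' @return List with `stratum`, `curves` (named list of [km_curve()]s),
#'   `logrank` and `n`, or `NULL` when skipped.
#' @export
stratified_km <- function(data, stratum_col, stratum_level, group_col,
                          time_col = "os_years", event_col = "os_event") {
  sub <- data[data[[stratum_col]] == stratum_level, , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning("empty stratum ", stratum_level, "; skipped")
    return(NULL)
  }
  g <- factor(sub[[group_col]])
  if (nlevels(droplevels(g)) < 2L) {
    warning("stratum ", stratum_level, " has a single group; skipped")
    return(NULL)
  }
  curves <- lapply(split(sub, droplevels(g)), function(d)
    km_curve(d[[time_col]], d[[event_col]]))
  lr <- logrank_test(sub[[time_col]], sub[[event_col]], droplevels(g))
  list(stratum = stratum_level, curves = curves, logrank = lr, n = nrow(sub))
}
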