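# Percent-inhibition normalization and the sigmoidal exposure-response
# layer.  Percent inhibition rescales a treated group's mean endpoint
# between the vehicle-treated negative control (100%) and positive
# control (0%): %inh = 100 - (Y/K1)*100 with K1 = pos - neg and
# Y = treated - neg group means.  Values outside [0, 100] are meaningful
# (overshoot below the negative control exceeds 100%) and are never
# clipped in computation; only the tabular report floors negatives at 0
# for display.

group_means <- function(table, endpoint) {
  rows <- table[table$endpoint == endpoint, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop(sprintf("no rows for endpoint '%s'", endpoint))
  }
  tapply(rows$value, rows$group, mean)
}

#' Percent inhibition of a treated group
#'
#' @param table a [pd_table].
#' @param endpoint endpoint label.
#' @param group treated-group label (must have >= 1 row for the endpoint).
#' @return an `inhibition_result` list: `endpoint`, `group`,
#'   `percent_inhibition`, `K1` (positive minus negative control mean) and
#'   `Y` (treated minus negative control mean).
#' @export
percent_inhibition <- function(table, endpoint, group) {
  means <- group_means(table, endpoint)
  for (g in c("negative_control", "positive_control", group)) {
    if (!(g %in% names(means))) {
      stop(sprintf("percent_inhibition: endpoint '%s' has no group '%s'",
                   endpoint, g))
    }
  }
  K1 <- unname(means["positive_control"] - means["negative_control"])
  Y <- unname(means[group] - means["negative_control"])
  if (K1 == 0) {
    stop(sprintf(
      "percent_inhibition: K1 = 0 for endpoint '%s' (controls coincide)",
      endpoint))
  }
  structure(list(endpoint = endpoint, group = group,
                 percent_inhibition = 100 - (Y / K1) * 100,
                 K1 = K1, Y = Y),
            class = "inhibition_result")
}

hill_curve <- function(exposure, I_max, EC50, h) {
  I_max * exposure^h / (EC50^h + exposure^h)
}

#' Fit a Hill exposure-response curve to inhibition data
#'
#' Least-squares fit of `I(c) = I_max * c^h / (EC50^h + c^h)` to
#' (exposure, percent inhibition) pairs.  By default the ceiling `I_max`
#' is fixed at 100% (inhibition is a bounded normalized quantity);
#' `fix_imax = FALSE` frees it.  The optimization runs on
#' `(log EC50, log h)` so positivity is structural, starting from
#' EC50 = geometric mean of the exposures and h = 1; the start rule makes
#' the fit deterministic.
#'
#' @param exposure positive exposures, >= 3 distinct values (>= 4 if
#'   `I_max` is free).
#' @param inhibition percent inhibition at each exposure.
#' @param fix_imax fix the ceiling at `imax` (default `TRUE`).
#' @param imax ceiling value when fixed (default 100).
#' @return a `hill_fit` list: `I_max`, `EC50`, `h`, `rss` (residual sum
#'   of squares), `fitted`, `residuals`, `converged`.
#' @export
fit_hill <- function(exposure, inhibition, fix_imax = TRUE, imax = 100) {
  stopifnot(length(exposure) == length(inhibition))
  if (any(exposure <= 0)) stop("fit_hill: exposures must be positive")
  n_distinct <- length(unique(exposure))
  need <- if (fix_imax) 3L else 4L
  if (n_distinct < need) {
    stop(sprintf("fit_hill: need >= %d distinct exposures, got %d",
                 need, n_distinct))
  }
  if (stats::sd(inhibition) == 0) {
    stop("fit_hill: all inhibition values equal; no curve to fit")
  }
  start <- c(log_ec50 = mean(log(exposure)), log_h = 0)
  if (!fix_imax) start <- c(start, I_max = max(inhibition))
  obj <- function(par) {
    im <- if (fix_imax) imax else par[3L]
    pred <- hill_curve(exposure, im, exp(par[1L]), exp(par[2L]))
    sum((inhibition - pred)^2)
  }
  opt <- stats::nlminb(start, obj,
                       control = list(rel.tol = 1e-15, x.tol = 1e-15,
                                      eval.max = 2000L, iter.max = 1000L))
  if (!(opt$convergence %in% c(0L, 1L)) && opt$objective > 1e-8) {
    stop(sprintf("fit_hill: optimizer did not converge (%s)", opt$message))
  }
  EC50 <- exp(opt$par[[1L]])
  h <- exp(opt$par[[2L]])
  I_max <- if (fix_imax) imax else opt$par[[3L]]
  fitted <- hill_curve(exposure, I_max, EC50, h)
  structure(list(I_max = I_max, EC50 = EC50, h = h,
                 rss = opt$objective,
                 fitted = fitted, residuals = inhibition - fitted,
                 converged = opt$convergence == 0L),
            class = "hill_fit")
}

#' Evaluate / invert a fitted Hill curve
#'
#' `inhibition_at` predicts percent inhibition at an exposure;
#' `exposure_at` inverts the curve, returning the exposure producing a
#' given inhibition.  They are mutual inverses on `exposure > 0` and
#' `0 < inhibition < I_max`; inversion at or above the ceiling is
#' undefined and errors.
#'
#' @param fit a `hill_fit`.
#' @param exposure positive exposure(s).
#' @param inhibition percent inhibition strictly inside `(0, I_max)`.
#' @return numeric vector of inhibitions / exposures.
#' @export
inhibition_at <- function(fit, exposure) {
  if (any(exposure <= 0)) stop("inhibition_at: exposure must be positive")
  hill_curve(exposure, fit$I_max, fit$EC50, fit$h)
}

#' @rdname inhibition_at
#' @export
exposure_at <- function(fit, inhibition) {
  if (any(inhibition <= 0 | inhibition >= fit$I_max)) {
    stop("exposure_at: inhibition must lie strictly between 0 and I_max")
  }
  fit$EC50 * (inhibition / (fit$I_max - inhibition))^(1 / fit$h)
}

#' Endpoint-by-treatment percent-inhibition profile
#'
#' Builds the tabular efficacy report: one row per endpoint, one column
#' per treated group, each cell the percent inhibition from
#' [percent_inhibition()].  For display the matrix floors negative values
#' at 0 (the convention of printed efficacy tables); the raw values are
#' attached unfloored.  A per-cell control failure (e.g. K1 = 0) is
#' recorded as NA and the run continues.
#'
#' @param table a [pd_table].
#' @param endpoints endpoint labels (default: all in the table).
#' @param groups treated-group labels (default: all non-control groups).
#' @return an `efficacy_profile` numeric matrix (endpoints x groups,
#'   display-floored) with attributes `raw` (unfloored matrix) and
#'   `errors` (character vector of per-cell failure messages).
#' @export
efficacy_profile <- function(table, endpoints = NULL, groups = NULL) {
  if (is.null(endpoints)) endpoints <- unique(table$endpoint)
  if (is.null(groups)) {
    groups <- setdiff(unique(table$group),
                      c("negative_control", "positive_control"))
  }
  raw <- matrix(NA_real_, length(endpoints), length(groups),
                dimnames = list(endpoints, groups))
  errors <- character(0)
  for (ep in endpoints) {
    for (g in groups) {
      res <- tryCatch(percent_inhibition(table, ep, g),
                      error = function(e) conditionMessage(e))
      if (is.character(res)) {
        errors <- c(errors, res)
      } else {
        raw[ep, g] <- res$percent_inhibition
      }
    }
  }
  display <- pmax(raw, 0)
  structure(display, raw = raw, errors = errors,
            class = c("efficacy_profile", "matrix", "array"))
}
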