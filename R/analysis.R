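# Statistics suite: multi-family regression with best-fit selection,
# correlation screening, trait dynamic curves, per-date distribution
# statistics, and prediction accuracy metrics.

.FIT_FAMILIES <- c("linear", "quadratic", "exponential", "power",
                   "logarithmic")

.fit_one_family <- function(family, x, y) {
  n <- length(x)
  predict_fn <- NULL
  coefficients <- NULL
  note <- NA_character_
  switch(family,
    linear = {
      X <- cbind(1, x)
      coefficients <- qr.solve(X, y)
      predict_fn <- function(c, x) c[1] + c[2] * x
    },
    quadratic = {
      X <- cbind(1, x, x^2)
      coefficients <- qr.solve(X, y)
      predict_fn <- function(c, x) c[1] + c[2] * x + c[3] * x^2
    },
    exponential = {
      # y = a * exp(b x); log-linearised start, refined on original scale
      if (any(y <= 0))
        return(list(family = family, skipped = TRUE,
                    note = "exponential initialization requires y > 0"))
      init <- qr.solve(cbind(1, x), log(y))
      start <- c(exp(init[1]), init[2])
      predict_fn <- function(c, x) c[1] * exp(c[2] * x)
      sse <- function(c) {
        p <- predict_fn(c, x)
        if (any(!is.finite(p))) return(Inf)
        sum((y - p)^2)
      }
      opt <- stats::optim(start, sse, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14))
      coefficients <- opt$par
    },
    power = {
      # y = a * x^b
      if (any(x <= 0) || any(y <= 0))
        return(list(family = family, skipped = TRUE,
                    note = "power fit requires x > 0 and y > 0"))
      init <- qr.solve(cbind(1, log(x)), log(y))
      start <- c(exp(init[1]), init[2])
      predict_fn <- function(c, x) c[1] * x^c[2]
      sse <- function(c) {
        p <- predict_fn(c, x)
        if (any(!is.finite(p))) return(Inf)
        sum((y - p)^2)
      }
      opt <- stats::optim(start, sse, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14))
      coefficients <- opt$par
    },
    logarithmic = {
      if (any(x <= 0))
        return(list(family = family, skipped = TRUE,
                    note = "logarithmic fit requires x > 0"))
      X <- cbind(1, log(x))
      coefficients <- qr.solve(X, y)
      predict_fn <- function(c, x) c[1] + c[2] * log(x)
    })
  fitted <- predict_fn(coefficients, x)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(family = family, skipped = FALSE,
       coefficients = unname(coefficients),
       rmse = sqrt(ss_res / n),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       n = n, note = note, predict = predict_fn)
}

#' Fit candidate curve families and select the best
#'
#' Least-squares fits of five function families on the ORIGINAL scale:
#' linear `y = a + b x`; quadratic `y = a + b x + c x^2`; exponential
#' `y = a e^(b x)`; power `y = a x^b`; logarithmic `y = a + b ln x`.
#' Nonlinear families are initialised by log-linearisation and refined by
#' minimising the residual sum of squares. `RMSE = sqrt(mean((y - yhat)^2))`
#' and `R^2 = 1 - SSres/SStot`. The best set contains every family tied
#' for minimal RMSE after rounding to 4 decimals — ties are reported, not
#' broken. Families whose domain constraints fail (e.g. `y <= 0` for the
#' exponential initialisation) are skipped with a note.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @param families subset of
#'   `c("linear","quadratic","exponential","power","logarithmic")`.
#' @return object of class `fit_curves`: list with `fits` (per family) and
#'   `best` (character vector of best family names).
#' @examples
#' x <- 1:10; fit <- fit_curves(x, 2 + 3 * x)
#' fit$best  # linear and quadratic tie at RMSE 0
#' @export
fit_curves <- function(x, y, families = .FIT_FAMILIES) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("curve fitting needs n >= 3")
  if (stats::var(y) == 0)
    warning("zero variance in y: R-squared undefined", call. = FALSE)
  families <- match.arg(families, .FIT_FAMILIES, several.ok = TRUE)
  fits <- lapply(families, .fit_one_family, x = x, y = y)
  names(fits) <- families
  usable <- !vapply(fits, `[[`, logical(1), "skipped")
  rmse <- vapply(fits[usable], `[[`, numeric(1), "rmse")
  best <- if (length(rmse)) {
    r4 <- round(rmse, 4)
    names(rmse)[r4 == min(r4)]
  } else character()
  structure(list(fits = fits, best = best), class = "fit_curves")
}

#' @export
print.fit_curves <- function(x, ...) {
  cat("<fit_curves>\n")
  for (f in x$fits) {
    if (isTRUE(f$skipped)) {
      cat(sprintf("  %-12s skipped: %s\n", f$family, f$note))
    } else {
      cat(sprintf("  %-12s rmse %.6g  R2 %.4f  coef (%s)%s\n", f$family,
                  f$rmse, f$r_squared,
                  paste(signif(f$coefficients, 6), collapse = ", "),
                  if (f$family %in% x$best) "  <- best" else ""))
    }
  }
  invisible(x)
}

#' Pearson correlation matrix with truth-ranked screening
#'
#' Pairwise-complete Pearson coefficients between the given variables of a
#' wide table. Constant columns yield `NA` coefficients. When `truth` names
#' a column, the remaining variables are also returned ranked by absolute
#' correlation with it — the screening step used to shortlist traits
#' against ground truth.
#'
#' @param wide data.frame (e.g. from [phenotype_wide()]).
#' @param variables column names to include.
#' @param truth optional column name of the ground-truth variable.
#' @return list: `matrix` (symmetric, unit diagonal), and `ranking`
#'   (data.frame variable/correlation, by decreasing `|r|`) when `truth`
#'   is given.
#' @export
correlation_matrix <- function(wide, variables, truth = NULL) {
  missing_cols <- setdiff(variables, names(wide))
  if (length(missing_cols))
    stop("unknown variable(s): ", paste(missing_cols, collapse = ", "))
  m <- as.matrix(wide[, variables, drop = FALSE])
  cm <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(cm) <- 1
  ranking <- NULL
  if (!is.null(truth)) {
    if (!truth %in% variables)
      stop("truth column '", truth, "' is not among the variables")
    others <- setdiff(variables, truth)
    r <- cm[truth, others]
    ord <- order(abs(r), decreasing = TRUE, na.last = TRUE)
    ranking <- data.frame(variable = others[ord], correlation = r[ord],
                          row.names = NULL, stringsAsFactors = FALSE)
  }
  list(matrix = cm, ranking = ranking)
}

.per_date_values <- function(table, trait) {
  df <- as.data.frame(table)
  if (!trait %in% df$trait)
    stop("unknown trait '", trait, "'")
  df <- df[df$trait == trait & !is.na(df$value), ]
  split(df$value, df$date)
}

#' Trait dynamic curve: per-date mean and max
#'
#' Change trend of a trait across flight dates: per date, the mean and
#' maximum across plots (missing values excluded). Dates whose values are
#' all missing are omitted with a warning.
#'
#' @param table a [phenotype_table()] (long format).
#' @param trait trait name.
#' @return data.frame: date, n, mean, max (date-ordered).
#' @export
dynamic_curve <- function(table, trait) {
  df <- as.data.frame(table)
  if (!trait %in% df$trait) stop("unknown trait '", trait, "'")
  all_dates <- sort(unique(df$date[df$trait == trait]))
  groups <- .per_date_values(table, trait)
  dropped <- setdiff(all_dates, names(groups))
  if (length(dropped))
    warning("date(s) with all-missing '", trait, "' omitted: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  dates <- sort(names(groups))
  data.frame(date = dates,
             n = vapply(groups[dates], length, integer(1)),
             mean = vapply(groups[dates], mean, numeric(1)),
             max = vapply(groups[dates], max, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-date distribution statistics (box-plot summary)
#'
#' For each date: min, lower quartile, median, upper quartile, max
#' (linear-interpolation quartiles, R type 7), and the values beyond
#' 1.5 IQR from the quartiles listed as outliers.
#'
#' @param table a [phenotype_table()] (long format).
#' @param trait trait name.
#' @return list with `stats` (data.frame date, n, min, q1, median, q3,
#'   max) and `outliers` (named list of numeric vectors per date).
#' @export
distribution_stats <- function(table, trait) {
  groups <- .per_date_values(table, trait)
  dates <- sort(names(groups))
  rows <- lapply(dates, function(d) {
    v <- groups[[d]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(date = d, n = length(v), min = min(v), q1 = q[1],
               median = q[2], q3 = q[3], max = max(v),
               stringsAsFactors = FALSE)
  })
  outliers <- lapply(dates, function(d) {
    v <- groups[[d]]
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    v[v < q[1] - 1.5 * iqr | v > q[2] + 1.5 * iqr]
  })
  names(outliers) <- dates
  list(stats = do.call(rbind, rows), outliers = outliers)
}

#' Prediction accuracy metrics
#'
#' `R^2 = 1 - SSres/SStot`, `RMSE = sqrt(mean((obs - pred)^2))`, and
#' `rRMSE = 100 * RMSE / mean(observed)` (percent). A constant observed
#' vector leaves R-squared undefined; a zero observed mean leaves rRMSE
#' undefined (both flagged as `NA` with a warning).
#'
#' @param predicted,observed numeric vectors of equal length, `n >= 2`.
#' @return list: `r_squared`, `rmse`, `rrmse` (percent), `n`.
#' @examples
#' accuracy_report(c(3, 3), c(2, 4))  # rmse 1, rrmse 33.33
#' @export
accuracy_report <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  ok <- stats::complete.cases(predicted, observed)
  predicted <- predicted[ok]; observed <- observed[ok]
  n <- length(observed)
  if (n < 2) stop("accuracy_report needs n >= 2")
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else {
    warning("constant observed values: R-squared undefined", call. = FALSE)
    NA_real_
  }
  rmse <- sqrt(ss_res / n)
  rrmse <- if (mean(observed) != 0) 100 * rmse / mean(observed) else {
    warning("zero mean observed: rRMSE undefined", call. = FALSE)
    NA_real_
  }
  list(r_squared = r2, rmse = rmse, rrmse = rrmse, n = n)
}
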