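#' Evaluate predictions against labels
#'
#' Computes the three regression measures used throughout the package:
#' the coefficient of determination `R2 = 1 - SS_res / SS_tot`, the
#' Pearson correlation `Rp = cov(Y, F) / (sigma_Y * sigma_F)` using
#' population (1/n) moments, and `RMSE = sqrt(mean((y - f)^2))`. The
#' regression sum of squares `SS_reg = sum((f - mean(y))^2)` is reported
#' for completeness although `R2` is defined through `SS_res`.
#'
#' Labels with zero variance leave `R2` and `Rp` undefined and raise an
#' error. Constant predictions leave only `Rp` undefined; it is returned
#' as `NA` with a warning so that the null model (predicting the label
#' mean, `R2 = 0`) can still be scored.
#'
#' @param labels Numeric vector of ground-truth responses.
#' @param predictions Numeric vector of predicted responses, same length.
#' @return A `metrics_report`: list with `r2`, `rp`, `rmse`, `n`,
#'   `ss_tot`, `ss_reg`, `ss_res`.
#' @examples
#' evaluate_predictions(c(0, 1, 2), c(0, 1, 1))
#' @export
evaluate_predictions <- function(labels, predictions) {
  if (!is.numeric(labels) || !is.numeric(predictions)) {
    stop("labels and predictions must be numeric")
  }
  if (length(labels) != length(predictions)) {
    stop(sprintf("length mismatch: %d labels vs %d predictions",
                 length(labels), length(predictions)))
  }
  n <- length(labels)
  if (n < 2L) stop("need at least 2 observations")
  if (any(!is.finite(labels)) || any(!is.finite(predictions))) {
    stop("labels and predictions must be finite")
  }
  ybar <- mean(labels)
  ss_tot <- sum((labels - ybar)^2)
  if (ss_tot == 0) {
    stop("undefined metric: R2 and Rp require non-constant labels")
  }
  e <- labels - predictions
  ss_res <- sum(e^2)
  ss_reg <- sum((predictions - ybar)^2)
  fbar <- mean(predictions)
  sd_y <- sqrt(mean((labels - ybar)^2))
  sd_f <- sqrt(mean((predictions - fbar)^2))
  rp <- if (sd_f == 0) {
    warning("undefined metric: Rp is NA for constant predictions")
    NA_real_
  } else {
    mean((labels - ybar) * (predictions - fbar)) / (sd_y * sd_f)
  }
  structure(list(r2 = 1 - ss_res / ss_tot,
                 rp = rp,
                 rmse = sqrt(ss_res / n),
                 n = n,
                 ss_tot = ss_tot, ss_reg = ss_reg, ss_res = ss_res),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  R2=%.4f  Rp=%.4f  RMSE=%.4f\n",
              x$n, x$r2, x$rp, x$rmse))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(r2 = x$r2, rp = x$rp, rmse = x$rmse, n = x$n,
             ss_tot = x$ss_tot, ss_reg = x$ss_reg, ss_res = x$ss_res)
}

# Collapse a list of metrics_report (or a data.frame of them) into one
# data.frame with a row per repetition.
reports_frame <- function(reports) {
  if (is.data.frame(reports)) return(reports)
  stopifnot(is.list(reports), length(reports) >= 1L)
  do.call(rbind, lapply(reports, as.data.frame))
}

#' Summarize metrics over repeated runs
#'
#' Reports, per metric, the mean and the top quartile (75th percentile,
#' linear interpolation) across repetitions — the two statistics used to
#' compare repeated evaluation runs.
#'
#' @param reports List of `metrics_report` objects (or a `data.frame`
#'   with columns `r2`, `rp`, `rmse`).
#' @return `data.frame` with columns `metric`, `mean`, `top_quartile`.
#' @export
summarize_repetitions <- function(reports) {
  df <- reports_frame(reports)
  if (nrow(df) == 0L) stop("no reports to summarize")
  mets <- c("r2", "rp", "rmse")
  data.frame(
    metric = mets,
    mean = vapply(mets, function(m) mean(df[[m]]), numeric(1)),
    top_quartile = vapply(mets, function(m) {
      unname(stats::quantile(df[[m]], 0.75, type = 7, names = FALSE))
    }, numeric(1)),
    row.names = NULL
  )
}

#' Write a metrics report as JSON
#'
#' @param report A `metrics_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' One-line CSV rendering of a metrics report for experiment logs
#'
#' @param report A `metrics_report`.
#' @return Single CSV line `r2,rp,rmse,n` (no header).
#' @export
metrics_csv_line <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  paste(report$r2, report$rp, report$rmse, report$n, sep = ",")
}
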