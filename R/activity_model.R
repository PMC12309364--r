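# Three-feature linear model of G4 component activity (REU ~ tract length +
# tract count + mean loop length), correlation statistics, structure-acting
# classification, standardized-residual outlier screening, and cross-context
# shift estimation. The regression and correlation statistics are computed
# from the normal equations / closed forms directly.

.feature_cols <- c("tract_length", "tract_count", "loop_length")

#' Fit the linear activity model
#'
#' Ordinary least squares of mean REU on the three design features
#' (G-tract length, G-tract number, mean loop length), solved via the normal
#' equations. Negative coefficients on tract length and count reflect that
#' longer and more numerous G-tracts form more stable quadruplexes and so
#' suppress expression more strongly.
#'
#' @param records Activity table: data.frame with columns `level`,
#'   `tract_length`, `tract_count`, `loop_length` and `reu_mean` (one row
#'   per component; `loop_length` is the mean loop length).
#' @param level Which level's records to fit, `"DNA"` or `"RNA"`.
#' @return Object of class `g4_activity_model`: named `coefficients`
#'   (intercept, tract_length, tract_count, loop_length), `r_squared`,
#'   `f_statistic`, `f_pvalue`, `n`, `sigma` (residual SD), `level`.
#' @export
fit_activity_model <- function(records, level = c("DNA", "RNA")) {
  level <- match.arg(toupper(level[1]), c("DNA", "RNA"))
  need <- c("level", .feature_cols, "reu_mean")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  rec <- records[records$level == level, , drop = FALSE]
  n <- nrow(rec)
  if (n < 5L) stop("need >= 5 records at level ", level, ", got ", n)

  X <- cbind(intercept = 1, as.matrix(rec[, .feature_cols]))
  y <- rec$reu_mean
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design: feature(s) ", paste(dropped, collapse = ", "),
         " are collinear with the others")
  }
  beta <- solve(crossprod(X), crossprod(X, y))[, 1]
  fitted <- as.vector(X %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("response has zero variance")
  r2 <- 1 - rss / tss
  p <- length(.feature_cols)
  df2 <- n - p - 1L
  fstat <- ((tss - rss) / p) / (rss / df2)
  fp <- stats::pf(fstat, p, df2, lower.tail = FALSE)
  structure(
    list(level = level, coefficients = beta, r_squared = r2,
         f_statistic = fstat, f_pvalue = fp, n = n,
         sigma = sqrt(rss / df2)),
    class = "g4_activity_model"
  )
}

#' @export
print.g4_activity_model <- function(x, ...) {
  cat(sprintf("<g4_activity_model> %s level, n = %d\n", x$level, x$n))
  print(round(x$coefficients, 4))
  cat(sprintf("R-squared %.4f, F = %.2f (p = %.3g)\n", x$r_squared,
              x$f_statistic, x$f_pvalue))
  invisible(x)
}

#' Predict component REU from design features
#'
#' Linear prediction clipped to `[0, 120]` REU (expression above the
#' unengineered control has been observed up to ~107%, hence the headroom).
#'
#' @param model A [fit_activity_model()] object, or any list with a
#'   4-element `coefficients` vector.
#' @param features Numeric length-3 vector `(tract_length, tract_count,
#'   mean loop length)`, or a data.frame with those columns.
#' @param bounds Clipping bounds, default `c(0, 120)`.
#' @return Predicted REU (vector when `features` is a data.frame).
#' @export
predict_reu <- function(model, features, bounds = c(0, 120)) {
  beta <- model$coefficients
  if (is.data.frame(features)) {
    X <- cbind(1, as.matrix(features[, .feature_cols]))
  } else {
    if (length(features) != 3L) {
      stop("'features' must be (tract_length, tract_count, loop_length)")
    }
    X <- matrix(c(1, features), nrow = 1L)
  }
  pmin(pmax(as.vector(X %*% beta), bounds[1]), bounds[2])
}

#' Pearson correlation with t-transform p-value
#'
#' Product-moment correlation; the two-sided p-value uses
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `p`, `t`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values in input")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) stop("constant input: correlation undefined")
  r <- sum(dx * dy) / sqrt(sxx * syy)
  if (abs(r) >= 1) {
    tstat <- Inf * sign(r); p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, t = tstat, n = n)
}

#' Partition components into structure-acting vs insertional-only
#'
#' Disabled (mutated) motifs still reduce expression by ~5-20% through a
#' generic insertional effect; only components whose reduction exceeds that
#' band are credited with secondary-structure-based control. A component is
#' `structure_acting` iff `100 - reu_mean > threshold` (strict).
#'
#' @param records Activity table with `reu_mean`.
#' @param threshold Reduction threshold in REU percentage points
#'   (default 20).
#' @return `records` with an added `classification` column.
#' @export
classify_components <- function(records, threshold = 20) {
  if (!"reu_mean" %in% names(records)) stop("records lack 'reu_mean'")
  records$classification <- ifelse(100 - records$reu_mean > threshold,
                                   "structure_acting", "insertional_only")
  records
}

#' Screen paired measurements for outliers by standardized residuals
#'
#' Fits a simple linear regression of `observed` on `reference`, computes
#' internally studentized residuals, and flags points with |z| above the
#' threshold. Reports the Pearson correlation before and after excluding
#' flagged points.
#'
#' @param observed,reference Paired numeric vectors, n >= 4.
#' @param z_threshold Flagging threshold on |standardized residual|
#'   (default 2.5).
#' @return List with `flags` (logical), `z`, `r_before`, `r_after`,
#'   `slope`, `intercept`.
#' @export
outlier_screen <- function(observed, reference, z_threshold = 2.5) {
  n <- length(observed)
  if (length(reference) != n) stop("paired series must have equal length")
  if (n < 4L) stop("need at least 4 paired observations")
  xbar <- mean(reference); ybar <- mean(observed)
  sxx <- sum((reference - xbar)^2)
  if (sxx == 0) stop("'reference' is constant")
  slope <- sum((reference - xbar) * (observed - ybar)) / sxx
  intercept <- ybar - slope * xbar
  res <- observed - (intercept + slope * reference)
  s2 <- sum(res^2) / (n - 2)
  h <- 1 / n + (reference - xbar)^2 / sxx
  z <- if (s2 == 0) rep(0, n) else res / sqrt(s2 * (1 - h))
  flags <- abs(z) > z_threshold
  r_before <- pearson_r(observed, reference)$r
  r_after <- if (sum(!flags) >= 3L && stats::var(reference[!flags]) > 0 &&
                 stats::var(observed[!flags]) > 0) {
    pearson_r(observed[!flags], reference[!flags])$r
  } else NA_real_
  list(flags = flags, z = z, r_before = r_before, r_after = r_after,
       slope = slope, intercept = intercept)
}

#' Mean expression shift between two cell contexts
#'
#' Pairs components by label across two activity tables and returns the mean
#' REU shift (b minus a) together with the Pearson correlation of the paired
#' REUs. A positive shift means the components inhibit less strongly in
#' context b.
#'
#' @param records_a,records_b Activity tables with `component_label` and
#'   `reu_mean`, covering the same components.
#' @return List with `mean_shift`, `r`, `n`.
#' @export
context_shift <- function(records_a, records_b) {
  for (r in list(records_a, records_b)) {
    if (!all(c("component_label", "reu_mean") %in% names(r))) {
      stop("records need 'component_label' and 'reu_mean'")
    }
  }
  only_a <- setdiff(records_a$component_label, records_b$component_label)
  only_b <- setdiff(records_b$component_label, records_a$component_label)
  if (length(only_a) || length(only_b)) {
    stop("unpaired component labels; only in a: [",
         paste(only_a, collapse = ", "), "]; only in b: [",
         paste(only_b, collapse = ", "), "]")
  }
  idx <- match(records_a$component_label, records_b$component_label)
  a <- records_a$reu_mean
  b <- records_b$reu_mean[idx]
  list(mean_shift = mean(b - a),
       r = if (length(a) >= 3L && stats::var(a) > 0 && stats::var(b) > 0)
         pearson_r(a, b)$r else NA_real_,
       n = length(a))
}
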