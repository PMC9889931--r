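#' Spearman rank correlation with a Fisher-transform confidence interval
#'
#' Ranks (average ranks for ties) are computed for both variables and the
#' product-moment correlation of the ranks is returned, with an
#' approximate CI from the Fisher r-to-z transform using standard error
#' `1/sqrt(n - 3)`. Incomplete pairs are dropped.
#'
#' @param x,y Numeric vectors of equal length.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `rho`, `n`, `conf_low`, `conf_high`.
#' @export
spearman_rho <- function(x, y, conf_level = 0.95) {
  cc <- stats::complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: an input is constant")
  }
  rho <- moment_cor(rank(x), rank(y))
  ci <- fisher_ci(rho, n, conf_level)
  list(rho = rho, n = n, conf_low = ci[[1L]], conf_high = ci[[2L]])
}

#' Pearson correlation with a Fisher-transform confidence interval
#'
#' @inheritParams spearman_rho
#' @return List with `r`, `n`, `conf_low`, `conf_high`.
#' @export
pearson_r_ci <- function(x, y, conf_level = 0.95) {
  cc <- stats::complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: an input is constant")
  }
  r <- moment_cor(x, y)
  ci <- fisher_ci(r, n, conf_level)
  list(r = r, n = n, conf_low = ci[[1L]], conf_high = ci[[2L]])
}

# Product-moment correlation from centered sums (implementation is kept
# independent of stats::cor so tests can use the latter as a cross-check).
moment_cor <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

fisher_ci <- function(r, n, conf_level) {
  if (abs(r) >= 1) return(c(r, r))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Compare two independent correlations via Fisher's z
#'
#' `z = (atanh(r2) - atanh(r1)) / sqrt(1/(n1-3) + 1/(n2-3))`; positive
#' when `r2 > r1`. Antisymmetric: swapping the two correlations flips
#' the sign.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes, each > 3.
#' @return List with `z` and two-sided `p`.
#' @examples
#' fisher_z_compare(0.302, 224, 0.825, 224)$z  # 9.05
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("Fisher transform is infinite at |r| = 1")
  }
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both samples")
  z <- (atanh(r2) - atanh(r1)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare two dependent correlations sharing a variable (Steiger's z)
#'
#' For correlations `r12` and `r13` measured on the same sample of size
#' `n`, with `r23` the correlation between the two non-shared variables.
#' Provided as the dependent-sample alternative to [fisher_z_compare()];
#' the independent-sample comparison remains the default elsewhere.
#'
#' @param r12,r13 The two correlations being compared (shared variable 1).
#' @param r23 Correlation between variables 2 and 3.
#' @param n Common sample size (> 3).
#' @return List with `z` and two-sided `p`.
#' @export
steiger_z_compare <- function(r12, r13, r23, n) {
  if (max(abs(c(r12, r13))) >= 1) {
    stop("Fisher transform is infinite at |r| = 1")
  }
  if (n <= 3) stop("need n > 3")
  rbar <- (r12 + r13) / 2
  # Steiger (1980): covariance of the two dependent z-transforms
  psi <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
  s <- psi / (1 - rbar^2)^2
  z <- (atanh(r12) - atanh(r13)) * sqrt((n - 3) / (2 - 2 * s))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(row sums))` over the
#' complete-case rows of a participants x items matrix.
#'
#' @param scores Numeric matrix or data frame, participants in rows,
#'   items in columns; rows with any missing cell are dropped.
#' @return Numeric scalar in (-Inf, 1].
#' @export
cronbach_alpha <- function(scores) {
  m <- as.matrix(scores)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2L) stop("need at least 2 items")
  if (nrow(m) < 3L) stop("need at least 3 complete rows")
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop("alpha undefined: total-score variance is zero")
  k / (k - 1) * (1 - sum(apply(m, 2L, stats::var)) / total_var)
}

#' Alpha implied by a covariance matrix
#'
#' Same formula as [cronbach_alpha()] applied to a k x k covariance
#' matrix directly; used for closed-form checks (e.g. a
#' compound-symmetric matrix gives `k*rbar / (1 + (k-1)*rbar)`).
#'
#' @param sigma Symmetric covariance matrix.
#' @return Numeric scalar.
#' @export
alpha_from_cov <- function(sigma) {
  sigma <- as.matrix(sigma)
  k <- ncol(sigma)
  if (k < 2L) stop("need at least 2 items")
  total <- sum(sigma)
  if (total == 0) stop("alpha undefined: total-score variance is zero")
  k / (k - 1) * (1 - sum(diag(sigma)) / total)
}

#' McDonald's omega and Hancock's coefficient H from a standardized
#' one-factor solution
#'
#' For standardized loadings `lambda` and residual variances `theta`
#' (default `1 - lambda^2`):
#' \itemize{
#'   \item `omega = (sum lambda)^2 / ((sum lambda)^2 + sum theta)` — the
#'     reliability of the unit-weighted composite;
#'   \item `H = 1 / (1 + 1 / sum(lambda^2 / (1 - lambda^2)))` — the
#'     maximal reliability of the optimally weighted composite.
#' }
#' Under homogeneous loadings with `theta = 1 - lambda^2` the two
#' coincide; with heterogeneous loadings `H >= omega` because H weights
#' strong indicators more.
#'
#' @param loadings Standardized loadings, all `|lambda| < 1`.
#' @param residual_variances Optional per-item residual variances;
#'   defaults to `1 - loadings^2`.
#' @return List with `omega` and `coefficient_h`.
#' @export
composite_reliability <- function(loadings,
                                  residual_variances = 1 - loadings^2) {
  if (any(abs(loadings) >= 1)) {
    stop("standardized loadings must satisfy |lambda| < 1")
  }
  if (any(residual_variances < 0)) {
    stop("residual variances must be non-negative")
  }
  s <- sum(loadings)
  omega <- s^2 / (s^2 + sum(residual_variances))
  h <- 1 / (1 + 1 / sum(loadings^2 / (1 - loadings^2)))
  list(omega = omega, coefficient_h = h)
}

#' Read a participants x variables score matrix
#'
#' Comma-separated, header row of variable names, one row per
#' participant, empty cells for missing values.
#'
#' @param path Path to the CSV file.
#' @return Numeric data frame.
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) stop("score matrix not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", na.strings = c("", "NA"))
  id_cols <- names(df) %in% c("participant_id")
  num <- df[!id_cols]
  num[] <- lapply(num, as.numeric)
  if (any(id_cols)) attr(num, "participant_id") <- df$participant_id
  num
}

#' Write a score matrix
#' @param scores Numeric data frame or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}
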