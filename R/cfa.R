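#' Specify a confirmatory factor-analysis model
#'
#' Simple-structure CFA: every observed variable loads on exactly one
#' factor (no cross-loadings). Factor variances are fixed to 1 for
#' identification, so all loadings are free and the factor covariance
#' matrix is a correlation matrix. Residuals are uncorrelated except for
#' explicitly listed pairs, which must join variables on *different*
#' factors (same-factor residual correlations are disallowed, as in
#' multitrait models where the same item measured under several scoring
#' dimensions is allowed correlated uniqueness across factors).
#'
#' @param factors Named list: factor name -> character vector of its
#'   indicator variables.
#' @param residual_pairs Optional list of length-2 character vectors, each
#'   a pair of variables whose residuals may covary.
#' @param factor_cov `"free"` (all factor pairs correlate) or `"none"`
#'   (orthogonal factors).
#' @return A `cfa_model_spec`.
#' @export
cfa_model <- function(factors, residual_pairs = list(),
                      factor_cov = c("free", "none")) {
  factor_cov <- match.arg(factor_cov)
  stopifnot(is.list(factors), length(factors) >= 1L,
            !is.null(names(factors)), all(nzchar(names(factors))))
  vars <- unlist(factors, use.names = FALSE)
  if (anyDuplicated(vars)) {
    stop("cross-loading not allowed: each variable must load on exactly ",
         "one factor (duplicated: ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "), ")")
  }
  var_factor <- rep(names(factors), lengths(factors))
  names(var_factor) <- vars
  for (pair in residual_pairs) {
    if (length(pair) != 2L || !all(pair %in% vars)) {
      stop("each residual pair must name two model variables")
    }
    if (var_factor[[pair[[1L]]]] == var_factor[[pair[[2L]]]]) {
      stop("residual pair (", pair[[1L]], ", ", pair[[2L]],
           ") joins two indicators of the same factor; not allowed")
    }
  }
  structure(list(factors = factors,
                 variables = vars,
                 var_factor = var_factor,
                 residual_pairs = residual_pairs,
                 factor_cov = factor_cov),
            class = "cfa_model_spec")
}

#' Read a CFA model spec from a plain-text config
#'
#' Format: `factor_name = v1, v2, v3` lines define factors; a
#' `residual_pairs` line (or several) lists semicolon-separated
#' `v1:v2` pairs. `#` comments and blank lines are ignored.
#'
#' @param path Path to the config file.
#' @param factor_cov Passed to [cfa_model()].
#' @return A `cfa_model_spec`.
#' @export
read_cfa_model <- function(path, factor_cov = "free") {
  if (!file.exists(path)) stop("model spec not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  factors <- list()
  pairs <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("bad model-spec line: ", ln)
    key <- trimws(parts[[1L]])
    val <- trimws(parts[[2L]])
    if (key == "residual_pairs") {
      for (pr in strsplit(val, ";", fixed = TRUE)[[1L]]) {
        ab <- trimws(strsplit(pr, ":", fixed = TRUE)[[1L]])
        if (length(ab) == 2L) pairs[[length(pairs) + 1L]] <- ab
      }
    } else {
      factors[[key]] <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    }
  }
  cfa_model(factors, residual_pairs = pairs, factor_cov = factor_cov)
}

# Parameter layout: [lambda (p)] [phi lower-tri (q*(q-1)/2 if free)]
# [theta diag (p)] [theta covariances (n_pairs)]
cfa_par_index <- function(spec) {
  p <- length(spec$variables)
  q <- length(spec$factors)
  n_phi <- if (spec$factor_cov == "free" && q > 1L) q * (q - 1L) / 2L else 0L
  n_pair <- length(spec$residual_pairs)
  list(p = p, q = q, n_phi = n_phi, n_pair = n_pair,
       i_lambda = seq_len(p),
       i_phi = if (n_phi > 0L) p + seq_len(n_phi) else integer(0L),
       i_theta = p + n_phi + seq_len(p),
       i_pair = if (n_pair > 0L) 2L * p + n_phi + seq_len(n_pair)
                else integer(0L),
       n_free = 2L * p + n_phi + n_pair)
}

cfa_matrices <- function(par, spec, idx) {
  p <- idx$p; q <- idx$q
  Lambda <- matrix(0, p, q,
                   dimnames = list(spec$variables, names(spec$factors)))
  Lambda[cbind(seq_len(p),
               match(spec$var_factor[spec$variables],
                     names(spec$factors)))] <- par[idx$i_lambda]
  Phi <- diag(q)
  if (idx$n_phi > 0L) {
    Phi[lower.tri(Phi)] <- par[idx$i_phi]
    Phi[upper.tri(Phi)] <- t(Phi)[upper.tri(Phi)]
  }
  Theta <- diag(par[idx$i_theta], p)
  dimnames(Theta) <- list(spec$variables, spec$variables)
  if (idx$n_pair > 0L) {
    for (k in seq_len(idx$n_pair)) {
      i <- match(spec$residual_pairs[[k]][[1L]], spec$variables)
      j <- match(spec$residual_pairs[[k]][[2L]], spec$variables)
      Theta[i, j] <- Theta[j, i] <- par[idx$i_pair[[k]]]
    }
  }
  list(Lambda = Lambda, Phi = Phi, Theta = Theta,
       Sigma = Lambda %*% Phi %*% t(Lambda) + Theta)
}

#' Fit a CFA model by maximum likelihood
#'
#' Minimizes the normal-theory ML discrepancy
#' `F = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p`
#' over the free parameters (loadings, factor correlations, residual
#' variances, listed residual covariances) by quasi-Newton (BFGS) descent
#' with the analytic gradient. Identification fixes every factor variance
#' to 1. The test statistic is `chi_square = (n - 1) * F_min`.
#'
#' Start values: loadings 0.5, residual variances 0.5, factor
#' correlations 0; convergence is declared when the gradient-based BFGS
#' run ends normally and a final polish step improves the discrepancy by
#' less than 1e-8. Non-convergence is flagged, never hidden.
#'
#' @param scores Participants x variables data frame or matrix; rows with
#'   missing cells are dropped (complete-case, with the retained n
#'   recorded).
#' @param spec A [cfa_model()] spec; its variables must all be columns of
#'   `scores`.
#' @return A `cfa_result`: list with `loadings` (raw), `std_loadings`,
#'   `factor_cor`, `residual_var`, `residual_cov`, `chi_square`, `df`,
#'   `n`, `p`, `F_min`, `S` (sample covariance), `Sigma` (implied),
#'   `baseline_chi_square`, `baseline_df`, `converged`.
#' @export
fit_cfa <- function(scores, spec) {
  stopifnot(inherits(spec, "cfa_model_spec"))
  m <- as.matrix(as.data.frame(scores)[spec$variables])
  storage.mode(m) <- "double"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  p <- length(spec$variables)
  if (n < p + 1L) stop("need more complete rows than variables (n = ", n, ")")
  for (f in names(spec$factors)) {
    if (length(spec$factors[[f]]) < 2L) {
      stop("factor ", f, " has fewer than 2 indicators; model unidentified")
    }
  }
  S <- stats::cov(m)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-10) {
    stop("sample covariance matrix is not positive definite")
  }
  logdetS <- sum(log(ev))

  idx <- cfa_par_index(spec)
  df <- p * (p + 1L) / 2L - idx$n_free
  if (df < 0L) stop("model has more free parameters than moments (df < 0)")

  objective <- function(par) {
    mats <- cfa_matrices(par, spec, idx)
    ch <- tryCatch(chol(mats$Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    val <- logdet + sum(Sinv * S) - logdetS - p
    if (!is.finite(val)) 1e10 else val
  }
  gradient <- function(par) {
    mats <- cfa_matrices(par, spec, idx)
    ch <- tryCatch(chol(mats$Sigma), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(par)))
    Sinv <- chol2inv(ch)
    # dF/dSigma = Sigma^-1 (Sigma - S) Sigma^-1
    G <- Sinv %*% (mats$Sigma - S) %*% Sinv
    g <- numeric(length(par))
    GLP <- G %*% mats$Lambda %*% mats$Phi
    g[idx$i_lambda] <- 2 * GLP[cbind(seq_len(p),
                                     match(spec$var_factor[spec$variables],
                                           names(spec$factors)))]
    if (idx$n_phi > 0L) {
      LGL <- t(mats$Lambda) %*% G %*% mats$Lambda
      g[idx$i_phi] <- 2 * LGL[lower.tri(LGL)]
    }
    g[idx$i_theta] <- diag(G)
    if (idx$n_pair > 0L) {
      for (k in seq_len(idx$n_pair)) {
        i <- match(spec$residual_pairs[[k]][[1L]], spec$variables)
        j <- match(spec$residual_pairs[[k]][[2L]], spec$variables)
        g[idx$i_pair[[k]]] <- 2 * G[i, j]
      }
    }
    g
  }

  start <- numeric(idx$n_free)
  start[idx$i_lambda] <- 0.5 * sqrt(diag(S))
  start[idx$i_theta] <- 0.5 * diag(S)
  # phi and residual covariances start at 0

  fit <- stats::optim(start, objective, gradient, method = "BFGS",
                      control = list(maxit = 1000L, reltol = 1e-12))
  polish <- stats::optim(fit$par, objective, gradient, method = "BFGS",
                         control = list(maxit = 1000L, reltol = 1e-12))
  converged <- polish$convergence == 0L &&
    abs(fit$value - polish$value) < 1e-8 && polish$value < 1e9
  F_min <- polish$value
  par <- polish$par

  mats <- cfa_matrices(par, spec, idx)
  sigma_jj <- diag(mats$Sigma)
  lambda <- par[idx$i_lambda]
  names(lambda) <- spec$variables
  std_lambda <- lambda / sqrt(sigma_jj)
  names(std_lambda) <- spec$variables
  resvar <- par[idx$i_theta]
  names(resvar) <- spec$variables
  rescov <- if (idx$n_pair > 0L) {
    stats::setNames(par[idx$i_pair],
                    vapply(spec$residual_pairs, paste, character(1L),
                           collapse = "~~"))
  } else numeric(0L)

  R <- stats::cov2cor(S)
  baseline_F <- -determinant(R, logarithm = TRUE)$modulus[[1L]]

  structure(list(spec = spec,
                 loadings = lambda,
                 std_loadings = std_lambda,
                 factor_cor = mats$Phi,
                 residual_var = resvar,
                 residual_cov = rescov,
                 chi_square = (n - 1) * F_min,
                 df = df,
                 n = n, p = p,
                 F_min = F_min,
                 S = S, Sigma = mats$Sigma,
                 baseline_chi_square = (n - 1) * baseline_F,
                 baseline_df = p * (p - 1L) / 2L,
                 converged = converged),
            class = "cfa_result")
}

#' @export
print.cfa_result <- function(x, ...) {
  cat("<cfa_result> ", length(x$spec$factors), " factor(s), ", x$p,
      " variables, n = ", x$n, "\n", sep = "")
  cat(sprintf("  chi-square %.3f on %d df%s\n", x$chi_square, x$df,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("  standardized loadings:\n")
  print(round(x$std_loadings, 3L))
  if (length(x$spec$factors) > 1L) {
    cat("  factor correlations:\n")
    print(round(x$factor_cor, 3L))
  }
  invisible(x)
}

#' RMSEA from a chi-square statistic
#'
#' `rmsea = sqrt(max(chisq - df, 0) / (df * (n - 1)))`, with the
#' confidence interval found by searching the noncentrality parameter of
#' the noncentral chi-square distribution (lower bound: ncp whose 95th
#' percentile region places the observed statistic at the `1 - alpha/2`
#' quantile; upper: at `alpha/2`).
#'
#' @param chi_square Observed statistic (>= 0).
#' @param df Model degrees of freedom (> 0).
#' @param n Sample size.
#' @param conf_level CI level (default 0.90, the conventional RMSEA CI).
#' @return List with `rmsea`, `conf_low`, `conf_high`.
#' @export
rmsea_from_chisq <- function(chi_square, df, n, conf_level = 0.90) {
  if (df <= 0L) return(list(rmsea = 0, conf_low = 0, conf_high = 0))
  rmsea <- sqrt(max(chi_square - df, 0) / (df * (n - 1)))
  alpha <- 1 - conf_level
  ncp_for <- function(target_p) {
    # largest ncp with pchisq(chi_square, df, ncp) >= target_p
    f <- function(l) stats::pchisq(chi_square, df, ncp = l) - target_p
    if (f(0) < 0) return(0)
    hi <- max(chi_square, 1)
    while (f(hi) > 0) hi <- hi * 2
    stats::uniroot(f, c(0, hi), tol = 1e-9)$root
  }
  lo <- ncp_for(1 - alpha / 2)
  hi <- ncp_for(alpha / 2)
  list(rmsea = rmsea,
       conf_low = sqrt(lo / (df * (n - 1))),
       conf_high = sqrt(hi / (df * (n - 1))))
}

#' Fit indices for a fitted CFA
#'
#' Computes RMSEA (with noncentrality CI), CFI, TLI, and SRMR from a
#' [fit_cfa()] result, using the independence (diagonal-covariance) model
#' on the same data as the baseline. All chi-square-based indices reduce
#' to their perfect-fit values (`rmsea = 0`, `cfi = 1`) whenever
#' `chi_square <= df`. SRMR is the root mean square of the standardized
#' residual covariances, diagonal included.
#'
#' @param result A `cfa_result`.
#' @param conf_level RMSEA CI level (default 0.90).
#' @return A `fit_indices` list: `chi_square`, `df`, `p_value`, `rmsea`,
#'   `rmsea_ci`, `cfi`, `tli`, `srmr`, `baseline_chi_square`,
#'   `baseline_df`.
#' @export
fit_indices <- function(result, conf_level = 0.90) {
  stopifnot(inherits(result, "cfa_result"))
  chisq <- result$chi_square
  df <- result$df
  n <- result$n
  chisq_b <- result$baseline_chi_square
  df_b <- result$baseline_df

  rm_ <- rmsea_from_chisq(chisq, df, n, conf_level)

  num <- max(chisq - df, 0)
  den <- max(chisq_b - df_b, chisq - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- if (df > 0L && df_b > 0L && (chisq_b / df_b) != 1) {
    ((chisq_b / df_b) - (chisq / df)) / ((chisq_b / df_b) - 1)
  } else 1

  sd_ <- sqrt(diag(result$S))
  res <- (result$S - result$Sigma) / tcrossprod(sd_)
  srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))

  structure(list(chi_square = chisq, df = df,
                 p_value = if (df > 0L) {
                   stats::pchisq(chisq, df, lower.tail = FALSE)
                 } else NA_real_,
                 rmsea = rm_$rmsea,
                 rmsea_ci = c(rm_$conf_low, rm_$conf_high),
                 cfi = cfi, tli = tli, srmr = srmr,
                 baseline_chi_square = chisq_b, baseline_df = df_b),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf(
    "chi-square %.3f (df %d, p %s) | RMSEA %.3f [%.3f, %.3f] | CFI %.3f | TLI %.3f | SRMR %.3f\n",
    x$chi_square, x$df,
    if (is.na(x$p_value)) "-" else sprintf("%.3f", x$p_value),
    x$rmsea, x$rmsea_ci[[1L]], x$rmsea_ci[[2L]], x$cfi, x$tli, x$srmr))
  invisible(x)
}
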