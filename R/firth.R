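#' @importFrom stats pchisq qchisq qnorm pnorm uniroot model.matrix glm
#'   binomial coef plogis rbinom rnorm runif rpois rlnorm sd complete.cases
#' @useDynLib rcnvassoc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.firth_validate <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (all(y == 0) || all(y == 1))
    stop("y contains a single class; a case-control outcome needs both")
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (collinear columns)")
  list(X = X, y = y)
}

#' Firth penalized-likelihood logistic regression
#'
#' Fits a logistic regression by maximizing the Jeffreys-prior-penalized
#' log-likelihood `l(beta) + 0.5 * log det I(beta)` (Firth's correction)
#' with Newton-Raphson on the hat-adjusted score and step-halving.
#' Estimates remain finite under complete or quasi-complete separation,
#' which is why this is the association engine for very rare CNV
#' exposures. Per-coefficient p-values come from the penalized
#' likelihood-ratio test (each coefficient fixed at zero, the rest
#' re-maximized); confidence intervals from the profile penalized
#' likelihood (or Wald, or skipped, for speed in large scans).
#'
#' @param X numeric design matrix including an intercept column.
#' @param y binary 0/1 outcome with both classes present.
#' @param terms columns (indices or names) for which p-values/CIs are
#'   computed; default all.
#' @param ci `"profile"` (default), `"wald"` or `"none"`.
#' @param pvalues compute penalized-LRT p-values (default `TRUE`).
#' @param alpha 1 - confidence level (default 0.05 for 95% CIs).
#' @param max_iter,tol Newton-Raphson iteration cap and convergence
#'   tolerance on the modified score.
#' @return an object of class `FirthFit`: list with `coefficients` (log
#'   odds), `se`, `ci_low`, `ci_high`, `p_two_sided`, `p_one_sided`
#'   (halved in the risk direction), `plik`, `var`, `converged`, `n_iter`.
#' @examples
#' # 2x2 table: 3 exposed cases, 0 exposed controls, 7411 / 5044 unexposed
#' y <- rep(c(1, 0, 1, 0), c(3, 0, 7411, 5044))
#' x <- rep(c(1, 1, 0, 0), c(3, 0, 7411, 5044))
#' fit <- firthFit(cbind(1, x), y, ci = "none")
#' exp(fit$coefficients[2])  # ~ Haldane-corrected cross-ratio 4.76
#' @export
firthFit <- function(X, y, terms = NULL, ci = c("profile", "wald", "none"),
                     pvalues = TRUE, alpha = 0.05,
                     max_iter = 50L, tol = 1e-5) {
  ci <- match.arg(ci)
  v <- .firth_validate(X, y)
  X <- v$X; y <- v$y
  k <- ncol(X)
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("b", seq_len(k) - 1L)
  full <- .firth_newton(X, y, fixed = -1L, max_iter = max_iter, tol = tol)
  beta <- drop(full$beta)
  names(beta) <- cn
  se <- sqrt(diag(full$var))
  names(se) <- cn
  if (is.null(terms)) terms <- seq_len(k)
  if (is.character(terms)) terms <- match(terms, cn)
  p2 <- p1 <- lo <- hi <- rep(NA_real_, k)
  names(p2) <- names(p1) <- names(lo) <- names(hi) <- cn
  if (pvalues) {
    for (j in terms) {
      con <- .firth_newton(X, y, fixed = j - 1L, fixed_value = 0,
                           max_iter = max_iter, tol = tol)
      lrt <- max(0, 2 * (full$plik - con$plik))
      p2[j] <- pchisq(lrt, df = 1, lower.tail = FALSE)
      p1[j] <- if (beta[j] > 0) p2[j] / 2 else 1 - p2[j] / 2
    }
  }
  if (ci == "wald") {
    z <- qnorm(1 - alpha / 2)
    lo[terms] <- beta[terms] - z * se[terms]
    hi[terms] <- beta[terms] + z * se[terms]
  } else if (ci == "profile") {
    for (j in terms) {
      b <- .firth_profile_ci(X, y, j, full$plik, beta[j], se[j],
                             alpha, max_iter, tol)
      lo[j] <- b[1]; hi[j] <- b[2]
    }
  }
  structure(list(coefficients = beta, se = se, ci_low = lo, ci_high = hi,
                 p_two_sided = p2, p_one_sided = p1,
                 plik = full$plik, var = full$var,
                 converged = full$converged, n_iter = full$n_iter),
            class = "FirthFit")
}

# one profile-penalized-likelihood bound pair for coefficient j
.firth_profile_ci <- function(X, y, j, plmax, bj, sej, alpha,
                              max_iter, tol) {
  qv <- qchisq(1 - alpha, df = 1)
  f <- function(b) {
    con <- .firth_newton(X, y, fixed = j - 1L, fixed_value = b,
                         max_iter = max_iter, tol = tol)
    2 * (plmax - con$plik) - qv
  }
  bound <- function(dir) {
    step <- max(sej, 0.5)
    for (i in 1:14) {
      b <- bj + dir * step * 2
      if (f(b) > 0)
        return(uniroot(f, sort(c(bj, b)), tol = 1e-6)$root)
      step <- step * 2
    }
    dir * Inf   # profile never crossed the cutoff within range
  }
  c(bound(-1), bound(1))
}

#' @export
print.FirthFit <- function(x, ...) {
  cat("Firth logistic regression (penalized LRT p, ",
      if (all(is.na(x$ci_low))) "no CI" else "95% CI", ")\n", sep = "")
  tab <- data.frame(coef = x$coefficients, se = x$se,
                    OR = exp(x$coefficients),
                    ci_low = exp(x$ci_low), ci_high = exp(x$ci_high),
                    p = x$p_two_sided)
  print(tab, digits = 4)
  cat(if (x$converged) "converged" else "NOT converged",
      "in", x$n_iter, "iterations\n")
  invisible(x)
}

.assoc_design <- function(samples, covariates = c("cohort", "pc1")) {
  df <- as.data.frame(samples)
  covariates <- intersect(covariates, colnames(df))
  X <- matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    v <- df[[cv]]
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      if (nlevels(v) > 1L) {
        mm <- model.matrix(~v)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cv, levels(v)[-1])
        X <- cbind(X, mm)
      }
    } else if (length(unique(v)) > 1L) {
      X <- cbind(X, matrix(v, ncol = 1, dimnames = list(NULL, cv)))
    }
  }
  X
}

#' Covariate-adjusted Firth association test of a carrier indicator
#'
#' Fits `status ~ carrier + cohort + pc1` by Firth regression and reports
#' the carrier effect as an odds ratio with CI and p-value of the
#' requested sidedness (one-sided p is the risk-direction half of the
#' penalized-LRT p). With zero carriers the locus is untestable and a row
#' with `status = "unobserved"` is returned; a carrier vector collinear
#' with the covariates is flagged with `status = "collinear"`.
#'
#' @param carrier binary 0/1 vector, one entry per sample.
#' @param samples sample table with `status` and the covariate columns.
#' @param covariates covariate column names (default cohort + pc1).
#' @param sided `"two"` or `"one"`.
#' @param ci CI method passed to [firthFit()] (default `"profile"`).
#' @return one-row `data.frame`: `n_case_carriers`, `n_control_carriers`,
#'   `beta`, `OR`, `ci_low`, `ci_high`, `p_two_sided`, `p_one_sided`,
#'   `p_sided`, `converged`, `status`.
#' @export
firthTest <- function(carrier, samples, covariates = c("cohort", "pc1"),
                      sided = c("two", "one"), ci = "profile") {
  sided <- match.arg(sided)
  df <- as.data.frame(samples)
  stopifnot(length(carrier) == nrow(df))
  carrier <- as.numeric(carrier)
  nca <- sum(carrier == 1 & df$status == 1)
  nco <- sum(carrier == 1 & df$status == 0)
  empty <- data.frame(n_case_carriers = nca, n_control_carriers = nco,
                      beta = NA_real_, OR = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_two_sided = NA_real_,
                      p_one_sided = NA_real_, p_sided = NA_real_,
                      converged = NA, status = "unobserved",
                      stringsAsFactors = FALSE)
  if (nca + nco == 0L) return(empty)
  X <- cbind(.assoc_design(df, covariates),
             matrix(carrier, ncol = 1, dimnames = list(NULL, "carrier")))
  fit <- tryCatch(
    firthFit(X, df$status, terms = "carrier", ci = ci),
    error = function(e) e)
  if (inherits(fit, "error")) {
    empty$status <- if (grepl("rank deficient", conditionMessage(fit)))
      "collinear" else "error"
    return(empty)
  }
  j <- "carrier"
  data.frame(n_case_carriers = nca, n_control_carriers = nco,
             beta = unname(fit$coefficients[j]),
             OR = exp(unname(fit$coefficients[j])),
             ci_low = exp(unname(fit$ci_low[j])),
             ci_high = exp(unname(fit$ci_high[j])),
             p_two_sided = unname(fit$p_two_sided[j]),
             p_one_sided = unname(fit$p_one_sided[j]),
             p_sided = unname(if (sided == "two") fit$p_two_sided[j]
                              else fit$p_one_sided[j]),
             converged = fit$converged, status = "tested",
             stringsAsFactors = FALSE)
}
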