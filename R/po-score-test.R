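#' Score test of the proportional-odds assumption
#'
#' Tests the common-slope (parallel-lines) assumption of the cumulative-logit
#' model: the null model constrains the treatment (and, if `adjusted`, the
#' covariate) log odds ratios to be equal across every cumulative split of the
#' ordinal outcome; the alternative allows a separate slope per split. The
#' statistic is the efficient score `U' I^{-1} U` of the unconstrained model
#' evaluated at the constrained maximum-likelihood fit, referred to a
#' chi-square with `(k - 2) * p` degrees of freedom (`k` occupied levels,
#' `p` slopes).
#'
#' @param dataset a [comparator_dataset()].
#' @param scale an [ordinal_scale()].
#' @param adjusted if `TRUE` the age/sex/diabetes covariates are included and
#'   their slopes tested for parallelism as well.
#' @param covariates adjustment covariates used when `adjusted = TRUE`.
#' @return list with `p_value`, `statistic`, `df`, and `applicable` (`FALSE`,
#'   with `p_value = NA`, when fewer than 3 levels are occupied: the
#'   assumption is then vacuous).
#' @export
proportional_odds_score_test <- function(dataset, scale, adjusted = FALSE,
                                         covariates = c("age", "sex", "diabetes")) {
  rec <- dataset$records
  level <- ordinalise(rec, scale)
  obs <- sort(unique(level))
  k <- length(obs)
  if (k < 3L)
    return(list(p_value = NA_real_, statistic = NA_real_, df = 0L,
                applicable = FALSE))
  y <- match(level, obs)                               # 1..k
  X <- cbind(trt = as.numeric(rec$arm == "treatment"))
  if (adjusted)
    X <- cbind(X, as.matrix(rec[, covariates, drop = FALSE]))
  p <- ncol(X)
  # constrained fit (common slopes) via the standard cumulative-logit fitter
  yf <- factor(y, ordered = TRUE)
  df_fit <- data.frame(yf = yf, X)
  f <- stats::reformulate(colnames(df_fit)[-1L], response = "yf")
  fit <- MASS::polr(f, data = df_fit, Hess = FALSE)
  zeta <- fit$zeta                                     # cutpoints, length k-1
  beta <- stats::coef(fit)                             # common slopes, length p
  # collapse duplicate (y, x) rows to weighted patterns: with a treatment-only
  # design this reduces the likelihood to at most 2k terms
  key <- do.call(paste, c(list(y), as.data.frame(X)))
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  y <- y[first]
  X <- X[first, , drop = FALSE]
  # unconstrained log-likelihood: logit P(Y <= j | x) = zeta_j - x' beta_j
  nobs <- length(y)
  loglik <- function(par) {
    th <- par[seq_len(k - 1L)]
    B <- matrix(par[-seq_len(k - 1L)], nrow = p)       # p x (k-1), col j = beta_j
    eta <- X %*% B                                     # n x (k-1)
    gam <- stats::plogis(sweep(-eta, 2L, th, "+"))     # P(Y <= j)
    cellp <- cbind(gam, 1) - cbind(0, gam)             # n x k
    pr <- cellp[cbind(seq_len(nobs), y)]
    sum(w * log(pmax(pr, 1e-300)))
  }
  par0 <- c(zeta, rep(beta, k - 1L))
  U <- pracma::grad(loglik, par0)
  H <- pracma::hessian(loglik, par0)
  I <- -H
  stat <- tryCatch(drop(t(U) %*% solve(I, U)), error = function(e) NA_real_)
  df <- (k - 2L) * p
  if (!is.finite(stat) || stat < 0)
    return(list(p_value = NA_real_, statistic = NA_real_, df = df,
                applicable = TRUE))
  list(p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       statistic = stat, df = df, applicable = TRUE)
}
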