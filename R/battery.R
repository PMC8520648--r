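#' Battery configuration
#'
#' @param alpha two-sided significance threshold used by downstream ranking and
#'   type-I-error summaries.
#' @param bootstrap_B bootstrap replicates for the bootstrap mean-rank test and
#'   the win-ratio small-count fallback (>= 100).
#' @param covariates adjustment covariates for the adjusted regressions; the
#'   variables common to all datasets are age, sex and history of diabetes.
#' @param seed seed for the battery's internal bootstrap streams.
#' @return list of class `battery_config`.
#' @export
battery_config <- function(alpha = 0.05, bootstrap_B = 500L,
                           covariates = c("age", "sex", "diabetes"),
                           seed = 1L) {
  if (bootstrap_B < 100L)
    stop("bootstrap_B must be >= 100 (tail estimates are unstable below that)")
  structure(list(alpha = alpha, bootstrap_B = as.integer(bootstrap_B),
                 covariates = covariates, seed = as.integer(seed)),
            class = "battery_config")
}

#' Method labels of the fifteen-test battery
#' @return character vector of the 15 method labels, in battery order.
#' @export
battery_methods <- function() {
  c("BLR_adj", "CPH", "CPH_adj", "CSB", "CSF", "CSO", "CAT", "OLR", "OLR_adj",
    "MWU", "MT", "TT", "MLR_adj", "WR", "BS")
}

.result <- function(method, p, estimate = NA_real_, label = NA_character_,
                    degenerate = FALSE, diagnostics = list()) {
  if (degenerate) p <- 1
  if (is.na(p) || !is.finite(p)) { p <- 1; degenerate <- TRUE }
  p <- min(max(p, 0), 1)
  list(method = method, p_value = p, estimate = estimate,
       estimate_label = label, degenerate = degenerate,
       diagnostics = diagnostics)
}

.degen <- function(method, why)
  .result(method, 1, degenerate = TRUE, diagnostics = list(note = why))

.wald_p <- function(est, se) 2 * stats::pnorm(-abs(est / se))

# 2x2 / 2xk Pearson chi-square without continuity correction; degenerate when
# any margin is empty (the statistic is undefined).
.chisq_p <- function(method, arm, x, label) {
  tab <- table(arm, x)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L || nrow(tab) < 2L || any(rowSums(tab) == 0))
    return(.degen(method, "contingency table has an empty margin"))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  .result(method, ct$p.value, unname(ct$statistic), "chi-square statistic",
          diagnostics = list(df = unname(ct$parameter)))
}

# ---- individual methods -----------------------------------------------------

.m_blr_adj <- function(rec, level, config) {
  ev <- as.integer(level > 0L)
  if (all(ev == 0L) || all(ev == 1L)) return(.degen("BLR_adj", "no outcome variation"))
  f <- stats::reformulate(c("arm", config$covariates), response = "ev")
  fit <- try(stats::glm(f, data = cbind(rec, ev = ev), family = stats::binomial()),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(.degen("BLR_adj", "glm failed"))
  co <- summary(fit)$coefficients
  row <- grep("^arm", rownames(co))[1L]
  if (is.na(row) || is.na(co[row, 2L])) return(.degen("BLR_adj", "treatment effect inestimable"))
  .result("BLR_adj", .wald_p(co[row, 1L], co[row, 2L]), exp(co[row, 1L]),
          "odds ratio (any event)")
}

.m_cph <- function(rec, level, config, adjusted) {
  method <- if (adjusted) "CPH_adj" else "CPH"
  if (!all(c("time", "observed") %in% names(rec)))
    return(.degen(method, "time-to-event columns absent"))
  ev <- as.integer(level > 0L)
  if (sum(ev) == 0L) return(.degen(method, "no events"))
  terms <- c("arm", if (adjusted) config$covariates)
  f <- stats::as.formula(paste("survival::Surv(time, ev) ~",
                               paste(terms, collapse = " + ")))
  fit <- try(survival::coxph(f, data = cbind(rec, ev = ev), ties = "efron"),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(.degen(method, "coxph failed"))
  co <- summary(fit)$coefficients
  row <- grep("^arm", rownames(co))[1L]
  if (is.na(row) || !is.finite(co[row, 3L])) return(.degen(method, "treatment effect inestimable"))
  .result(method, .wald_p(co[row, 1L], co[row, 3L]), exp(co[row, 1L]),
          "hazard ratio (any event)")
}

.m_cat <- function(rec, level, k) {
  # Cochran-Armitage trend across ordered levels, equally spaced scores
  # 0..k-1: chi-square (1 df) for linear trend in the treatment proportion.
  tab <- table(factor(level, levels = 0:(k - 1L)), rec$arm)
  keep <- rowSums(tab) > 0
  if (sum(keep) < 2L || any(colSums(tab) == 0))
    return(.degen("CAT", "fewer than two occupied levels"))
  tab <- tab[keep, , drop = FALSE]
  score <- (0:(k - 1L))[keep]
  tr <- try(suppressWarnings(
    stats::prop.trend.test(tab[, "treatment"], rowSums(tab), score = score)),
    silent = TRUE)
  if (inherits(tr, "try-error") || is.na(tr$p.value))
    return(.degen("CAT", "trend statistic undefined"))
  .result("CAT", tr$p.value, unname(tr$statistic), "trend chi-square (1 df)")
}

# polr occasionally fails to find starting values (notably on aggregated
# weighted tables); retry with slopes at zero and cutpoints at the empirical
# cumulative logits.
.polr_fit <- function(f, data, weighted = FALSE) {
  run <- function(start = NULL) {
    if (weighted)
      MASS::polr(f, data = data, weights = w, Hess = TRUE, start = start)
    else
      MASS::polr(f, data = data, Hess = TRUE, start = start)
  }
  fit <- try(suppressWarnings(run()), silent = TRUE)
  if (!inherits(fit, "try-error")) return(fit)
  yname <- all.vars(f)[1L]
  y <- data[[yname]]
  wt <- if (weighted) data$w else rep(1, length(y))
  cum <- cumsum(tapply(wt, y, sum, default = 0)) / sum(wt)
  zeta0 <- qlogis(pmin(pmax(cum[-length(cum)], 1e-6), 1 - 1e-6))
  nslope <- length(attr(stats::terms(f), "term.labels"))
  try(suppressWarnings(run(start = c(rep(0, nslope), zeta0))), silent = TRUE)
}

.m_olr <- function(rec, level, config, adjusted) {
  method <- if (adjusted) "OLR_adj" else "OLR"
  obs <- sort(unique(level))
  if (length(obs) < 2L) return(.degen(method, "fewer than two occupied levels"))
  y <- factor(level, levels = obs, ordered = TRUE)
  fit <- if (adjusted) {
    f <- stats::reformulate(c("arm", config$covariates), response = "y")
    .polr_fit(f, cbind(rec, y = y))
  } else {
    agg <- stats::aggregate(list(w = rep(1L, length(y))),
                            by = list(y = y, arm = rec$arm), FUN = sum)
    .polr_fit(y ~ arm, agg, weighted = TRUE)
  }
  if (inherits(fit, "try-error")) return(.degen(method, "cumulative-logit fit failed"))
  co <- try(summary(fit)$coefficients, silent = TRUE)
  if (inherits(co, "try-error")) return(.degen(method, "Hessian not invertible"))
  row <- grep("^arm", rownames(co))[1L]
  if (is.na(row) || !is.finite(co[row, 2L]) || co[row, 2L] <= 0)
    return(.degen(method, "treatment effect inestimable"))
  .result(method, .wald_p(co[row, 1L], co[row, 2L]), exp(co[row, 1L]),
          "common odds ratio (higher severity)")
}

.m_mwu <- function(rec, level) {
  x <- level[rec$arm == "treatment"]; y <- level[rec$arm == "control"]
  if (length(x) == 0L || length(y) == 0L || stats::sd(level) == 0)
    return(.degen("MWU", "no outcome variation"))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  if (is.na(wt$p.value)) return(.degen("MWU", "tie-corrected variance is zero"))
  pwin <- 1 - unname(wt$statistic) / (length(x) * length(y)) # P(trt better) + P(tie)/2
  .result("MWU", wt$p.value, pwin, "probabilistic index P(trt better) + P(tie)/2")
}

.m_mt <- function(rec, level) {
  med <- stats::median(level)
  hi <- level > med
  if (all(hi) || !any(hi))
    return(.degen("MT", "one side of the median split is empty"))
  .chisq_p2 <- .chisq_p("MT", rec$arm, hi, "median-split chi-square")
  .chisq_p2$estimate_label <- "median-split chi-square"
  .chisq_p2
}

.m_tt <- function(rec, level) {
  x <- level[rec$arm == "treatment"]; y <- level[rec$arm == "control"]
  tt <- try(stats::t.test(x, y, var.equal = TRUE), silent = TRUE)
  if (inherits(tt, "try-error") || is.na(tt$p.value))
    return(.degen("TT", "scores essentially constant"))
  .result("TT", tt$p.value, mean(x) - mean(y), "difference in mean score")
}

.m_mlr_adj <- function(rec, level, config) {
  f <- stats::reformulate(c("arm", config$covariates), response = "level")
  fit <- try(stats::lm(f, data = cbind(rec, level = level)), silent = TRUE)
  if (inherits(fit, "try-error")) return(.degen("MLR_adj", "lm failed"))
  co <- summary(fit)$coefficients
  row <- grep("^arm", rownames(co))[1L]
  if (is.na(row) || is.na(co[row, 2L]) || co[row, 2L] == 0)
    return(.degen("MLR_adj", "treatment effect inestimable"))
  .result("MLR_adj", co[row, 4L], co[row, 1L], "adjusted difference in mean score")
}

# ---- win ratio --------------------------------------------------------------

#' Win ratio test on the severity hierarchy of an ordinal scale
#'
#' Every treatment-control pair of participants is compared down the clinical
#' hierarchy derived from the scale's levels, most severe first (fatal, then
#' each lower severity in turn); the first outcome on which the pair differs
#' decides the win or loss, otherwise the pair is tied. This is equivalent to
#' comparing ordinal levels directly, and the win count satisfies
#' `Nw + 0.5 * Nt = U`, the Mann-Whitney statistic of treatment over control.
#'
#' The two-sided p-value comes from a normal approximation on `log(Nw/Nl)`
#' with the variance of the win and loss proportions estimated by the
#' two-sample U-statistic projection estimator. When any of the win/loss
#' counts is below 10 the approximation is replaced by a within-arm bootstrap
#' (`B` replicates).
#'
#' @param dataset a [comparator_dataset()].
#' @param scale an [ordinal_scale()]; the hierarchy is its levels, top down.
#' @param B bootstrap replicates for the small-count fallback.
#' @param seed seed for the fallback bootstrap.
#' @return a battery result list: `method`, `p_value`, `estimate` (`Nw/Nl`),
#'   `degenerate`, and `diagnostics` holding `Nw`, `Nl`, `Nt`.
#' @export
win_ratio_test <- function(dataset, scale, B = 500L, seed = 1L) {
  rec <- dataset$records
  level <- ordinalise(rec, scale)
  k <- n_levels(scale)
  nt <- tabulate(level[rec$arm == "treatment"] + 1L, nbins = k)
  nc <- tabulate(level[rec$arm == "control"] + 1L, nbins = k)
  n1 <- sum(nt); n2 <- sum(nc)
  if (n1 < 1L || n2 < 1L) return(.degen("WR", "an arm is empty"))
  # control-level tail counts: number of controls strictly worse / better
  worse_c  <- rev(cumsum(rev(nc)))[-1L]; worse_c <- c(worse_c, 0)  # > a
  better_c <- cumsum(nc) - nc                                      # < a
  Nw <- sum(nt * worse_c); Nl <- sum(nt * better_c); Nt <- sum(nt * nc)
  diag <- list(Nw = Nw, Nl = Nl, Nt = Nt)
  if (Nw + Nl == 0L)
    return(.result("WR", 1, NA_real_, "win ratio", degenerate = TRUE,
                   diagnostics = c(diag, list(note = "no discordant pairs"))))
  est <- if (Nl == 0L) Inf else Nw / Nl
  if (Nl == 0L || Nw == 0L) {
    # one-sided extreme: p from the discordant-pair count statistic
    p <- stats::binom.test(Nw, Nw + Nl, 0.5)$p.value
    return(.result("WR", p, est, "win ratio",
                   diagnostics = c(diag, list(note = "count-statistic p"))))
  }
  if (min(Nw, Nl) < 10L) {
    set.seed(seed)
    logwr <- numeric(B)
    for (b in seq_len(B)) {
      bt <- stats::rmultinom(1L, n1, nt / n1)[, 1L]
      bc <- stats::rmultinom(1L, n2, nc / n2)[, 1L]
      wc <- c(rev(cumsum(rev(bc)))[-1L], 0); bcp <- cumsum(bc) - bc
      logwr[b] <- log((sum(bt * wc) + 0.5) / (sum(bt * bcp) + 0.5))
    }
    p <- max(2 / B, 2 * min(mean(logwr <= 0), mean(logwr >= 0)))
    return(.result("WR", min(p, 1), est, "win ratio",
                   diagnostics = c(diag, list(note = "bootstrap fallback", B = B))))
  }
  # projection (Hajek) variance of the win / loss proportions
  tw <- Nw / (n1 * n2); tl <- Nl / (n1 * n2)
  w_t <- worse_c / n2; l_t <- better_c / n2          # per treatment level a
  worse_t <- c(rev(cumsum(rev(nt)))[-1L], 0); better_t <- cumsum(nt) - nt
  w_c <- better_t / n1; l_c <- worse_t / n1          # per control level b
  wmean <- function(x, w) sum(w * x) / sum(w)
  vw <- wmean((w_t - tw)^2, nt) / n1 + wmean((w_c - tw)^2, nc) / n2
  vl <- wmean((l_t - tl)^2, nt) / n1 + wmean((l_c - tl)^2, nc) / n2
  cv <- wmean((w_t - tw) * (l_t - tl), nt) / n1 +
        wmean((w_c - tw) * (l_c - tl), nc) / n2
  v_log <- vw / tw^2 + vl / tl^2 - 2 * cv / (tw * tl)
  if (!is.finite(v_log) || v_log <= 0)
    return(.result("WR", 1, est, "win ratio", degenerate = TRUE,
                   diagnostics = c(diag, list(note = "variance inestimable"))))
  z <- log(tw / tl) / sqrt(v_log)
  .result("WR", 2 * stats::pnorm(-abs(z)), est, "win ratio", diagnostics = diag)
}

# ---- bootstrap mean-rank ----------------------------------------------------

# pooled mid-ranks per level, given combined category counts
.midranks <- function(counts) {
  below <- cumsum(counts) - counts
  below + (counts + 1) / 2
}

#' Bootstrap test of the difference in mean rank
#'
#' The statistic is the treatment-minus-control difference in mean mid-rank
#' over the pooled ordinal ranking. Within-arm resampling (category counts
#' redrawn from each arm's multinomial) gives the bootstrap distribution of the
#' statistic, and the two-sided p-value inverts the percentile interval:
#' `p = 2 * min(F(0), 1 - F(0))`, floored at `2/B`, where `F` is the bootstrap
#' distribution (centred, as bootstrap distributions are, at the observed
#' difference). The rank difference itself is reported descriptively only; the
#' method makes no distributional assumptions.
#'
#' @param dataset a [comparator_dataset()].
#' @param scale an [ordinal_scale()].
#' @param B bootstrap replicates (>= 100).
#' @param seed integer seed; the p-value is deterministic given it.
#' @return a battery result list.
#' @export
bootstrap_mean_rank_test <- function(dataset, scale, B = 500L, seed = 1L) {
  if (B < 100L) stop("B must be >= 100 (tail estimates are unstable below that)")
  rec <- dataset$records
  level <- ordinalise(rec, scale)
  k <- n_levels(scale)
  nt <- tabulate(level[rec$arm == "treatment"] + 1L, nbins = k)
  nc <- tabulate(level[rec$arm == "control"] + 1L, nbins = k)
  n1 <- sum(nt); n2 <- sum(nc)
  if (n1 < 2L || n2 < 2L) return(.degen("BS", "an arm has fewer than 2 records"))
  mr <- .midranks(nt + nc)
  d_obs <- sum(nt * mr) / n1 - sum(nc * mr) / n2
  if (stats::sd(level) == 0)
    return(.result("BS", 1, 0, "difference in mean rank", degenerate = TRUE,
                   diagnostics = list(note = "no outcome variation", B = B)))
  set.seed(seed)
  bt <- stats::rmultinom(B, n1, nt / n1)
  bc <- stats::rmultinom(B, n2, nc / n2)
  tot <- bt + bc
  below <- apply(tot, 2L, cumsum) - tot
  mrb <- below + (tot + 1) / 2
  d_b <- colSums(bt * mrb) / n1 - colSums(bc * mrb) / n2
  p <- max(2 / B, 2 * min(mean(d_b <= 0), mean(d_b >= 0)))
  .result("BS", min(p, 1), d_obs, "difference in mean rank",
          diagnostics = list(B = B, boot_mean = mean(d_b)))
}

# ---- battery driver ---------------------------------------------------------

.one_method <- function(method, rec, level, k, dataset, scale, config, seed) {
  switch(method,
    BLR_adj = .m_blr_adj(rec, level, config),
    CPH     = .m_cph(rec, level, config, adjusted = FALSE),
    CPH_adj = .m_cph(rec, level, config, adjusted = TRUE),
    CSB     = .chisq_p("CSB", rec$arm, as.integer(level > 0L), "any event"),
    CSF     = .chisq_p("CSF", rec$arm, as.integer(level == k - 1L), "fatal event"),
    CSO     = .chisq_p("CSO", rec$arm, factor(level, levels = 0:(k - 1L)), "ordinal"),
    CAT     = .m_cat(rec, level, k),
    OLR     = .m_olr(rec, level, config, adjusted = FALSE),
    OLR_adj = .m_olr(rec, level, config, adjusted = TRUE),
    MWU     = .m_mwu(rec, level),
    MT      = .m_mt(rec, level),
    TT      = .m_tt(rec, level),
    MLR_adj = .m_mlr_adj(rec, level, config),
    WR      = win_ratio_test(dataset, scale, B = config$bootstrap_B,
                             seed = derive_seed(seed, 1L)),
    BS      = bootstrap_mean_rank_test(dataset, scale, B = config$bootstrap_B,
                                       seed = derive_seed(seed, 2L)),
    stop("unknown method '", method, "'"))
}

#' Run the fifteen-method analysis battery on one comparator dataset
#'
#' Applies the full battery (binary, time-to-event, ordinal and rank-based
#' methods plus the win ratio and bootstrap tests) to one two-arm comparison
#' and returns one comparable two-sided p-value per method. Methods whose
#' statistic is undefined on the data (e.g. no events in either arm, or a
#' missing time column for the proportional-hazards models) return a
#' degenerate result with `p = 1` so that every dataset still ranks all 15
#' methods.
#'
#' @param dataset a [comparator_dataset()].
#' @param scale an [ordinal_scale()].
#' @param config a [battery_config()].
#' @param methods subset of [battery_methods()] to run (default: all 15).
#' @return data frame of class `battery_result` with columns `method`,
#'   `p_value`, `estimate`, `estimate_label`, `degenerate`, and a list column
#'   `diagnostics`; attribute `dataset_id`.
#' @export
run_battery <- function(dataset, scale, config = battery_config(),
                        methods = battery_methods()) {
  stopifnot(inherits(dataset, "comparator_dataset"),
            inherits(scale, "ordinal_scale"))
  bad <- setdiff(methods, battery_methods())
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  rec <- dataset$records
  level <- ordinalise(rec, scale)
  k <- n_levels(scale)
  if (!all(c("time", "observed") %in% names(rec)) &&
      any(c("CPH", "CPH_adj") %in% methods))
    warning("dataset '", dataset$id,
            "' has no time column; proportional-hazards methods flagged degenerate")
  res <- lapply(methods, function(m)
    tryCatch(.one_method(m, rec, level, k, dataset, scale, config, config$seed),
             error = function(e) .degen(m, conditionMessage(e))))
  out <- data.frame(method = vapply(res, `[[`, "", "method"),
                    p_value = vapply(res, `[[`, 0, "p_value"),
                    estimate = vapply(res, `[[`, 0, "estimate"),
                    estimate_label = vapply(res, `[[`, "", "estimate_label"),
                    degenerate = vapply(res, `[[`, TRUE, "degenerate"),
                    stringsAsFactors = FALSE)
  out$diagnostics <- lapply(res, `[[`, "diagnostics")
  attr(out, "dataset_id") <- dataset$id
  class(out) <- c("battery_result", class(out))
  out
}

#' Write battery results as tidy CSV
#'
#' @param results a `battery_result` or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_battery_csv <- function(results, path) {
  if (inherits(results, "battery_result")) results <- list(results)
  rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(dataset = attr(r, "dataset_id"), method = r$method,
               p_value = r$p_value, estimate = r$estimate,
               degenerate = as.integer(r$degenerate))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
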