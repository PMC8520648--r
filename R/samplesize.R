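.zz <- function(alpha, power)
  (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2

.round_even <- function(N) 2 * ceiling(N / 2)

#' Sample size for a two-sample comparison of binary proportions
#'
#' Unpooled two-proportion formula with equal allocation:
#' `N = 2 * ceil((z_{1-a/2} + z_{1-b})^2 (p1(1-p1) + p2(1-p2)) / (p1 - p2)^2)`.
#'
#' @param p1,p2 event proportions in the two arms, both in (0, 1) and unequal.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return total N across both arms (even).
#' @export
n_binary <- function(p1, p2, alpha = 0.05, power = 0.90) {
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1)
    stop("p1 and p2 must lie strictly in (0, 1)")
  if (p1 == p2) stop("undefined effect: p1 equals p2")
  per_group <- .zz(alpha, power) * (p1 * (1 - p1) + p2 * (1 - p2)) / (p1 - p2)^2
  2 * ceiling(per_group)
}

#' Sample size for the proportional-odds (cumulative logit) analysis
#'
#' Whitehead's formula for an ordered categorical outcome under proportional
#' odds, equal allocation, total across both arms:
#' `N = 12 (z_{1-a/2} + z_{1-b})^2 / ((log OR)^2 (1 - sum(pbar_i^3)))`,
#' where `pbar` is the mean category-probability vector across arms. With two
#' categories at `pbar = (0.5, 0.5)` this collapses exactly to the binary
#' log-odds-ratio sample size.
#'
#' @param pbar mean category probabilities across arms (sums to 1, >= 2
#'   categories with positive mass).
#' @param or_po anticipated common (proportional) odds ratio, not 1.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param round round the result up to the next even integer (default); set
#'   `FALSE` for the raw formula value (used in limit checks).
#' @return total N across both arms.
#' @export
n_olr <- function(pbar, or_po, alpha = 0.05, power = 0.90, round = TRUE) {
  if (abs(sum(pbar) - 1) > 1e-8) stop("pbar must sum to 1")
  if (sum(pbar > 0) < 2L) stop("need >= 2 categories with positive mass")
  if (or_po == 1) stop("undefined effect: or_po = 1")
  if (or_po <= 0) stop("or_po must be positive")
  N <- 12 * .zz(alpha, power) / (log(or_po)^2 * (1 - sum(pbar^3)))
  if (round) .round_even(N) else N
}

#' Sample size for the Mann-Whitney U test (Noether's formula)
#'
#' `N = (z_{1-a/2} + z_{1-b})^2 / (3 (p_win - 0.5)^2)`, equal allocation,
#' rounded up to even. Ties enter only through the probabilistic index
#' `p_win` itself; no separate tie correction is applied.
#'
#' @param p_win probabilistic index `P(treatment better) + 0.5 P(tie)`, not 0.5.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param round round up to the next even integer (default).
#' @return total N across both arms.
#' @export
n_mwu <- function(p_win, alpha = 0.05, power = 0.90, round = TRUE) {
  if (p_win < 0 || p_win > 1) stop("p_win must lie in [0, 1]")
  if (p_win == 0.5) stop("undefined effect: p_win = 0.5")
  N <- .zz(alpha, power) / (3 * (p_win - 0.5)^2)
  if (round) .round_even(N) else N
}

#' Sample size for the two-sample pooled-variance t-test
#'
#' Per group `n = 2 sigma^2 (z_{1-a/2} + z_{1-b})^2 / delta^2`, doubled for
#' the total.
#'
#' @param delta anticipated difference in mean score, non-zero.
#' @param sd pooled score standard deviation, positive.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param round round up (default).
#' @return total N across both arms.
#' @export
n_ttest <- function(delta, sd, alpha = 0.05, power = 0.90, round = TRUE) {
  if (delta == 0) stop("undefined effect: delta = 0")
  if (sd <= 0) stop("sd must be positive")
  per_group <- 2 * sd^2 * .zz(alpha, power) / delta^2
  if (round) 2 * ceiling(per_group) else 2 * per_group
}

#' Estimate the effect summaries a sample-size comparison needs
#'
#' From one comparator dataset: per-arm any-event proportions, the common
#' (proportional) odds ratio from the unadjusted cumulative-logit fit, the
#' probabilistic index `P(treatment score < control score) + 0.5 P(tie)`, the
#' difference in mean integer score with its pooled standard deviation, and
#' the mean category-probability vector across arms.
#'
#' @param dataset a [comparator_dataset()].
#' @param scale an [ordinal_scale()].
#' @return list of class `effect_summary`: `p_event` (named c(control,
#'   treatment)), `or_po`, `p_win`, `delta`, `sd`, `pbar`.
#' @export
estimate_effects <- function(dataset, scale) {
  rec <- dataset$records
  level <- ordinalise(rec, scale)
  if (sum(level > 0L) == 0L) stop("cannot estimate effects: no events in the data")
  k <- n_levels(scale)
  trt <- rec$arm == "treatment"
  nt <- tabulate(level[trt] + 1L, nbins = k); n1 <- sum(nt)
  nc <- tabulate(level[!trt] + 1L, nbins = k); n2 <- sum(nc)
  p_event <- c(control = mean(level[!trt] > 0L), treatment = mean(level[trt] > 0L))
  # probabilistic index by direct pairwise counting on the category table
  worse_c <- c(rev(cumsum(rev(nc)))[-1L], 0)
  p_win <- (sum(nt * worse_c) + 0.5 * sum(nt * nc)) / (n1 * n2)
  delta <- sum(nt * (0:(k - 1L))) / n1 - sum(nc * (0:(k - 1L))) / n2
  sd_pooled <- stats::sd(level)
  pbar <- (nt / n1 + nc / n2) / 2
  obs <- sort(unique(level))
  or_po <- NA_real_
  if (length(obs) >= 2L) {
    y <- factor(level, levels = obs, ordered = TRUE)
    agg <- stats::aggregate(list(w = rep(1L, length(y))),
                            by = list(y = y, arm = rec$arm), FUN = sum)
    fit <- .polr_fit(y ~ arm, agg, weighted = TRUE)
    if (!inherits(fit, "try-error")) or_po <- exp(unname(stats::coef(fit)[1L]))
  }
  structure(list(p_event = p_event, or_po = or_po, p_win = p_win,
                 delta = delta, sd = sd_pooled, pbar = pbar),
            class = "effect_summary")
}

.round_multiplier <- function(m)
  ifelse(abs(m) < 0.1, signif(m, 2), round(m, 2))

#' Ordinal-versus-binary sample-size multiplier report
#'
#' For each row of required sample sizes, every column is divided by the
#' binary-proportions sample size and rounded to the printed precision (two
#' significant figures below 0.1, otherwise two decimals); the summary gives
#' the median and quartiles per multiplier column.
#'
#' @param rows data frame with columns `n_binary`, `n_ordinal`, `n_mwu`,
#'   `n_ttest` (one row per comparator dataset), optionally `dataset`.
#' @return list of class `multiplier_report` with `rows` (sample sizes plus
#'   `mult_*` columns) and `summary` (median, q1, q3 per multiplier column).
#' @export
multiplier_report <- function(rows) {
  need <- c("n_binary", "n_ordinal", "n_mwu", "n_ttest")
  if (!all(need %in% names(rows)))
    stop("rows must have columns ", paste(need, collapse = ", "))
  if (any(rows$n_binary <= 0)) stop("binary sample size must be positive")
  out <- rows
  out$mult_binary  <- .round_multiplier(rows$n_binary / rows$n_binary)
  out$mult_ordinal <- .round_multiplier(rows$n_ordinal / rows$n_binary)
  out$mult_mwu     <- .round_multiplier(rows$n_mwu / rows$n_binary)
  out$mult_ttest   <- .round_multiplier(rows$n_ttest / rows$n_binary)
  qs <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE)
  summary <- data.frame(
    column = c("ordinal", "mwu", "ttest"),
    rbind(qs(out$mult_ordinal), qs(out$mult_mwu), qs(out$mult_ttest)))
  names(summary)[2:4] <- c("median", "q1", "q3")
  structure(list(rows = out, summary = summary), class = "multiplier_report")
}

#' @export
print.multiplier_report <- function(x, ...) {
  cat("Sample-size multipliers (method N / binary N):\n")
  print(x$rows, row.names = FALSE)
  cat("\nSummary (median [Q1-Q3]):\n")
  with(x$summary, cat(sprintf("  %-8s %.2f (%s-%s)\n", column, median,
                              format(q1), format(q3)), sep = ""))
  invisible(x)
}

#' Load the packaged published sample-size comparison rows
#'
#' Thirteen comparator-dataset rows of required sample sizes for the 4-level
#' stroke/TIA outcome (binary proportions, ordinal logistic regression,
#' Mann-Whitney U, t-test), together with the multipliers as printed in the
#' source publication's comparison table.
#'
#' @return data frame with columns `dataset`, `n_binary`, `n_ordinal`,
#'   `n_mwu`, `n_ttest`, `pub_mult_binary`, `pub_mult_ordinal`,
#'   `pub_mult_mwu`, `pub_mult_ttest`.
#' @export
load_published_samplesize_rows <- function() {
  path <- system.file("extdata", "samplesize_stroketia4.csv", package = "ordvasc",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
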