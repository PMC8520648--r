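#' Rank p-values within one dataset
#'
#' Rank 1 goes to the smallest p-value; ties receive the mean of the spanned
#' ranks (mid-ranks), so every row of a rank matrix sums to `k(k+1)/2`
#' regardless of the tie pattern.
#'
#' @param p numeric vector of p-values in `[0, 1]`. `NA`/`NaN` entries are an
#'   error: degenerate methods must be pre-converted to `p = 1`.
#' @return numeric vector of ranks.
#' @export
rank_pvalues <- function(p) {
  if (anyNA(p))
    stop("NA p-values must be pre-converted to degenerate p = 1 before ranking")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  rank(p, ties.method = "average")
}

#' Build a rank matrix from a list of battery results
#'
#' @param batteries list of `battery_result` data frames (one per comparator
#'   dataset, same method set in each).
#' @return object of class `rank_matrix`: list with `datasets`, `methods`, and
#'   the datasets x methods `ranks` matrix.
#' @export
rank_matrix <- function(batteries) {
  stopifnot(length(batteries) >= 1L)
  methods <- batteries[[1L]]$method
  ranks <- t(vapply(batteries, function(b) {
    stopifnot(identical(b$method, methods))
    rank_pvalues(b$p_value)
  }, numeric(length(methods))))
  ids <- vapply(batteries, function(b) attr(b, "dataset_id") %||% NA_character_,
                character(1))
  ids[is.na(ids)] <- paste0("dataset", which(is.na(ids)))
  dimnames(ranks) <- list(ids, methods)
  structure(list(datasets = ids, methods = methods, ranks = ranks),
            class = "rank_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rank_matrix <- function(x, ...) {
  cat("Rank matrix:", length(x$datasets), "datasets x", length(x$methods),
      "methods\n")
  cat("  mean ranks:\n")
  print(round(sort(colMeans(x$ranks)), 2))
  invisible(x)
}

#' Friedman two-way ANOVA on ranks, adjusted for ties
#'
#' Tests whether the `k` methods differ in their average within-dataset rank
#' across `n` datasets (blocks). The chi-square statistic divides the
#' classical Friedman statistic by the tie correction
#' `C = 1 - sum(t^3 - t) / (n k (k^2 - 1))`, summed over tie groups `t` within
#' each row; with no ties it equals the unadjusted statistic. When every row is
#' fully tied (`C = 0`) the statistic is defined as 0 with `p = 1`.
#'
#' @param rm a [rank_matrix()] with at least 2 datasets.
#' @return list with `statistic`, `p_value`, `df`, `tie_correction`.
#' @export
friedman_with_ties <- function(rm) {
  stopifnot(inherits(rm, "rank_matrix"))
  R <- rm$ranks
  n <- nrow(R); k <- ncol(R)
  if (n < 2L) stop("Friedman test needs >= 2 datasets (blocks)")
  A <- 12 * sum(colSums(R)^2) / (n * k * (k + 1)) - 3 * n * (k + 1)
  ties <- sum(apply(R, 1L, function(r) {
    t <- table(r); sum(t^3 - t)
  }))
  C <- 1 - ties / (n * k * (k^2 - 1))
  if (C <= .Machine$double.eps)
    return(list(statistic = 0, p_value = 1, df = k - 1L, tie_correction = 0))
  stat <- A / C
  list(statistic = stat, p_value = stats::pchisq(stat, k - 1L, lower.tail = FALSE),
       df = k - 1L, tie_correction = C)
}

#' Duncan's multiple range test on method mean ranks
#'
#' Step-down studentized-range procedure on the `k` method mean ranks, with the
#' error variance and degrees of freedom taken from the two-way
#' (dataset x method) ANOVA of the rank matrix: `df = (n - 1)(k - 1)`. A range
#' of `p` adjacent ordered means is significant when its span exceeds
#' `q(1 - alpha_p, p, df) * sqrt(MSE / n)` with the classic Duncan protection
#' level `alpha_p = 1 - (1 - alpha)^(p - 1)`; ranges contained in a
#' non-significant range are not tested. Letters are assigned so that methods
#' sharing a letter are not significantly different.
#'
#' Applied only when the Friedman test is significant: otherwise the grouping
#' is skipped and the result carries a single "not significant" group.
#'
#' @param rm a [rank_matrix()].
#' @param alpha significance level for both the Friedman gate and the
#'   protection levels.
#' @return object of class `duncan_grouping`: data frame `groups` (method,
#'   mean_rank, letters; ascending mean rank), `friedman_stat`, `friedman_p`,
#'   `significant`.
#' @export
duncan_groups <- function(rm, alpha = 0.05) {
  stopifnot(inherits(rm, "rank_matrix"))
  fr <- friedman_with_ties(rm)
  R <- rm$ranks
  n <- nrow(R); k <- ncol(R)
  means <- stats::setNames(colMeans(R), rm$methods)
  ord <- order(means)
  m <- means[ord]
  if (fr$p_value >= alpha) {
    groups <- data.frame(method = names(m), mean_rank = unname(m),
                         letters = rep("A", k), stringsAsFactors = FALSE)
    return(structure(list(groups = groups, friedman_stat = fr$statistic,
                          friedman_p = fr$p_value, significant = FALSE,
                          alpha = alpha),
                     class = "duncan_grouping"))
  }
  # residual variance of the two-way ANOVA on ranks; every row mean equals the
  # grand mean (k+1)/2 because row sums are conserved, so the residual reduces
  # to deviations from the column (method) means
  sse <- sum(sweep(R, 2L, means)^2)
  dfe <- (n - 1L) * (k - 1L)
  mse <- sse / dfe
  se <- sqrt(mse / n)
  nonsig <- matrix(FALSE, k, k)            # span i..j declared non-significant
  for (span in k:2) {
    alpha_p <- 1 - (1 - alpha)^(span - 1L)
    crit <- stats::qtukey(1 - alpha_p, span, dfe) * se
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      contained <- FALSE
      if (span < k) {
        for (a in seq_len(k)) for (b in seq_len(k)) {
          if (nonsig[a, b] && a <= i && j <= b && (b - a) > (j - i)) {
            contained <- TRUE; break
          }
        }
      }
      if (contained || (m[j] - m[i]) <= crit) nonsig[i, j] <- TRUE
    }
  }
  # letters from maximal non-significant spans (singletons covered by none get
  # their own letter)
  spans <- list()
  for (i in seq_len(k)) for (j in i:k) {
    if (i == j || nonsig[i, j]) {
      maximal <- TRUE
      for (a in seq_len(k)) for (b in a:k) {
        if ((a < i || b > j) && a <= i && j <= b && (a != i || b != j) &&
            (a == b || nonsig[a, b])) { maximal <- FALSE; break }
      }
      if (maximal) spans[[length(spans) + 1L]] <- c(i, j)
    }
  }
  spans <- unique(spans)
  spans <- spans[order(vapply(spans, `[`, 0, 1L), vapply(spans, `[`, 0, 2L))]
  lett <- rep("", k)
  for (s in seq_along(spans)) {
    rng <- spans[[s]][1L]:spans[[s]][2L]
    lett[rng] <- paste0(lett[rng], LETTERS[s])
  }
  groups <- data.frame(method = names(m), mean_rank = unname(m),
                       letters = lett, stringsAsFactors = FALSE)
  structure(list(groups = groups, friedman_stat = fr$statistic,
                 friedman_p = fr$p_value, significant = TRUE, alpha = alpha,
                 mse = mse, df_error = dfe),
            class = "duncan_grouping")
}

#' Construct a Duncan grouping directly from means and letters
#'
#' Utility for building a `duncan_grouping` from an already-known letter
#' display (e.g. a published rating table) so that [rating_table()] can be
#' applied to it.
#'
#' @param method,mean_rank,letters parallel vectors.
#' @param friedman_stat,friedman_p optional Friedman results.
#' @return a `duncan_grouping`.
#' @export
duncan_grouping <- function(method, mean_rank, letters,
                            friedman_stat = NA_real_, friedman_p = NA_real_) {
  ord <- order(mean_rank)
  groups <- data.frame(method = method[ord], mean_rank = mean_rank[ord],
                       letters = letters[ord], stringsAsFactors = FALSE)
  structure(list(groups = groups, friedman_stat = friedman_stat,
                 friedman_p = friedman_p, significant = TRUE, alpha = 0.05),
            class = "duncan_grouping")
}

#' @export
print.duncan_grouping <- function(x, ...) {
  cat("Duncan multiple range grouping (Friedman chi-square = ",
      round(x$friedman_stat, 2), ", p = ", signif(x$friedman_p, 3), ")\n",
      sep = "")
  if (!x$significant)
    cat("  Friedman not significant at alpha =", x$alpha,
        "- no grouping performed\n")
  print(transform(x$groups, mean_rank = round(mean_rank, 2)), row.names = FALSE)
  invisible(x)
}

#' Rating table from a Duncan grouping
#'
#' Methods are sorted by ascending mean rank and assigned ratings 1..k; the
#' `top_group` flag marks every method sharing a letter with the rating-1
#' method (the set that is most efficient and does not differ significantly
#' from the best).
#'
#' @param grouping a `duncan_grouping`.
#' @return data frame with columns `rating`, `method`, `mean_rank`, `letters`,
#'   `top_group`.
#' @export
rating_table <- function(grouping) {
  stopifnot(inherits(grouping, "duncan_grouping"))
  g <- grouping$groups
  first <- strsplit(g$letters[1L], "")[[1L]]
  shares <- vapply(strsplit(g$letters, ""), function(l) any(l %in% first), TRUE)
  data.frame(rating = seq_len(nrow(g)), method = g$method,
             mean_rank = g$mean_rank, letters = g$letters,
             top_group = shares, stringsAsFactors = FALSE)
}

#' Render a rating table as monospace text
#'
#' @param ratings a [rating_table()] result.
#' @param title optional heading.
#' @return character vector of lines (also printed); top-group methods are
#'   marked with an asterisk.
#' @export
render_rating_table <- function(ratings, title = "Rating of statistical tests") {
  lines <- c(title,
             sprintf("%-3s %-10s %9s  %-6s %s", "#", "method", "mean rank",
                     "group", ""),
             sprintf("%-3d %-10s %9.2f  %-6s %s", ratings$rating,
                     ratings$method, ratings$mean_rank, ratings$letters,
                     ifelse(ratings$top_group, "*", "")))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Run the rank/Friedman/Duncan/rating pipeline within subgroups
#'
#' The full comparison pipeline is run independently within every value of a
#' metadata tag; subgroups with fewer than `min_datasets` comparator datasets
#' are skipped with a note.
#'
#' @param batteries list of `battery_result` objects.
#' @param tags character vector of the tag value for each battery (same
#'   order).
#' @param alpha significance level passed to [duncan_groups()].
#' @param min_datasets minimum datasets per retained subgroup.
#' @return named list per tag value: either a list with `ratings`, `grouping`,
#'   `n_datasets`, or a list with `skipped = TRUE`.
#' @export
compare_by_subgroup <- function(batteries, tags, alpha = 0.05,
                                min_datasets = 2L) {
  stopifnot(length(batteries) == length(tags))
  out <- list()
  for (v in unique(tags)) {
    sub <- batteries[tags == v]
    if (length(sub) < min_datasets) {
      message("subgroup '", v, "' skipped: only ", length(sub), " dataset(s)")
      out[[v]] <- list(skipped = TRUE, n_datasets = length(sub))
      next
    }
    rm <- rank_matrix(sub)
    gr <- duncan_groups(rm, alpha = alpha)
    out[[v]] <- list(ratings = rating_table(gr), grouping = gr,
                     n_datasets = length(sub), skipped = FALSE)
  }
  out
}

#' Bootstrap type-I-error assessment
#'
#' From a dataset with a neutral (dummy) treatment label, draws `B` resamples
#' with replacement and counts, for each method, how many resampled datasets
#' give `p < alpha`. With a valid test the count should be close to
#' `B * alpha` (about 50 of 1000 at the 5% level).
#'
#' By default the dummy treatment label is re-randomized (fair coin) within
#' every resample. This is essential for the count to be binomial around
#' `B * alpha`: resampling rows with their arm labels attached preserves
#' whatever chance arm-outcome association the one observed dataset carries,
#' so the significant-result count would then track the observed statistic
#' rather than the null. Set `reassign_arm = FALSE` to get that conditional
#' (observed-association-preserving) behaviour.
#'
#' @param dataset a [comparator_dataset()] whose arm label carries no true
#'   effect ([simulate_null()] or a dummy-relabelled real dataset).
#' @param scale an [ordinal_scale()].
#' @param methods battery methods to assess (default: the two most efficient
#'   ordinal tests).
#' @param B number of resamples (>= 100).
#' @param alpha significance threshold.
#' @param seed root seed; resample `b` uses the derived stream
#'   `derive_seed(seed, b)`.
#' @param config a [battery_config()].
#' @param reassign_arm re-randomize the dummy arm label within each resample
#'   (default `TRUE`; see Details).
#' @return named integer vector of significant counts, with attributes `B` and
#'   `alpha`.
#' @export
assess_type1_error <- function(dataset, scale, methods = c("MWU", "OLR"),
                               B = 1000L, alpha = 0.05, seed = 1L,
                               config = battery_config(),
                               reassign_arm = TRUE) {
  if (B < 100L) stop("B must be >= 100")
  counts <- stats::setNames(integer(length(methods)), methods)
  for (b in seq_len(B)) {
    rs <- resample_with_replacement(dataset, derive_seed(seed, b))
    if (reassign_arm) {
      # RNG state continues from the resampling stream: still deterministic
      n <- nrow(rs$records)
      rs$records$arm <- factor(ifelse(stats::rbinom(n, 1L, 0.5) == 1L,
                                      "treatment", "control"),
                               levels = c("control", "treatment"))
    }
    res <- run_battery(rs, scale, config = config, methods = methods)
    counts <- counts + as.integer(res$p_value < alpha & !res$degenerate)
  }
  attr(counts, "B") <- B
  attr(counts, "alpha") <- alpha
  counts
}

#' Boxplot of within-dataset p-value ranks per method
#'
#' @param rm a [rank_matrix()].
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the boxplot stats.
#' @export
plot_rank_distribution <- function(rm, ...) {
  stopifnot(inherits(rm, "rank_matrix"))
  ord <- order(colMeans(rm$ranks))
  invisible(graphics::boxplot(rm$ranks[, ord, drop = FALSE], las = 2,
                              ylab = "within-dataset rank of p-value", ...))
}
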