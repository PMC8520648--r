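test_that("a perfectly symmetric dataset gives the maximal p for every method", {
  sc <- default_scales()$strokeTIA4
  half <- simulate_comparator(sim_config(sc, n_per_arm = 400, seed = 5))$records
  half <- half[half$arm == "control", ]
  mirror <- half; mirror$arm <- "treatment"
  ds <- comparator_dataset("sym", rbind(half, mirror))
  res <- run_battery(ds, sc, battery_config(seed = 2))
  for (i in seq_len(nrow(res))) {
    tol <- if (res$method[i] == "BS") 0.8 else 0.95   # bootstrap p is granular
    expect_gte(res$p_value[i], tol)
  }
  wr <- res[res$method == "WR", ]
  expect_equal(wr$estimate, 1.0)
})

test_that("an all-zero-event dataset yields 15 results, most degenerate", {
  sc <- default_scales()$stroke3
  rec <- records_from_levels(rep(0L, 20), rep(0L, 20), sc)
  ds <- comparator_dataset("zero", rec)
  res <- run_battery(ds, sc)
  expect_identical(nrow(res), 15L)
  expect_identical(res$method, battery_methods())
  expect_gte(sum(res$degenerate), 12L)
  expect_true(all(res$p_value == 1))
})

test_that("missing time columns degrade only the proportional-hazards methods", {
  sc <- default_scales()$stroke3
  rec <- records_from_levels(c(0L, 1L, 2L, 0L, 0L), c(0L, 0L, 1L, 0L, 2L), sc,
                             with_time = FALSE)
  ds <- comparator_dataset("nt", rec)
  expect_warning(res <- run_battery(ds, sc), "time column")
  expect_true(all(res$degenerate[res$method %in% c("CPH", "CPH_adj")]))
  expect_false(any(res$degenerate[res$method %in% c("MWU", "CSB")]))
})

test_that("win ratio counts match brute-force pair enumeration", {
  sc <- default_scales()$strokeTIA4
  # worked example: treatment {none, none, TIA}, control {fatal, none, none}
  ds <- dataset_from_levels(c(0L, 0L, 1L), c(3L, 0L, 0L), sc)
  wr <- win_ratio_test(ds, sc)
  expect_equal(wr$diagnostics$Nw, 3)
  expect_equal(wr$diagnostics$Nl, 2)
  expect_equal(wr$diagnostics$Nt, 4)
  expect_equal(wr$estimate, 1.5)
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(3:4, 1)
    scale <- if (k == 3) default_scales()$stroke3 else sc
    lt <- sample(0:(k - 1), sample(4:15, 1), TRUE)
    lc <- sample(0:(k - 1), sample(4:15, 1), TRUE)
    wr <- win_ratio_test(dataset_from_levels(lt, lc, scale), scale)
    oracle <- enumerate_wr(lt, lc)
    expect_equal(wr$diagnostics$Nw, unname(oracle["Nw"]))
    expect_equal(wr$diagnostics$Nl, unname(oracle["Nl"]))
    expect_equal(wr$diagnostics$Nt, unname(oracle["Nt"]))
    # identity with the Mann-Whitney U statistic of treatment over control
    expect_equal(wr$diagnostics$Nw + 0.5 * wr$diagnostics$Nt,
                 enumerate_u(lt, lc))
  }
})

test_that("the tie-corrected normal moments equal the permutation moments exactly", {
  # the MWU p-value rests on mu = n1(n+1)/2 and the tie-corrected variance;
  # both must equal the exact moments of the rank-sum permutation distribution
  set.seed(17)
  for (rep in 1:10) {
    x <- sample(0:3, sample(5:8, 1), TRUE)
    y <- sample(0:3, sample(5:8, 1), TRUE)
    if (sd(c(x, y)) == 0) next
    pd <- perm_ranksum(x, y)
    n1 <- length(x); n2 <- length(y); n <- n1 + n2
    t <- table(c(x, y))
    var_formula <- n1 * n2 / 12 * ((n + 1) - sum(t^3 - t) / (n * (n - 1)))
    expect_equal(mean(pd$W), n1 * (n + 1) / 2, tolerance = 1e-12)
    expect_equal(mean((pd$W - mean(pd$W))^2), var_formula, tolerance = 1e-8)
  }
})

test_that("MWU agrees with the standard implementation and reports the probabilistic index", {
  sc <- default_scales()$strokeTIA4
  lt <- c(0L, 0L, 1L, 2L, 0L, 3L, 0L, 1L)
  lc <- c(0L, 1L, 2L, 2L, 3L, 0L, 1L, 1L)
  ds <- dataset_from_levels(lt, lc, sc)
  res <- run_battery(ds, sc, methods = "MWU")
  ref <- wilcox.test(lt, lc, exact = FALSE, correct = FALSE)
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$estimate, enumerate_u(lt, lc) / (length(lt) * length(lc)))
})

test_that("the bootstrap mean-rank statistic matches the hand mid-rank computation", {
  sc <- default_scales()$stroke3
  ds <- dataset_from_levels(c(0L, 0L, 2L), c(0L, 1L, 1L), sc)
  res <- bootstrap_mean_rank_test(ds, sc, B = 200, seed = 12)
  expect_equal(res$estimate, -1 / 3, tolerance = 1e-12)
  res2 <- bootstrap_mean_rank_test(ds, sc, B = 200, seed = 12)
  expect_identical(res$p_value, res2$p_value)
  expect_error(bootstrap_mean_rank_test(ds, sc, B = 50), ">= 100")
})

test_that("the ordinal chi-square collapses to the binary chi-square with two occupied levels", {
  sc <- default_scales()$stroke3
  lt <- c(rep(0L, 30), rep(2L, 6))
  lc <- c(rep(0L, 33), rep(2L, 2))
  ds <- dataset_from_levels(lt, lc, sc)
  res <- run_battery(ds, sc, methods = c("CSB", "CSO"))
  expect_equal(res$p_value[res$method == "CSO"],
               res$p_value[res$method == "CSB"], tolerance = 1e-12)
})

test_that("the trend test dominates the omnibus chi-square under a monotone shift", {
  sc <- default_scales()$strokeTIA4
  # the 1-df directed statistic beats the (k-1)-df omnibus when the arm split
  # trends linearly in the level scores (the alternative the trend test is
  # built for; under a proportional-odds shift with 90% mass at "none" the
  # split is monotone but nonlinear, and the omnibus picks up the rest)
  wins <- 0L
  n <- 4000
  for (r in 1:40) {
    set.seed(derive_seed(23, r))
    lev <- sample(0:3, n, TRUE, prob = c(0.90, 0.04, 0.04, 0.02))
    arm_lab <- ifelse(rbinom(n, 1, 0.45 + 0.09 * lev) == 1,
                      "treatment", "control")
    ds <- comparator_dataset("lin", records_from_levels(
      lev[arm_lab == "treatment"], lev[arm_lab == "control"], sc))
    res <- run_battery(ds, sc, methods = c("CAT", "CSO"))
    if (res$p_value[res$method == "CAT"] <= res$p_value[res$method == "CSO"])
      wins <- wins + 1L
  }
  expect_gte(wins, 36L)  # >= 90% of 40
})

test_that("ordinal analysis outranks the binary chi-square when treatment also reduces severity", {
  # the premise of severity-graded outcomes: an effective treatment alters
  # both the risk and the severity of events; the binary chi-square is blind
  # to the severity component, so the rank test should produce the smaller p
  sc <- default_scales()$strokeTIA4
  wins <- 0L
  for (r in 1:100) {
    cfg <- sim_config(sc, n_per_arm = 2000, treatment_logOR = log(0.85),
                      severity_logOR = log(0.5), seed = derive_seed(29, r))
    ds <- simulate_comparator(cfg)
    res <- run_battery(ds, sc, methods = c("MWU", "CSB"))
    if (res$p_value[res$method == "MWU"] < res$p_value[res$method == "CSB"])
      wins <- wins + 1L
  }
  expect_gte(wins, 80L)
})

test_that("under a pure proportional-odds benefit the rank test still at least matches the binary test", {
  # with ~90% of mass at "none" the severity tail adds little information, so
  # the advantage is small but should not reverse on average
  sc <- default_scales()$strokeTIA4
  zdiff <- numeric(100)
  for (r in 1:100) {
    cfg <- sim_config(sc, n_per_arm = 5000, treatment_logOR = log(0.7),
                      seed = derive_seed(31, r))
    ds <- simulate_comparator(cfg)
    res <- run_battery(ds, sc, methods = c("MWU", "CSB"))
    zdiff[r] <- qnorm(res$p_value[res$method == "CSB"] / 2) -
      qnorm(res$p_value[res$method == "MWU"] / 2)
  }
  # |z_MWU| - |z_CSB| is positive on average (small: the tail is thin)
  expect_gt(mean(zdiff), 0)
})

test_that("the win-ratio falls back gracefully on one-sided extremes", {
  sc <- default_scales()$stroke3
  ds <- dataset_from_levels(rep(0L, 10), c(rep(0L, 8), 1L, 2L), sc)
  wr <- win_ratio_test(ds, sc, seed = 3)
  expect_equal(wr$diagnostics$Nl, 0)
  expect_true(is.infinite(wr$estimate))
  expect_true(wr$p_value > 0 && wr$p_value <= 1)
})
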