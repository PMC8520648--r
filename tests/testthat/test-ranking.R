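test_that("p-value ranking uses mid-ranks and conserves the row sum", {
  p <- c(0.01, 0.20, 0.05, 0.30, 0.40, 0.50, 0.60, 0.65, 0.70, 0.75, 0.80,
         0.85, 0.90, 0.95, 1.00)
  expect_identical(rank_pvalues(p)[1:3], c(1, 3, 2))
  tied <- c(0.01, 0.01, seq(0.1, 1, length.out = 13))
  r <- rank_pvalues(tied)
  expect_equal(r[1:2], c(1.5, 1.5))
  expect_equal(sum(r), 120)
  expect_equal(rank_pvalues(rep(0.5, 15)), rep(8, 15))
  expect_error(rank_pvalues(c(NA, rep(0.5, 14))), "degenerate")
  expect_error(rank_pvalues(c(2, rep(0.5, 14))), "\\[0, 1\\]")
})

test_that("tie-adjusted Friedman matches closed forms and the untied classic", {
  # identical untied rankings in every row: statistic = n(k-1)
  R <- matrix(rep(1:3, each = 10), nrow = 10)
  rm <- structure(list(datasets = paste0("d", 1:10), methods = c("a", "b", "c"),
                       ranks = R), class = "rank_matrix")
  fr <- friedman_with_ties(rm)
  expect_equal(fr$statistic, 10 * (3 - 1), tolerance = 1e-12)
  # fully tied rows: statistic defined as 0, p = 1
  Rt <- matrix(2, nrow = 4, ncol = 3)
  rmt <- structure(list(datasets = paste0("d", 1:4), methods = c("a", "b", "c"),
                        ranks = Rt), class = "rank_matrix")
  frt <- friedman_with_ties(rmt)
  expect_identical(frt$statistic, 0)
  expect_identical(frt$p_value, 1)
  # no ties: equals stats::friedman.test on the same data
  set.seed(61)
  y <- matrix(rnorm(8 * 5), nrow = 8)
  ranks <- t(apply(y, 1, rank))
  rmu <- structure(list(datasets = paste0("d", 1:8), methods = paste0("m", 1:5),
                        ranks = ranks), class = "rank_matrix")
  expect_equal(friedman_with_ties(rmu)$statistic,
               unname(stats::friedman.test(y)$statistic), tolerance = 1e-10)
  expect_error(friedman_with_ties(structure(list(datasets = "d1",
                                                 methods = c("a", "b"),
                                                 ranks = matrix(1:2, 1)),
                                            class = "rank_matrix")),
               ">= 2 datasets")
})

test_that("tie-adjusted Friedman p matches the exact permutation distribution where it is used", {
  # the chi-square approximation on a 4x3 matrix is only consumed at the
  # significance gate; in that regime it tracks the exact permutation p
  # closely (in the centre of the null distribution, chi-square p-values on
  # 4 blocks are far from exact, as for any chi-square approximation at n=4)
  agreement_patterns <- list(
    matrix(rep(1:3, each = 4), nrow = 4),                      # full agreement
    rbind(matrix(rep(1:3, each = 3), nrow = 3), c(1, 3, 2)),   # one dissent
    rbind(matrix(rep(1:3, each = 3), nrow = 3), c(2, 1, 3)),
    rbind(matrix(rep(c(1.5, 1.5, 3), each = 3), nrow = 3), c(1, 2, 3)))
  for (ranks in agreement_patterns) {
    rm <- structure(list(datasets = paste0("d", 1:4),
                         methods = c("a", "b", "c"), ranks = ranks),
                    class = "rank_matrix")
    fr <- friedman_with_ties(rm)
    pex <- perm_friedman_p(ranks)
    expect_lte(pex, 0.06)          # these patterns sit at the gate
    expect_lt(abs(fr$p_value - pex), 0.02 + 1e-9)
  }
})

test_that("Duncan grouping separates clustered methods and respects the Friedman gate", {
  # two clusters: methods 1-2 always occupy ranks {1, 2}, methods 3-4 {3, 4}
  set.seed(71)
  n <- 12
  ranks <- t(replicate(n, c(sample(1:2), sample(3:4))))
  rm <- structure(list(datasets = paste0("d", seq_len(n)),
                       methods = paste0("m", 1:4), ranks = ranks),
                  class = "rank_matrix")
  gr <- duncan_groups(rm, alpha = 0.05)
  expect_true(gr$significant)
  g <- gr$groups
  low <- strsplit(g$letters[g$method %in% c("m1", "m2")], "")
  high <- strsplit(g$letters[g$method %in% c("m3", "m4")], "")
  expect_length(intersect(unlist(low), unlist(high)), 0L)
  # the all-pairs studentized-range oracle agrees with the cross-cluster split
  expect_true(range_significant(ranks, 2, 3))
  expect_true(range_significant(ranks, 1, 4))
  # flat matrix: Friedman not significant, single group
  flat <- matrix(rep(c(1.5, 1.5, 3.5, 3.5), 2), nrow = 2, byrow = TRUE)
  colnames(flat) <- paste0("m", 1:4)
  rmf <- structure(list(datasets = c("d1", "d2"), methods = paste0("m", 1:4),
                        ranks = t(apply(flat, 1, function(x) rank(rep(1, 4))))),
                   class = "rank_matrix")
  grf <- duncan_groups(rmf)
  expect_false(grf$significant)
  expect_true(all(grf$groups$letters == "A"))
})

test_that("Duncan letters are transitive-consistent with the tested ranges", {
  set.seed(73)
  n <- 10; k <- 6
  ranks <- t(replicate(n, rank(rnorm(k, mean = seq_len(k) * 0.6))))
  rm <- structure(list(datasets = paste0("d", seq_len(n)),
                       methods = paste0("m", seq_len(k)), ranks = ranks),
                  class = "rank_matrix")
  gr <- duncan_groups(rm)
  if (gr$significant) {
    g <- gr$groups
    letters_of <- strsplit(g$letters, "")
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i < j && length(intersect(letters_of[[i]], letters_of[[j]]))) {
        # sharing a letter means the whole span i..j was non-significant,
        # so every enclosed pair must share that letter too
        shared <- intersect(letters_of[[i]], letters_of[[j]])
        for (l in i:j)
          expect_true(length(intersect(shared, letters_of[[l]])) > 0)
      }
    }
  }
})

test_that("a method that always wins excludes the consistent loser from its group", {
  set.seed(79)
  n <- 20; k <- 5
  ranks <- t(replicate(n, c(1, rank(rnorm(3)) + 1, 5)))
  rm <- structure(list(datasets = paste0("d", seq_len(n)),
                       methods = c("best", "a", "b", "c", "worst"),
                       ranks = ranks), class = "rank_matrix")
  gr <- duncan_groups(rm)
  expect_true(gr$significant)
  g <- gr$groups
  best <- strsplit(g$letters[g$method == "best"], "")[[1]]
  worst <- strsplit(g$letters[g$method == "worst"], "")[[1]]
  expect_length(intersect(best, worst), 0L)
})

test_that("rating tables flag the published top group from the letter display", {
  # strictly increasing means, distinct letters: identity permutation
  gr <- duncan_grouping(paste0("m", 1:4), c(1, 2, 3, 4),
                        c("A", "B", "C", "D"))
  rt <- rating_table(gr)
  expect_identical(rt$rating, 1:4)
  expect_identical(rt$method, paste0("m", 1:4))
  # letter-sharing rule
  gr2 <- duncan_grouping(c("x", "y", "z"), c(1, 2, 3), c("A", "AB", "B"))
  expect_identical(rating_table(gr2)$top_group, c(TRUE, TRUE, FALSE))
  # the published 4-level stroke/TIA letter display
  pub <- data.frame(
    method = c("MWU", "OLR", "OLR_adj", "BS", "WR", "CAT", "TT", "MLR_adj",
               "MT", "BLR_adj", "CPH", "CPH_adj", "CSB", "CSO", "CSF"),
    mean_rank = c(4.69, 6.26, 6.31, 6.43, 6.69, 6.71, 6.89, 6.91, 8.06, 8.49,
                  9.06, 9.34, 10.37, 11.14, 12.66),
    letters = c("A", "AB", "ABC", "ABC", "ABC", "ABC", "BC", "BC", "BCD",
                "CDE", "DE", "DEF", "EF", "FG", "G"),
    stringsAsFactors = FALSE)
  rt3 <- rating_table(duncan_grouping(pub$method, pub$mean_rank, pub$letters))
  expect_identical(rt3$method[rt3$rating == 1], "MWU")
  expect_setequal(rt3$method[rt3$top_group],
                  c("MWU", "OLR", "OLR_adj", "BS", "WR", "CAT"))
})

test_that("subgroup comparison reduces to the overall table for a single tag value", {
  sc <- default_scales()$strokeTIA4
  batteries <- lapply(1:4, function(d) {
    cfg <- sim_config(sc, n_per_arm = 250, treatment_logOR = log(0.7),
                      seed = derive_seed(83, d))
    run_battery(simulate_comparator(cfg, id = paste0("d", d)), sc,
                battery_config(seed = d))
  })
  overall <- rating_table(duncan_groups(rank_matrix(batteries)))
  sub <- compare_by_subgroup(batteries, rep("APT", 4))
  expect_identical(sub$APT$ratings, overall)
  expect_message(sub2 <- compare_by_subgroup(batteries, c("a", "a", "a", "b")),
                 "skipped")
  expect_true(sub2$b$skipped)
  expect_false(sub2$a$skipped)
})

test_that("the type-I-error assessment is deterministic and respects alpha", {
  sc <- default_scales()$stroke3
  ds <- simulate_null(sim_config(sc, n_per_arm = 150, seed = 89))
  c1 <- assess_type1_error(ds, sc, methods = c("MWU", "TT"), B = 100, seed = 7)
  c2 <- assess_type1_error(ds, sc, methods = c("MWU", "TT"), B = 100, seed = 7)
  expect_identical(c1, c2)
  c0 <- assess_type1_error(ds, sc, methods = c("MWU", "TT"), B = 100,
                           alpha = 0, seed = 7)
  expect_true(all(c0 == 0L))
  expect_error(assess_type1_error(ds, sc, B = 50), ">= 100")
})

test_that("MWU and OLR hold the bootstrap type-I error on a 5-level stroke scale", {
  sc <- default_scales()$stroke5
  ds <- simulate_null(sim_config(sc, n_per_arm = 1000, seed = 97))
  counts <- assess_type1_error(ds, sc, methods = c("MWU", "OLR"), B = 400,
                               seed = 11)
  # 99% binomial band around 400 * 0.05 = 20
  expect_true(all(counts >= 9L & counts <= 31L))
})
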