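example_table <- function() matrix(c(2L, 1L, 0L, 2L), 2, 2, byrow = TRUE)

test_that("percentage agreement counts within-tolerance pairs", {
  expect_equal(percentage_agreement(diag(c(3L, 4L, 5L))), 100)
  expect_equal(percentage_agreement(example_table()), 80)
  p <- paired_sample(c(10, 12, 14), c(11, 12, 16), C = 35)
  expect_equal(percentage_agreement(p, 0), 100 / 3)
  expect_equal(percentage_agreement(p, 1), 200 / 3)
  expect_equal(percentage_agreement(p, 2), 100)
  expect_error(percentage_agreement(p, -1), "nonnegative")
})

test_that("minimum tolerance is the smallest k reaching the threshold", {
  expect_equal(min_tolerance(diag(c(2L, 2L))), 0)
  p <- paired_sample(c(10, 12, 14), c(11, 12, 16), C = 35)
  tab <- build_contingency(p)
  expect_equal(min_tolerance(tab, 70), 2)
  expect_equal(min_tolerance(tab, 100), 2)
  expect_equal(min_tolerance(tab, 30), 0)
  expect_error(min_tolerance(tab, 0), "threshold")
})

test_that("RP, RC, RV and ROC reproduce hand-enumerated cases", {
  tab <- example_table()
  expect_equal(relative_position(tab), 0.2)  # (9 - 4) / 25 over marginal pairs
  expect_equal(relative_rank_variance(tab), 0)  # purely systematic shift
  roc <- roc_points(tab)
  expect_equal(roc$u, c(0, 0.6, 1))
  expect_equal(roc$v, c(0, 0.4, 1))
  # maximal upward shift
  all_up <- build_contingency(paired_sample(rep(0, 4), rep(1, 4), C = 2))
  expect_equal(relative_position(all_up), 1)
  # 2-category scales admit no betweenness
  expect_equal(relative_concentration(tab), 0)
  # first assessment at the extremes, second all central
  tab3 <- matrix(0L, 3, 3); tab3[1, 2] <- 2L; tab3[3, 2] <- 2L
  expect_equal(relative_concentration(tab3), 0.5)
  # crossing table: disagreement purely random
  cross <- matrix(c(1L, 1L, 1L, 1L), 2, 2)
  expect_equal(relative_rank_variance(cross), 0.1875)
  # identical marginals: no systematic disagreement, diagonal ROC
  sym <- matrix(c(3L, 1L, 1L, 2L), 2, 2)
  expect_equal(relative_position(sym), 0)
  expect_equal(relative_concentration(sym), 0)
  expect_equal(roc_points(sym)$u, roc_points(sym)$v)
})

test_that("augmented mean ranks match the subject-level construction", {
  one_cell <- matrix(0L, 3, 3); one_cell[2, 2] <- 7L
  r <- augmented_mean_ranks(one_cell)
  expect_equal(r$R1[2, 2], 4)  # (n + 1) / 2
  expect_equal(r$R2[2, 2], 4)
  tab <- example_table()
  r <- augmented_mean_ranks(tab)
  expect_equal(r$R1[1, 1], 1.5); expect_equal(r$R2[1, 1], 1.5)
  expect_equal(r$R1[1, 2], 3);   expect_equal(r$R2[1, 2], 3)
  expect_equal(r$R1[2, 2], 4.5); expect_equal(r$R2[2, 2], 4.5)
  anti <- matrix(c(0L, 1L, 1L, 0L), 2, 2, byrow = TRUE)
  r <- augmented_mean_ranks(anti)
  expect_equal(r$R1[1, 2], 1); expect_equal(r$R2[1, 2], 2)
  expect_equal(r$R1[2, 1], 2); expect_equal(r$R2[2, 1], 1)
})

test_that("augmented ranks sum to n(n+1)/2 under both assessments", {
  set.seed(7)
  for (rep in 1:30) {
    p <- random_pairs(n = sample(2:12, 1), C = sample(2:5, 1))
    tab <- build_contingency(paired_sample(p$x, p$y, C = p$C))
    r <- augmented_mean_ranks(tab)
    n <- sum(tab)
    expect_equal(sum(tab * r$R1), n * (n + 1) / 2)
    expect_equal(sum(tab * r$R2), n * (n + 1) / 2)
  }
})

test_that("closed forms agree with enumeration oracles on random tables", {
  set.seed(101)
  for (rep in 1:60) {
    p <- random_pairs(n = sample(2:12, 1), C = sample(2:5, 1),
                      diagonal_bias = stats::runif(1, 0, 0.8))
    tab <- build_contingency(paired_sample(p$x, p$y, C = p$C))
    k <- sample(0:(p$C - 1), 1)
    expect_equal(percentage_agreement(tab, k), oracle_pa(p$x, p$y, k),
                 tolerance = 1e-12)
    expect_equal(relative_position(tab), oracle_rp(p$x, p$y),
                 tolerance = 1e-12)
    expect_equal(relative_concentration(tab), oracle_rc(p$x, p$y),
                 tolerance = 1e-12)
    expect_equal(relative_rank_variance(tab), oracle_rv(p$x, p$y, p$C),
                 tolerance = 1e-12)
  }
})

test_that("transpose and category reversal behave as symmetries", {
  set.seed(202)
  for (rep in 1:40) {
    p <- random_pairs(n = sample(2:12, 1), C = sample(2:5, 1))
    tab <- build_contingency(paired_sample(p$x, p$y, C = p$C))
    tt <- t(tab)
    expect_equal(relative_position(tt), -relative_position(tab))
    expect_equal(relative_concentration(tt), -relative_concentration(tab))
    expect_equal(relative_rank_variance(tt), relative_rank_variance(tab))
    expect_equal(percentage_agreement(tt, 1), percentage_agreement(tab, 1))
    rev_tab <- tab[p$C:1, p$C:1]
    expect_equal(relative_position(rev_tab), -relative_position(tab))
    expect_equal(percentage_agreement(rev_tab), percentage_agreement(tab))
    expect_equal(relative_rank_variance(rev_tab),
                 relative_rank_variance(tab))
  }
})

test_that("RP, RC and the ROC curve depend only on the marginals", {
  set.seed(303)
  for (rep in 1:20) {
    C <- sample(2:5, 1)
    p <- random_pairs(n = 12, C = C)
    tab <- build_contingency(paired_sample(p$x, p$y, C = C))
    # shuffle the pairing: same marginals, different joint distribution
    q <- build_contingency(paired_sample(sample(p$x), sample(p$y), C = C))
    expect_equal(relative_position(q), relative_position(tab))
    expect_equal(relative_concentration(q), relative_concentration(tab))
    expect_equal(roc_points(q), roc_points(tab))
  }
})

test_that("tolerance agreement is nondecreasing and saturates at C-1", {
  set.seed(404)
  for (rep in 1:20) {
    p <- random_pairs(n = sample(2:12, 1), C = sample(2:5, 1))
    tab <- build_contingency(paired_sample(p$x, p$y, C = p$C))
    pas <- vapply(0:(p$C - 1), function(k) percentage_agreement(tab, k), 0)
    expect_true(all(diff(pas) >= 0))
    expect_equal(pas[p$C], 100)
  }
})

test_that("degenerate tables are handled without error", {
  single <- matrix(5L, 1, 1)
  expect_equal(percentage_agreement(single), 100)
  expect_equal(relative_position(single), 0)
  expect_equal(relative_concentration(single), 0)
  expect_equal(relative_rank_variance(single), 0)
  expect_equal(roc_points(single)$u, c(0, 1))
  diagonal <- diag(c(2L, 0L, 3L))
  expect_equal(percentage_agreement(diagonal), 100)
  expect_equal(relative_position(diagonal), 0)
  expect_equal(relative_concentration(diagonal), 0)
  expect_equal(relative_rank_variance(diagonal), 0)
})

test_that("rank_agreement bundles the statistics coherently", {
  fit <- rank_agreement(example_table(), tolerances = 1, ci = FALSE)
  expect_s3_class(fit, "rank_agreement")
  expect_equal(unname(coef(fit)), c(80, 0.2, relative_concentration(example_table()), 0))
  expect_equal(unname(fit$pa_k["PA_1"]), 100)
  expect_equal(fit$min_k, 0)
  expect_output(print(fit), "PA = 80")
  s <- summary(fit)
  expect_equal(s$estimates$estimate[s$estimates$statistic == "RP"], 0.2)
  fit2 <- rank_agreement(c(0, 1, 2, 2), c(0, 1, 2, 2), ci = FALSE)
  expect_equal(unname(coef(fit2)), c(100, 0, 0, 0))
  expect_equal(sum(residuals(fit2)^2), 0)
})

test_that("large samples separate systematic from random disagreement", {
  set.seed(505)
  C <- 35L; n <- 2000L
  x <- sample.int(C, n, replace = TRUE) - 1L
  indep <- paired_sample(x, sample.int(C, n, replace = TRUE) - 1L, C = C)
  expect_gt(relative_rank_variance(indep), 0.85)  # -> 1 under independence
  ident <- paired_sample(x, x, C = C)
  expect_equal(percentage_agreement(ident), 100)
  expect_equal(relative_rank_variance(ident), 0)
})
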