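test_that("fixed-margin draws preserve margins exactly", {
  expect_equal(patefield_sample(5, 5, seed = 1), matrix(5))
  expect_error(patefield_sample(c(2, 2), c(3, 2)),
               class = "antnets_validation_error")
  set.seed(2)
  r <- c(7, 3, 5); cc <- c(6, 4, 5)
  draws <- patefield_sample(r, cc, n = 500, seed = 9)
  expect_true(all(vapply(draws, function(d) {
    all(rowSums(d) == r) && all(colSums(d) == cc)
  }, logical(1))))
})

test_that("2x2 fixed-margin draws follow the hypergeometric law", {
  # margins (2,2)/(2,2): a11 ~ P(0)=1/6, P(1)=4/6, P(2)=1/6
  n <- 6000
  draws <- patefield_sample(c(2, 2), c(2, 2), n = n, seed = 4)
  a11 <- vapply(draws, function(d) d[1, 1], numeric(1))
  freq <- tabulate(a11 + 1L, 3) / n
  p <- c(1, 4, 1) / 6
  sigma <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) < 4 * sigma))
})

test_that("metric significance uses the pseudocount convention", {
  D <- named_layer(diag(4, 5, 5))
  rep_h2 <- metric_significance(D, h2prime, n_null = 99, "greater", seed = 8)
  # the diagonal matrix attains the maximum H2'
  expect_equal(rep_h2$observed, 1)
  expect_lte(rep_h2$p_value, 2 / 100)
  expect_gt(rep_h2$p_value, 0)

  # a margin-conserved statistic is never extreme
  total_fn <- function(m) sum(m)
  rep_f <- metric_significance(D, total_fn, n_null = 49, "two-sided", seed = 8)
  expect_equal(rep_f$p_value, 1)
  expect_equal(length(rep_f$null_values), 49L)

  # bit-reproducible given the seed
  a <- metric_significance(D, wnodf, n_null = 29, "greater", seed = 31)
  b <- metric_significance(D, wnodf, n_null = 29, "greater", seed = 31)
  expect_identical(a$null_values, b$null_values)
  expect_identical(a$p_value, b$p_value)
})

test_that("standardized Q flags planted structure and degenerate nulls", {
  pm <- planted_modular_matrix(6, 6, 2, 0.02, 120, seed = 3)
  sq <- standardized_Q(pm$matrix, n_null = 50, n_iter = 3, seed = 12)
  expect_false(sq$degenerate)
  expect_gte(sq$z, 2)
  expect_true(sq$significant)

  # a structureless matrix is never flagged significant (its Q of 0 can sit
  # below the null mean, so only the upper tail is meaningful)
  U <- named_layer(matrix(3, 3, 3))
  squ <- standardized_Q(U, n_null = 40, n_iter = 2, seed = 12)
  expect_lt(squ$z, 2)
  expect_false(squ$significant)

  # margins (1,1)/(1,1): every null table is a permutation matrix with the
  # same optimal Q, so the null SD collapses
  P <- named_layer(matrix(c(1, 0, 0, 1), 2, 2))
  expect_warning(sqd <- standardized_Q(P, n_null = 20, n_iter = 2, seed = 1),
                 "degenerate")
  expect_true(sqd$degenerate)
  expect_true(is.na(sqd$z))
})

test_that("layer difference test is null under identical layers", {
  set.seed(6)
  A <- named_layer(random_count_matrix(5, 4, 60), resource = "EFN")
  cmp <- layer_difference_test(A, A, wnodf, n = 99, seed = 14)
  expect_equal(cmp$observed_diff, 0)
  expect_gt(cmp$p_value, 0.05)
  expect_false(cmp$significant)

  # totals are conserved by the nulls: all null differences equal observed
  cmp_f <- layer_difference_test(A, A, function(m) sum(m), n = 49, seed = 2)
  expect_equal(cmp_f$p_value, 1)
  expect_true(all(cmp_f$null_diffs == cmp_f$observed_diff))
})

test_that("p-values stay within (0, 1]", {
  set.seed(44)
  for (rep in 1:3) {
    A <- named_layer(random_count_matrix(4, 4, 30))
    r1 <- metric_significance(A, h2prime, n_null = 19, "greater",
                              seed = rep)
    r2 <- metric_significance(A, horn_overlap, n_null = 19, "two-sided",
                              seed = rep)
    expect_true(r1$p_value > 0 && r1$p_value <= 1)
    expect_true(r2$p_value > 0 && r2$p_value <= 1)
  }
})
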