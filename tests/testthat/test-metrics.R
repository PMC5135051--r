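test_that("H2' hits its analytic endpoints", {
  D <- named_layer(diag(5, 3, 3))
  expect_equal(h2prime(D)$value, 1)
  I <- named_layer(matrix(1, 2, 2))
  expect_equal(h2prime(I)$value, 0)
  # outer-product matrix at the independence expectation
  E <- named_layer(outer(c(2, 4), c(1, 2, 3)))  # margins (12,24)/(6,12,18)
  expect_equal(h2prime(E)$value, 0, tolerance = 1e-10)
  expect_error(h2prime(named_layer(matrix(1:3, 1, 3))),
               class = "antnets_undefined_metric")
})

test_that("H2' matches margin-constrained enumeration on small matrices", {
  # the 3x3 case with margins (4,3,2)/(3,3,3)
  M <- named_layer(matrix(c(2, 1, 1,
                            1, 1, 1,
                            0, 1, 1), 3, 3, byrow = TRUE))
  expect_equal(rowSums(unclass_mat(M)), c(P01 = 4, P02 = 3, P03 = 2))
  expect_equal(h2prime(M)$value, oracle_h2prime(unclass_mat(M)))
  set.seed(31)
  for (rep in 1:10) {
    M <- random_count_matrix(3, 3, sample(4:10, 1))
    expect_equal(h2prime(named_layer(M))$value, oracle_h2prime(M),
                 tolerance = 1e-10)
  }
})

test_that("H2' is invariant to integer rescaling of the matrix", {
  M <- matrix(c(4, 1, 0, 3, 1, 1), 2, 3)
  base <- h2prime(named_layer(M))$value
  # exact bounds below total 12, heuristic fills above: the index is scale
  # free up to the small heuristic/exact bound gap
  for (k in c(3, 10)) {
    expect_equal(h2prime(named_layer(k * M))$value, base, tolerance = 0.06)
  }
  # within the heuristic regime the greedy fills scale almost exactly
  expect_equal(h2prime(named_layer(5 * M))$value,
               h2prime(named_layer(10 * M))$value, tolerance = 0.01)
})

test_that("WNODF follows the decreasing-fill overlap definition", {
  # equal margins: no pair satisfies decreasing fill
  U <- named_layer(matrix(2, 3, 3))
  expect_equal(wnodf(U)$value, 0)
  # anti-diagonal: no overlapping positive cells
  A <- named_layer(matrix(c(0, 0, 1, 0, 2, 0, 3, 0, 0), 3, 3))
  expect_equal(wnodf(A)$value, 0)
  # perfectly nested weighted matrix: hand evaluation gives 100
  N <- named_layer(matrix(c(3, 2, 1, 2, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE))
  expect_equal(wnodf(N)$value, oracle_wnodf(unclass_mat(N)))
  expect_equal(wnodf(N)$value, 100)
  set.seed(7)
  for (rep in 1:10) {
    M <- random_count_matrix(4, 3, 20)
    v <- wnodf(named_layer(M))$value
    expect_equal(v, oracle_wnodf(M))
    expect_gte(v, 0); expect_lte(v, 100)
  }
})

test_that("Morisita-Horn overlap matches its closed form", {
  expect_equal(horn_pair(c(1, 0, 2), c(2, 0, 4)), 1)
  expect_equal(horn_pair(c(1, 0), c(0, 3)), 0)
  expect_equal(horn_pair(c(1, 1), c(1, 3)), 8 / 9)
  M <- named_layer(matrix(c(1, 1, 1, 3, 2, 0), 2, 3))
  expect_equal(horn_overlap(M)$value, oracle_horn_ants(unclass_mat(M)))
  # plants guild is the transpose view
  expect_equal(horn_overlap(M, "plants")$value,
               oracle_horn_ants(t(unclass_mat(M))))
  expect_error(horn_overlap(named_layer(matrix(1:2, 2, 1))),
               class = "antnets_undefined_metric")
  set.seed(13)
  for (rep in 1:5) {
    M <- random_count_matrix(5, 4, 30)
    v <- horn_overlap(named_layer(M))$value
    expect_equal(v, oracle_horn_ants(M))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("degree centrality counts distinct partners", {
  L <- build_layer(toy_events(), "EFN")
  deg <- degree_centrality(L)
  expect_equal(unname(c(deg$plants, deg$ants)), rep(1, 4))
  Mfull <- named_layer(matrix(1:9, 3, 3))
  deg <- degree_centrality(Mfull)
  expect_equal(unname(deg$plants), rep(3, 3))
  set.seed(5)
  M <- random_count_matrix(6, 4, 18)
  deg <- degree_centrality(named_layer(M))
  expect_equal(unname(deg$plants), unname(apply(M > 0, 1, sum)))
  expect_equal(unname(deg$ants), unname(apply(M > 0, 2, sum)))
  expect_equal(sum(deg$plants), sum(deg$ants))
  expect_equal(sum(deg$plants), sum(M > 0))
})

test_that("metrics are invariant to joint row/column permutation", {
  set.seed(99)
  for (rep in 1:5) {
    M <- random_count_matrix(5, 4, 40)
    P <- M[sample.int(5), sample.int(4)]
    expect_equal(h2prime(named_layer(P))$value, h2prime(named_layer(M))$value,
                 tolerance = 1e-10)
    expect_equal(wnodf(named_layer(P))$value, wnodf(named_layer(M))$value,
                 tolerance = 1e-10)
    expect_equal(horn_overlap(named_layer(P))$value,
                 horn_overlap(named_layer(M))$value, tolerance = 1e-10)
  }
})
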