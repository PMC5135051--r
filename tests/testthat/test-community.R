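test_that("site descriptors summarize the site-level layer", {
  d <- site_descriptors(toy_events(), "EFN", "S1")
  expect_equal(d$size, 2L)       # P1 and A1
  expect_equal(d$richness, 1L)
  expect_equal(d$frequency, 2L)
  expect_false(d$empty)

  d2 <- site_descriptors(toy_events(), "flower", "S1")
  expect_true(d2$empty)
  expect_equal(unlist(d2[c("size", "richness", "frequency")]),
               c(size = 0L, richness = 0L, frequency = 0L))
  expect_error(site_descriptors(toy_events(), "EFN", "S9"),
               class = "antnets_validation_error")

  # 2x2 layer [[2,0],[0,1]]: 4 species, 2 pairs, 3 events
  ev <- toy_events(); ev$site_id <- "S1"
  d3 <- site_descriptors(ev, "EFN", "S1")
  expect_equal(unlist(d3[c("size", "richness", "frequency")]),
               c(size = 4L, richness = 2L, frequency = 3L))
})

test_that("descriptor table agrees with generator bookkeeping", {
  g <- generate_events(generator_config(seed = 77))
  tab <- descriptor_table(g$events)
  expect_equal(sum(tab$frequency),
               sum(g$events$resource %in% c("EFN", "flower", "trophobiont")))
  one <- tab[tab$site_id == "S3" & tab$resource == "EFN", ]
  ev <- g$events[g$events$site_id == "S3" & g$events$resource == "EFN", ]
  if (nrow(ev) > 0) {
    expect_equal(one$frequency, nrow(ev))
    expect_equal(one$size,
                 length(unique(ev$plant_sp)) + length(unique(ev$ant_sp)))
    expect_equal(one$richness,
                 nrow(unique(ev[, c("plant_sp", "ant_sp")])))
  }
})

test_that("Poisson GLM deviance matches its closed form", {
  d <- data.frame(resource = rep(c("EFN", "flower"), each = 2),
                  size = c(10L, 12L, 20L, 22L))
  res <- poisson_glm_test(d, "size")
  y <- d$size
  mu1 <- rep(tapply(y, d$resource, mean), each = 2)
  mu0 <- rep(mean(y), 4)
  dev_direct <- 2 * sum(y * log(y / mu0)) - 2 * sum(y * log(y / mu1))
  expect_equal(res$deviance, dev_direct, tolerance = 1e-8)
  expect_equal(res$df, 1L)
  expect_equal(res$p_value, pchisq(dev_direct, 1, lower.tail = FALSE))
  # intercept-only fitted value is the grand mean under the log link
  expect_equal(unique(round(fitted(glm(size ~ 1, poisson(), d)), 8)),
               round(mean(y), 8))

  flat <- data.frame(resource = rep(c("EFN", "flower"), each = 2),
                     size = rep(6L, 4))
  res0 <- poisson_glm_test(flat, "size")
  expect_equal(res0$deviance, 0, tolerance = 1e-6)
  expect_equal(res0$p_value, 1, tolerance = 1e-6)

  bad <- d; bad$size <- bad$size + 0.5
  expect_error(poisson_glm_test(bad, "size"),
               class = "antnets_validation_error")
})

test_that("core extraction applies the strict above-average-degree rule", {
  # all species degree 1: nobody exceeds the mean
  ring <- named_layer(diag(2, 3, 3))
  cs <- extract_core(ring)
  expect_equal(length(cs$core_ants) + length(cs$core_plants), 0L)

  # star: the hub ant is the entire core
  star <- named_layer(matrix(1, 5, 1))
  cs <- extract_core(star)
  expect_equal(names(cs$core_ants), "A01")
  expect_equal(length(cs$core_plants), 0L)

  set.seed(10)
  M <- named_layer(random_count_matrix(8, 5, 40))
  cs <- extract_core(M)
  deg <- degree_centrality(M)
  thr <- mean(c(deg$plants, deg$ants))
  expect_setequal(names(cs$core_plants), names(deg$plants[deg$plants > thr]))
  expect_setequal(names(cs$core_ants), names(deg$ants[deg$ants > thr]))

  # idempotent under species relabeling
  M2 <- M
  rownames(M2) <- rev(rownames(M2))
  cs2 <- extract_core(named_layer(unclass_mat(M2)))
  expect_equal(length(cs2$core_plants), length(cs$core_plants))

  # per-guild thresholds
  csg <- extract_core(M, per_guild = TRUE)
  expect_setequal(names(csg$core_ants),
                  names(deg$ants[deg$ants > mean(deg$ants)]))
})

test_that("PERMANOVA partitioning matches vegan::adonis2", {
  set.seed(20)
  X <- matrix(rbinom(10 * 6, 1, 0.5), 10, 6)
  X[rowSums(X) == 0, 1] <- 1
  grp <- rep(c("a", "b"), each = 5)
  d <- vegan::vegdist(X, "jaccard", binary = TRUE)
  mine <- permanova(d, grp, n_perm = 999, seed = 3)
  ref <- vegan::adonis2(d ~ grp, data = data.frame(grp = grp),
                        permutations = 999)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)
  expect_lt(abs(mine$p_value - ref$`Pr(>F)`[1]), 0.08)
  expect_gte(mine$pseudo_F, 0)
  expect_true(mine$R2 >= 0 && mine$R2 <= 1)
})

test_that("Monte-Carlo PERMANOVA converges to the exhaustive p-value", {
  set.seed(9)
  X <- matrix(rnorm(4 * 3), 4, 3)
  grp <- c("a", "a", "b", "b")
  d <- dist(X)
  ex <- permanova(d, grp, permutations = all_permutations(4))
  mc <- permanova(d, grp, n_perm = 4999, seed = 5)
  expect_lt(abs(mc$p_value - ex$p_value), 0.05)
  # and at n = 5
  X5 <- matrix(rnorm(5 * 3), 5, 3)
  g5 <- c("a", "a", "b", "b", "b")
  ex5 <- permanova(dist(X5), g5, permutations = all_permutations(5))
  mc5 <- permanova(dist(X5), g5, n_perm = 4999, seed = 6)
  expect_lt(abs(mc5$p_value - ex5$p_value), 0.05)
})

test_that("core-composition PERMANOVA separates disjoint species pools", {
  make_core <- function(site, res, sp) {
    structure(list(core_ants = stats::setNames(rep(2L, length(sp)), sp),
                   core_plants = stats::setNames(integer(0), character(0)),
                   threshold = c(pooled = 1), resource = res,
                   sites = site, site_id = site), class = "core_set")
  }
  # same composition in both groups (site-level variation only): the
  # resource grouping explains nothing
  same <- c(lapply(1:3, function(s) make_core(paste0("S", s), "EFN",
                                              c("A1", paste0("X", s)))),
            lapply(1:3, function(s) make_core(paste0("S", s), "flower",
                                              c("A1", paste0("X", s)))))
  res_same <- core_similarity_permanova(same, "ants", n_perm = 199, seed = 2)
  expect_gt(res_same$p_value, 0.05)

  # disjoint pools: clear separation. With g sites per group the smallest
  # attainable free-permutation p is ~ 2 (g!)^2 / (2g)!: about 0.10 at
  # g = 3, so four sites per group are needed to reach the 5% level.
  disj <- c(lapply(1:4, function(s) make_core(paste0("S", s), "EFN",
                                              c("A1", "A2"))),
            lapply(1:4, function(s) make_core(paste0("S", s), "flower",
                                              c("A3", "A4"))))
  res_disj <- core_similarity_permanova(disj, "ants", n_perm = 999, seed = 2)
  expect_lte(res_disj$p_value, 0.05)

  # all-empty guild is a degenerate design
  expect_error(core_similarity_permanova(same, "plants"),
               class = "antnets_validation_error")
})

test_that("NMDS reaches near-zero stress on embeddable configurations", {
  x <- c(0, 1, 2, 3.5, 5)
  d <- dist(x)
  fit <- nmds(d, k = 1, n_starts = 10, seed = 3)
  expect_lt(fit$stress, 0.01)
  expect_equal(colMeans(fit$points), c(NMDS1 = 0), tolerance = 1e-8)

  set.seed(8)
  X <- matrix(rnorm(12 * 4), 12, 4)
  d <- dist(X)
  f1 <- nmds(d, k = 1, n_starts = 8, seed = 4)
  f2 <- nmds(d, k = 2, n_starts = 8, seed = 4, y0 = cbind(f1$points, 0))
  expect_lte(f2$stress, f1$stress + 1e-8)

  expect_error(nmds(dist(c(0, 0, 0)), k = 1),
               class = "antnets_degenerate_design")
  expect_error(nmds(dist(c(0, 1)), k = 1), class = "antnets_validation_error")
})

test_that("NMDS best-of-starts is self-consistent", {
  set.seed(15)
  X <- matrix(rnorm(4 * 2), 4, 2)
  d <- dist(X)
  few <- nmds(d, k = 2, n_starts = 5, seed = 1)
  many <- nmds(d, k = 2, n_starts = 100, seed = 2)
  expect_lt(abs(few$stress - many$stress), 0.02)
})
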