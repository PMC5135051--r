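test_that("event CSV parsing validates schema and vocabulary", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(toy_events(), path)
  ev <- read_events(path)
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$plant_sp, c("P1", "P1", "P2"))

  bad <- toy_events()
  bad$resource[2] <- "nectar"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, path2, row.names = FALSE)
  expect_error(read_events(path2), class = "antnets_schema_error")

  # empty file with header parses to zero events
  writeLines("site_id,plot_id,season,plant_sp,ant_sp,resource,workers", path2)
  expect_equal(nrow(read_events(path2)), 0L)

  expect_error(validate_events(toy_events()[, -3]),
               class = "antnets_schema_error")
  neg <- toy_events(); neg$workers[3] <- -1L
  err <- tryCatch(validate_events(neg), error = function(e) conditionMessage(e))
  expect_match(err, "row 3")
})

test_that("build_layer counts events and drops absent species", {
  L <- build_layer(toy_events(), "EFN")
  expect_equal(unclass(L)[, ], matrix(c(2L, 0L, 0L, 1L), 2, 2,
               dimnames = list(c("P1", "P2"), c("A1", "A2"))),
               ignore_attr = TRUE)
  expect_equal(rownames(L), c("P1", "P2"))
  expect_error(build_layer(toy_events(), "flower"),
               class = "antnets_empty_layer")
})

test_that("build_layer agrees with an exhaustive tally on random events", {
  set.seed(11)
  for (rep in 1:5) {
    ev <- data.frame(
      site_id = "S1", plot_id = "p1", season = "Jan",
      plant_sp = sample(paste0("P", 1:3), 10, replace = TRUE),
      ant_sp = sample(paste0("A", 1:3), 10, replace = TRUE),
      resource = "EFN", workers = 1L
    )
    L <- build_layer(ev, "EFN")
    for (i in rownames(L)) for (j in colnames(L)) {
      expect_equal(L[i, j], sum(ev$plant_sp == i & ev$ant_sp == j))
    }
    expect_equal(sum(L), 10L)
    expect_true(all(rowSums(L) > 0) && all(colSums(L) > 0))
    # determinism under event reordering
    L2 <- build_layer(ev[sample.int(10), ], "EFN")
    expect_identical(unclass_mat(L), unclass_mat(L2))
  }
})

test_that("multilayer pooling conserves events and is additive by layer", {
  ml <- build_multilayer(toy_events())
  expect_equal(sum(ml$pooled), 3L)

  ev <- toy_events()
  ev$resource <- c("EFN", "visit", "visit")
  ml <- build_multilayer(ev)
  expect_equal(sum(ml$pooled), nrow(ev))
  expect_equal(ml$pooled["P1", "A1"],
               ml$layers$EFN["P1", "A1"] + ml$layers$visit["P1", "A1"])
  expect_null(ml$layers$fruit)

  g <- generate_events(generator_config(seed = 303))
  ml <- build_multilayer(g$events)
  expect_equal(sum(ml$pooled), nrow(g$events))
  layer_total <- sum(vapply(ml$layers, function(L) {
    if (is.null(L)) 0L else sum(L)
  }, integer(1)))
  expect_equal(layer_total, sum(ml$pooled))
})

test_that("pajek export writes the bipartite structure and round-trips", {
  L <- build_layer(toy_events(), "EFN")
  path <- withr::local_tempfile(fileext = ".net")
  export_pajek(L, path)
  lines <- readLines(path)
  expect_equal(lines[1], "*Vertices 4 2")
  arcs <- lines[(which(lines == "*Edges") + 1):length(lines)]
  expect_equal(length(arcs), 2L)
  expect_setequal(arcs, c("1 3 2", "2 4 1"))
  back <- read_pajek(path, resource = "EFN")
  expect_identical(unclass_mat(back), unclass_mat(L))

  set.seed(21)
  M <- named_layer(random_count_matrix(5, 5, 30))
  export_pajek(M, path)
  lines <- readLines(path)
  n_arcs <- length(lines) - which(lines == "*Edges")
  expect_equal(n_arcs, sum(M > 0))
  expect_identical(unclass_mat(read_pajek(path)), unclass_mat(M))
})

test_that("TSV matrix output round-trips", {
  set.seed(4)
  M <- named_layer(random_count_matrix(4, 3, 17), resource = "flower")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_layer_tsv(M, path)
  back <- read_layer_tsv(path, resource = "flower")
  expect_identical(unclass_mat(back), unclass_mat(M))
})

test_that("degenerate layer construction is rejected", {
  expect_error(layer_matrix(matrix(0L, 2, 2,
    dimnames = list(c("P1", "P2"), c("A1", "A2")))),
    class = "antnets_validation_error")
  expect_error(build_layer(toy_events()[0, ], "EFN"),
               class = "antnets_empty_layer")
})
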