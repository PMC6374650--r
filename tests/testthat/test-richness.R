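test_that("build_grid covers the extent with ceiling division", {
  g <- build_grid(c(0, 100, 0, 100), 10)
  expect_equal(c(g$n_rows, g$n_cols), c(10L, 10L))
  g2 <- build_grid(c(0, 95, 0, 95), 10)
  expect_equal(c(g2$n_rows, g2$n_cols), c(10L, 10L))
  g3 <- build_grid(c(5, 5, 5, 5), 10)  # degenerate zero-span extent
  expect_equal(c(g3$n_rows, g3$n_cols), c(1L, 1L))
})

test_that("assign_point_to_cell uses half-open cells", {
  g <- build_grid(c(0, 100, 0, 100), 10)
  expect_equal(unlist(assign_point_to_cell(0, 0, g)),
               c(row = 1L, col = 1L))
  # interior boundary belongs to the higher-index cell
  expect_equal(unlist(assign_point_to_cell(10, 0, g)),
               c(row = 1L, col = 2L))
  expect_equal(unlist(assign_point_to_cell(0, 10, g)),
               c(row = 2L, col = 1L))
  # the outer upper/right boundary is outside
  expect_true(is.na(assign_point_to_cell(100, 50, g)$col))
  expect_true(is.na(assign_point_to_cell(50, -0.001, g)$row))
})

test_that("richness_grid counts distinct species, not records", {
  spec <- build_grid(c(0, 40, 0, 40), 10)
  one <- occurrence_dataset(
    data.frame(species_id = "a", x = 5, y = 5), "planar_km")
  rg <- richness_grid(one, spec)
  expect_equal(sum(rg$counts), 1L)
  expect_equal(rg$counts[1, 1], 1L)

  many <- occurrence_dataset(
    data.frame(species_id = "a", x = runif(10, 0, 10),
               y = runif(10, 0, 10)), "planar_km")
  expect_equal(max(richness_grid(many, spec)$counts), 1L)

  outside <- occurrence_dataset(
    data.frame(species_id = "a", x = 500, y = 500), "planar_km")
  expect_warning(rg0 <- richness_grid(outside, spec), "outside")
  expect_equal(sum(rg0$counts), 0L)

  # subset restriction
  ds3 <- occurrence_dataset(
    data.frame(species_id = c("a", "b", "c"), x = c(5, 5, 15),
               y = c(5, 5, 5)), "planar_km")
  rg3 <- richness_grid(ds3, spec, species_subset = c("a", "c"))
  expect_equal(rg3$counts[1, 1], 1L)
  expect_equal(rg3$counts[1, 2], 1L)
})

test_that("richness_grid matches the set-counting oracle", {
  set.seed(606)
  spec <- build_grid(c(0, 50, 0, 50), 10)
  for (rep in 1:40) {
    rec <- data.frame(
      species_id = sample(letters[1:5], 30, replace = TRUE),
      x = runif(30, -5, 55), y = runif(30, -5, 55))
    ds <- occurrence_dataset(rec, "planar_km")
    rg <- suppressWarnings(richness_grid(ds, spec))
    expect_identical(rg$counts, oracle_richness(rec, spec))
  }
})

test_that("top_fraction_cells ranks occupied cells with tie inclusion", {
  spec <- build_grid(c(0, 100, 0, 10), 10)
  mk <- function(vals) {
    structure(list(spec = spec,
                   counts = matrix(as.integer(vals), 1),
                   subset_label = "t", n_species = max(vals)),
              class = "richness_grid")
  }
  # 10 occupied cells with distinct values, q = 0.2 -> exactly top 2
  ts <- top_fraction_cells(mk(1:10), 0.2)
  expect_setequal(ts$cells$value, c(9L, 10L))
  # ties at the boundary are all included
  ts2 <- top_fraction_cells(mk(c(5, 5, 5, 1, 1, 0, 0, 0, 0, 0)), 0.2)
  expect_equal(sort(ts2$cells$value), c(5L, 5L, 5L))
  expect_equal(ts2$threshold_value, 5L)
  expect_error(top_fraction_cells(mk(rep(0, 10))), "no occupied")
})

test_that("top_fraction_cells matches the strict-rank oracle", {
  set.seed(707)
  for (rep in 1:40) {
    counts <- matrix(rpois(48, 2), 6, 8)
    grid <- structure(list(spec = build_grid(c(0, 80, 0, 60), 10),
                           counts = counts, subset_label = "r",
                           n_species = max(counts) + 1L),
                      class = "richness_grid")
    if (all(counts == 0)) next
    q <- runif(1, 0.1, 0.5)
    ts <- top_fraction_cells(grid, q)
    ora <- oracle_top_cells(counts, q)
    expect_setequal(paste(ts$cells$row, ts$cells$col),
                    paste(ora[, 1], ora[, 2]))
  }
})

test_that("congruence_map overlays member counts", {
  spec <- build_grid(c(0, 30, 0, 30), 10)
  mk_ts <- function(cells) {
    structure(list(spec = spec,
                   cells = data.frame(row = cells[, 1], col = cells[, 2],
                                      value = 1L),
                   q = 0.2, threshold_value = 1L, n_occupied = 9L,
                   subset_label = "x"),
              class = "top_cell_set")
  }
  disjoint <- lapply(1:8, function(i)
    mk_ts(cbind((i - 1) %/% 3 + 1, (i - 1) %% 3 + 1)))
  cg <- congruence_map(disjoint)
  expect_equal(sum(cg$levels == 1L), 8L)
  expect_equal(max(cg$levels), 1L)

  shared <- lapply(1:8, function(i) mk_ts(cbind(2, 2)))
  expect_equal(max(congruence_map(shared)$levels), 8L)

  # order invariance
  set.seed(1)
  sets <- lapply(1:5, function(i)
    mk_ts(cbind(sample(3, 2, TRUE), sample(3, 2, TRUE))))
  expect_equal(congruence_map(sets)$levels,
               congruence_map(rev(sets))$levels)

  other <- mk_ts(cbind(1, 1))
  other$spec <- build_grid(c(0, 30, 0, 30), 5)
  expect_error(congruence_map(list(disjoint[[1]], other)),
               "different grid")
})

test_that("congruence_map matches the per-cell membership oracle", {
  set.seed(808)
  spec <- build_grid(c(0, 50, 0, 50), 10)
  for (rep in 1:30) {
    sets <- lapply(seq_len(sample(2:8, 1)), function(i) {
      n <- sample(1:6, 1)
      structure(list(spec = spec,
                     cells = unique(data.frame(
                       row = sample(5, n, TRUE),
                       col = sample(5, n, TRUE), value = 1L)),
                     q = 0.2, threshold_value = 1L, n_occupied = 25L,
                     subset_label = "x"),
                class = "top_cell_set")
    })
    expect_identical(congruence_map(sets)$levels,
                     oracle_congruence(sets, 5L, 5L))
  }
})

test_that("congruence_area_summary: areas, percentages, cumulative rows", {
  spec <- build_grid(c(0, 30, 0, 30), 10)
  cg <- structure(list(spec = spec,
                       levels = matrix(c(1L, 1L, rep(0L, 7)), 3, 3),
                       n_groups = 8L),
                  class = "congruence_grid")
  s <- congruence_area_summary(cg, 100)
  expect_equal(s$area_km2[1], 200)
  expect_equal(s$percent[1], 100)
  expect_equal(attr(s, "total_area_km2"), 200)

  cg2 <- cg
  cg2$levels <- matrix(c(1L, 1L, 2L, 3L, rep(0L, 5)), 3, 3)
  s2 <- congruence_area_summary(cg2, 100)
  expect_equal(s2$n_cells, c(2L, 1L, 1L))
  expect_equal(s2$cum_n_cells, c(4L, 2L, 1L))
  expect_equal(s2$cum_area_km2[1], attr(s2, "total_area_km2"))
  expect_equal(sum(s2$percent), 100)

  cg0 <- cg
  cg0$levels[] <- 0L
  expect_error(congruence_area_summary(cg0, 100), "empty congruence")
})

test_that("aggregation monotonicity: coarse richness >= finest cell max", {
  set.seed(909)
  rec <- data.frame(
    species_id = sample(sprintf("s%02d", 1:20), 200, replace = TRUE),
    x = runif(200, 0, 100), y = runif(200, 0, 100))
  ds <- occurrence_dataset(rec, "planar_km")
  fine <- richness_grid(ds, build_grid(c(0, 100, 0, 100), 10))
  coarse <- richness_grid(ds, build_grid(c(0, 100, 0, 100), 50))
  for (R in 1:2) for (C in 1:2) {
    fr <- (R - 1) * 5 + 1:5
    fc <- (C - 1) * 5 + 1:5
    expect_gte(coarse$counts[R, C], max(fine$counts[fr, fc]))
  }
})
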