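test_that("default grid tiles 11 x 11 cells and excludes 15 around fixation", {
  grid <- build_ungrouped_grid()
  expect_equal(nrow(grid), 106)

  no_excl <- build_ungrouped_grid(grid_spec(exclusion_width = 0,
                                            exclusion_height = 0))
  expect_equal(nrow(no_excl), 121) # floor(6 / 0.54) = 11 per axis
  expect_equal(nrow(dplyr::distinct(no_excl)), 121)

  # no kept cell centre inside the exclusion rectangle
  expect_false(any(abs(grid$x) < 2.73 / 2 & abs(grid$y) < 1.64 / 2))
  # cell centres are at least one cell pitch apart
  d <- as.matrix(dist(grid))
  expect_gte(min(d[upper.tri(d)]), 0.54 - 1e-9)
})

test_that("invalid grid specs are rejected", {
  expect_error(grid_spec(exclusion_width = 7), "fit inside")
  expect_error(grid_spec(cell_size = 0), "positive")
})

test_that("configuration table matches the printed design", {
  cfg <- configuration_table()
  expect_equal(nrow(cfg), 36)
  expect_equal(sort(unique(cfg$numerosity)), 5:16)
  expect_true(all(table(cfg$numerosity) == 3))
  # each decomposition sums to its numerosity, 2-4 subgroups of 1-5 items
  for (i in seq_len(nrow(cfg))) {
    expect_equal(sum(cfg$sizes[[i]]), cfg$numerosity[i])
    expect_true(length(cfg$sizes[[i]]) %in% 2:4)
    expect_true(all(cfg$sizes[[i]] >= 1 & cfg$sizes[[i]] <= 5))
  }
  # spot-check printed entries and their order
  expect_equal(cfg$configuration[cfg$numerosity == 5][1], "2,2,1")
  expect_true("5,5,3" %in% cfg$configuration[cfg$numerosity == 13])
  expect_equal(cfg$configuration[cfg$numerosity == 16],
               c("4,4,4,4", "4,4,3,5", "5,5,4,2"))
})

test_that("ungrouped sampling is uniform over the grid and reproducible", {
  a <- sample_ungrouped(5, seed = 42)
  b <- sample_ungrouped(5, seed = 42)
  expect_identical(a$positions, b$positions)
  expect_equal(nrow(dplyr::distinct(a$positions)), 5)

  expect_error(sample_ungrouped(107), "exceeds the 106")

  grid <- build_ungrouped_grid()
  key <- paste(grid$x, grid$y)
  for (s in 1:100) {
    arr <- sample_ungrouped(16, seed = s)
    expect_true(all(paste(arr$positions$x, arr$positions$y) %in% key))
  }
  # different seeds give different arrays (with overwhelming probability)
  arrs <- vapply(1:100, function(s)
    paste(sample_ungrouped(8, seed = s)$positions$x, collapse = ","),
    character(1))
  expect_gt(length(unique(arrs)), 95)
})

test_that("grouped sampling honours quadrant structure", {
  slots <- quadrant_slots()
  # slot geometry: 12 per quadrant, inside the quadrant rectangle, clear of
  # the fixation exclusion zone
  expect_equal(nrow(slots), 48)
  e <- 3 / sqrt(2)
  expect_true(all(abs(abs(slots$x) - e) <= 1.64 / 2 + 1e-9))
  expect_true(all(abs(abs(slots$y) - e) <= 2.2 / 2 + 1e-9))
  expect_false(any(abs(slots$x) < 2.73 / 2 & abs(slots$y) < 1.64 / 2))

  a <- sample_grouped(c(3, 3), seed = 1)
  expect_equal(a$numerosity, 6L)
  expect_equal(length(unique(a$group)), 2)
  # find each item's quadrant from its position signs
  quad_of <- function(p) paste(sign(p$x), sign(p$y))
  expect_equal(length(unique(quad_of(a$positions))), 2)

  b <- sample_grouped(c(4, 4, 4, 4), seed = 2)
  expect_equal(length(unique(quad_of(b$positions))), 4)
  expect_equal(unname(table(b$group)), rep(4L, 4), ignore_attr = TRUE)

  expect_error(sample_grouped(c(1, 1, 1, 1, 1)), "at most 4")
  expect_error(sample_grouped(c(13, 2)), "exceeds the 12")
})

test_that("all printed configurations sample valid arrays across seeds", {
  cfg <- configuration_table()
  slots <- quadrant_slots()
  key <- paste(round(slots$x, 9), round(slots$y, 9))
  for (i in seq_len(nrow(cfg))) {
    for (s in c(1, 17)) {
      arr <- sample_grouped(cfg[i, ], seed = s * 1000 + i)
      expect_equal(arr$numerosity, cfg$numerosity[i])
      expect_equal(nrow(arr$positions), arr$numerosity)
      pk <- paste(round(arr$positions$x, 9), round(arr$positions$y, 9))
      expect_true(all(pk %in% key))
      expect_equal(anyDuplicated(pk), 0)
      # each subgroup sits wholly in one quadrant; subgroups in distinct ones
      qs <- paste(sign(arr$positions$x), sign(arr$positions$y))
      per_group <- tapply(qs, arr$group, function(v) length(unique(v)))
      expect_true(all(per_group == 1))
      expect_equal(length(unique(tapply(qs, arr$group, `[`, 1))),
                   length(unique(arr$group)))
    }
  }
})

test_that("stimulus arrays export to JSON and round-trip their fields", {
  path <- withr::local_tempfile(fileext = ".json")
  arrs <- list(sample_ungrouped(5, seed = 3), sample_grouped("3,3,2", seed = 4))
  export_stimuli(arrs, path)
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$numerosity, c(5, 8))
  expect_equal(rec$arrangement, c("ungrouped", "grouped"))
  expect_equal(unlist(rec$x[2]), arrs[[2]]$positions$x)
})
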