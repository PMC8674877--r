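# Bright-field cell segmentation and morphology filtering.

disc_image <- function(centres, radii_px, size = c(120L, 120L),
                       bg = 200, cell = 60) {
  px <- matrix(bg, size[1], size[2])
  rg <- matrix(seq_len(size[1]), size[1], size[2])
  cg <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  for (i in seq_len(nrow(centres))) {
    inside <- (rg - centres[i, 1])^2 + (cg - centres[i, 2])^2 <= radii_px[i]^2
    px[inside] <- cell
  }
  brightfield(px, 2.5)
}

test_that("well-separated discs are each recovered as one passing segment", {
  cen <- rbind(c(25, 25), c(25, 85), c(60, 55), c(95, 25), c(95, 85))
  bf <- disc_image(cen, rep(3, 5))  # 15 um diameter at 2.5 um/px
  seg <- segment_cells(bf)
  expect_equal(nrow(seg$table), 5L)
  expect_equal(sum(seg$table$pass), 5L)
  expect_equal(sort(table(seg$labels[seg$labels > 0])), sort(rep(29L, 5)),
               ignore_attr = TRUE)
  expect_equal(seg$table$eq_diameter_um, rep(equivalent_diameter(29, 2.5), 5),
               tolerance = 1e-8)
})

test_that("a blank image yields zero segments without error", {
  seg <- segment_cells(brightfield(matrix(200, 60, 60), 2.5))
  expect_equal(nrow(seg$table), 0L)
  expect_true(all(seg$labels == 0L))
})

test_that("diameter filters separate cells from debris with a reason", {
  bf <- disc_image(rbind(c(40, 40), c(90, 90)), c(3, 0.8))
  seg <- segment_cells(bf, min_diameter_um = 10)
  expect_equal(nrow(seg$table), 2L)
  expect_equal(sum(seg$table$pass), 1L)
  expect_equal(seg$table$fail_reason[!seg$table$pass], "too_small")
})

test_that("filter configuration is validated", {
  bf <- disc_image(rbind(c(40, 40)), 3)
  expect_error(segment_cells(bf, min_diameter_um = 30, max_diameter_um = 8),
               "min_diameter")
  expect_error(segment_cells(bf, min_circularity = 1.4), "\\[0, 1\\]")
})

test_that("segmentation count is exact over random non-overlapping placements", {
  for (seed in c(101, 202, 303, 404)) {
    n <- 15L
    sim <- simulate_image(image_sim_params(image_size_px = c(360L, 360L),
                                           n_cells = n, seed = seed))
    seg <- segment_cells(sim$brightfield)
    expect_equal(nrow(seg$table), n)
    expect_equal(sum(seg$table$pass), n)
  }
})

test_that("segments carry sane shape scores", {
  sim <- simulate_image(image_sim_params(n_cells = 10, seed = 31))
  seg <- segment_cells(sim$brightfield)
  expect_true(all(seg$table$circularity >= 0 & seg$table$circularity <= 1))
  expect_true(all(seg$table$convexity >= 0 & seg$table$convexity <= 1))
  expect_true(all(seg$table$convexity > 0.9))  # discs are convex
  # areas match the generator's painted discs
  expect_equal(sort(seg$table$area_px), sort(sim$truth$area_px))
})
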