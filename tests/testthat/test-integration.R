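# Segment transfer, intensity integration, image-side quantification and
# per-cell LOD.

dcal <- fit_droplet_calibration(c(0, 10, 20), c(0, 1000, 2000))  # 100 c/fg

test_that("uniform and zero channels integrate to n*v and 0", {
  sim <- simulate_image(image_sim_params(n_cells = 4, noise = FALSE, seed = 2))
  pm <- sim$pixel_map
  pm$channels$`195Pt`[] <- 7
  pm$channels$`23Na`[] <- 0
  seg <- segment_cells(sim$brightfield)
  seg <- transfer_and_integrate(seg, pm)
  expect_equal(seg$table$sum_195Pt, 7 * seg$table$map_area_px)
  expect_equal(seg$table$sum_23Na, rep(0, 4))
  expect_false(any(seg$table$edge_touching))
})

test_that("painted per-cell totals are recovered exactly under identity", {
  sim <- simulate_image(image_sim_params(n_cells = 6, noise = FALSE,
                                         seed = 13))
  seg <- segment_cells(sim$brightfield)
  seg <- transfer_and_integrate(seg, sim$pixel_map)
  # match segments to truth by centroid
  ord <- vapply(seq_len(6), function(i)
    which.min((seg$table$row - sim$truth$row[i])^2 +
              (seg$table$col - sim$truth$col[i])^2), integer(1))
  painted <- sim$truth$mass_fg * 400  # generator slope: 400 counts per fg
  expect_equal(seg$table$sum_195Pt[ord], painted, tolerance = 1e-9)
  masses <- cell_mass_from_image(seg$table$sum_195Pt[ord],
                                 list(slope = 400))
  expect_equal(masses, sim$truth$mass_fg, tolerance = 1e-9)
})

test_that("segments reaching beyond the map are clipped and flagged", {
  sim <- simulate_image(image_sim_params(n_cells = 5, noise = FALSE, seed = 3))
  seg <- segment_cells(sim$brightfield)
  crop <- sim$pixel_map
  crop$channels <- lapply(crop$channels, function(m) m[1:150, 1:150])
  seg <- transfer_and_integrate(seg, crop)
  out_of_frame <- seg$table$row > 150 | seg$table$col > 150
  expect_true(all(seg$table$edge_touching[out_of_frame] |
                  seg$table$map_area_px[out_of_frame] == 0))
})

test_that("image-side mass conversion is linear with a floor at zero", {
  expect_equal(cell_mass_from_image(0, dcal), 0)
  expect_equal(cell_mass_from_image(500, dcal), 5)
  expect_equal(cell_mass_from_image(1000, dcal), 10)
  expect_equal(cell_mass_from_image(-50, dcal), 0)
  expect_error(cell_mass_from_image(1, list(slope = 0)), "slope")
})

test_that("per-cell LOD scales with background sigma and cell footprint", {
  expect_equal(la_lod(rep(3, 100), dcal, 30), 0)          # sigma = 0
  bg <- rep(c(0, 4), 50)                                  # sd = 2.01 approx
  ref <- 3 * sd(bg) / 100 * 30
  expect_equal(la_lod(bg, dcal, 30), ref)
  expect_equal(la_lod(bg, dcal, 60), 2 * ref)             # doubling pixels/cell
  # droplet spread over 100 px halves per-pixel sensitivity vs 50 px
  expect_equal(la_lod(bg, dcal, 30, droplet_pixels = 100),
               2 * la_lod(bg, dcal, 30, droplet_pixels = 50))
  expect_error(la_lod(numeric(0), dcal, 30), "empty")
  expect_error(la_lod(bg, dcal, 0.5), ">= 1")
})

test_that("quantify_cells requires integrated sums and adds mass columns", {
  sim <- simulate_image(image_sim_params(n_cells = 3, noise = FALSE, seed = 8))
  seg <- segment_cells(sim$brightfield)
  expect_error(quantify_cells(seg, dcal, "195Pt"), "transfer_and_integrate")
  seg <- transfer_and_integrate(seg, sim$pixel_map)
  seg <- quantify_cells(seg, dcal, "195Pt")
  expect_true("mass_195Pt_fg" %in% names(seg$table))
  expect_true(all(seg$table$mass_195Pt_fg >= 0))
})
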