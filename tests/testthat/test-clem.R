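test_that("co-localization counts follow the fraction-of-object rule", {
  f <- generate_label_field(20, 0, seed = 1)
  cl <- colocalize(f)
  expect_equal(cl$n_positive, 0)
  expect_equal(cl$percent_positive, 0)
  # probe covering everything: 100%
  f$probe[] <- TRUE
  cl <- colocalize(f)
  expect_equal(cl$n_positive, 20)
  expect_equal(cl$percent_positive, 100)
  # threshold is a fraction of the object's own pixels
  f2 <- generate_label_field(2, 1, seed = 2)
  cl2 <- colocalize(f2, min_overlap_fraction = 0.25)
  expect_equal(cl2$objects$overlap_frac[cl2$objects$positive], 1)
  # shape mismatch is an input error
  expect_error(label_field(f$nuclei, f$host, f$probe[1:5, 1:5, drop = FALSE],
                           f$protein, 0.1), "shape")
})

test_that("the generator-quantifier closed loop recovers pooled counts", {
  # the printed pooled counts: 792 of 2,697 DAPI objects probe-positive,
  # 154 host cells
  f <- generate_label_field(2697, 792, n_host_cells = 154, seed = 3)
  cl <- colocalize(f)
  expect_equal(cl$n_nuclei, 2697)
  expect_equal(cl$n_positive, 792)
  expect_equal(round(cl$percent_positive, 1), 29.4)   # pooled percentage
  dr <- density_and_ratio(f, cl)
  expect_equal(dr$n_host_cells, 154)
  expect_equal(round(dr$cells_per_host, 2), 5.14)     # 792 / 154
  expect_false(dr$undefined)
})

test_that("positivity is invariant under label permutation and translation", {
  f <- generate_label_field(30, 12, seed = 4)
  base <- colocalize(f)$percent_positive
  # permute labels
  perm <- sample(30)
  f2 <- f
  f2$nuclei[f$nuclei > 0] <- perm[f$nuclei[f$nuclei > 0]]
  expect_equal(colocalize(f2)$percent_positive, base)
  # translate the whole field
  f3 <- f
  pad <- matrix(0L, 7, ncol(f$nuclei))
  f3$nuclei <- rbind(pad, f$nuclei[1:(nrow(f$nuclei) - 7), ])
  padl <- matrix(FALSE, 7, ncol(f$nuclei))
  f3$probe <- rbind(padl, f$probe[1:(nrow(f$probe) - 7), ])
  f3$protein <- rbind(padl, f$protein[1:(nrow(f$protein) - 7), ])
  f3$host <- rbind(pad, f$host[1:(nrow(f$host) - 7), ])
  expect_equal(colocalize(f3)$percent_positive, base)
})

test_that("protein positivity uses probe-positive objects as denominator", {
  f <- generate_label_field(60, 40, n_protein_positive = 37, seed = 5)
  cl <- colocalize(f)
  pp <- protein_positivity(f, cl)
  expect_equal(pp$n_positive, 40)
  expect_equal(pp$n_protein, 37)
  expect_equal(pp$percent, 92.5)                      # 37/40
  f2 <- generate_label_field(15, 10, n_protein_positive = 10, seed = 6)
  pp2 <- protein_positivity(f2, colocalize(f2))
  expect_equal(pp2$percent, 100)                      # 10/10
  f3 <- generate_label_field(15, 10, n_protein_positive = 0, seed = 7)
  pp3 <- protein_positivity(f3, colocalize(f3))
  expect_equal(pp3$percent, 0)
  # no probe-positive objects: undefined, flagged
  f4 <- generate_label_field(5, 0, seed = 8)
  pp4 <- protein_positivity(f4, colocalize(f4))
  expect_true(pp4$undefined)
})

test_that("density is positives per field area", {
  f <- generate_label_field(150, 100, seed = 9)
  f$field_area <- 0.01                                # mm^2, set directly
  dr <- density_and_ratio(f, colocalize(f))
  expect_equal(dr$density_per_mm2, 1e4)
  expect_true(dr$undefined)                           # no host cells
  f$field_area <- 0
  expect_error(density_and_ratio(f, colocalize(f)), "positive")
})

test_that("field summaries use per-area means and n-1 standard deviation", {
  rows <- tibble::tibble(field = c("a", "b", "c", "d"),
                         percent = c(20, 21, 22, 25))
  s <- summarize_fields(rows)
  expect_equal(s$mean[s$column == "percent"], 22)
  expect_equal(s$sd[s$column == "percent"], sd(c(20, 21, 22, 25)))
  expect_equal(round(s$sd[s$column == "percent"], 3), 2.160)
  # one field: sd undefined (NA)
  expect_true(is.na(summarize_fields(rows[1, ])$sd))
  # identical fields: sd 0
  expect_equal(summarize_fields(rows[c(1, 1, 1), ])$sd[1], 0)
})

test_that("digitised spheres reproduce analytic volume and diameter", {
  sp <- voxel_sphere(0.084, 0.010)                    # 10 nm voxels
  m <- granule_morphometry(sp)
  v_true <- 4 / 3 * pi * 0.084^3
  expect_lt(abs(m$granules$volume_um3 - v_true) / v_true, 0.03)
  expect_lt(abs(m$granules$eq_diameter_nm - 168) / 168, 0.03)
  # error shrinks monotonically with voxel size
  errs <- vapply(c(0.02, 0.01, 0.005), function(vx) {
    mm <- granule_morphometry(voxel_sphere(0.084, vx))
    abs(mm$granules$volume_um3 - v_true) / v_true
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("granule morphometry flags degenerate cases and bipolarity", {
  # no granules: volume fraction 0, polarity undefined
  m0 <- granule_morphometry(voxel_model(array(TRUE, c(5, 5, 5)),
                                        array(0L, c(5, 5, 5))))
  expect_equal(m0$volume_fraction, 0)
  expect_true(m0$polarity_undefined)
  # granule voxels outside the cell are an input error
  g <- array(0L, c(5, 5, 5)); g[1, 1, 1] <- 1L
  cell <- array(TRUE, c(5, 5, 5)); cell[1, 1, 1] <- FALSE
  expect_error(voxel_model(cell, g), "outside")
  # two granules planted at opposite poles: polarity score 1
  vc <- generate_voxel_cell(seed = 10)
  m <- granule_morphometry(vc)
  expect_equal(m$n_granules, 2)
  expect_equal(m$polarity_score, 1)
  expect_gt(m$volume_fraction, 0)
  expect_lt(m$volume_fraction, 1)
  # same-pole granules: polarity 0
  vc2 <- generate_voxel_cell(granule_positions = c(0.5, 0.8), seed = 11)
  expect_equal(granule_morphometry(vc2)$polarity_score, 0)
})

test_that("anisotropic voxels weigh volume by the voxel-size product", {
  # one granule voxel of 10 x 10 x 100 nm
  cell <- array(TRUE, c(4, 4, 4))
  g <- array(0L, c(4, 4, 4)); g[2, 2, 2] <- 1L
  m <- granule_morphometry(voxel_model(cell, g,
                                       voxel_size = c(0.01, 0.01, 0.1)))
  expect_equal(m$granules$volume_um3, 0.01 * 0.01 * 0.1)
  expect_equal(m$cell_volume_um3, 64 * 1e-5)
})

test_that("generators are reproducible and arrays round-trip as plain text", {
  f1 <- generate_label_field(25, 10, n_host_cells = 3, seed = 12)
  f2 <- generate_label_field(25, 10, n_host_cells = 3, seed = 12)
  expect_identical(f1$nuclei, f2$nuclei)
  expect_identical(f1$probe, f2$probe)
  # zero objects: empty label image
  f0 <- generate_label_field(0, 0, seed = 13)
  expect_equal(max(f0$nuclei), 0)
  # capacity error when objects cannot fit
  expect_error(generate_voxel_cell(granule_radius_um = 2,
                                   semi_axes_um = c(0.2, 0.2, 0.2)),
               "outside|capacity")
  d <- withr::local_tempdir()
  p <- write_array(f1$nuclei, file.path(d, "nuclei.txt"))
  back <- read_array(p)
  expect_equal(back, unclass(f1$nuclei), ignore_attr = FALSE)
  vc <- generate_voxel_cell(seed = 14)
  p2 <- write_array(vc$granules, file.path(d, "gran.txt"))
  expect_equal(read_array(p2), vc$granules)
})
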