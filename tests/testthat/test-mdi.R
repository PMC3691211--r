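test_that("radial lines are generated at the configured angular interval", {
  geo <- centered_circle(200, 80)
  expect_equal(nrow(radial_lines(geo, mdi_config(angle_interval_deg = 3))), 120)
  expect_equal(nrow(radial_lines(geo, mdi_config(angle_interval_deg = 90))), 4)
  expect_equal(nrow(radial_lines(geo, mdi_config(angle_interval_deg = 7))),
               floor(360 / 7))
})

test_that("radial lines end at the first boundary crossing with correct length", {
  # circle: every line length equals the radius (within half a pixel for the
  # polygon approximation)
  geo <- centered_circle(200, 80, n_vertices = 180L)
  ln <- radial_lines(geo, mdi_config())
  expect_true(all(abs(ln$length_px - 80) < 0.5))

  # square boundary centred on the center: 4 lines at 90 degrees, equal length
  ctr <- c(50, 50)
  sq <- cell_geometry(ctr, rbind(c(20, 20), c(80, 20), c(80, 80), c(20, 80)))
  ln4 <- radial_lines(sq, mdi_config(angle_interval_deg = 90))
  expect_equal(nrow(ln4), 4)
  expect_equal(ln4$length_px, rep(30, 4))

  # concave polygon: the ray must stop at the first crossing, not a later one
  poly <- rbind(c(10, 10), c(90, 10), c(90, 40), c(40, 40), c(40, 60),
                c(90, 60), c(90, 90), c(10, 90))
  geo_c <- cell_geometry(c(20, 50), poly)
  ln_c <- radial_lines(geo_c, mdi_config(angle_interval_deg = 360))
  expect_equal(ln_c$x1, 40) # hits the notch edge, not x = 90
})

test_that("center outside the polygon is rejected", {
  expect_error(cell_geometry(c(200, 200),
                             rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))),
               "outside")
})

test_that("uniform images give R = 1 on every line and MDI = 1", {
  img <- cell_image(matrix(7.3, 200, 200), 0.1)
  geo <- centered_circle(200, 80)
  res <- compute_mdi(img, geo)
  expect_equal(res$mdi, 1, tolerance = 1e-6)
  expect_true(all(abs(res$per_line_R - 1) < 1e-6))
  expect_equal(res$n_lines, 120)
  # max aggregation behaves identically on a uniform image
  res_max <- compute_mdi(img, geo, mdi_config(aggregate = "max"))
  expect_equal(res_max$mdi, 1, tolerance = 1e-6)
})

test_that("intensity concentrated in the inner window gives MDI = 0", {
  side <- 200
  geo <- centered_circle(side, 80)
  # bright disc of radius 6 px << inner 10% of the ~80 px lines
  img <- radial_image(side, geo$center_px, function(d) ifelse(d <= 6, 100, 0))
  res <- compute_mdi(img, geo)
  expect_equal(res$mdi, 0)
  expect_true(all(res$per_line_R == 0))
})

test_that("MDI is invariant to intensity scaling", {
  spec <- image_spec(160, 160, psf_sigma_px = 1.5, seed = 42)
  img <- make_filament_image(spec, 25, c(2, 5))$image
  geo <- centered_circle(160, 75)
  m1 <- compute_mdi(img, geo)$mdi
  img$pixels <- img$pixels * 37.5
  m2 <- compute_mdi(img, geo)$mdi
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("line ratios agree with dense numeric integration on an analytic profile", {
  side <- 257
  lambda <- 30
  ctr <- c((side - 1) / 2, (side - 1) / 2)
  img <- radial_image(side, ctr, function(d) exp(-d / lambda))
  geo <- centered_circle(side, 100, n_vertices = 720L)
  cfg <- mdi_config()
  ln <- radial_lines(geo, cfg)
  # dense trapezoid sampling of the analytic profile along the ray
  oracle_R <- function(L) {
    s <- seq(0, L, length.out = 10001)
    v <- exp(-s / lambda)
    mean(v[s <= cfg$inner_fraction * L]) -> ii
    mean(v[s >= (1 - cfg$outer_fraction) * L]) -> oo
    oo / ii
  }
  for (i in c(1, 17, 45, 80, 111)) {
    R_pkg <- line_ratio(img, ln[i, ], cfg)
    expect_equal(R_pkg, oracle_R(ln$length_px[i]), tolerance = 0.01)
  }
  # and the full-cell average stays within 1% as well
  R_o <- mean(vapply(ln$length_px, oracle_R, numeric(1)))
  expect_equal(compute_mdi(img, geo, cfg)$mdi, R_o, tolerance = 0.01)
})

test_that("MDI is invariant under a joint 90-degree rotation of image and geometry", {
  side <- 160
  spec <- image_spec(side, side, psf_sigma_px = 1.5, seed = 11)
  img <- make_filament_image(spec, 20, c(2, 5))$image
  ctr <- c(70, 85) # deliberately off-center
  geo <- cell_geometry(ctr, rbind(c(20, 25), c(140, 15), c(150, 130), c(30, 145)))
  m1 <- compute_mdi(img, geo)$mdi

  # rotate 90 degrees counterclockwise about the pixel grid:
  # (x, y) -> (y, side - 1 - x); matrix: new = t(m)[side:1, ]
  rot_pt <- function(p) c(p[2], side - 1 - p[1])
  img_r <- cell_image(t(img$pixels)[side:1, ], img$pixel_size_um)
  geo_r <- cell_geometry(rot_pt(ctr), t(apply(geo$boundary_px, 1, rot_pt)))
  m2 <- compute_mdi(img_r, geo_r)$mdi
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("moving intensity from the outer band to the center decreases MDI", {
  side <- 200
  geo <- centered_circle(side, 80)
  base <- radial_image(side, geo$center_px, function(d) rep(10, length(d)))
  m_base <- compute_mdi(base, geo)$mdi
  # transport mass: +5 inside radius 7, -5 in the outer annulus (d in 55..80)
  moved <- radial_image(side, geo$center_px, function(d) {
    10 + 5 * (d <= 7) - 5 * (d >= 55 & d <= 80)
  })
  m_moved <- compute_mdi(moved, geo)$mdi
  expect_lt(m_moved, m_base)
})

test_that("the MDI lies between the per-line extremes", {
  spec <- image_spec(160, 160, psf_sigma_px = 1.5, seed = 99)
  img <- make_filament_image(spec, 30, c(2, 5))$image
  res <- compute_mdi(img, centered_circle(160, 70))
  R <- res$per_line_R[!is.na(res$per_line_R)]
  expect_gte(res$mdi, min(R))
  expect_lte(res$mdi, max(R))
})

test_that("aster images score lower MDI than dispersed images of equal total length", {
  for (seed in c(3, 8)) {
    spec <- image_spec(192, 192, psf_sigma_px = 1.5, seed = seed)
    a <- make_filament_image(spec, 40, c(2, 6), layout = "aster")
    d <- make_filament_image(spec, 40, c(2, 6), layout = "dispersed")
    geo <- centered_circle(192, 90)
    expect_lt(compute_mdi(a$image, geo)$mdi, compute_mdi(d$image, geo)$mdi)
  }
})

test_that("degenerate MDI inputs raise errors", {
  img <- cell_image(matrix(0, 100, 100), 0.1)
  geo <- centered_circle(100, 40)
  expect_error(compute_mdi(img, geo), "MDI undefined")
  seg <- data.frame(x0 = 5, y0 = 5, x1 = 5, y1 = 5)
  expect_error(line_ratio(cell_image(matrix(1, 10, 10), 0.1), seg),
               "zero-length")
  expect_error(mdi_config(inner_fraction = 0.7, outer_fraction = 0.4))
})
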