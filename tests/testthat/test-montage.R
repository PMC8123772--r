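test_that("packaged montage has the 32-channel set with a Cz vertex", {
  m <- fixture_montage
  expected <- c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5",
                "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4",
                "Fz", "F4", "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6",
                "CP2", "P4", "P8", "PO4", "O2")
  expect_setequal(m$label, expected)
  expect_equal(nrow(m), 32)
  expect_false(anyDuplicated(m$label) > 0)
  expect_equal(m$elevation_deg[m$label == "Cz"], 90)
  expect_true(all(m$elevation_deg >= -90 & m$elevation_deg <= 90))
  expect_true(all(m$azimuth_deg > -180 & m$azimuth_deg <= 180))
})

test_that("left/right homologues have mirrored azimuths", {
  m <- fixture_montage
  az <- setNames(m$azimuth_deg, m$label)
  el <- setNames(m$elevation_deg, m$label)
  pairs <- c(Fp1 = "Fp2", AF3 = "AF4", F3 = "F4", F7 = "F8", FC5 = "FC6",
             FC1 = "FC2", C3 = "C4", T7 = "T8", CP5 = "CP6", CP1 = "CP2",
             P3 = "P4", P7 = "P8", PO3 = "PO4", O1 = "O2")
  for (l in names(pairs)) {
    expect_equal(az[[l]], -az[[pairs[l]]])
    expect_equal(el[[l]], el[[pairs[l]]])
  }
})

test_that("projection preserves vertex distance and direction", {
  m <- fixture_montage
  p <- aep_project(m)
  # pole maps to origin
  expect_equal(unlist(p[p$label == "Cz", c("x", "y")]),
               c(x = 0, y = 0), tolerance = 1e-12)
  rho <- sqrt(p$x^2 + p$y^2)
  # equal elevations give equal planar radii
  ring <- m$elevation_deg == 18
  expect_lt(diff(range(rho[ring])), 1e-12)

  # planar radius equals the great-circle arc from Cz, computed
  # independently from Cartesian coordinates
  d2r <- pi / 180
  xyz <- cbind(cos(m$elevation_deg * d2r) * cos(m$azimuth_deg * d2r),
               cos(m$elevation_deg * d2r) * sin(m$azimuth_deg * d2r),
               sin(m$elevation_deg * d2r))
  cz <- xyz[m$label == "Cz", ]
  arc <- acos(pmin(pmax(xyz %*% cz, -1), 1))
  expect_equal(rho, as.vector(arc), tolerance = 1e-9)
  # rank order of vertex distances is preserved (ties averaged)
  expect_equal(rank(round(rho, 9), ties.method = "average"),
               rank(round(arc, 9), ties.method = "average"))
})

test_that("an equatorial electrode projects to radius pi/2", {
  m <- tibble::tibble(label = c("Cz", "EQ1", "EQ2"),
                      azimuth_deg = c(0, 0, 90),
                      elevation_deg = c(90, 0, 0))
  attr(m, "vertex") <- "Cz"
  p <- aep_project(m)
  expect_equal(sqrt(p$x^2 + p$y^2)[2:3], c(pi / 2, pi / 2))
})

test_that("projection is injective on the montage", {
  p <- aep_project(fixture_montage)
  d <- as.matrix(dist(cbind(p$x, p$y)))
  diag(d) <- Inf
  expect_gt(min(d), 1e-9)
})

test_that("montage reader rejects malformed tables", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,azimuth_deg,elevation_deg",
               "Cz,0,80", "F3,30,40", "F4,-30,40"), tmp)
  expect_error(read_montage(tmp), "elevation 90")
  writeLines(c("label,azimuth_deg", "Cz,0"), tmp)
  expect_error(read_montage(tmp), "lacks column")
})

test_that("default layout satisfies every invariant", {
  rep <- validate_layout(default_dmd_layout())
  expect_true(all(rep$pass))
  g <- default_dmd_layout()$grid
  expect_equal(length(g), 36)
  expect_equal(which(g == "Fz"), which(g %in% "Fz"))
  pos <- which(g == "Fz", arr.ind = TRUE)
  expect_equal(sort(pos[, "col"]), c(2, 3))
  expect_equal(unique(pos[, "row"]), 3)
})

test_that("layout validation reports specific failures without raising", {
  bad <- default_dmd_layout()
  bad$grid[3, 3] <- "AF3"   # Fz now once, AF3 twice
  rep <- validate_layout(bad)
  expect_false(rep$pass[rep$check == "midline_duplicated_centrally"])
  expect_false(rep$pass[rep$check == "other_channels_once"])

  unk <- default_dmd_layout()
  unk$grid[1, 1] <- "XX"
  rep2 <- validate_layout(unk)
  expect_false(rep2$pass[rep2$check == "labels_known"])
  expect_match(rep2$detail[rep2$check == "labels_known"], "XX")
})

test_that("layout files round-trip through the reader", {
  lay <- read_dmd_layout(system.file("extdata", "dmd_layout_default.txt",
                                     package = "topospectra"))
  expect_identical(lay$grid, default_dmd_layout()$grid)
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a b c", "d e f"), tmp)
  expect_error(read_dmd_layout(tmp), "9 non-empty lines")
})
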