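fixture_proj <- aep_project(fixture_montage)

test_that("DMD cells tile 227 px and carry their channel's value", {
  vals <- named_values(1)
  m <- render_dmd(vals)
  expect_equal(dim(m$values), c(227, 227))

  re <- diff(round((0:9) * 227 / 9))
  ce <- diff(round((0:4) * 227 / 4))
  expect_equal(sum(re), 227)
  expect_equal(sum(ce), 227)
  expect_true(all(re %in% c(25, 26)))
  expect_true(all(ce %in% c(56, 57)))

  # the hottest channel's cells are exactly the image maximum
  hot <- names(which.max(vals))
  lay <- default_dmd_layout()
  rr <- cumsum(c(0, re)); cc <- cumsum(c(0, ce))
  for (r in 1:9) for (k in 1:4) {
    cell <- m$values[(rr[r] + 1):rr[r + 1], (cc[k] + 1):cc[k + 1]]
    expect_true(all(cell == vals[[lay$grid[r, k]]]))
  }
  expect_equal(max(m$values), vals[[hot]])

  strict <- render_dmd(vals, strict = TRUE)
  # first 8 row bands are exactly 25 px tall
  for (r in 1:8) {
    expect_equal(length(unique
                        (strict$values[((r - 1) * 25 + 1):(r * 25), 1])), 1)
  }
  expect_error(render_dmd(vals[1:10]), "missing channel")
})

test_that("DMDi interpolates through cell centers", {
  vals <- named_values(2)
  m <- render_dmdi(vals)
  centers <- topospectra:::dmd_cell_centers(default_dmd_layout())
  at_nodes <- m$values[cbind(centers$row, centers$col)]
  expect_lt(max(abs(at_nodes - vals[centers$label])), 1e-6)

  const <- setNames(rep(2.5, 32), names(vals))
  expect_lt(max(abs(render_dmdi(const)$values - 2.5)), 1e-9)

  # a single hot channel peaks inside its own cell neighborhood
  hotv <- setNames(rep(0, 32), names(vals))
  hotv["F3"] <- 1
  hm <- render_dmdi(hotv)$values
  peak <- which(hm == max(hm), arr.ind = TRUE)[1, ]
  f3 <- centers[centers$label == "F3", ]
  expect_lt(abs(peak["row"] - f3$row), 14)
  expect_lt(abs(peak["col"] - f3$col), 29)
})

test_that("AEP maps the vertex to the image center and mirrors", {
  vals <- named_values(3)
  px <- topospectra:::aep_pixels(fixture_proj)
  expect_equal(unlist(px[px$label == "Cz", c("row", "col")]),
               c(row = 114, col = 114))

  m <- render_aep(vals, fixture_proj)
  at_nodes <- m$values[cbind(px$row, px$col)]
  expect_lt(max(abs(at_nodes - vals[px$label])), 1e-6)

  const <- setNames(rep(-1.5, 32), names(vals))
  cm <- render_aep(const, fixture_proj)
  expect_lt(max(abs(cm$values[cm$mask] + 1.5)), 1e-9)

  # swapping left/right homologue values mirrors the image columns
  pairs <- c(Fp1 = "Fp2", AF3 = "AF4", F3 = "F4", F7 = "F8", FC5 = "FC6",
             FC1 = "FC2", C3 = "C4", T7 = "T8", CP5 = "CP6", CP1 = "CP2",
             P3 = "P4", P7 = "P8", PO3 = "PO4", O1 = "O2")
  sw <- vals
  for (l in names(pairs)) {
    sw[l] <- vals[pairs[l]]
    sw[pairs[l]] <- vals[l]
  }
  m2 <- render_aep(sw, fixture_proj)
  expect_lt(max(abs(m2$values - m$values[, 227:1])), 1e-6)

  # masked pixels carry the in-disc minimum
  expect_equal(unique(m$values[!m$mask]), min(m$values[m$mask]))
})

test_that("jet palette endpoints and midpoint follow the formula", {
  pal <- jet_palette()
  expect_equal(unname(pal[1, ]), c(0, 0, 128))     # dark blue at minimum
  expect_equal(unname(pal[256, ]), c(128, 0, 0))   # dark red at maximum
  mid <- pal[129, ]
  expect_equal(unname(mid["g"]), 255)
  expect_true(all(pal >= 0 & pal <= 255))

  vals <- named_values(4)
  img <- jet_quantize(render_dmd(vals))
  lo <- which(render_dmd(vals)$values == min(vals), arr.ind = TRUE)[1, ]
  hi <- which(render_dmd(vals)$values == max(vals), arr.ind = TRUE)[1, ]
  expect_equal(as.integer(img[lo[1], lo[2], ]), c(0, 0, 128))
  expect_equal(as.integer(img[hi[1], hi[2], ]), c(128, 0, 0))
  expect_warning(jet_quantize(render_dmd(setNames(rep(1, 32),
                                                  names(vals)))),
                 "constant")
})

test_that("rendered RGB is invariant under positive affine rescaling", {
  vals <- named_values(5)
  for (scheme in c("dmd", "dmdi", "aep")) {
    a <- topospectra:::render_map(vals, scheme, "pt",
                                  default_dmd_layout(), fixture_proj)
    b <- topospectra:::render_map(3.2 * vals + 17, scheme, "pt",
                                  default_dmd_layout(), fixture_proj)
    expect_identical(jet_quantize(a), jet_quantize(b))
  }
})

test_that("cubes stack the five bands in canonical order", {
  vals <- named_values(6)
  maps <- lapply(c("pt", "theta", "alpha", "beta", "gamma"),
                 function(b) render_dmd(vals * (1 + match(b, c(
                   "pt", "theta", "alpha", "beta", "gamma"))), band = b))
  cube <- stack_cube(rev(maps))   # order-insensitive input
  expect_equal(dim(cube$values), c(227, 227, 5))
  expect_equal(cube$bands, c("pt", "theta", "alpha", "beta", "gamma"))
  # slice 1 is the normalized pt map
  pt <- maps[[1]]$values
  expect_equal(cube$values[, , 1],
               (pt - min(pt)) / (max(pt) - min(pt)), tolerance = 1e-12)
  expect_true(all(cube$values >= 0 & cube$values <= 1))

  expect_error(stack_cube(maps[1:4]), "five maps")
  expect_error(stack_cube(c(maps[1:4], maps[1])), "duplicate")
  bad <- maps
  bad[[2]] <- render_aep(vals, fixture_proj, band = "theta")
  expect_error(stack_cube(bad), "one scheme")
})

test_that("image batches preserve counts and are byte-deterministic", {
  set.seed(10)
  bp <- purrr::map_dfr(1:2, function(tid) {
    purrr::map_dfr(1:6, function(ei) {
      dplyr::bind_cols(
        tibble::tibble(trial_id = tid, epoch_idx = ei,
                       class = ifelse(tid == 1, "calm", "distress")),
        tibble::tibble(label = fixture_montage$label, pt = runif(32),
                       theta = runif(32), alpha = runif(32),
                       beta = runif(32), gamma = runif(32)))
    })
  })
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  b1 <- image_batch(bp, scheme = "dmd", band = "pt", out_dir = dir1)
  b2 <- image_batch(bp, scheme = "dmd", band = "pt", out_dir = dir2)
  expect_equal(nrow(b1$manifest), 12)
  expect_length(b1$images, 12)
  f1 <- sort(list.files(dir1, pattern = "png$", full.names = TRUE))
  f2 <- sort(list.files(dir2, pattern = "png$", full.names = TRUE))
  expect_identical(lapply(f1, readBin, what = "raw", n = 1e6),
                   lapply(f2, readBin, what = "raw", n = 1e6))

  cubes <- image_batch(bp[bp$trial_id == 1, ], scheme = "dmd",
                       band = "cube")
  expect_length(cubes$images, 6)
  expect_s3_class(cubes$images[[1]], "spectral_cube")

  expect_error(image_batch(bp, scheme = "nope"), "unknown scheme")
  expect_error(image_batch(bp, band = "delta"), "unknown band")
})
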