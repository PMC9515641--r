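test_that("grid enumeration is deterministic and correctly sized", {
  cnt <- grid_axis_counts(grid_spec())
  expect_identical(unname(cnt), c(57L, 26L, 21L, 11L))
  expect_identical(prod(cnt), 342342)

  toy <- grid_spec(c(10, 12, 2), c(0.8, 0.9, 0.1), c(1.40, 1.42, 0.02),
                   c(1.36, 1.38, 0.02))
  g <- build_grid(toy)
  expect_identical(nrow(g), 16L)
  # diameter slowest, cytoplasmic RI fastest
  expect_equal(g$diameter_um, rep(c(10, 12), each = 8))
  expect_equal(g$ri_cytoplasm, rep(c(1.36, 1.38), times = 8),
               tolerance = 1e-12)
  expect_equal(unlist(g[1, ]),
               c(diameter_um = 10, nc_ratio = 0.8, ri_nucleus = 1.40,
                 ri_cytoplasm = 1.36))

  expect_error(grid_spec(diameter = c(10, 12, 5)), "step larger")
  expect_error(build_grid(grid_spec(), cap = 1000), "cap")
})

test_that("normalisation is scale invariant and handles degenerate input", {
  v <- runif(50, 0.1, 10)
  expect_equal(normalize_lsp(v), normalize_lsp(1000 * v), tolerance = 1e-12)
  expect_equal(normalize_lsp(rep(3, 20)), rep(0, 20))
  expect_error(normalize_lsp(rep(0, 20)), "all-zero")
  one <- lsp_intensity(core_shell_cell(11.76, 0.85, 1.42, 1.38))
  expect_length(normalize_lsp(one), 281)
  expect_true(all(is.finite(normalize_lsp(one))))
})

test_that("lookup build is reproducible and stores normalised forwards", {
  tab <- toy_table()
  expect_identical(nrow(tab$curves), nrow(build_grid(toy_grid())))
  i <- 37
  cell <- core_shell_cell(tab$params$diameter_um[i], tab$params$nc_ratio[i],
                          tab$params$ri_nucleus[i], tab$params$ri_cytoplasm[i])
  expect_equal(tab$curves[i, ],
               normalize_lsp(lsp_intensity(cell, toy_optics())),
               tolerance = 1e-12)

  again <- build_lookup(toy_grid(), toy_optics(), quiet = TRUE)
  expect_identical(tab$curves, again$curves)

  # cache round-trip and configuration mismatch detection
  cache <- tempfile(fileext = ".rds")
  t1 <- build_lookup(toy_grid(), toy_optics(), cache_path = cache,
                     quiet = TRUE)
  t2 <- build_lookup(toy_grid(), toy_optics(), cache_path = cache,
                     quiet = TRUE)
  expect_identical(t1$curves, t2$curves)
  expect_error(build_lookup(toy_grid(), optical_config(), cache_path = cache,
                            quiet = TRUE), "different configuration")
  unlink(cache)
})

test_that("self-match returns the stored row with zero residual", {
  tab <- toy_table()
  ang <- lsp_angles(toy_optics())
  for (i in c(1L, 100L, nrow(tab$curves))) {
    cell <- core_shell_cell(tab$params$diameter_um[i], tab$params$nc_ratio[i],
                            tab$params$ri_nucleus[i],
                            tab$params$ri_cytoplasm[i])
    m <- match_lsp(lsp_intensity(cell, toy_optics()), tab)
    expect_identical(m$index, i)
    expect_identical(m$residual, 0)
    expect_gt(m$runner_up_gap, 0)
  }
})

test_that("matcher agrees with an exhaustive scan and bounds every row", {
  tab <- toy_table()
  set.seed(11)
  for (r in 1:50) {
    cell <- core_shell_cell(runif(1, 8, 18), runif(1, 0.75, 0.90),
                            runif(1, 1.38, 1.44), runif(1, 1.35, 1.41))
    prof <- lsp_intensity(cell, toy_optics())
    q <- normalize_lsp(prof)
    bf <- brute_force_match(q, tab)
    m <- match_lsp(prof, tab)
    expect_identical(m$index, bf$index)
    expect_equal(m$residual, bf$residual, tolerance = 1e-9)
    expect_true(all(m$residual <= bf$all + 1e-12))
  }
})

test_that("noise-free off-grid cells invert close to the truth", {
  # the coated-sphere inverse problem is weakly degenerate (distinct
  # parameter tuples can produce near-identical profiles), so closeness is
  # asserted on the median per-axis deviation, not on every single draw
  tab <- toy_table()
  step <- vapply(toy_grid(), `[`, numeric(1), 3)
  set.seed(13)
  devs <- t(vapply(1:15, function(r) {
    truth <- c(runif(1, 9, 17), runif(1, 0.78, 0.88), runif(1, 1.39, 1.43),
               runif(1, 1.36, 1.40))
    cell <- core_shell_cell(truth[1], truth[2], truth[3], truth[4])
    m <- match_lsp(lsp_intensity(cell, toy_optics()), tab)
    abs(unlist(unclass(m$best)) - truth) / step
  }, numeric(4)))
  expect_true(all(apply(devs, 2, median) <= 1))
})

test_that("query resampling interpolates and refuses extrapolation", {
  tab <- toy_table()
  cell <- core_shell_cell(14, 0.85, 1.42, 1.39)
  fine <- lsp_intensity(cell, optical_config(angle_step = 0.1))
  m <- match_lsp(fine, tab)   # 0.1 deg query onto 0.5 deg table
  expect_lt(abs(m$best$diameter_um - 14), 1 + 1e-9)
  short <- lsp(seq(5, 20, 0.5),
               approx(fine$angles, fine$intensities,
                      xout = seq(5, 20, 0.5))$y)
  expect_error(match_lsp(short, tab), "cover")
})

test_that("batch feature extraction preserves order and flags failures", {
  tab <- toy_table()
  idx <- c(5, 250, 401)
  cells <- tab$params[idx, ]
  mat <- lsp_intensity(cells, toy_optics())
  feats <- batch_extract_features(mat, tab, labels = c("a", "b", "c"))
  expect_identical(nrow(feats), 3L)
  expect_identical(feats$label, c("a", "b", "c"))
  expect_identical(feats$residual, rep(0, 3))
  expect_identical(feats$D_um, cells$diameter_um)

  # an all-zero record is flagged, not dropped
  mat2 <- rbind(mat, 0)
  expect_warning(f2 <- batch_extract_features(mat2, tab), "flagged")
  expect_identical(nrow(f2), 4L)
  expect_true(f2$flagged[4] && !any(f2$flagged[1:3]))
  expect_true(all(is.na(f2$D_um[4])))

  expect_error(lsp_fit(list(), tab), "empty")
})
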