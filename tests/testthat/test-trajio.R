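test_that("text dialect round-trips arbitrary valid series exactly", {
  set.seed(101)
  for (i in 1:8) {
    zs <- random_zseries(n = sample(5:40, 1), k = sample(1:4, 1),
                         with_lipid = i %% 2 == 0)
    f <- tempfile(fileext = ".zser")
    back <- read_zseries_text(write_zseries_text(zs, f))
    expect_identical(back$times, zs$times)
    expect_identical(unname(back$z), unname(zs$z))
    expect_identical(back$box_z, zs$box_z)
    expect_identical(back$temperature, zs$temperature)
    expect_identical(back$label, zs$label)
    if (is.null(zs$lipid_ref_z)) {
      expect_null(back$lipid_ref_z)
    } else {
      expect_identical(unname(back$lipid_ref_z), unname(zs$lipid_ref_z))
    }
  }
})

test_that("generator output round-trips bit-identically at 1e4 frames", {
  sp <- synthetic_spec(1.5, 0.5, 0.5, n_solutes = 3, dt = 0.01,
                       n_steps = 1e4, seed = 5)
  zs <- simulate_langevin(sp)
  f <- tempfile(fileext = ".zser")
  back <- read_zseries_text(write_zseries_text(zs, f))
  expect_identical(unname(back$z), unname(zs$z))
  expect_identical(back$times, zs$times)
})

test_that("dialect errors: missing header keys, empty body, ragged rows", {
  f <- tempfile()
  writeLines(c("# label: x", "# n_solutes: 1", "0 12 0.5"), f)
  expect_error(read_zseries_text(f), "temperature_K",
               class = "permcount_dialect_error")
  writeLines(c("# label: x", "# temperature_K: 440", "# n_solutes: 1",
               "# lipid_ref: no"), f)
  expect_error(read_zseries_text(f), "no data rows",
               class = "permcount_dialect_error")
  writeLines(c("# label: x", "# temperature_K: 440", "# n_solutes: 1",
               "# lipid_ref: no", "0 12 0.5", "1 12"), f)
  expect_error(read_zseries_text(f), "ragged",
               class = "permcount_dialect_error")
})

test_that("zseries constructor enforces its invariants", {
  expect_error(zseries(c(0, 1, 1), c(0, 0, 0), 12, 440),
               class = "permcount_corrupt_input")
  expect_error(zseries(0:1, c(0, 7), 12, 440), "wrapped",
               class = "permcount_input_error")
  expect_error(zseries(0:1, c(0, 0), -1, 440),
               class = "permcount_input_error")
  expect_error(zseries(0:1, c(0, 0), 12, 0),
               class = "permcount_input_error")
})

test_that("recentre_and_wrap: identity, wrap arithmetic, idempotence", {
  zs <- zseries(0:3, c(-3, 0, 2, 4), box_z = 12, temperature = 440)
  out <- recentre_and_wrap(zs)
  expect_equal(unname(out$z), unname(zs$z))

  # value beyond +L/2 wraps to the negative side
  zs2 <- zseries(0:1, c(0, 0), box_z = 12, temperature = 440,
                 wrapped = FALSE)
  zs2$z[2, 1] <- 6.1
  out2 <- recentre_and_wrap(zs2)
  expect_equal(out2$z[2, 1], -5.9)

  # recentring a shifted series then recentring again is a fixed point
  zs3 <- zseries(0:2, c(1, 2, 3), box_z = 12, temperature = 440)
  once <- recentre_and_wrap(zs3, midplane = 1)
  twice <- recentre_and_wrap(once)
  expect_identical(unname(once$z), unname(twice$z))
  expect_identical(attr(once, "jump"), attr(twice, "jump"))
})

test_that("a path crossing the periodic boundary is flagged exactly once", {
  z <- c(5.0, 5.8, -5.9, -5.2)   # crosses +L/2 between frames 2 and 3
  zs <- zseries(0:3, z, box_z = 12, temperature = 440)
  out <- recentre_and_wrap(zs)
  expect_identical(which(attr(out, "jump")), 3L)
})

test_that("multi-model PDB adapter extracts z, leaflets and stride", {
  skip_if_not_installed("bio3d")
  zmat <- matrix(c(0, 1, 2), ncol = 1)
  f <- tempfile(fileext = ".pdb")
  write_pdb_fixture(f, zmat)
  zs <- load_zseries(f, solute_selector = list(resid = "SOL"),
                     lipid_selector = list(elety = "P"),
                     temperature = 440)
  expect_equal(unname(zs$z[, 1]), c(0, 1, 2), tolerance = 1e-6)
  expect_equal(unname(zs$lipid_ref_z[1, ]), c(-2, 2), tolerance = 1e-6)
  expect_equal(zs$box_z[1], 12)

  # stride = 2 on a 10-frame trajectory keeps ceiling(10/2) = 5 frames
  f2 <- tempfile(fileext = ".pdb")
  write_pdb_fixture(f2, matrix(seq(0, 0.9, by = 0.1), ncol = 1))
  zs2 <- load_zseries(f2, solute_selector = list(resid = "SOL"),
                      stride = 2, temperature = 440)
  expect_equal(n_frames(zs2), 5L)

  expect_error(load_zseries(f, solute_selector = list(resid = "XXX"),
                            temperature = 440),
               class = "permcount_selection_error")
  f3 <- tempfile(fileext = ".xtc"); file.create(f3)
  expect_error(load_zseries(f3, solute_selector = list(resid = "SOL")),
               class = "permcount_format_error")
})

test_that("generator output re-read through the adapter formats agrees", {
  skip_if_not_installed("bio3d")
  sp <- synthetic_spec(0.5, 0.5, 0.5, n_solutes = 2, dt = 0.01,
                       n_steps = 200, record_stride = 10, seed = 9)
  zs <- simulate_langevin(sp)
  f <- tempfile(fileext = ".pdb")
  write_pdb_fixture(f, zs$z, lipid_z_nm = c(-1, 1), box_z_nm = sp$box_z)
  back <- load_zseries(f, solute_selector = list(resid = "SOL"),
                       lipid_selector = list(elety = "P"),
                       temperature = sp$temperature)
  # PDB stores 3 decimals in Angstrom: 1e-4 nm quantisation
  expect_equal(unname(back$z), unname(zs$z), tolerance = 1e-4)
})
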