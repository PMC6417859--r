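test_that("bundled presets load from their config files with the expected couplings", {
  trph <- rp_preset("FAD-TrpH")
  expect_equal(vapply(trph$nuclei, `[[`, numeric(1), "coupling_uT"),
               c(523, 189, 322))
  expect_equal(vapply(trph$nuclei, `[[`, character(1), "electron"),
               c("A", "A", "B"))
  expect_equal(trph$M, 27L)
  fadz <- rp_preset("FAD-Z")
  expect_equal(length(fadz$nuclei), 2L)
  expect_equal(fadz$M, 9L)
})

test_that("system configs round-trip through YAML as well as JSON", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: custom",
               "nuclei:",
               "  - {label: Na, spin: 0.5, coupling_uT: 120.5, electron: A}",
               "  - {label: Nb, spin: 1, coupling_uT: -30, electron: B}"),
             path)
  sys <- read_radical_pair(path)
  expect_equal(sys$name, "custom")
  expect_equal(sys$dim, 4L * 2L * 3L)
  expect_equal(sys$nuclei[[2]]$coupling_uT, -30)
  expect_error(read_radical_pair("no/such/file.json"), "not found")
})

test_that("sweep CSV output round-trips numerically at 15 significant digits", {
  sw <- phi_vs_field(rp_preset("FAD-Z"),
                     reaction_kinetics(tau = 1e-6, r = 1e6),
                     c(0, 37.512345678901234, 500))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(sw, path)
  back <- read_sweep_csv(path)
  expect_equal(back$axis_name, sw$axis_name)
  expect_equal(back$axis_values, sw$axis_values, tolerance = 1e-15)
  expect_equal(back$values, sw$values, tolerance = 1e-15)
  expect_equal(back$metadata$system, "FAD-Z")
  jpath <- withr::local_tempfile(fileext = ".json")
  write_sweep_json(sw, jpath)
  dat <- jsonlite::fromJSON(jpath)
  expect_equal(dat$values, sw$values, tolerance = 1e-15)
})

test_that("figure data writer produces one parsable curve per case", {
  dir <- withr::local_tempdir()
  files <- run_figure_data("fig4",
                           config = list(points_per_decade = 2L),
                           out_dir = dir)
  expect_length(files, 4L)  # elf + gmf for each of two systems
  expect_true(all(file.exists(files)))
  sw <- read_sweep_csv(files[1])
  expect_equal(sw$axis_name, "tau_s")
  expect_true(all(is.finite(sw$values)))
  expect_error(run_figure_data("fig9"), "unknown figure id")
})

test_that("the summary table carries six quantities for both presets", {
  tab <- run_table1(config = list(points_per_decade = 4L))
  expect_s3_class(tab, "rp_table")
  expect_equal(nrow(tab), 6L)
  expect_named(tab, c("quantity", "conditions", "FAD-TrpH", "FAD-Z"))
  omega_row <- tab$quantity == "Omega"
  mfe_rows <- tab$quantity %in% c("mfeELFmax_ppm", "mfeGMFmax_ppm")
  # Omega is the ratio of the two extremised effects, per system
  expect_equal(tab[["FAD-TrpH"]][omega_row],
               tab[["FAD-TrpH"]][tab$quantity == "mfeGMFmax_ppm"] /
                 tab[["FAD-TrpH"]][tab$quantity == "mfeELFmax_ppm"])
  # the coupling-poor partner amplifies both field effects
  expect_true(all(abs(tab[["FAD-Z"]][mfe_rows]) >
                    abs(tab[["FAD-TrpH"]][mfe_rows])))
})
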