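test_that("concentration matrix construction validates its invariants", {
  cm <- tiny_conc()
  expect_s3_class(cm, "concentration_matrix")
  expect_identical(unname(unclass(cm)[, "Pb"]), c(10, 30))

  bad <- matrix(c(1, -5, 2, 3), 2, dimnames = list(c("S1", "S2"), c("Pb", "Zn")))
  expect_error(concentration_matrix(bad), "S2.*Pb|Pb.*S2")
  expect_error(concentration_matrix(matrix(NA_real_, 1, 1,
    dimnames = list("S1", "Pb"))), "invalid concentration")
  dup <- matrix(1:4, 2, dimnames = list(c("S1", "S1"), c("Pb", "Zn")))
  expect_error(concentration_matrix(dup), "duplicate site")
  dup2 <- matrix(1:4, 2, dimnames = list(c("S1", "S2"), c("Pb", "Pb")))
  expect_error(concentration_matrix(dup2), "duplicate element")
  expect_error(concentration_matrix(matrix(numeric(0), 0, 0)), "at least one")
  # zeros are allowed
  expect_silent(concentration_matrix(matrix(0, 1, 1, dimnames = list("S1", "Pb"))))
})

test_that("concentration CSV reading is a validated identity and errors are precise", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,Pb,Zn", "S1,10,20", "S2,30,40"), path)
  cm <- read_concentration_csv(path)
  expect_identical(dimnames(cm), list(c("S1", "S2"), c("Pb", "Zn")))
  expect_identical(as.vector(unclass(cm)), c(10, 30, 20, 40))

  writeLines(c("site,Pb,Zn", "S1,10,20", "S2,-5,40"), path)
  expect_error(read_concentration_csv(path), "S2.*Pb|Pb.*S2")

  writeLines(c("site,Pb,Pb", "S1,10,20"), path)
  expect_error(read_concentration_csv(path), "duplicate")

  writeLines(c("site,Pb,Zn", "S1,abc,20"), path)
  expect_error(read_concentration_csv(path), "non-numeric.*S1.*Pb")

  expect_error(read_concentration_csv(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("write/read round-trip is lossless at 12 significant digits", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(7)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    m <- sample(2:5, 1)
    vals <- matrix(exp(runif(n * m, -4, 10)), n, m,
                   dimnames = list(paste0("S", 1:n), paste0("E", 1:m)))
    cm <- concentration_matrix(vals)
    write_concentration_csv(cm, path)
    back <- read_concentration_csv(path)
    expect_equal(unclass(back), unclass(cm), tolerance = 1e-11)
  }
})

test_that("exposure parameter defaults reproduce the receptor tables exactly", {
  pnames <- c(
    "ingestion_rate", "skin_area", "skin_adherence", "dermal_absorption",
    "inhalation_rate", "particle_emission_factor", "exposure_frequency",
    "exposure_duration", "body_weight", "averaging_time_noncarcinogenic",
    "averaging_time_carcinogenic", "conversion_factor", "volatilization_factor"
  )
  child <- exposure_parameters("child")
  expect_identical(
    unlist(child[pnames], use.names = FALSE),
    c(200, 2800, 0.2, 0.001, 7.6, 1.4e9, 285, 6, 15, 2190, 25550, 1e-6, 32675.6)
  )
  adult <- exposure_parameters("adult")
  expect_identical(
    unlist(adult[pnames], use.names = FALSE),
    c(100, 5700, 0.7, 0.001, 20, 1.4e9, 285, 30, 70, 10950, 25550, 1e-6, 32675.6)
  )
  # the non-carcinogenic averaging time is always ED * 365
  expect_equal(child$averaging_time_noncarcinogenic, child$exposure_duration * 365)
  expect_equal(adult$averaging_time_noncarcinogenic, adult$exposure_duration * 365)
})

test_that("exposure parameter overrides recompute or validate the averaging time", {
  p <- exposure_parameters("child", exposure_duration = 3)
  expect_equal(p$averaging_time_noncarcinogenic, 1095)
  expect_error(exposure_parameters("child", body_weight = 0), "body_weight")
  expect_error(exposure_parameters("child", nonsense = 1), "valid keys")
  expect_error(
    exposure_parameters("child", exposure_duration = 3,
                        averaging_time_noncarcinogenic = 2190),
    "must equal exposure_duration"
  )
})

test_that("reference-dose defaults match the published table including gaps", {
  rfd <- rfd_table()
  expect_identical(rfd["As", "ingestion"], 0.0003)
  expect_identical(rfd["As", "dermal"], 0.000123)
  expect_identical(rfd["As", "inhalation"], 0.000301)
  expect_identical(rfd["Zr", "ingestion"], 0.00008)
  expect_true(is.na(rfd["Zr", "dermal"]) && is.na(rfd["Zr", "inhalation"]))
  expect_identical(rfd["Cr", "inhalation"], 0.00003)
  expect_identical(rfd["Pb", "dermal"], 0.00053)
  expect_false(any(c("Sc", "Rb") %in% rownames(rfd)))
  expect_error(rfd_table(data.frame(element = "X", ingestion = -1,
                                    dermal = NA, inhalation = NA)), "> 0")
})

test_that("configuration files override defaults with full validation and provenance", {
  cfg <- withr::local_tempfile(fileext = ".ini")

  writeLines(character(0), cfg)
  conf <- load_config(cfg, quiet = TRUE)
  expect_equal(conf$child$ingestion_rate, 200)
  expect_equal(conf$adult$body_weight, 70)
  expect_length(conf$provenance, 0)

  writeLines(c("[child]", "exposure_duration = 3"), cfg)
  conf <- load_config(cfg, quiet = TRUE)
  expect_equal(conf$child$averaging_time_noncarcinogenic, 1095)
  expect_true("child.exposure_duration" %in% conf$provenance)

  writeLines(c("[child]", "body_weight = 0"), cfg)
  expect_error(load_config(cfg, quiet = TRUE), "body_weight")

  writeLines(c("[child]", "shoe_size = 40"), cfg)
  expect_error(load_config(cfg, quiet = TRUE), "valid keys")

  writeLines(c("[bogus]", "x = 1"), cfg)
  expect_error(load_config(cfg, quiet = TRUE), "valid sections")

  writeLines(c("[rfd]", "Zr_dermal = 0.001", "[background]", "Pb = 40",
               "[pmf]", "k_candidates = 4,5", "[options]",
               "inhalation_uses_ingestion_rate = true"), cfg)
  conf <- load_config(cfg, quiet = TRUE)
  expect_equal(conf$rfd["Zr", "dermal"], 0.001)
  expect_equal(unname(conf$background["Pb"]), 40)
  expect_identical(conf$pmf$k_candidates, c(4L, 5L))
  expect_true(conf$options$inhalation_uses_ingestion_rate)
  expect_message(load_config(cfg), "from file")
})

test_that("PM series construction enforces ordering and non-negativity", {
  expect_s3_class(pm_series(1:3, c(1, 2, 3), c(2, 4, 6)), "pm_series")
  expect_error(pm_series(c(1, 1, 2), 1:3, 1:3), "strictly increasing")
  expect_error(pm_series(1:2, c(1, -1), c(1, 1)), ">= 0")
  expect_error(pm_series(1:2, 1, c(1, 1)), "equal lengths")
})

test_that("background tables validate positivity and element names", {
  expect_error(background_table(c(Pb = 0)), "> 0")
  expect_error(background_table(c(5, 10)), "named")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("element,background_mg_kg", "Pb,27", "Zn,70"), path)
  bg <- read_background_csv(path)
  expect_equal(unname(bg["Zn"]), 70)
  bg_def <- default_background()
  expect_setequal(names(bg_def), dust_elements())
  expect_true(all(bg_def > 0))
})
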