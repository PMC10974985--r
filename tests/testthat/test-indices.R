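test_that("geo-accumulation index follows its defining identity and class scheme", {
  b <- c(Pb = 40)
  cm <- function(v) concentration_matrix(matrix(v, ncol = 1,
    dimnames = list(paste0("S", seq_along(v)), "Pb")))

  r <- geo_accumulation_index(cm(1.5 * 40), b)
  expect_equal(r$value, 0)
  expect_match(r$class, "class 0")

  r <- geo_accumulation_index(cm(3 * 40), b)
  expect_equal(r$value, 1)
  expect_match(r$class, "class 1")

  r <- geo_accumulation_index(cm(96), c(Pb = 1))
  expect_equal(r$value, log2(64))
  expect_match(r$class, "class 6")

  r <- geo_accumulation_index(cm(0), b)
  expect_true(is.na(r$value))
  expect_match(r$class, "class 0")

  expect_error(geo_accumulation_index(tiny_conc(), c(Pb = 5)), "Zn")
})

test_that("Igeo shifts by exactly one when concentrations double", {
  set.seed(11)
  for (i in 1:50) {
    conc <- matrix(exp(runif(6, -2, 8)), 2, 3,
                   dimnames = list(c("S1", "S2"), c("A", "B", "C")))
    bg <- setNames(exp(runif(3, -1, 5)), c("A", "B", "C"))
    v1 <- geo_accumulation_index(concentration_matrix(conc), bg)$value
    v2 <- geo_accumulation_index(concentration_matrix(2 * conc), bg)$value
    expect_equal(v2, v1 + 1, tolerance = 1e-12)
  }
})

test_that("contamination factor is the background ratio with the published classes", {
  r <- contamination_factor(
    concentration_matrix(matrix(50, 1, 1, dimnames = list("S1", "Pb"))),
    c(Pb = 25))
  expect_equal(r$value, 2)
  expect_identical(r$class, "moderate contamination")

  expect_identical(classify_cf(1), "moderate contamination")    # lower boundary
  expect_identical(classify_cf(7), "very high contamination")
  expect_identical(classify_cf(0.99), "low contamination")
  expect_identical(classify_cf(3), "considerable contamination")
  expect_identical(classify_cf(6), "considerable contamination") # boundary convention

  # scale covariance: CF(kC, kB) = CF(C, B)
  set.seed(3)
  for (i in 1:25) {
    conc <- matrix(exp(runif(4, 0, 6)), 2, 2,
                   dimnames = list(c("S1", "S2"), c("A", "B")))
    bg <- setNames(exp(runif(2, 0, 4)), c("A", "B"))
    k <- exp(runif(1, -2, 2))
    expect_equal(
      contamination_factor(concentration_matrix(k * conc), k * bg)$value,
      contamination_factor(concentration_matrix(conc), bg)$value,
      tolerance = 1e-12
    )
  }
})

test_that("modified degree of contamination averages CFs with the seven-level scheme", {
  expect_equal(modified_degree_of_contamination(rep(2.7, 8))$value, 2.7)
  r <- modified_degree_of_contamination(c(1, 2, 3))
  expect_equal(r$value, 2)
  expect_identical(r$class, "low") # boundary 2 is inclusive for "low"
  r <- modified_degree_of_contamination(c(4, 6))
  expect_equal(r$value, 5)
  expect_identical(r$class, "high")
  expect_error(modified_degree_of_contamination(numeric(0)), "empty")

  # mCd always lies between the min and max CF
  set.seed(5)
  for (i in 1:50) {
    cf <- exp(runif(sample(2:12, 1), -3, 4))
    v <- modified_degree_of_contamination(cf)$value
    expect_gte(v, min(cf))
    expect_lte(v, max(cf))
  }
})

test_that("pollution load index is the geometric mean, in log space", {
  r <- pollution_load_index_site(c(4, 1))
  expect_equal(r$value, 2)
  r <- pollution_load_index_site(rep(1, 5))
  expect_equal(r$value, 1)
  expect_identical(r$class, "baseline levels of pollutants")
  expect_error(pollution_load_index_site(c(1, 0)), "positive")
  expect_error(pollution_load_index_site(numeric(0)), "empty")

  # direct-product oracle on 50 log-uniform CFs
  set.seed(9)
  cf <- exp(runif(50, -5, 5))
  expect_equal(pollution_load_index_site(cf)$value,
               prod(cf)^(1 / length(cf)), tolerance = 1e-12)
})

test_that("zone PLI is the geometric mean of site PLIs and is permutation-invariant", {
  expect_equal(pollution_load_index_zone(3.7)$value, 3.7)
  expect_equal(pollution_load_index_zone(c(1, 4))$value, 2)
  set.seed(13)
  plis <- exp(runif(10, -1, 2))
  expect_equal(pollution_load_index_zone(plis)$value,
               pollution_load_index_zone(sample(plis))$value, tolerance = 1e-12)
  expect_error(pollution_load_index_zone(numeric(0)), "empty")
})

test_that("site contamination summary covers every site plus the zone", {
  ds <- generate_dataset(synthetic_spec(seed = 2))
  s <- site_contamination_summary(ds$conc, default_background())
  expect_equal(nrow(s), 2 * nrow(ds$conc) + 1)
  expect_identical(s$site[nrow(s)], "zone")
  # zone PLI equals the geometric mean of the site PLIs
  expect_equal(s$value[nrow(s)],
               geometric_mean(s$value[s$index == "pli"]), tolerance = 1e-12)
  # element restriction works and unknown elements error
  s2 <- site_contamination_summary(ds$conc, default_background(),
                                   elements = c("As", "Pb"))
  expect_equal(nrow(s2), 2 * nrow(ds$conc) + 1)
  expect_error(site_contamination_summary(ds$conc, default_background(),
                                          elements = "Xx"), "Xx")
})

test_that("enrichment factor uses the iron reference and the published classes", {
  bg <- c(Pb = 20, Fe = 10000)
  cm <- concentration_matrix(matrix(c(60, 120, 30000, 20000), 2, 2,
    dimnames = list(c("S1", "S2"), c("Pb", "Fe"))))
  r <- enrichment_factor(cm, bg)
  expect_true(all(r$value[r$element == "Fe"] == 1))

  # sample ratios equal to background ratios -> EF 1 everywhere
  cm2 <- concentration_matrix(matrix(c(2 * 20, 3 * 20, 2 * 10000, 3 * 10000), 2, 2,
    dimnames = list(c("S1", "S2"), c("Pb", "Fe"))))
  expect_equal(enrichment_factor(cm2, bg)$value, rep(1, 4), tolerance = 1e-12)

  # hand-computed: sample ratio 120, background ratio 2 -> EF 60
  cm3 <- concentration_matrix(matrix(c(120, 1, 10), 1, 3,
    dimnames = list("S1", c("Cu", "Fe", "X"))))
  r3 <- enrichment_factor(cm3, c(Cu = 2, Fe = 1, X = 10))
  cu <- r3[r3$element == "Cu", ]
  expect_equal(cu$value, 60)
  expect_identical(cu$class, "extremely severe enrichment")

  zero_ref <- concentration_matrix(matrix(c(5, 0), 1, 2,
    dimnames = list("S1", c("Pb", "Fe"))))
  expect_error(enrichment_factor(zero_ref, bg), "S1")

  # invariance to scaling all of a site's concentrations
  set.seed(21)
  conc <- matrix(exp(runif(8, 0, 6)), 2, 4,
                 dimnames = list(c("S1", "S2"), c("A", "B", "C", "Fe")))
  bg4 <- setNames(exp(runif(4, 0, 4)), c("A", "B", "C", "Fe"))
  scaled <- conc
  scaled[1, ] <- 7 * scaled[1, ]
  expect_equal(enrichment_factor(concentration_matrix(conc), bg4)$value,
               enrichment_factor(concentration_matrix(scaled), bg4)$value,
               tolerance = 1e-12)
})

test_that("classification functions are total with closed label vocabularies", {
  set.seed(17)
  x <- c(exp(runif(200, -8, 8)), 1, 3, 6, 50, 0.5, 1.5, 2, 4, 8, 16, 32)
  expect_true(all(classify_cf(x) %in% c(
    "low contamination", "moderate contamination",
    "considerable contamination", "very high contamination")))
  expect_true(all(classify_mcd(x) %in% c(
    "uncontaminated to very low", "low", "moderate", "high",
    "very high", "extremely high", "ultra-high")))
  expect_true(all(classify_ef(x) %in% c(
    "no enrichment", "natural weathering",
    "significant non-crustal contribution", "extremely severe enrichment")))
  expect_true(all(grepl("^class [0-6]", classify_igeo(c(log2(x), NA)))))
  expect_true(all(classify_pli(x) %in% c(
    "no pollution", "baseline levels of pollutants", "deteriorated")))
})

test_that("PM ratio summary flags combustion dominance above 0.5 and handles zeros", {
  s <- pm_series(1:3, c(5, 5, 5), c(10, 10, 10))
  r <- pm_ratio_summary(s)
  expect_equal(r$ratios$ratio, rep(0.5, 3))
  expect_false(any(r$ratios$combustion_dominated)) # strict >
  expect_equal(r$mean, 0.5)
  expect_equal(r$min, r$max) # constant series

  s2 <- pm_series(1:2, c(7.4, 3), c(10, 10))
  r2 <- pm_ratio_summary(s2)
  expect_equal(r2$ratios$ratio[1], 0.74)
  expect_true(r2$ratios$combustion_dominated[1])

  s3 <- pm_series(1:3, c(5, 2, 12), c(10, 0, 10))
  expect_warning(expect_warning(r3 <- pm_ratio_summary(s3), "PM10 = 0"),
                 "PM2.5 > PM10")
  expect_true(is.na(r3$ratios$ratio[2]))
  expect_equal(r3$n_undefined, 1)
  expect_true(r3$ratios$pm25_exceeds_pm10[3])
  expect_equal(r3$mean, mean(c(0.5, 1.2)))
})
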