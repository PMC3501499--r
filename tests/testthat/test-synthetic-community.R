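small_species <- function(tissues = "incisor;bone", n = 1) {
  data.frame(species = paste("Species", seq_len(n)), family = "other",
             d13C_mean = -17, d13C_sd = 0.5, c4_prob = 0, c4_shift = 0,
             tissues = tissues, stringsAsFactors = FALSE)
}

noiseless <- function(...) {
  simulation_config(co3_po4_offset_sd = 0, individual_sd = 0,
                    measurement_sd = c(d18O_co3 = 0, d18O_po4 = 0,
                                       d13C = 0), ...)
}

test_that("water_series is a cosine with exact annual mean", {
  cfg <- simulation_config()
  w <- water_series(cfg)
  expect_equal(w(cfg$phase_peak_day), -7.3 + 2)       # cosine peak
  expect_equal(mean(w(1:365)), -7.3, tolerance = 1e-9)
  flat <- water_series(simulation_config(seasonal_amplitude = 0))
  expect_equal(flat(c(1, 100, 300)), rep(-7.3, 3))
  # periodic: day t and t + 365 coincide
  expect_equal(w(40), w(405))
})

test_that("record_tissue is deterministic and respects windows", {
  cfg <- noiseless()
  # no seasonality: every tissue of every individual reads the annual mean
  cfg0 <- noiseless(seasonal_amplitude = 0)
  expected <- from_local_water("longinelli_2003", -7.3)
  for (tis in c("incisor", "M1", "bone")) {
    rt <- record_tissue(cfg0, death_day = 230, tissue = tis,
                        birth_day = -50)
    expect_equal(rt$d18O_po4, expected, tolerance = 1e-9)
    expect_equal(rt$d18O_co3, expected + 10.9, tolerance = 1e-9)
  }
  # summer death: the short incisor window reads enriched summer water,
  # the lifetime bone window averages most of the year
  inc <- record_tissue(cfg, death_day = 240, tissue = "incisor",
                       birth_day = -60)
  bone <- record_tissue(cfg, death_day = 240, tissue = "bone",
                        birth_day = -60)
  expect_gt(inc$d18O_po4, bone$d18O_po4)
  # a window longer than the post-weaning lifespan is truncated and flagged
  tr <- record_tissue(cfg, death_day = 50, tissue = "M1", birth_day = 10)
  expect_true(tr$truncated)
  expect_equal(tr$window[1], 10 + cfg$weaning_day)
  expect_error(record_tissue(cfg, death_day = 10, tissue = "bone",
                             birth_day = 10),
               class = "rodiso_invalid_input")
  expect_error(simulation_config(calibration = "missing_eq"),
               class = "rodiso_not_found")
})

test_that("generate_community is reproducible and correctly sized", {
  cfg <- simulation_config(n_per_species = 10, seed = 42,
                           species_table = small_species("incisor", n = 7))
  d1 <- generate_community(cfg)
  d2 <- generate_community(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_equal(nrow(d1), 70L)             # 7 species x 10 incisors
  expect_s3_class(d1, "specimen_records")
  d3 <- generate_community(simulation_config(n_per_species = 10, seed = 43,
                                             species_table =
                                               small_species("incisor", 7)))
  expect_false(identical(d1$d18O_co3, d3$d18O_co3))
  # truth is carried alongside
  tr <- attr(d1, "truth")
  expect_equal(nrow(tr$individuals), 70L)
  expect_true(all(tr$individuals$lifespan >= 90))
})

test_that("generated datasets round-trip through the CSV layer", {
  cfg <- simulation_config(n_per_species = 5, seed = 3,
                           species_table = small_species())
  d <- generate_community(cfg)
  p <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, p)
  back <- read_dataset(p)
  expect_equal(back$d18O_co3, d$d18O_co3, tolerance = 1e-12)
  expect_equal(back$d18O_po4, d$d18O_po4, tolerance = 1e-12)
  expect_equal(back$d13C, d$d13C, tolerance = 1e-12)
  expect_identical(back$specimen_id, d$specimen_id)
})

test_that("zero offset noise pins the carbonate-phosphate difference", {
  cfg <- noiseless(n_per_species = 20, seed = 5,
                   species_table = small_species())
  d <- generate_community(cfg)
  expect_equal(d$d18O_co3 - d$d18O_po4, rep(10.9, nrow(d)),
               tolerance = 1e-9)
})

test_that("offset and diet parameters are recovered from moderate samples", {
  cfg <- simulation_config(n_per_species = 500, seed = 8,
                           species_table = small_species("incisor"))
  d <- generate_community(cfg)
  est <- estimate_offset(d)
  se <- est$sd_offset / sqrt(est$n_pairs)
  expect_lt(abs(est$mean_offset - 10.9), 3 * se)
  # generated offset SD reflects the configured 0.8 plus measurement noise
  expect_equal(est$sd_offset, sqrt(0.8^2 + 0.1^2 + 0.2^2),
               tolerance = 0.1)
  ds <- diet_summary(d, by = "species")
  expect_lt(abs(ds$diet_mean - (-17 - 9.9)), 3 * ds$diet_sd / sqrt(ds$n))
})

test_that("seasonal amplitude drives the incisor-bone offset monotonically", {
  prop_pos <- function(amplitude) {
    cfg <- simulation_config(seasonal_amplitude = amplitude,
                             n_per_species = 150, seed = 99,
                             species_table = small_species())
    ib <- paired_tissue_offsets(generate_community(cfg), "incisor", "bone",
                                "d18O_co3")
    mean(ib$pairs$offset)
  }
  low <- prop_pos(0.5)
  high <- prop_pos(3)
  expect_gt(high, low - 0.05)  # up to Monte-Carlo jitter
})

test_that("recovery_experiment reports coherent discrepancies", {
  cfg <- simulation_config(n_per_species = 60, seed = 12,
                           species_table = small_species(n = 2))
  re <- recovery_experiment(cfg)
  expect_s3_class(re, "recovery_report")
  expect_equal(re$offset$true, 10.9)
  expect_equal(re$offset$estimated - re$offset$true, re$offset$error)
  expect_equal(nrow(re$diet), 2L)
  expect_lt(abs(re$water$error), 1)
  expect_gte(re$incisor_bone$proportion_positive, 0)
})
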