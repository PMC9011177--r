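test_that("config validation rejects bad fields by name", {
  cfg <- tiny_config()
  bad <- cfg; bad$n <- -5
  expect_error(validate_sim_config(bad), "field 'n'")
  bad <- cfg; bad$regions$weight <- c(0.6, 0.6)
  expect_error(validate_sim_config(bad), "field 'regions'")
  bad <- cfg; bad$background_rate <- c(g1 = 1.2, g2 = 0.006)
  expect_error(validate_sim_config(bad), "field 'background_rate'")
  bad <- cfg; bad$true_or$rr[1] <- 0
  expect_error(validate_sim_config(bad), "field 'true_or'")
  bad <- cfg; bad$baseline_hazards <- cfg$baseline_hazards[-1, ]
  expect_error(validate_sim_config(bad), "field 'baseline_hazards'")
  bad <- cfg; bad$founder_variants$region <- "nowhere"
  expect_error(validate_sim_config(bad), "field 'founder_variants'")
})

test_that("simulation is bit-identical under a fixed seed and changes with it", {
  cfg <- tiny_config(n = 2000, seed = 11)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$calls, s2$calls)
  cfg2 <- tiny_config(n = 2000, seed = 12)
  s3 <- simulate_cohort(cfg2)
  expect_false(identical(s1$cohort, s3$cohort))
})

test_that("cohort structure honors construction rules", {
  sim <- simulate_cohort(tiny_config(n = 6000, seed = 3))
  co <- sim$cohort
  expect_true(all(co$age_registration >= 20 & co$age_registration <= 99))
  expect_true(all(co$sex %in% c("F", "M")))
  # female-restricted cancer has no male cases
  expect_true(all(co$sex[co$case_siteB == 1] == "F"))
  # diagnosis age never exceeds registration age for naturally generated onsets
  dx <- co$agedx_siteA[co$case_siteA == 1]
  reg <- co$age_registration[co$case_siteA == 1]
  expect_true(all(dx <= reg))
  # controls carry no case flags and no family-history flags
  ctrl <- co[co$status == "control", ]
  expect_true(all(ctrl$n_cancer_types == 0))
  expect_true(all(ctrl$fh_siteA == 0 & ctrl$fh_siteB == 0))
  # cancer-free individuals reporting family history are excluded, not controls
  excl <- co[co$status == "excluded", ]
  expect_true(all(excl$n_cancer_types == 0))
  expect_true(all(rowSums(excl[, c("fh_siteA", "fh_siteB")]) > 0))
})

test_that("founder variant carriers are confined to their region", {
  sim <- simulate_cohort(tiny_config(n = 20000, seed = 5))
  fcalls <- sim$calls[sim$calls$variant_id == "g1_fndrA", ]
  expect_gt(nrow(fcalls), 0)
  reg <- sim$cohort$region[match(fcalls$individual_id, sim$cohort$individual_id)]
  expect_true(all(reg == "a"))
  expect_true(all(fcalls$founder))
})

test_that("realized carrier frequency matches configuration within 3 binomial SDs per region", {
  cfg <- tiny_config(n = 1e6, seed = 21)
  sim <- simulate_cohort(cfg)
  fr <- sim$truth$region_carrier_freq
  expected <- list(
    g1 = c(a = 1 - (1 - 0.004) * (1 - 0.01), b = 0.004),
    g2 = c(a = 0.006, b = 0.006))
  for (g in c("g1", "g2")) {
    for (r in c("a", "b")) {
      n_r <- sum(sim$cohort$region == r)
      p <- expected[[g]][[r]]
      got <- fr$freq[fr$gene == g & fr$region == r]
      expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / n_r))
    }
  }
})

test_that("multiple-primary fraction hits its target within 2 percentage points", {
  # topping-up path: natural co-occurrence below target
  cfg <- tiny_config(n = 50000, seed = 8, multi_primary_target = 0.063)
  sim <- simulate_cohort(cfg)
  pats <- sim$cohort[sim$cohort$status == "case", ]
  expect_lt(abs(mean(pats$n_cancer_types >= 2) - 0.063), 0.02)
  # thinning path: the 14-type config naturally overshoots the target
  sim2 <- simulate_cohort(demo_config(n = 50000, seed = 9))
  pats2 <- sim2$cohort[sim2$cohort$status == "case", ]
  expect_lt(abs(mean(pats2$n_cancer_types >= 2) - 0.063), 0.02)
})

test_that("null relative risks give equal carrier frequency in cases and controls", {
  # two-proportion z-test should be non-significant at alpha = 0.01 in
  # nearly every replicate when every true RR is 1
  ok <- vapply(1:50, function(s) {
    cfg <- calibration_config(n = 4000, carrier_freq = 0.02, rr = 1,
                              lifetime_risk = 0.10, seed = s)
    sim <- simulate_cohort(cfg)
    carr <- sim$truth$carrier$gene1
    case <- sim$cohort$case_site1 == 1
    ctrl <- sim$cohort$status == "control"
    p <- suppressWarnings(stats::prop.test(
      c(sum(carr[case]), sum(carr[ctrl])),
      c(sum(case), sum(ctrl)), correct = FALSE)$p.value)
    p > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("incidence table is the exact configured mixture", {
  # hand arithmetic: p = 0.01, rr = 10, lambda0 = 0.001 -> 0.00109
  cfg <- calibration_config(n = 100, carrier_freq = 0.01, rr = 10,
                            lifetime_risk = 1 - exp(-0.001 * 85), seed = 1)
  inc <- simulate_incidence_table(cfg)
  expect_equal(unique(round(inc$rate, 15)), 0.00109, tolerance = 1e-12)
  # p = 0: population rate equals baseline
  cfg0 <- calibration_config(n = 100, carrier_freq = 0, rr = 10,
                             lifetime_risk = 1 - exp(-0.001 * 85), seed = 1)
  inc0 <- simulate_incidence_table(cfg0)
  expect_equal(inc0$rate, cfg0$baseline_hazards$rate[order(cfg0$baseline_hazards$sex,
                                                           cfg0$baseline_hazards$age_lo)],
               tolerance = 1e-15)
  # completeness: every (cancer, applicable sex, band) exactly once
  cfg2 <- tiny_config()
  inc2 <- simulate_incidence_table(cfg2)
  key <- paste(inc2$cancer, inc2$sex, inc2$age_lo)
  expect_false(any(duplicated(key)))
  expect_equal(nrow(inc2), 2 * 17 + 17) # siteA both sexes + siteB female
})

test_that("config round-trips through YAML and JSON with validation", {
  cfg <- tiny_config(n = 500, seed = 2)
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("cfg.", ext))
    write_sim_config(cfg, path)
    back <- read_sim_config(path)
    expect_identical(simulate_cohort(back)$cohort, simulate_cohort(cfg)$cohort)
  }
  expect_error(read_sim_config(file.path(tempdir(), "nope.yaml")), "not found")
})
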