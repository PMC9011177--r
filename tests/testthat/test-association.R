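sim_with_carriers <- function(...) {
  sim <- simulate_cohort(tiny_config(...))
  carr <- collapse_carriers(sim$calls, c("g1", "g2"),
                            roster = sim$cohort$individual_id)
  list(sim = sim, carr = carr)
}

test_that("fewer than 3 carriers in a category gates the result", {
  # constructed cohort with exactly 2 carrier cases
  n_case <- 100; n_ctrl <- 400
  cohort <- data.frame(
    individual_id = sprintf("X%03d", 1:(n_case + n_ctrl)),
    sex = "F", region = "a",
    status = rep(c("case", "control"), c(n_case, n_ctrl)),
    age_registration = 60,
    n_cancer_types = rep(c(1L, 0L), c(n_case, n_ctrl)),
    case_siteA = rep(c(1L, 0L), c(n_case, n_ctrl)),
    agedx_siteA = rep(c(55L, NA), c(n_case, n_ctrl)),
    fh_siteA = 0L)
  calls <- make_calls(c("X001", "g1", "v1", "P"), c("X002", "g1", "v1", "P"),
                      c("X101", "g1", "v1", "P"), c("X102", "g1", "v1", "P"),
                      c("X103", "g1", "v1", "P"), c("X104", "g1", "v1", "P"))
  carr <- collapse_carriers(calls, "g1", roster = cohort$individual_id)
  res <- run_association(cohort, carr, "g1", "siteA", "no_family_history")
  expect_true(res$gated)
  expect_equal(res$gate_reason, "carrier count < 3")
  expect_equal(res$carriers_case, 2)
  expect_true(all(is.na(res[c("beta", "se", "or", "lo", "hi", "p")])))
  # shift one control carrier to a case: 3 carriers on both sides -> estimated
  calls2 <- rbind(calls, make_calls(c("X003", "g1", "v1", "P")))
  carr2 <- collapse_carriers(calls2, "g1", roster = cohort$individual_id)
  res2 <- run_association(cohort, carr2, "g1", "siteA", "no_family_history")
  expect_false(res2$gated)
  expect_false(is.na(res2$or))
})

test_that("the all-patients design reports the p-value but withholds estimates", {
  x <- sim_with_carriers(n = 20000, seed = 31, rr1 = 8)
  res <- run_association(x$sim$cohort, x$carr, "g1", "siteA", "all_patients")
  expect_false(res$gated)
  expect_false(is.na(res$p))
  expect_true(all(is.na(res[c("beta", "se", "or", "lo", "hi")])))
})

test_that("designs filter cases as specified, never controls", {
  x <- sim_with_carriers(n = 20000, seed = 33, rr1 = 8,
                         multi_primary_target = 0.1)
  co <- x$sim$cohort
  all_p <- run_association(co, x$carr, "g1", "siteA", "all_patients")
  nofh <- run_association(co, x$carr, "g1", "siteA", "no_family_history")
  single <- run_association(co, x$carr, "g1", "siteA", "single_cancer_only")
  # same control pool throughout; case pool shrinks monotonically
  expect_equal(all_p$n_control, nofh$n_control)
  expect_equal(nofh$n_control, single$n_control)
  expect_gt(all_p$n_case, nofh$n_case)
  expect_gte(nofh$n_case, single$n_case)
  # no_family_history case count matches a direct tally
  fh_free_cases <- sum(co$case_siteA == 1 & co$fh_siteA == 0 & co$fh_siteB == 0)
  expect_equal(nofh$n_case, fh_free_cases)
  # fh_scope = "same" only looks at the analyzed cancer
  nofh_same <- run_association(co, x$carr, "g1", "siteA", "no_family_history",
                               fh_scope = "same")
  expect_equal(nofh_same$n_case, sum(co$case_siteA == 1 & co$fh_siteA == 0))
  # single_cancer_only drops multiple-primary patients
  expect_equal(single$n_case,
               sum(co$case_siteA == 1 & co$fh_siteA == 0 & co$fh_siteB == 0 &
                     co$n_cancer_types == 1))
})

test_that("region-adjusted design estimates remain close to the main design", {
  x <- sim_with_carriers(n = 30000, seed = 35, rr1 = 8)
  main <- run_association(x$sim$cohort, x$carr, "g1", "siteA", "no_family_history")
  adj <- run_association(x$sim$cohort, x$carr, "g1", "siteA", "region_adjusted")
  expect_false(adj$gated)
  expect_lt(abs(adj$beta - main$beta), 0.2)
})

test_that("unknown gene or cancer raises an input error", {
  x <- sim_with_carriers(n = 1000, seed = 2)
  expect_error(run_association(x$sim$cohort, x$carr, "g9", "siteA"), "unknown gene")
  expect_error(run_association(x$sim$cohort, x$carr, "g1", "siteZ"), "unknown cancer")
  expect_error(run_association(x$sim$cohort, x$carr, "g1", "siteA", "oddball"),
               "unknown design")
})

test_that("the association grid applies Bonferroni and the burden threshold as columns", {
  x <- sim_with_carriers(n = 30000, seed = 37, rr1 = 12)
  grid <- run_all_associations(x$sim$cohort, x$carr, c("g1", "g2"),
                               data.frame(cancer = c("siteA", "siteB"),
                                          sex_restrict = c("both", "F")))
  expect_equal(nrow(grid), 4)
  expect_true(all(grid$p_bonferroni >= grid$p, na.rm = TRUE))
  expect_true(all(grid$sig_burden == (!is.na(grid$p) & grid$p < 1e-4))) # no row dropped
  ord <- order(grid$p)
  expect_equal(order(grid$p_bonferroni[ord]), seq_along(ord)) # monotone in raw p
})

test_that("age-at-diagnosis shift recovers an injected carrier effect", {
  set.seed(101)
  n_case <- 5000
  carrier <- rbinom(n_case, 1, 0.1) == 1
  agedx <- round(rnorm(n_case, 62, 10) - 5.7 * carrier)
  cohort <- data.frame(
    individual_id = sprintf("S%05d", 1:n_case), sex = "F", region = "a",
    status = "case", age_registration = agedx,
    n_cancer_types = 1L, case_siteA = 1L, agedx_siteA = agedx, fh_siteA = 0L)
  calls <- data.frame(individual_id = cohort$individual_id[carrier],
                      gene = "g1", variant_id = "v1", class = "P", founder = FALSE)
  carr <- collapse_carriers(calls, "g1", roster = cohort$individual_id)
  sh <- age_at_diagnosis_shift(cohort, carr, "g1", "siteA")
  expect_false(sh$gated)
  expect_lt(abs(sh$diff - (-5.7)), 0.5)
  expect_lt(sh$p, 0.001)
  expect_lt(abs(sh$p - sh$p_welch), 0.05)
  # equal age distributions give a difference near zero
  cohort0 <- cohort
  cohort0$agedx_siteA <- 60L
  sh0 <- age_at_diagnosis_shift(cohort0, carr, "g1", "siteA")
  expect_equal(sh0$diff, 0)
  # a single carrier gates the computation
  calls1 <- calls[1, ]
  carr1 <- collapse_carriers(calls1, "g1", roster = cohort$individual_id)
  sh1 <- age_at_diagnosis_shift(cohort, carr1, "g1", "siteA")
  expect_true(sh1$gated)
})

test_that("both designs agree on the effect direction when the effect is real", {
  agree <- vapply(1:20, function(s) {
    cfg <- calibration_config(n = 15000, carrier_freq = 0.015, rr = 3,
                              lifetime_risk = 0.10, seed = s)
    sim <- simulate_cohort(cfg)
    carr <- collapse_carriers(sim$calls, "gene1", roster = sim$cohort$individual_id)
    a <- run_association(sim$cohort, carr, "gene1", "site1", "all_patients")
    b <- run_association(sim$cohort, carr, "gene1", "site1", "no_family_history")
    # all_patients withholds beta; refit to compare signs via the frame
    d <- pvburden:::build_assoc_frame(sim$cohort, carr, "gene1", "site1", "all_patients")
    fa <- wald_carrier(fit_logistic(d$.y, d$.carrier, data.frame(age = d$.age)))
    (!b$gated) && sign(fa$beta) == sign(b$beta)
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})
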