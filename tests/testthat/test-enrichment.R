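make_regional_cohort <- function(n_per_region, carrier_per_region,
                                 founder_extra = 0) {
  # builds a cohort of cases plus a matching carrier/call set;
  # founder_extra adds founder-variant carriers to the first region
  regions <- names(n_per_region)
  rows <- list(); calls <- list(); k <- 0
  for (r in regions) {
    n <- n_per_region[[r]]; nc <- carrier_per_region[[r]]
    ids <- sprintf("R%s%04d", r, seq_len(n))
    rows[[r]] <- data.frame(individual_id = ids, sex = "F", region = r,
                            status = "case", age_registration = 60,
                            n_cancer_types = 1L, case_siteA = 1L,
                            agedx_siteA = 55L, fh_siteA = 0L)
    if (nc > 0) {
      calls[[paste0(r, "bg")]] <- data.frame(
        individual_id = ids[seq_len(nc)], gene = "g1",
        variant_id = "g1_rare", class = "P", founder = FALSE)
    }
    if (r == regions[1] && founder_extra > 0) {
      calls[[paste0(r, "f")]] <- data.frame(
        individual_id = ids[nc + seq_len(founder_extra)], gene = "g1",
        variant_id = "g1_founder", class = "P", founder = TRUE)
    }
  }
  cohort <- do.call(rbind, rows)
  calls <- do.call(rbind, calls)
  carr <- collapse_carriers(calls, "g1", roster = cohort$individual_id)
  list(cohort = cohort, calls = calls, carr = carr)
}

test_that("identical regional proportions give a null chi-square", {
  x <- make_regional_cohort(c(a = 500, b = 500, c = 500),
                            c(a = 5, b = 5, c = 5))
  bd <- regional_breakdown(x$cohort, x$carr, x$calls, "g1")
  res <- regional_chisq(bd)
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_equal(res$p, 1, tolerance = 1e-10)
  expect_equal(attr(bd, "fold_difference"), 1)
})

test_that("founder-driven regional heterogeneity disappears when founders are excluded", {
  sizes <- c(a = 2000, b = 2000, c = 2000, d = 2000, e = 2000, f = 2000, g = 2000)
  bgs <- c(a = 10, b = 10, c = 10, d = 10, e = 10, f = 10, g = 10)
  x <- make_regional_cohort(sizes, bgs, founder_extra = 40) # 5x proportion in region a
  bd <- regional_breakdown(x$cohort, x$carr, x$calls, "g1")
  expect_gt(attr(bd, "fold_difference"), 4)
  with_f <- regional_chisq(bd)
  expect_lt(with_f$p, 0.001)
  no_f <- regional_chisq(bd, exclude_founders = TRUE)
  expect_gt(no_f$p, 0.1)
  # cross-check the significant table against a Monte-Carlo permutation p
  mc <- stats::chisq.test(with_f$table, simulate.p.value = TRUE, B = 5000)
  expect_lt(mc$p.value, 0.01)
})

test_that("the 2x2 chi-square equals the classical closed form", {
  x <- make_regional_cohort(c(a = 300, b = 200), c(a = 24, b = 6))
  bd <- regional_breakdown(x$cohort, x$carr, x$calls, "g1")
  res <- regional_chisq(bd)
  a <- 24; b <- 300 - 24; c_ <- 6; d <- 200 - 6; N <- 500
  closed <- (a * d - b * c_)^2 * N / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  expect_equal(res$statistic, closed, tolerance = 1e-10)
  # relabeling regions leaves the statistic unchanged
  x2 <- x; x2$cohort$region <- chartr("ab", "zy", x2$cohort$region)
  bd2 <- regional_breakdown(x2$cohort, x$carr, x$calls, "g1")
  expect_equal(regional_chisq(bd2)$statistic, res$statistic)
})

test_that("family-history profile counts distinct reported cancer types", {
  cohort <- data.frame(individual_id = c("A", "B", "C"),
                       fh_siteA = c(0L, 1L, 1L), fh_siteB = c(0L, 0L, 1L),
                       fh_siteC = c(0L, 0L, 1L))
  pr <- fh_profile(cohort, c("siteA", "siteB", "siteC"))
  expect_equal(pr$fh_count, c(0, 1, 3))
  expect_equal(as.character(pr$fh_category), c("0", "1", "2+"))
  expect_error(fh_profile(cohort, "siteX"), "lacks family-history columns")
})

test_that("the trend statistic is null, signed and antisymmetric", {
  cat3 <- factor(rep(c("0", "1", "2+"), c(600, 300, 100)),
                 levels = c("0", "1", "2+"), ordered = TRUE)
  # identical carrier proportion across categories
  carrier <- unlist(lapply(c(600, 300, 100), function(n)
    rep(c(TRUE, FALSE), c(n / 20, n - n / 20))))
  res <- fh_trend(carrier, cat3)
  expect_lt(abs(res$z), 1e-10)
  # a strong increasing trend is highly significant and positive
  carrier2 <- c(rep(c(TRUE, FALSE), c(6, 594)), rep(c(TRUE, FALSE), c(15, 285)),
                rep(c(TRUE, FALSE), c(20, 80)))
  res2 <- fh_trend(carrier2, cat3)
  expect_gt(res2$z, 0)
  expect_lt(res2$p, 0.001)
  # reversing category order flips the sign
  rev_cat <- factor(as.character(cat3), levels = c("2+", "1", "0"))
  lv <- c("0", "1", "2+")[match(as.character(rev_cat), c("2+", "1", "0"))]
  res3 <- fh_trend(carrier2, factor(lv, levels = c("0", "1", "2+")))
  expect_equal(res3$z, -res2$z, tolerance = 1e-10)
  expect_error(fh_trend(logical(0), factor(character(), levels = c("0", "1", "2+"))),
               "empty")
})

test_that("the trend statistic matches prop.trend.test and the two-group z-test", {
  cat3 <- factor(rep(c("0", "1", "2+"), c(1000, 300, 50)),
                 levels = c("0", "1", "2+"), ordered = TRUE)
  carrier <- c(rep(c(TRUE, FALSE), c(10, 990)), rep(c(TRUE, FALSE), c(15, 285)),
               rep(c(TRUE, FALSE), c(10, 40)))
  res <- fh_trend(carrier, cat3)
  pt <- stats::prop.trend.test(c(10, 15, 10), c(1000, 300, 50), score = 0:2)
  expect_equal(res$z^2, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(res$p, pt$p.value, tolerance = 1e-10)
  expect_lt(res$p, 0.001)
  # with the third category empty it reduces to the two-sample proportion z
  cat2 <- factor(rep(c("0", "1"), c(400, 200)), levels = c("0", "1", "2+"))
  carrier2 <- c(rep(c(TRUE, FALSE), c(8, 392)), rep(c(TRUE, FALSE), c(12, 188)))
  res2 <- fh_trend(carrier2, cat2)
  pz <- suppressWarnings(stats::prop.test(c(8, 12), c(400, 200), correct = FALSE))
  expect_equal(res2$z^2, unname(pz$statistic), tolerance = 1e-10)
})

test_that("family-history cross-tabulation uses exact tests with grid Bonferroni", {
  # single 2x2: 3/7 carriers among FH-positive vs 10/190 among FH-negative
  cohort <- data.frame(
    individual_id = sprintf("T%03d", 1:200), sex = "F", region = "a",
    status = "case", age_registration = 60, n_cancer_types = 1L,
    case_siteA = 1L, agedx_siteA = 55L,
    fh_siteA = rep(c(1L, 0L), c(10, 190)))
  carrier_ids <- c(sprintf("T%03d", 1:3), sprintf("T%03d", 11:20))
  calls <- data.frame(individual_id = carrier_ids, gene = "g1",
                      variant_id = "v", class = "P", founder = FALSE)
  carr <- collapse_carriers(calls, "g1", roster = cohort$individual_id)
  xt <- fh_cross_tab(cohort, carr, "g1", "siteA")
  expect_equal(xt$carriers_fh, 3)
  expect_equal(xt$n_fh, 10)
  # hypergeometric tail oracle for the one-table Fisher p
  m <- 13; n_ <- 187; k <- 10
  probs <- stats::dhyper(0:10, m, n_, k)
  p_oracle <- sum(probs[probs <= stats::dhyper(3, m, n_, k) * (1 + 1e-7)])
  expect_equal(xt$p_fisher, p_oracle, tolerance = 1e-8)
  expect_equal(xt$p_bonferroni, min(1, xt$p_fisher * 1))
  # a 7x7 grid carries a Bonferroni factor of 49
  sim <- simulate_cohort(tiny_config(n = 8000, seed = 41))
  carr2 <- collapse_carriers(sim$calls, c("g1", "g2"),
                             roster = sim$cohort$individual_id)
  grid <- fh_cross_tab(sim$cohort, carr2, "g1", c("siteA", "siteB"))
  expect_equal(nrow(grid), 4)
  expect_equal(grid$p_bonferroni, pmin(1, grid$p_fisher * 4))
})

test_that("cohort summary aggregates deterministically", {
  sim <- simulate_cohort(tiny_config(n = 10000, seed = 43,
                                     multi_primary_target = 0.063))
  carr <- collapse_carriers(sim$calls, c("g1", "g2"),
                            roster = sim$cohort$individual_id)
  s <- summarize_cohort(sim$cohort, carr)
  co <- sim$cohort
  i <- co$case_siteA == 1
  expect_equal(s$by_cancer$n_total[s$by_cancer$cancer == "siteA"], sum(i))
  expect_equal(s$by_cancer$agedx_mean[s$by_cancer$cancer == "siteA"],
               round(mean(co$agedx_siteA[i]), 1))
  expect_equal(s$by_cancer$pct_fh_same[s$by_cancer$cancer == "siteA"],
               round(100 * mean(co$fh_siteA[i] == 1), 1))
  pats <- co$status == "case"
  expect_equal(s$overall$pct_multi_primary,
               round(100 * mean(co$n_cancer_types[pats] >= 2), 1))
  # age-band carrier counts conserve the overall carrier count
  ab <- s$carriers_by_ageband
  g1 <- ab[ab$gene == "g1", ]
  m <- match(co$individual_id[pats], carr$individual_id)
  expect_equal(sum(g1$carriers), sum(carr$carrier_g1[m]))
  expect_equal(sum(g1$n), sum(pats))
  expect_equal(sum(g1$prop * g1$n), sum(carr$carrier_g1[m]), tolerance = 1e-10)
  # an SD over a single case is emitted as missing
  one <- data.frame(individual_id = "Z1", sex = "F", region = "a",
                    status = "case", age_registration = 60,
                    n_cancer_types = 1L, case_siteA = 1L, agedx_siteA = 50L,
                    fh_siteA = 0L)
  s1 <- summarize_cohort(one)
  expect_true(is.na(s1$by_cancer$agedx_sd))
  expect_equal(s1$by_cancer$agedx_mean, 50)
})
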