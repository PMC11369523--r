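md <- data.frame(
  participant_id = c("A", "B", "C", "D", "E", "F"),
  age = c(62, 67, 72, 77, 82, 72),
  sex = c("male", "female", "male", "female", "male", "female"),
  cohort = c("healthy", "MCI", "ADRD", "healthy", "missing", "MCI"),
  mmse_total = c(28, 27, 20, 30, 25, 28),
  ravlt_total = c(50, 35, 20, 55, 30, 40),
  ravlt_long_delay = c(8, 4, 1, 10, 3, 6),
  faq_total = c(0, 6, 15, 5, 8, 2),
  stringsAsFactors = FALSE)

test_that("dichotomization applies the documented threshold semantics", {
  # MMSE: strictly below 28 is impaired
  mm <- dichotomize(md, "mmse")
  expect_equal(as.character(mm$label),
               c("intact", "impaired", "impaired", "intact", "impaired",
                 "intact"))
  # FAQ: >= 6 is functionally impaired (inclusive)
  fq <- dichotomize(md, "faq")
  expect_equal(as.character(fq$label),
               c("intact", "impaired", "impaired", "intact", "impaired",
                 "intact"))
  # cohort2: MCI and ADRD merge into impaired; missing stays missing
  c2 <- dichotomize(md, "cohort2")
  expect_equal(as.character(c2$label),
               c("intact", "impaired", "impaired", "intact", NA,
                 "impaired"))
  # cohort3 keeps three levels
  expect_equal(levels(dichotomize(md, "cohort3")$label),
               c("healthy", "MCI", "ADRD"))
  # RAVLT long delay: age-bucket cut, impaired strictly below
  rv <- dichotomize(md, "ravlt_long")
  cuts <- c(7, 6, 5, 3, 3, 5)
  expect_equal(as.character(rv$label),
               ifelse(md$ravlt_long_delay < cuts, "impaired", "intact"))
  expect_error(dichotomize(md, "nope"), "unknown scheme")
})

test_that("label agreement counts the 2x2 diagonal", {
  a <- dichotomize(md, "mmse")
  expect_equal(labelAgreement(a, a)$accuracy, 100)
  b <- a
  b$label <- factor(ifelse(a$label == "impaired", "intact", "impaired"),
                    levels = levels(a$label))
  expect_equal(labelAgreement(a, b)$accuracy, 0)
  # constructed 75% agreement on 100 participants
  ids <- sprintf("x%d", 1:100)
  mk <- function(lab) data.frame(participant_id = ids,
                                 label = factor(lab, c("impaired",
                                                       "intact")))
  a2 <- mk(rep(c("impaired", "intact"), c(50, 50)))
  b2 <- mk(rep(c("impaired", "intact", "impaired"), c(50, 25, 25)))
  ag <- labelAgreement(a2, b2)
  expect_equal(ag$accuracy, 75)
  expect_equal(ag$n, 100)
})

test_that("signed-rank test flags a uniform decrement and degenerates to p=1", {
  withr::with_seed(41, {
    st <- runif(50, 50, 100)
    res <- pairedConditionTest(st, st - 10)
    expect_lt(res$p_value, 0.001)
    expect_equal(res$n, 50)
  })
  expect_warning(res0 <- pairedConditionTest(1:10, 1:10), "degenerate")
  expect_equal(res0$p_value, 1)
})

test_that("signed-rank p matches exhaustive sign-flip enumeration at n=8", {
  st <- c(12, 9, 14, 11, 16, 8, 13, 10)
  dt <- c(11, 4, 15.5, 8.2, 9, 8.7, 5, 3.5)   # distinct |differences|
  res <- pairedConditionTest(st, dt)
  d <- st - dt
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  # enumerate all 2^8 sign assignments of the ranked magnitudes
  Ws <- vapply(0:(2^8 - 1), function(m) {
    signs <- as.integer(intToBits(m))[1:8]
    sum(rk[signs == 1])
  }, numeric(1))
  p_exact <- mean(abs(Ws - mean(Ws)) >= abs(W - mean(Ws)))
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
})

test_that("rank-sum test detects shifted groups and matches enumeration", {
  withr::with_seed(42, {
    a <- rnorm(60); b <- rnorm(60) + 1
    expect_lt(groupDifferenceTest(a, b)$p_value, 0.01)
  })
  expect_error(groupDifferenceTest(numeric(0), 1:3), "non-empty")
  # n = 5 vs 5 integers (no ties): exact enumeration over C(10,5) splits
  x <- c(3, 8, 1, 9, 12); y <- c(5, 2, 11, 4, 7)
  res <- groupDifferenceTest(x, y)
  pooled <- c(x, y)
  rks <- rank(pooled)
  Wobs <- sum(rks[1:5]) - 5 * 6 / 2          # Mann-Whitney U of group x
  combos <- combn(10, 5)
  Us <- apply(combos, 2, function(ix) sum(rks[ix]) - 15)
  p_exact <- mean(abs(Us - mean(Us)) >= abs(Wobs - mean(Us)))
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
})

test_that("rank tests are invariant under strictly monotone transforms", {
  withr::with_seed(43, {
    a <- rlnorm(30); b <- rlnorm(30) * 1.5
    expect_equal(groupDifferenceTest(a, b)$p_value,
                 groupDifferenceTest(log(a), log(b))$p_value)
    st <- runif(20, 1, 2); dt <- st * runif(20, 0.7, 1.1)
    expect_equal(spearmanAssoc(st, dt)$statistic,
                 spearmanAssoc(exp(st), dt^3)$statistic)
  })
})

test_that("Spearman association handles monotone, reversed and hand-ranked data", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearmanAssoc(x, x^3)$statistic, 1)
  expect_equal(spearmanAssoc(x, -x)$statistic, -1)
  # 6-point table: rho from the rank correlation computed by hand
  f <- c(2.3, 1.1, 5.2, 3.3, 4.1, 0.4)
  s <- c(21, 25, 10, 18, 12, 26)
  rho_hand <- cor(rank(f), rank(s))
  expect_equal(spearmanAssoc(f, s)$statistic, rho_hand, tolerance = 1e-12)
  expect_true(is.na(spearmanAssoc(rep(1, 6), x)$statistic))
  expect_error(spearmanAssoc(1:3, 1:3), "5 complete pairs")
})

test_that("age-adjusted ANCOVA reduces to t^2 when age is orthogonal", {
  withr::with_seed(44, {
    n <- 40
    grp <- factor(rep(c("impaired", "intact"), each = n / 2))
    age <- rep(seq(60, 80, length.out = n / 2), 2)   # identical per group
    # noise orthogonalized against {1, age, group}: age then explains
    # exactly nothing and the nested F is the two-sample t^2 up to the
    # residual-df ratio
    eps <- residuals(lm(rnorm(n) ~ age + grp))
    y <- eps + (grp == "impaired") * 0.8
    res <- ancovaCohort(y, grp, age)
    tt <- t.test(y ~ grp, var.equal = TRUE)
    expect_equal(res$statistic,
                 unname(tt$statistic^2) * (n - 3) / (n - 2),
                 tolerance = 1e-8)
  })
})

test_that("ANCOVA group term is powered under a 1-SD offset at n=300", {
  withr::with_seed(45, {
    n <- 300
    age <- runif(n, 60, 85)
    grp <- factor(sample(c("impaired", "intact"), n, replace = TRUE))
    y <- 0.05 * age + rnorm(n) + (grp == "impaired") * 1
    expect_lt(ancovaCohort(y, grp, age)$p_value, 0.01)
  })
})

test_that("collinear designs are refused with a named term", {
  grp <- factor(rep(c("impaired", "intact"), each = 10))
  age <- as.numeric(grp == "impaired")          # perfectly collinear
  expect_error(ancovaCohort(rnorm(20), grp, age), "collinear")
})

test_that("FAQ independence adjusts for the cognitive covariate and age", {
  withr::with_seed(46, {
    n <- 300
    age <- runif(n, 60, 85)
    mmse <- pmin(30, round(rnorm(n, 27, 2)))
    faq <- factor(sample(c("impaired", "intact"), n, replace = TRUE))
    # feature depends on FAQ beyond mmse and age
    y <- 0.1 * mmse + 0.02 * age + rnorm(n) + (faq == "impaired") * 0.8
    expect_lt(faqIndependence(y, faq, mmse, age)$p_value, 0.01)
    expect_error(faqIndependence(y, faq, NULL, age), "covariate")
  })
})

test_that("tidy report carries raw and BH-adjusted p-values per family", {
  cc <- defaultCohortConfig(n_per_cohort = c(healthy = 3, MCI = 3,
                                             ADRD = 3),
                            n_missing_label = 0, seed = 88)
  ch <- simulateCohort(cc)
  ft <- buildFeatureTable(ch$sessions, ch$metadata)
  rep_df <- statsReport(ft, features = c("pct_time_in_circle",
                                         "rms_accel"))
  expect_true(all(rep_df$p_value >= 0 & rep_df$p_value <= 1, na.rm = TRUE))
  expect_true(all(rep_df$p_adjusted >= rep_df$p_value - 1e-12,
                  na.rm = TRUE))
  expect_true(all(c("signed_rank", "rank_sum", "ancova_age", "spearman",
                    "faq_independence") %in% rep_df$test))
  # one signed-rank row per feature
  expect_equal(sum(rep_df$test == "signed_rank"), 2)
})
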