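test_that("Mann-Whitney p-values match enumeration on worked examples", {
  # C(4,2) = 6 assignments; the observed split is the most extreme
  expect_equal(mann_whitney_p(c(1, 2), c(3, 4)), 2 / 6, tolerance = 1e-12)
  # identical samples carry no rank separation
  expect_equal(mann_whitney_p(c(1, 2, 3), c(1, 2, 3)), 1)
  # rank statistic: invariant under strictly increasing transforms
  set.seed(2)
  x <- rnorm(5); y <- rnorm(6)
  expect_equal(mann_whitney_p(x, y), mann_whitney_p(exp(x), exp(y)))
  expect_error(mann_whitney_p(numeric(0), 1:3), "non-empty")
})

test_that("exact path agrees with wilcox.test on tie-free data", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(mann_whitney_p(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("normal approximation stays within 0.05 of enumeration", {
  set.seed(4)
  for (i in 1:25) {
    x <- rnorm(5)
    y <- rnorm(6) + sample(0:2, 1)
    p_ex <- mann_whitney_p(x, y)
    p_ap <- mann_whitney_p(x, y, exact = FALSE)
    expect_lt(abs(p_ex - p_ap), 0.05)
  }
  # the approximation degrades gracefully under ties but stays a p-value
  set.seed(14)
  for (i in 1:10) {
    x <- sample(1:4, 5, replace = TRUE)
    y <- sample(1:4, 6, replace = TRUE)
    p <- mann_whitney_p(x, y, exact = FALSE)
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("Holm step-down matches the from-definition procedure", {
  hb <- holm_bonferroni(0.04)
  expect_true(hb$reject)
  expect_equal(hb$adjusted, 0.04)

  hb2 <- holm_bonferroni(c(0.01, 0.04))
  expect_true(all(hb2$reject))

  expect_false(any(holm_bonferroni(rep(1, 10))$reject))

  # family of m tests all at alpha/(2m) is fully rejected
  m <- 20
  expect_true(all(holm_bonferroni(rep(0.05 / (2 * m), m))$reject))

  set.seed(5)
  for (i in 1:30) {
    p <- runif(sample(2:40, 1))^2
    hb <- holm_bonferroni(p)
    o <- oracle_holm(p)
    expect_equal(hb$adjusted, o$adjusted, tolerance = 1e-12)
    expect_identical(hb$reject, o$reject)
    # uniformly more powerful than Bonferroni; rejections monotone in p
    expect_true(all(hb$reject | !(p.adjust(p, "bonferroni") <= 0.05)))
    if (any(hb$reject)) {
      expect_lte(max(p[hb$reject]), min(c(p[!hb$reject], Inf)))
    }
  }
  expect_error(holm_bonferroni(c(0.5, 0)), "0, 1")
})

test_that("screening flags structure, nulls and injected separation", {
  # small synthetic feature table: 2 features x 1 status x 3 orders
  set.seed(6)
  make_tbl <- function() {
    grid <- expand.grid(subject_id = sprintf("S%02d", 1:8),
                        condition = c("BE", "E1", "E2", "E3"),
                        feature = c("energy", "entropy"),
                        status = "filtered", order = 0:2,
                        stringsAsFactors = FALSE)
    grid$value <- rnorm(nrow(grid))
    grid
  }
  tbl <- make_tbl()
  # constant cell across conditions -> p = 1 everywhere in that row
  tbl$value[tbl$feature == "energy" & tbl$order == 0] <- 7
  # strong injected separation at (entropy, order 2)
  sep <- tbl$feature == "entropy" & tbl$order == 2 & tbl$condition != "BE"
  tbl$value[sep] <- tbl$value[sep] + 10

  sc <- screen_features(tbl)
  expect_s3_class(sc, "ppg_screening")
  expect_equal(nrow(sc), 6)
  null_row <- sc[sc$feature == "energy" & sc$order == 0, ]
  expect_equal(unlist(null_row[, c("p1", "p2", "p3")]),
               c(p1 = 1, p2 = 1, p3 = 1))
  sep_row <- sc[sc$feature == "entropy" & sc$order == 2, ]
  expect_lt(sep_row$p_mean, stats::median(sc$p_mean))
  expect_true(sep_row$block_min_pmean)
  expect_equal(sc$p_mean, (sc$p1 + sc$p2 + sc$p3) / 3)
  # rejection monotonicity across the Holm family
  ps <- unlist(sc[, c("p1", "p2", "p3")])
  rej <- unlist(sc[, c("reject1", "reject2", "reject3")])
  if (any(rej) && any(!rej)) expect_lt(max(ps[rej]), min(ps[!rej]) + 1e-12)

  expect_error(screen_features(tbl[tbl$condition == "BE", ]), "stress")
})

test_that("orders_1_20 family leaves order-0 rows uncorrected", {
  coh <- generate_cohort(small_config(n_subjects = 5, seed = 19))
  ft <- cohort_features(coh, max_order = 2)
  sc <- screen_features(ft, family = "orders_1_20")
  expect_true(all(is.na(sc$holm_p1[sc$order == 0])))
  expect_true(all(!is.na(sc$holm_p1[sc$order >= 1])))
})
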