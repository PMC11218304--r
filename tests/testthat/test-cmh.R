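test_that("single-stratum support of size two gives the uniform p of 1", {
  # margins 10/10 with one carrier: S in {0,1}, each with mass 0.5
  tab <- tibble(a = 1, b = 9, c = 0, d = 10)
  fit <- exact_cmh(tab)
  expect_equal(fit$p.value, 1)
  expect_false(fit$untestable)
})

test_that("tables with no carriers anywhere are untestable with p = 1", {
  tab <- tibble(a = c(0, 0), b = c(10, 20), c = c(0, 0), d = c(15, 25))
  fit <- exact_cmh(tab)
  expect_equal(fit$p.value, 1)
  expect_true(fit$untestable)
})

test_that("exact CMH equals full enumeration over margin-fixed configurations", {
  withr::local_seed(101)
  for (i in 1:120) {
    tab <- random_strat_table(sample(1:3, 1))
    expect_lt(abs(exact_cmh(tab)$p.value - enum_cmh_p(tab)), 1e-12)
  }
})

test_that("single-stratum exact CMH is the two-sided Fisher probability-mass test", {
  withr::local_seed(202)
  for (i in 1:60) {
    tab <- random_strat_table(1, max_m = 15)
    m <- matrix(c(tab$a, tab$b, tab$c, tab$d), 2, byrow = TRUE)
    expect_equal(exact_cmh(tab)$p.value, fisher.test(m)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("multi-stratum exact CMH matches the independent exact implementation in stats", {
  withr::local_seed(303)
  for (i in 1:40) {
    K <- sample(2:4, 1)
    tab <- random_strat_table(K)
    arr <- array(0, c(2, 2, K))
    for (s in 1:K) {
      arr[, , s] <- matrix(c(tab$a[s], tab$c[s], tab$b[s], tab$d[s]), 2)
    }
    expect_equal(exact_cmh(tab)$p.value,
                 stats::mantelhaen.test(arr, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("p is invariant to stratum order, label swap, and empty strata", {
  withr::local_seed(404)
  for (i in 1:25) {
    tab <- random_strat_table(3)
    p0 <- exact_cmh(tab)$p.value
    # reorder strata
    expect_equal(exact_cmh(tab[c(3, 1, 2), ])$p.value, p0)
    # swap case<->control together with carrier<->non-carrier
    swapped <- tibble(a = tab$d, b = tab$c, c = tab$b, d = tab$a)
    expect_equal(exact_cmh(swapped)$p.value, p0, tolerance = 1e-12)
    # append a stratum with no carriers in either arm
    padded <- bind_rows(tab, tibble(unit = "u", cluster = "cl9",
                                    a = 0, b = 7, c = 0, d = 9))
    expect_equal(exact_cmh(padded)$p.value, p0, tolerance = 1e-12)
    expect_equal(unname(exact_cmh(padded)$estimate),
                 unname(exact_cmh(tab)$estimate))
  }
})

test_that("MH pooled odds ratio follows the stratum-weighted formula", {
  one <- tibble(a = 4, b = 6, c = 1, d = 9)
  expect_equal(unname(exact_cmh(one)$estimate), 6)         # ad/bc
  two <- bind_rows(one, one)
  expect_equal(unname(exact_cmh(two)$estimate), 6)         # replication-invariant
  # all-control-zero carriers: +Inf with undefined CI
  zc <- tibble(a = c(3, 2), b = c(7, 8), c = c(0, 0), d = c(10, 10))
  fit <- exact_cmh(zc)
  expect_identical(unname(fit$estimate), Inf)
  expect_true(all(is.na(fit$conf.int)))
  # no carriers at all: undefined
  expect_true(is.na(mh_odds_ratio(tibble(a = 0, b = 5, c = 0, d = 5))$or))
})

test_that("RBG confidence interval brackets the point estimate and shrinks with data", {
  tab <- tibble(a = 30, b = 70, c = 10, d = 90)
  or <- mh_odds_ratio(tab)
  expect_true(or$ci_low < or$or && or$or < or$ci_high)
  bigger <- tibble(a = 300, b = 700, c = 100, d = 900)
  or2 <- mh_odds_ratio(bigger)
  expect_lt(or2$ci_high / or2$ci_low, or$ci_high / or$ci_low)
  expect_equal(or$or, or2$or)
})

test_that("log-space convolution keeps extreme tails exact", {
  # strong imbalance across many strata drives p far below double's
  # naive-summation comfort zone; compare against the log-space sum of the
  # lower tail computed directly per stratum (independence)
  K <- 12
  tab <- tibble(a = rep(9, K), b = rep(91, K), c = rep(0, K),
                d = rep(300, K))
  fit <- exact_cmh(tab)
  expect_gt(fit$p.value, 0)
  expect_lt(fit$p.value, 1e-30)
  # observed total is the maximum of the support: its two-sided p equals
  # P(S = s_max) + mass of any points with smaller probability; the
  # extreme point mass itself is prod of per-stratum extreme masses
  lp_max <- K * dhyper(9, 100, 300, 9, log = TRUE)
  expect_gte(log(fit$p.value), lp_max - 1e-6)
})

test_that("large-margin exact p agrees with the continuity-corrected chi-square CMH", {
  withr::local_seed(505)
  arr <- array(0, c(2, 2, 3))
  tab <- tibble(a = c(40, 35, 25), b = c(960, 965, 975),
                c = c(30, 20, 15), d = c(1970, 1980, 1985))
  for (s in 1:3) {
    arr[, , s] <- matrix(c(tab$a[s], tab$c[s], tab$b[s], tab$d[s]), 2)
  }
  p_exact <- exact_cmh(tab)$p.value
  p_asym <- stats::mantelhaen.test(arr, correct = TRUE)$p.value
  expect_lt(abs(log10(p_exact) - log10(p_asym)) / abs(log10(p_asym)), 0.1)
})

test_that("doubled one-tail alternative is valid and never below the one-tail", {
  tab <- tibble(a = c(5, 3), b = c(45, 47), c = c(1, 0), d = c(99, 100))
  pm <- exact_cmh(tab)$p.value
  dbl <- exact_cmh(tab, alternative = "doubled")$p.value
  expect_lte(dbl, 1)
  expect_gt(dbl, 0)
  # probability-mass p never exceeds the doubled p by more than ties allow
  expect_lte(pm, min(1, dbl * (1 + 1e-7)))
})

test_that("significance flagging uses p <= alpha with the study-wide default", {
  res <- tibble(unit = c("g1", "g2", "g3"),
                p_value = c(4.88e-7, 5.0e-7, 1e-10))
  flagged <- apply_significance(res)
  expect_identical(flagged$significant, c(TRUE, FALSE, TRUE))
  expect_identical(nrow(apply_significance(res[0, ])), 0L)
})

test_that("cmh_scan sorts by p and carries counts and strata", {
  withr::local_seed(606)
  strat <- bind_rows(
    random_strat_table(2) |> mutate(unit = "g1"),
    random_strat_table(3) |> mutate(unit = "g2"),
    random_strat_table(1) |> mutate(unit = "g3")
  )
  res <- cmh_scan(strat, alpha = 0.05)
  expect_identical(nrow(res), 3L)
  expect_true(!is.unsorted(res$p_value))
  expect_setequal(res$n_strata, c(2L, 3L, 1L))
  for (u in res$unit) {
    sub <- filter(strat, unit == u)
    expect_equal(res$p_value[res$unit == u], exact_cmh(sub)$p.value)
    expect_equal(res$case_carriers[res$unit == u], sum(sub$a))
  }
})

test_that("attainable alpha is the null mass of the rejection region", {
  tab <- tibble(unit = "u", a = 4, b = 96, c = 1, d = 199)
  att <- cmh_attainable_alpha(tab, alpha = 0.05)$attainable_alpha
  pmf <- rarecollapse:::cmh_pmf(100, 200, 5)
  pt <- rarecollapse:::cmh_p_table(pmf)
  expect_equal(att, sum(exp(pmf$logp)[pt <= 0.05]))
  expect_lte(att, 0.05 + 1e-12)
})

test_that("tidy and glance summarise a CMH fit", {
  fit <- exact_cmh(tibble(a = 4, b = 6, c = 1, d = 9))
  td <- tidy(fit)
  expect_identical(nrow(td), 1L)
  expect_equal(td$estimate, 6)
  expect_equal(td$p.value, fit$p.value)
  gl <- glance(fit)
  expect_identical(gl$n_strata, 1L)
})
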