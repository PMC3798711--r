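test_that("two-tailed Fisher reproduces the study's printed p-values", {
  # haplogroup L2: 8 of 22 cases vs 4 of 22 controls
  expect_equal(round(fisher_exact_two_tailed(c(8, 14, 4, 18)), 2), 0.31)
  # identical rows
  expect_equal(fisher_exact_two_tailed(c(5, 17, 5, 17)), 1)
  # novel nonsynonymous carriers, 1/22 vs 14/27 (prior-study comparison):
  # the exact two-tailed value rounds to the printed 4e-4 bound
  p <- fisher_exact_two_tailed(c(1, 21, 14, 13))
  expect_lt(p, 5e-4)
  expect_equal(round(p, 4), 4e-4)
  # novel transversion carriers, 0/22 vs 17/27
  expect_lt(fisher_exact_two_tailed(c(0, 22, 17, 10)), 1e-4)
})

test_that("Fisher matches the enumeration oracle over all margins <= 30", {
  withr::with_seed(42L, {
    for (rep in 1:200) {
      n1 <- sample(0:30, 1); n2 <- sample(0:30, 1)
      if (n1 + n2 == 0) next
      a <- if (n1 > 0) sample(0:n1, 1) else 0L
      c_ <- if (n2 > 0) sample(0:n2, 1) else 0L
      tab <- c(a, n1 - a, c_, n2 - c_)
      expect_equal(fisher_exact_two_tailed(tab),
                   fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                   tolerance = 1e-9)
    }
  })
})

test_that("Fisher is invariant under row and column swaps", {
  withr::with_seed(9L, {
    for (rep in 1:25) {
      tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        p <- fisher_exact_two_tailed(tab)
        expect_equal(fisher_exact_two_tailed(tab[2:1, ]), p)
        expect_equal(fisher_exact_two_tailed(tab[, 2:1]), p)
      }
    }
  })
  expect_equal(fisher_exact_two_tailed(c(0, 0, 3, 4)), 1)  # degenerate row
})

test_that("modified-Wald CIs reproduce the five printed intervals", {
  pct <- function(ci) {
    c(sign(ci$lower) * floor(abs(100 * ci$lower) + 0.5),
      sign(ci$upper) * floor(abs(100 * ci$upper) + 0.5))
  }
  expect_equal(pct(modified_wald_ci(4, 44)), c(3, 22))   # 9.1% (3% to 22%)
  expect_equal(pct(modified_wald_ci(3, 22)), c(4, 34))   # 13.6% (4% to 34%)
  ci1 <- modified_wald_ci(1, 22)                         # <0.01% to 24%
  expect_true(ci1$clipped_low)
  expect_equal(pct(ci1)[2], 24)
  ci0 <- modified_wald_ci(0, 22)                         # 0% to 18%
  expect_equal(ci0$lower, 0)
  expect_equal(pct(ci0)[2], 18)
  ci144 <- modified_wald_ci(1, 44)                       # <0.01% to 13%
  expect_true(ci144$clipped_low)
  expect_equal(pct(ci144)[2], 13)
  expect_error(modified_wald_ci(5, 4), "0 <= x <= n")
})

test_that("modified-Wald intervals behave as intervals should", {
  # width shrinks monotonically in n at fixed x/n
  widths <- vapply(c(20, 40, 80, 160, 320), function(n) {
    ci <- modified_wald_ci(n / 4, n)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # interval contains the adjusted center; bounds in [0, 1]
  withr::with_seed(13L, {
    for (rep in 1:50) {
      n <- sample(1:200, 1); x <- sample(0:n, 1)
      ci <- modified_wald_ci(x, n)
      expect_gte(ci$adjusted_center, ci$lower)
      expect_lte(ci$adjusted_center, ci$upper)
      expect_gte(ci$lower, 0); expect_lte(ci$upper, 1)
      expect_lte(ci$lower, ci$upper)
    }
  })
  # clipped lower bound with a positive point estimate renders as <0.01%
  expect_match(format_ci(modified_wald_ci(1, 22)), "<0.01%")
})

test_that("Welch t from summaries reproduces the clinical-table statistics", {
  # maximum IOP OD: 26 (6.2) vs 17 (2.8), both n = 22
  iop <- two_sample_t_from_summary(26, 6.2, 22, 17, 2.8, 22)
  expect_equal(round(iop$t, 1), 6.2)
  expect_lt(iop$p_value, 1e-4)
  # age at enrollment: 69 (12) vs 66 (11)
  age <- two_sample_t_from_summary(69, 12, 22, 66, 11, 22)
  expect_equal(round(age$t, 2), 0.86)
  expect_gt(age$p_value, 0.05)
  # identical summaries
  expect_equal(two_sample_t_from_summary(5, 1, 10, 5, 1, 10)$t, 0)
  # antisymmetry
  a <- two_sample_t_from_summary(26, 6.2, 22, 17, 2.8, 22)
  b <- two_sample_t_from_summary(17, 2.8, 22, 26, 6.2, 22)
  expect_equal(a$t, -b$t)
  expect_equal(a$df, b$df)
  # zero variance, unequal means
  z <- two_sample_t_from_summary(5, 0, 10, 4, 0, 10)
  expect_true(z$infinite)
})

test_that("ts:tv ratios label the observed spectrum", {
  cases <- tstv_ratio(1093, 41)
  expect_equal(cases$label, "27:1")
  expect_equal(round(cases$ratio, 2), 26.66)
  controls <- tstv_ratio(979, 33)
  expect_equal(controls$label, "30:1")
  expect_equal(tstv_ratio(0, 5)$ratio, 0)
  inf <- tstv_ratio(10, 0)
  expect_true(inf$infinite)
})

test_that("variation grid conserves instance counts and computes shares", {
  sim <- default_sim()
  grid <- variation_table(sim$callsets, sim$catalog)
  expect_equal(sum(grid$n), nrow(sim$callsets))
  for (g in c("case", "control")) {
    expect_equal(sum(grid$pct[grid$group == g]), 100)
  }
  # the planted novel keys are exactly the grid's novel cells
  expect_equal(sum(grid$n[grid$novelty == "novel"]),
               sum(variant_key(sim$callsets) %in% sim$truth$novel))
  # empty cohort gives an all-zero grid
  empty <- sim$callsets[0, ]
  g0 <- variation_table(empty, sim$catalog)
  expect_true(all(g0$n == 0L))
  # previously-reported share from the published totals
  printed <- tibble::tibble(
    novelty = c("reported", "novel"),
    n = c(1146L + 1020L - 4L, 4L)
  )
  expect_equal(round(100 * reported_share(printed), 1), 99.8)
})

test_that("rarity histogram conserves observations and flags singletons", {
  sim <- default_sim()
  h <- rarity_histogram(sim$callsets)
  expect_equal(sum(h$n_observations * h$n_variants), nrow(sim$callsets))
  expect_gt(attr(h, "singleton_share"), 0.3)
  # three samples share one variant, one sample has a private variant
  toy <- tibble::tibble(
    sample = c("a", "b", "c", "a"),
    position = c(100L, 100L, 100L, 200L),
    ref = "A", alt = "G", class = "transition", allele_fraction = 1
  )
  ht <- rarity_histogram(toy)
  expect_equal(ht$n_variants[ht$n_observations == 1L], 1L)
  expect_equal(ht$n_variants[ht$n_observations == 3L], 1L)
  h0 <- rarity_histogram(toy[0, ])
  expect_equal(nrow(h0), 0L)
})

test_that("disease table means match the printed totals arithmetic", {
  sim <- default_sim()
  d <- disease_variant_table(sim$callsets, sim$catalog)
  expect_equal(unname(d$means), unname(d$totals) / c(22, 22))
  expect_equal(sum(d$table$case) + sum(d$table$control),
               sum(is_disease_associated(sim$callsets, sim$catalog)))
  # printed-totals arithmetic: 84 case instances over 22 cases
  expect_equal(round(84 / 22, 1), 3.8)
  expect_equal(round(87 / 22, 1), 4.0)
  # no disease-associated variants -> zero table
  plain <- sim$callsets[!is_disease_associated(sim$callsets, sim$catalog), ]
  d0 <- disease_variant_table(plain, sim$catalog)
  expect_equal(unname(d0$totals), c(0L, 0L))
  expect_equal(nrow(d0$table), 0L)
  # disease variants in the default simulation are all transitions
  expect_true(all(d$transversion_share == 0, na.rm = TRUE))
})
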