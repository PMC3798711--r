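test_that("simulation is deterministic in the seed", {
  c1 <- simulate_cohort(simulation_config(n_cases = 4, n_controls = 4,
                                          seed = 7L))
  c2 <- simulate_cohort(simulation_config(n_cases = 4, n_controls = 4,
                                          seed = 7L))
  expect_identical(c1$callsets, c2$callsets)
  expect_identical(c1$truth$haplogroups, c2$truth$haplogroups)
  c3 <- simulate_cohort(simulation_config(n_cases = 4, n_controls = 4,
                                          seed = 8L))
  expect_false(identical(c1$callsets, c3$callsets))
})

test_that("the default cohort matches the study's scale", {
  sim <- default_sim()
  cs <- sim$callsets
  expect_equal(length(unique(cs$sample)), 44L)
  expect_equal(length(unique(cs$sample[cs$group == "case"])), 22L)
  # total variant instances within +/-15% of the observed 2,166
  expect_gt(nrow(cs), 2166 * 0.85)
  expect_lt(nrow(cs), 2166 * 1.15)
  # pooled ts:tv of emitted variants in the plausible band around 28:1
  tab <- table(class_group <- ifelse(cs$class %in% c("insertion", "deletion"),
                                     "indel", cs$class))
  ratio <- tab[["transition"]] / tab[["transversion"]]
  expect_gt(ratio, 20); expect_lt(ratio, 40)
  # heteroplasmic fractions inside the configured range
  het <- cs[cs$state == "heteroplasmic", ]
  expect_true(all(het$allele_fraction >= 0.25 & het$allele_fraction <= 0.60))
  # all other calls are homoplasmic
  expect_true(all(cs$allele_fraction[cs$state == "homoplasmic"] == 1))
})

test_that("novel rate zero yields no novel variants", {
  sim <- simulate_cohort(simulation_config(n_cases = 6, n_controls = 6,
                                           novel_rate = 0, seed = 3L))
  expect_length(sim$truth$novel, 0L)
  expect_false(any(is_novel(sim$callsets, sim$catalog)))
})

test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(macro_weights = c(L2 = 0.5, L3 = 0.4)),
               "sum to 1")
  expect_error(simulation_config(novel_rate = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(heteroplasmy_rate = -0.1), "\\[0, 1\\]")
})

test_that("the injected error ledger matches the emitted discrepancies", {
  sim <- default_sim()
  pe <- simulate_platform_errors(sim$callsets, platform_profile(),
                                 sim$reference, seed = 11L)
  per_sample <- lapply(unique(sim$callsets$sample), function(s) {
    compare_callsets(pe$test[pe$test$sample == s, ],
                     pe$orthogonal[pe$orthogonal$sample == s, ],
                     pe$regions[[s]])
  })
  pooled <- pool_concordance(per_sample)
  led <- pe$ledger
  for (g in c("transition", "transversion", "indel")) {
    expect_equal(pooled$S[pooled$class_group == g],
                 sum(led$type == "FN" & led$class_group == g))
    expect_equal(pooled$I[pooled$class_group == g],
                 sum(led$type == "FP" & led$class_group == g))
  }
})

test_that("a zero-error profile reproduces truth on the screened region", {
  sim <- default_sim()
  quiet <- platform_profile(
    fn = c(transition = 0, transversion = 0, indel = 0),
    fp = c(transition = 0, transversion = 0, indel = 0))
  pe <- simulate_platform_errors(sim$callsets, quiet, sim$reference,
                                 seed = 2L)
  expect_equal(nrow(pe$ledger), 0L)
  s <- unique(sim$callsets$sample)[1]
  cc <- compare_callsets(pe$test[pe$test$sample == s, ],
                         pe$orthogonal[pe$orthogonal$sample == s, ],
                         pe$regions[[s]])
  expect_equal(sum(cc$S), 0L)
  expect_equal(sum(cc$I), 0L)
})

test_that("certain indel false negatives empty the test set of indels", {
  sim <- default_sim()
  harsh <- platform_profile(
    fn = c(transition = 0, transversion = 0, indel = 1),
    fp = c(transition = 0, transversion = 0, indel = 0))
  pe <- simulate_platform_errors(sim$callsets, harsh, sim$reference,
                                 seed = 2L)
  in_region <- vapply(seq_len(nrow(pe$test)), function(i) {
    s <- pe$test$sample[i]
    pe$test$position[i] %in% pe$regions[[s]]$positions
  }, logical(1))
  expect_false(any(pe$test$class[in_region] %in% c("insertion", "deletion")))
})

test_that("simulated error rates recover the configured probabilities", {
  # a larger cohort so the per-class counts support rate estimation
  big <- simulate_cohort(simulation_config(n_cases = 150, n_controls = 150,
                                           seed = 19L))
  profile <- platform_profile()
  pe <- simulate_platform_errors(big$callsets, profile, big$reference,
                                 seed = 19L)
  pooled <- pool_concordance(lapply(unique(big$callsets$sample), function(s) {
    compare_callsets(pe$test[pe$test$sample == s, ],
                     pe$orthogonal[pe$orthogonal$sample == s, ],
                     pe$regions[[s]])
  }))
  er <- error_rates(pooled)
  for (g in c("transition", "transversion", "indel")) {
    row <- er[er$class_group == g, ]
    expect_true(binom_consistent(row$S, row$S + row$B, profile$fn[[g]]))
    expect_true(binom_consistent(
      row$I, row$B, profile$fp[[g]] / (1 - profile$fp[[g]])))
  }
})

test_that("simulator writes and re-reads its call sets faithfully", {
  sim <- simulate_cohort(simulation_config(n_cases = 3, n_controls = 3,
                                           seed = 13L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calls_tsv(sim$callsets, path)
  back <- read_calls_tsv(path, sim$reference)
  expect_equal(sort(paste(back$sample, variant_key(back))),
               sort(paste(sim$callsets$sample, variant_key(sim$callsets))))
})
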