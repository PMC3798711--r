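region_fixture <- function(ref) screened_region(1000:2000, ref)

calls_fixture <- function(positions, ref_alleles, alt_alleles, sample = "s1") {
  v <- mt_variants(positions, ref_alleles, alt_alleles)
  tibble::tibble(sample = sample, position = v$position, ref = v$ref,
                 alt = v$alt, class = v$class, allele_fraction = 1)
}

test_that("identical callsets are fully concordant", {
  ref <- synthetic_ref()
  region <- region_fixture(ref)
  pos <- seq(1010L, 1100L, by = 10L)
  calls <- calls_fixture(pos, reference_base(ref, pos),
                         unname(c(A = "G", G = "A", C = "T", T = "C")[
                           reference_base(ref, pos)]))
  cc <- compare_callsets(calls, calls, region)
  expect_equal(sum(cc$B), 10L)
  expect_equal(sum(cc$S), 0L)
  expect_equal(sum(cc$I), 0L)
})

test_that("injected discordances land in the right class cells", {
  ref <- synthetic_ref()
  region <- screened_region(1:16569, ref)
  # truth has 3 tract indels that the test set misses
  truth <- rbind(
    calls_fixture(c(309L, 467L, 16260L), c("", "", ""), c("C", "C", "C")),
    calls_fixture(1500L, reference_base(ref, 1500L),
                  unname(c(A = "G", G = "A", C = "T", T = "C")[
                    reference_base(ref, 1500L)]))
  )
  test <- truth[4, ]
  cc <- compare_callsets(test, truth, region)
  expect_equal(cc$S[cc$class_group == "indel"], 3L)
  expect_equal(cc$B[cc$class_group == "transition"], 1L)
  # test has one extra transversion
  b2000 <- reference_base(ref, 2000L)
  tv_alt <- if (b2000 %in% c("A", "G")) "C" else "A"
  test2 <- rbind(test, calls_fixture(2000L, b2000, tv_alt))
  cc2 <- compare_callsets(test2, truth, region)
  expect_equal(cc2$I[cc2$class_group == "transversion"], 1L)
  # everything in the union is counted exactly once
  expect_equal(sum(cc2$S + cc2$B + cc2$I), 5L)
})

test_that("swapping test and truth swaps S and I and preserves B", {
  sim <- default_sim()
  pe <- simulate_platform_errors(sim$callsets, platform_profile(),
                                 sim$reference, seed = 3L)
  s <- unique(sim$callsets$sample)[1]
  a <- compare_callsets(pe$test[pe$test$sample == s, ],
                        pe$orthogonal[pe$orthogonal$sample == s, ],
                        pe$regions[[s]])
  b <- compare_callsets(pe$orthogonal[pe$orthogonal$sample == s, ],
                        pe$test[pe$test$sample == s, ],
                        pe$regions[[s]])
  expect_equal(a$S, b$I)
  expect_equal(a$I, b$S)
  expect_equal(a$B, b$B)
})

test_that("variants outside the screened region are ignored", {
  ref <- synthetic_ref()
  region <- region_fixture(ref)
  inside <- calls_fixture(1500L, reference_base(ref, 1500L),
                          unname(c(A = "G", G = "A", C = "T", T = "C")[
                            reference_base(ref, 1500L)]))
  outside <- calls_fixture(5000L, reference_base(ref, 5000L),
                           unname(c(A = "G", G = "A", C = "T", T = "C")[
                             reference_base(ref, 5000L)]))
  cc <- compare_callsets(rbind(inside, outside), inside, region)
  expect_equal(sum(cc$S + cc$B + cc$I), 1L)
})

test_that("error rates implement S/(S+B) and I/(I+B) with undefined flags", {
  counts <- tibble::tibble(
    class_group = c("transition", "transversion", "indel"),
    S = c(1L, 0L, 3L), B = c(499L, 57L, 0L), I = c(2L, 2L, 0L)
  )
  er <- error_rates(counts)
  expect_equal(er$fn_rate[1], 1 / 500)
  expect_equal(er$fn_rate[2], 0)
  expect_equal(er$fp_rate[1], 2 / 501)
  # the smallest-count realization of an 11.8% FP rate
  er2 <- error_rates(tibble::tibble(class_group = "transversion",
                                    S = 0L, B = 15L, I = 2L))
  expect_equal(round(er2$fp_rate, 3), 0.118)
  # zero denominators are flagged undefined
  expect_true(er$fp_undefined[3])
  expect_true(is.na(er$fp_rate[3]))
  expect_error(error_rates(tibble::tibble(class_group = "indel",
                                          S = -1L, B = 0L, I = 0L)),
               "non-negative")
})

test_that("accuracy uses screened bases as the denominator", {
  counts <- tibble::tibble(class_group = "transition",
                           S = 43L, B = 100L, I = 6L)
  expect_gt(concordance_accuracy(counts, 59038L), 0.999)
  expect_equal(concordance_accuracy(counts, 59038L), (59038 - 49) / 59038)
  zero <- tibble::tibble(class_group = "transition", S = 0L, B = 5L, I = 0L)
  expect_equal(concordance_accuracy(zero, 1000L), 1)
  one <- tibble::tibble(class_group = "transition", S = 1L, B = 5L, I = 0L)
  expect_equal(concordance_accuracy(one, 1000L), 0.999)
})

test_that("screened regions exclude the placeholder and convert BED", {
  ref <- synthetic_ref()
  region <- screened_region(3100:3110, ref)
  expect_false(3107L %in% region$positions)
  expect_equal(region$n_bases, 10L)
  path <- withr::local_tempfile(fileext = ".bed")
  write_screened_bed(region, path)
  back <- load_screened_bed(path, ref)
  expect_identical(back$positions, region$positions)
  expect_error(screened_region(c(1L, 20000L), ref), "outside")
})

test_that("per-class union accounting holds on simulated pairs", {
  sim <- default_sim()
  pe <- simulate_platform_errors(sim$callsets, platform_profile(),
                                 sim$reference, seed = 3L)
  for (s in utils::head(unique(sim$callsets$sample), 5L)) {
    test <- pe$test[pe$test$sample == s, ]
    orth <- pe$orthogonal[pe$orthogonal$sample == s, ]
    region <- pe$regions[[s]]
    cc <- compare_callsets(test, orth, region)
    union_keys <- union(
      variant_key(test[test$position %in% region$positions, ]),
      variant_key(orth))
    expect_equal(sum(cc$S + cc$B + cc$I), length(union_keys))
  }
})
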