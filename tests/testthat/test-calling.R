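test_that("heteroplasmy state follows the 25% filter and homoplasmic cutoff", {
  expect_equal(heteroplasmy_state(0.50), "heteroplasmic")
  expect_equal(heteroplasmy_state(0.20), "excluded")
  expect_equal(heteroplasmy_state(1.00), "homoplasmic")
  expect_equal(heteroplasmy_state(c(0.249, 0.25, 0.949, 0.95)),
               c("excluded", "heteroplasmic", "heteroplasmic", "homoplasmic"))
  expect_equal(heteroplasmy_state(0.80, homoplasmic_cutoff = 0.75),
               "homoplasmic")
  expect_error(heteroplasmy_state(0), "\\(0, 1\\]")
  expect_error(heteroplasmy_state(1.5), "\\(0, 1\\]")
})

make_calls <- function(fractions, start_pos = 1000L) {
  n <- length(fractions)
  tibble::tibble(
    sample = "s1",
    position = start_pos + seq_len(n) - 1L,
    ref = "A", alt = "G", class = "transition",
    allele_fraction = fractions
  )
}

test_that("filter_calls applies the reporting and heteroplasmy thresholds", {
  raw <- make_calls(c(0.03, 0.20, 0.40, 1.0))
  out <- filter_calls(raw)
  expect_equal(sort(out$allele_fraction), c(0.40, 1.0))
  expect_setequal(out$state, c("heteroplasmic", "homoplasmic"))
  expect_equal(nrow(filter_calls(make_calls(numeric(0)))), 0L)
  high <- filter_calls(make_calls(c(0.95, 0.99, 1.0)))
  expect_equal(nrow(high), 3L)
  expect_true(all(high$state == "homoplasmic"))
})

test_that("filter_calls is monotone in the reporting threshold", {
  withr::with_seed(11L, {
    raw <- make_calls(runif(50, 0.01, 1))
    thresholds <- c(0.01, 0.05, 0.10, 0.30, 0.50, 0.90)
    kept <- lapply(thresholds, function(th) {
      variant_key(filter_calls(raw, report_threshold = th))
    })
    for (i in seq_along(kept)[-1]) {
      expect_true(all(kept[[i]] %in% kept[[i - 1]]))
    }
  })
})

test_that("duplicate keys collapse to the maximum fraction", {
  raw <- tibble::tibble(
    sample = "s1", position = c(1000L, 1000L), ref = "A", alt = "G",
    class = "transition", allele_fraction = c(0.4, 0.9)
  )
  out <- filter_calls(raw)
  expect_equal(nrow(out), 1L)
  expect_equal(out$allele_fraction, 0.9)
})

test_that("confirmation keeps a call iff any one source repeats it", {
  primary <- filter_calls(make_calls(c(1.0, 0.5)))
  conf_full <- primary
  conf_partial <- primary[1, ]
  expect_equal(nrow(confirm_calls(primary, list(conf_full))), 2L)
  # any-one-source disjunction
  expect_equal(nrow(confirm_calls(primary, list(conf_partial, primary))), 2L)
  expect_equal(nrow(confirm_calls(primary, list(conf_partial))), 1L)
  expect_equal(nrow(confirm_calls(primary, list(primary[0, ]))), 0L)
  expect_equal(nrow(confirm_calls(primary[0, ], list(primary))), 0L)
  # output is a subset of the primary input
  out <- confirm_calls(primary, list(conf_partial))
  expect_true(all(variant_key(out) %in% variant_key(primary)))
})

test_that("raw-call TSV round-trips through read_calls_tsv", {
  ref <- synthetic_ref()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample\tposition\tref\talt\tfraction\tsource",
    "s1\t310\tT\tC\t0.42\tprimary",
    "s1\t8274\tC\tT\t1.0\tprimary",
    "s2\t303\t\tC\t1.0\tprimary"
  ), path)
  calls <- read_calls_tsv(path, ref)
  expect_equal(nrow(calls), 3L)
  expect_equal(calls$class, c("transition", "transition", "insertion"))
  # the tract insertion was normalized on input
  expect_equal(calls$position[3], 309L)
})

test_that("VCF raw calls are read with allele fractions and anchored indels", {
  ref <- synthetic_ref()
  b302 <- reference_base(ref, 302L)
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrM,length=16569>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Allele fraction">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chrM\t310\t.\tT\tC\t.\tPASS\t.\tGT:AF\t0/1:0.42",
    "chrM\t8274\t.\tC\tT\t.\tPASS\t.\tGT:AF\t1/1:1.0",
    sprintf("chrM\t302\t.\t%s\t%sC\t.\tPASS\t.\tGT:AF\t1/1:1.0", b302, b302)
  ), path)
  calls <- read_calls_vcf(path, ref)
  expect_equal(nrow(calls), 3L)
  expect_equal(calls$allele_fraction[calls$position == 310L], 0.42)
  ins <- calls[calls$class == "insertion", ]
  expect_equal(ins$position, 309L)  # anchored 302 insC normalizes into the run
  expect_equal(ins$alt, "C")
})

test_that("planted heteroplasmy truth tables are recovered exactly", {
  sim <- default_sim()
  cs <- sim$callsets
  rc <- simulate_raw_calls(cs, sim$reference, seed = 5L)
  proc <- process_raw_calls(rc$primary, rc$confirmations)
  got <- sort(paste(proc$callsets$sample, variant_key(proc$callsets)))
  want <- sort(paste(cs$sample, variant_key(cs)))
  expect_identical(got, want)
  # every true heteroplasmy survives with its fraction and state
  het <- sim$truth$heteroplasmies
  if (nrow(het) > 0L) {
    out_keys <- paste(proc$callsets$sample, variant_key(proc$callsets))
    for (i in seq_len(nrow(het))) {
      j <- match(paste(het$sample[i], het$key[i]), out_keys)
      expect_false(is.na(j))
      expect_equal(proc$callsets$allele_fraction[j], het$allele_fraction[i])
      expect_equal(proc$callsets$state[j], "heteroplasmic")
    }
  }
  # no sub-25% call survives
  expect_true(all(proc$callsets$allele_fraction >= 0.25))
  # the removal log is monotone
  expect_true(all(diff(proc$log$n_calls) <= 0))
})
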