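#' Heteroplasmy state from an allele fraction
#'
#' Candidate variants with mixed base calls below the 25% filtering
#' threshold are excluded; fractions between the filtering threshold and the
#' homoplasmic cutoff are heteroplasmic; at or above the cutoff the allele
#' is treated as fixed (homoplasmic). The cutoff defaults to 0.95 to
#' tolerate sequencing noise at fixed alleles.
#'
#' @param fraction Numeric vector of allele fractions in (0, 1].
#' @param exclude_below Filtering threshold (default 0.25).
#' @param homoplasmic_cutoff Lower bound of the homoplasmic range
#'   (default 0.95).
#' @return Character vector: `"excluded"`, `"heteroplasmic"` or
#'   `"homoplasmic"`.
#' @export
heteroplasmy_state <- function(fraction, exclude_below = 0.25,
                               homoplasmic_cutoff = 0.95) {
  if (any(is.na(fraction) | fraction <= 0 | fraction > 1)) {
    stop("allele fractions must lie in (0, 1]")
  }
  ifelse(fraction < exclude_below, "excluded",
         ifelse(fraction < homoplasmic_cutoff, "heteroplasmic",
                "homoplasmic"))
}

#' Filter raw calls by reporting and heteroplasmy thresholds
#'
#' Calls below the reporting threshold (the variant caller's 5% reporting
#' setting) are removed, survivors are annotated with their heteroplasmy
#' state, and excluded-state calls (mixed calls under the 25% filter) are
#' removed. Duplicate keys within one sample collapse to the maximum
#' fraction, making the result order-independent.
#'
#' @param raw A raw-call tibble with at least `position`, `ref`, `alt`,
#'   `class`, `allele_fraction` (and optionally `sample`, `source`).
#' @param report_threshold Reporting threshold in (0, 1), default 0.05.
#' @param exclude_below,homoplasmic_cutoff Passed to
#'   [heteroplasmy_state()].
#' @return The filtered tibble with a `state` column.
#' @export
filter_calls <- function(raw, report_threshold = 0.05,
                         exclude_below = 0.25, homoplasmic_cutoff = 0.95) {
  stopifnot(report_threshold > 0, report_threshold < 1)
  if (nrow(raw) == 0L) {
    raw$state <- character(0)
    return(raw)
  }
  if (!"sample" %in% names(raw)) raw$sample <- "sample"
  raw <- raw |>
    dplyr::mutate(.key = variant_key(raw)) |>
    dplyr::group_by(.data$sample, .data$.key) |>
    dplyr::slice_max(.data$allele_fraction, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  kept <- raw[raw$allele_fraction >= report_threshold, , drop = FALSE]
  kept$state <- heteroplasmy_state(kept$allele_fraction, exclude_below,
                                   homoplasmic_cutoff)
  kept <- kept[kept$state != "excluded", , drop = FALSE]
  kept$.key <- NULL
  kept
}

#' Confirm primary calls against orthogonal call lists
#'
#' A primary call is retained iff its variant key appears in at least one
#' confirmation list (reanalysis, a sequencing rerun, or an orthogonal
#' platform) — any one source suffices. Retained calls keep the primary
#' allele fraction.
#'
#' @param primary A filtered call tibble for one sample.
#' @param confirmations A list of call tibbles (possibly empty tibbles).
#' @return The confirmed subset of `primary`.
#' @export
confirm_calls <- function(primary, confirmations) {
  if (nrow(primary) == 0L) return(primary)
  confirmed_keys <- unique(unlist(lapply(confirmations, function(cc) {
    if (is.null(cc) || nrow(cc) == 0L) character(0) else variant_key(cc)
  })))
  primary[variant_key(primary) %in% confirmed_keys, , drop = FALSE]
}

#' Read raw calls from TSV
#'
#' Tab-delimited with columns `sample`, `position`, `ref`, `alt`,
#' `fraction` (or `allele_fraction`) and optionally `source` and `group`.
#'
#' @param path Path to the TSV.
#' @param ref An [mt_reference()] for normalization.
#' @return A normalized raw-call tibble.
#' @export
read_calls_tsv <- function(path, ref) {
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if ("fraction" %in% names(d) && !"allele_fraction" %in% names(d)) {
    d$allele_fraction <- d$fraction
  }
  need <- c("sample", "position", "ref", "alt", "allele_fraction")
  if (!all(need %in% names(d))) {
    stop("call TSV must have columns: ", paste(need, collapse = ", "))
  }
  d$ref[is.na(d$ref)] <- ""
  d$alt[is.na(d$alt)] <- ""
  v <- normalize_variants(
    mt_variants(d$position, d$ref, d$alt, d$allele_fraction), ref)
  out <- tibble::tibble(
    sample = d$sample,
    position = v$position, ref = v$ref, alt = v$alt, class = v$class,
    allele_fraction = v$allele_fraction
  )
  if ("source" %in% names(d)) out$source <- d$source
  if ("group" %in% names(d)) out$group <- d$group
  out
}

#' Write a call-set tibble to TSV
#'
#' @param calls A call tibble (any of the shapes used in this package).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  readr::write_tsv(calls, path)
  invisible(path)
}

#' Read raw calls from a VCF
#'
#' One- or multi-sample VCF against the mitochondrial reference; the allele
#' fraction is taken from FORMAT/AF when present, else INFO/AF. VCF-style
#' anchored indels (e.g. REF `CA` / ALT `C`) are converted to the package's
#' anchor-free representation before normalization.
#'
#' @param path Path to the VCF (plain text or bgzipped).
#' @param ref An [mt_reference()].
#' @return A normalized raw-call tibble.
#' @export
read_calls_vcf <- function(path, ref) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n_alt <- lengths(rr$ALT)
  pos <- rep(GenomicRanges::start(rr), n_alt)
  refs <- rep(as.character(rr$REF), n_alt)
  alts <- as.character(unlist(rr$ALT))
  # allele fractions
  geno <- VariantAnnotation::geno(vcf)
  if ("AF" %in% names(geno)) {
    af_mat <- geno$AF
    samples <- colnames(af_mat)
    rows <- lapply(seq_along(samples), function(j) {
      af <- unlist(af_mat[, j])
      tibble::tibble(sample = samples[j], position = pos, ref = refs,
                     alt = alts, allele_fraction = as.numeric(af))
    })
    d <- dplyr::bind_rows(rows)
  } else {
    info <- VariantAnnotation::info(vcf)
    af <- if ("AF" %in% names(info)) as.numeric(unlist(info$AF)) else 1
    d <- tibble::tibble(sample = "sample", position = pos, ref = refs,
                        alt = alts, allele_fraction = rep_len(af, length(pos)))
  }
  d <- d[!is.na(d$allele_fraction) & d$allele_fraction > 0, , drop = FALSE]
  # convert VCF anchored indels to the anchor-free representation
  for (i in seq_len(nrow(d))) {
    r <- d$ref[i]; a <- d$alt[i]
    if (nchar(r) == nchar(a)) next
    k <- 0L
    while (k < min(nchar(r), nchar(a)) &&
           substr(r, k + 1L, k + 1L) == substr(a, k + 1L, k + 1L)) {
      k <- k + 1L
    }
    if (nchar(r) > nchar(a)) {
      d$ref[i] <- substr(r, k + 1L, nchar(r))
      d$alt[i] <- ""
      d$position[i] <- d$position[i] + k   # first deleted base
    } else {
      d$alt[i] <- substr(a, k + 1L, nchar(a))
      d$ref[i] <- ""
      d$position[i] <- d$position[i] + k - 1L  # base after which inserted
    }
  }
  if (any(nchar(d$ref) == nchar(d$alt) & nchar(d$ref) > 1L)) {
    stop("multi-base substitutions in VCF are not supported; ",
         "decompose them into SNVs upstream")
  }
  v <- normalize_variants(
    mt_variants(d$position, d$ref, d$alt, d$allele_fraction), ref)
  tibble::tibble(sample = d$sample, position = v$position, ref = v$ref,
                 alt = v$alt, class = v$class,
                 allele_fraction = v$allele_fraction)
}
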