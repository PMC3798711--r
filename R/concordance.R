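#' Screened regions
#'
#' The set of reference positions covered by the orthogonal validation
#' method (e.g. Sanger reads after QV<25 trimming). The rCRS placeholder
#' position 3107 is always excluded: no true base exists there, so it never
#' enters a screened-base denominator.
#'
#' @param positions Integer vector of 1-based covered positions.
#' @param ref An [mt_reference()] (bounds check).
#' @return An object of class `screened_region` with fields `positions` and
#'   `n_bases`.
#' @export
screened_region <- function(positions, ref) {
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) && (min(positions) < 1L || max(positions) > ref$length)) {
    stop("screened positions outside the reference")
  }
  positions <- setdiff(positions, 3107L)
  structure(list(positions = positions, n_bases = length(positions)),
            class = "screened_region")
}

#' @export
print.screened_region <- function(x, ...) {
  cat(sprintf("<screened_region> %s bases\n", format(x$n_bases, big.mark = ",")))
  invisible(x)
}

#' Read a screened region from BED
#'
#' BED intervals (0-based half-open) are converted to 1-based inclusive
#' positions.
#'
#' @param path Path to a BED file.
#' @param ref An [mt_reference()].
#' @return A [screened_region()].
#' @export
load_screened_bed <- function(path, ref) {
  gr <- rtracklayer::import(path, format = "BED")
  pos <- unlist(lapply(seq_along(gr), function(i) {
    seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])
  }))
  screened_region(pos, ref)
}

#' Write a screened region to BED
#'
#' @param region A [screened_region()].
#' @param path Output path.
#' @param chrom Chromosome label for the BED records.
#' @return `path`, invisibly.
#' @export
write_screened_bed <- function(region, path, chrom = "chrM") {
  p <- region$positions
  if (length(p) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  brk <- c(0L, which(diff(p) != 1L), length(p))
  starts <- p[brk[-length(brk)] + 1L]
  ends <- p[brk[-1L]]
  writeLines(sprintf("%s\t%d\t%d", chrom, starts - 1L, ends), path)
  invisible(path)
}

#' Compare a test call set against an orthogonal truth call set
#'
#' Restricted to variants whose positions lie inside the screened region,
#' each distinct normalized variant key contributes to exactly one of
#' S (detected only by the truth/orthogonal method: a false negative of the
#' test method), B (detected by both) or I (detected only by the test
#' method: a false positive), in exactly one class group (transitions,
#' transversions, or insertions plus deletions). Matching is key-exact and
#' fraction-blind: differing allele fractions do not break a match.
#'
#' @param test,truth Normalized call tibbles for the same sample(s).
#' @param region A [screened_region()].
#' @return A `concordance_counts` tibble with columns `class_group`, `S`,
#'   `B`, `I` (one row per class group, in the order transition,
#'   transversion, indel).
#' @export
compare_callsets <- function(test, truth, region) {
  groups <- c("transition", "transversion", "indel")
  in_region <- function(v) v[v$position %in% region$positions, , drop = FALSE]
  test <- in_region(test)
  truth <- in_region(truth)
  tk <- unique(variant_key(test))
  rk <- unique(variant_key(truth))
  all_keys <- union(tk, rk)
  cls <- c(stats::setNames(class_group(test$class), variant_key(test)),
           stats::setNames(class_group(truth$class), variant_key(truth)))
  cls <- cls[!duplicated(names(cls))]
  status <- ifelse(all_keys %in% tk & all_keys %in% rk, "B",
                   ifelse(all_keys %in% rk, "S", "I"))
  counts <- table(factor(cls[all_keys], levels = groups),
                  factor(status, levels = c("S", "B", "I")))
  out <- tibble::tibble(
    class_group = groups,
    S = as.integer(counts[, "S"]),
    B = as.integer(counts[, "B"]),
    I = as.integer(counts[, "I"])
  )
  class(out) <- c("concordance_counts", class(out))
  out
}

#' Class-stratified error rates
#'
#' The false-negative variant rate is S/(S+B) and the false-positive
#' variant rate is I/(I+B), per class group. A rate with a zero denominator
#' is undefined: it is returned as `NA` with its flag column set.
#'
#' @param counts A `concordance_counts` tibble (see [compare_callsets()]),
#'   or any tibble with columns `class_group`, `S`, `B`, `I`.
#' @return A tibble with columns `class_group`, `S`, `B`, `I`,
#'   `fn_rate`, `fp_rate`, `fn_undefined`, `fp_undefined`.
#' @export
error_rates <- function(counts) {
  stopifnot(all(c("class_group", "S", "B", "I") %in% names(counts)))
  if (any(counts$S < 0 | counts$B < 0 | counts$I < 0)) {
    stop("S, B, I must be non-negative")
  }
  dplyr::mutate(
    tibble::as_tibble(counts),
    fn_undefined = (.data$S + .data$B) == 0L,
    fp_undefined = (.data$I + .data$B) == 0L,
    fn_rate = ifelse(.data$fn_undefined, NA_real_,
                     .data$S / (.data$S + .data$B)),
    fp_rate = ifelse(.data$fp_undefined, NA_real_,
                     .data$I / (.data$I + .data$B))
  )
}

#' Concordance-based sequencing accuracy
#'
#' Estimated from the number of concordant calls over the screened bases:
#' (screened bases - total S - total I) / screened bases. Every screened
#' base without a discordant call counts as concordant.
#'
#' @param counts A `concordance_counts` tibble, possibly pooled over
#'   samples.
#' @param screened_bases Total screened base count (an integer, or a
#'   [screened_region()] whose `n_bases` is used).
#' @return Accuracy as a proportion in \[0, 1\].
#' @export
concordance_accuracy <- function(counts, screened_bases) {
  if (inherits(screened_bases, "screened_region")) {
    screened_bases <- screened_bases$n_bases
  }
  stopifnot(screened_bases > 0)
  errors <- sum(counts$S) + sum(counts$I)
  (screened_bases - errors) / screened_bases
}

#' Pool concordance counts over samples
#'
#' @param count_list A list of `concordance_counts` tibbles.
#' @return A single pooled `concordance_counts` tibble.
#' @export
pool_concordance <- function(count_list) {
  pooled <- dplyr::bind_rows(count_list) |>
    dplyr::group_by(.data$class_group) |>
    dplyr::summarise(S = sum(.data$S), B = sum(.data$B), I = sum(.data$I),
                     .groups = "drop")
  pooled <- pooled[match(c("transition", "transversion", "indel"),
                         pooled$class_group), , drop = FALSE]
  class(pooled) <- c("concordance_counts", class(pooled))
  pooled
}
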