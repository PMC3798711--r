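#' Variant tables
#'
#' Variants are held as tibbles with one row per variant and columns
#' `position` (1-based rCRS coordinate), `ref`, `alt` (allele strings; an
#' insertion has `ref = ""` and its `position` is the base *after which* the
#' sequence is inserted; a deletion has `alt = ""`), `class` (one of
#' `"transition"`, `"transversion"`, `"insertion"`, `"deletion"`) and
#' `allele_fraction` (proportion in (0, 1], `NA` when unknown).
#'
#' Multi-base substitutions (equal-length `ref`/`alt` longer than one base)
#' are decomposed into adjacent single-base substitutions, since the
#' transition/transversion taxonomy is per base.
#'
#' @param position Integer vector of 1-based positions.
#' @param ref,alt Character vectors of alleles (`""` allowed as above).
#' @param allele_fraction Numeric vector in (0, 1] or `NA`.
#'
#' @return A tibble of class described above.
#' @export
mt_variants <- function(position, ref, alt, allele_fraction = NA_real_) {
  v <- tibble::tibble(
    position = as.integer(position),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    allele_fraction = as.numeric(allele_fraction)
  )
  if (any(is.na(v$position) | v$position < 1L)) {
    stop("variant positions must be positive integers")
  }
  if (any(v$ref == "" & v$alt == "")) {
    stop("variant with empty ref and empty alt")
  }
  bad_af <- !is.na(v$allele_fraction) &
    (v$allele_fraction <= 0 | v$allele_fraction > 1)
  if (any(bad_af)) {
    stop("allele fractions must lie in (0, 1]")
  }
  # decompose multi-base substitutions into single-base substitutions
  multi <- nchar(v$ref) == nchar(v$alt) & nchar(v$ref) > 1L
  if (any(multi)) {
    pieces <- lapply(which(multi), function(i) {
      r <- strsplit(v$ref[i], "")[[1]]
      a <- strsplit(v$alt[i], "")[[1]]
      keep <- r != a
      if (!any(keep)) stop("substitution with identical ref and alt")
      tibble::tibble(
        position = v$position[i] + which(keep) - 1L,
        ref = r[keep], alt = a[keep],
        allele_fraction = v$allele_fraction[i]
      )
    })
    v <- dplyr::bind_rows(v[!multi, ], dplyr::bind_rows(pieces))
    v <- dplyr::arrange(v, .data$position)
  }
  v$class <- classify_variant(v$ref, v$alt)
  v[, c("position", "ref", "alt", "class", "allele_fraction")]
}

#' Classify variants into the substitution taxonomy
#'
#' Single-base substitutions are transitions when purine<->purine (A<->G) or
#' pyrimidine<->pyrimidine (C<->T), transversions otherwise (A<->C, A<->T,
#' G<->C, G<->T). Length-changing variants are insertions or deletions.
#'
#' @param ref,alt Character vectors of alleles (`""` for the empty side of
#'   an indel).
#' @return Character vector: `"transition"`, `"transversion"`,
#'   `"insertion"` or `"deletion"`.
#' @export
classify_variant <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  n <- length(ref)
  stopifnot(length(alt) == n)
  out <- character(n)
  ins <- ref == "" & alt != ""
  del <- alt == "" & ref != ""
  sub <- nchar(ref) == 1L & nchar(alt) == 1L & !ins & !del
  other <- !(ins | del | sub)
  if (any(other)) {
    stop("unclassifiable allele pair (use mt_variants() to decompose ",
         "multi-base substitutions)")
  }
  if (any(sub)) {
    r <- ref[sub]; a <- alt[sub]
    if (any(r == a)) stop("substitution with identical ref and alt")
    if (any(r == "N" | a == "N")) {
      stop("substitution involving the placeholder base N")
    }
    purine <- c("A", "G")
    same_type <- (r %in% purine) == (a %in% purine)
    out[sub] <- ifelse(same_type, "transition", "transversion")
  }
  out[ins] <- "insertion"
  out[del] <- "deletion"
  out
}

# Three-way class grouping used by the concordance statistics.
class_group <- function(class) {
  ifelse(class %in% c("insertion", "deletion"), "indel", class)
}

#' Normalized variant keys
#'
#' A key string `"<position>:<ref>><alt>"` (with `-` for the empty side of
#' an indel) that identifies a variant for catalog lookup and call-set
#' comparison. Keys are placement-invariant only after
#' [normalize_variants()].
#'
#' @param v A variant tibble ([mt_variants()]).
#' @return Character vector of keys.
#' @export
variant_key <- function(v) {
  sprintf("%d:%s>%s", v$position,
          ifelse(v$ref == "", "-", v$ref),
          ifelse(v$alt == "", "-", v$alt))
}

#' Normalize variants against a reference
#'
#' Substitutions are returned unchanged (after checking the ref allele
#' against the reference). Insertions and deletions inside a repeated tract
#' are shifted to the canonical 3'-most placement (the HGVS convention), so
#' that all placements yielding the same edited sequence share one key.
#' Shifting wraps across the origin on circular references.
#'
#' @param v A variant tibble.
#' @param ref An [mt_reference()].
#' @param check_ref Validate substitution/deletion ref alleles against the
#'   reference sequence (default `TRUE`).
#' @return The normalized variant tibble.
#' @export
normalize_variants <- function(v, ref, check_ref = TRUE) {
  if (nrow(v) == 0L) return(v)
  L <- ref$length
  for (i in seq_len(nrow(v))) {
    if (v$class[i] == "insertion") {
      p <- v$position[i]
      a <- strsplit(v$alt[i], "")[[1]]
      steps <- 0L
      while (steps < L &&
             reference_base(ref, circular_position(p + 1L, L)) == a[1]) {
        p <- circular_position(p + 1L, L)
        a <- c(a[-1], a[1])
        steps <- steps + 1L
      }
      if (steps >= L) stop("degenerate insertion: tract spans whole genome")
      v$position[i] <- p
      v$alt[i] <- paste(a, collapse = "")
    } else if (v$class[i] == "deletion") {
      p <- v$position[i]
      k <- nchar(v$ref[i])
      if (check_ref) {
        obs <- paste(reference_base(ref, circular_position(p + 0:(k - 1L), L)),
                     collapse = "")
        if (obs != v$ref[i]) {
          stop(sprintf("deletion ref '%s' does not match reference at %d",
                       v$ref[i], p))
        }
      }
      steps <- 0L
      while (steps < L &&
             reference_base(ref, circular_position(p + k, L)) ==
             reference_base(ref, p)) {
        p <- circular_position(p + 1L, L)
        steps <- steps + 1L
      }
      if (steps >= L) stop("degenerate deletion: tract spans whole genome")
      v$position[i] <- p
      v$ref[i] <- paste(reference_base(ref, circular_position(p + 0:(k - 1L), L)),
                        collapse = "")
    } else if (check_ref) {
      if (reference_base(ref, v$position[i]) != v$ref[i]) {
        stop(sprintf("ref allele '%s' does not match reference base '%s' at %d",
                     v$ref[i], reference_base(ref, v$position[i]),
                     v$position[i]))
      }
    }
  }
  v
}

#' HGVS m. labels for variants
#'
#' Substitutions as `m.<pos><ref>><alt>` (e.g. `m.8274C>T`), deletions as
#' `m.<pos>del<ref>` or `m.<start>_<end>del<ref>`, insertions as
#' `m.<pos>_<pos+1>ins<alt>`.
#'
#' @param v A variant tibble.
#' @param ref An [mt_reference()]; needed only to wrap insertion flanks on
#'   circular genomes (defaults to a 16,569-bp frame).
#' @return Character vector of labels.
#' @export
hgvs_label <- function(v, ref = NULL) {
  L <- if (is.null(ref)) 16569L else ref$length
  vapply(seq_len(nrow(v)), function(i) {
    switch(v$class[i],
      transition = ,
      transversion = sprintf("m.%d%s>%s", v$position[i], v$ref[i], v$alt[i]),
      insertion = sprintf("m.%d_%dins%s", v$position[i],
                          circular_position(v$position[i] + 1L, L), v$alt[i]),
      deletion = {
        k <- nchar(v$ref[i])
        if (k == 1L) {
          sprintf("m.%ddel%s", v$position[i], v$ref[i])
        } else {
          sprintf("m.%d_%ddel%s", v$position[i],
                  circular_position(v$position[i] + k - 1L, L), v$ref[i])
        }
      }
    )
  }, character(1))
}

#' Parse HGVS m. labels
#'
#' Accepts the substitution, deletion and insertion forms emitted by
#' [hgvs_label()]. Substitution and deletion ref alleles are validated
#' against the reference; results are normalized.
#'
#' @param labels Character vector of `m.` labels.
#' @param ref An [mt_reference()].
#' @return A normalized variant tibble.
#' @export
parse_hgvs <- function(labels, ref) {
  rows <- lapply(labels, function(lab) {
    m <- stringr::str_match(lab, "^m\\.(\\d+)([ACGT])>([ACGT])$")
    if (!is.na(m[1, 1])) {
      return(tibble::tibble(position = as.integer(m[1, 2]),
                            ref = m[1, 3], alt = m[1, 4]))
    }
    m <- stringr::str_match(lab, "^m\\.(\\d+)(?:_(\\d+))?del([ACGT]*)$")
    if (!is.na(m[1, 1])) {
      p1 <- as.integer(m[1, 2])
      p2 <- if (is.na(m[1, 3])) p1 else as.integer(m[1, 3])
      k <- if (p2 >= p1) p2 - p1 + 1L else ref$length - p1 + 1L + p2
      del <- paste(reference_base(ref, circular_position(p1 + 0:(k - 1L),
                                                         ref$length)),
                   collapse = "")
      if (nzchar(m[1, 4]) && m[1, 4] != del) {
        stop("deleted sequence in '", lab, "' does not match the reference")
      }
      return(tibble::tibble(position = p1, ref = del, alt = ""))
    }
    m <- stringr::str_match(lab, "^m\\.(\\d+)_(\\d+)ins([ACGT]+)$")
    if (!is.na(m[1, 1])) {
      p1 <- as.integer(m[1, 2])
      p2 <- as.integer(m[1, 3])
      if (circular_position(p1 + 1L, ref$length) != p2) {
        stop("insertion flanks in '", lab, "' are not adjacent")
      }
      return(tibble::tibble(position = p1, ref = "", alt = m[1, 3 + 1]))
    }
    stop("malformed HGVS label: '", lab, "'")
  })
  d <- dplyr::bind_rows(rows)
  v <- mt_variants(d$position, d$ref, d$alt)
  normalize_variants(v, ref)
}
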