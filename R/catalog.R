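#' Variant catalogs
#'
#' A catalog is a flat lookup table of previously reported mtDNA variants
#' (MITOMAP-style): one row per (position, ref, alt) key with a locus name,
#' an amino-acid change label (`"Syn."`, `"-"` or a replacement such as
#' `"Thr>Ala"`) and zero or more semicolon-delimited disease-association
#' annotations. A variant absent from the catalog is "novel"; a variant is
#' "disease-associated" when its entry carries at least one annotation.
#'
#' @name catalog
NULL

new_catalog <- function(entries, source = "unknown", version = "unknown") {
  entries$key <- variant_key(entries)
  if (anyDuplicated(entries$key)) {
    stop("duplicate catalog keys: ",
         paste(unique(entries$key[duplicated(entries$key)]), collapse = ", "))
  }
  structure(
    list(entries = entries, source = source, version = version),
    class = "mt_catalog"
  )
}

#' @export
print.mt_catalog <- function(x, ...) {
  cat(sprintf("<mt_catalog> %s (%s): %d entries, %d disease-associated\n",
              x$source, x$version, nrow(x$entries),
              sum(x$entries$disease_annotations != "")))
  invisible(x)
}

#' Build a catalog from a variant table
#'
#' @param variants A variant tibble ([mt_variants()]), already normalized.
#' @param locus Character vector of locus names (default: from
#'   [locus_annotation()]).
#' @param aa_change Character vector of amino-acid change labels.
#' @param disease_annotations Character vector; multiple annotations joined
#'   by `"; "`, `""` for none.
#' @param source,version Provenance labels surfaced in reports.
#' @return An object of class `mt_catalog`.
#' @export
catalog_from_variants <- function(variants,
                                  locus = locus_annotation(variants$position),
                                  aa_change = "-",
                                  disease_annotations = "",
                                  source = "user", version = "unversioned") {
  entries <- tibble::tibble(
    position = variants$position,
    ref = variants$ref,
    alt = variants$alt,
    class = variants$class,
    locus = locus,
    aa_change = rep_len(aa_change, nrow(variants)),
    disease_annotations = rep_len(disease_annotations, nrow(variants))
  )
  new_catalog(entries, source = source, version = version)
}

#' Read a catalog TSV
#'
#' Tab-delimited UTF-8 with `#` comments and columns `position`, `ref`,
#' `alt`, `locus`, `aa_change`, `disease_annotations` (semicolon-delimited,
#' empty for none). Indel keys are normalized against the reference before
#' indexing, so lookups are placement-invariant at homopolymers; ref alleles
#' must match the reference.
#'
#' @param path Path to the TSV.
#' @param ref An [mt_reference()] used for normalization.
#' @param source,version Provenance labels (default: file name, mtime).
#' @return An `mt_catalog`.
#' @export
load_catalog <- function(path, ref,
                         source = basename(path),
                         version = format(file.mtime(path))) {
  d <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    position = readr::col_integer(),
    ref = readr::col_character(),
    alt = readr::col_character(),
    locus = readr::col_character(),
    aa_change = readr::col_character(),
    disease_annotations = readr::col_character()
  ))
  need <- c("position", "ref", "alt", "locus", "aa_change",
            "disease_annotations")
  if (!all(need %in% names(d))) {
    stop("catalog TSV must have columns: ", paste(need, collapse = ", "))
  }
  d$ref[is.na(d$ref)] <- ""
  d$alt[is.na(d$alt)] <- ""
  d$aa_change[is.na(d$aa_change)] <- "-"
  d$disease_annotations[is.na(d$disease_annotations)] <- ""
  if (any(nchar(d$ref) > 1L & nchar(d$ref) == nchar(d$alt))) {
    stop("catalog rows must be single-base substitutions or indels")
  }
  # single-base rows: mt_variants() preserves row order, so metadata
  # columns stay aligned through normalization
  v <- normalize_variants(mt_variants(d$position, d$ref, d$alt), ref)
  entries <- tibble::tibble(
    position = v$position, ref = v$ref, alt = v$alt, class = v$class,
    locus = d$locus, aa_change = d$aa_change,
    disease_annotations = d$disease_annotations
  )
  new_catalog(entries, source = source, version = version)
}

#' Write a catalog TSV
#'
#' @param catalog An `mt_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  header <- sprintf("# variant catalog: %s (%s)", catalog$source,
                    catalog$version)
  writeLines(header, path)
  readr::write_tsv(
    catalog$entries[, c("position", "ref", "alt", "locus", "aa_change",
                        "disease_annotations")],
    path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Novelty of variants against a catalog
#'
#' A variant is novel when its normalized key is absent from the catalog.
#' Novelty is keyed on (position, ref, alt), not position alone, and is
#' fraction-blind: heteroplasmic and homoplasmic observations of an allele
#' share one key.
#'
#' @param v A normalized variant tibble.
#' @param catalog An `mt_catalog`.
#' @return Logical vector, `TRUE` where novel.
#' @export
is_novel <- function(v, catalog) {
  !(variant_key(v) %in% catalog$entries$key)
}

#' Disease annotations for a variant
#'
#' @param v A normalized variant tibble (one or more rows).
#' @param catalog An `mt_catalog`.
#' @return For one row, a character vector of annotation strings (length 0
#'   for absent or unannotated entries); for several rows, a list of such
#'   vectors.
#' @export
disease_annotations <- function(v, catalog) {
  keys <- variant_key(v)
  idx <- match(keys, catalog$entries$key)
  out <- lapply(idx, function(i) {
    if (is.na(i)) return(character(0))
    ann <- catalog$entries$disease_annotations[i]
    if (!nzchar(ann)) return(character(0))
    trimws(strsplit(ann, ";")[[1]])
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Disease-association flag
#'
#' @inheritParams disease_annotations
#' @return Logical vector, `TRUE` where the catalog entry carries at least
#'   one disease annotation.
#' @export
is_disease_associated <- function(v, catalog) {
  idx <- match(variant_key(v), catalog$entries$key)
  ann <- catalog$entries$disease_annotations[idx]
  !is.na(idx) & !is.na(ann) & nzchar(ann)
}
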