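#' Haplogroup definition tables
#'
#' A haplogroup table is a tibble with one row per haplogroup: `name`,
#' `parent` (`NA` for the root), `macrohaplogroup`, and `defining` — a
#' comma-separated list of defining variants in HGVS `m.` notation carried
#' on the edge leading to that haplogroup. Definitions must form a tree;
#' every non-root node has a non-empty defining set, the reference
#' haplogroup (the root, haplogroup H for the rCRS) has an empty one.
#'
#' @name haplogroup_table
NULL

validate_haplogroup_table <- function(d) {
  stopifnot(all(c("name", "parent", "macrohaplogroup", "defining") %in%
                  names(d)))
  if (anyDuplicated(d$name)) stop("duplicate haplogroup names")
  roots <- which(is.na(d$parent) | d$parent == "")
  if (length(roots) != 1L) stop("haplogroup table must have exactly one root")
  known <- d$name
  bad <- !is.na(d$parent) & d$parent != "" & !(d$parent %in% known)
  if (any(bad)) {
    stop("unknown parent haplogroup: ", paste(d$parent[bad], collapse = ", "))
  }
  # cycle check: walk to root from every node
  for (nm in d$name) {
    seen <- character(0)
    cur <- nm
    while (!is.na(cur) && cur != "") {
      if (cur %in% seen) stop("cycle in haplogroup table at ", cur)
      seen <- c(seen, cur)
      cur <- d$parent[match(cur, d$name)]
    }
  }
  nonroot_empty <- seq_len(nrow(d)) != roots &
    (is.na(d$defining) | d$defining == "")
  if (any(nonroot_empty)) {
    stop("non-root haplogroup with empty defining set: ",
         paste(d$name[nonroot_empty], collapse = ", "))
  }
  invisible(d)
}

#' Read a haplogroup definition TSV
#'
#' Columns `name`, `parent` (empty for the root), `macrohaplogroup`,
#' `defining` (comma-separated `m.` labels). Defining variants are parsed,
#' validated against the reference and normalized.
#'
#' @param path Path to the TSV.
#' @param ref An [mt_reference()].
#' @return A `haplogroup_defs` object: the validated tibble with a
#'   `defining_keys` list column of normalized variant keys.
#' @export
load_haplogroup_table <- function(path, ref) {
  d <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    name = readr::col_character(),
    parent = readr::col_character(),
    macrohaplogroup = readr::col_character(),
    defining = readr::col_character()
  ))
  haplogroup_defs(d, ref)
}

#' Build validated haplogroup definitions from a tibble
#'
#' @param d A tibble with columns `name`, `parent`, `macrohaplogroup`,
#'   `defining`.
#' @param ref An [mt_reference()].
#' @return A `haplogroup_defs` object.
#' @export
haplogroup_defs <- function(d, ref) {
  validate_haplogroup_table(d)
  d$defining_keys <- lapply(seq_len(nrow(d)), function(i) {
    def <- d$defining[i]
    if (is.na(def) || def == "") return(character(0))
    labels <- trimws(strsplit(def, ",")[[1]])
    variant_key(parse_hgvs(labels, ref))
  })
  # cumulative root-to-node path keys and depth
  idx <- stats::setNames(seq_len(nrow(d)), d$name)
  path_keys <- vector("list", nrow(d))
  depth <- integer(nrow(d))
  get_path <- function(i) {
    if (!is.null(path_keys[[i]])) return(path_keys[[i]])
    par <- d$parent[i]
    if (is.na(par) || par == "") {
      path_keys[[i]] <<- d$defining_keys[[i]]
      depth[i] <<- 0L
    } else {
      j <- idx[[par]]
      pk <- get_path(j)
      path_keys[[i]] <<- union(pk, d$defining_keys[[i]])
      depth[i] <<- depth[j] + 1L
    }
    path_keys[[i]]
  }
  for (i in seq_len(nrow(d))) get_path(i)
  d$path_keys <- path_keys
  d$depth <- depth
  class(d) <- c("haplogroup_defs", class(d))
  d
}

#' Write a haplogroup definition TSV
#'
#' @param defs A `haplogroup_defs` object or compatible tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplogroup_table <- function(defs, path) {
  readr::write_tsv(defs[, c("name", "parent", "macrohaplogroup", "defining")],
                   path)
  invisible(path)
}

#' Assign a haplogroup to one sample
#'
#' Scores every haplogroup by the cumulative match fraction of its
#' root-to-node path: (defining variants on the path present in the
#' call set) / (path defining-set size). Candidates are nodes with at least
#' one matched defining variant; when none matches (e.g. a call set with no
#' variants relative to the rCRS) the sample is assigned the root
#' (reference) haplogroup. Ties break to the deepest node, then
#' lexicographically by name. Private (non-defining) variants never change
#' the score.
#'
#' @param calls A normalized call tibble for one sample.
#' @param defs A `haplogroup_defs` object.
#' @return A one-row tibble: `haplogroup`, `macrohaplogroup`, `score`,
#'   `runner_up`, `runner_up_score`, `depth`.
#' @export
assign_haplogroup <- function(calls, defs) {
  if (nrow(defs) == 0L) stop("empty haplogroup definition table")
  keys <- unique(variant_key(calls))
  score <- vapply(defs$path_keys, function(pk) {
    if (length(pk) == 0L) 0 else sum(pk %in% keys) / length(pk)
  }, numeric(1))
  matched <- vapply(defs$path_keys, function(pk) sum(pk %in% keys) > 0L,
                    logical(1))
  root <- which(is.na(defs$parent) | defs$parent == "")
  if (!any(matched)) {
    best <- root
    runner <- NA_integer_
  } else {
    cand <- which(matched)
    ord <- cand[order(-score[cand], -defs$depth[cand], defs$name[cand])]
    best <- ord[1]
    runner <- if (length(ord) > 1L) ord[2] else NA_integer_
  }
  tibble::tibble(
    haplogroup = defs$name[best],
    macrohaplogroup = defs$macrohaplogroup[best],
    score = score[best],
    runner_up = if (is.na(runner)) NA_character_ else defs$name[runner],
    runner_up_score = if (is.na(runner)) NA_real_ else score[runner],
    depth = defs$depth[best]
  )
}

#' Assign haplogroups to a cohort
#'
#' @param callsets A cohort call tibble with a `sample` column (and
#'   optionally `group`).
#' @param defs A `haplogroup_defs` object.
#' @return A tibble with one row per sample: `sample`, `group` (if
#'   present), plus the [assign_haplogroup()] columns.
#' @export
assign_haplogroups <- function(callsets, defs) {
  samples <- unique(callsets$sample)
  rows <- lapply(samples, function(s) {
    calls <- callsets[callsets$sample == s, , drop = FALSE]
    out <- assign_haplogroup(calls, defs)
    out$sample <- s
    if ("group" %in% names(callsets)) out$group <- calls$group[1]
    out
  })
  d <- dplyr::bind_rows(rows)
  dplyr::relocate(d, "sample")
}

#' Cohort macrohaplogroup composition
#'
#' Counts and percentages per macrohaplogroup, overall and split by
#' case/control group when available. Percentages are of the total cohort
#' size.
#'
#' @param assignments Output of [assign_haplogroups()].
#' @return A tibble with `macrohaplogroup`, per-group counts (when a
#'   `group` column is present), `n`, `pct`.
#' @export
cohort_haplogroup_summary <- function(assignments) {
  total <- nrow(assignments)
  base <- assignments |>
    dplyr::count(.data$macrohaplogroup, name = "n") |>
    dplyr::mutate(pct = 100 * .data$n / total)
  if ("group" %in% names(assignments)) {
    by_group <- assignments |>
      dplyr::count(.data$macrohaplogroup, .data$group) |>
      tidyr::pivot_wider(names_from = "group", values_from = "n",
                         values_fill = 0L)
    base <- dplyr::left_join(by_group, base, by = "macrohaplogroup")
  }
  dplyr::arrange(base, dplyr::desc(.data$n))
}
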