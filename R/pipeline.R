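#' Filter and confirm raw calls for a cohort
#'
#' Applies the reporting threshold, the heteroplasmy filter and the
#' confirmation rule (any one confirming source suffices) per sample, and
#' returns the confirmed cohort call sets together with the counts of
#' calls removed at each step.
#'
#' @param primary Raw-call cohort tibble (with `sample`, variant columns,
#'   `allele_fraction`).
#' @param confirmations A single confirmation tibble or a list of them
#'   (each with `sample` and variant columns).
#' @param report_threshold,exclude_below,homoplasmic_cutoff Thresholds,
#'   see [filter_calls()] / [heteroplasmy_state()].
#' @return A list: `callsets` (confirmed cohort tibble with `state`),
#'   `log` (tibble of per-step removal counts).
#' @export
process_raw_calls <- function(primary, confirmations,
                              report_threshold = 0.05,
                              exclude_below = 0.25,
                              homoplasmic_cutoff = 0.95) {
  if (!is.list(confirmations) || is.data.frame(confirmations)) {
    confirmations <- list(confirmations)
  }
  samples <- unique(primary$sample)
  out <- vector("list", length(samples))
  n_raw <- nrow(primary)
  n_filtered <- 0L
  for (i in seq_along(samples)) {
    s <- samples[i]
    prim <- primary[primary$sample == s, , drop = FALSE]
    filt <- filter_calls(prim, report_threshold, exclude_below,
                         homoplasmic_cutoff)
    n_filtered <- n_filtered + nrow(filt)
    confs <- lapply(confirmations, function(cc) {
      cc[cc$sample == s, , drop = FALSE]
    })
    out[[i]] <- confirm_calls(filt, confs)
  }
  callsets <- dplyr::bind_rows(out)
  list(
    callsets = callsets,
    log = tibble::tibble(
      step = c("raw", "after_thresholds", "after_confirmation"),
      n_calls = c(n_raw, n_filtered, nrow(callsets))
    )
  )
}

#' Run the full case-control variant-spectrum study
#'
#' Orchestrates the whole analysis over confirmed cohort call sets: the
#' classification grid (reported/novel x transition/transversion/indel per
#' group), transition:transversion ratios, the novel-variant list with
#' loci, per-group novel-carrier proportions with modified-Wald confidence
#' intervals, two-tailed Fisher exact tests (novel carriers, novel
#' transversion carriers, heteroplasmy carriers and a configurable
#' haplogroup contrast), the disease-associated variant table, the rarity
#' histogram, haplogroup assignments and the cohort ancestry composition.
#'
#' @param callsets Confirmed cohort call tibble with `sample`, `group`
#'   (values `"case"`/`"control"`), variant columns and `allele_fraction`.
#' @param catalog An `mt_catalog`.
#' @param tree A `haplogroup_defs` object.
#' @param haplogroup_contrast Macrohaplogroup tested case vs control
#'   (default `"L2"`).
#' @param confidence CI level (default 0.95).
#' @return A `study_report` list; see Details.
#' @details The returned list has elements `grid`, `reported_share`,
#'   `tstv`, `novel_variants`, `novel_carriers`, `proportion_cis`,
#'   `fisher_tests`, `disease`, `rarity`, `heteroplasmies`, `assignments`,
#'   `haplogroup_summary`, `provenance`.
#' @export
run_study <- function(callsets, catalog, tree,
                      haplogroup_contrast = "L2", confidence = 0.95) {
  stopifnot(all(c("sample", "group", "position", "ref", "alt", "class",
                  "allele_fraction") %in% names(callsets)))
  groups <- c("case", "control")
  if (!all(groups %in% callsets$group)) {
    stop("callsets must contain both case and control samples")
  }
  n_by_group <- callsets |>
    dplyr::distinct(.data$sample, .data$group) |>
    dplyr::count(.data$group)
  n_case <- n_by_group$n[n_by_group$group == "case"]
  n_control <- n_by_group$n[n_by_group$group == "control"]

  grid <- variation_table(callsets, catalog)
  tstv <- lapply(stats::setNames(groups, groups), function(g) {
    rep_rows <- grid[grid$group == g & grid$novelty == "reported", ]
    tstv_ratio(rep_rows$n[rep_rows$class_group == "transition"],
               rep_rows$n[rep_rows$class_group == "transversion"])
  })

  novel_flag <- is_novel(callsets, catalog)
  novel <- callsets[novel_flag, , drop = FALSE]
  novel_variants <- if (nrow(novel) == 0L) {
    tibble::tibble(group = character(0), label = character(0),
                   locus = character(0), class = character(0))
  } else {
    tibble::tibble(
      group = novel$group,
      label = hgvs_label(novel),
      locus = locus_annotation(novel$position),
      class = novel$class,
      sample = novel$sample
    )
  }

  carriers <- function(d) length(unique(d$sample))
  x_case <- carriers(novel[novel$group == "case", ])
  x_control <- carriers(novel[novel$group == "control", ])
  novel_tv <- novel[class_group(novel$class) == "transversion", ,
                    drop = FALSE]
  xtv_case <- carriers(novel_tv[novel_tv$group == "case", ])
  xtv_control <- carriers(novel_tv[novel_tv$group == "control", ])

  cis <- dplyr::bind_rows(
    dplyr::mutate(modified_wald_ci(x_case + x_control, n_case + n_control,
                                   confidence),
                  quantity = "novel_carriers_all"),
    dplyr::mutate(modified_wald_ci(x_case, n_case, confidence),
                  quantity = "novel_carriers_case"),
    dplyr::mutate(modified_wald_ci(x_control, n_control, confidence),
                  quantity = "novel_carriers_control"),
    dplyr::mutate(modified_wald_ci(xtv_case + xtv_control,
                                   n_case + n_control, confidence),
                  quantity = "novel_tv_carriers_all"),
    dplyr::mutate(modified_wald_ci(xtv_case, n_case, confidence),
                  quantity = "novel_tv_carriers_case"),
    dplyr::mutate(modified_wald_ci(xtv_control, n_control, confidence),
                  quantity = "novel_tv_carriers_control")
  )

  het <- callsets[callsets$state == "heteroplasmic", , drop = FALSE]
  h_case <- carriers(het[het$group == "case", ])
  h_control <- carriers(het[het$group == "control", ])

  assignments <- assign_haplogroups(callsets, tree)
  hap_summary <- cohort_haplogroup_summary(assignments)
  in_contrast <- assignments$macrohaplogroup == haplogroup_contrast
  hc_case <- sum(in_contrast & assignments$group == "case")
  hc_control <- sum(in_contrast & assignments$group == "control")

  fisher <- tibble::tibble(
    test = c("novel_carriers", "novel_transversion_carriers",
             "heteroplasmy_carriers",
             paste0("haplogroup_", haplogroup_contrast)),
    a = c(x_case, xtv_case, h_case, hc_case),
    b = c(n_case - x_case, n_case - xtv_case, n_case - h_case,
          n_case - hc_case),
    c = c(x_control, xtv_control, h_control, hc_control),
    d = c(n_control - x_control, n_control - xtv_control,
          n_control - h_control, n_control - hc_control)
  )
  fisher$p_value <- vapply(seq_len(nrow(fisher)), function(i) {
    fisher_exact_two_tailed(c(fisher$a[i], fisher$b[i],
                              fisher$c[i], fisher$d[i]))
  }, numeric(1))
  fisher$significant <- fisher$p_value < 0.05

  structure(list(
    grid = grid,
    reported_share = reported_share(grid),
    tstv = tstv,
    novel_variants = novel_variants,
    novel_carriers = tibble::tibble(
      group = groups, carriers = c(x_case, x_control),
      n = c(n_case, n_control)
    ),
    proportion_cis = cis,
    fisher_tests = fisher,
    disease = disease_variant_table(callsets, catalog),
    rarity = rarity_histogram(callsets),
    heteroplasmies = het,
    assignments = assignments,
    haplogroup_summary = hap_summary,
    provenance = list(
      catalog_source = catalog$source, catalog_version = catalog$version,
      n_case = n_case, n_control = n_control,
      n_instances = nrow(callsets),
      confidence = confidence
    )
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<study_report> %d cases, %d controls, %s variant instances\n",
              p$n_case, p$n_control, format(p$n_instances, big.mark = ",")))
  cat(sprintf("  previously reported: %.1f%%; ts:tv %s (cases), %s (controls)\n",
              100 * x$reported_share, x$tstv$case$label, x$tstv$control$label))
  cat(sprintf("  novel carriers: %d/%d cases, %d/%d controls\n",
              x$novel_carriers$carriers[1], x$novel_carriers$n[1],
              x$novel_carriers$carriers[2], x$novel_carriers$n[2]))
  invisible(x)
}

#' Write the study report tables to a directory
#'
#' One TSV per report section plus a plain-text summary.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(report$grid, file.path(dir, "variation_grid.tsv"))
  readr::write_tsv(report$novel_variants, file.path(dir, "novel_variants.tsv"))
  readr::write_tsv(report$proportion_cis, file.path(dir, "proportion_cis.tsv"))
  readr::write_tsv(report$fisher_tests, file.path(dir, "fisher_tests.tsv"))
  readr::write_tsv(report$disease$table, file.path(dir, "disease_variants.tsv"))
  readr::write_tsv(report$rarity, file.path(dir, "rarity_histogram.tsv"))
  readr::write_tsv(report$assignments, file.path(dir, "haplogroup_assignments.tsv"))
  readr::write_tsv(report$haplogroup_summary,
                   file.path(dir, "haplogroup_summary.tsv"))
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(report)
  invisible(dir)
}
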