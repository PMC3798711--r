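#' Disease-associated mtDNA variants with case/control observation counts
#'
#' The 31 disease-associated polymorphisms (MITOMAP-annotated, at least one
#' published disease linkage) observed in the 22-case / 22-control study
#' cohort, with their loci, amino-acid changes, annotation strings and the
#' number of carriers in each group. These printed counts drive the default
#' carriage frequencies of the cohort simulator.
#'
#' @return A tibble: `position`, `ref`, `alt`, `locus`, `aa_change`,
#'   `disease_annotations`, `case_n`, `control_n`.
#' @export
mitomap_disease_variants <- function() {
  tibble::tribble(
    ~position, ~ref, ~alt, ~locus, ~aa_change, ~disease_annotations, ~case_n, ~control_n,
    150L, "C", "T", "D-loop", "-", "Longevity; cervical carcinoma; HPV infection risk", 9L, 11L,
    195L, "T", "C", "D-loop", "-", "Bipolar disorder-associated", 13L, 11L,
    921L, "T", "C", "12S rRNA", "-", "Possibly left ventricular non-compaction-associated", 0L, 3L,
    961L, "T", "C", "12S rRNA", "-", "DEAF; possibly left ventricular non-compaction-associated", 0L, 1L,
    2352L, "T", "C", "16S rRNA", "-", "Possibly left ventricular non-compaction-associated", 7L, 8L,
    3010L, "G", "A", "16S rRNA", "-", "Cyclic vomiting syndrome with migraine", 4L, 1L,
    3308L, "T", "C", "ND1", "Met>Thr", "MELAS; DEAF enhancer; hypertension", 3L, 3L,
    3396L, "T", "C", "ND1", "Syn.", "Non-syndromic hearing loss; maternally inherited DM & deafness", 2L, 0L,
    3866L, "T", "C", "ND1", "Ile>Thr", "LHON (secondary mutation); limb claudication", 0L, 1L,
    4216L, "T", "C", "ND1", "Tyr>His", "LHON (secondary mutation); insulin resistance", 1L, 0L,
    5460L, "G", "A", "ND2", "Ala>Thr", "Alzheimer's disease; Parkinson's disease", 1L, 1L,
    5655L, "T", "C", "tRNA Ala", "-", "DEAF enhancer", 3L, 3L,
    6150L, "G", "A", "CO1", "Val>Ile", "Prostate cancer", 2L, 1L,
    6253L, "T", "C", "CO1", "Met>Thr", "Prostate cancer", 1L, 0L,
    6480L, "G", "A", "CO1", "Val>Ile", "Prostate cancer", 1L, 0L,
    6663L, "A", "G", "CO1", "Ile>Val", "Prostate cancer", 2L, 0L,
    8932L, "C", "T", "ATP6", "Pro>Ser", "Prostate cancer", 2L, 0L,
    10398L, "A", "G", "ND3", "Thr>Ala", "PD protective factor; longevity; alt. cell pH; met. syn.; breast cancer risk", 21L, 19L,
    11467L, "A", "G", "ND4", "Syn.", "Altered brain pH", 0L, 1L,
    12236L, "G", "A", "tRNA Ser (2)", "-", "DEAF", 3L, 2L,
    12308L, "A", "G", "tRNA Leu (2)", "-", "CPEO; stroke; CM; breast, renal, prostate cancer risk; alt. brain pH", 0L, 1L,
    12372L, "G", "A", "ND5", "Syn.", "Altered brain pH", 0L, 1L,
    13135L, "G", "A", "ND5", "Ala>Thr", "Possible hypertrophic cardiomyopathy association", 1L, 0L,
    13708L, "G", "A", "ND5", "Ala>Thr", "LHON; increased MS risk; higher frequency in PD and AD", 1L, 2L,
    14319L, "T", "C", "ND6", "Asn>Asp", "Parkinson's disease, early onset", 0L, 1L,
    15043L, "G", "A", "CYB", "Syn.", "Major depressive disorder", 0L, 2L,
    15497L, "G", "A", "CYB", "Gly>Ser", "Obesity; exercise intolerance", 0L, 1L,
    15812L, "G", "A", "CYB", "Val>Met", "LHON (secondary mutation)", 0L, 1L,
    15927L, "G", "A", "tRNA Thr", "-", "Multiple sclerosis; DEAF1555 increased penetrance", 0L, 1L,
    15942L, "T", "C", "tRNA Thr", "-", "Possibly left ventricular non-compaction-associated", 2L, 1L,
    16189L, "T", "C", "D-loop", "-", "DM type 2; cardiomyopathy; endometrial cancer risk; mtDNA copy #; met. syn.", 5L, 10L
  )
}

#' The six confirmed heteroplasmic variants of the study cohort
#'
#' @return A tibble `position`, `ref`, `alt` (all previously reported
#'   transitions, observed at allele fractions between 25% and 60%).
#' @export
known_heteroplasmies <- function() {
  tibble::tibble(
    position = c(310L, 1999L, 13581L, 16150L, 16390L, 16399L),
    ref = c("T", "A", "T", "C", "G", "A"),
    alt = c("C", "G", "C", "T", "A", "G")
  )
}

# transition partner / transversion partners of a base
transition_partner <- function(base) {
  c(A = "G", G = "A", C = "T", T = "C")[base]
}
transversion_partners <- function(base) {
  if (base %in% c("A", "G")) c("C", "T") else c("A", "G")
}

# Deterministic synthetic universe shared by synthetic_catalog() and
# synthetic_haplogroup_tree(): haplogroup tree with defining variants, a
# reported-polymorphism pool and common indel polymorphisms, all with
# alleles consistent with the synthetic reference. Internal fixed seed:
# identical across sessions, independent of user seeds.
synthetic_defs <- function(ref = rcrs_synthetic()) {
  dv <- mitomap_disease_variants()
  het <- known_heteroplasmies()
  reserved <- c(dv$position, het$position,
                301:311, 3107L,
                unlist(lapply(rcrs_planted_tracts(),
                              function(t) t$start:(t$start + t$len - 1L))))
  # call space mirrors the single long amplicon: 10..16496
  avail <- setdiff(10:16496, reserved)
  # n_def: defining variants on the edge into each node; n_tv: how many of
  # them are transversions. The tv allocation is deterministic and chosen
  # so the edge-inclusion-weighted expected instance ratio of defining
  # variants is ~28:1 ts:tv under the default macrohaplogroup weights
  # (random placement would make the cohort ratio converge to whatever the
  # draw happened to put on heavily shared edges).
  tree_shape <- tibble::tribble(
    ~name, ~parent, ~macrohaplogroup, ~n_def, ~n_tv,
    "H", NA_character_, "H", 0L, 0L,
    "U", "H", "U", 10L, 1L,
    "U6", "U", "U", 3L, 0L,
    "J", "H", "J", 14L, 1L,
    "M", "H", "M", 30L, 2L,
    "L3", "H", "L3", 34L, 1L,
    "L3e", "L3", "L3", 4L, 1L,
    "L2", "H", "L2", 36L, 1L,
    "L2a", "L2", "L2", 5L, 1L,
    "L1", "H", "L1", 38L, 1L,
    "L1b", "L1", "L1", 5L, 0L,
    "L0", "H", "L0", 42L, 2L,
    "L0a", "L0", "L0", 4L, 0L
  )
  withr::with_seed(24601L, {
    n_def_total <- sum(tree_shape$n_def)
    def_pos <- sample(avail, n_def_total)
    avail2 <- setdiff(avail, def_pos)
    n_pool_ts <- 560L
    n_pool_tv <- 20L
    pool_pos <- sample(avail2, n_pool_ts + n_pool_tv)

    make_subs <- function(positions, is_tv) {
      is_tv <- rep_len(is_tv, length(positions))
      refb <- reference_base(ref, positions)
      alt <- ifelse(is_tv,
                    vapply(refb, function(b) sample(transversion_partners(b), 1),
                           character(1)),
                    unname(transition_partner(refb)))
      tibble::tibble(position = positions, ref = refb, alt = unname(alt))
    }
    # first n_tv positions of each edge's block are transversions
    def_is_tv <- unlist(lapply(seq_len(nrow(tree_shape)), function(i) {
      k <- tree_shape$n_def[i]
      if (k == 0L) return(logical(0))
      seq_len(k) <= tree_shape$n_tv[i]
    }))
    defining <- make_subs(def_pos, def_is_tv)
    pool <- rbind(
      make_subs(pool_pos[seq_len(n_pool_ts)], FALSE),
      make_subs(pool_pos[n_pool_ts + seq_len(n_pool_tv)], TRUE)
    )
    # common indel polymorphisms at homopolymer tracts, canonical placement
    indels <- tibble::tibble(
      position = c(309L, 467L, 16260L, 8870L),
      ref = c("", "", "", "T"),
      alt = c("C", "C", "C", "")
    )
    indels_v <- normalize_variants(
      mt_variants(indels$position, indels$ref, indels$alt), ref)

    # distribute defining variants over tree edges
    edge_idx <- rep(seq_len(nrow(tree_shape)), tree_shape$n_def)
    tree <- tree_shape[, c("name", "parent", "macrohaplogroup")]
    tree$defining <- vapply(seq_len(nrow(tree_shape)), function(i) {
      rows <- defining[edge_idx == i, , drop = FALSE]
      if (nrow(rows) == 0L) return("")
      v <- mt_variants(rows$position, rows$ref, rows$alt)
      paste(hgvs_label(v, ref), collapse = ",")
    }, character(1))

    list(ref = ref, tree = tree, defining = defining, pool = pool,
         indels = indels_v, disease = dv, heteroplasmies = het)
  })
}

#' Synthetic haplogroup definition table
#'
#' A curated fixture tree of the eight macrohaplogroups observed in the
#' study population (African L0-L3; Eurasian M, J, H, U), two to three
#' levels deep, with the reference haplogroup H at the root (empty defining
#' set) and disjoint defining-variant sets across macrohaplogroups.
#' Defining-set sizes scale with each lineage's divergence from the
#' rCRS-like root, so African genomes carry realistically many more
#' variants than European ones. Deterministic; alleles are consistent with
#' [rcrs_synthetic()].
#'
#' @param ref The reference the definitions are written against (default
#'   [rcrs_synthetic()]).
#' @return A `haplogroup_defs` object (see [haplogroup_defs()]).
#' @export
synthetic_haplogroup_tree <- function(ref = rcrs_synthetic()) {
  defs <- synthetic_defs(ref)
  haplogroup_defs(defs$tree, ref)
}

#' Synthetic variant catalog
#'
#' A MITOMAP-like catalog fixture: the 31 disease-associated variants with
#' their printed annotations, the six confirmed heteroplasmic variants, all
#' haplogroup-defining variants of the synthetic tree, a
#' transition-dominated pool of common polymorphisms (580 substitutions at
#' a 28:1 transition:transversion composition) and four indel polymorphisms
#' at homopolymer tracts. Deterministic and consistent with
#' [rcrs_synthetic()].
#'
#' @param ref Reference (default [rcrs_synthetic()]).
#' @return An `mt_catalog`.
#' @export
synthetic_catalog <- function(ref = rcrs_synthetic()) {
  defs <- synthetic_defs(ref)
  dv <- defs$disease
  het <- defs$heteroplasmies
  entries <- dplyr::bind_rows(
    tibble::tibble(position = dv$position, ref = dv$ref, alt = dv$alt,
                   locus = dv$locus, aa_change = dv$aa_change,
                   disease_annotations = dv$disease_annotations),
    tibble::tibble(position = het$position, ref = het$ref, alt = het$alt,
                   locus = locus_annotation(het$position),
                   aa_change = "-", disease_annotations = ""),
    tibble::tibble(position = defs$defining$position,
                   ref = defs$defining$ref, alt = defs$defining$alt,
                   locus = locus_annotation(defs$defining$position),
                   aa_change = ifelse(
                     is_coding_position(defs$defining$position), "Syn.", "-"),
                   disease_annotations = ""),
    tibble::tibble(position = defs$pool$position, ref = defs$pool$ref,
                   alt = defs$pool$alt,
                   locus = locus_annotation(defs$pool$position),
                   aa_change = ifelse(
                     is_coding_position(defs$pool$position), "Syn.", "-"),
                   disease_annotations = ""),
    tibble::tibble(position = defs$indels$position, ref = defs$indels$ref,
                   alt = defs$indels$alt,
                   locus = locus_annotation(defs$indels$position),
                   aa_change = "-", disease_annotations = "")
  )
  v <- mt_variants(entries$position, entries$ref, entries$alt)
  entries$class <- v$class
  entries <- entries[, c("position", "ref", "alt", "class", "locus",
                         "aa_change", "disease_annotations")]
  new_catalog(entries, source = "synthetic_mitomap_subset", version = "1.0")
}

#' Simulation configuration
#'
#' Defaults emulate the study cohort: 22 cases and 22 age-matched controls;
#' macrohaplogroup composition matching the observed 86% African / 11%
#' European / 2% Asian maternal ancestry; a mean total variant burden near
#' 49 per sample (about 2,166 instances cohort-wide); a 28:1 transition
#' bias among reported variants; a 0.2% novel-variant rate per instance; a
#' 6/44 per-sample heteroplasmy rate with fractions uniform on
#' \[0.25, 0.60\]; and carriage of the 31 disease-associated variants at the
#' printed per-group frequencies.
#'
#' @param n_cases,n_controls Group sizes.
#' @param macro_weights Named macrohaplogroup sampling weights (must sum
#'   to 1). Defaults to the observed cohort composition.
#' @param private_mean Poisson mean of private variants per sample.
#' @param ts_tv_ratio Transition:transversion bias of private substitutions.
#' @param novel_rate Novel-variant rate per emitted variant instance.
#' @param heteroplasmy_rate Per-sample probability of one heteroplasmy.
#' @param heteroplasmy_range Allele-fraction range of heteroplasmies.
#' @param common_indel_freqs Carriage frequencies of the catalog's four
#'   common indel polymorphisms.
#' @param use_disease_freqs Carry the disease-associated variants at their
#'   printed per-group frequencies (`TRUE`) or not at all (`FALSE`).
#' @param seed Integer random seed.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_cases = 22L, n_controls = 22L,
                              macro_weights = c(L0 = 2, L1 = 9, L2 = 12,
                                                L3 = 15, M = 1, J = 2,
                                                H = 1, U = 2) / 44,
                              private_mean = 10,
                              ts_tv_ratio = 28,
                              novel_rate = 0.002,
                              heteroplasmy_rate = 6 / 44,
                              heteroplasmy_range = c(0.25, 0.60),
                              common_indel_freqs = c(0.55, 0.50, 0.25, 0.05),
                              use_disease_freqs = TRUE,
                              seed = 1L) {
  if (abs(sum(macro_weights) - 1) > 1e-8) {
    stop("macrohaplogroup weights must sum to 1")
  }
  rates <- c(novel_rate, heteroplasmy_rate, common_indel_freqs)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  stopifnot(n_cases >= 1L, n_controls >= 1L, private_mean >= 0,
            ts_tv_ratio > 0,
            heteroplasmy_range[1] >= 0.25, heteroplasmy_range[2] <= 1)
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    macro_weights = macro_weights, private_mean = private_mean,
    ts_tv_ratio = ts_tv_ratio, novel_rate = novel_rate,
    heteroplasmy_rate = heteroplasmy_rate,
    heteroplasmy_range = heteroplasmy_range,
    common_indel_freqs = common_indel_freqs,
    use_disease_freqs = use_disease_freqs,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# expected total variant instances per sample under a config + tree
expected_burden <- function(config, defs_tree, disease) {
  # mean path defining-set size per macrohaplogroup (average over that
  # macrohaplogroup's nodes, sampled uniformly within the lineage)
  per_macro <- vapply(names(config$macro_weights), function(m) {
    nodes <- which(defs_tree$macrohaplogroup == m)
    mean(vapply(defs_tree$path_keys[nodes], length, integer(1)))
  }, numeric(1))
  e_def <- sum(config$macro_weights * per_macro)
  e_dis <- if (config$use_disease_freqs) {
    n <- config$n_cases + config$n_controls
    (config$n_cases * sum(disease$case_n / 22) +
       config$n_controls * sum(disease$control_n / 22)) / n
  } else 0
  e_def + e_dis + sum(config$common_indel_freqs) + config$private_mean
}

#' Simulate a case-control mtDNA cohort with full truth tables
#'
#' Each sample draws a haplogroup (a node of the synthetic tree, uniformly
#' within its sampled macrohaplogroup) and receives the defining variants
#' of its root-to-node path; disease-associated variants at the printed
#' per-group carriage frequencies; common indel polymorphisms at
#' homopolymer tracts; and Poisson-distributed private variants drawn from
#' the catalog's reported-polymorphism pool with the configured transition
#' bias. A private draw is novel (a substitution at a position absent from
#' the catalog) with a probability calibrated so the per-instance novel
#' rate matches `config$novel_rate`. One variant per sample is made
#' heteroplasmic (fraction uniform on the configured range) with
#' probability `config$heteroplasmy_rate`; all other variants are
#' homoplasmic (fraction 1).
#'
#' @param config A [simulation_config()].
#' @param ref Reference (default [rcrs_synthetic()]).
#' @return A list: `callsets` (cohort call tibble with `sample`, `group`,
#'   variant columns, `allele_fraction`, `state`), `truth` (a list with
#'   `haplogroups`, `heteroplasmies`, `novel` key vector, `config`),
#'   `catalog`, `tree`, `reference`.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            ref = rcrs_synthetic()) {
  defs <- synthetic_defs(ref)
  tree <- synthetic_haplogroup_tree(ref)
  catalog <- synthetic_catalog(ref)
  disease <- defs$disease
  n <- config$n_cases + config$n_controls
  samples <- sprintf("S%02d", seq_len(n))
  groups <- c(rep("case", config$n_cases), rep("control", config$n_controls))
  p_tv <- 1 / (1 + config$ts_tv_ratio)
  e_total <- expected_burden(config, tree, disease)
  p_novel <- min(1, config$novel_rate * e_total /
                   max(config$private_mean, 1e-9))
  pool_v <- mt_variants(defs$pool$position, defs$pool$ref, defs$pool$alt)
  pool_keys <- variant_key(pool_v)
  indel_v <- defs$indels
  het_v <- mt_variants(defs$heteroplasmies$position,
                       defs$heteroplasmies$ref, defs$heteroplasmies$alt)
  catalog_positions <- unique(catalog$entries$position)

  withr::with_seed(config$seed, {
    truth_hap <- character(n)
    all_rows <- vector("list", n)
    het_truth <- list()
    novel_keys <- character(0)

    for (i in seq_len(n)) {
      macro <- sample(names(config$macro_weights), 1,
                      prob = config$macro_weights)
      nodes <- which(tree$macrohaplogroup == macro)
      node <- if (length(nodes) == 1L) nodes else sample(nodes, 1)
      truth_hap[i] <- tree$name[node]
      path <- tree$path_keys[[node]]

      rows <- list()
      if (length(path) > 0L) {
        pm <- stringr::str_match(path, "^(\\d+):(.+)>(.+)$")
        rows$defining <- tibble::tibble(position = as.integer(pm[, 2]),
                                        ref = pm[, 3], alt = pm[, 4])
      }
      if (config$use_disease_freqs) {
        freq <- if (groups[i] == "case") disease$case_n else disease$control_n
        carry <- stats::runif(nrow(disease)) < freq / 22
        if (any(carry)) {
          rows$disease <- disease[carry, c("position", "ref", "alt")]
        }
      }
      carry_ind <- stats::runif(nrow(indel_v)) < config$common_indel_freqs
      if (any(carry_ind)) {
        rows$indel <- indel_v[carry_ind, c("position", "ref", "alt")]
      }
      n_priv <- stats::rpois(1, config$private_mean)
      if (n_priv > 0L) {
        priv <- vector("list", n_priv)
        for (k in seq_len(n_priv)) {
          if (stats::runif(1) < p_novel) {
            repeat {
              p <- sample(10:16496, 1)
              if (p == 3107L || p %in% catalog_positions) next
              rb <- reference_base(ref, p)
              if (rb == "N") next
              alt <- if (stats::runif(1) < p_tv) {
                sample(transversion_partners(rb), 1)
              } else {
                unname(transition_partner(rb))
              }
              priv[[k]] <- tibble::tibble(position = p, ref = rb, alt = alt)
              novel_keys <- c(novel_keys, sprintf("%d:%s>%s", p, rb, alt))
              break
            }
          } else {
            j <- sample(length(pool_keys), 1)
            priv[[k]] <- defs$pool[j, c("position", "ref", "alt")]
          }
        }
        rows$private <- dplyr::bind_rows(priv)
      }
      d <- dplyr::bind_rows(rows)
      d <- d[!duplicated(sprintf("%d:%s>%s", d$position,
                                 ifelse(d$ref == "", "-", d$ref),
                                 ifelse(d$alt == "", "-", d$alt))), ,
             drop = FALSE]
      d$allele_fraction <- 1
      # heteroplasmy: one of the six known heteroplasmic variants
      if (stats::runif(1) < config$heteroplasmy_rate) {
        hv <- het_v[sample(nrow(het_v), 1), ]
        frac <- stats::runif(1, config$heteroplasmy_range[1],
                             config$heteroplasmy_range[2])
        hk <- variant_key(hv)
        dk <- sprintf("%d:%s>%s", d$position, d$ref, d$alt)
        if (hk %in% dk) {
          d$allele_fraction[dk == hk] <- frac
        } else {
          d <- dplyr::bind_rows(
            d, tibble::tibble(position = hv$position, ref = hv$ref,
                              alt = hv$alt, allele_fraction = frac))
        }
        het_truth[[length(het_truth) + 1L]] <-
          tibble::tibble(sample = samples[i], group = groups[i],
                         key = hk, allele_fraction = frac)
      }
      v <- mt_variants(d$position, d$ref, d$alt, d$allele_fraction)
      all_rows[[i]] <- tibble::tibble(
        sample = samples[i], group = groups[i],
        position = v$position, ref = v$ref, alt = v$alt, class = v$class,
        allele_fraction = v$allele_fraction,
        state = heteroplasmy_state(v$allele_fraction)
      )
    }

    callsets <- dplyr::bind_rows(all_rows)
    list(
      callsets = callsets,
      truth = list(
        haplogroups = tibble::tibble(sample = samples, group = groups,
                                     haplogroup = truth_hap),
        heteroplasmies = dplyr::bind_rows(het_truth),
        novel = unique(novel_keys),
        config = config
      ),
      catalog = catalog,
      tree = tree,
      reference = ref
    )
  })
}

#' Platform error profile
#'
#' Per-class false-negative probabilities (applied to each true in-region
#' variant) and false-positive rates (the target I/(I+B); spurious calls
#' are injected per retained true variant with odds fp/(1-fp), so the
#' realized rate estimates the configured one). Defaults follow the
#' observed platform behaviour: indel false negatives dominate, the
#' transversion false-positive rate is high relative to its small base.
#'
#' @param fn Named numeric: FN probability per class group.
#' @param fp Named numeric: target FP rate per class group.
#' @param coding_window Width of the per-sample random coding-region window
#'   added to the D-loop screened region (bp).
#' @return A `platform_profile` list.
#' @export
platform_profile <- function(fn = c(transition = 0.002, transversion = 0,
                                    indel = 0.75),
                             fp = c(transition = 0.01, transversion = 0.118,
                                    indel = 0),
                             coding_window = 300L) {
  stopifnot(all(fn >= 0 & fn <= 1), all(fp >= 0 & fp < 1))
  groups <- c("transition", "transversion", "indel")
  stopifnot(all(groups %in% names(fn)), all(groups %in% names(fp)))
  structure(list(fn = fn[groups], fp = fp[groups],
                 coding_window = as.integer(coding_window)),
            class = "platform_profile")
}

#' Overlay platform-specific errors on truth call sets
#'
#' Emulates the deep-sequencing vs orthogonal-validation comparison: each
#' sample receives a screened region (the D-loop portion of the amplicon
#' plus one random coding window, mimicking validation that targets the
#' most variable region), the orthogonal call set is the truth restricted
#' to that region, and the test call set is the truth minus sampled
#' false negatives plus sampled false positives. Errors are injected only
#' inside the screened region (outside it they would be unobservable to
#' the comparison) and every injection is recorded in a ledger.
#'
#' @param callsets Truth cohort call tibble (from [simulate_cohort()]).
#' @param profile A [platform_profile()].
#' @param ref Reference (default [rcrs_synthetic()]).
#' @param seed Integer seed for the error draws.
#' @return A list: `test` (cohort call tibble with errors), `orthogonal`
#'   (region-restricted truth), `regions` (named list of
#'   [screened_region()] per sample), `screened_bases` (total), `ledger`
#'   (tibble `sample`, `class_group`, `type` (`"FN"`/`"FP"`), `key`).
#' @export
simulate_platform_errors <- function(callsets, profile = platform_profile(),
                                     ref = rcrs_synthetic(), seed = 1L) {
  samples <- unique(callsets$sample)
  dloop <- c(10:576, 16024:16496)
  withr::with_seed(seed + 104729L, {
    test_rows <- list(); orth_rows <- list(); ledger <- list()
    regions <- list()
    for (s in samples) {
      calls <- callsets[callsets$sample == s, , drop = FALSE]
      win_start <- sample(600:16100, 1)
      region <- screened_region(
        c(dloop, win_start:(win_start + profile$coding_window - 1L)), ref)
      regions[[s]] <- region
      in_reg <- calls$position %in% region$positions
      inside <- calls[in_reg, , drop = FALSE]
      outside <- calls[!in_reg, , drop = FALSE]
      orth_rows[[s]] <- inside

      cg <- class_group(inside$class)
      fn_draw <- stats::runif(nrow(inside)) < profile$fn[cg]
      retained <- inside[!fn_draw, , drop = FALSE]
      if (any(fn_draw)) {
        ledger[[length(ledger) + 1L]] <- tibble::tibble(
          sample = s, class_group = cg[fn_draw], type = "FN",
          key = variant_key(inside[fn_draw, , drop = FALSE]))
      }
      # false positives: per retained true variant, same class, odds f/(1-f)
      rg <- class_group(retained$class)
      fp_odds <- profile$fp[rg] / (1 - profile$fp[rg])
      fp_draw <- stats::runif(nrow(retained)) < fp_odds
      fp_rows <- list()
      if (any(fp_draw)) {
        used <- c(inside$position, 3107L)
        for (idx in which(fp_draw)) {
          repeat {
            p <- sample(region$positions, 1)
            if (p %in% used) next
            rb <- reference_base(ref, p)
            if (rb == "N") next
            alt <- if (rg[idx] == "transition") {
              unname(transition_partner(rb))
            } else {
              sample(transversion_partners(rb), 1)
            }
            fp_rows[[length(fp_rows) + 1L]] <- tibble::tibble(
              sample = s, group = retained$group[1],
              position = p, ref = rb, alt = alt,
              class = classify_variant(rb, alt),
              allele_fraction = 1, state = "homoplasmic")
            used <- c(used, p)
            ledger[[length(ledger) + 1L]] <- tibble::tibble(
              sample = s, class_group = rg[idx], type = "FP",
              key = sprintf("%d:%s>%s", p, rb, alt))
            break
          }
        }
      }
      test_rows[[s]] <- dplyr::bind_rows(c(list(retained, outside), fp_rows))
    }
    list(
      test = dplyr::bind_rows(test_rows),
      orthogonal = dplyr::bind_rows(orth_rows),
      regions = regions,
      screened_bases = sum(vapply(regions, function(r) r$n_bases,
                                  integer(1))),
      ledger = dplyr::bind_rows(ledger)
    )
  })
}

#' Expand truth call sets into raw candidate calls with noise
#'
#' Produces the raw material for the filtering/confirmation workflow: a
#' primary call list per sample containing every true variant plus
#' low-fraction noise calls (below the 25% filtering threshold, some below
#' the 5% reporting threshold), and one confirmation list containing
#' exactly the true variants (so noise is never confirmed).
#'
#' @param callsets Truth cohort call tibble.
#' @param ref Reference.
#' @param noise_per_sample Mean number of sub-threshold noise calls.
#' @param seed Integer seed.
#' @return A list: `primary` (cohort raw-call tibble with `source =
#'   "primary"`), `confirmations` (tibble with `source = "reanalysis"`).
#' @export
simulate_raw_calls <- function(callsets, ref = rcrs_synthetic(),
                               noise_per_sample = 3, seed = 1L) {
  withr::with_seed(seed + 7919L, {
    samples <- unique(callsets$sample)
    noise <- list()
    for (s in samples) {
      k <- stats::rpois(1, noise_per_sample)
      if (k == 0L) next
      calls <- callsets[callsets$sample == s, , drop = FALSE]
      rows <- list()
      for (j in seq_len(k)) {
        repeat {
          p <- sample(10:16496, 1)
          rb <- reference_base(ref, p)
          if (rb == "N" || p %in% calls$position) next
          alt <- unname(transition_partner(rb))
          rows[[j]] <- tibble::tibble(
            sample = s, group = calls$group[1], position = p, ref = rb,
            alt = alt, class = "transition",
            allele_fraction = stats::runif(1, 0.01, 0.24))
          break
        }
      }
      noise[[s]] <- dplyr::bind_rows(rows)
    }
    primary <- dplyr::bind_rows(
      dplyr::mutate(callsets[, c("sample", "group", "position", "ref",
                                 "alt", "class", "allele_fraction")],
                    source = "primary"),
      dplyr::mutate(dplyr::bind_rows(noise), source = "primary")
    )
    confirmations <- dplyr::mutate(
      callsets[, c("sample", "group", "position", "ref", "alt", "class",
                   "allele_fraction")],
      source = "reanalysis")
    list(primary = primary, confirmations = confirmations)
  })
}
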