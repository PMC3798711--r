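#' Mitochondrial reference genome
#'
#' A light container for a circular mitochondrial reference sequence with
#' 1-based HGVS coordinates.
#'
#' @param sequence Single character string over A/C/G/T/N.
#' @param id Accession label, e.g. `"NC_012920.1"`.
#' @param circular Logical; mitochondrial genomes are circular.
#'
#' @return An object of class `mt_reference` with fields `id`, `sequence`,
#'   `length` and `circular`.
#' @export
mt_reference <- function(sequence, id = "custom", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    stop("reference sequence has zero length")
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("reference sequence contains characters outside A/C/G/T/N")
  }
  structure(
    list(
      id = id,
      sequence = sequence,
      length = nchar(sequence),
      circular = isTRUE(circular)
    ),
    class = "mt_reference"
  )
}

#' @export
print.mt_reference <- function(x, ...) {
  cat(sprintf(
    "<mt_reference> %s: %s bp%s\n",
    x$id, format(x$length, big.mark = ","),
    if (x$circular) ", circular" else ""
  ))
  invisible(x)
}

#' Read a single-record reference FASTA
#'
#' @param path Path to a FASTA file containing exactly one sequence record
#'   (wrapped or unwrapped).
#' @param circular Logical, whether the genome is circular.
#'
#' @return An [mt_reference()] object; the record name (first word) becomes
#'   the reference `id`.
#' @export
load_reference <- function(path, circular = TRUE) {
  if (!file.exists(path)) {
    stop("reference FASTA not found: ", path)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L) {
    stop("reference FASTA must contain exactly one record, found ", length(seqs))
  }
  id <- strsplit(names(seqs)[1], "\\s+")[[1]][1]
  mt_reference(as.character(seqs[[1]]), id = id, circular = circular)
}

#' Write a reference to FASTA
#'
#' @param ref An [mt_reference()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  seqs <- Biostrings::DNAStringSet(ref$sequence)
  names(seqs) <- ref$id
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

# Wrap a (possibly out-of-range) coordinate onto the circular genome.
circular_position <- function(pos, len) {
  ((pos - 1L) %% len) + 1L
}

#' Reference base(s) at 1-based positions
#'
#' Positions wrap around the origin on circular references.
#'
#' @param ref An [mt_reference()].
#' @param positions Integer vector of 1-based positions.
#' @return Character vector of single bases.
#' @export
reference_base <- function(ref, positions) {
  if (!ref$circular && any(positions < 1L | positions > ref$length)) {
    stop("position outside a linear reference")
  }
  pos <- circular_position(as.integer(positions), ref$length)
  vapply(pos, function(p) substr(ref$sequence, p, p), character(1))
}

# Position sets used when constructing the synthetic rCRS stand-in: every
# coordinate whose reference allele the printed tables pin down.
rcrs_constrained_bases <- function() {
  c(
    # placeholder base of the rCRS
    "3107" = "N",
    # control-region poly-C tract and its flanks
    "302" = "A", "303" = "C", "304" = "C", "305" = "C", "306" = "C",
    "307" = "C", "308" = "C", "309" = "C", "310" = "T",
    # novel variants (cases then control)
    "8274" = "C", "11813" = "C", "12266" = "A", "10694" = "A",
    # heteroplasmic variants
    "1999" = "A", "13581" = "T", "16150" = "C", "16390" = "G", "16399" = "A",
    # disease-associated catalog entries
    "150" = "C", "195" = "T", "921" = "T", "961" = "T", "2352" = "T",
    "3010" = "G", "3308" = "T", "3396" = "T", "3866" = "T", "4216" = "T",
    "5460" = "G", "5655" = "T", "6150" = "G", "6253" = "T", "6480" = "G",
    "6663" = "A", "8932" = "C", "10398" = "A", "11467" = "A", "12236" = "G",
    "12308" = "A", "12372" = "G", "13135" = "G", "13708" = "G", "14319" = "T",
    "15043" = "G", "15497" = "G", "15812" = "G", "15927" = "G", "15942" = "T",
    "16189" = "T"
  )
}

# Additional homopolymer windows planted in the synthetic reference so that
# indel error modelling has realistic sequence context beyond 303-309.
# Chosen away from every constrained position above.
rcrs_planted_tracts <- function() {
  list(
    list(start = 460L, base = "C", len = 8L),
    list(start = 1655L, base = "A", len = 6L),
    list(start = 5895L, base = "C", len = 7L),
    list(start = 8865L, base = "T", len = 6L),
    list(start = 12418L, base = "A", len = 8L),
    list(start = 16254L, base = "C", len = 7L)
  )
}

#' Synthetic rCRS stand-in
#'
#' A deterministic 16,569-bp synthetic reference that mirrors the coordinate
#' frame of the rCRS (NC_012920.1): the placeholder `N` at position 3107, the
#' poly-C tract at 303-309, several additional homopolymer tracts, and the
#' reference allele fixed at every position that appears in the bundled
#' variant catalog. All other bases are pseudo-random with a fixed internal
#' seed, so the sequence is identical across sessions. It is *not* the real
#' rCRS sequence; coordinates and local context match, genome-wide content
#' does not.
#'
#' @return An [mt_reference()] of length 16,569 with id
#'   `"NC_012920.1_synthetic"`.
#' @export
rcrs_synthetic <- function() {
  bases <- withr::with_seed(20130913L, {
    sample(c("A", "C", "G", "T"), 16569L, replace = TRUE,
           prob = c(0.31, 0.31, 0.13, 0.25))
  })
  for (tr in rcrs_planted_tracts()) {
    bases[tr$start:(tr$start + tr$len - 1L)] <- tr$base
  }
  fixed <- rcrs_constrained_bases()
  bases[as.integer(names(fixed))] <- unname(fixed)
  # avoid accidental extension of the 303-309 tract and other fixed runs
  bases[c(301L, 311L)] <- c("T", "A")
  mt_reference(paste(bases, collapse = ""), id = "NC_012920.1_synthetic")
}

# Simplified rCRS feature map (standard NC_012920.1 annotation). Used to
# label catalog entries and novel variants with a locus name.
mt_feature_table <- function() {
  tibble::tribble(
    ~locus, ~start, ~end,
    "D-loop", 1L, 576L,
    "tRNA Phe", 577L, 647L,
    "12S rRNA", 648L, 1601L,
    "tRNA Val", 1602L, 1670L,
    "16S rRNA", 1671L, 3229L,
    "tRNA Leu", 3230L, 3304L,
    "ND1", 3307L, 4262L,
    "tRNA Ile", 4263L, 4331L,
    "tRNA Gln", 4329L, 4400L,
    "tRNA Met", 4402L, 4469L,
    "ND2", 4470L, 5511L,
    "tRNA Trp", 5512L, 5579L,
    "tRNA Ala", 5587L, 5655L,
    "tRNA Asn", 5657L, 5729L,
    "tRNA Cys", 5761L, 5826L,
    "tRNA Tyr", 5826L, 5891L,
    "CO1", 5904L, 7445L,
    "tRNA Ser (1)", 7446L, 7514L,
    "tRNA Asp", 7518L, 7585L,
    "CO2", 7586L, 8269L,
    "tRNA Lys", 8295L, 8364L,
    "ATP8", 8366L, 8526L,
    "ATP6", 8527L, 9207L,
    "CO3", 9208L, 9990L,
    "tRNA Gly", 9991L, 10058L,
    "ND3", 10059L, 10404L,
    "tRNA Arg", 10405L, 10469L,
    "ND4L", 10470L, 10766L,
    "ND4", 10767L, 12137L,
    "tRNA His", 12138L, 12206L,
    "tRNA Ser (2)", 12207L, 12265L,
    "tRNA Leu (2)", 12266L, 12336L,
    "ND5", 12337L, 14148L,
    "ND6", 14149L, 14673L,
    "tRNA Glu", 14674L, 14742L,
    "CYB", 14747L, 15887L,
    "tRNA Thr", 15888L, 15953L,
    "tRNA Pro", 15956L, 16023L,
    "D-loop", 16024L, 16569L
  )
}

#' Locus annotation for mtDNA positions
#'
#' Maps 1-based rCRS positions onto the standard mitochondrial feature map
#' (genes, rRNAs, tRNAs, D-loop). Positions in inter-genic gaps are labelled
#' `"Non-coding"`.
#'
#' @param positions Integer vector of 1-based positions.
#' @return Character vector of locus names.
#' @export
locus_annotation <- function(positions) {
  feats <- mt_feature_table()
  vapply(as.integer(positions), function(p) {
    hit <- which(feats$start <= p & feats$end >= p)
    if (length(hit) == 0L) "Non-coding" else feats$locus[hit[1]]
  }, character(1))
}

#' Coding-region flag for mtDNA positions
#'
#' `TRUE` for positions inside a protein-coding gene of the standard feature
#' map.
#'
#' @param positions Integer vector of 1-based positions.
#' @return Logical vector.
#' @export
is_coding_position <- function(positions) {
  coding <- c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3", "ND3",
              "ND4L", "ND4", "ND5", "ND6", "CYB")
  locus_annotation(positions) %in% coding
}

#' PCR amplicon geometry against a reference
#'
#' The study design amplifies the mitochondrial genome as a single long PCR
#' amplicon that leaves a short stretch of the D-loop uncovered. Given the
#' uncovered coordinate ranges, this reports the uncovered size and the
#' fraction of the genome covered.
#'
#' @param ref An [mt_reference()].
#' @param uncovered A two-column matrix or data frame of 1-based inclusive
#'   (start, end) uncovered ranges. Defaults to the study amplicon's
#'   uncovered D-loop stretch: positions 1-9 and 16,497-16,569.
#'
#' @return A list with `uncovered_bp`, `covered_bp` and `coverage` (fraction
#'   of the genome inside the amplicon).
#' @export
amplicon_geometry <- function(ref,
                              uncovered = rbind(c(1L, 9L), c(16497L, 16569L))) {
  uncovered <- as.matrix(uncovered)
  stopifnot(ncol(uncovered) == 2L, all(uncovered[, 2] >= uncovered[, 1]))
  pos <- unique(unlist(apply(uncovered, 1L, function(r) seq(r[1], r[2]),
                             simplify = FALSE)))
  if (any(pos < 1L | pos > ref$length)) {
    stop("uncovered range outside the reference")
  }
  uncovered_bp <- length(pos)
  list(
    uncovered_bp = uncovered_bp,
    covered_bp = ref$length - uncovered_bp,
    coverage = (ref$length - uncovered_bp) / ref$length
  )
}

#' Homopolymer tracts of a reference
#'
#' Runs of `min_len` or more identical bases. The placeholder `N` never
#' forms a tract. Tracts are reported on the linear coordinate frame (a run
#' spanning the origin of a circular genome is reported as two runs).
#'
#' @param ref An [mt_reference()].
#' @param min_len Minimum run length (default 4).
#' @return A tibble with columns `start`, `end`, `base`, `length`.
#' @export
homopolymer_tracts <- function(ref, min_len = 4L) {
  bases <- strsplit(ref$sequence, "")[[1]]
  r <- rle(bases)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len & r$values != "N"
  tibble::tibble(
    start = starts[keep],
    end = ends[keep],
    base = r$values[keep],
    length = r$lengths[keep]
  )
}
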