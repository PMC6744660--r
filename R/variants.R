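# SNP and deletion calling from a gapped multiple alignment, with chemical
# (purine/pyrimidine) and codon-effect annotation.

ALIGNMENT_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Construct an alignment set
#'
#' Bundle a gapped multiple sequence alignment with its designated reference
#' and reading-frame offset. All sequences must have the same aligned length
#' and use only the alphabet `A,C,G,T,N,-`.
#'
#' @param sequences Named character vector of gapped (or ungapped) nucleotide
#'   strings; names are sample labels and must be unique.
#' @param reference_label Label of the reference sequence, present in
#'   `sequences`.
#' @param frame_offset 1-based ungapped reference position at which codon 1
#'   begins (default 1).
#' @return An object of class `alignment_set`: a list with elements
#'   `sequences`, `reference_label`, `frame_offset`.
#' @examples
#' aln <- alignment_set(c(ref = "ATGAAA", s1 = "ATGAAG"), "ref")
#' call_snps(aln, "s1")
#' @export
alignment_set <- function(sequences, reference_label, frame_offset = 1L) {
  md_check(is.character(sequences) && length(sequences) >= 1L,
           "`sequences` must be a named character vector")
  labels <- names(sequences)
  md_check(!is.null(labels) && all(nzchar(labels)) && !anyDuplicated(labels),
           "sequence labels must be unique and non-empty")
  sequences <- toupper(sequences)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    md_stop("aligned sequences must all have the same length",
            "musadicho_invalid_alignment")
  }
  bad <- vapply(strsplit(sequences, ""),
                function(s) any(!s %in% ALIGNMENT_ALPHABET), logical(1))
  if (any(bad)) {
    md_stop(sprintf("sequence '%s' contains characters outside {A,C,G,T,N,-}",
                    labels[which(bad)[1L]]),
            "musadicho_invalid_alignment")
  }
  md_check(is_string(reference_label), "`reference_label` must be a string")
  if (!reference_label %in% labels) {
    md_stop(sprintf("reference '%s' not present in the alignment",
                    reference_label),
            "musadicho_missing_sample")
  }
  md_check(is_count(frame_offset, min = 1L), "`frame_offset` must be >= 1")
  ref_len <- sum(strsplit(sequences[[reference_label]], "")[[1]] != "-")
  md_check(ref_len >= frame_offset + 2L,
           "reference must contain at least one full codon past `frame_offset`")
  structure(list(sequences = sequences,
                 reference_label = reference_label,
                 frame_offset = as.integer(frame_offset)),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("Alignment set: %d sequences x %d columns (reference '%s', frame offset %d)\n",
              length(x$sequences), nchar(x$sequences[[1L]]),
              x$reference_label, x$frame_offset))
  invisible(x)
}

#' Classify a nucleotide substitution chemically
#'
#' Assigns each base to the purine (`Pu` = A, G) or pyrimidine (`Py` = C, T)
#' class and calls the substitution a transition when the classes agree
#' (purine-to-purine or pyrimidine-to-pyrimidine) and a transversion
#' otherwise. Of the 12 ordered unequal base pairs, 4 are transitions and 8
#' transversions.
#'
#' @param ref_base,alt_base Single unambiguous bases in `A,C,G,T`; must
#'   differ.
#' @return Named character vector with elements `ref_class`, `alt_class`
#'   (`"Pu"` or `"Py"`) and `subst_class` (`"transition"` or
#'   `"transversion"`).
#' @examples
#' classify_substitution("G", "A") # transition
#' classify_substitution("T", "G") # transversion
#' @export
classify_substitution <- function(ref_base, alt_base) {
  md_check(is_string(ref_base) && ref_base %in% NUCLEOTIDES,
           "`ref_base` must be one of A, C, G, T")
  md_check(is_string(alt_base) && alt_base %in% NUCLEOTIDES,
           "`alt_base` must be one of A, C, G, T")
  md_check(ref_base != alt_base, "`ref_base` and `alt_base` must differ")
  rc <- base_class(ref_base)
  ac <- base_class(alt_base)
  c(ref_class = rc, alt_class = ac,
    subst_class = if (rc == ac) "transition" else "transversion")
}

#' Annotate the codon-level effect of a substitution
#'
#' Locates the codon containing an ungapped reference position, translates
#' the reference codon and the codon with the alternate base substituted
#' (standard genetic code), and reports whether the change is synonymous.
#'
#' @param position 1-based ungapped reference coordinate of the substitution.
#' @param ref_base,alt_base The reference and alternate bases (A/C/G/T).
#' @param reference_ungapped The ungapped reference sequence (character
#'   scalar).
#' @param frame_offset 1-based ungapped position where codon 1 begins.
#' @return A list with `codon_index`, `ref_aa`, `alt_aa` (3-letter symbols,
#'   stops as `"Ter"`) and `effect` (`"synonymous"` or `"non-synonymous"`).
#' @examples
#' annotate_codon_effect(6, "A", "G", "ATGAAA") # Lys -> Lys, synonymous
#' @export
annotate_codon_effect <- function(position, ref_base, alt_base,
                                  reference_ungapped, frame_offset = 1L) {
  md_check(is_count(position, min = 1L), "`position` must be a positive integer")
  md_check(is_string(reference_ungapped), "`reference_ungapped` must be a string")
  md_check(is_count(frame_offset, min = 1L), "`frame_offset` must be >= 1")
  ref <- strsplit(toupper(reference_ungapped), "")[[1]]
  n <- length(ref)
  md_check(position <= n, "`position` beyond the reference length")
  if (position < frame_offset) {
    md_stop(sprintf("position %d lies before the reading frame (offset %d)",
                    position, frame_offset),
            "musadicho_out_of_frame")
  }
  codon_index <- (position - frame_offset) %/% 3L + 1L
  start <- frame_offset + 3L * (codon_index - 1L)
  if (start + 2L > n) {
    md_stop(sprintf("position %d falls in an incomplete trailing codon",
                    position),
            "musadicho_out_of_frame")
  }
  codon <- ref[start:(start + 2L)]
  md_check(identical(codon[position - start + 1L], toupper(ref_base)),
           sprintf("reference base at position %d is '%s', not '%s'",
                   position, codon[position - start + 1L], ref_base))
  classify_substitution(ref_base, alt_base) # validates the base pair
  alt_codon <- codon
  alt_codon[position - start + 1L] <- toupper(alt_base)
  ref_aa <- translate_codon(paste(codon, collapse = ""))
  alt_aa <- translate_codon(paste(alt_codon, collapse = ""))
  list(codon_index = codon_index, ref_aa = ref_aa, alt_aa = alt_aa,
       effect = if (ref_aa == alt_aa) "synonymous" else "non-synonymous")
}

# Resolve a sample from an alignment_set and precompute the column map.
.aln_sample <- function(alignment, sample) {
  md_check(inherits(alignment, "alignment_set"),
           "`alignment` must be an alignment_set (see alignment_set())")
  if (!sample %in% names(alignment$sequences)) {
    md_stop(sprintf("sample '%s' not present in the alignment", sample),
            "musadicho_missing_sample")
  }
  ref <- strsplit(alignment$sequences[[alignment$reference_label]], "")[[1]]
  smp <- strsplit(alignment$sequences[[sample]], "")[[1]]
  ungapped_pos <- cumsum(ref != "-") # reference coordinate per column
  list(ref = ref, smp = smp, ungapped_pos = ungapped_pos,
       reference_ungapped = paste(ref[ref != "-"], collapse = ""))
}

#' Call SNPs for one sample against the alignment reference
#'
#' Reports one record per alignment column where both the reference and the
#' sample carry an unambiguous base (A/C/G/T) and those bases differ.
#' Columns holding a gap (`-`) or `N` on either side are excluded (their
#' count is available as attribute `n_excluded`). Positions are 1-based
#' ungapped reference coordinates, sorted ascending; each record carries the
#' chemical classification and the codon effect.
#'
#' @param alignment An [alignment_set()].
#' @param sample Label of the sample to compare against the reference.
#' @return A data frame of class `snp_records` with columns `position`,
#'   `ref_base`, `alt_base`, `ref_class`, `alt_class`, `subst_class`,
#'   `codon_index`, `ref_aa`, `alt_aa`, `effect`.
#' @examples
#' aln <- alignment_set(c(ref = "ATGAAA", s1 = "ATGAAG"), "ref")
#' call_snps(aln, "s1")
#' @export
call_snps <- function(alignment, sample) {
  a <- .aln_sample(alignment, sample)
  usable <- a$ref %in% NUCLEOTIDES & a$smp %in% NUCLEOTIDES
  diff_cols <- which(usable & a$ref != a$smp)
  excluded <- sum((a$ref != "-" | a$smp != "-") & !usable)
  rows <- lapply(diff_cols, function(col) {
    pos <- a$ungapped_pos[col]
    cls <- classify_substitution(a$ref[col], a$smp[col])
    eff <- annotate_codon_effect(pos, a$ref[col], a$smp[col],
                                 a$reference_ungapped,
                                 alignment$frame_offset)
    data.frame(position = pos, ref_base = a$ref[col], alt_base = a$smp[col],
               ref_class = unname(cls["ref_class"]),
               alt_class = unname(cls["alt_class"]),
               subst_class = unname(cls["subst_class"]),
               codon_index = eff$codon_index, ref_aa = eff$ref_aa,
               alt_aa = eff$alt_aa, effect = eff$effect,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), ref_base = character(),
               alt_base = character(), ref_class = character(),
               alt_class = character(), subst_class = character(),
               codon_index = integer(), ref_aa = character(),
               alt_aa = character(), effect = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excluded
  attr(out, "sample") <- sample
  class(out) <- c("snp_records", "data.frame")
  out
}

#' Detect deletions in a sample relative to the reference
#'
#' Finds maximal runs of `-` in the sample that sit opposite non-gap
#' reference bases and reports each run once, with its 1-based ungapped
#' reference start and length. Gaps in the *reference* opposite sample bases
#' are insertions, reported by [detect_insertions()] and never counted here.
#'
#' @inheritParams call_snps
#' @return Data frame with columns `start`, `length`, `kind` (always
#'   `"deletion"`).
#' @export
detect_deletions <- function(alignment, sample) {
  a <- .aln_sample(alignment, sample)
  del_col <- a$smp == "-" & a$ref != "-"
  r <- rle(del_col)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start = integer(), length = integer(),
                    kind = character(), stringsAsFactors = FALSE)
  for (k in keep) {
    cols <- starts[k]:ends[k]
    ref_bases <- sum(a$ref[cols] != "-")
    out <- rbind(out, data.frame(start = a$ungapped_pos[cols[1L]],
                                 length = ref_bases, kind = "deletion",
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Detect insertions in a sample relative to the reference
#'
#' Maximal runs where the reference holds `-` opposite sample bases. These
#' are reported separately and excluded from SNP-site summaries.
#'
#' @inheritParams call_snps
#' @return Data frame with columns `after` (ungapped reference position the
#'   insertion follows; 0 for an insertion before the first base), `length`
#'   and `kind` (always `"insertion"`).
#' @export
detect_insertions <- function(alignment, sample) {
  a <- .aln_sample(alignment, sample)
  ins_col <- a$ref == "-" & a$smp != "-"
  r <- rle(ins_col)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(after = integer(), length = integer(),
                    kind = character(), stringsAsFactors = FALSE)
  for (k in keep) {
    out <- rbind(out, data.frame(after = a$ungapped_pos[starts[k]],
                                 length = ends[k] - starts[k] + 1L,
                                 kind = "insertion", stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Summarise a sample's SNPs as a per-cultivar substitution profile
#'
#' Condenses a set of SNP records into the per-cultivar row format used for
#' reporting: total SNP-site count, the two most frequent substitution types
#' (ties broken lexicographically), the majority purine/pyrimidine pattern,
#' a representative amino-acid change, and the mutation type (non-synonymous
#' if *any* record is non-synonymous, else synonymous).
#'
#' @param snps A data frame as returned by [call_snps()].
#' @param cultivar Cultivar label for the summary row.
#' @return A [substitution_profile()] object.
#' @export
summarize_cultivar <- function(snps, cultivar) {
  md_check(is.data.frame(snps), "`snps` must be a data frame of SNP records")
  md_check(is_string(cultivar), "`cultivar` must be a string")
  n <- nrow(snps)
  if (n == 0L) {
    return(substitution_profile(cultivar = cultivar, n_snp_sites = 0L,
                                listed_types = NULL,
                                overall_class = NA_character_,
                                aa_change = NULL,
                                mutation_type = "synonymous"))
  }
  pair <- paste0(snps$ref_base, ">", snps$alt_base)
  tab <- table(pair)
  ord <- order(-as.integer(tab), names(tab)) # count desc, then lexicographic
  top <- names(tab)[ord][seq_len(min(2L, length(tab)))]
  listed <- data.frame(
    ref_base = substr(top, 1L, 1L),
    alt_base = substr(top, 3L, 3L),
    count = as.integer(tab[top]),
    stringsAsFactors = FALSE)

  patt <- paste0(snps$ref_class, "-", snps$alt_class)
  ptab <- table(patt)
  overall <- names(ptab)[order(-as.integer(ptab), names(ptab))][1L]

  mutation_type <- if (any(snps$effect == "non-synonymous"))
    "non-synonymous" else "synonymous"
  rep_rec <- if (mutation_type == "non-synonymous")
    snps[snps$effect == "non-synonymous", ][1L, ] else snps[1L, ]
  aa_change <- list(from_aa = rep_rec$ref_aa,
                    codon_index = rep_rec$codon_index,
                    to_aa = rep_rec$alt_aa)
  substitution_profile(cultivar = cultivar, n_snp_sites = n,
                       listed_types = listed, overall_class = overall,
                       aa_change = aa_change, mutation_type = mutation_type)
}
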