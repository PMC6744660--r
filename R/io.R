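# Plain-text readers and writers: FASTA, phenology/cytology CSV, histogram
# TSV + manifest, minimal VCF, and the study-style summary TSVs. All output
# is UTF-8 with LF line endings.

#' Read a (gapped) multi-FASTA file
#'
#' Parses via Biostrings, preserves record order, uppercases sequences and
#' validates that labels are unique and that sequences use only
#' `A,C,G,T,N,-`. Format violations name the offending record.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  md_check(is_string(path) && file.exists(path),
           sprintf("FASTA file not found: '%s'", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) md_stop(
                    sprintf("cannot parse FASTA '%s': %s", path,
                            conditionMessage(e)),
                    "musadicho_format_error"))
  if (!length(set)) {
    md_stop(sprintf("FASTA '%s' holds no records", path),
            "musadicho_format_error")
  }
  labels <- sub("\\s.*$", "", names(set)) # first token of the header
  if (anyDuplicated(labels)) {
    md_stop(sprintf("duplicate FASTA label '%s' in '%s'",
                    labels[duplicated(labels)][1L], path),
            "musadicho_format_error")
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- labels
  for (lbl in labels) {
    chars <- unique(strsplit(seqs[[lbl]], "")[[1]])
    bad <- setdiff(chars, ALIGNMENT_ALPHABET)
    if (length(bad)) {
      md_stop(sprintf("record '%s' contains invalid character(s): %s",
                      lbl, paste(bad, collapse = ", ")),
              "musadicho_format_error")
    }
  }
  seqs
}

#' Write sequences as 60-column wrapped FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  md_check(is.character(sequences) && !is.null(names(sequences)) &&
             !anyDuplicated(names(sequences)),
           "`sequences` must be uniquely named")
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read and write phenology tables
#'
#' CSV schema: `plant_id,cultivar,cycle,bunches` (empty `bunches` for
#' dead/missing observations).
#'
#' @param path CSV path.
#' @return `read_phenology()`: the phenology data frame.
#' @export
read_phenology <- function(path) {
  md_check(is_string(path) && file.exists(path),
           sprintf("phenology file not found: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "cultivar", "cycle", "bunches")
  if (!all(need %in% names(df))) {
    md_stop(sprintf("phenology CSV '%s' must have columns %s", path,
                    paste(need, collapse = ", ")),
            "musadicho_format_error")
  }
  df$bunches <- as.integer(df$bunches)
  df
}

#' @param records Phenology data frame.
#' @rdname read_phenology
#' @export
write_phenology <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cytology (chromosome-count) table
#'
#' CSV schema: `plant_id,cell_index,chromosome_count`.
#'
#' @param path CSV path.
#' @return Data frame with one row per counted metaphase cell.
#' @export
read_cytology <- function(path) {
  md_check(is_string(path) && file.exists(path),
           sprintf("cytology file not found: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "cell_index", "chromosome_count")
  if (!all(need %in% names(df))) {
    md_stop(sprintf("cytology CSV '%s' must have columns %s", path,
                    paste(need, collapse = ", ")),
            "musadicho_format_error")
  }
  df
}

#' Write and read flow histograms as TSV files with a manifest
#'
#' Each histogram is written as a two-column `channel<TAB>count` TSV named
#' `<plant_id>.tsv`; the manifest CSV (`plant_id,file`) records the cohort.
#'
#' @param histograms List of [flow_histogram()] objects.
#' @param dir Output directory (created if needed).
#' @param manifest Manifest file name within `dir`.
#' @return `write_histograms()`: the manifest path, invisibly;
#'   `read_histograms()`: a list of [flow_histogram()] objects.
#' @export
write_histograms <- function(histograms, dir, manifest = "manifest.csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(histograms, function(h) {
    f <- paste0(h$plant_id, ".tsv")
    utils::write.table(data.frame(channel = h$channels, count = h$counts),
                       file.path(dir, f), sep = "\t", row.names = FALSE,
                       quote = FALSE)
    data.frame(plant_id = h$plant_id, file = f, stringsAsFactors = FALSE)
  })
  mpath <- file.path(dir, manifest)
  utils::write.csv(do.call(rbind, rows), mpath, row.names = FALSE,
                   quote = FALSE)
  invisible(mpath)
}

#' @param manifest_path Path to a manifest CSV written by
#'   `write_histograms()`.
#' @rdname write_histograms
#' @export
read_histograms <- function(manifest_path) {
  md_check(is_string(manifest_path) && file.exists(manifest_path),
           sprintf("manifest not found: '%s'", manifest_path))
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  md_check(all(c("plant_id", "file") %in% names(man)),
           "manifest needs columns plant_id, file")
  dir <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    df <- utils::read.delim(file.path(dir, man$file[i]))
    flow_histogram(man$plant_id[i], df$channel, df$count)
  })
}

#' Write SNP records as a minimal VCF-style file
#'
#' One line per record: `CHROM` is the reference label, `POS` the ungapped
#' reference coordinate, `REF`/`ALT` the bases, and `INFO` carries
#' `SUBST` (transition/transversion), `EFFECT`, `CODON` (codon index) and
#' `AA` (`ref>alt` three-letter symbols). No genotype columns: samples are
#' haplotype consensus sequences.
#'
#' @param snps SNP records from [call_snps()].
#' @param reference_label Value for the `CHROM` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(snps, reference_label, path) {
  md_check(is.data.frame(snps), "`snps` must be a data frame")
  md_check(is_string(reference_label), "`reference_label` must be a string")
  header <- c("##fileformat=VCFv4.2",
              "##source=musadicho",
              paste0("##INFO=<ID=SUBST,Number=1,Type=String,",
                     "Description=\"transition or transversion\">"),
              paste0("##INFO=<ID=EFFECT,Number=1,Type=String,",
                     "Description=\"synonymous or non-synonymous\">"),
              "##INFO=<ID=CODON,Number=1,Type=Integer,Description=\"codon index\">",
              "##INFO=<ID=AA,Number=1,Type=String,Description=\"amino-acid change\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(snps)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSUBST=%s;EFFECT=%s;CODON=%d;AA=%s>%s",
            reference_label, snps$position, snps$ref_base, snps$alt_base,
            snps$subst_class, snps$effect, snps$codon_index, snps$ref_aa,
            snps$alt_aa)
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal VCF-style variant file
#'
#' Inverse of [write_variants_vcf()] for files written by this package.
#'
#' @param path VCF path.
#' @return Data frame with the [call_snps()] columns plus `chrom`.
#' @export
read_variants_vcf <- function(path) {
  md_check(is_string(path) && file.exists(path),
           sprintf("VCF file not found: '%s'", path))
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  empty <- data.frame(chrom = character(), position = integer(),
                      ref_base = character(), alt_base = character(),
                      subst_class = character(), effect = character(),
                      codon_index = integer(), ref_aa = character(),
                      alt_aa = character(), stringsAsFactors = FALSE)
  if (!length(body)) return(empty)
  parts <- strsplit(body, "\t", fixed = TRUE)
  info_field <- function(info, key) {
    m <- regmatches(info, regexec(paste0(key, "=([^;]+)"), info))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }
  rows <- lapply(parts, function(p) {
    if (length(p) < 8L) {
      md_stop(sprintf("malformed VCF line in '%s'", path),
              "musadicho_format_error")
    }
    aa <- strsplit(info_field(p[8], "AA"), ">", fixed = TRUE)[[1]]
    data.frame(chrom = p[1], position = as.integer(p[2]), ref_base = p[4],
               alt_base = p[5], subst_class = info_field(p[8], "SUBST"),
               effect = info_field(p[8], "EFFECT"),
               codon_index = as.integer(info_field(p[8], "CODON")),
               ref_aa = aa[1], alt_aa = aa[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a study-style per-cultivar substitution summary TSV
#'
#' One row per profile: SNP-site count, the listed substitution types, the
#' overall chemical pattern, the representative amino-acid change and the
#' mutation type.
#'
#' @param profiles List of [substitution_profile()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_substitution_table <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    types <- if (nrow(p$listed_types))
      paste(sprintf("%d%s>%s", p$listed_types$count, p$listed_types$ref_base,
                    p$listed_types$alt_base), collapse = " / ")
    else ""
    aa <- if (is.null(p$aa_change)) "" else
      sprintf("%s %d %s", p$aa_change$from_aa, p$aa_change$codon_index,
              p$aa_change$to_aa)
    data.frame(cultivar = p$cultivar, n_snp_sites = p$n_snp_sites,
               substitution_types = types,
               overall_class = ifelse(is.na(p$overall_class), "",
                                      p$overall_class),
               aa_change = aa, mutation_type = p$mutation_type,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
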