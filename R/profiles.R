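# Per-cultivar profiles: the simulation parameters and reporting rows.

#' Construct a substitution profile
#'
#' A substitution profile is one reporting row for a cultivar: how many SNP
#' sites it carries relative to the reference, the explicitly listed
#' substitution types with their counts, the overall purine/pyrimidine
#' pattern, a named amino-acid change, and whether the row is synonymous or
#' non-synonymous overall. Profiles are both the *output* of
#' [summarize_cultivar()] and the *input* to [implant_variants()].
#'
#' @param cultivar Cultivar label.
#' @param n_snp_sites Total number of SNP sites (>= sum of listed counts).
#' @param listed_types `NULL` or a data frame with columns `ref_base`,
#'   `alt_base`, `count`: the explicitly listed substitution types.
#' @param overall_class Majority chemical pattern: one of `"Pu-Pu"`,
#'   `"Py-Py"`, `"Pu-Py"`, `"Py-Pu"` (or `NA` for an empty profile).
#'   `Pu-Pu`/`Py-Py` profiles are transition-dominated, the others
#'   transversion-dominated.
#' @param aa_change `NULL` or a list with `from_aa`, `codon_index`, `to_aa`
#'   (3-letter amino-acid symbols, 1-based codon index).
#' @param mutation_type `"synonymous"` or `"non-synonymous"`; must agree
#'   with `aa_change` (`from_aa == to_aa` iff synonymous).
#' @return An object of class `substitution_profile`.
#' @examples
#' substitution_profile("Agbagba", 55,
#'   data.frame(ref_base = c("G", "A"), alt_base = c("A", "G"),
#'              count = c(26L, 12L)),
#'   "Pu-Pu", list(from_aa = "Lys", codon_index = 14, to_aa = "Lys"),
#'   "synonymous")
#' @export
substitution_profile <- function(cultivar, n_snp_sites, listed_types = NULL,
                                 overall_class = NA_character_,
                                 aa_change = NULL,
                                 mutation_type = c("synonymous",
                                                   "non-synonymous")) {
  md_check(is_string(cultivar), "`cultivar` must be a string")
  md_check(is_count(n_snp_sites), "`n_snp_sites` must be a non-negative integer")
  mutation_type <- match.arg(mutation_type)
  if (is.null(listed_types)) {
    listed_types <- data.frame(ref_base = character(), alt_base = character(),
                               count = integer(), stringsAsFactors = FALSE)
  }
  md_check(is.data.frame(listed_types) &&
             all(c("ref_base", "alt_base", "count") %in% names(listed_types)),
           "`listed_types` needs columns ref_base, alt_base, count")
  if (nrow(listed_types)) {
    md_check(all(listed_types$ref_base %in% NUCLEOTIDES) &&
               all(listed_types$alt_base %in% NUCLEOTIDES) &&
               all(listed_types$ref_base != listed_types$alt_base),
             "`listed_types` must hold unequal unambiguous base pairs")
    md_check(all(listed_types$count >= 0),
             "`listed_types$count` must be non-negative")
  }
  if (sum(listed_types$count) > n_snp_sites) {
    md_stop(sprintf(
      "listed substitution counts (%d) exceed n_snp_sites (%d) for '%s'",
      sum(listed_types$count), n_snp_sites, cultivar),
      "musadicho_invalid_profile")
  }
  if (!is.na(overall_class)) {
    md_check(overall_class %in% c("Pu-Pu", "Py-Py", "Pu-Py", "Py-Pu"),
             "`overall_class` must be one of Pu-Pu, Py-Py, Pu-Py, Py-Pu")
  }
  if (!is.null(aa_change)) {
    md_check(is.list(aa_change) &&
               all(c("from_aa", "codon_index", "to_aa") %in% names(aa_change)),
             "`aa_change` needs from_aa, codon_index, to_aa")
    md_check(is_count(aa_change$codon_index, min = 1L),
             "`aa_change$codon_index` must be a positive integer")
    syn <- identical(aa_change$from_aa, aa_change$to_aa)
    md_check(syn == (mutation_type == "synonymous"),
             "`mutation_type` inconsistent with `aa_change`")
  }
  structure(list(cultivar = cultivar,
                 n_snp_sites = as.integer(n_snp_sites),
                 listed_types = listed_types,
                 overall_class = overall_class,
                 aa_change = aa_change,
                 mutation_type = mutation_type),
            class = "substitution_profile")
}

#' @export
print.substitution_profile <- function(x, ...) {
  types <- if (nrow(x$listed_types))
    paste(sprintf("%d %s>%s", x$listed_types$count, x$listed_types$ref_base,
                  x$listed_types$alt_base), collapse = " / ")
  else "none listed"
  aa <- if (is.null(x$aa_change)) "-" else
    sprintf("%s %d %s", x$aa_change$from_aa, x$aa_change$codon_index,
            x$aa_change$to_aa)
  cat(sprintf("Substitution profile '%s': %d SNP sites, %s [%s], aa change %s, %s\n",
              x$cultivar, x$n_snp_sites, types,
              ifelse(is.na(x$overall_class), "-", x$overall_class), aa,
              x$mutation_type))
  invisible(x)
}

#' Built-in cultivar profiles for the six study cultivars
#'
#' Returns the simulation parameters for the single-bunching control
#' ('Agbagba') and the five inflorescence-dichotomous cultivars (DB1P, DB2P,
#' TB1P, TB2P, TB3P): plant-crop bunch count, ratoon-crop concordance
#' probability, true ploidy (x-multiplier of the basic number), and the
#' per-cultivar substitution profile. These encode the study conditions the
#' generators emulate: the control is triploid with 55 all-transition,
#' all-synonymous SNP sites, while the dichotomous cultivars are diploid
#' with 77-86 transversion-dominated, non-synonymous sites.
#'
#' @return Named list of `cultivar_profile` objects (fields `label`,
#'   `plant_crop_bunches`, `ratoon_concordance_prob`, `ploidy_truth`,
#'   `substitution_profile`).
#' @examples
#' names(cultivar_profiles())
#' cultivar_profiles()[["DB1P"]]$substitution_profile
#' @export
cultivar_profiles <- function() {
  lt <- function(r1, a1, c1, r2, a2, c2) {
    data.frame(ref_base = c(r1, r2), alt_base = c(a1, a2),
               count = as.integer(c(c1, c2)), stringsAsFactors = FALSE)
  }
  aa <- function(from, idx, to) list(from_aa = from, codon_index = idx,
                                     to_aa = to)
  spec <- list(
    Agbagba = list(1L, 1.00, 3L, substitution_profile(
      "Agbagba", 55L, lt("G", "A", 26, "A", "G", 12), "Pu-Pu",
      aa("Lys", 14L, "Lys"), "synonymous")),
    DB1P = list(2L, 0.65, 2L, substitution_profile(
      "DB1P", 82L, lt("T", "G", 46, "C", "A", 23), "Py-Pu",
      aa("Gly", 27L, "Val"), "non-synonymous")),
    DB2P = list(2L, 0.45, 2L, substitution_profile(
      "DB2P", 77L, lt("A", "C", 33, "G", "T", 12), "Pu-Py",
      aa("Leu", 16L, "Pro"), "non-synonymous")),
    TB1P = list(3L, 0.15, 2L, substitution_profile(
      "TB1P", 81L, lt("T", "A", 40, "C", "G", 18), "Py-Pu",
      aa("Val", 22L, "Lys"), "non-synonymous")),
    TB2P = list(3L, 0.05, 2L, substitution_profile(
      "TB2P", 79L, lt("A", "T", 33, "C", "A", 19), "Py-Pu",
      aa("Leu", 23L, "Gly"), "non-synonymous")),
    TB3P = list(3L, 0.00, 2L, substitution_profile(
      "TB3P", 86L, lt("G", "C", 28, "T", "G", 21), "Pu-Py",
      aa("Gly", 19L, "Val"), "non-synonymous"))
  )
  lapply(stats::setNames(names(spec), names(spec)), function(lbl) {
    s <- spec[[lbl]]
    structure(list(label = lbl,
                   plant_crop_bunches = s[[1]],
                   ratoon_concordance_prob = s[[2]],
                   ploidy_truth = s[[3]],
                   substitution_profile = s[[4]]),
              class = "cultivar_profile")
  })
}

#' @export
print.cultivar_profile <- function(x, ...) {
  cat(sprintf("Cultivar '%s': %d bunch(es) in plant crop, ratoon concordance %.2f, ploidy %dx\n",
              x$label, x$plant_crop_bunches, x$ratoon_concordance_prob,
              x$ploidy_truth))
  print(x$substitution_profile)
  invisible(x)
}
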