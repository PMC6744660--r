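# Crop-cycle concordance of bunch phenotypes.

#' Compute the crop-cycle concordance coefficient for a cultivar
#'
#' The concordance coefficient CC measures how faithfully a cultivar's
#' bunch phenotype persists across crop cycles:
#' `CC = sum(Nii) / (sum(Nii) + sum(Nij))`, where `Nii` counts ratoon-crop
#' observations whose bunch number equals the same plant's plant-crop bunch
#' number and `Nij` (i != j) counts those that differ. Both ratoon cycles
#' are pooled into one denominator. Ratoon observations with missing bunch
#' counts (dead plants) are excluded. CC is reported on `[0, 1]` (1 = fully
#' persistent, 0 = fully random); set `percent = TRUE` for the 0-100 scale.
#'
#' @param records Phenology data frame with columns `plant_id`, `cultivar`,
#'   `cycle` (`"plant"`, `"ratoon1"`, `"ratoon2"`) and `bunches` (1-3,
#'   `NA` for dead/missing).
#' @param cultivar Cultivar to summarise.
#' @param percent If `TRUE`, report `cc` on the 0-100 scale.
#' @return An object of class `concordance_summary`: a list with
#'   `cultivar`, `n_plants`, `n_concordant`, `n_discordant`, `cc` and
#'   `scale` (`"fraction"` or `"percent"`).
#' @examples
#' ph <- generate_phenology(cultivar_profiles()["Agbagba"], 10, 2, seed = 1)
#' compute_concordance(ph$records, "Agbagba")
#' @export
compute_concordance <- function(records, cultivar, percent = FALSE) {
  md_check(is.data.frame(records) &&
             all(c("plant_id", "cultivar", "cycle", "bunches") %in%
                   names(records)),
           "`records` needs columns plant_id, cultivar, cycle, bunches")
  md_check(is_string(cultivar), "`cultivar` must be a string")
  rec <- records[records$cultivar == cultivar, , drop = FALSE]
  md_check(nrow(rec) > 0L, sprintf("no records for cultivar '%s'", cultivar))
  md_check(all(rec$cycle %in% c("plant", "ratoon1", "ratoon2")),
           "`cycle` must be one of plant, ratoon1, ratoon2")

  plant_rec <- rec[rec$cycle == "plant", , drop = FALSE]
  md_check(nrow(plant_rec) > 0L,
           sprintf("no plant-crop record for cultivar '%s'", cultivar))
  md_check(!anyDuplicated(plant_rec$plant_id),
           "each plant must have exactly one plant-crop record")
  baseline <- stats::setNames(plant_rec$bunches, plant_rec$plant_id)

  ratoon <- rec[rec$cycle != "plant" & !is.na(rec$bunches), , drop = FALSE]
  if (nrow(ratoon) == 0L) {
    md_stop(sprintf("no ratoon observations for cultivar '%s': concordance undefined",
                    cultivar),
            "musadicho_undefined_concordance")
  }
  md_check(all(ratoon$plant_id %in% names(baseline)),
           "every ratoon observation needs a matching plant-crop record")

  n_conc <- sum(ratoon$bunches == baseline[ratoon$plant_id])
  n_disc <- nrow(ratoon) - n_conc
  cc <- n_conc / (n_conc + n_disc)
  structure(list(cultivar = cultivar,
                 n_plants = nrow(plant_rec),
                 n_concordant = as.integer(n_conc),
                 n_discordant = as.integer(n_disc),
                 cc = if (percent) 100 * cc else cc,
                 scale = if (percent) "percent" else "fraction"),
            class = "concordance_summary")
}

#' Classify occurrence and persistence from a concordance summary
#'
#' A cultivar whose concordance coefficient reaches the threshold (default
#' 1.0, i.e. perfect agreement across cycles) is classified as having a
#' Normal occurrence and a Persistent phenotype; anything below is Random
#' and Non-persistent.
#'
#' @param summary A [compute_concordance()] result.
#' @param threshold Concordance threshold on `[0, 1]` (compared on the
#'   fraction scale regardless of how `cc` was reported).
#' @return Named character vector with elements `occurrence` (`"Normal"` or
#'   `"Random"`) and `persistence` (`"Persistent"` or `"Non-persistent"`).
#' @examples
#' ph <- generate_phenology(cultivar_profiles()["Agbagba"], 10, 2, seed = 1)
#' classify_persistence(compute_concordance(ph$records, "Agbagba"))
#' @export
classify_persistence <- function(summary, threshold = 1.0) {
  md_check(inherits(summary, "concordance_summary"),
           "`summary` must be a concordance_summary")
  md_check(is_number(threshold) && threshold >= 0 && threshold <= 1,
           "`threshold` must lie in [0, 1]")
  cc <- if (identical(summary$scale, "percent")) summary$cc / 100 else summary$cc
  if (cc >= threshold) {
    c(occurrence = "Normal", persistence = "Persistent")
  } else {
    c(occurrence = "Random", persistence = "Non-persistent")
  }
}

#' @export
print.concordance_summary <- function(x, ...) {
  cls <- classify_persistence(x)
  cat(sprintf("Concordance for '%s': %d/%d ratoon observations concordant, CC = %s -> %s, %s\n",
              x$cultivar, x$n_concordant, x$n_concordant + x$n_discordant,
              format(round(x$cc, 2), nsmall = 2), cls[["occurrence"]],
              cls[["persistence"]]))
  invisible(x)
}

#' Tabulate concordance for every cultivar in a phenology table
#'
#' Applies [compute_concordance()] and [classify_persistence()] to each
#' cultivar present and returns one summary row per cultivar, in the format
#' of the study's concordance table.
#'
#' @inheritParams compute_concordance
#' @param threshold Persistence threshold passed to
#'   [classify_persistence()].
#' @return Data frame with columns `cultivar`, `plant_crop_n`, `ratoon_n`,
#'   `concordant_n`, `cc`, `occurrence`, `persistence`.
#' @export
concordance_table <- function(records, threshold = 1.0) {
  cultivars <- unique(records$cultivar)
  rows <- lapply(cultivars, function(cv) {
    s <- compute_concordance(records, cv)
    cls <- classify_persistence(s, threshold)
    data.frame(cultivar = cv, plant_crop_n = s$n_plants,
               ratoon_n = s$n_concordant + s$n_discordant,
               concordant_n = s$n_concordant, cc = s$cc,
               occurrence = cls[["occurrence"]],
               persistence = cls[["persistence"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
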