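# Seeded synthetic-data generators. Every generator is deterministic for a
# fixed seed, leaves the caller's RNG state untouched, and returns explicit
# ground-truth labels so downstream callers can be validated by round-trip.

#' Generate a random protein-coding reference sequence
#'
#' Draws codons uniformly from the 61 sense codons of the standard genetic
#' code, so the sequence carries no in-frame internal stop codon (reading
#' frame starting at position 1). Where the length allows, the translated
#' product contains every amino acid at least once — as any real
#' protein-coding region of this size would — so that a named amino-acid
#' change can always be implanted. Stands in for the conserved gene region
#' the variant generators mutate.
#'
#' @param length Sequence length in bases; a positive multiple of 3.
#' @param seed Integer seed; identical arguments give identical sequences.
#' @return A character scalar over `A,C,G,T` of exactly `length` bases.
#' @examples
#' generate_reference_cds(30, seed = 7)
#' @export
generate_reference_cds <- function(length, seed) {
  if (!is_count(length, min = 3L) || length %% 3L != 0L) {
    md_stop("`length` must be a positive multiple of 3",
            "musadicho_invalid_argument")
  }
  with_seed(seed, {
    codons <- sample(SENSE_CODONS, length %/% 3L, replace = TRUE)
    aa <- unname(GENETIC_CODE_3[codons])
    all_aas <- setdiff(unique(unname(GENETIC_CODE_3)), "Ter")
    missing <- setdiff(all_aas, unique(aa))
    for (m in if (length(missing)) sample(missing) else character()) {
      # replace a codon of an amino acid that occurs at least twice
      tab <- table(aa)
      donors <- which(tab[aa] >= 2L)
      if (!length(donors)) break
      i <- donors[sample.int(length(donors), 1L)]
      cands <- SENSE_CODONS[GENETIC_CODE_3[SENSE_CODONS] == m]
      codons[i] <- cands[sample.int(length(cands), 1L)]
      aa[i] <- m
    }
    paste(codons, collapse = "")
  })
}

# Validate and normalise a deletion spec c(start, length).
.check_deletion_spec <- function(deletion_spec, ref_len) {
  if (is.null(deletion_spec)) return(NULL)
  md_check(is.numeric(deletion_spec) && length(deletion_spec) == 2L &&
             all(deletion_spec == floor(deletion_spec)),
           "`deletion_spec` must be c(start, length)")
  start <- as.integer(deletion_spec[[1]])
  len <- as.integer(deletion_spec[[2]])
  md_check(start >= 1L && len >= 1L && start + len - 1L <= ref_len,
           "`deletion_spec` interval must lie inside the reference")
  c(start = start, length = len)
}

#' Implant substitutions and an optional deletion into a reference
#'
#' Builds a mutant haplotype that realises a [substitution_profile()]
#' exactly: every listed substitution type occurs its listed count of times,
#' the remaining sites (up to `n_snp_sites`) carry substitutions of the
#' profile's overall class (transitions for `Pu-Pu`/`Py-Py` profiles,
#' transversions otherwise), and the named amino-acid change is realised at
#' its codon (or, failing that, at the first feasible codon). Some printed
#' amino-acid changes are not reachable by a single base change under the
#' genetic code; those are realised as the minimal set of single-base
#' substitutions within one codon, each counting as one SNP site. No two
#' substitutions share an alignment column, and for a synonymous profile
#' every individual substitution is synonymous. Filler substitutions avoid
#' the listed type pairs and are capped below the smallest listed count, so
#' the listed types remain the exact top of the substitution spectrum.
#'
#' @param reference Ungapped `A,C,G,T` reference sequence (character
#'   scalar), at least `3 * n_snp_sites` bases long.
#' @param profile A [substitution_profile()].
#' @param deletion_spec Optional `c(start, length)`: a contiguous block to
#'   delete from the mutant (rendered as a gap run in the alignment).
#' @param seed Integer seed.
#' @param ref_label,sample_label Labels used in the returned alignment;
#'   `sample_label` defaults to the profile's cultivar.
#' @return A list with `alignment` (an [alignment_set()] of reference and
#'   mutant), `mutant` (the gapped mutant string) and `truth`: a list with
#'   `variant_truth` (data frame `position`, `ref_base`, `alt_base`,
#'   `effect`, positions strictly increasing) and `deletion_truth` (data
#'   frame `start`, `length`).
#' @examples
#' ref <- generate_reference_cds(300, seed = 1)
#' prof <- cultivar_profiles()[["Agbagba"]]$substitution_profile
#' imp <- implant_variants(ref, prof, seed = 2)
#' nrow(imp$truth$variant_truth) # 55
#' @export
implant_variants <- function(reference, profile, deletion_spec = NULL, seed,
                             ref_label = "reference",
                             sample_label = profile$cultivar) {
  md_check(is_string(reference), "`reference` must be a character scalar")
  ref <- strsplit(toupper(reference), "")[[1]]
  md_check(all(ref %in% NUCLEOTIDES),
           "`reference` must be an ungapped A/C/G/T sequence")
  md_check(inherits(profile, "substitution_profile"),
           "`profile` must be a substitution_profile")
  L <- length(ref)
  md_check(L >= 3L * profile$n_snp_sites,
           "reference too short: need at least 3 bases per SNP site")
  del <- .check_deletion_spec(deletion_spec, L)
  del_pos <- if (is.null(del)) integer() else del["start"]:(del["start"] + del["length"] - 1L)

  n_codons <- L %/% 3L
  codon_str <- vapply(seq_len(n_codons), function(ci)
    paste(ref[(3L * ci - 2L):(3L * ci)], collapse = ""), character(1))
  codon_aa <- unname(GENETIC_CODE_3[codon_str])
  syn_only <- profile$mutation_type == "synonymous"

  # Candidate table: one row per (position, alternate base) within complete
  # codons and outside the deletion, with its synonymy flag.
  pos_all <- setdiff(seq_len(3L * n_codons), del_pos)
  pos <- rep(pos_all, each = 3L)
  alt <- as.vector(vapply(ref[pos_all], function(b) setdiff(NUCLEOTIDES, b),
                          character(3)))
  ci <- (pos - 1L) %/% 3L + 1L
  off <- (pos - 1L) %% 3L + 1L
  cd <- codon_str[ci]
  alt_codon <- paste0(substr(cd, 1L, off - 1L), alt, substr(cd, off + 1L, 3L))
  cand <- data.frame(pos = pos, ref = ref[pos], alt = alt,
                     syn = unname(GENETIC_CODE_3[alt_codon]) == codon_aa[ci],
                     stringsAsFactors = FALSE)
  cand$class <- ifelse(base_class(cand$ref) == base_class(cand$alt),
                       "transition", "transversion")
  cand$pair <- paste0(cand$ref, ">", cand$alt)

  listed <- profile$listed_types
  remaining <- if (nrow(listed)) listed$count else integer()
  listed_pairs <- if (nrow(listed))
    paste0(listed$ref_base, ">", listed$alt_base) else character()

  with_seed(seed, {
    used <- rep(FALSE, L)
    ev_pos <- integer(); ev_alt <- character()

    take <- function(pos, alt) {
      ev_pos <<- c(ev_pos, pos)
      ev_alt <<- c(ev_alt, alt)
      used[pos] <<- TRUE
    }

    # 1. realise the named amino-acid change at its codon if feasible, else
    #    at the first feasible codon
    if (!is.null(profile$aa_change) && profile$n_snp_sites > 0L) {
      from <- profile$aa_change$from_aa
      to <- profile$aa_change$to_aa
      targets <- SENSE_CODONS[GENETIC_CODE_3[SENSE_CODONS] == to]
      feasible <- function(ci) {
        if (any(used[(3L * ci - 2L):(3L * ci)]) ||
            any((3L * ci - 2L):(3L * ci) %in% del_pos)) return(FALSE)
        if (!identical(codon_aa[ci], from)) return(FALSE)
        tc <- setdiff(targets, codon_str[ci])
        if (!length(tc)) return(FALSE)
        d <- vapply(tc, function(t)
          sum(strsplit(t, "")[[1]] != strsplit(codon_str[ci], "")[[1]]),
          integer(1))
        # a synonymous profile needs a single-base synonymous neighbour
        if (syn_only) any(d == 1L) else TRUE
      }
      cands <- Filter(feasible, seq_len(n_codons))
      if (!length(cands)) {
        md_stop(sprintf("no codon can realise the amino-acid change %s->%s",
                        from, to),
                "musadicho_placement_failure")
      }
      ci <- if (profile$aa_change$codon_index %in% cands)
        profile$aa_change$codon_index else cands[[1]]
      rc <- strsplit(codon_str[ci], "")[[1]]
      tc <- setdiff(targets, codon_str[ci])
      score <- lapply(tc, function(t) {
        t_chars <- strsplit(t, "")[[1]]
        diff <- which(t_chars != rc)
        pairs <- paste0(rc[diff], ">", t_chars[diff])
        list(codon = t, diff = diff, alt = t_chars[diff],
             dist = length(diff),
             n_listed = sum(pairs %in% listed_pairs))
      })
      if (syn_only) score <- Filter(function(s) s$dist == 1L, score)
      ord <- order(vapply(score, `[[`, integer(1), "dist"),
                   -vapply(score, `[[`, integer(1), "n_listed"),
                   vapply(score, `[[`, character(1), "codon"))
      best <- score[[ord[[1]]]]
      for (k in seq_along(best$diff)) {
        p <- 3L * (ci - 1L) + best$diff[k]
        take(p, best$alt[k])
        pr <- paste0(ref[p], ">", best$alt[k])
        hit <- which(listed_pairs == pr & remaining > 0L)
        if (length(hit)) remaining[hit[1]] <- remaining[hit[1]] - 1L
      }
    }

    # 2. listed substitution types, exact counts
    if (nrow(listed)) {
      for (i in seq_len(nrow(listed))) {
        k <- remaining[i]
        if (k <= 0L) next
        pool <- cand[cand$pair == listed_pairs[i] & !used[cand$pos] &
                       (!syn_only | cand$syn), , drop = FALSE]
        if (nrow(pool) < k) {
          md_stop(sprintf(
            "cannot place %d %s substitutions: only %d eligible positions",
            k, listed_pairs[i], nrow(pool)),
            "musadicho_placement_failure")
        }
        pick <- pool[sample.int(nrow(pool), k), , drop = FALSE]
        for (j in seq_len(k)) take(pick$pos[j], pick$alt[j])
      }
    }

    # 3. filler sites of the profile's overall class
    n_fill <- profile$n_snp_sites - length(ev_pos)
    if (n_fill < 0L) {
      md_stop("aa-change site plus listed counts exceed n_snp_sites",
              "musadicho_invalid_profile")
    }
    if (n_fill > 0L) {
      md_check(!is.na(profile$overall_class),
               "`overall_class` required to draw filler substitutions")
      want <- if (profile$overall_class %in% c("Pu-Pu", "Py-Py"))
        "transition" else "transversion"
      pool <- cand[cand$class == want & !(cand$pair %in% listed_pairs) &
                     (!syn_only | cand$syn), , drop = FALSE]
      cap <- if (nrow(listed)) max(min(listed$count) - 1L, 1L) else Inf
      pair_count <- integer(0)
      for (i in seq_len(n_fill)) {
        avail <- pool[!used[pool$pos], , drop = FALSE]
        over <- names(pair_count)[pair_count >= cap]
        avail <- avail[!(avail$pair %in% over), , drop = FALSE]
        if (!nrow(avail)) {
          md_stop("cannot place filler substitutions without exceeding the listed-type caps",
                  "musadicho_placement_failure")
        }
        row <- avail[sample.int(nrow(avail), 1L), ]
        take(row$pos, row$alt)
        pair_count[row$pair] <- (if (row$pair %in% names(pair_count))
          pair_count[[row$pair]] else 0L) + 1L
      }
    }

    # assemble mutant, alignment and truth
    mutant <- ref
    mutant[ev_pos] <- ev_alt
    if (length(del_pos)) mutant[del_pos] <- "-"
    ord <- order(ev_pos)
    effect <- vapply(seq_along(ev_pos), function(k) {
      row <- cand[cand$pos == ev_pos[k] & cand$alt == ev_alt[k], ]
      if (row$syn[1]) "synonymous" else "non-synonymous"
    }, character(1))
    variant_truth <- data.frame(position = ev_pos[ord],
                                ref_base = ref[ev_pos][ord],
                                alt_base = ev_alt[ord],
                                effect = effect[ord],
                                stringsAsFactors = FALSE)
    deletion_truth <- if (is.null(del))
      data.frame(start = integer(), length = integer()) else
      data.frame(start = unname(del["start"]), length = unname(del["length"]))
    seqs <- stats::setNames(c(paste(ref, collapse = ""),
                              paste(mutant, collapse = "")),
                            c(ref_label, sample_label))
    list(alignment = alignment_set(seqs, ref_label),
         mutant = paste(mutant, collapse = ""),
         truth = list(variant_truth = variant_truth,
                      deletion_truth = deletion_truth))
  })
}

#' Generate a synthetic phenology table
#'
#' Emulates the field design: each plant receives one plant-crop record with
#' its cultivar's bunch count and `n_ratoon_obs_per_plant` ratoon-crop
#' records (alternating first/second ratoon), each independently concordant
#' with the plant crop with probability `ratoon_concordance_prob`.
#' Discordant observations — the reversals in bunch number common in the
#' dichotomous cultivars — draw a different bunch count uniformly from
#' `{1,2,3}`.
#'
#' @param profiles List of cultivar profiles as from [cultivar_profiles()]
#'   (may be a subset); must be non-empty.
#' @param n_plants_per_cultivar Plants per cultivar (>= 1).
#' @param n_ratoon_obs_per_plant Ratoon observations per plant (>= 1).
#' @param seed Integer seed.
#' @return A list with `records` (data frame `plant_id`, `cultivar`,
#'   `cycle`, `bunches`) and `truth` (per-observation concordance flags and
#'   the per-plant plant-crop bunch counts).
#' @examples
#' ph <- generate_phenology(cultivar_profiles(), 10, 2, seed = 1)
#' head(ph$records)
#' @export
generate_phenology <- function(profiles, n_plants_per_cultivar,
                               n_ratoon_obs_per_plant, seed) {
  if (!is.list(profiles) || !length(profiles)) {
    md_stop("`profiles` must be a non-empty list of cultivar profiles",
            "musadicho_invalid_argument")
  }
  md_check(all(vapply(profiles, inherits, logical(1), "cultivar_profile")),
           "`profiles` elements must be cultivar_profile objects")
  md_check(is_count(n_plants_per_cultivar, min = 1L),
           "`n_plants_per_cultivar` must be >= 1")
  md_check(is_count(n_ratoon_obs_per_plant, min = 1L),
           "`n_ratoon_obs_per_plant` must be >= 1")
  with_seed(seed, {
    rec <- list(); conc <- list()
    for (prof in profiles) {
      p <- prof$ratoon_concordance_prob
      b0 <- prof$plant_crop_bunches
      for (i in seq_len(n_plants_per_cultivar)) {
        pid <- sprintf("%s_%02d", prof$label, i)
        rec[[length(rec) + 1L]] <- data.frame(
          plant_id = pid, cultivar = prof$label, cycle = "plant",
          bunches = b0, stringsAsFactors = FALSE)
        is_conc <- stats::runif(n_ratoon_obs_per_plant) < p
        other <- setdiff(1:3, b0)
        bun <- ifelse(is_conc, b0,
                      other[sample.int(length(other), n_ratoon_obs_per_plant,
                                       replace = TRUE)])
        rec[[length(rec) + 1L]] <- data.frame(
          plant_id = pid, cultivar = prof$label,
          cycle = paste0("ratoon", (seq_len(n_ratoon_obs_per_plant) - 1L) %% 2L + 1L),
          bunches = as.integer(bun), stringsAsFactors = FALSE)
        conc[[length(conc) + 1L]] <- data.frame(
          plant_id = pid, cultivar = prof$label,
          obs = seq_len(n_ratoon_obs_per_plant),
          concordant = is_conc, stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, rec)
    rownames(records) <- NULL
    list(records = records,
         truth = list(phenotype_truth = records,
                      concordant = do.call(rbind, conc)))
  })
}

#' Construct a flow histogram object
#'
#' @param plant_id Plant identifier.
#' @param channels Strictly increasing positive integer channel positions.
#' @param counts Non-negative nucleus counts, one per channel.
#' @return An object of class `flow_histogram`.
#' @export
flow_histogram <- function(plant_id, channels, counts) {
  md_check(is_string(plant_id), "`plant_id` must be a string")
  md_check(is.numeric(channels) && length(channels) >= 1L &&
             all(channels > 0) && all(diff(channels) > 0),
           "`channels` must be strictly increasing and positive")
  md_check(is.numeric(counts) && length(counts) == length(channels) &&
             all(counts >= 0),
           "`counts` must be non-negative, one per channel")
  structure(list(plant_id = plant_id, channels = as.integer(channels),
                 counts = as.integer(counts)),
            class = "flow_histogram")
}

#' @export
print.flow_histogram <- function(x, ...) {
  cat(sprintf("Flow histogram '%s': %d channels, %d nuclei, mode at channel %d\n",
              x$plant_id, length(x$channels), sum(x$counts),
              x$channels[which.max(x$counts)]))
  invisible(x)
}

#' @param x A `flow_histogram`.
#' @param ... Passed to [plot()].
#' @rdname flow_histogram
#' @export
plot.flow_histogram <- function(x, ...) {
  plot(x$channels, x$counts, type = "h",
       xlab = "Relative DNA content (channel)", ylab = "Number of nuclei",
       main = x$plant_id, ...)
  invisible(x)
}

#' Generate a DNA-content fluorescence histogram
#'
#' Simulates a flow-cytometry run of a sample of known ploidy co-analysed
#' with an internal standard of known ploidy: the dominant sample peak is a
#' discretised Gaussian centred at `control_channel * ploidy /
#' control_ploidy` with standard deviation `cv` times the centre, the
#' control peak sits at `control_channel`, and a `debris_fraction` share of
#' counts decays geometrically over the lowest 20% of channels. Total
#' counts equal `n_nuclei` exactly. When the sample has the control's own
#' ploidy the two peaks merge at `control_channel`.
#'
#' @param ploidy Sample ploidy (x-multiplier, >= 1).
#' @param control_ploidy Ploidy of the internal standard (default 3, the
#'   triploid single-bunching control).
#' @param control_channel Channel of the control peak (default 75, placing
#'   a diploid sample at channel 50).
#' @param n_nuclei Total nuclei counted (default 5000).
#' @param cv Coefficient of variation of each peak (0 < cv < 0.5; default
#'   0.03).
#' @param debris_fraction Fraction of counts assigned to low-channel debris
#'   (0 <= f < 1; default 0.10).
#' @param n_channels Number of channels (default 256).
#' @param seed Integer seed.
#' @param plant_id Identifier stored in the histogram.
#' @param control_fraction Share of non-debris nuclei in the control peak
#'   (default 0.25, keeping the sample peak dominant).
#' @return A [flow_histogram()].
#' @examples
#' h <- generate_flow_histogram(2, seed = 1)
#' sum(h$counts) # 5000
#' @export
generate_flow_histogram <- function(ploidy, control_ploidy = 3L,
                                    control_channel = 75,
                                    n_nuclei = 5000L, cv = 0.03,
                                    debris_fraction = 0.10,
                                    n_channels = 256L, seed,
                                    plant_id = "plant",
                                    control_fraction = 0.25) {
  md_check(is_count(ploidy, min = 1L), "`ploidy` must be an integer >= 1")
  md_check(is_count(control_ploidy, min = 1L),
           "`control_ploidy` must be an integer >= 1")
  md_check(is_number(control_channel) && control_channel > 0,
           "`control_channel` must be positive")
  md_check(is_count(n_nuclei, min = 1L), "`n_nuclei` must be >= 1")
  md_check(is_number(cv) && cv > 0 && cv < 0.5, "`cv` must be in (0, 0.5)")
  md_check(is_number(debris_fraction) && debris_fraction >= 0 &&
             debris_fraction < 1, "`debris_fraction` must be in [0, 1)")
  md_check(is_count(n_channels, min = 2L), "`n_channels` must be >= 2")
  md_check(is_number(control_fraction) && control_fraction >= 0 &&
             control_fraction < 0.5,
           "`control_fraction` must be in [0, 0.5)")
  center <- control_channel * ploidy / control_ploidy
  if (round(center) > n_channels || control_channel > n_channels) {
    md_stop(sprintf(
      "peak centre (channel %.1f) beyond the %d-channel range: mis-scaled simulation",
      max(center, control_channel), n_channels),
      "musadicho_invalid_argument")
  }
  with_seed(seed, {
    n_debris <- round(debris_fraction * n_nuclei)
    n_signal <- n_nuclei - n_debris
    if (ploidy == control_ploidy) {
      n_ctrl <- 0L
      n_samp <- n_signal
    } else {
      n_ctrl <- round(control_fraction * n_signal)
      n_samp <- n_signal - n_ctrl
    }
    clamp <- function(x) pmin(pmax(round(x), 1L), n_channels)
    ch <- c(clamp(stats::rnorm(n_samp, center, cv * center)),
            clamp(stats::rnorm(n_ctrl, control_channel, cv * control_channel)))
    if (n_debris > 0L) {
      dmax <- max(1L, floor(0.2 * n_channels))
      w <- (1 - 0.1)^(seq_len(dmax) - 1L) # geometric decay, rate 0.1
      ch <- c(ch, sample.int(dmax, n_debris, replace = TRUE, prob = w))
    }
    flow_histogram(plant_id, seq_len(n_channels),
                   tabulate(ch, nbins = n_channels))
  })
}

#' Generate a cohort of flow histograms with known ploidy truth
#'
#' One histogram per plant, each seeded reproducibly from the master seed,
#' for a cohort whose ploidy composition is given as (ploidy, count) pairs
#' — for example 95 diploids and 5 tetraploids measured against the
#' triploid internal standard.
#'
#' @param composition Data frame with columns `ploidy` and `count`, or a
#'   list of `c(ploidy, count)` pairs; must be non-empty with counts >= 0.
#' @inheritParams generate_flow_histogram
#' @return A list with `histograms` (list of [flow_histogram()]) and
#'   `truth` (`ploidy_truth`: named integer vector of true ploidies).
#' @examples
#' coh <- generate_cohort(data.frame(ploidy = c(2, 4), count = c(9, 1)),
#'                        seed = 1)
#' table(coh$truth$ploidy_truth)
#' @export
generate_cohort <- function(composition, control_ploidy = 3L,
                            control_channel = 75, n_nuclei = 5000L,
                            cv = 0.03, debris_fraction = 0.10,
                            n_channels = 256L, seed,
                            control_fraction = 0.25) {
  if (is.list(composition) && !is.data.frame(composition)) {
    composition <- do.call(rbind, lapply(composition, function(x)
      data.frame(ploidy = x[[1]], count = x[[2]])))
  }
  if (is.null(composition) || !is.data.frame(composition) ||
      !nrow(composition)) {
    md_stop("`composition` must be non-empty (ploidy, count) pairs",
            "musadicho_invalid_argument")
  }
  md_check(all(c("ploidy", "count") %in% names(composition)),
           "`composition` needs columns ploidy and count")
  md_check(all(composition$count >= 0) && all(composition$ploidy >= 1),
           "`composition` counts must be >= 0 and ploidies >= 1")
  ploidies <- rep(as.integer(composition$ploidy),
                  times = as.integer(composition$count))
  md_check(length(ploidies) >= 1L, "`composition` must yield at least one plant")
  ids <- sprintf("plant_%03d", seq_along(ploidies))
  histograms <- lapply(seq_along(ploidies), function(i) {
    generate_flow_histogram(ploidies[i], control_ploidy = control_ploidy,
                            control_channel = control_channel,
                            n_nuclei = n_nuclei, cv = cv,
                            debris_fraction = debris_fraction,
                            n_channels = n_channels,
                            seed = derive_seed(seed, "flow", i),
                            plant_id = ids[i],
                            control_fraction = control_fraction)
  })
  list(histograms = histograms,
       truth = list(ploidy_truth = stats::setNames(ploidies, ids)))
}

#' Generate per-plant metaphase chromosome-count tables
#'
#' Emulates manual counting of at least ten metaphase spreads per plant: a
#' plant of true ploidy `k` yields cells counting `k * basic_number`
#' chromosomes, with each cell independently miscounted by +/-1 with
#' probability `miscount_prob` (the occasional poorly spread metaphase).
#'
#' @param ploidy_truth Named integer vector: true ploidy per plant.
#' @param n_cells Metaphase cells per plant (default 10).
#' @param basic_number Basic chromosome number x (default 11).
#' @param miscount_prob Per-cell probability of a +/-1 miscount (default
#'   0.1).
#' @param seed Integer seed.
#' @return A list with `counts` (data frame `plant_id`, `cell_index`,
#'   `chromosome_count`) and `truth` (the input `ploidy_truth`).
#' @export
generate_chromosome_counts <- function(ploidy_truth, n_cells = 10L,
                                       basic_number = 11L,
                                       miscount_prob = 0.1, seed) {
  md_check(is.numeric(ploidy_truth) && length(ploidy_truth) >= 1L &&
             !is.null(names(ploidy_truth)),
           "`ploidy_truth` must be a named integer vector")
  md_check(is_count(n_cells, min = 1L), "`n_cells` must be >= 1")
  md_check(is_count(basic_number, min = 1L), "`basic_number` must be >= 1")
  md_check(is_number(miscount_prob) && miscount_prob >= 0 &&
             miscount_prob < 0.5, "`miscount_prob` must be in [0, 0.5)")
  with_seed(seed, {
    rows <- lapply(names(ploidy_truth), function(pid) {
      true_n <- as.integer(ploidy_truth[[pid]]) * basic_number
      dev <- ifelse(stats::runif(n_cells) < miscount_prob,
                    sample(c(-1L, 1L), n_cells, replace = TRUE), 0L)
      data.frame(plant_id = pid, cell_index = seq_len(n_cells),
                 chromosome_count = true_n + dev, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    list(counts = out, truth = list(ploidy_truth = ploidy_truth))
  })
}
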