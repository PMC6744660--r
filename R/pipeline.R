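# Config-driven orchestration: simulate -> concordance -> snp-call ->
# ploidy-call -> report, all randomness derived from one master seed.

PIPELINE_STAGES <- c("simulate", "concordance", "snp-call", "ploidy-call",
                     "report")

#' Default pipeline configuration
#'
#' Every parameter has a default except `ploidy$control_channel`, which is
#' mandatory whenever the flow-calling stage runs: the fluorescence channel
#' scale is instrument-dependent, so the control peak position must be
#' stated per run.
#'
#' @return Nested configuration list (see [run_pipeline()]).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "musadicho-run",
    stages = PIPELINE_STAGES,
    verbose = FALSE,
    simulate = list(
      n_plants_per_cultivar = 10L,
      n_ratoon_obs_per_plant = 2L,
      reference_length = 600L,
      deletion = c(421L, 12L), # gap block implanted in dichotomous cultivars
      cohort_composition = data.frame(ploidy = c(2L, 4L), count = c(95L, 5L)),
      n_nuclei = 5000L,
      cv = 0.03,
      debris_fraction = 0.10,
      n_channels = 256L,
      n_cells = 10L,
      miscount_prob = 0.1
    ),
    concordance = list(threshold = 1.0),
    variants = list(frame_offset = 1L),
    ploidy = list(
      control_channel = NULL, # mandatory for flow runs
      control_ploidy = 3L,
      basic_number = 11L,
      tolerance = 1L,
      smooth_window = 5L,
      min_prominence_frac = 0.05,
      max_rel_deviation = 0.2,
      control_band = 0.1
    )
  )
}

# Merge a user config into the defaults, rejecting unknown keys.
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    md_check(file.exists(config), sprintf("config file not found: '%s'", config))
    config <- yaml::read_yaml(config)
  }
  md_check(is.list(config), "`config` must be a list or a YAML file path")
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    md_stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
            "musadicho_invalid_config")
  }
  for (block in c("simulate", "concordance", "variants", "ploidy")) {
    if (!is.null(config[[block]])) {
      md_check(is.list(config[[block]]),
               sprintf("config block '%s' must be a list", block))
      bad <- setdiff(names(config[[block]]), names(defaults[[block]]))
      if (length(bad)) {
        md_stop(sprintf("unknown key(s) in config block '%s': %s", block,
                        paste(bad, collapse = ", ")),
                "musadicho_invalid_config")
      }
      defaults[[block]][names(config[[block]])] <- config[[block]]
    }
  }
  for (key in c("seed", "out_dir", "stages", "verbose")) {
    if (!is.null(config[[key]])) defaults[[key]] <- config[[key]]
  }
  md_check(all(defaults$stages %in% PIPELINE_STAGES),
           sprintf("stages must be among: %s",
                   paste(PIPELINE_STAGES, collapse = ", ")))
  if ("ploidy-call" %in% defaults$stages &&
      is.null(defaults$ploidy$control_channel)) {
    md_stop("`ploidy$control_channel` is required when the ploidy-call stage is enabled",
            "musadicho_invalid_config")
  }
  defaults
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages against a configuration (a nested list or
#' a YAML file path; see [default_config()]): `simulate` writes a synthetic
#' phenology CSV, a variant-implanted multi-FASTA alignment (all six
#' cultivars against a synthetic ancestral reference), a chromosome-count
#' CSV and a flow-histogram directory; `concordance`, `snp-call` and
#' `ploidy-call` read those files back and write study-style summary TSVs;
#' `report` writes a plain-text run summary. All randomness flows from the
#' single configured seed via per-stage derived sub-seeds, so two runs with
#' the same config produce identical output trees. Any stage error aborts
#' with a stage-named message.
#'
#' @param config Configuration list or YAML path; unknown keys are
#'   rejected before any work.
#' @return Invisibly, a report bundle: the resolved config, the output file
#'   paths, and the in-memory summary tables.
#' @examples
#' \donttest{
#' cfg <- list(out_dir = tempfile("run"), ploidy = list(control_channel = 75))
#' bundle <- run_pipeline(cfg)
#' names(bundle$outputs)
#' }
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      md_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              "musadicho_stage_error")
    })
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  tables <- list()
  profiles <- cultivar_profiles()
  paths <- list(
    phenology = file.path(cfg$out_dir, "phenology.csv"),
    alignment = file.path(cfg$out_dir, "alignment.fasta"),
    cytology = file.path(cfg$out_dir, "cytology.csv"),
    flow_dir = file.path(cfg$out_dir, "flow"),
    flow_manifest = file.path(cfg$out_dir, "flow", "manifest.csv"),
    variant_truth = file.path(cfg$out_dir, "variant_truth.tsv"),
    concordance = file.path(cfg$out_dir, "concordance.tsv"),
    substitutions = file.path(cfg$out_dir, "substitutions.tsv"),
    ploidy = file.path(cfg$out_dir, "ploidy.tsv"),
    cohort = file.path(cfg$out_dir, "cohort_tally.tsv"),
    report = file.path(cfg$out_dir, "report.txt")
  )

  if ("simulate" %in% cfg$stages) {
    stage("simulate", {
      sm <- cfg$simulate
      say("simulate: seed %d", cfg$seed)
      ph <- generate_phenology(profiles, sm$n_plants_per_cultivar,
                               sm$n_ratoon_obs_per_plant,
                               seed = derive_seed(cfg$seed, "phenology"))
      write_phenology(ph$records, paths$phenology)

      ref <- generate_reference_cds(sm$reference_length,
                                    seed = derive_seed(cfg$seed, "reference"))
      seqs <- c(ancestral_reference = ref)
      truth_rows <- list()
      for (i in seq_along(profiles)) {
        prof <- profiles[[i]]
        del <- if (prof$label == "Agbagba") NULL else sm$deletion
        imp <- implant_variants(ref, prof$substitution_profile,
                                deletion_spec = del,
                                seed = derive_seed(cfg$seed, "variants", i))
        seqs[prof$label] <- imp$mutant
        vt <- imp$truth$variant_truth
        if (nrow(vt)) vt$cultivar <- prof$label
        truth_rows[[i]] <- vt
      }
      write_fasta(seqs, paths$alignment)
      utils::write.table(do.call(rbind, truth_rows), paths$variant_truth,
                         sep = "\t", row.names = FALSE, quote = FALSE)

      ploidy_truth <- integer()
      for (prof in profiles) {
        ids <- sprintf("%s_%02d", prof$label, seq_len(sm$n_plants_per_cultivar))
        ploidy_truth[ids] <- prof$ploidy_truth
      }
      cy <- generate_chromosome_counts(ploidy_truth, n_cells = sm$n_cells,
                                       miscount_prob = sm$miscount_prob,
                                       seed = derive_seed(cfg$seed, "cytology"))
      utils::write.csv(cy$counts, paths$cytology, row.names = FALSE,
                       quote = FALSE)

      control_channel <- if (is.null(cfg$ploidy$control_channel)) 75
        else cfg$ploidy$control_channel
      coh <- generate_cohort(sm$cohort_composition,
                             control_ploidy = cfg$ploidy$control_ploidy,
                             control_channel = control_channel,
                             n_nuclei = sm$n_nuclei, cv = sm$cv,
                             debris_fraction = sm$debris_fraction,
                             n_channels = sm$n_channels,
                             seed = derive_seed(cfg$seed, "cohort"))
      write_histograms(coh$histograms, paths$flow_dir)
      out$simulate <- paths[c("phenology", "alignment", "cytology",
                              "flow_manifest", "variant_truth")]
    })
  }

  if ("concordance" %in% cfg$stages) {
    stage("concordance", {
      say("concordance: threshold %.2f", cfg$concordance$threshold)
      records <- read_phenology(paths$phenology)
      tab <- concordance_table(records, threshold = cfg$concordance$threshold)
      utils::write.table(tab, paths$concordance, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      tables$concordance <- tab
      out$concordance <- paths$concordance
    })
  }

  if ("snp-call" %in% cfg$stages) {
    stage("snp-call", {
      seqs <- read_fasta(paths$alignment)
      aln <- alignment_set(seqs, names(seqs)[1L],
                           frame_offset = cfg$variants$frame_offset)
      samples <- setdiff(names(seqs), aln$reference_label)
      say("snp-call: %d samples vs '%s'", length(samples),
          aln$reference_label)
      prof_list <- lapply(samples, function(s) {
        snps <- call_snps(aln, s)
        write_variants_vcf(snps, aln$reference_label,
                           file.path(cfg$out_dir, paste0(s, ".vcf")))
        summarize_cultivar(snps, s)
      })
      write_substitution_table(prof_list, paths$substitutions)
      tables$substitutions <- prof_list
      out$snp_call <- paths$substitutions
    })
  }

  if ("ploidy-call" %in% cfg$stages) {
    stage("ploidy-call", {
      pl <- cfg$ploidy
      say("ploidy-call: control channel %.1f (%dx standard)",
          pl$control_channel, pl$control_ploidy)
      cyt <- read_cytology(paths$cytology)
      counting <- lapply(split(cyt, cyt$plant_id), function(df) {
        tryCatch(count_to_ploidy(df, basic_number = pl$basic_number,
                                 tolerance = pl$tolerance),
                 musadicho_error = function(e) e)
      })
      hists <- read_histograms(paths$flow_manifest)
      flow <- call_cohort(hists, control_channel = pl$control_channel,
                          control_ploidy = pl$control_ploidy,
                          max_rel_deviation = pl$max_rel_deviation,
                          control_band = pl$control_band,
                          smooth_window = pl$smooth_window,
                          min_prominence_frac = pl$min_prominence_frac)
      cohort <- summarize_cohort(flow)
      tally <- data.frame(ploidy = names(cohort$tally),
                          n = as.integer(cohort$tally),
                          stringsAsFactors = FALSE)
      utils::write.table(tally, paths$cohort, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      ctab <- data.frame(
        plant_id = names(counting),
        counting = vapply(counting, function(x)
          if (inherits(x, "ploidy_call")) sprintf("%dx", x$ploidy) else "?",
          character(1)),
        stringsAsFactors = FALSE)
      utils::write.table(ctab, paths$ploidy, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      tables$cohort <- cohort
      tables$counting <- counting
      out$ploidy_call <- paths[c("ploidy", "cohort")]
    })
  }

  if ("report" %in% cfg$stages) {
    stage("report", {
      lines <- c(
        "musadicho pipeline report",
        sprintf("seed: %d", cfg$seed),
        sprintf("stages: %s", paste(cfg$stages, collapse = ", ")),
        sprintf("output directory: %s", cfg$out_dir))
      if (!is.null(tables$concordance)) {
        lines <- c(lines, "", "concordance (cultivar: cc):",
                   sprintf("  %s: %.2f", tables$concordance$cultivar,
                           tables$concordance$cc))
      }
      if (!is.null(tables$substitutions)) {
        lines <- c(lines, "", "SNP sites per cultivar:",
                   vapply(tables$substitutions, function(p)
                     sprintf("  %s: %d", p$cultivar, p$n_snp_sites),
                     character(1)))
      }
      if (!is.null(tables$cohort)) {
        lines <- c(lines, "", "flow-cytometry cohort tally:",
                   sprintf("  %sx: %d", names(tables$cohort$tally),
                           tables$cohort$tally))
      }
      writeLines(lines, paths$report)
      out$report <- paths$report
    })
  }

  invisible(list(config = cfg, outputs = out, tables = tables))
}
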