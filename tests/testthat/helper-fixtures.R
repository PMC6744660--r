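# Shared fixtures: the published concordance design and a deterministic
# phenology encoding of it.

table1_rows <- function() {
  data.frame(
    cultivar = c("Agbagba", "DB1P", "DB2P", "TB1P", "TB2P", "TB3P"),
    bunches = c(1L, 2L, 2L, 3L, 3L, 3L),
    n_concordant = c(20L, 13L, 9L, 3L, 1L, 0L),
    cc = c(1.00, 0.65, 0.45, 0.15, 0.05, 0.00),
    persistence = c("Persistent", rep("Non-persistent", 5)),
    stringsAsFactors = FALSE
  )
}

# Deterministic phenology table: n_plants plants, n_obs ratoon observations
# each; the first n_concordant ratoon observations (in plant-then-cycle
# order) match the plant crop, the rest take a different bunch count.
encode_phenology <- function(cultivar, bunches, n_concordant,
                             n_plants = 10L, n_obs = 2L) {
  ids <- sprintf("%s_%02d", cultivar, seq_len(n_plants))
  plant <- data.frame(plant_id = ids, cultivar = cultivar, cycle = "plant",
                      bunches = bunches, stringsAsFactors = FALSE)
  k <- 0L
  ratoon <- list()
  for (i in seq_len(n_plants)) {
    for (j in seq_len(n_obs)) {
      k <- k + 1L
      b <- if (k <= n_concordant) bunches else setdiff(1:3, bunches)[1L]
      ratoon[[k]] <- data.frame(plant_id = ids[i], cultivar = cultivar,
                                cycle = paste0("ratoon", (j - 1L) %% 2L + 1L),
                                bunches = b, stringsAsFactors = FALSE)
    }
  }
  rbind(plant, do.call(rbind, ratoon))
}

# Independent translation oracle for codon-effect checks.
oracle_translate <- function(seq) {
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     no.init.codon = TRUE))
}
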