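test_that("published concordance design reproduces the printed coefficients", {
  rows <- table1_rows()
  for (i in seq_len(nrow(rows))) {
    rec <- encode_phenology(rows$cultivar[i], rows$bunches[i],
                            rows$n_concordant[i])
    s <- compute_concordance(rec, rows$cultivar[i])
    expect_equal(s$cc, rows$cc[i])
    expect_equal(s$n_concordant + s$n_discordant, 20L)
    cls <- classify_persistence(s)
    expect_equal(unname(cls["persistence"]), rows$persistence[i])
  }
})

test_that("concordance is permutation-invariant and monotone", {
  rec <- encode_phenology("DB1P", 2L, 13L)
  base <- compute_concordance(rec, "DB1P")$cc
  set.seed(1)
  for (k in 1:5) {
    perm <- rec[sample.int(nrow(rec)), , drop = FALSE]
    expect_equal(compute_concordance(perm, "DB1P")$cc, base)
  }
  # flipping one discordant ratoon observation to concordant raises cc
  disc <- which(rec$cycle != "plant" & rec$bunches != 2L)[1]
  rec2 <- rec
  rec2$bunches[disc] <- 2L
  expect_gt(compute_concordance(rec2, "DB1P")$cc, base)
})

test_that("dead-plant observations are excluded, not counted discordant", {
  rec <- encode_phenology("DB1P", 2L, 13L)
  # mark two discordant ratoon observations as dead/missing
  dead <- which(rec$cycle != "plant" & rec$bunches != 2L)[1:2]
  rec$bunches[dead] <- NA_integer_
  s <- compute_concordance(rec, "DB1P")
  expect_equal(s$n_concordant + s$n_discordant, 18L)
  expect_equal(s$cc, 13 / 18)
})

test_that("undefined concordance is an error, not zero", {
  rec <- encode_phenology("DB1P", 2L, 13L)
  only_plant <- rec[rec$cycle == "plant", , drop = FALSE]
  expect_error(compute_concordance(only_plant, "DB1P"),
               class = "musadicho_undefined_concordance")
  all_dead <- rec
  all_dead$bunches[all_dead$cycle != "plant"] <- NA_integer_
  expect_error(compute_concordance(all_dead, "DB1P"),
               class = "musadicho_undefined_concordance")
})

test_that("persistence classification honours the threshold contract", {
  rec <- encode_phenology("DB2P", 2L, 9L)
  s <- compute_concordance(rec, "DB2P")
  # cc equal to the threshold is Persistent, by the >= contract
  expect_equal(unname(classify_persistence(s, threshold = 0.45)["persistence"]),
               "Persistent")
  expect_equal(unname(classify_persistence(s, threshold = 0.46)["persistence"]),
               "Non-persistent")
  expect_error(classify_persistence(s, threshold = 1.5),
               class = "musadicho_invalid_argument")
  # percent flag rescales the coefficient but not the classification
  sp <- compute_concordance(rec, "DB2P", percent = TRUE)
  expect_equal(sp$cc, 45)
  expect_equal(unname(classify_persistence(sp, threshold = 0.45)["persistence"]),
               "Persistent")
})

test_that("cc estimates the generator's concordance probability", {
  # long-run convergence: many ratoon observations per plant
  ph <- generate_phenology(cultivar_profiles()["DB1P"], 10, 200, seed = 31)
  s <- compute_concordance(ph$records, "DB1P")
  expect_lt(abs(s$cc - 0.65), 0.05)
})

test_that("concordance_table summarises every cultivar", {
  rows <- table1_rows()
  rec <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i)
    encode_phenology(rows$cultivar[i], rows$bunches[i], rows$n_concordant[i])))
  tab <- concordance_table(rec)
  expect_equal(tab$cc[match(rows$cultivar, tab$cultivar)], rows$cc)
  expect_equal(tab$persistence[match(rows$cultivar, tab$cultivar)],
               rows$persistence)
})
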