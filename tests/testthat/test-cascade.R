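# Screening-cascade stages, audit trail, and oracle equivalence.

toy_table <- function() {
  score_table(data.frame(
    compound_id = rep(c("A", "B", "C"), times = 2),
    target_id = rep(c("sRANKL", "mRANKL"), each = 3),
    scorer_id = "moe",
    score = c(-7, -7, -5, -2, -8, -2),
    stringsAsFactors = FALSE
  ))
}

test_that("score tables load from CSV/TSV and reject malformed input", {
  df <- data.frame(compound_id = c("c1", "c2"), target_id = "sRANKL",
                   scorer_id = "moe", score = c(-6.5, -7.1))
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, csv, row.names = FALSE)
  tab <- load_score_table(csv)
  expect_s3_class(tab, "ScoreTable")
  expect_equal(nrow(tab), 2)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(load_score_table(tsv)$score, df$score)

  # missing column
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[, -4], bad, row.names = FALSE)
  expect_error(load_score_table(bad), "lacks column")

  # NaN score
  df2 <- df; df2$score[1] <- NaN
  utils::write.csv(df2, csv, row.names = FALSE)
  expect_error(load_score_table(csv), "non-finite")

  # duplicate key
  df3 <- rbind(df, df[1, ])
  utils::write.csv(df3, csv, row.names = FALSE)
  expect_error(load_score_table(csv), "duplicate")
})

test_that("the differential rule keeps compounds binding only the positive
           target", {
  st <- stage_differential_binder("moe", "sRANKL", "mRANKL", -6)
  res <- apply_stage(c("A", "B", "C"), st, toy_table())
  expect_identical(res$survivors, "A")
  expect_setequal(res$audit$compound_id, c("B", "C"))
  expect_identical(res$audit$reason[res$audit$compound_id == "B"],
                   "also binds negative target")
  expect_identical(res$audit$reason[res$audit$compound_id == "C"],
                   "positive-target score above cutoff")
})

test_that("cutoffs are strict and missing scores behave asymmetrically", {
  tab <- score_table(data.frame(
    compound_id = c("x", "y", "z", "z"),
    target_id = c("sRANKL", "sRANKL", "sRANKL", "mRANKL"),
    scorer_id = "glide",
    score = c(-3.5, -3.6, -7, -7)
  ))
  st <- stage_threshold("glide", "sRANKL", -3.5)
  res <- apply_stage(c("x", "y", "z"), st, tab)
  expect_setequal(res$survivors, c("y", "z"))  # -3.5 fails the strict "<"

  # differential: no mRANKL score counts as not binding, no sRANKL score
  # fails the positive requirement
  st2 <- stage_differential_binder("glide", "sRANKL", "mRANKL", -3.5)
  res2 <- apply_stage(c("x", "y", "z"), st2, tab)
  expect_identical(res2$survivors, "y")
  expect_identical(
    res2$audit$reason[res2$audit$compound_id == "z"],
    "also binds negative target")

  tab3 <- score_table(data.frame(
    compound_id = c("p", "q"), target_id = "mRANKL",
    scorer_id = "glide", score = c(-9, -9)))
  tab3 <- score_table(rbind(as.data.frame(tab3)[, 1:4],
                            data.frame(compound_id = "p",
                                       target_id = "sRANKL",
                                       scorer_id = "glide", score = -9)))
  res3 <- apply_stage(c("p", "q"),
                      stage_differential_binder("glide", "sRANKL",
                                                "mRANKL", -3.5), tab3)
  expect_identical(res3$audit$reason[res3$audit$compound_id == "q"],
                   "no-score")
})

test_that("rank_top keeps the k lowest scores with lexicographic
           tie-breaks", {
  tab <- score_table(data.frame(
    compound_id = c("d", "b", "a", "c"),
    target_id = "sRANKL", scorer_id = "ifd",
    score = c(-5, -7, -7, -6)))
  st <- stage_rank_top("ifd", "sRANKL", 2)
  res <- apply_stage(c("a", "b", "c", "d"), st, tab)
  expect_setequal(res$survivors, c("a", "b"))  # tie at -7 broken by id
})

test_that("empty survivor sets pass through stages unchanged", {
  st <- stage_threshold("moe", "sRANKL", -6)
  res <- apply_stage(character(0), st, toy_table())
  expect_length(res$survivors, 0)
  expect_equal(nrow(res$audit), 0)
})

test_that("unknown scorer or target ids are config errors", {
  expect_error(apply_stage("A", stage_threshold("nope", "sRANKL", -6),
                           toy_table()), "unknown scorer")
  expect_error(apply_stage("A", stage_threshold("moe", "xRANKL", -6),
                           toy_table()), "unknown target")
})

test_that("cascades nest survivors, audit every compound once, and are
           idempotent at the final stage", {
  sim <- simulate_score_tables(planted_screen(seed = 3))
  cc <- default_cascade_config(k_final = 20)
  res <- run_cascade(sim$table, cc)
  sizes <- vapply(res$survivors, length, 0L)
  expect_true(all(diff(c(length(res$universe), sizes)) <= 0))
  expect_setequal(res$audit$compound_id, res$universe)
  expect_equal(nrow(res$audit), length(res$universe))

  # idempotence: re-applying the last stage changes nothing
  last <- cc$stages[[length(cc$stages)]]
  again <- apply_stage(res$final, last, sim$table)
  expect_identical(sort(again$survivors), sort(res$final))
})

test_that("the cascade recovers exactly the planted selective set", {
  sim <- simulate_score_tables(planted_screen(n_compounds = 500,
                                              n_selective = 20, seed = 1))
  res <- run_cascade(sim$table, default_cascade_config(k_final = 20))
  planted <- sim$labels$compound_id[sim$labels$class == "selective"]
  expect_setequal(res$final, planted)

  # nothing survives when nothing selective is planted
  sim0 <- simulate_score_tables(planted_screen(n_selective = 0, seed = 1))
  res0 <- run_cascade(sim0$table, default_cascade_config())
  expect_length(res0$final, 0)
})

test_that("stages agree with an independent per-compound rule evaluator", {
  sim <- simulate_score_tables(planted_screen(n_compounds = 200,
                                              n_selective = 10,
                                              n_pan = 30, seed = 7))
  stages <- list(stage_differential_binder("moe", "sRANKL", "mRANKL", -6),
                 stage_threshold("glide", "sRANKL", -3.5),
                 stage_rank_top("ifd", "sRANKL", 5))
  cc <- do.call(cascade_config, stages)
  res <- run_cascade(sim$table, cc)
  brute <- brute_cascade(sim$table, stages, res$universe)
  for (k in seq_along(stages)) {
    expect_setequal(res$survivors[[k]], brute[[k]])
  }
})

test_that("stage order matters and the audit trail shows it", {
  # u binds both targets weakly on moe but passes glide; with the glide
  # threshold first, the differential stage sees u; reversed, u is gone
  tab <- score_table(data.frame(
    compound_id = c("u", "u", "u", "v", "v", "v"),
    target_id = c("sRANKL", "mRANKL", "sRANKL",
                  "sRANKL", "mRANKL", "sRANKL"),
    scorer_id = c("moe", "moe", "glide", "moe", "moe", "glide"),
    score = c(-5, -2, -4, -7, -2, -2)))
  diff_st <- stage_differential_binder("moe", "sRANKL", "mRANKL", -6)
  thr_st <- stage_threshold("glide", "sRANKL", -3.5)
  r1 <- run_cascade(tab, cascade_config(diff_st, thr_st))
  r2 <- run_cascade(tab, cascade_config(thr_st, diff_st))
  expect_identical(r1$final, character(0))   # v fails glide, u fails diff
  expect_identical(r2$final, character(0))
  # but the removal stages differ, visible in the audit
  s1 <- r1$audit$stage_index[r1$audit$compound_id == "v"]
  s2 <- r2$audit$stage_index[r2$audit$compound_id == "v"]
  expect_identical(s1, 2L)
  expect_identical(s2, 1L)
})
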