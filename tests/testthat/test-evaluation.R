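# Fold construction, confusion metrics and the mean +/- population-sd
# aggregation convention.

make_manifest <- function(n_specimens = 4, per_spec = 4) {
  do.call(rbind, lapply(seq_len(n_specimens) - 1, function(sp)
    data.frame(path = sprintf("s%d_%d.wav", sp, seq_len(per_spec)),
               specimen_id = sp, screw_id = 1L, sensor_id = 1L,
               condition = rep(c("fixed", "loose"), per_spec / 2),
               sweep_index = seq_len(per_spec))))
}

test_that("loso folds partition the manifest by specimen", {
  man <- make_manifest(4, 6)
  folds <- loso_folds(man)
  expect_length(folds, 4)
  test_rows <- do.call(rbind, lapply(folds, `[[`, "test"))
  expect_equal(nrow(test_rows), nrow(man))
  expect_false(any(duplicated(test_rows$path)))
  for (f in folds) {
    expect_true(all(f$test$specimen_id == f$test_specimen_id))
    expect_false(f$test_specimen_id %in% f$train$specimen_id)
    expect_equal(nrow(f$train) + nrow(f$test), nrow(man))
  }

  # two specimens give two complementary folds
  man2 <- make_manifest(2, 4)
  folds2 <- loso_folds(man2)
  expect_length(folds2, 2)
  expect_equal(sort(c(folds2[[1]]$test$path, folds2[[2]]$test$path)),
               sort(man2$path))

  expect_error(loso_folds(make_manifest(1, 4)),
               class = "vibroscrew_input_error")
})

test_that("confusion metrics follow the loose-positive convention", {
  # 94/6 split on both classes, the strongest reference fold
  preds <- c(rep("loose", 94), rep("fixed", 6), rep("fixed", 94),
             rep("loose", 6))
  labs <- c(rep("loose", 100), rep("fixed", 100))
  fr <- confusion_metrics(preds, labs)
  expect_equal(fr$sensitivity, 94)
  expect_equal(fr$specificity, 94)
  expect_equal(fr$tp + fr$fn + fr$tn + fr$fp, 200)

  # hand-computed small confusion: TP 3, FN 1, TN 2, FP 2
  fr2 <- confusion_metrics(c("loose", "loose", "loose", "fixed",
                             "loose", "loose", "fixed", "fixed"),
                           c("loose", "loose", "loose", "loose",
                             "fixed", "fixed", "fixed", "fixed"))
  expect_equal(fr2$sensitivity, 75)
  expect_equal(fr2$specificity, 50)
  expect_equal(fr2$accuracy, 62.5)

  perfect <- confusion_metrics(c("loose", "fixed"), c("loose", "fixed"))
  expect_equal(c(perfect$sensitivity, perfect$specificity,
                 perfect$accuracy), c(100, 100, 100))

  expect_error(confusion_metrics(c("loose", "loose"), c("loose", "loose")),
               class = "vibroscrew_input_error")
  expect_error(confusion_metrics("loose", c("loose", "fixed")),
               class = "vibroscrew_input_error")
})

test_that("aggregation reproduces the reference mean +/- spread", {
  # per-fold sensitivities and specificities of the reference experiment
  sens <- summarize_folds(c(94.00, 81.00, 92.00, 99.00))
  expect_equal(round(sens$mean[["value"]], 2), 91.50)
  expect_equal(round(sens$sd[["value"]], 2), 6.58)

  spec <- summarize_folds(c(94.00, 87.76, 90.62, 92.00))
  expect_equal(round(spec$mean[["value"]], 2), 91.10)
  expect_equal(round(spec$sd[["value"]], 2), 2.27)

  # the sample (n-1) convention would NOT reproduce the reference spread
  expect_false(isTRUE(all.equal(round(sd(c(94, 81, 92, 99)), 2), 6.58)))
})

test_that("summarize_folds aggregates fold results and edge cases", {
  f1 <- confusion_metrics(c("loose", "fixed"), c("loose", "fixed"), 0L)
  f2 <- confusion_metrics(c("fixed", "fixed"), c("loose", "fixed"), 1L)
  s <- summarize_folds(list(f1, f2))
  expect_equal(s$mean[["sensitivity"]], 50)
  expect_equal(s$mean[["accuracy"]], 75)
  expect_true(all(s$mean >= apply(s$folds[c("sensitivity", "specificity",
                                            "accuracy")], 2, min)))
  expect_true(all(s$mean <= apply(s$folds[c("sensitivity", "specificity",
                                            "accuracy")], 2, max)))

  # identical folds -> zero spread; single fold -> zero spread
  s2 <- summarize_folds(list(f1, f1))
  expect_true(all(s2$sd == 0))
  s3 <- summarize_folds(list(f1))
  expect_true(all(s3$sd == 0))
  expect_error(summarize_folds(list()), class = "vibroscrew_input_error")
})

test_that("cross-validation runs end to end on a tiny dataset", {
  design <- study_design(n_specimens = 2L, screws_per_specimen = 1L,
                         sweeps_per_screw = 3L, master_seed = 5L)
  man <- generate_dataset(design, condition_effect(),
                          excitation = tiny_excitation(),
                          write_audio = FALSE)
  expect_equal(nrow(man), 12)
  cv <- cross_validate(man, tiny_feature_config(),
                       tiny_model_config(epochs = 2L),
                       augment_per_sample = 0L, seed = 3L)
  expect_s3_class(cv, "cv_summary")
  expect_equal(nrow(cv$folds), 2)
  expect_true(all(cv$folds$tp + cv$folds$fp + cv$folds$tn + cv$folds$fn == 6))
  expect_true(all(cv$mean >= 0 & cv$mean <= 100))

  p <- withr::local_tempfile(fileext = ".csv")
  write_fold_report(cv, p)
  rep <- read.csv(p)
  expect_equal(names(rep), c("fold", "specimen_id", "tp", "fp", "tn", "fn",
                             "sensitivity", "specificity", "accuracy"))
})

test_that("augmented training folds keep the pipeline consistent", {
  design <- study_design(n_specimens = 2L, screws_per_specimen = 1L,
                         sweeps_per_screw = 2L, master_seed = 8L)
  man <- generate_dataset(design, condition_effect(),
                          excitation = tiny_excitation(),
                          write_audio = FALSE)
  cv <- cross_validate(man, tiny_feature_config(),
                       tiny_model_config(epochs = 1L),
                       norm_scope = "entire_dataset",
                       augment_per_sample = 1L, seed = 2L)
  expect_equal(nrow(cv$folds), 2)
  expect_true(all(is.finite(unlist(cv$mean))))
})

test_that("SE recalibration does not hurt LOSO accuracy", {
  # separation-reduced data so neither variant saturates; three seeds,
  # same folds, same training protocol -- only the SE blocks differ
  design <- study_design(n_specimens = 2L, screws_per_specimen = 2L,
                         sweeps_per_screw = 8L, master_seed = 13L)
  man <- generate_dataset(design, condition_effect(separation = 0.7),
                          excitation = tiny_excitation(),
                          write_audio = FALSE)
  accs <- sapply(1:3, function(s) {
    sapply(c(TRUE, FALSE), function(use_se) {
      cv <- cross_validate(man, tiny_feature_config(),
                           tiny_model_config(use_se = use_se),
                           augment_per_sample = 0L, seed = s)
      cv$mean[["accuracy"]]
    })
  })
  mean_se <- mean(accs[1, ])
  mean_plain <- mean(accs[2, ])
  expect_gte(mean_se, mean_plain - 2)
})
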