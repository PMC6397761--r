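make_table <- function(dir, cfg = synth_config(n_bands = 15, bags_per_class = 5,
                                               signature_scale = 0.5, seed = 71)) {
  x <- simulate_two_level(toy_genus_map(), cfg, similarity = 0.3)
  f <- file.path(dir, "train.csv")
  write_instance_table(x, f)
  list(path = f, bagset = x)
}

test_that("run_train / run_predict reproduce the test-on-train protocol", {
  dir <- withr::local_tempdir()
  tb <- make_table(dir)
  cfg <- run_config(train_table = tb$path, test_table = tb$path,
                    model_dir = file.path(dir, "model"),
                    out = file.path(dir, "preds.csv"),
                    level = "hierarchical", seed = 1, verbose = FALSE,
                    water_band_ranges = list())
  model <- run_train(cfg)
  expect_s3_class(model, "miace_ovo")
  expect_true(file.exists(file.path(dir, "model", "manifest.json")))
  expect_true(file.exists(file.path(dir, "model", "training_report.csv")))
  # genus model + only the multi-species genus has a sub-model
  expect_identical(model$hierarchy$AC, "ACRU")
  expect_s3_class(model$hierarchy$PI, "miace_ovo")

  preds <- run_predict(cfg)
  df <- utils::read.csv(cfg$out)
  expect_equal(nrow(df), n_bags(tb$bagset))
  expect_true(all(c("bag_id", "predicted", "genus_predicted") %in% names(df)))
  # separable synthetic data: test-on-train is perfect
  expect_equal(rank1_accuracy(preds), 1)

  # retraining with the same config yields identical model files
  cfg2 <- cfg; cfg2$model_dir <- file.path(dir, "model2")
  run_train(cfg2)
  f1 <- readLines(file.path(dir, "model", "manifest.json"))
  f2 <- readLines(file.path(dir, "model2", "manifest.json"))
  expect_identical(f1, f2)
  c1 <- readLines(file.path(dir, "model", "classifier_001.json"))
  c2 <- readLines(file.path(dir, "model2", "classifier_001.json"))
  expect_identical(c1, c2)
})

test_that("run_train at genus level on 4 classes yields 6 classifiers", {
  dir <- withr::local_tempdir()
  x <- simulate_bags(synth_config(n_classes = 4, n_bands = 12,
                                  bags_per_class = 4, signature_scale = 0.5,
                                  seed = 41))
  write_instance_table(x, file.path(dir, "t.csv"))
  cfg <- run_config(train_table = file.path(dir, "t.csv"),
                    model_dir = file.path(dir, "m"), level = "genus",
                    verbose = FALSE, water_band_ranges = list())
  model <- run_train(cfg)
  expect_length(model$classifiers, 6)
})

test_that("run_evaluate writes the metric report", {
  dir <- withr::local_tempdir()
  tb <- make_table(dir)
  cfg <- run_config(train_table = tb$path, test_table = tb$path,
                    model_dir = file.path(dir, "m"),
                    out = file.path(dir, "p.csv"), level = "hierarchical",
                    epsilon = 0.01, verbose = FALSE, water_band_ranges = list())
  run_train(cfg)
  preds <- run_predict(cfg)
  ecfg <- cfg; ecfg$out <- file.path(dir, "report")
  res <- run_evaluate(preds, ecfg)
  expect_true(file.exists(file.path(dir, "report", "confusion.csv")))
  expect_true(file.exists(file.path(dir, "report", "per_class_metrics.csv")))
  expect_equal(res$accuracy, 1)
  expect_false(is.na(res$cross_entropy))   # softened -> finite
})

test_that("run configs round-trip through JSON", {
  dir <- withr::local_tempdir()
  cfg <- run_config(train_table = "a.csv", seed = 7, epsilon = 0.017,
                    pairs_mode = "two", cv_repeats = 3, verbose = FALSE)
  f <- file.path(dir, "cfg.json")
  write_run_config(cfg, f)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2[order(names(cfg2))], cfg[order(names(cfg2))])
})

test_that("cross-validation is stratified at the bag level and excludes singletons", {
  x <- simulate_bags(synth_config(n_classes = 2, n_bands = 12,
                                  bags_per_class = 8, signature_scale = 0.5,
                                  seed = 61))
  cv <- crossval_ovo(x, level = "species", repeats = 2, seed = 3)
  # separable two-class data: mean CV accuracy 1
  expect_equal(cv$accuracy, 1)
  # each per-repeat confusion covers every crown exactly once
  for (cm in cv$confusions) expect_equal(sum(cm), n_bags(x))
  expect_equal(rowSums(cv$mean_confusion),
               c(table(x$bags$species)), ignore_attr = TRUE)
  # single repeat on a fixed seed is deterministic
  cv1 <- crossval_ovo(x, level = "species", repeats = 1, seed = 5)
  cv2 <- crossval_ovo(x, level = "species", repeats = 1, seed = 5)
  expect_identical(cv1$confusions, cv2$confusions)

  # a class with one crown is excluded with a warning
  y <- simulate_bags(synth_config(n_classes = 3, n_bands = 12,
                                  bags_per_class = 4, signature_scale = 0.5,
                                  seed = 62))
  first_c3 <- which(y$bags$species == "C3")[1]
  y1 <- subset_bags(y, y$bags$species != "C3" |
                      seq_len(n_bags(y)) == first_c3)
  expect_warning(cv3 <- crossval_ovo(y1, level = "species", repeats = 1, seed = 1),
                 "fewer than 2")
  expect_false("C3" %in% cv3$classes)
})

test_that("the command-line front-end runs the full workflow", {
  skip_on_os("windows")
  dir <- withr::local_tempdir()
  cli <- system.file("cli", "miace.R", package = "miace")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- file.path(dir, "sim.csv")
  st <- system2(rscript, c(cli, "simulate", "--out", out, "--seed", "3"),
                stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  st2 <- system2(rscript, c(cli, "train", "--train", out, "--model",
                            file.path(dir, "m"), "--level", "genus",
                            "--seed", "3"), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "m", "manifest.json")))
  st3 <- system2(rscript, c(cli, "predict", "--model", file.path(dir, "m"),
                            "--test", out, "--out", file.path(dir, "p.csv"),
                            "--seed", "3"), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "p.csv")))
})
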