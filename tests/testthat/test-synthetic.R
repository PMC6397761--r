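test_that("generated bags follow the scaled-target Gaussian model", {
  d <- 8
  s1 <- c(rep(0.3, 4), rep(0, 4))
  cfg <- synth_config(n_classes = 1, n_bands = d,
                      class_signatures = matrix(s1, 1),
                      background_mean = rep(0.2, d),
                      background_cov = diag(d) * 0.04,
                      abundance = c(1, 1), target_fraction = 1,
                      bags_per_class = 40, instances_per_bag = c(25, 25),
                      seed = 5)
  x <- simulate_bags(cfg)
  expect_equal(n_bags(x), 40)
  expect_equal(n_instances(x), 1000)
  # every instance mean is alpha*s + mu_b; sample mean within 3 SE
  se <- sqrt(0.04 / 1000)
  expect_true(all(abs(colMeans(x$spectra) - (s1 + 0.2)) < 3 * se))
  gt <- attr(x, "ground_truth")
  expect_true(all(gt$role == "target"))
  expect_true(all(gt$alpha == 1))
})

test_that("the generator is deterministic given the seed and validates inputs", {
  cfg <- synth_config(n_classes = 2, n_bands = 10, bags_per_class = 3, seed = 8)
  x1 <- simulate_bags(cfg)
  x2 <- simulate_bags(cfg)
  expect_equal(x1$spectra, x2$spectra)
  expect_identical(attr(x1, "ground_truth"), attr(x2, "ground_truth"))
  x3 <- simulate_bags(synth_config(n_classes = 2, n_bands = 10,
                                   bags_per_class = 3, seed = 9))
  expect_false(isTRUE(all.equal(x1$spectra, x3$spectra)))
  # abundance must exclude zero
  expect_error(synth_config(abundance = c(0, 0)), "alpha != 0")
  expect_error(synth_config(abundance = c(-1, 1)), "alpha != 0")
  expect_error(simulate_bags(synth_config(
    n_bands = 3, background_cov = matrix(0, 3, 3))), "positive definite")
  # every positive bag keeps at least one target even at tiny fractions
  x4 <- simulate_bags(synth_config(n_classes = 2, n_bands = 10,
                                   bags_per_class = 4, target_fraction = 0.01,
                                   contamination_fraction = 0.5, seed = 3))
  gt4 <- attr(x4, "ground_truth")
  expect_true(all(tapply(gt4$role == "target", gt4$bag_id, sum) >= 1))
  expect_true(any(gt4$role == "contamination"))
  expect_true(all(gt4$source_class[gt4$role == "contamination"] != ""))
})

test_that("two-level generation mirrors a genus/species hierarchy", {
  cfg <- synth_config(n_bands = 16, bags_per_class = 3, seed = 21)
  x <- simulate_two_level(toy_genus_map(), cfg, similarity = 0.5)
  expect_setequal(unique(x$bags$species), c("ACRU", "PIEL", "PIPA", "PITA"))
  expect_equal(x$bags$genus[x$bags$species == "PIEL"][1], "PI")
  expect_equal(n_bags(x), 4 * 3)
  # single genus reduces to plain generation (one genus label everywhere)
  xs <- simulate_two_level(list(QU = c("QULA", "QUNI")), cfg)
  expect_true(all(xs$bags$genus == "QU"))
  expect_error(simulate_two_level(list(AC = character(0)), cfg), "zero species")
  expect_error(simulate_two_level(toy_genus_map(), cfg, similarity = 1),
               "similarity")
})

test_that("within-genus similarity trades species accuracy against genus accuracy", {
  base <- synth_config(n_bands = 20, bags_per_class = 8,
                       instances_per_bag = c(8, 12), signature_scale = 0.4,
                       seed = 31)
  acc <- vapply(c(0.2, 0.97), function(sim) {
    x <- simulate_two_level(list(AA = c("S1", "S2"), BB = c("S3", "S4")),
                            base, similarity = sim)
    m <- miace_ovo(x, level = "genus", hierarchical = TRUE)
    p <- predict_hierarchical(m, x, seed = 1)
    c(genus = mean(p$genus_predicted == x$bags$genus),
      species = rank1_accuracy(p))
  }, numeric(2))
  # genus stays easy; species degrade as signatures within a genus converge
  expect_true(all(acc["genus", ] > 0.9))
  expect_lt(acc["species", 2], acc["species", 1])
})

test_that("accuracy degrades gracefully as the target fraction shrinks", {
  acc <- vapply(c(1, 0.5, 0.1), function(tf) {
    mean(vapply(1:3, function(seed) {
      x <- simulate_bags(synth_config(
        n_classes = 2, n_bands = 50, bags_per_class = 12,
        instances_per_bag = c(10, 10), target_fraction = tf,
        signature_scale = 0.4, seed = seed))
      rank1_accuracy(predict(miace_ovo(x, level = "species"), x, seed = 1))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(acc[1], 1)              # full-target crowns: perfect
  expect_true(all(diff(acc) <= 0.05))  # no cliff as targets get sparse
  expect_gt(acc[3], 0.75)              # one target pixel in ten: well above chance
})

test_that("instance selection recovers the signature better than all-pixel averaging", {
  # at one target pixel per bag, the discriminative selected-instance estimate
  # should align with the planted direction better than the naive mean
  # signature computed from every (mostly background) positive pixel
  cos_pair <- vapply(1:10, function(seed) {
    x <- simulate_bags(synth_config(
      n_classes = 2, n_bands = 50, bags_per_class = 12,
      instances_per_bag = c(10, 10), target_fraction = 0.1,
      signature_scale = 0.4, seed = seed))
    bc <- bags_by_class(x, "species")
    fit <- mi_ace(bc[["C1"]], bc[["C2"]])
    tw <- whiten(attr(x, "signatures")[1, ] + attr(x, "background_mean"),
                 fit$background)
    tw <- tw / sqrt(sum(tw^2))
    pos_px <- x$spectra[x$bags$species[x$bag] == "C1", , drop = FALSE]
    naive <- miace_signature(colMeans(pos_px) - fit$background$mean,
                             fit$background)
    c(mi = sum(fit$s * tw), naive = sum(naive$s * tw))
  }, numeric(2))
  expect_true(all(cos_pair["mi", ] > cos_pair["naive", ]))
  expect_gt(mean(cos_pair["mi", ]), 0.9)
})
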