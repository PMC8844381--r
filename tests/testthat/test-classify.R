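test_that("cohort splitting is embryo-level, sized, and seeded", {
  ids <- sprintf("e%03d", 1:89)
  sp <- split_cohort(ids, counts = c(70, 19), seed = 1)
  expect_length(sp$train, 70)
  expect_length(sp$test, 19)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)

  sp2 <- split_cohort(sprintf("e%d", 1:10), test_fraction = 0.2, seed = 9)
  expect_length(sp2$train, 8)
  expect_length(sp2$test, 2)
  expect_identical(split_cohort(ids, counts = c(70, 19), seed = 5),
                   split_cohort(ids, counts = c(70, 19), seed = 5))
  expect_error(split_cohort(ids[1]), "at least 2")
  expect_error(split_cohort(ids, counts = c(89, 0)), "empty")
})

test_that("gradients match numerical differentiation", {
  m <- polarcall:::init_cnn(16, c(2, 3, 4), seed = 1)
  set.seed(60)
  x <- array(rnorm(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  y <- rbind(c(1, 0), c(0, 1))
  fwd <- polarcall:::cnn_forward(m$params, x, keep_cache = TRUE)
  gr <- polarcall:::cnn_backward(m$params, fwd, y)
  loss <- function(par) {
    -mean(colSums(y * log(polarcall:::cnn_forward(par, x)$probs)))
  }
  for (nm in names(m$params)) {
    eps <- 1e-5
    p2 <- m$params
    i <- sample(length(p2[[nm]]), 1)
    p2[[nm]][i] <- p2[[nm]][i] + eps; lp <- loss(p2)
    p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; lm <- loss(p2)
    expect_equal(gr[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("training separates a separable texture problem quickly", {
  toy <- toy_texture_set(12)
  cfg <- ensemble_config(n_members = 2, epochs = 5, seed = 3)
  sgd <- train_member(toy$frames, toy$labels, 0, cfg)
  adam <- train_member(toy$frames, toy$labels, 1, cfg)
  expect_equal(sgd$optimizer, "sgd")
  expect_equal(adam$optimizer, "adam")
  expect_equal(sgd$train_accuracy, 1)
  expect_equal(adam$train_accuracy, 1)
  # probabilities live on the simplex
  pr <- predict_proba(sgd, toy$frames[1:5])
  expect_true(all(pr >= 0))
  expect_equal(unname(rowSums(pr)), rep(1, 5))
  # seeded reproducibility: same member index, same weights
  again <- train_member(toy$frames, toy$labels, 0, cfg)
  expect_identical(sgd$params, again$params)
  # single-class data refuses to train
  expect_error(train_member(toy$frames, rep(1, length(toy$labels)), 0, cfg),
               "single class")
})

test_that("default optimizer assignment is half SGD, half Adam", {
  cfg <- ensemble_config(n_members = 6)
  half <- ceiling(cfg$n_members / 2)
  expect_equal(half, 3)
  # member indices 0..2 -> sgd, 3..5 -> adam (checked without full training)
  toy <- toy_texture_set(2, size = 32)
  cfg_small <- ensemble_config(n_members = 6, epochs = 1, input_size = 32,
                               channels = c(2, 2, 2), seed = 1)
  kinds <- vapply(c(0, 2, 3, 5), function(i) {
    train_member(toy$frames, toy$labels, i, cfg_small)$optimizer
  }, character(1))
  expect_equal(kinds, c("sgd", "sgd", "adam", "adam"))
})

test_that("ensemble prediction averages probabilities with documented ties", {
  toy <- toy_texture_set(6, size = 32)
  cfg <- ensemble_config(n_members = 2, epochs = 2, input_size = 32,
                         channels = c(2, 3, 4), seed = 8)
  ens <- train_ensemble(toy$frames, toy$labels, cfg)
  expect_length(ens$members, 2)
  p1 <- predict_proba(ens$members[[1]], toy$frames[1:6])
  p2 <- predict_proba(ens$members[[2]], toy$frames[1:6])
  pred <- ensemble_predict(ens, toy$frames[1:6])
  expect_equal(pred$p_after, unname((p1[, 2] + p2[, 2]) / 2))
  expect_equal(pred$p_before + pred$p_after, rep(1, 6))
  expect_equal(pred$label, as.integer(pred$p_after > 0.5))

  # identical members: ensemble equals single member in both modes
  twin <- ens; twin$members <- list(ens$members[[1]], ens$members[[1]])
  single <- as.integer(p1[, 2] > 0.5)
  expect_equal(ensemble_predict(twin, toy$frames[1:6])$label, single)
  cfg_mv <- ensemble_config(n_members = 2, epochs = 2, input_size = 32,
                            channels = c(2, 3, 4), seed = 8,
                            ensemble_mode = "label_majority")
  expect_equal(ensemble_predict(twin, toy$frames[1:6], cfg_mv)$label, single)

  # a mean of exactly 0.5 is called before-onset (strict threshold)
  expect_equal(as.integer(0.5 > 0.5), 0L)
  # majority ties go to before-onset: 1 vote vs 1 vote
  votes_tied <- ensemble_predict(
    list(ens$members[[1]], ens$members[[2]]), toy$frames[1:6], cfg_mv)
  disagree <- which((p1[, 2] > 0.5) != (p2[, 2] > 0.5))
  if (length(disagree)) expect_true(all(votes_tied$label[disagree] == 0))
  expect_error(ensemble_predict(list(), toy$frames[1:2]), "at least one")
})

test_that("class activation maps satisfy the GAP logit identity", {
  toy <- toy_texture_set(6, size = 32)
  cfg <- ensemble_config(n_members = 1, epochs = 2, input_size = 32,
                         channels = c(2, 3, 4), seed = 12)
  model <- train_member(toy$frames, toy$labels, 0, cfg)

  set.seed(61)
  for (i in 1:4) {
    frame <- matrix(rnorm(32 * 32), 32)
    for (cls in 0:1) {
      cam <- compute_cam(model, frame, cls)
      expect_lt(abs(mean(cam$raw) - (cam$logit - cam$bias)), 1e-4)
      expect_equal(dim(cam$map), c(32, 32))
    }
  }

  # zero dense weights -> identically zero map
  z <- model; z$params$wd[] <- 0
  cam0 <- compute_cam(z, matrix(rnorm(32 * 32), 32), 1)
  expect_true(all(cam0$raw == 0))

  # a single feature map with unit weight reproduces that feature map
  one <- train_member(toy$frames, toy$labels, 0,
                      ensemble_config(n_members = 1, epochs = 1,
                                      input_size = 32, channels = c(2, 2, 1),
                                      seed = 2))
  one$params$wd <- matrix(c(0, 1), 2, 1)  # after-class weight 1
  one$params$bd <- c(0, 0)
  frame <- matrix(rnorm(32 * 32), 32)
  cam1 <- compute_cam(one, frame, 1)
  x <- polarcall:::prep_frames(frame, 32)
  feat <- polarcall:::cnn_forward(one$params, x)$features[, , , 1]
  expect_equal(cam1$raw, feat, tolerance = 1e-12)

  expect_error(compute_cam(model, matrix(0, 32, 32), 2), "class_index")
})
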