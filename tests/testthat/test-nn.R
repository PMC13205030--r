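mf <- glycohrv:::model_forward
mb <- glycohrv:::model_backward
flg <- glycohrv:::focal_loss_grad

tiny_inputs <- function(B = 4, TT = 3, seed = 42) {
  set.seed(seed)
  list(beats = array(rnorm(B * TT * 200, sd = 0.3), c(B, TT, 200)),
       hrv = matrix(rnorm(B * 31), B, 31),
       y = rep(c(1L, 2L), length.out = B))
}

test_that("focal loss reduces to cross-entropy and matches hand arithmetic", {
  p <- c(0.9, 0.4, 0.7)
  expect_equal(focal_loss(p, gamma = 0, alpha = 1), mean(-log(p)))
  expect_equal(focal_loss(1, gamma = 2), 0)
  expect_equal(focal_loss(0.5, gamma = 2, alpha = 1), 0.25 * log(2))
  expect_true(is.finite(focal_loss(0)))   # clipped, not -Inf
  expect_error(focal_loss(1.2), "probabilities")
})

test_that("focal loss gradient matches finite differences", {
  set.seed(1)
  B <- 5
  z <- matrix(rnorm(B * 2), B, 2)
  y <- c(1L, 2L, 2L, 1L, 2L)
  sm <- glycohrv:::softmax
  loss_of <- function(z) {
    p <- sm(z)
    focal_loss(p[cbind(1:B, y)], 2, 0.25)
  }
  g <- flg(sm(z), y, 2, 0.25)
  for (i in seq_along(z)) {
    zp <- z; zp[i] <- zp[i] + 1e-6
    zm <- z; zm[i] <- zm[i] - 1e-6
    expect_equal(g[i], (loss_of(zp) - loss_of(zm)) / 2e-6, tolerance = 1e-5)
  }
})

test_that("network gradients match central finite differences", {
  inp <- tiny_inputs()
  sp <- model_spec(n_beats = 3, dropout = 0, seed = 3)
  m <- build_model(sp)
  loss_fn <- function(params) {
    mm <- build_model(sp)
    mm$params <- params
    fw <- mf(mm, inp$beats, inp$hrv, training = TRUE)
    focal_loss(fw$probs[cbind(seq_along(inp$y), inp$y)], 2, 0.25)
  }
  fw <- mf(m, inp$beats, inp$hrv, training = TRUE)
  dlog <- flg(fw$probs, inp$y, 2, 0.25)
  bw <- mb(m, fw$cache, dlog)
  set.seed(11)
  for (k in names(bw$grads)) {
    g <- bw$grads[[k]]
    for (i in sample(length(g), min(3, length(g)))) {
      p <- m$params
      p[[k]][i] <- p[[k]][i] + 1e-6; lp <- loss_fn(p)
      p[[k]][i] <- p[[k]][i] - 2e-6; lm <- loss_fn(p)
      num <- (lp - lm) / 2e-6
      expect_lt(abs(num - g[i]), 1e-5 + 1e-3 * (abs(num) + abs(g[i])))
    }
  }
  # input gradients (basis of the saliency map)
  for (i in sample(length(inp$beats), 6)) {
    b2 <- inp$beats
    b2[i] <- b2[i] + 1e-6
    lp <- { fw2 <- mf(m, b2, inp$hrv, TRUE); focal_loss(fw2$probs[cbind(1:4, inp$y)], 2, 0.25) }
    b2[i] <- b2[i] - 2e-6
    lm <- { fw2 <- mf(m, b2, inp$hrv, TRUE); focal_loss(fw2$probs[cbind(1:4, inp$y)], 2, 0.25) }
    num <- (lp - lm) / 2e-6
    expect_lt(abs(num - bw$d_beats[i]), 1e-6 + 1e-3 * (abs(num) + abs(bw$d_beats[i])))
  }
})

test_that("forward pass produces normalized probabilities in all ablation arms", {
  inp <- tiny_inputs()
  for (arm in c("both", "ecg", "hrv")) {
    sp <- model_spec(n_beats = 3, inputs = arm, seed = 2)
    m <- build_model(sp)
    fw <- mf(m, inp$beats, inp$hrv, training = FALSE)
    expect_true(all(abs(rowSums(fw$probs) - 1) < 1e-6))
    expect_true(all(fw$probs >= 0))
  }
  # zeroed HRV still yields valid probabilities
  sp <- model_spec(n_beats = 3, seed = 2)
  m <- build_model(sp)
  fw0 <- mf(m, inp$beats, inp$hrv * 0, training = FALSE)
  expect_true(all(is.finite(fw0$probs)))
})

test_that("beat order matters to a trained model (recurrent sensitivity)", {
  set.seed(3)
  n <- 48; TT <- 4
  beats <- array(rnorm(n * TT * 200, sd = 0.3), c(n, TT, 200))
  # plant a beat-order-dependent signal: class flips with ramp direction
  ramp <- seq(-0.5, 0.5, length.out = TT)
  y <- rep(c("euglycemia", "hyperglycemia"), each = n / 2)
  for (i in 1:n) {
    s <- if (y[i] == "hyperglycemia") ramp else rev(ramp)
    for (t in 1:TT) beats[i, t, ] <- beats[i, t, ] + s[t]
  }
  hrv <- matrix(0, n, 31)
  sp <- model_spec(n_beats = TT, max_epochs = 6, es_patience = 6, seed = 4)
  m <- build_model(sp)
  m <- train_model(m, beats, hrv, y)
  p1 <- predict(m, beats[1:6, , , drop = FALSE], hrv[1:6, ])
  p2 <- predict(m, beats[1:6, TT:1, , drop = FALSE], hrv[1:6, ])
  expect_gt(max(abs(p1 - p2)), 1e-4)
})

test_that("training tracks a running loss minimum and is seed-deterministic", {
  set.seed(6)
  n <- 64
  beats <- array(rnorm(n * 3 * 200, sd = 0.3), c(n, 3, 200))
  hrv <- matrix(rnorm(n * 31), n, 31)
  y <- rep(c("euglycemia", "hyperglycemia"), each = n / 2)
  hrv[, 1] <- hrv[, 1] + ifelse(y == "hyperglycemia", -2.5, 0)
  sp <- model_spec(n_beats = 3, max_epochs = 5, es_patience = 5, seed = 9)
  m1 <- train_model(build_model(sp), beats, hrv, y)
  m2 <- train_model(build_model(sp), beats, hrv, y)
  expect_equal(tail(m1$history, 1), tail(m2$history, 1), tolerance = 1e-6)
  expect_true(all(diff(cummin(m1$history)) <= 0))
  expect_error(train_model(build_model(sp), beats, hrv, rep("euglycemia", n)),
               "both classes")
})

test_that("training accuracy reaches 0.95 on strongly coupled windows", {
  set.seed(5)
  n <- 96; TT <- 4
  t0 <- seq(-80, 119) / 250 * 1000
  tpl <- function(qt) {
    0.15 * exp(-0.5 * ((t0 + 150) / 20)^2) - 0.12 * exp(-0.5 * ((t0 + 25) / 8)^2) +
      exp(-0.5 * (t0 / 10)^2) - 0.2 * exp(-0.5 * ((t0 - 25) / 8)^2) +
      0.3 * exp(-0.5 * ((t0 - 280 - qt) / 45)^2)
  }
  y <- rep(c("euglycemia", "hyperglycemia"), each = n / 2)
  beats <- array(0, c(n, TT, 200))
  hrv <- matrix(rnorm(n * 31), n, 31)
  for (i in 1:n) {
    for (t in 1:TT) {
      beats[i, t, ] <- tpl(if (y[i] == "hyperglycemia") 15 else 0) + rnorm(200, 0, 0.05)
    }
  }
  hrv[, 1] <- hrv[, 1] + ifelse(y == "hyperglycemia", -2, 0)
  sp <- model_spec(n_beats = TT, max_epochs = 8, es_patience = 8, seed = 2)
  m <- train_model(build_model(sp), beats, hrv, y)
  acc <- evaluate_predictions(predict(m, beats, hrv)[, 2], y)["accuracy"]
  expect_gte(unname(acc), 0.95)
})

test_that("evaluation metrics match hand arithmetic and tie conventions", {
  # TP=3, FP=1, TN=5, FN=1
  p <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.3, 0.1, 0.2)
  y <- c("hyperglycemia", "hyperglycemia", "hyperglycemia", "euglycemia",
         "hyperglycemia", "euglycemia", "euglycemia", "euglycemia",
         "euglycemia", "euglycemia")
  met <- evaluate_predictions(p, y)
  expect_equal(unname(met["accuracy"]), 0.8)
  expect_equal(unname(met["precision"]), 0.75)
  expect_equal(unname(met["sensitivity"]), 0.75)
  expect_equal(unname(met["specificity"]), 5 / 6)
  expect_equal(unname(met["f1"]), 0.75)
  # perfect separation
  expect_equal(unname(evaluate_predictions(c(0.9, 0.8, 0.1), c("hyperglycemia", "hyperglycemia", "euglycemia"))["auc"]), 1)
  # all-tied scores
  expect_equal(unname(evaluate_predictions(rep(0.5, 6), rep(c("hyperglycemia", "euglycemia"), 3))["auc"]), 0.5)
  # one-class test set: AUC missing
  expect_true(is.na(evaluate_predictions(c(0.2, 0.3), rep("euglycemia", 2))["auc"]))
})

test_that("fold summary reproduces the reference mean and sample sd", {
  ref <- ref_fold_metrics()
  fs <- fold_summary(ref)
  avg <- fs[fs$fold == "AVG", ]
  std <- fs[fs$fold == "STD", ]
  expect_equal(round(avg$accuracy, 3), 0.892)
  expect_equal(round(std$accuracy, 3), 0.071)
  expect_equal(round(avg$f1, 3), 0.791)
  expect_equal(nrow(fs), 7)   # 5 folds + AVG + STD
})
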