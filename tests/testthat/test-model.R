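test_that("pair features are row-major outer products", {
  expect_equal(pair_feature(c(1, 2), c(3, 4)), c(3, 4, 6, 8))
  expect_equal(pair_feature(c(0, 0), c(3, 4)), c(0, 0, 0, 0))
  set.seed(1)
  p <- rnorm(10); r <- rnorm(10)
  expect_equal(pair_feature(2 * p, r), 2 * pair_feature(p, r))
  expect_error(pair_feature(numeric(0), r), "empty")
})

test_that("raw score equals the explicit bilinear form p' M r", {
  # identity matrix in 2-D: score is the plain inner product
  ch <- channel_model(k = c(1, 0, 0, 1), m1 = c(1, 0, 0, 1) / 2,
                      m2 = -c(1, 0, 0, 1) / 2)
  expect_equal(raw_score(ch, pair_feature(c(1, 2), c(3, 4))), 11)
  expect_equal(raw_score(ch, rep(0, 4)), 0)
  expect_error(raw_score(ch, rep(1, 5)), "dimension")
  # reshape oracle on random instances
  set.seed(11)
  for (rep in 1:1000) {
    dp <- sample(2:10, 1); dr <- sample(2:10, 1)
    k <- rnorm(dp * dr)
    m1 <- rnorm(dp * dr)
    ch <- tryCatch(channel_model(k, m1, m1 - k / sum(k^2)),
                   error = function(e) NULL)
    if (is.null(ch)) next
    p <- rnorm(dp); r <- rnorm(dr)
    M <- channel_matrix(ch, dp, dr)
    expect_equal(raw_score(ch, pair_feature(p, r)),
                 as.numeric(t(p) %*% M %*% r), tolerance = 1e-12)
  }
})

test_that("Fisher direction matches the closed form on a 2-D toy", {
  pos <- rbind(c(1, 0), c(2, 0))
  neg <- rbind(c(0, 1), c(0, 2))
  fit <- fisher_direction(pos, neg, ridge = 0)
  # S_W = 0.5 I, m1 - m2 = (1.5, -1.5)  =>  direction prop to (1, -1)
  expect_equal(fit$k / sqrt(sum(fit$k^2)), c(1, -1) / sqrt(2),
               tolerance = 1e-12)
  expect_true(sum(fit$k * fit$m1) > sum(fit$k * fit$m2))  # orientation
  expect_error(fisher_direction(pos, pos, ridge = 0), "degenerate")
  expect_error(fisher_direction(matrix(0, 0, 2), neg), "nonempty")
})

test_that("returned direction optimizes the Fisher criterion", {
  set.seed(23)
  d <- 5
  pos <- matrix(rnorm(40 * d), ncol = d) + 1.5
  neg <- matrix(rnorm(40 * d), ncol = d)
  fit <- fisher_direction(pos, neg, ridge = 0)
  Jof <- function(u) {
    p1 <- pos %*% u; p2 <- neg %*% u
    (mean(p1) - mean(p2))^2 /
      (sum((p1 - mean(p1))^2) + sum((p2 - mean(p2))^2))
  }
  # closed form attains J within 1e-9 of its own evaluation and beats
  # 1000 random unit directions
  expect_equal(Jof(fit$k / sqrt(sum(fit$k^2))), fit$J, tolerance = 1e-9)
  for (rep in 1:1000) {
    u <- rnorm(d); u <- u / sqrt(sum(u^2))
    expect_true(fit$J >= Jof(u) - 1e-12)
  }
})

test_that("score calibration has the midpoint / mean fixed points", {
  ch <- channel_model(k = 1, m1 = 10, m2 = -10)
  expect_identical(transform_score(ch, 0), 50)    # X = c       -> 50
  expect_equal(transform_score(ch, 10), 75)       # X = c1      -> 75
  expect_equal(transform_score(ch, -10), 25)      # X = c2      -> 25
  # monotone, bounded in (0, 100)
  xs <- seq(-1e6, 1e6, length.out = 101)
  ys <- transform_score(ch, xs)
  expect_true(all(diff(ys) > 0))
  expect_true(all(ys > 0 & ys < 100))
  bad <- ch; bad$c1 <- bad$c2 <- 1
  expect_error(transform_score(bad, 0), "c1 == c2")
})

test_that("calibration is invariant to positive rescaling of k", {
  set.seed(2)
  k <- rnorm(9); m1 <- rnorm(9)
  m2 <- m1 - k   # guarantees c1 > c2
  ch1 <- channel_model(k, m1, m2)
  ch2 <- channel_model(7.3 * k, m1, m2)
  ch2$c1 <- 7.3 * ch1$c1; ch2$c2 <- 7.3 * ch1$c2; ch2$c <- 7.3 * ch1$c
  x <- rnorm(9)
  expect_equal(transform_score(ch1, raw_score(ch1, x)),
               transform_score(ch2, raw_score(ch2, x)), tolerance = 1e-12)
})

test_that("training produces a five-channel, deterministic model", {
  sim <- small_planted()
  m1 <- train_model(sim$pairs, sim$rna, sim$protein)
  m2 <- train_model(sim$pairs, sim$rna, sim$protein)
  expect_identical(m1, m2)                       # bit-identical retrain
  expect_length(m1$channels, 5)
  expect_identical(names(m1$channels),
                   c("structure", "grantham_hbond", "zimmerman_hbond",
                     "kd_vdw", "bb_vdw"))
  for (ch in m1$channels) {
    expect_true(ch$c1 > ch$c2)
    expect_equal(ch$c, (ch$c1 + ch$c2) / 2)
  }
})

test_that("degenerate training errors name the offending channel", {
  sim <- small_planted()
  enc <- encode_dataset(sim$pairs, sim$rna, sim$protein)
  enc$features$kd_vdw[] <- 1   # constant features: identical class means
  expect_error(
    rpiscore:::fit_channels(enc$features, enc$labels, model_config()),
    "kd_vdw")
})

test_that("final score is the weighted mean and threshold 50 is strict", {
  expect_equal(rpiscore:::fuse_scores(c(10, 20, 30, 40, 50), rep(0.2, 5)),
               30)
  expect_equal(rpiscore:::fuse_scores(rep(42, 5), rep(0.2, 5)), 42)
  # the alternative published weighting is expressible through config
  expect_equal(rpiscore:::fuse_scores(c(60, 10, 10, 10, 10),
                                      c(1 / 3, 1 / 6, 1 / 6, 1 / 6, 1 / 6)),
               60 / 3 + 40 / 6)
  # a final score of exactly 50 is non-interactive ("over 50" is strict)
  fake <- structure(
    list(version = 1L,
         channels = stats::setNames(
           lapply(names(rpiscore:::CHANNEL_PAIRINGS), function(nm)
             channel_model(1, 1, -1, pairing = nm)),
           names(rpiscore:::CHANNEL_PAIRINGS)),
         config = model_config(), scales = default_scales()),
    class = "rpi_model")
  feats <- stats::setNames(
    rep(list(matrix(0, 1, 1)), 5), names(rpiscore:::CHANNEL_PAIRINGS))
  out <- rpiscore:::score_features(fake, feats)
  expect_identical(out$final, 50)
  expect_identical(out$predicted, "non-interactive")
})

test_that("scoring a pair reports five calibrated channels and a label", {
  sim <- small_planted()
  m <- train_model(sim$pairs, sim$rna, sim$protein)
  rep1 <- score_pair(m, sim$rna[1], sim$protein[1])
  expect_length(rep1$calibrated, 5)
  expect_true(all(rep1$calibrated > 0 & rep1$calibrated < 100))
  expect_equal(rep1$final, mean(rep1$calibrated))
  expect_true(rep1$predicted %in% c("interactive", "non-interactive"))
})

test_that("model archive round-trips bit-exactly", {
  sim <- small_planted()
  m <- train_model(sim$pairs, sim$rna, sim$protein)
  f <- tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m$config, m2$config)
  for (nm in names(m$channels))
    expect_identical(m$channels[[nm]][c("k", "m1", "m2", "c1", "c2", "c")],
                     m2$channels[[nm]][c("k", "m1", "m2", "c1", "c2", "c")])
  expect_identical(unclass(m$scales$grantham),
                   unclass(m2$scales$grantham))  # tables travel with model
  s1 <- score_pair(m, sim$rna[3], sim$protein[3])
  s2 <- score_pair(m2, sim$rna[3], sim$protein[3])
  expect_identical(s1, s2)
  expect_error(load_model(tempfile()), "not found")
  bad <- tempfile(); writeLines("{not json", bad)
  expect_error(load_model(bad), "corrupted|version")
})
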