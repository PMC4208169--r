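# Chunked running moments, chunk combination and the Gaussian likelihood.

batch_stats <- function(x) {
  list(mu = mean(x), v = mean(x^2), sigma2 = mean(x^2) - mean(x)^2)
}

stream <- function(x) {
  Reduce(chunk_update, as.list(x), chunk_stats(1))
}

test_that("chunk_update reproduces batch mean and mean-of-squares", {
  s <- chunk_update(chunk_stats(1), 5)
  expect_equal(s$N, 1L)
  expect_equal(s$mu, 5)
  expect_equal(s$v, 25)
  expect_equal(chunk_finalize(s)$sigma2, 0)

  s <- stream(c(1, 2, 3))
  expect_equal(s$N, 3L)
  expect_equal(s$mu, 2)
  expect_equal(s$v, 14 / 3)
  expect_equal(chunk_finalize(s)$sigma2, 2 / 3)

  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(1:200, 1), sd = runif(1, 0.1, 10))
    b <- batch_stats(x)
    s <- stream(x)
    expect_equal(s$mu, b$mu, tolerance = 1e-12)
    expect_equal(s$v, b$v, tolerance = 1e-12)
  }
})

test_that("chunk statistics are order-invariant and reject bad input", {
  x <- c(1, 2, 3, 4.5, -2)
  a <- stream(x)
  b <- stream(rev(x))
  expect_equal(a$mu, b$mu)
  expect_equal(a$v, b$v)
  expect_error(chunk_update(chunk_stats(1), NaN), class = "harf_validation_error")
  expect_error(chunk_update(chunk_stats(2), 1), class = "harf_validation_error")
  expect_error(chunk_finalize(chunk_stats(1)), class = "harf_validation_error")
})

test_that("sigma2 stays non-negative for near-constant streams", {
  set.seed(4)
  for (i in 1:50) {
    x <- rep(runif(1, -100, 100), sample(2:100, 1)) + rnorm(1, 0, 1e-12)
    fin <- chunk_finalize(stream(x))
    expect_gte(fin$sigma2, 0)
  }
})

test_that("combine_chunks matches its worked examples in both modes", {
  c1 <- chunk_finalize(stream(c(0, 0)))
  c2 <- chunk_finalize(stream(c(2, 2)))
  paper <- combine_chunks(list(c1, c2), mode = "paper")
  expect_equal(paper$mu_m, 1)
  expect_equal(paper$mu_v, 1e-6) # zero within-chunk variance -> floor
  pooled <- combine_chunks(list(c1, c2), mode = "pooled")
  expect_equal(pooled$mu_m, 1)
  expect_equal(pooled$mu_v, 1) # batch variance of c(0,0,2,2)

  one <- combine_chunks(list(c1), mode = "paper")
  expect_equal(one$mu_m, 0)
  expect_equal(one$mu_v, 1e-6)
  expect_equal(combine_chunks(list(c1), mode = "pooled"), one)

  expect_error(combine_chunks(list()), class = "harf_validation_error")
  expect_error(
    combine_chunks(list(list(mu = 0, sigma2 = 0, N = 0))),
    class = "harf_validation_error"
  )
})

test_that("pooled combine equals batch moments for arbitrary chunkings", {
  set.seed(99)
  for (i in 1:100) {
    x <- rnorm(sample(2:500, 1), mean = runif(1, -5, 5), sd = runif(1, 0.1, 4))
    cuts <- sort(sample(seq_len(length(x) - 1), sample(0:min(8, length(x) - 1), 1)))
    parts <- split(x, findInterval(seq_along(x), cuts + 1))
    chunks <- lapply(parts, function(p) chunk_finalize(stream(p)))
    pooled <- combine_chunks(chunks, mode = "pooled", variance_floor = 1e-12)
    b <- batch_stats(x)
    expect_equal(pooled$mu_m, b$mu, tolerance = 1e-9)
    expect_equal(pooled$mu_v, b$sigma2, tolerance = 1e-9)
  }
})

test_that("paper-mode combine converges to pooled for stationary equal chunks", {
  set.seed(7)
  n_per <- 1e4
  x <- rnorm(10 * n_per, mean = 1, sd = 2)
  chunks <- lapply(split(x, rep(1:10, each = n_per)),
                   function(p) chunk_finalize(stream(p)))
  paper <- combine_chunks(chunks, mode = "paper")
  pooled <- combine_chunks(chunks, mode = "pooled")
  expect_equal(paper$mu_m, pooled$mu_m, tolerance = 1e-9) # equal sizes: exact
  # CLT-scale agreement of the variance estimates
  expect_lt(abs(paper$mu_v - pooled$mu_v), 6 * 4 * sqrt(2 / n_per))
})

test_that("paper mode is chunk-boundary sensitive on drifting data, pooled is not", {
  x <- as.numeric(1:100)
  chunks10 <- lapply(split(x, rep(1:10, each = 10)),
                     function(p) chunk_finalize(stream(p)))
  chunks1 <- list(chunk_finalize(stream(x)))
  paper10 <- combine_chunks(chunks10, mode = "paper")
  paper1 <- combine_chunks(chunks1, mode = "paper")
  expect_false(isTRUE(all.equal(paper10$mu_v, paper1$mu_v)))
  pooled10 <- combine_chunks(chunks10, mode = "pooled")
  expect_equal(pooled10$mu_v, batch_stats(x)$sigma2, tolerance = 1e-9)
})

test_that("gaussian_log_likelihood matches the closed form and its contracts", {
  expect_equal(gaussian_log_likelihood(0, 0, 1), -0.5 * log(2 * pi))
  expect_equal(gaussian_log_likelihood(3.2, 3.2, 1), -0.918939,
               tolerance = 1e-6)
  d <- 1.7
  expect_equal(gaussian_log_likelihood(5 + d, 5, 2.3),
               gaussian_log_likelihood(5 - d, 5, 2.3))
  expect_gt(gaussian_log_likelihood(1, 0, 1), gaussian_log_likelihood(2, 0, 1))
  expect_error(gaussian_log_likelihood(0, 0, 1e-9),
               class = "harf_validation_error")
})

test_that("train_class with a single chunk equals batch statistics", {
  set.seed(21)
  x <- matrix(rnorm(100 * 3), ncol = 3)
  for (mode in c("paper", "pooled")) {
    m <- train_class(x, "a", chunk_size = 100, mode = mode,
                     variance_floor = 1e-12)
    expect_equal(m$j, 1L)
    expect_equal(m$mu_m, colMeans(x), ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(m$mu_v, apply(x, 2, function(c) mean(c^2) - mean(c)^2),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("pooled-mode chunked training equals the batch oracle", {
  set.seed(33)
  x <- rnorm(100, 3, 2)
  m <- train_class(x, "a", chunk_size = 25, mode = "pooled",
                   variance_floor = 1e-12)
  expect_equal(m$j, 4L)
  expect_equal(m$mu_m, mean(x), tolerance = 1e-9)
  expect_equal(m$mu_v, mean(x^2) - mean(x)^2, tolerance = 1e-9)
})

test_that("training rejects inconsistent vector lengths, naming the offender", {
  expect_error(
    train_class(list(c(1, 2), c(1, 2), c(1, 2, 3)), "a"),
    "feature vector 3",
    class = "harf_validation_error"
  )
})

test_that("trailing partial chunks are finalized with their own count", {
  x <- as.numeric(1:7)
  m <- train_class(x, "a", chunk_size = 3, mode = "pooled",
                   variance_floor = 1e-12)
  expect_equal(m$j, 3L) # chunks of 3, 3 and 1
  expect_equal(m$mu_m, mean(x), tolerance = 1e-12)
})

test_that("train_models assigns priors that sum to one", {
  set.seed(5)
  x <- matrix(rnorm(60), ncol = 2)
  labels <- rep(c("a", "b", "c"), times = c(15, 10, 5))
  ms <- train_models(x, labels)
  priors <- vapply(ms$models, `[[`, numeric(1), "prior")
  expect_equal(sum(priors), 1, tolerance = 1e-12)
  expect_equal(unname(priors["a"]), 0.5)
  msu <- train_models(x, labels, priors = "uniform")
  expect_equal(unname(vapply(msu$models, `[[`, numeric(1), "prior")),
               rep(1 / 3, 3))
})
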