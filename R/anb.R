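#' Adaptive naive Bayes: bounded-memory chunked Gaussian training
#'
#' The adaptive naive Bayes (A-NB) trainer never stores raw samples. Feature
#' vectors are streamed one at a time into a per-chunk accumulator holding,
#' for every feature, the sample count `N`, the running mean `mu_N` and the
#' running mean of squares `v_N`; the per-chunk population variance is
#' `sigma2_N = v_N - mu_N^2`. Every `chunk_size` vectors the accumulator is
#' finalized and reset, so peak state is proportional to the number of
#' features and chunks, never to the number of samples. Finalized chunk
#' summaries `(mu_k, sigma2_k, N_k)` are then combined into one
#' class-conditional Gaussian per feature.
#'
#' Two combination rules are provided. `"paper"` takes the unweighted mean of
#' the chunk means and the unweighted mean of the chunk variances — the
#' canonical A-NB rule, exact when chunks are equal-sized and identically
#' distributed but biased under drift or a short trailing chunk. `"pooled"`
#' applies the law of total variance with chunk-size weights and reproduces
#' the exact batch mean and population variance for any chunking.
#'
#' @name anb
NULL

#' Create an empty chunk accumulator
#'
#' @param n_features Number of features tracked by the accumulator.
#' @return An object of class `chunk_stats` with `N = 0` and zeroed moments.
#' @seealso [chunk_update()], [chunk_finalize()]
#' @export
#' @examples
#' s <- chunk_stats(1)
#' s <- chunk_update(s, 5)
#' chunk_finalize(s)
chunk_stats <- function(n_features) {
  if (!is.numeric(n_features) || length(n_features) != 1L || n_features < 1) {
    harf_validation_error("n_features must be a single positive number")
  }
  structure(
    list(N = 0L, mu = rep(0, n_features), v = rep(0, n_features)),
    class = "chunk_stats"
  )
}

#' Stream one observation into a chunk accumulator
#'
#' Updates the running mean and running mean-of-squares in place-style,
#' keeping constant memory:
#' `mu_N = (mu_{N-1} (N-1) + x) / N`, `v_N = (v_{N-1} (N-1) + x^2) / N`.
#'
#' @param stats A `chunk_stats` accumulator.
#' @param x Numeric vector with one value per tracked feature; must be finite.
#' @return The updated `chunk_stats`.
#' @export
chunk_update <- function(stats, x) {
  if (!inherits(stats, "chunk_stats")) {
    harf_validation_error("stats must be a chunk_stats object")
  }
  x <- as.numeric(x)
  if (length(x) != length(stats$mu)) {
    harf_validation_error(sprintf(
      "observation has %d values but the accumulator tracks %d features",
      length(x), length(stats$mu)
    ))
  }
  if (!all(is.finite(x))) {
    harf_validation_error("non-finite value in observation; rejected")
  }
  n <- stats$N + 1L
  stats$mu <- (stats$mu * (n - 1) + x) / n
  stats$v <- (stats$v * (n - 1) + x^2) / n
  stats$N <- n
  stats
}

#' Finalize a chunk accumulator into a chunk summary
#'
#' The population variance `v_N - mu_N^2` can dip a hair below zero in
#' floating point for near-constant data; it is clamped to zero here.
#'
#' @param stats A `chunk_stats` accumulator with `N >= 1`.
#' @return A list with elements `mu`, `sigma2` (both per-feature vectors)
#'   and `N`.
#' @export
chunk_finalize <- function(stats) {
  if (!inherits(stats, "chunk_stats")) {
    harf_validation_error("stats must be a chunk_stats object")
  }
  if (stats$N < 1L) harf_validation_error("cannot finalize an empty chunk")
  list(mu = stats$mu, sigma2 = pmax(stats$v - stats$mu^2, 0), N = stats$N)
}

#' Combine finalized chunk summaries into a class-conditional Gaussian
#'
#' @param chunks A list of chunk summaries as returned by [chunk_finalize()].
#' @param mode `"paper"` (unweighted means of chunk means and chunk
#'   variances) or `"pooled"` (count-weighted exact batch moments via the law
#'   of total variance).
#' @param variance_floor Minimum admissible combined variance; combined
#'   variances are clamped up to this value so constant features cannot
#'   produce infinite densities.
#' @return A list with per-feature vectors `mu_m` (combined mean) and `mu_v`
#'   (combined variance, floored).
#' @export
#' @examples
#' a <- chunk_finalize(Reduce(chunk_update, list(0, 0), chunk_stats(1)))
#' b <- chunk_finalize(Reduce(chunk_update, list(2, 2), chunk_stats(1)))
#' combine_chunks(list(a, b), mode = "paper")  # mean 1, variance at floor
#' combine_chunks(list(a, b), mode = "pooled") # mean 1, variance 1
combine_chunks <- function(chunks, mode = c("paper", "pooled"),
                           variance_floor = 1e-6) {
  mode <- match.arg(mode)
  if (!is.list(chunks) || length(chunks) == 0L) {
    harf_validation_error("chunks must be a non-empty list of chunk summaries")
  }
  ns <- vapply(chunks, function(ch) as.numeric(ch$N), numeric(1))
  if (any(ns < 1)) {
    harf_validation_error("every chunk must contain at least one sample (N_k >= 1)")
  }
  mus <- do.call(rbind, lapply(chunks, function(ch) as.numeric(ch$mu)))
  s2s <- do.call(rbind, lapply(chunks, function(ch) as.numeric(ch$sigma2)))
  if (mode == "paper") {
    mu_m <- colMeans(mus)
    mu_v <- colMeans(s2s)
  } else {
    n_tot <- sum(ns)
    mu_m <- colSums(mus * ns) / n_tot
    # law of total variance: E[X^2] - E[X]^2 with E[X^2] rebuilt per chunk
    mu_v <- colSums((s2s + mus^2) * ns) / n_tot - mu_m^2
  }
  list(mu_m = unname(mu_m), mu_v = unname(pmax(mu_v, variance_floor)))
}

#' Gaussian log-likelihood of an observation under a class model
#'
#' Evaluates `log p'(F_i = v | C)` for the class-conditional normal with
#' mean `mu_m` and variance `mu_v`, in log space to avoid underflow.
#' Vectorized over features.
#'
#' @param v Observed value(s).
#' @param mu_m Class-conditional mean(s).
#' @param mu_v Class-conditional variance(s); must satisfy
#'   `mu_v >= variance_floor`.
#' @param variance_floor Contract floor below which variances are rejected.
#' @return Numeric vector of log densities.
#' @export
gaussian_log_likelihood <- function(v, mu_m, mu_v, variance_floor = 1e-6) {
  if (any(!is.finite(mu_v)) || any(mu_v < variance_floor)) {
    harf_validation_error(sprintf(
      "variance below the admissible floor %g; finalize models with a variance floor",
      variance_floor
    ))
  }
  -0.5 * (log(2 * pi * mu_v) + (v - mu_m)^2 / mu_v)
}

#' Train one activity class model from a stream of feature vectors
#'
#' Streams the rows of `x` through a chunk accumulator, finalizing every
#' `chunk_size` vectors (the chunk period); the trailing partial chunk, if
#' any, is finalized with its own count and combined unweighted like the
#' others. The retained state during training is one accumulator plus the
#' finalized chunk summaries — raw vectors are never stored.
#'
#' @param x Numeric matrix (rows = feature vectors), data frame, or a list of
#'   equal-length numeric vectors.
#' @param label Class label for the resulting model.
#' @param chunk_size Number of vectors per chunk (the period `t` expressed as
#'   a sample count); default 50.
#' @param prior Prior probability `p(C)` recorded in the model.
#' @param mode Chunk combination mode, see [combine_chunks()].
#' @param variance_floor Minimum admissible per-feature variance.
#' @param feature_names Optional feature names; defaults to column names of
#'   `x` or `F1..Fn`.
#' @param keep_chunks If `TRUE`, retain the per-chunk summaries in the model
#'   for audit.
#' @return An object of class `anb_model`: list with `label`, `prior`,
#'   `feature_names`, `mu_m`, `mu_v`, `j` (chunk count), `mode`,
#'   `variance_floor` and optionally `chunks`.
#' @export
train_class <- function(x, label, chunk_size = 50L, prior = 1,
                        mode = c("paper", "pooled"), variance_floor = 1e-6,
                        feature_names = NULL, keep_chunks = FALSE) {
  mode <- match.arg(mode)
  if (!is.numeric(chunk_size) || chunk_size < 1) {
    harf_validation_error("chunk_size must be >= 1")
  }
  chunk_size <- as.integer(chunk_size)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (is.null(feature_names)) feature_names <- colnames(x)
    rows <- lapply(seq_len(nrow(x)), function(i) as.numeric(x[i, ]))
  } else if (is.list(x)) {
    rows <- lapply(x, as.numeric)
  } else if (is.numeric(x)) {
    rows <- as.list(as.numeric(x))
  } else {
    harf_validation_error("x must be a matrix, data frame, list or numeric vector")
  }
  if (length(rows) == 0L) {
    harf_validation_error("at least one feature vector is required")
  }
  n_feat <- length(rows[[1L]])
  stats <- chunk_stats(n_feat)
  chunks <- list()
  for (i in seq_along(rows)) {
    xi <- rows[[i]]
    if (length(xi) != n_feat) {
      harf_validation_error(sprintf(
        "feature vector %d has length %d, expected %d", i, length(xi), n_feat
      ))
    }
    stats <- chunk_update(stats, xi)
    if (stats$N == chunk_size) {
      chunks[[length(chunks) + 1L]] <- chunk_finalize(stats)
      stats <- chunk_stats(n_feat)
    }
  }
  if (stats$N > 0L) chunks[[length(chunks) + 1L]] <- chunk_finalize(stats)
  comb <- combine_chunks(chunks, mode = mode, variance_floor = variance_floor)
  structure(
    list(
      label = label,
      prior = prior,
      feature_names = feature_names %||% paste0("F", seq_len(n_feat)),
      mu_m = comb$mu_m,
      mu_v = comb$mu_v,
      j = length(chunks),
      mode = mode,
      variance_floor = variance_floor,
      chunks = if (keep_chunks) chunks else NULL
    ),
    class = "anb_model"
  )
}

#' Train a full activity model set from labeled feature vectors
#'
#' @param x Numeric matrix of feature vectors (rows).
#' @param labels Class label per row of `x`.
#' @param chunk_size,mode,variance_floor Passed to [train_class()].
#' @param priors `"empirical"` (class frequencies) or `"uniform"`.
#' @param keep_chunks Retain per-chunk summaries in each model.
#' @return An object of class `anb_model_set`: list with `models` (named list
#'   of `anb_model`), `feature_names`, `mode`, `variance_floor`,
#'   `chunk_size`. Priors sum to one.
#' @export
train_models <- function(x, labels, chunk_size = 50L,
                         mode = c("paper", "pooled"),
                         priors = c("empirical", "uniform"),
                         variance_floor = 1e-6, keep_chunks = FALSE) {
  mode <- match.arg(mode)
  priors <- match.arg(priors)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) harf_validation_error("x must be a matrix of feature vectors")
  if (nrow(x) != length(labels)) {
    harf_validation_error("labels must have one entry per row of x")
  }
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  pr <- if (priors == "uniform") {
    stats::setNames(rep(1 / length(classes), length(classes)), classes)
  } else {
    tab <- table(labels)
    stats::setNames(as.numeric(tab[classes]) / length(labels), classes)
  }
  feature_names <- colnames(x) %||% paste0("F", seq_len(ncol(x)))
  models <- lapply(classes, function(cl) {
    train_class(x[labels == cl, , drop = FALSE], label = cl,
                chunk_size = chunk_size, prior = pr[[cl]], mode = mode,
                variance_floor = variance_floor,
                feature_names = feature_names, keep_chunks = keep_chunks)
  })
  names(models) <- classes
  new_model_set(models, feature_names, mode, variance_floor, chunk_size)
}

new_model_set <- function(models, feature_names, mode, variance_floor,
                          chunk_size) {
  pr_sum <- sum(vapply(models, function(m) m$prior, numeric(1)))
  if (abs(pr_sum - 1) > 1e-9) {
    harf_validation_error(sprintf("model priors sum to %.12f, expected 1", pr_sum))
  }
  structure(
    list(models = models, feature_names = feature_names, mode = mode,
         variance_floor = variance_floor, chunk_size = as.integer(chunk_size)),
    class = "anb_model_set"
  )
}

#' @export
print.anb_model_set <- function(x, ...) {
  cat(sprintf("A-NB model set: %d classes, %d features, mode '%s'\n",
              length(x$models), length(x$feature_names), x$mode))
  for (m in x$models) {
    cat(sprintf("  %-30s prior %.4f  chunks %d\n", m$label, m$prior, m$j))
  }
  invisible(x)
}
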