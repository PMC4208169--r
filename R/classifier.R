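#' Naive Bayes posterior scoring and classification
#'
#' The posterior over candidate activities follows Bayes' rule under the
#' naive conditional-independence assumption: each class accumulates
#' `log p(C) + sum_i log p'(F_i | C)` and the evidence term is handled by
#' log-sum-exp normalization over the candidate set only. All arithmetic is
#' in log space; with a dozen features and small variances the linear-space
#' product underflows.
#'
#' @name nb_classifier
NULL

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

check_feature_vector <- function(models, fv) {
  v <- as.numeric(fv)
  if (length(v) != length(models$feature_names)) {
    harf_compat_error(sprintf(
      "feature vector has %d values but the model schema declares %d features (%s)",
      length(v), length(models$feature_names),
      paste(models$feature_names, collapse = ", ")
    ))
  }
  nm <- names(fv)
  if (!is.null(nm) && !identical(nm, models$feature_names)) {
    harf_compat_error(
      "feature vector names do not match the model schema's feature order"
    )
  }
  if (!all(is.finite(v))) {
    harf_validation_error("feature vector contains non-finite values")
  }
  v
}

#' Score candidate activities for a feature vector
#'
#' @param models An `anb_model_set` (see [train_models()]).
#' @param fv Numeric feature vector; if named, names must match the model
#'   feature order exactly.
#' @param candidates Optional subset of model labels to score; defaults to
#'   all classes. Posteriors are normalized over this set only.
#' @return A data frame with columns `label`, `log_score` (unnormalized
#'   `log p(C) + sum log p'(F_i|C)`) and `posterior` (normalized over the
#'   candidates; sums to one).
#' @export
nb_score <- function(models, fv, candidates = NULL) {
  if (!inherits(models, "anb_model_set")) {
    harf_validation_error("models must be an anb_model_set")
  }
  v <- check_feature_vector(models, fv)
  labels <- names(models$models)
  if (is.null(candidates)) candidates <- labels
  unknown <- setdiff(candidates, labels)
  if (length(unknown) > 0L) {
    harf_compat_error(sprintf(
      "candidate label(s) not in the model set: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  if (length(candidates) == 0L) harf_validation_error("empty candidate set")
  logs <- vapply(candidates, function(lb) {
    m <- models$models[[lb]]
    log(m$prior) +
      sum(gaussian_log_likelihood(v, m$mu_m, m$mu_v, m$variance_floor))
  }, numeric(1))
  post <- exp(logs - logsumexp(logs))
  post <- post / sum(post)
  data.frame(label = candidates, log_score = unname(logs),
             posterior = unname(post), stringsAsFactors = FALSE)
}

#' Classify a feature vector as the maximum-posterior activity
#'
#' Ties on the log score are broken deterministically in favour of the
#' lexicographically smallest label and flagged.
#'
#' @inheritParams nb_score
#' @return A list with `label` (chosen class), `tie` (logical), and `scores`
#'   (the [nb_score()] data frame).
#' @export
nb_classify <- function(models, fv, candidates = NULL) {
  sc <- nb_score(models, fv, candidates)
  best <- max(sc$log_score)
  tied <- sc$label[sc$log_score == best]
  list(label = sort(tied)[1L], tie = length(tied) > 1L, scores = sc)
}
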