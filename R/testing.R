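#' Pseudo-estimated breeding values at a target accuracy
#'
#' Testing is modelled without phenotypes or genomic prediction machinery:
#' an estimated breeding value is the true breeding value plus Gaussian
#' noise, `ebv = tbv + e`, with `e ~ Normal(0, sigma_A^2 (1 - r^2) / r^2)`
#' where `sigma_A^2` is the TBV variance of the candidate group at hand.
#' This calibrates the expected correlation between `ebv` and `tbv` — the
#' accuracy — to `r` within the group where selection acts. Noise is drawn
#' fresh and independently at every invocation, so repeated tests of the
#' same animals are conditionally independent given the TBVs.
#'
#' When the candidate group has zero TBV variance (e.g. a trait with all
#' effects zero) there is no signal to scale the noise against; the EBVs then
#' equal the TBVs and the realised accuracy is undefined (`NA`).
#'
#' @param tbv Named numeric vector of true breeding values (names = ids), or
#'   a `cohort` with TBVs.
#' @param accuracy Target accuracy `r`, in (0, 1].
#' @param stage Optional stage label (`"S0"`, `"S1"`, `"S2"`, ...) recorded
#'   on the result for audit.
#' @return A tibble of class `test_result` with columns `id`, `tbv`, `ebv`,
#'   and attributes `accuracy` (target), `realized_accuracy` and `stage`.
#' @export
#' @examples
#' set.seed(1)
#' res <- pseudo_ebv(rnorm(500), accuracy = 0.7)
#' attr(res, "realized_accuracy")
pseudo_ebv <- function(tbv, accuracy, stage = NA_character_) {
  if (inherits(tbv, "cohort")) {
    if (is.null(tbv$tbv)) abort("cohort has no TBVs; call add_tbv() first")
    tbv <- setNames(tbv$tbv, tbv$id)
  }
  accuracy <- .check_prob(accuracy, "accuracy")
  ids <- names(tbv) %||% as.character(seq_along(tbv))
  sigma2 <- var(tbv)
  noise_sd <- if (accuracy == 1 || sigma2 == 0) {
    0
  } else {
    sqrt(sigma2 * (1 - accuracy^2) / accuracy^2)
  }
  ebv <- tbv + rnorm(length(tbv), 0, noise_sd)
  realized <- if (sigma2 > 0 && length(tbv) > 2) {
    suppressWarnings(cor(tbv, ebv))
  } else {
    NA_real_
  }
  out <- tibble(id = ids, tbv = unname(tbv), ebv = unname(ebv))
  attr(out, "accuracy") <- accuracy
  attr(out, "realized_accuracy") <- realized
  attr(out, "stage") <- stage
  class(out) <- c("test_result", class(out))
  out
}

#' Accuracy of a sire progeny test
#'
#' Classical progeny-test accuracy for a sire evaluated on the mean of `n`
#' half-sib progeny: `r = sqrt(n / (n + (4 - h2) / h2))`. Strictly increasing
#' in both arguments, tending to 1 as `n` grows.
#'
#' @param n_progeny Number of progeny per candidate (>= 1). Vectorised.
#' @param h2 Trait heritability in (0, 1].
#' @return Accuracy in (0, 1).
#' @export
#' @examples
#' progeny_test_accuracy(100, 0.25) # sqrt(100/115)
progeny_test_accuracy <- function(n_progeny, h2 = 0.25) {
  if (any(n_progeny < 1)) abort("`n_progeny` must be >= 1")
  h2 <- .check_prob(h2, "h2")
  sqrt(n_progeny / (n_progeny + (4 - h2) / h2))
}

#' Select the top candidates of a test
#'
#' Returns the ids of the `k` candidates with the largest estimated breeding
#' values, in descending EBV order. Ties are broken by ascending id, a
#' deterministic, seed-independent rule.
#'
#' @param test_result A `test_result` from [pseudo_ebv()] (any data frame
#'   with `id` and `ebv` columns works).
#' @param k Number of candidates to keep.
#' @return Character vector of `k` ids.
#' @export
select_top <- function(test_result, k) {
  k <- .check_count(k, "k")
  if (k > nrow(test_result)) {
    abort(sprintf("k = %d exceeds the %d candidates", k, nrow(test_result)))
  }
  ord <- order(-test_result$ebv, test_result$id)
  test_result$id[ord[seq_len(k)]]
}

# index form used by the engines (same ordering rule, on positions)
.top_idx <- function(ebv, id, k) {
  ord <- order(-ebv, id)
  ord[seq_len(k)]
}

#' Selection intensity of truncation selection
#'
#' Expected mean, in standard deviations, of the selected upper fraction `p`
#' of a standard normal distribution: `i = dnorm(z_p) / p` with `z_p` the
#' upper-`p` quantile. `i(1) = 0`; `i` is strictly decreasing in `p`.
#' Selecting the top 20% gives `i = 1.4`; the top 0.2% gives `i = 3.2`.
#'
#' @param p Selected proportion(s), each in (0, 1]. Vectorised.
#' @return Selection intensity (standard deviations).
#' @export
#' @examples
#' round(selection_intensity(c(0.2, 0.04, 0.002, 0.0004)), 1)
selection_intensity <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("`p` must be in (0, 1]")
  }
  ifelse(p == 1, 0, dnorm(qnorm(1 - p)) / p)
}

#' Write a test result to CSV for audit
#'
#' @param test_result A `test_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_test_result <- function(test_result, path) {
  df <- as.data.frame(test_result)
  df$stage <- attr(test_result, "stage")
  df$target_accuracy <- attr(test_result, "accuracy")
  df$realized_accuracy <- attr(test_result, "realized_accuracy")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
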