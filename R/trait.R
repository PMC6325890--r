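#' Sample an additive trait architecture
#'
#' Causal loci are sampled uniformly without replacement, a fixed number per
#' chromosome, and each receives an allele-substitution effect drawn from
#' Normal(0, `effect_sd`). By default `effect_sd = 1 / sqrt(total causal)`,
#' so a 10 x 1,000 architecture has effect standard deviation 0.01. The trait
#' is purely additive: no dominance, no epistasis.
#'
#' @param panel A `hap_panel` defining the available loci.
#' @param n_causal_per_chromosome Causal loci per chromosome; default all
#'   loci of the panel.
#' @param effect_sd Standard deviation of allele-substitution effects;
#'   default `1 / sqrt(n_causal_total)`.
#' @return An object of class `trait_arch`: per-chromosome causal locus
#'   indices (sorted, 1-based within chromosome) and effects.
#' @export
#' @examples
#' set.seed(1)
#' p <- sim_haplotype_panel(10, 2, 20)
#' arch <- sim_trait_architecture(p, n_causal_per_chromosome = 5)
#' arch
sim_trait_architecture <- function(panel, n_causal_per_chromosome = NULL,
                                   effect_sd = NULL) {
  dims <- panel_dim(panel)
  n_causal_per_chromosome <- n_causal_per_chromosome %||% min(dims$n_loci)
  n_causal_per_chromosome <- .check_count(n_causal_per_chromosome, "n_causal_per_chromosome")
  if (any(dims$n_loci < n_causal_per_chromosome)) {
    abort(sprintf(
      "panel has only %d loci on its smallest chromosome; %d causal requested",
      min(dims$n_loci), n_causal_per_chromosome
    ))
  }
  total <- n_causal_per_chromosome * dims$n_chromosomes
  effect_sd <- effect_sd %||% (1 / sqrt(total))
  causal <- lapply(dims$n_loci, function(L) {
    sort(sample.int(L, n_causal_per_chromosome))
  })
  effects <- lapply(seq_len(dims$n_chromosomes), function(chr) {
    rnorm(n_causal_per_chromosome, 0, effect_sd)
  })
  names(effects) <- names(causal)
  structure(
    list(
      causal = causal, effects = effects,
      effect_sd = effect_sd, n_causal = total
    ),
    class = "trait_arch"
  )
}

#' @export
print.trait_arch <- function(x, ...) {
  cat(sprintf(
    "<trait_arch> %d causal loci on %d chromosomes, effect sd %.4g\n",
    x$n_causal, length(x$causal), x$effect_sd
  ))
  invisible(x)
}

#' True breeding values of a cohort
#'
#' The true breeding value (TBV) of an individual is the sum over causal loci
#' of the allele-substitution effect times the count of the "1" allele
#' (0, 1 or 2). `true_breeding_values()` computes the whole cohort at once;
#' `true_breeding_value()` is the single-individual form; `add_tbv()` returns
#' the cohort with its `tbv` field populated (and is idempotent).
#'
#' @param cohort A `cohort`.
#' @param architecture A `trait_arch`.
#' @return Numeric vector of TBVs, named by individual id.
#' @export
true_breeding_values <- function(cohort, architecture) {
  n <- cohort_size(cohort)
  tbv <- numeric(n)
  for (chr in seq_along(cohort$maternal)) {
    idx <- architecture$causal[[chr]]
    eff <- architecture$effects[[chr]]
    geno <- cohort$maternal[[chr]][, idx, drop = FALSE] +
      cohort$paternal[[chr]][, idx, drop = FALSE]
    tbv <- tbv + drop(geno %*% eff)
  }
  setNames(tbv, cohort$id)
}

#' @rdname true_breeding_values
#' @param individual A single-individual `cohort`.
#' @export
true_breeding_value <- function(individual, architecture) {
  unname(true_breeding_values(individual, architecture)[1])
}

#' @rdname true_breeding_values
#' @export
add_tbv <- function(cohort, architecture) {
  if (is.null(cohort$tbv)) {
    cohort$tbv <- unname(true_breeding_values(cohort, architecture))
  }
  cohort
}

#' Genic variance at causal loci
#'
#' Sum over causal loci of `2 p q e^2`, the additive variance expected under
#' Hardy-Weinberg at current allele frequencies. A diagnostic for the erosion
#' of variance under drift and truncation selection.
#'
#' @inheritParams true_breeding_values
#' @return A single number (trait-unit variance).
#' @export
genic_variance <- function(cohort, architecture) {
  n2 <- 2 * cohort_size(cohort)
  v <- 0
  for (chr in seq_along(cohort$maternal)) {
    idx <- architecture$causal[[chr]]
    p <- (colSums(cohort$maternal[[chr]][, idx, drop = FALSE]) +
      colSums(cohort$paternal[[chr]][, idx, drop = FALSE])) / n2
    v <- v + sum(2 * p * (1 - p) * architecture$effects[[chr]]^2)
  }
  v
}

#' Base-population scaling constants
#'
#' Mean and standard deviation (denominator `n - 1`) of a cohort's true
#' breeding values, used to express all merit trajectories in units of base
#' genetic standard deviations. Errors when the cohort's TBV variance is
#' zero, since scaling would then be undefined.
#'
#' @param x A `cohort` with TBVs, or a numeric vector of TBVs.
#' @param architecture A `trait_arch`, needed when `x` is a cohort without
#'   cached TBVs.
#' @return An object of class `base_scale` with fields `mean` and `sd`.
#' @export
base_scale <- function(x, architecture = NULL) {
  tbv <- if (inherits(x, "cohort")) {
    if (is.null(x$tbv)) {
      if (is.null(architecture)) abort("cohort has no TBVs; supply `architecture`")
      unname(true_breeding_values(x, architecture))
    } else {
      x$tbv
    }
  } else {
    as.numeric(x)
  }
  s <- sd(tbv)
  if (!is.finite(s) || s == 0) {
    abort("base cohort has zero TBV variance; scaling is undefined")
  }
  structure(list(mean = mean(tbv), sd = s), class = "base_scale")
}

#' @export
print.base_scale <- function(x, ...) {
  cat(sprintf("<base_scale> mean %.4f, sd %.4f\n", x$mean, x$sd))
  invisible(x)
}

#' Export or import a trait architecture as a plain-text table
#'
#' Three tab-separated columns: chromosome, locus index (1-based within
#' chromosome), effect. Round-trips exactly for replicate reproducibility.
#'
#' @param architecture A `trait_arch`.
#' @param path File path.
#' @return `write_architecture()`: `path` invisibly;
#'   `read_architecture()`: a `trait_arch`.
#' @export
write_architecture <- function(architecture, path) {
  df <- data.frame(
    chrom = rep(
      names(architecture$causal) %||% paste0("chr", seq_along(architecture$causal)),
      lengths(architecture$causal)
    ),
    locus = unlist(architecture$causal),
    effect = unlist(architecture$effects)
  )
  write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  chrs <- unique(df$chrom)
  causal <- lapply(chrs, function(ch) df$locus[df$chrom == ch])
  effects <- lapply(chrs, function(ch) df$effect[df$chrom == ch])
  names(causal) <- names(effects) <- chrs
  total <- sum(lengths(causal))
  structure(
    list(
      causal = causal, effects = effects,
      effect_sd = 1 / sqrt(total), n_causal = total
    ),
    class = "trait_arch"
  )
}
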