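# Independent oracles and small fixtures used across the suite. These are
# deliberately naive re-implementations (plain loops, sort()) kept separate
# from the package's code paths.

# brute-force TBV: loop over individuals and causal loci
naive_tbv <- function(cohort, arch) {
  n <- cohort_size(cohort)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (chr in seq_along(cohort$maternal)) {
      idx <- arch$causal[[chr]]
      eff <- arch$effects[[chr]]
      for (j in seq_along(idx)) {
        count <- cohort$maternal[[chr]][i, idx[j]] + cohort$paternal[[chr]][i, idx[j]]
        s <- s + eff[j] * count
      }
    }
    out[i] <- s
  }
  out
}

# selection intensity by numerical quadrature: mean of the upper-p tail
intensity_quadrature <- function(p) {
  z <- qnorm(1 - p)
  stats::integrate(function(x) x * dnorm(x), lower = z, upper = Inf,
    rel.tol = 1e-10
  )$value / p
}

# naive multi-stage donor pipeline on a TBV vector: at each stage add
# Normal noise scaled to the current group's variance for the stage's
# accuracy, sort, keep the top k; returns the mean TBV of the final keep
naive_donor_mean <- function(tbv, accuracies, keeps) {
  g <- tbv
  for (s in seq_along(accuracies)) {
    r <- accuracies[s]
    noise_sd <- if (r == 1) 0 else sqrt(var(g) * (1 - r^2) / r^2)
    score <- g + rnorm(length(g), 0, noise_sd)
    g <- g[order(score, decreasing = TRUE)][seq_len(keeps[s])]
  }
  mean(g)
}

# a tiny panel + architecture + founder cohort for structural tests
tiny_world <- function(n_hap = 20, n_chr = 2, n_loci = 30, n_ind = 10,
                       seed = 42) {
  set.seed(seed)
  panel <- sim_haplotype_panel(n_hap, n_chr, n_loci)
  arch <- sim_trait_architecture(panel)
  cohort <- add_tbv(sample_founders(panel, n_ind), arch)
  list(panel = panel, arch = arch, cohort = cohort)
}

# a single-locus-per-chromosome "hand" cohort with known genotypes:
# geno is a list per chromosome of cbind(maternal, paternal) allele columns
hand_cohort <- function(maternal, paternal, sex = NULL, generation = 0L) {
  n <- nrow(maternal[[1]])
  new_cohort(
    maternal = maternal, paternal = paternal,
    sex = sex %||% rep_len(c("male", "female"), n),
    id = sprintf("H%d", seq_len(n)),
    generation = generation
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# heterozygous single parent: hap1 all 0, hap2 all 1 on each chromosome
het_parent <- function(n_chr = 1, n_loci = 100, sex = "male") {
  new_cohort(
    maternal = replicate(n_chr, matrix(0L, 1, n_loci), simplify = FALSE),
    paternal = replicate(n_chr, matrix(1L, 1, n_loci), simplify = FALSE),
    sex = sex, id = "het1", generation = 0L
  )
}

# a fast nucleus configuration for properties that need full runs
fast_run <- function(accuracy = 0.5, seed = 1, cohort_size = 300,
                     first = -8L, last = 12L, n_sires = 15L,
                     n_chr = 3, n_loci = 60) {
  set.seed(seed)
  panel <- sim_haplotype_panel(60, n_chr, n_loci)
  arch <- sim_trait_architecture(panel)
  run_nucleus(panel, arch,
    cohort_size = cohort_size, n_sires = n_sires,
    genomic_accuracy = accuracy, first_generation = first,
    last_generation = last, base_generation = 0L
  )
}
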