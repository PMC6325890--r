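test_that("the standard architecture has effect sd 1/sqrt(n) = 0.01", {
  set.seed(1)
  panel <- sim_haplotype_panel(50, 10, 1000)
  arch <- sim_trait_architecture(panel, 1000)
  expect_equal(arch$effect_sd, 0.01)
  expect_equal(arch$n_causal, 10000L)
  # empirical sd of the 10,000 sampled effects within chi-square bounds
  s2 <- var(unlist(arch$effects))
  bounds <- 0.01^2 * stats::qchisq(c(0.0005, 0.9995), 9999) / 9999
  expect_gt(s2, bounds[1])
  expect_lt(s2, bounds[2])
})

test_that("requesting all loci makes the causal set exhaustive", {
  w <- tiny_world(n_loci = 15)
  arch <- sim_trait_architecture(w$panel) # default: all loci
  expect_equal(arch$causal, list(chr1 = 1:15, chr2 = 1:15), ignore_attr = TRUE)
  expect_error(
    sim_trait_architecture(w$panel, 16),
    "only 15 loci"
  )
})

test_that("TBV matches the brute-force per-locus oracle exactly", {
  w <- tiny_world(n_ind = 8)
  expect_equal(unname(true_breeding_values(w$cohort, w$arch)), naive_tbv(w$cohort, w$arch))
})

test_that("degenerate genotypes give the forced TBVs", {
  arch <- structure(
    list(
      causal = list(chr1 = 1L), effects = list(chr1 = 0.37),
      effect_sd = 1, n_causal = 1L
    ),
    class = "trait_arch"
  )
  zero <- hand_cohort(list(chr1 = matrix(0L, 1, 1)), list(chr1 = matrix(0L, 1, 1)))
  het <- hand_cohort(list(chr1 = matrix(0L, 1, 1)), list(chr1 = matrix(1L, 1, 1)))
  hom <- hand_cohort(list(chr1 = matrix(1L, 1, 1)), list(chr1 = matrix(1L, 1, 1)))
  expect_equal(true_breeding_value(zero, arch), 0)
  expect_equal(true_breeding_value(het, arch), 0.37)
  expect_equal(true_breeding_value(hom, arch), 0.74)
})

test_that("base_scale gives sample statistics and rejects zero variance", {
  expect_error(base_scale(rep(1.5, 10)), "zero TBV variance")
  bs <- base_scale(c(-1, 1))
  expect_equal(bs$mean, 0)
  expect_equal(bs$sd, sqrt(2))
  # self-standardization
  w <- tiny_world(n_ind = 20)
  bs2 <- base_scale(w$cohort)
  z <- standardize(w$cohort$tbv, bs2)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  # identity scale is idempotent
  ident <- structure(list(mean = 0, sd = 1), class = "base_scale")
  expect_equal(standardize(standardize(z, ident), ident), z)
})

test_that("TBV decomposes additively over parental gamete origins", {
  w <- tiny_world(n_ind = 6)
  tbv <- true_breeding_values(w$cohort, w$arch)
  # maternal-only and paternal-only half-genomes sum to the full TBV
  half <- function(side) {
    ghost <- w$cohort
    other <- setdiff(c("maternal", "paternal"), side)
    ghost[[other]] <- lapply(ghost[[other]], function(m) m * 0L)
    true_breeding_values(ghost, w$arch)
  }
  expect_equal(half("maternal") + half("paternal"), tbv)
})

test_that("architecture tables round-trip through plain text", {
  w <- tiny_world()
  f <- tempfile(fileext = ".tsv")
  write_architecture(w$arch, f)
  back <- read_architecture(f)
  expect_equal(back$causal, w$arch$causal, ignore_attr = TRUE)
  expect_equal(back$effects, w$arch$effects, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(
    unname(true_breeding_values(w$cohort, back)),
    unname(true_breeding_values(w$cohort, w$arch))
  )
})

test_that("mean TBV is a martingale under random mating without selection", {
  # no selection: every male is a potential sire
  set.seed(10)
  changes <- replicate(40, {
    panel <- sim_haplotype_panel(30, 1, 40)
    arch <- sim_trait_architecture(panel)
    cohort <- add_tbv(sample_founders(panel, 60, generation = 0L), arch)
    start <- mean(cohort$tbv)
    for (g in 1:4) {
      cohort <- advance_generation(
        cohort, arch, panel$map, panel$chromosome_length,
        n_sires = 30L, genomic_accuracy = 0.5
      )$cohort
    }
    mean(cohort$tbv) - start
  })
  se <- sd(changes) / sqrt(length(changes))
  expect_lt(abs(mean(changes)), 4 * se)
})

test_that("genic variance erodes in expectation under selection and drift", {
  set.seed(11)
  ratio <- replicate(30, {
    panel <- sim_haplotype_panel(30, 1, 50)
    arch <- sim_trait_architecture(panel)
    cohort <- add_tbv(sample_founders(panel, 100, generation = 0L), arch)
    v0 <- genic_variance(cohort, arch)
    for (g in 1:10) {
      cohort <- advance_generation(
        cohort, arch, panel$map, panel$chromosome_length,
        n_sires = 5L, genomic_accuracy = 0.9
      )$cohort
    }
    genic_variance(cohort, arch) / v0
  })
  expect_lt(mean(ratio), 1)
})
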