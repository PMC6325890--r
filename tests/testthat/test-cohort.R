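test_that("founders from a single-haplotype panel are fully homozygous", {
  # a degenerate panel (one haplotype) cannot segregate, so build it directly
  hap <- matrix(c(0L, 1L, 0L, 1L, 1L), nrow = 1)
  panel <- surrosire:::new_hap_panel(
    alleles = list(chr1 = hap), map = list(chr1 = seq(0.1, 0.9, length.out = 5)),
    chromosome_length = 1
  )
  set.seed(1)
  f <- sample_founders(panel, 4)
  expect_identical(f$maternal$chr1, f$paternal$chr1)
  expect_true(all(f$maternal$chr1 == rep(hap, each = 4)))
})

test_that("founder haplotype origins are uniform over the panel", {
  # 2-haplotype panel: hap1 all 0, hap2 all 1 -> origin is readable per locus
  panel <- surrosire:::new_hap_panel(
    alleles = list(chr1 = rbind(rep(0L, 10), rep(1L, 10)),
                   chr2 = rbind(rep(0L, 10), rep(1L, 10))),
    map = list(chr1 = seq(0.05, 0.95, length.out = 10),
               chr2 = seq(0.05, 0.95, length.out = 10)),
    chromosome_length = 1
  )
  set.seed(2)
  n <- 10000
  f <- sample_founders(panel, n)
  for (chr in c("chr1", "chr2")) {
    for (side in c("maternal", "paternal")) {
      p_hat <- mean(f[[side]][[chr]][, 1] == 1L)
      expect_lt(abs(p_hat - 0.5), 4 * sqrt(0.25 / n)) # binomial 4-sigma
    }
  }
})

test_that("founder sampling is deterministic given the seed", {
  w <- tiny_world()
  set.seed(9)
  a <- sample_founder(w$panel, "x", "male")
  set.seed(9)
  b <- sample_founder(w$panel, "x", "male")
  expect_identical(a$maternal, b$maternal)
  expect_identical(a$paternal, b$paternal)
})

test_that("zero-length chromosomes never recombine", {
  parent <- new_cohort(
    maternal = list(chr1 = matrix(0L, 1, 1)),
    paternal = list(chr1 = matrix(1L, 1, 1)),
    sex = "male", id = "p", generation = 0L
  )
  set.seed(3)
  g <- replicate(200, make_gamete(parent, map = list(chr1 = 0), chromosome_length = 0)$chr1)
  expect_true(all(g %in% c(0L, 1L))) # always an unmodified parental haplotype
  expect_gt(mean(g), 0.3) # both haplotypes occur
  expect_lt(mean(g), 0.7)
})

test_that("crossover counts are Poisson with mean = chromosome length", {
  # dense equally spaced loci on a het parent make crossovers observable as
  # strand switches; with 1,000 loci the chance of an unobserved double
  # crossover within a gap is negligible
  n_loci <- 1000
  pos <- seq(0.0005, 0.9995, length.out = n_loci)
  M <- matrix(0L, 1, n_loci)
  P <- matrix(1L, 1, n_loci)
  set.seed(4)
  n <- 1e5
  gam <- surrosire:::.meiosis(M, P, pos, 1, rep(1L, n))
  switches <- rowSums(gam[, -1] != gam[, -n_loci])
  span <- pos[n_loci] - pos[1]
  expect_lt(abs(mean(switches) - span), 4 * sqrt(1 / n)) # mean 1 Morgan
  dispersion <- var(switches) / mean(switches)
  expect_gt(dispersion, 0.9)
  expect_lt(dispersion, 1.1)
})

test_that("allele transmission from a heterozygote is Mendelian", {
  n_loci <- 50
  pos <- seq(0.01, 0.99, length.out = n_loci)
  M <- matrix(0L, 1, n_loci)
  P <- matrix(1L, 1, n_loci)
  set.seed(5)
  n <- 2e4
  gam <- surrosire:::.meiosis(M, P, pos, 1, rep(1L, n))
  freq <- colMeans(gam)
  expect_true(all(abs(freq - 0.5) < 4 * sqrt(0.25 / n)))

  # the pure-R reference implementation transmits identically (within
  # Monte-Carlo error), cross-checking the compiled kernel
  gam_r <- surrosire:::.meiosis_r(M, P, pos, 1, rep(1L, n))
  freq_r <- colMeans(gam_r)
  expect_true(all(abs(freq_r - 0.5) < 4 * sqrt(0.25 / n)))
  expect_lt(abs(mean(gam) - mean(gam_r)), 4 * sqrt(0.5 / (n * n_loci)))
})

test_that("gamete alleles always come from the parent", {
  w <- tiny_world()
  parent <- cohort_subset(w$cohort, 1)
  set.seed(6)
  for (i in 1:5) {
    g <- make_gamete(parent, w$panel$map, w$panel$chromosome_length)
    for (chr in seq_along(g)) {
      from_parent <- g[[chr]] == parent$maternal[[chr]][1, ] |
        g[[chr]] == parent$paternal[[chr]][1, ]
      expect_true(all(from_parent))
    }
  }
})

test_that("offspring of a pair average to the mid-parent TBV", {
  w <- tiny_world(n_hap = 30, n_loci = 50, n_ind = 4)
  dam <- cohort_subset(w$cohort, which(w$cohort$sex == "female")[1])
  sire <- cohort_subset(w$cohort, which(w$cohort$sex == "male")[1])
  mid <- (dam$tbv + sire$tbv) / 2
  set.seed(7)
  off <- mate(dam, sire, 4000, w$panel$map, w$panel$chromosome_length)
  off <- add_tbv(off, w$arch)
  se <- sd(off$tbv) / sqrt(4000)
  expect_lt(abs(mean(off$tbv) - mid), 4 * se)
})

test_that("the alternating sex policy yields one male and one female per pair", {
  w <- tiny_world()
  dam <- cohort_subset(w$cohort, which(w$cohort$sex == "female")[1])
  sire <- cohort_subset(w$cohort, which(w$cohort$sex == "male")[1])
  off <- mate(dam, sire, 2, w$panel$map, w$panel$chromosome_length)
  expect_equal(off$sex, c("male", "female"))
  expect_error(
    mate(sire, dam, 2, w$panel$map, w$panel$chromosome_length),
    "must be female"
  )
})

test_that("identical homozygous parents breed true", {
  n_loci <- 20
  geno <- matrix(rep(c(0L, 1L), each = 10), 1, n_loci)
  mk <- function(sex, id) {
    new_cohort(
      maternal = list(chr1 = geno), paternal = list(chr1 = geno),
      sex = sex, id = id, generation = 0L
    )
  }
  dam <- mk("female", "d")
  sire <- mk("male", "s")
  arch <- structure(
    list(
      causal = list(chr1 = 1:n_loci),
      effects = list(chr1 = rnorm(n_loci, 0, 0.1)),
      effect_sd = 0.1, n_causal = n_loci
    ),
    class = "trait_arch"
  )
  set.seed(8)
  off <- add_tbv(
    mate(dam, sire, 50, list(chr1 = seq(0.1, 0.9, length.out = n_loci)), 1),
    arch
  )
  expect_true(all(off$tbv == true_breeding_value(mk("male", "p"), arch)))
})
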