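test_that("generated panels satisfy dimension and segregation invariants", {
  set.seed(1)
  panel <- sim_haplotype_panel(40, 3, 100)
  expect_no_error(validate_hap_panel(panel))
  d <- panel_dim(panel)
  expect_equal(d$n_haplotypes, 40)
  expect_equal(d$n_chromosomes, 3)
  expect_equal(unname(d$n_loci), rep(100, 3))
  expect_equal(sum(d$n_loci), 300)
  for (chr in 1:3) {
    cs <- colSums(panel$alleles[[chr]])
    expect_true(all(cs > 0 & cs < 40)) # every locus segregates
    expect_true(all(diff(panel$map[[chr]]) > 0))
    expect_true(all(panel$map[[chr]] >= 0 & panel$map[[chr]] <= 1))
  }
})

test_that("a 2-haplotype single-locus panel is forced to one 0 and one 1", {
  set.seed(7)
  panel <- sim_haplotype_panel(2, 1, 1, frequency_model = "uniform")
  expect_equal(sort(as.vector(panel$alleles[[1]])), c(0L, 1L))
})

test_that("panel generation is deterministic given the seed", {
  set.seed(11)
  p1 <- sim_haplotype_panel(30, 2, 40)
  set.seed(11)
  p2 <- sim_haplotype_panel(30, 2, 40)
  expect_identical(p1$alleles, p2$alleles)
  expect_identical(p1$map, p2$map)
})

test_that("neutral-sfs allele frequencies follow the 1/x spectrum", {
  set.seed(3)
  n_hap <- 200
  panel <- sim_haplotype_panel(n_hap, 1, 20000, frequency_model = "neutral-sfs")
  freq <- colSums(panel$alleles[[1]]) / n_hap

  # The sampled *latent* frequency is 1/x on [lo, hi]; the realised panel
  # frequency is its binomial draw conditioned on segregating. Compare the
  # empirical distribution with the analytic expectation integrated over
  # the spectrum (Monte Carlo on the latent draw, huge n, no panel code).
  lo <- 1 / (2 * n_hap)
  hi <- 1 - lo
  set.seed(4)
  latent <- lo * (hi / lo)^runif(4e5)
  ref <- rbinom(length(latent), n_hap, latent)
  ref <- ref[ref > 0 & ref < n_hap] / n_hap

  breaks <- c(0, 0.01, 0.05, 0.1, 0.25, 0.5, 1)
  emp <- as.vector(table(cut(freq, breaks))) / length(freq)
  exp_p <- as.vector(table(cut(ref, breaks))) / length(ref)
  # each bin within 4 binomial standard errors of the reference proportion
  se <- sqrt(exp_p * (1 - exp_p) / length(freq))
  expect_true(all(abs(emp - exp_p) < 4 * se + 1e-9))

  # and the spectrum density itself is what the generator advertises
  dens <- frequency_spectrum_density(c(0.01, 0.1, 0.4), n_hap, "neutral-sfs")
  expect_equal(dens, 1 / (c(0.01, 0.1, 0.4) * log(hi / lo)))
})

test_that("haplotype matrix files round-trip exactly", {
  set.seed(5)
  panel <- sim_haplotype_panel(12, 2, 25)
  hp <- tempfile(fileext = ".txt")
  mp <- tempfile(fileext = ".map")
  write_haplotypes(panel, hp, mp)
  back <- import_haplotypes(hp, "matrix", map = mp)
  expect_equal(unname(lapply(back$alleles, unname)),
    unname(lapply(panel$alleles, unname)),
    ignore_attr = TRUE
  )
  expect_equal(unname(unlist(back$map)), unname(unlist(panel$map)), tolerance = 1e-12)
  expect_equal(attr(back, "dropped_loci"), 0L)
})

test_that("monomorphic columns are dropped on import with a logged count", {
  hp <- tempfile(fileext = ".txt")
  mp <- tempfile(fileext = ".map")
  writeLines(c(
    "chr1_1 chr1_2 chr1_3",
    "0 1 1",
    "1 1 0",
    "0 1 1"
  ), hp)
  writeLines(c(
    "chrom\tid\tcM",
    "chr1\tchr1_1\t10",
    "chr1\tchr1_2\t20",
    "chr1\tchr1_3\t30"
  ), mp)
  expect_message(
    panel <- import_haplotypes(hp, "matrix", map = mp),
    "dropped 1 non-segregating"
  )
  expect_equal(attr(panel, "dropped_loci"), 1L)
  expect_equal(ncol(panel$alleles[[1]]), 2L)
  expect_equal(panel$map[[1]], c(10, 30) / 100)
})

test_that("phased VCF import reconstructs haplotypes and flags unphased sites", {
  skip_if_not_installed("vcfR")
  vcf <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2"
  )
  body <- c(
    "1\t1000000\t.\tA\tC\t.\tPASS\t.\tGT\t0|1\t1|1",
    "1\t2000000\t.\tG\tT\t.\tPASS\t.\tGT\t1|0\t0|0",
    "2\t1500000\t.\tT\tA\t.\tPASS\t.\tGT\t0|0\t1|0"
  )
  writeLines(c(header, body), vcf)
  panel <- import_haplotypes(vcf, "vcf")
  # haplotype rows: S1a, S1b, S2a, S2b
  expect_equal(unname(panel$alleles[["1"]][, 1]), c(0L, 1L, 1L, 1L))
  expect_equal(unname(panel$alleles[["1"]][, 2]), c(1L, 0L, 0L, 0L))
  expect_equal(unname(panel$alleles[["2"]][, 1]), c(0L, 0L, 1L, 0L))
  expect_equal(panel$map[["1"]], c(1e6, 2e6) * 1e-8) # 1 cM/Mb

  writeLines(c(header, sub("0\\|1", "0/1", body[1]), body[2:3]), vcf)
  expect_error(
    import_haplotypes(vcf, "vcf"),
    "unphased.*1:1000000.*S1"
  )
})
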