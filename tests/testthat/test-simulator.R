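noise_free <- function(n_loci, seed = NULL, maf = c(0.05, 0.5)) {
  simulation_config(n_loci = n_loci, maf_sampler = maf,
                    error_rate = 0, nocall_rate = 0, cn_abnormal_rate = 0,
                    seed = seed)
}

test_that("config validation rejects impossible rate combinations", {
  expect_error(simulation_config(n_loci = 0), "positive")
  expect_error(simulation_config(error_rate = -0.1), "\\[0, 1\\)")
  expect_error(simulation_config(error_rate = 0.5, nocall_rate = 0.5), "< 1")
  expect_error(simulation_config(maf_sampler = c(0.6, 0.7)), "within \\[0, 0.5\\]")
})

test_that("allele-frequency draws are seeded, bounded and have the uniform mean", {
  cfg <- simulation_config(n_loci = 1e5, seed = 3)
  q1 <- draw_allele_frequencies(cfg)
  q2 <- draw_allele_frequencies(cfg)
  expect_identical(q1, q2)
  expect_true(all(q1 >= 0.05 & q1 <= 0.5))
  # mean of U(0.05, 0.5) is 0.275, sd 0.45/sqrt(12)
  se <- (0.45 / sqrt(12)) / sqrt(1e5)
  expect_lt(abs(mean(q1) - 0.275), 3 * se)
  # degenerate point-mass sampler
  point <- draw_allele_frequencies(simulation_config(n_loci = 10, maf_sampler = c(0.5, 0.5)))
  expect_equal(point, rep(0.5, 10))
})

test_that("founders follow Hardy-Weinberg genotype proportions", {
  cfg <- noise_free(20000, seed = 4, maf = c(0.5, 0.5))
  f <- simulate_founder(draw_allele_frequencies(cfg), cfg)
  expect_s3_class(f, "genotype_table")
  het <- substr(f$call, 1, 1) != substr(f$call, 2, 2)
  se <- sqrt(0.5 * 0.5 / 20000)
  expect_lt(abs(mean(het) - 0.5), 3 * se)
  # q = 0 everywhere: every call is the major homozygote
  cfg0 <- noise_free(500, seed = 5, maf = c(0, 0))
  f0 <- simulate_founder(draw_allele_frequencies(cfg0), cfg0)
  dos0 <- attr(f0, "true_dosage")
  expect_true(all(dos0 == 0L))
  expect_true(all(substr(f0$call, 1, 1) == substr(f0$call, 2, 2)))
  # determinism
  expect_identical(
    as.data.frame(simulate_founder(draw_allele_frequencies(cfg), cfg)),
    as.data.frame(simulate_founder(draw_allele_frequencies(cfg), cfg))
  )
})

test_that("Mendelian transmission forces and mixes genotypes per the Punnett square", {
  cfg <- noise_free(30000, seed = 6, maf = c(0.5, 0.5))
  set.seed(6)
  q <- rep(0.5, 30000)
  mother <- simulate_founder(q, simulation_config(n_loci = 30000, maf_sampler = c(0.5, 0.5),
                                                  error_rate = 0, nocall_rate = 0,
                                                  cn_abnormal_rate = 0))
  father <- simulate_relative("unrelated", list(mother), config = noise_free(30000))
  child <- simulate_child(mother, father, noise_free(30000))
  dm <- attr(mother, "true_dosage"); df <- attr(father, "true_dosage")
  dc <- attr(child, "true_dosage")
  # forced transmissions
  expect_true(all(dc[dm == 0 & df == 0] == 0L))
  expect_true(all(dc[dm == 2 & df == 2] == 2L))
  expect_true(all(dc[dm == 0 & df == 2] == 1L))
  # both parents heterozygous: 1/4, 1/2, 1/4
  hh <- dc[dm == 1 & df == 1]
  n <- length(hh)
  expect_gt(n, 4000)
  expect_lt(abs(mean(hh == 0) - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  expect_lt(abs(mean(hh == 1) - 0.5), 3 * sqrt(0.25 / n))
  expect_lt(abs(mean(hh == 2) - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("child simulation refuses mismatched locus panels", {
  cfg <- noise_free(100, seed = 8)
  a <- simulate_founder(draw_allele_frequencies(cfg), cfg)
  cfg2 <- noise_free(100, seed = 9)
  b <- simulate_founder(draw_allele_frequencies(cfg2), cfg2)
  # same ids but different alleles is fine to merge; different lengths are not
  cfg3 <- noise_free(50, seed = 8)
  c3 <- simulate_founder(draw_allele_frequencies(cfg3), cfg3)
  expect_error(simulate_child(a, c3, cfg), "locus mismatch")
  plain <- gt(c("rs1"), c("AA"))
  expect_error(simulate_child(plain, a, cfg), "true genotypes")
})

test_that("noise layers hit their boundary behaviours", {
  cfg <- noise_free(2000, seed = 10)
  f <- simulate_founder(draw_allele_frequencies(cfg), cfg)
  # all rates zero: unchanged
  expect_identical(as.data.frame(apply_noise(f, noise_free(2000))), as.data.frame(f))
  # nocall_rate ~ 1: every record is a no-call
  all_nc <- simulation_config(n_loci = 2000, error_rate = 0, nocall_rate = 0.9999,
                              cn_abnormal_rate = 0)
  set.seed(1)
  noisy <- apply_noise(f, all_nc)
  expect_gt(mean(is.na(noisy$call)), 0.995)
  # CN-abnormal layer yields 1- or 3-copy strings over the true alleles
  all_cn <- simulation_config(n_loci = 2000, error_rate = 0, nocall_rate = 0,
                              cn_abnormal_rate = 0.9999)
  set.seed(2)
  cn <- apply_noise(f, all_cn)
  lens <- nchar(cn$call)
  expect_true(all(lens %in% c(1L, 3L) | lens == 2L))
  expect_gt(mean(lens %in% c(1L, 3L)), 0.995)
  # miscall layer always changes the two-copy genotype
  all_err <- simulation_config(n_loci = 2000, error_rate = 0.9999, nocall_rate = 0,
                               cn_abnormal_rate = 0)
  set.seed(3)
  err <- apply_noise(f, all_err)
  changed <- err$call != f$call
  expect_gt(mean(changed), 0.995)
  expect_true(all(nchar(err$call) == 2L))
})

test_that("noise-free parent-child pairs obey the Mendelian zero law", {
  cfg <- noise_free(5000, seed = 123)
  cohort <- simulate_cohort(2, cfg)
  ped <- cohort$pedigree
  for (i in 1:2) {
    for (role in c("mother", "father")) {
      cmp <- compare_pair(cohort$tables[[ped$proband[i]]],
                          cohort$tables[[ped[[role]][i]]])
      expect_identical(cmp$n_discordant, 0L)
    }
  }
})

test_that("unrelated pairs match the closed-form discordance at q = 0.5", {
  # among both-homozygous loci with q = 0.5, P(opposite) = 0.5;
  # P(informative) = (q^2 + p^2)^2 = 0.25
  cfg <- noise_free(30000, seed = 31, maf = c(0.5, 0.5))
  cohort <- simulate_cohort(1, cfg)
  cmp <- compare_pair(cohort$tables$trio01_mother, cohort$tables$trio01_father)
  expect_lt(abs(cmp$proportion_discordant - 0.5), 3 * sqrt(0.25 / cmp$n_informative))
  frac <- cmp$n_informative / cmp$n_merged
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / cmp$n_merged))
})

test_that("the informative fraction of unrelated pairs matches mean((q^2+p^2)^2)", {
  cfg <- noise_free(30000, seed = 32)
  cohort <- simulate_cohort(1, cfg)
  q <- cohort$loci$maf; p <- 1 - q
  e <- (q^2 + p^2)^2
  cmp <- compare_pair(cohort$tables$trio01_mother, cohort$tables$trio01_father)
  se <- sqrt(sum(e * (1 - e))) / length(e)
  expect_lt(abs(cmp$n_informative / cmp$n_merged - mean(e)), 3 * se)
})

test_that("relatedness classes behave as declared", {
  cfg <- noise_free(30000, seed = 33, maf = c(0.5, 0.5))
  cohort <- simulate_cohort(1, cfg)
  ctx <- list(mother = cohort$tables$trio01_mother,
              father = cohort$tables$trio01_father)
  sib <- simulate_relative("full-sibling", ctx, noise_free(30000), sample_id = "sib")

  # sibling vs parent is a true parent-child pair: zero discordance noise-free
  for (parent in ctx) {
    expect_identical(compare_pair(sib, parent)$n_discordant, 0L)
  }

  # sibling vs proband at both-heterozygous-parent loci: opposite homozygotes
  # with probability (1/4)(1/4)*2 = 1/8
  proband <- cohort$tables$trio01_proband
  dm <- attr(ctx$mother, "true_dosage"); df <- attr(ctx$father, "true_dosage")
  hh <- dm == 1L & df == 1L
  ds <- attr(sib, "true_dosage")[hh]; dp <- attr(proband, "true_dosage")[hh]
  opposite <- (ds == 0L & dp == 2L) | (ds == 2L & dp == 0L)
  n <- sum(hh)
  expect_lt(abs(mean(opposite) - 1 / 8), 3 * sqrt((1 / 8) * (7 / 8) / n))

  expect_error(simulate_relative("full-sibling", list(mother = ctx$mother)),
               "both `mother` and `father`")
  expect_error(simulate_relative("cousin", ctx), "must be one of")
})

test_that("cohorts are reproducible and correctly sized", {
  cfg <- simulation_config(n_loci = 800, seed = 55)
  c1 <- simulate_cohort(3, cfg)
  c2 <- simulate_cohort(3, cfg)
  expect_equal(length(c1$tables), 9L)
  expect_equal(nrow(c1$pedigree), 3L)
  expect_identical(lapply(c1$tables, as.data.frame), lapply(c2$tables, as.data.frame))
  expect_equal(length(simulate_cohort(1, simulation_config(n_loci = 50, seed = 1))$tables), 3L)
  expect_true(all(vapply(c1$tables, nrow, 0L) == 800L))
  shared <- lapply(c1$tables, function(t) t$locus_id)
  expect_true(all(vapply(shared, identical, TRUE, shared[[1]])))
})

test_that("a written cohort round-trips through its manifest", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_loci = 400, seed = 60)
  cohort <- simulate_cohort(2, cfg)
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  expect_equal(names(back$tables), names(cohort$tables))
  strip <- function(t) {
    d <- as.data.frame(t)
    attributes(d) <- attributes(d)[c("names", "row.names", "class")]
    d
  }
  expect_equal(strip(back$tables[[1]]), strip(cohort$tables[[1]]))
  expect_equal(back$pedigree$proband, cohort$pedigree$proband)
  expect_equal(back$manifest$config$seed, 60L)
})
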