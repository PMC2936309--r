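test_that("exact m distribution matches brute-force pattern enumeration", {
  for (n in c(1L, 4L, 7L, 10L, 12L)) {
    expect_equal(exact_m_distribution(n), enumerate_m_distribution(n),
                 tolerance = 1e-12)
  }
  # masses sum to 1 for all n up to 30
  for (n in 1:30) expect_equal(sum(exact_m_distribution(n)), 1)
  expect_equal(exact_m_distribution(1), c("0" = 0.5, "1" = 0.5))
  expect_equal(unname(exact_m_distribution(4)[["2"]]), 0.375) # 6 of 16
  expect_error(exact_m_distribution(0), "positive")
})

test_that("scheme probabilities reproduce the printed egg percentages", {
  # all-concordant segregation: 2 * (1/2)^18 = 7.63e-4 percent of eggs
  expect_equal(signif(prob_scheme_A(18) * 100, 3), 7.63e-4)
  # half-and-half segregation: 18.5 percent of eggs
  expect_equal(signif(prob_scheme_B(18) * 100, 3), 18.5)
  expect_equal(prob_scheme_B(18), dbinom(9, 18, 0.5))
  # small-n oracles: enumeration over all orientation patterns
  expect_equal(prob_scheme_A(1), 1)       # one trivalent always concordant
  expect_equal(prob_scheme_A(3), 0.25)    # 2 of 8 patterns
  expect_equal(prob_scheme_B(2), 0.5)     # 2 of 4 patterns
  expect_equal(prob_scheme_B(4), 0.375)   # 6 of 16 patterns
  expect_error(prob_scheme_B(3), "even")
  # consistency identity: P(scheme A) = P(m = 0) + P(m = n)
  for (n in c(2L, 5L, 18L)) {
    dm <- exact_m_distribution(n)
    expect_equal(prob_scheme_A(n), unname(dm[["0"]] + dm[[as.character(n)]]))
  }
})

test_that("segregation delivers n + m chromosomes to the oocyte II", {
  all_two <- segregate(segregation_pattern(rep(TRUE, 18)))
  expect_equal(total_cn(all_two), 36L)
  expect_true(all(all_two$group_copies == 2L))
  half <- segregate(segregation_pattern(rep(c(TRUE, FALSE), 9)))
  expect_equal(total_cn(half), 27L)
  all_one <- segregate(segregation_pattern(rep(FALSE, 18)))
  expect_equal(total_cn(all_one), 18L)
  expect_equal(ploidy_class(all_one), "haploid")
  expect_error(segregate(segregation_pattern(rep(TRUE, 5)),
                         karyotype(3L, n_groups = 18L)),
               "does not match")
  expect_error(segregate(segregation_pattern(rep(TRUE, 18)),
                         karyotype(2L)), "triploid")
})

test_that("anaphasic restitution doubles the complement and classifies eggs", {
  # scheme A: 36-chromosome oocyte -> 72-chromosome soumiae-like egg
  eggA <- apply_restitution(segregate(segregation_pattern(rep(TRUE, 18))))
  expect_equal(total_cn(eggA$karyotype), 72L)
  expect_true(all(eggA$karyotype$group_copies == 4L))
  expect_equal(eggA$egg_class, "soumiae_like")
  # scheme B: 27-chromosome oocyte -> 54-chromosome gallica-like egg
  eggB <- apply_restitution(segregate(segregation_pattern(rep(c(TRUE, FALSE), 9))))
  expect_equal(total_cn(eggB$karyotype), 54L)
  expect_equal(sum(eggB$karyotype$group_copies == 4L), 9L)
  expect_equal(sum(eggB$karyotype$group_copies == 2L), 9L)
  expect_equal(eggB$egg_class, "gallica_like")
  # m = 0: doubling a single complete series gives the diploid-like egg
  egg0 <- apply_restitution(segregate(segregation_pattern(rep(FALSE, 18))))
  expect_equal(total_cn(egg0$karyotype), 36L)
  expect_equal(egg0$egg_class, "diploid_like")
  # m = 17: one group short of scheme A is aneuploid (cn = 70)
  egg17 <- apply_restitution(segregate(segregation_pattern(
    c(rep(TRUE, 17), FALSE))))
  expect_equal(total_cn(egg17$karyotype), 70L)
  expect_equal(egg17$egg_class, "other_aneuploid")
  # every restituted egg has even copy counts and cn = 2(n + m)
  set.seed(42)
  for (i in 1:25) {
    flags <- runif(18) < 0.5
    egg <- apply_restitution(segregate(segregation_pattern(flags)))
    expect_true(all(egg$karyotype$group_copies %% 2L == 0L))
    expect_equal(total_cn(egg$karyotype), 2L * (18L + sum(flags)))
  }
})

test_that("Monte-Carlo egg simulation is seeded, normalized and consistent", {
  sim <- simulate_eggs(18, 2e4, seed = 7)
  expect_equal(sum(sim$freq), 1)
  expect_identical(simulate_eggs(18, 1000, seed = 3)$freq,
                   simulate_eggs(18, 1000, seed = 3)$freq)
  # n = 1: only m in {0, 1} can occur
  sim1 <- simulate_eggs(1, 1e4, seed = 1)
  expect_true(all(sim1$m %in% 0:1))
  expect_equal(unname(sim1$freq[["male_35_like"]]), 0)
  # gallica-like frequency within 3 Monte-Carlo SE of the exact 0.18547
  p <- prob_scheme_B(18)
  se <- sqrt(p * (1 - p) / 2e4)
  expect_lt(abs(sim$freq[["gallica_like"]] - p), 3 * se)
  # egg objects agree with the m vector
  sim_small <- simulate_eggs(18, 50, seed = 9, keep_eggs = TRUE)
  cns <- vapply(sim_small$eggs, function(e) total_cn(e$karyotype), numeric(1))
  expect_equal(cns, 2 * (18 + sim_small$m))
})

test_that("androgen derivations give the cn = 53 and cn = 35 males", {
  eggB <- apply_restitution(segregate(segregation_pattern(
    rep(c(TRUE, FALSE), 9))))
  # accidental X loss from the 54-chromosome gallica-like genome
  m53 <- derive_androgen(eggB$karyotype, "x_loss")
  expect_equal(total_cn(m53), 53L)
  expect_equal(sex_copies(m53), sex_copies(eggB$karyotype) - 1L)
  expect_equal(total_cn(m53) %% 2L, 1L)   # x_loss always gives odd cn
  # X mis-segregation at meiosis I of the triploid female, no restitution
  m35 <- derive_androgen(karyotype(3L), "scheme_A_mis_segregation")
  expect_equal(total_cn(m35), 35L)
  expect_equal(sex_copies(m35), 1L)
  expect_equal(classify_egg(m35), "male_35_like")
  # direct hybridization of two diploid forms
  m35b <- derive_androgen(karyotype(2L), "direct_hybrid")
  expect_equal(total_cn(m35b), 35L)
  expect_error(derive_androgen(karyotype(2L), "scheme_A_mis_segregation"),
               "triploid")
  expect_error(derive_androgen(karyotype(0L), "x_loss"), "X-free")
})

test_that("meiosis report tabulates exact and simulated distributions", {
  rep18 <- meiosis_report(18, n_eggs = 5000, seed = 2)
  expect_equal(nrow(rep18), 19)
  expect_equal(rep18$cn, 2 * (18 + 0:18))
  expect_equal(sum(rep18$exact_prob), 1)
  expect_equal(sum(rep18$sim_freq), 1)
  expect_equal(rep18$class[rep18$m == 9], "gallica_like")
  expect_equal(rep18$class[rep18$m == 18], "soumiae_like")
})
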