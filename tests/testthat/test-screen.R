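test_that("delta-beta is a plain difference with recorded moments", {
  tab <- data.frame(gene = c("a", "b", "c"),
                    beta_control = c(0.1, -0.2, 0.5),
                    beta_treated = c(0.4, -0.2, -1.0))
  got <- deltaBeta(tab)
  expect_equal(got$delta_beta, c(0.3, 0, -1.5))
  expect_equal(attr(got, "delta_mean"), mean(c(0.3, 0, -1.5)))

  same <- deltaBeta(data.frame(beta_control = 1:5 / 10,
                               beta_treated = 1:5 / 10))
  expect_true(all(same$delta_beta == 0))

  shifted <- deltaBeta(data.frame(beta_control = 1:5 / 10,
                                  beta_treated = 1:5 / 10 + 0.7))
  expect_equal(shifted$delta_beta, rep(0.7, 5))
})

test_that("hit gating combines the SD fence with the FDR cutoff", {
  tab <- makeScreenTable(200, n_hits = 0, seed = 1)
  tab <- deltaBeta(tab)
  mu <- mean(tab$delta_beta); sdv <- sd(tab$delta_beta)
  tab$delta_beta[1] <- mu + 2 * sdv
  tab$fdr[1] <- 0.05
  tab$delta_beta[2] <- mu + 2 * sdv
  tab$fdr[2] <- 0.5
  got <- selectHits(tab, fdr_max = 0.3)
  expect_identical(got$hit_class[1], "resistance")
  expect_identical(got$hit_class[2], "none")

  ## selection is invariant to affine rescaling of the scores
  tab2 <- tab
  tab2$delta_beta <- tab$delta_beta * 3.2 + 1.4
  expect_identical(selectHits(tab2, fdr_max = 0.3)$hit_class,
                   got$hit_class)

  zero <- deltaBeta(data.frame(beta_control = 1:5, beta_treated = 1:5))
  expect_error(selectHits(zero), "zero standard deviation")
})

test_that("planted hits at 4 SD are fully recalled at the printed gate", {
  tab <- deltaBeta(makeScreenTable(50, n_hits = 5, effect_sd_units = 4,
                                   fdr_hit_max = 0.01, seed = 2))
  got <- selectHits(tab, sd_multiplier = 1.5, fdr_max = 0.3)
  planted <- got$true_class != "null"
  expect_true(all(got$hit_class[planted] != "none"))
  expect_identical(got$hit_class[planted], got$true_class[planted])
})

test_that("null gating flags the normal tail fraction before FDR", {
  tab <- deltaBeta(makeScreenTable(5000, n_hits = 0, seed = 3))
  got <- selectHits(tab, sd_multiplier = 1.5, fdr_max = NULL)
  frac <- mean(got$hit_class != "none")
  expected <- 2 * pnorm(-1.5)               # 0.1336
  se <- sqrt(expected * (1 - expected) / 5000)
  expect_lt(abs(frac - expected), 4 * se)
})

test_that("Fisher enrichment equals the hypergeometric enumeration", {
  universe <- sprintf("g%04d", 1:1000)
  gene_set <- universe[1:20]
  hits <- universe[c(1:10, 101:110)]
  got <- enrichmentFisher(hits, gene_set, universe)
  expect_equal(got$p_value, enumFisherP(got$table), tolerance = 1e-12)

  ## the spec'd 2x2 example, via explicitly constructed memberships
  uni2 <- sprintf("h%04d", 1:1000)
  set2 <- uni2[1:20]
  hits2 <- c(uni2[1:10], uni2[21:110])  # 10 in-set, 90 out-of-set hits
  got2 <- enrichmentFisher(hits2, set2, uni2)
  expect_equal(unname(as.vector(got2$table)),
               c(10, 10, 90, 890))
  expect_equal(got2$p_value, enumFisherP(got2$table), tolerance = 1e-12)

  ## independent hits: odds ratio near 1 (here exactly 1 by construction)
  hits3 <- c(uni2[1:2], uni2[21:118])  # 10% of set, 10% of complement
  got3 <- enrichmentFisher(hits3, set2, uni2)
  expect_equal(got3$odds_ratio, 1, tolerance = 1e-9)

  ## all hits inside the set: minimal p for the margins
  got4 <- enrichmentFisher(set2[1:5], set2, uni2)
  direct <- sum(vapply(5, function(x)
    choose(20, x) * choose(980, 5 - x) / choose(1000, 5), numeric(1)))
  expect_equal(got4$p_value, direct, tolerance = 1e-10)

  expect_error(enrichmentFisher("a", "a", character(0)), "empty universe")
  expect_error(enrichmentFisher("zz", set2, uni2), "subsets")
})
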