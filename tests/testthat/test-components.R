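# Exported building blocks: unit scores, weights, collapsed and per-unit
# statistics, permutation p-values, trained weights.

test_that("trio scores count transmissions minus non-transmissions", {
  # het carrier parent transmits, other parent non-carrier
  expect_equal(trio_score(c(1, 0), c(0, 0)), 1L)
  # both parents homozygous: uninformative
  expect_equal(trio_score(c(1, 1), c(1, 1)), 0L)
  expect_equal(trio_score(c(0, 0), c(0, 0)), 0L)
  # both parents heterozygous, neither transmits the unit
  expect_equal(trio_score(c(0, 0), c(1, 1)), -2L)
  # full enumeration of the four meiosis outcomes for two het parents
  outcomes <- expand.grid(t1 = 0:1, t2 = 0:1)
  scores <- apply(outcomes, 1, function(o) {
    trio_score(c(o[1], o[2]), c(1 - o[1], 1 - o[2]))
  })
  expect_setequal(scores, c(-2L, 0L, 0L, 2L))
  expect_equal(mean(scores), 0)  # null expectation over random meioses
})

test_that("sib-pair scores are affected minus unaffected copy counts", {
  expect_equal(sibpair_score(1, 0), 1L)
  expect_equal(sibpair_score(2, 2), 0L)
  expect_equal(sibpair_score(0, 2), -2L)
})

test_that("family scores average unit scores over n_T + n_S", {
  # one site; father het transmits minor to the affected child (trio +1),
  # affected sib carries 1 vs unaffected 0 (DSP +1) -> D = (1+1)/2 = 1
  ped <- make_ped(list(F1 = list(
    list(id = "fa", affected = FALSE, hap = c("1", "0")),
    list(id = "mo", affected = FALSE, hap = c("0", "0")),
    list(id = "s1", father = "fa", mother = "mo", affected = TRUE,
         hap = c("1", "0")),
    list(id = "s2", father = "fa", mother = "mo", affected = FALSE,
         hap = c("0", "0")))))
  s <- pdt_scores(ped, "variant", rare_range = c(0.001, 0.4))
  expect_equal(s$score, 1)
  expect_true(all(s$informative))

  # two trios scoring +1 and -1 plus two uninformative DSPs average to 0
  ped2 <- make_ped(list(F1 = list(
    list(id = "fa", affected = FALSE, hap = c("1", "0")),
    list(id = "mo", affected = FALSE, hap = c("0", "0")),
    list(id = "s1", father = "fa", mother = "mo", affected = TRUE,
         hap = c("1", "0")),
    list(id = "s2", father = "fa", mother = "mo", affected = TRUE,
         hap = c("0", "0")),
    list(id = "s3", father = "fa", mother = "mo", affected = FALSE,
         hap = c("1", "0")))))
  s2 <- pdt_scores(ped2, "variant", rare_range = c(0.001, 0.4))
  # trios: +1, -1; DSPs: s1 - s3 = 0, s2 - s3 = -1 -> (1 - 1 + 0 - 1)/4
  expect_equal(s2$score, -0.25)

  # a family with no affected children is flagged uninformative
  ped3 <- dplyr::bind_rows(ped, make_ped(list(F2 = list(
    list(id = "fa", affected = FALSE, hap = c("1", "0")),
    list(id = "mo", affected = FALSE, hap = c("0", "0")),
    list(id = "s1", father = "fa", mother = "mo", affected = FALSE,
         hap = c("0", "0"))))))
  s3 <- pdt_scores(ped3, "variant", rare_range = c(0.001, 0.4))
  expect_equal(s3$score[s3$family_id == "F2"], 0)
  expect_false(any(s3$informative[s3$family_id == "F2"]))
})

test_that("frequency weights follow the inverse binomial standard deviation", {
  expect_equal(frequency_weights(0.5, 1), 2)
  expect_equal(frequency_weights(0.01, 1000), 1 / sqrt(1000 * 0.01 * 0.99),
               tolerance = 1e-12)
  expect_equal(round(frequency_weights(0.01, 1000), 4), 0.3178)
  # strictly decreasing in q on (0, 0.5]
  q <- seq(0.001, 0.5, length.out = 50)
  expect_true(all(diff(frequency_weights(q, 100)) < 0))
  expect_warning(w <- frequency_weights(c(0, 0.2, 1), 10), "excluded")
  expect_true(is.na(w[1]) && is.na(w[3]))
})

test_that("the collapsed statistic is a self-normalised weighted sum", {
  expect_equal(collapsed_statistic(matrix(1, 1, 1), 1)$statistic, 1)
  res <- collapsed_statistic(matrix(c(1, -1), 2, 1), 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(collapsed_statistic(matrix(c(2, 1, 1), 3, 1), 1)$statistic,
               4 / sqrt(6), tolerance = 1e-12)
  # degenerate cases
  expect_true(collapsed_statistic(matrix(0, 3, 2), c(1, 1))$degenerate)
  expect_true(collapsed_statistic(matrix(1, 3, 2), c(0, 0))$degenerate)
  # weighting matters: unequal weights change the statistic
  D <- matrix(c(1, 0, -1, 2, 0, 1), 3, 2)
  expect_false(isTRUE(all.equal(
    collapsed_statistic(D, c(1, 1))$statistic,
    collapsed_statistic(D, c(2, 1))$statistic)))
})

test_that("per-unit statistics normalise column sums and flip sign oddly", {
  z <- per_unit_z(matrix(c(1, 1), 2, 1))
  expect_equal(z$z, sqrt(2), tolerance = 1e-12)
  expect_equal(per_unit_z(matrix(0, 4, 1))$z, 0)
  D <- matrix(rnorm(30), 10, 3)
  expect_equal(per_unit_z(-D)$z, -per_unit_z(D)$z, tolerance = 1e-12)
})

test_that("the maximum statistic is the signed maximum and is monotone", {
  expect_equal(max_statistic(c(0.5, -2.0, 1.3))$statistic, 1.3)
  expect_equal(max_statistic(2.2)$statistic, 2.2)
  expect_equal(max_statistic(c(0.5, -2.0, 1.3), signed = FALSE)$statistic, 2)
  expect_true(max_statistic(numeric(0))$degenerate)
  # adding a unit can only increase or preserve the maximum
  z <- rnorm(5)
  expect_gte(max_statistic(c(z, rnorm(1)))$statistic,
             max_statistic(z)$statistic - 1e-15)
})

test_that("permutation p-values use the add-one rule with ties as exceedances", {
  expect_equal(permutation_pvalue(5, rep(0, 9999)), 1e-4)
  expect_equal(permutation_pvalue(-3, c(1, 2, 3)), 1)
  expect_equal(permutation_pvalue(2, c(2, 1, 0)), 2 / 4)  # tie counts
  expect_gt(permutation_pvalue(Inf, rnorm(100)), 0)
})

test_that("pooled permutation p-values generalise the single-sample rule", {
  set.seed(2)
  t_obs <- rnorm(7)
  t_perm <- matrix(rnorm(7 * 50), 7, 50)
  pooled <- pooled_permutation_pvalues(t_obs, t_perm)
  direct <- vapply(t_obs, function(t) {
    (1 + sum(t_perm >= t)) / (length(t_perm) + 1)
  }, numeric(1))
  expect_equal(pooled, direct)
  # R = 1 reduces exactly to the single-sample p-value
  expect_equal(pooled_permutation_pvalues(t_obs[1], t_perm[1, , drop = FALSE]),
               permutation_pvalue(t_obs[1], t_perm[1, ]))
  # degenerate replicates propagate NA
  expect_true(is.na(pooled_permutation_pvalues(c(NA, 0), t_perm[1:2, ])[1]))
})

test_that("trained weights threshold and sign the base weights", {
  expect_equal(trained_weights(c(0.5, -2, 1.5), c(1, 3, 2)), c(0, -3, 2))
  expect_equal(trained_weights(0.5, 1, mu = 1.04), 0)
  expect_equal(trained_weights(-1.04, 5, mu = 1.04), 0)  # strict inequality
  # mu = 1.04 is the two-sided normal critical value for level 0.3
  expect_equal(qnorm(1 - 0.3 / 2), 1.04, tolerance = 0.005)
  expect_equal(qnorm(1 - 0.2 / 2), 1.28, tolerance = 0.005)
  expect_equal(qnorm(1 - 0.1 / 2), 1.64, tolerance = 0.005)
})
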