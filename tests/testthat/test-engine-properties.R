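# Structural invariants of the scoring engine.

test_that("each trio's transmission scores sum to zero over all haplotypes", {
  # every trio transmits two haplotypes and withholds two, so summing the
  # per-unit scores over the complete catalog must give zero
  ped <- sim_hap_pedigrees(30, sim_hap_setting(1), seed = 13)
  cp <- rvpdt:::as_cped(ped)
  si <- rvpdt:::score_inputs_hap(cp, exclude_most = FALSE)
  expect_gt(nrow(si$Cm), 0)
  expect_equal(max(abs(rowSums(si$Cm))), 0)
})

test_that("swapping case/control roles negates every score and the statistic", {
  ped <- sim_hap_pedigrees(40, sim_hap_setting(2), seed = 17)
  cp <- rvpdt:::as_cped(ped)
  for (mode in c("haplotype", "variant")) {
    si <- if (mode == "haplotype") {
      rvpdt:::score_inputs_hap(cp)
    } else {
      rvpdt:::score_inputs_var(cp)
    }
    D <- rvpdt:::d_matrix(si)
    # swapped roles: transmitted <-> untransmitted, affected <-> unaffected
    Dn <- rvpdt:::d_matrix(si, Cm = -si$Cm, Cs = -si$Cs)
    expect_equal(Dn, -D)
    z1 <- rvpdt:::collapse_stat(D, si$w)$statistic
    z2 <- rvpdt:::collapse_stat(Dn, si$w)$statistic
    expect_equal(z2, -z1, tolerance = 1e-12)
    expect_equal(rvpdt:::unit_z_vec(Dn), -rvpdt:::unit_z_vec(D),
                 tolerance = 1e-12)
  }
})

test_that("permutation leaves homozygous-parent trios unchanged", {
  ped <- make_ped(list(F1 = list(
    list(id = "fa", affected = FALSE, hap = c("10", "10")),
    list(id = "mo", affected = FALSE, hap = c("01", "01")),
    list(id = "s1", father = "fa", mother = "mo", affected = TRUE,
         hap = c("10", "01")),
    list(id = "s2", father = "fa", mother = "mo", affected = TRUE,
         hap = c("10", "01")))))
  cp <- rvpdt:::as_cped(ped)
  si <- rvpdt:::score_inputs_hap(cp, exclude_most = FALSE)
  t_obs <- rvpdt:::max_stat(rvpdt:::unit_z_vec(rvpdt:::d_matrix(si)))
  set.seed(1)
  t_perm <- rvpdt:::perm_max_stats(si, 25)
  expect_true(all(t_perm == t_obs))
})

test_that("permuted family scores have expectation zero (exact enumeration)", {
  # one trio (2 meioses) and one DSP: enumerate all 2^3 sign patterns and
  # average the resulting family score matrices exactly
  ped <- make_ped(list(F1 = list(
    list(id = "fa", affected = FALSE, hap = c("10", "01")),
    list(id = "mo", affected = FALSE, hap = c("00", "11")),
    list(id = "s1", father = "fa", mother = "mo", affected = TRUE,
         hap = c("10", "00")),
    list(id = "s2", father = "fa", mother = "mo", affected = FALSE,
         hap = c("01", "11")))))
  cp <- rvpdt:::as_cped(ped)
  si <- rvpdt:::score_inputs_hap(cp, exclude_most = FALSE)
  expect_equal(nrow(si$Cm), 2)
  expect_equal(nrow(si$Cs), 1)
  total <- matrix(0, 1, si$K)
  for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1)) {
    D <- rvpdt:::d_matrix(si, Cm = si$Cm * c(s1, s2), Cs = si$Cs * s3)
    total <- total + D
  }
  expect_equal(max(abs(total)), 0)
})

test_that("the collapsed haplotype statistic matches a first-principles oracle", {
  fams <- toy_families()
  ped <- make_ped(fams)
  oracle <- oracle_hpdt(fams)

  s <- pdt_scores(ped, "haplotype")
  res <- collapsed_statistic(s)
  expect_equal(res$statistic, oracle$z, tolerance = 1e-12)

  units <- attr(s, "units")
  expect_equal(sort(units$unit), sort(oracle$units))
  expect_equal(units$weight[match(oracle$units, units$unit)], oracle$w,
               tolerance = 1e-12)

  # and on a larger simulated set, family by family
  ped2 <- sim_hap_pedigrees(12, sim_hap_setting(3), seed = 31)
  fams2 <- split(seq_len(nrow(ped2)), ped2$family_id)
  as_list <- lapply(fams2, function(rows) {
    lapply(rows, function(i) {
      list(id = ped2$id[i],
           father = if (is.na(ped2$father_id[i])) NULL else ped2$father_id[i],
           mother = if (is.na(ped2$mother_id[i])) NULL else ped2$mother_id[i],
           affected = ped2$affected[i],
           hap = c(paste(ped2$hap_pat[[i]], collapse = ""),
                   paste(ped2$hap_mat[[i]], collapse = "")))
    })
  })
  oracle2 <- oracle_hpdt(as_list)
  res2 <- collapsed_statistic(pdt_scores(ped2, "haplotype"))
  expect_equal(res2$statistic, oracle2$z, tolerance = 1e-12)
})

test_that("variant scores need no phase: unphased input gives identical results", {
  ped <- sim_hap_pedigrees(30, sim_hap_setting(3), seed = 23)
  unph <- ped[setdiff(names(ped), c("hap_pat", "hap_mat"))]
  s1 <- pdt_scores(ped, "variant")
  s2 <- pdt_scores(unph, "variant")
  expect_equal(s1$score, s2$score)
  res1 <- collapsed_statistic(s1)
  res2 <- collapsed_statistic(s2)
  expect_equal(res1$statistic, res2$statistic)
})

test_that("all-individual frequencies bias the null collapsed statistic downwards", {
  # children's haplotypes are transmitted copies, so frequencies taken over
  # all individuals couple the weights to the transmissions: under the null
  # the weighted Z drifts negative; founder-based frequencies do not
  set.seed(55)
  z_all <- z_fo <- numeric(80)
  for (r in seq_len(80)) {
    cp <- rvpdt:::gen_design(design_variant_study(n_families = 100,
                                                  null = TRUE))
    si_a <- rvpdt:::score_inputs_hap(cp, founders_only = FALSE)
    si_f <- rvpdt:::score_inputs_hap(cp, founders_only = TRUE)
    z_all[r] <- rvpdt:::collapse_stat(rvpdt:::d_matrix(si_a), si_a$w)$statistic
    z_fo[r] <- rvpdt:::collapse_stat(rvpdt:::d_matrix(si_f), si_f$w)$statistic
  }
  expect_lt(mean(z_all), mean(z_fo) - 0.2)
  expect_lt(mean(z_all), -0.2)
  expect_gt(mean(z_fo), -0.25)
})
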