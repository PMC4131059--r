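# Phase-configuration enumeration and the EM over gene flows.

unphase <- function(ped) ped[setdiff(names(ped), c("hap_pat", "hap_mat"))]

test_that("a fully homozygous family has exactly one configuration", {
  ped <- make_ped(list(F1 = list(
    list(id = "fa", affected = FALSE, geno = c(0, 2)),
    list(id = "mo", affected = FALSE, geno = c(2, 0)),
    list(id = "s1", father = "fa", mother = "mo", affected = TRUE,
         geno = c(1, 1)))), phased = FALSE)
  ph <- enumerate_phases(ped)
  expect_equal(length(ph$families[[1]]$configs), 1)
  expect_equal(ph$families[[1]]$weights, 1)
})

test_that("enumeration matches brute force on ambiguous trios", {
  # double-heterozygous father, mother and child: four distinct flows
  gf <- c(1, 1); gm <- c(1, 1); gk <- list(c(1, 1))
  ped <- make_ped(list(F1 = list(
    list(id = "fa", affected = FALSE, geno = gf),
    list(id = "mo", affected = FALSE, geno = gm),
    list(id = "s1", father = "fa", mother = "mo", affected = TRUE,
         geno = gk[[1]]))), phased = FALSE)
  ph <- enumerate_phases(ped)
  expect_equal(package_phase_keys(ph), oracle_phase_configs(gf, gm, gk))
  # uniform initial weights
  nc <- length(ph$families[[1]]$configs)
  expect_equal(ph$families[[1]]$weights, rep(1 / nc, nc))
})

test_that("enumeration matches brute force on random small families", {
  set.seed(7)
  for (rep in 1:20) {
    M <- sample(2:3, 1)
    nk <- sample(1:2, 1)
    # draw parent haplotypes, transmit, then discard phase
    fh <- matrix(rbinom(2 * M, 1, 0.4), 2)
    mh <- matrix(rbinom(2 * M, 1, 0.4), 2)
    gf <- colSums(fh); gm <- colSums(mh)
    gk <- lapply(seq_len(nk), function(i) {
      fh[sample(2, 1), ] + mh[sample(2, 1), ]
    })
    # occasionally blank a site of one child
    if (rep %% 4 == 0) gk[[1]][1] <- NA
    members <- list(
      list(id = "fa", affected = FALSE, geno = gf),
      list(id = "mo", affected = FALSE, geno = gm))
    for (i in seq_len(nk)) {
      members[[length(members) + 1]] <- list(
        id = paste0("s", i), father = "fa", mother = "mo",
        affected = i == 1, geno = gk[[i]])
    }
    ped <- make_ped(list(F1 = members), phased = FALSE)
    ph <- enumerate_phases(ped)
    expect_equal(package_phase_keys(ph), oracle_phase_configs(gf, gm, gk),
                 info = paste("replicate", rep))
  }
})

test_that("a Mendelian-inconsistent family yields no configurations", {
  ped <- make_ped(list(F1 = list(
    list(id = "fa", affected = FALSE, geno = c(0, 0)),
    list(id = "mo", affected = FALSE, geno = c(0, 0)),
    list(id = "s1", father = "fa", mother = "mo", affected = TRUE,
         geno = c(2, 0)))), phased = FALSE)
  ph <- enumerate_phases(ped)
  expect_equal(length(ph$families[[1]]$configs), 0)
})

test_that("the ambiguity cap triggers an overflow error", {
  geno <- rep(1, 14)  # 2^13 phase pairs for a single founder
  ped <- make_ped(list(F1 = list(
    list(id = "fa", affected = FALSE, geno = geno),
    list(id = "mo", affected = FALSE, geno = rep(0, 14)),
    list(id = "s1", father = "fa", mother = "mo", affected = TRUE,
         geno = rep(1, 14)))), phased = FALSE)
  expect_error(enumerate_phases(ped, max_configs = 64),
               class = "rvpdt_ambiguity_overflow")
})

test_that("EM on unambiguous families equals founder counting in one pass", {
  ped <- unphase(sim_hap_pedigrees(12, sim_hap_setting(0), seed = 21))
  ph0 <- enumerate_phases(ped)
  ambiguous <- vapply(ph0$families, function(fl) length(fl$configs) > 1,
                      logical(1))
  expect_false(all(ambiguous))
  # restrict to the unambiguous families
  keep <- unique(ped$family_id)[!ambiguous]
  ped1 <- ped[ped$family_id %in% keep, ]
  ph <- em_hap_frequencies(enumerate_phases(ped1))
  expect_true(ph$converged)
  # frequencies = raw founder counting proportions
  founders <- ped1[is.na(ped1$father_id), ]
  ph_true <- sim_hap_pedigrees(12, sim_hap_setting(0), seed = 21)
  ph_true <- ph_true[ph_true$family_id %in% keep & is.na(ph_true$father_id), ]
  chrom <- c(vapply(ph_true$hap_pat, paste, "", collapse = ""),
             vapply(ph_true$hap_mat, paste, "", collapse = ""))
  counted <- table(chrom) / length(chrom)
  expect_equal(ph$freq[match(names(counted), ph$catalog$key)],
               as.numeric(counted), tolerance = 1e-9)
})

test_that("symmetric configurations keep symmetric weights", {
  # father and mother both double-het, child double-het: the flows come in
  # frequency-symmetric pairs, so EM leaves equal weights equal
  ped <- make_ped(list(F1 = list(
    list(id = "fa", affected = FALSE, geno = c(1, 1)),
    list(id = "mo", affected = FALSE, geno = c(1, 1)),
    list(id = "s1", father = "fa", mother = "mo", affected = TRUE,
         geno = c(1, 1)))), phased = FALSE)
  ph <- phase_families(ped)
  w <- ph$families[[1]]$weights
  expect_equal(sum(w), 1)
  # configurations sharing the same founder haplotype multiset stay tied
  groups <- split(ph$families[[1]]$weights,
                  vapply(ph$families[[1]]$configs, function(cfg) {
                    paste(sort(c(cfg$pat[1:2], cfg$mat[1:2])), collapse = "-")
                  }, ""))
  for (g in groups) expect_equal(max(g) - min(g), 0, tolerance = 1e-12)
})

test_that("EM log-likelihood is monotone and frequencies stay a simplex", {
  ped <- unphase(sim_hap_pedigrees(40, sim_hap_setting(1), seed = 5))
  ph <- phase_families(ped)
  expect_true(all(diff(ph$loglik) > -1e-8))
  expect_equal(sum(ph$freq), 1, tolerance = 1e-9)
  expect_true(all(ph$freq >= 0))
  for (fl in ph$families) {
    if (length(fl$weights)) {
      expect_equal(sum(fl$weights), 1, tolerance = 1e-9)
    }
  }
})

test_that("EM recovers known haplotype frequencies from ambiguous data", {
  # truth: three haplotypes over two sites with frequencies 0.6 / 0.3 / 0.1;
  # genotype (1,1) individuals are phase-ambiguous
  set.seed(11)
  pool <- rbind(c(1, 1), c(1, 0), c(0, 0))
  freq <- c(0.6, 0.3, 0.1)
  fams <- list()
  for (i in 1:200) {
    fh <- sample(3, 2, TRUE, freq); mh <- sample(3, 2, TRUE, freq)
    tp <- sample(2, 1); tm <- sample(2, 1)
    fams[[paste0("F", i)]] <- list(
      list(id = "fa", affected = FALSE,
           geno = pool[fh[1], ] + pool[fh[2], ]),
      list(id = "mo", affected = FALSE,
           geno = pool[mh[1], ] + pool[mh[2], ]),
      list(id = "s1", father = "fa", mother = "mo", affected = TRUE,
           geno = pool[fh[tp], ] + pool[mh[tm], ]))
  }
  ph <- phase_families(make_ped(fams, phased = FALSE))
  expect_true(ph$converged)
  est <- ph$freq[match(c("11", "10", "00"), ph$catalog$key)]
  expect_true(all(abs(est - freq) <= 0.03))
})

test_that("flow-weighted scores combine configurations linearly", {
  ped <- make_ped(list(F1 = list(
    list(id = "fa", affected = FALSE, geno = c(1, 1)),
    list(id = "mo", affected = FALSE, geno = c(0, 0)),
    list(id = "s1", father = "fa", mother = "mo", affected = TRUE,
         geno = c(1, 0)))), phased = FALSE)
  ph <- enumerate_phases(ped)
  expect_equal(length(ph$families[[1]]$configs), 1)
  # single configuration, weight one: identical to the plain scorer
  res <- flow_weighted_scores(ph, function(cfg) sum(cfg$pat) + sum(cfg$mat))
  expect_equal(res$score, sum(ped$genotype[[1]]) + sum(ped$genotype[[2]]) +
                 sum(ped$genotype[[3]]))

  # synthetic two-flow family: weights (0.8, 0.2) with scores (2, -1) -> 1.4
  ph2 <- enumerate_phases(make_ped(list(F1 = list(
    list(id = "fa", affected = FALSE, geno = c(1, 1)),
    list(id = "mo", affected = FALSE, geno = c(1, 1)),
    list(id = "s1", father = "fa", mother = "mo", affected = TRUE,
         geno = c(1, 1)))), phased = FALSE))
  expect_gte(length(ph2$families[[1]]$configs), 2)
  ph2$families[[1]]$configs <- ph2$families[[1]]$configs[1:2]
  ph2$families[[1]]$weights <- c(0.8, 0.2)
  scores <- c(2, -1)
  calls <- 0
  res2 <- flow_weighted_scores(ph2, function(cfg) {
    calls <<- calls + 1
    scores[calls]
  })
  expect_equal(res2$score, 0.8 * 2 + 0.2 * (-1))

  # symmetric flows with opposite scores cancel
  ph2$families[[1]]$weights <- c(0.5, 0.5)
  calls <- 0
  scores <- c(1, -1)
  res3 <- flow_weighted_scores(ph2, function(cfg) {
    calls <<- calls + 1
    scores[calls]
  })
  expect_equal(res3$score, 0)
})

test_that("phased scoring and flow-weighted scoring agree on unambiguous data", {
  ped <- sim_hap_pedigrees(25, sim_hap_setting(1), seed = 9)
  ph <- phase_families(unphase(ped))
  ambiguous <- vapply(ph$families, function(fl) length(fl$configs) > 1,
                      logical(1))
  keep <- unique(ped$family_id)[!ambiguous]
  expect_gte(length(keep), 5)
  ped1 <- ped[ped$family_id %in% keep, ]
  ph1 <- phase_families(unphase(ped1))

  s_phased <- pdt_scores(ped1, "haplotype")
  s_flows <- pdt_scores(unphase(ped1), "haplotype", phases = ph1)
  m1 <- tidyr::pivot_wider(s_phased, names_from = unit, values_from = score)
  m2 <- tidyr::pivot_wider(s_flows, names_from = unit, values_from = score)
  shared <- intersect(names(m1), names(m2))
  expect_gt(length(shared), 2)
  expect_equal(m1[shared], m2[shared], tolerance = 1e-12)
})
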