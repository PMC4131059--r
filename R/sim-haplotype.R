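# The fully specified 15-haplotype linkage-disequilibrium simulation design:
# a 10-site region, a fixed haplotype pool, a logit penetrance model on
# haplotype pairs, and ascertained 2-affected / 1-unaffected sibships.

hap_pool_strings <- c(
  "1010000000", "0110000000", "1001000000", "0101000000",
  "1000000000", "0100000000", "0010000000", "0001000000",
  "0000100000", "0000010000", "0000001000", "0000000100",
  "0000000010", "0000000001", "0000000000")

hap_pool_matrix <- function() {
  m <- do.call(rbind, lapply(strsplit(hap_pool_strings, ""), as.integer))
  dimnames(m) <- NULL
  m
}

#' Built-in haplotype simulation settings
#'
#' The linkage-disequilibrium design uses 15 fixed haplotypes over 10 rare
#' variants: four two-variant haplotypes, ten single-variant haplotypes and
#' the all-major haplotype, with frequencies 0.01 (x14) and 0.86. The minor
#' allele frequencies are 0.03 at the first four variants and 0.01 at the
#' remaining six. Affection follows
#' `logit P(affected | h_k1, h_k2) = beta_k1 + beta_k2`. Three built-in
#' effect settings are provided:
#' \enumerate{
#'   \item `beta1 = beta4 = 3`, `beta5 = beta6 = beta7 = beta8 = -3`
#'     (per-variant cumulative effects all zero);
#'   \item `beta1 = beta4 = 3`, `beta5 = beta6 = 1`, `beta7 = beta8 = -3`;
#'   \item `beta1 = beta2 = beta3 = beta4 = 2` (strong per-variant effects).
#' }
#' Unspecified betas are zero; `beta_case = 0` gives the null (all zero).
#'
#' @param beta_case 0, 1, 2 or 3.
#' @return An object of class `hap_setting`: list with `haplotypes`
#'   (15 x 10 binary matrix), `frequencies`, `beta` and `beta_case`.
#' @examples
#' s <- sim_hap_setting(3)
#' s$beta
#' @export
sim_hap_setting <- function(beta_case = 1) {
  if (!beta_case %in% 0:3) {
    abort("beta_case must be 0 (null), 1, 2 or 3")
  }
  b <- numeric(15)
  if (beta_case == 1) {
    b[c(1, 4)] <- 3
    b[5:8] <- -3
  } else if (beta_case == 2) {
    b[c(1, 4)] <- 3
    b[c(5, 6)] <- 1
    b[c(7, 8)] <- -3
  } else if (beta_case == 3) {
    b[1:4] <- 2
  }
  hap_setting(hap_pool_matrix(), c(rep(0.01, 14), 0.86), b,
              beta_case = beta_case)
}

#' Construct a custom haplotype setting
#'
#' @param haplotypes binary matrix, one haplotype per row.
#' @param frequencies haplotype pool frequencies (must sum to 1).
#' @param beta per-haplotype log-odds effects on affection.
#' @param beta_case optional label.
#' @return A `hap_setting` object.
#' @export
hap_setting <- function(haplotypes, frequencies, beta, beta_case = NA) {
  haplotypes <- as.matrix(haplotypes)
  stopifnot(all(haplotypes %in% 0:1),
            length(frequencies) == nrow(haplotypes),
            all(frequencies > 0),
            abs(sum(frequencies) - 1) < 1e-9,
            length(beta) == nrow(haplotypes))
  structure(list(haplotypes = haplotypes, frequencies = frequencies,
                 beta = beta, beta_case = beta_case),
            class = "hap_setting")
}

#' Affection probability under the logit haplotype model
#'
#' @param setting a `hap_setting`.
#' @param k1,k2 haplotype indices of the individual's pair.
#' @return `plogis(beta[k1] + beta[k2])`, vectorised.
#' @examples
#' hap_affection_prob(sim_hap_setting(1), 15, 15)  # 0.5
#' @export
hap_affection_prob <- function(setting, k1, k2) {
  stopifnot(inherits(setting, "hap_setting"))
  plogis(setting$beta[k1] + setting$beta[k2])
}

#' Pairwise linkage disequilibrium (R-squared) of a haplotype pool
#'
#' Computes, for every pair of sites, the squared correlation
#' \eqn{R^2_{ij} = D^2 / (p_i (1 - p_i) p_j (1 - p_j))} with
#' \eqn{D = p_{ij} - p_i p_j}, from the haplotype frequency table.
#' Monomorphic sites have undefined LD; their entries are reported as 0 and
#' flagged in the `"monomorphic"` attribute.
#'
#' @param setting a `hap_setting`.
#' @return An M x M numeric matrix (diagonal 1 for polymorphic sites).
#' @examples
#' r2 <- pairwise_r2(sim_hap_setting(1))
#' r2[1, 3]  # ~ 0.098
#' @export
pairwise_r2 <- function(setting) {
  stopifnot(inherits(setting, "hap_setting"))
  H <- setting$haplotypes
  f <- setting$frequencies
  p <- as.vector(crossprod(H, f))           # per-site minor allele freq
  pij <- crossprod(H, H * f)                # joint carrier frequency
  D <- pij - outer(p, p)
  v <- p * (1 - p)
  denom <- outer(v, v)
  mono <- v == 0
  r2 <- matrix(0, length(p), length(p))
  ok <- denom > 0
  r2[ok] <- D[ok]^2 / denom[ok]
  attr(r2, "monomorphic") <- which(mono)
  r2
}

# vectorised rejection sampler on the compact representation; returns a cped
# plus truth (haplotype pool indices) and the acceptance rate
r_hap_families <- function(n, setting, n_children = 3, n_affected = 2) {
  freq <- setting$frequencies
  beta <- setting$beta
  nh <- length(freq)
  got <- 0
  tried <- 0
  keep_FH <- keep_MH <- NULL
  keep_kp <- keep_km <- keep_aff <- NULL
  keep_paff <- NULL
  while (got < n) {
    m <- max(200L, ceiling((n - got) / 0.1))
    FH <- matrix(sample.int(nh, 2 * m, replace = TRUE, prob = freq), m, 2)
    MH <- matrix(sample.int(nh, 2 * m, replace = TRUE, prob = freq), m, 2)
    kp <- km <- matrix(0L, m, n_children)
    aff <- matrix(FALSE, m, n_children)
    for (j in seq_len(n_children)) {
      bp <- runif(m) < 0.5
      bm <- runif(m) < 0.5
      kp[, j] <- ifelse(bp, FH[, 1], FH[, 2])
      km[, j] <- ifelse(bm, MH[, 1], MH[, 2])
      aff[, j] <- runif(m) < plogis(beta[kp[, j]] + beta[km[, j]])
    }
    paff <- cbind(runif(m) < plogis(beta[FH[, 1]] + beta[FH[, 2]]),
                  runif(m) < plogis(beta[MH[, 1]] + beta[MH[, 2]]))
    ok <- rowSums(aff) == n_affected
    tried <- tried + m
    if (any(ok)) {
      keep_FH <- rbind(keep_FH, FH[ok, , drop = FALSE])
      keep_MH <- rbind(keep_MH, MH[ok, , drop = FALSE])
      keep_kp <- rbind(keep_kp, kp[ok, , drop = FALSE])
      keep_km <- rbind(keep_km, km[ok, , drop = FALSE])
      keep_aff <- rbind(keep_aff, aff[ok, , drop = FALSE])
      keep_paff <- rbind(keep_paff, paff[ok, , drop = FALSE])
      got <- got + sum(ok)
    }
    if (tried >= 2e4 && got / tried < 1e-4) {
      abort(paste0("ascertainment acceptance probability below 1e-4 ",
                   "(accepted ", got, " of ", tried,
                   " sibships); adjust the disease model"))
    }
  }
  take <- seq_len(n)
  assemble_cped(
    FH = keep_FH[take, , drop = FALSE], MH = keep_MH[take, , drop = FALSE],
    kp = keep_kp[take, , drop = FALSE], km = keep_km[take, , drop = FALSE],
    kid_aff = keep_aff[take, , drop = FALSE],
    par_aff = keep_paff[take, , drop = FALSE],
    hap = setting$haplotypes,
    acceptance = got / tried)
}

# Assemble a cped from per-family haplotype-index matrices. Children are
# reordered affected-first within each family.
assemble_cped <- function(FH, MH, kp, km, kid_aff, par_aff, hap, acceptance) {
  n <- nrow(FH)
  nk <- ncol(kp)
  fam_size <- 2L + nk
  # affected-first child order
  ord <- t(vapply(seq_len(n), function(i) order(!kid_aff[i, ]),
                  integer(nk)))
  for (i in seq_len(n)) {
    kp[i, ] <- kp[i, ord[i, ]]
    km[i, ] <- km[i, ord[i, ]]
    kid_aff[i, ] <- kid_aff[i, ord[i, ]]
  }
  # member rows: father, mother, children...
  pat_idx <- cbind(FH[, 1], MH[, 1], kp)
  mat_idx <- cbind(FH[, 2], MH[, 2], km)
  pat_idx <- as.vector(t(pat_idx))
  mat_idx <- as.vector(t(mat_idx))
  aff <- as.vector(t(cbind(par_aff, kid_aff)))

  fam <- rep(seq_len(n), each = fam_size)
  member <- rep(seq_len(fam_size), times = n)
  base <- (fam - 1L) * fam_size
  father <- ifelse(member > 2, base + 1L, NA_integer_)
  mother <- ifelse(member > 2, base + 2L, NA_integer_)
  id <- c("fa", "mo", paste0("s", seq_len(nk)))[member]
  sex <- ifelse(member == 1, 1L, ifelse(member == 2, 2L, NA_integer_))

  pat <- hap[pat_idx, , drop = FALSE]
  mat <- hap[mat_idx, , drop = FALSE]
  cp <- structure(list(
    n = n * fam_size, M = ncol(hap),
    fam_id = sprintf("F%04d", seq_len(n)), fam = fam, id = id,
    father = father, mother = mother, sex = sex, affected = aff,
    geno = pat + mat, pat = pat, mat = mat, phased = TRUE
  ), class = "cped")
  attr(cp, "truth") <- tibble(
    family_id = cp$fam_id[fam], id = id,
    hap1_index = pat_idx, hap2_index = mat_idx)
  attr(cp, "acceptance_rate") <- acceptance
  cp
}

#' Simulate ascertained nuclear families from a haplotype pool
#'
#' Draws four founder haplotypes per family i.i.d. from the pool
#' frequencies, transmits one haplotype from each parent to each of three
#' children without recombination, assigns affection by the logit model of
#' the setting, and keeps only sibships with exactly two affected and one
#' unaffected child (affected sibs listed first). Parental affection is
#' simulated but not conditioned on. Each family has 5 members, so
#' `n_families = 200` yields 1000 individuals.
#'
#' @param n_families number of ascertained families to return.
#' @param setting a [sim_hap_setting()] / [hap_setting()] object.
#' @param seed optional RNG seed.
#' @return A phased pedigree tibble with attributes `truth` (the pool index
#'   of every haplotype), `acceptance_rate` (ascertainment acceptance
#'   fraction) and `setting`.
#' @examples
#' ped <- sim_hap_pedigrees(10, sim_hap_setting(1), seed = 7)
#' nrow(ped)  # 50
#' @export
sim_hap_pedigrees <- function(n_families, setting = sim_hap_setting(1),
                              seed = NULL) {
  stopifnot(n_families >= 1)
  if (!is.null(seed)) set.seed(seed)
  cp <- r_hap_families(n_families, setting)
  out <- cped_to_tibble(cp)
  attr(out, "truth") <- attr(cp, "truth")
  attr(out, "acceptance_rate") <- attr(cp, "acceptance_rate")
  attr(out, "setting") <- setting
  out
}
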