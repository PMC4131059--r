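# Parametric rare-variant simulation design: a sampled site spectrum,
# a population-attributable-risk disease model with multiplicative
# penetrance, and the flat-penetrance null model, feeding the same
# ascertained 2-affected / 1-unaffected sibship generator.

#' Sample a rare-variant site spectrum
#'
#' Draws the number of rare variants in a test region from a truncated
#' normal (rounded, at least `min_count`) and each site's minor allele
#' frequency from a truncated `1/f` density on `maf_range` -- a
#' neutral-spectrum stand-in concentrating mass at the rare end.
#'
#' @param mean_count,sd_count mean and standard deviation of the site count
#'   (defaults emulate a 20 kb region holding about 22 rare variants).
#' @param min_count lower truncation for the site count.
#' @param maf_range the window of minor allele frequencies defining "rare".
#' @return A tibble with columns `site`, `maf`, `is_rare` (all `TRUE`).
#' @examples
#' sim_variant_sites()
#' @export
sim_variant_sites <- function(mean_count = 22, sd_count = 4.7,
                              min_count = 5, maf_range = c(0.001, 0.05)) {
  repeat {
    m <- round(rnorm(1, mean_count, sd_count))
    if (m >= min_count) break
  }
  u <- runif(m)
  maf <- maf_range[1] * (maf_range[2] / maf_range[1])^u
  tibble(site = seq_len(m), maf = maf, is_rare = TRUE)
}

#' Genotype relative risk from the population attributable risk
#'
#' Converts a per-variant population attributable risk (PAR) into a genotype
#' relative risk so that rarer variants receive larger per-allele effects:
#' \eqn{GRR_l = 1 + PAR / (f_l (1 - PAR))} for a causal variant with minor
#' allele frequency \eqn{f_l}. Each causal variant carries the same PAR
#' (default 0.006), so a site with `maf = 0.01` gets a GRR near 1.6 while a
#' `maf = 0.001` site gets one near 7. Setting `n_causal > 1` instead splits
#' `par` as a total budget equally across that many variants
#' (`PAR / n_causal` each).
#'
#' @param maf minor allele frequency (vectorised).
#' @param par population attributable risk per causal variant
#'   (or in total, see `n_causal`).
#' @param n_causal number of causal variants sharing `par`; the default 1
#'   treats `par` as per-variant.
#' @return Genotype relative risks (> 1 when `par > 0`).
#' @examples
#' grr_from_par(0.01)  # ~ 1.603
#' @export
grr_from_par <- function(maf, par = 0.006, n_causal = 1) {
  stopifnot(all(maf > 0 & maf < 1), n_causal >= 1, par >= 0, par < 1)
  1 + par / (n_causal * maf * (1 - par))
}

#' Build a rare-variant disease model
#'
#' Randomly selects `d_causal` of the rare sites to be causal and, among
#' those, `r_risk` to increase risk (the rest decrease it). Each causal site
#' gets a genotype relative risk from [grr_from_par()]; protective sites act
#' through the reciprocal `1/GRR`, a symmetric effect on the log-risk scale.
#' Penetrance is multiplicative over causal minor-allele copies with baseline
#' `f0`, capped at 1 (see [penetrance()]).
#'
#' @param sites a site tibble from [sim_variant_sites()].
#' @param d_causal fraction of rare sites that are causal (rounded count).
#' @param r_risk fraction of causal sites that increase risk.
#' @param par population attributable risk of each causal variant.
#' @param f0 baseline penetrance.
#' @return An object of class `disease_model` with a `sites` tibble
#'   (`site`, `maf`, `causal`, `direction`, `grr`).
#' @export
sim_disease_model <- function(sites, d_causal = 0.5, r_risk = 1,
                              par = 0.006, f0 = 0.10) {
  stopifnot(is.data.frame(sites), all(c("site", "maf") %in% names(sites)),
            d_causal >= 0, d_causal <= 1, r_risk >= 0, r_risk <= 1,
            f0 > 0, f0 < 1)
  m <- nrow(sites)
  mc <- round(d_causal * m)
  if (mc < 1) {
    abort("no causal sites: d_causal rounds to zero causal variants")
  }
  causal <- sort(sample.int(m, mc))
  n_up <- round(r_risk * mc)
  up <- if (n_up > 0) sort(sample(causal, n_up)) else integer(0)
  direction <- rep(NA_integer_, m)
  direction[causal] <- -1L
  direction[up] <- 1L
  grr <- rep(NA_real_, m)
  grr[causal] <- grr_from_par(sites$maf[causal], par)
  structure(list(
    type = "par",
    f0 = f0, par = par,
    sites = tibble(site = sites$site, maf = sites$maf,
                   causal = seq_len(m) %in% causal,
                   direction = direction, grr = grr)
  ), class = "disease_model")
}

#' Null disease model with flat penetrance
#'
#' Affection independent of genotype: `P(affected) = penetrance` for every
#' haplotype pair. The default 30\% keeps ascertained sibships common enough
#' to sample efficiently in type-I-error studies.
#'
#' @param penetrance the flat affection probability.
#' @return A `disease_model` of type `"null"`.
#' @export
sim_null_model <- function(penetrance = 0.30) {
  stopifnot(penetrance > 0, penetrance < 1)
  structure(list(type = "null", f0 = penetrance),
            class = "disease_model")
}

#' Penetrance of a genotype under a disease model
#'
#' For the PAR model the affection probability of an individual carrying
#' `c_l` copies of the rare allele at each causal site `l` is
#' \eqn{\min(1, f_0 \prod_l r_l^{c_l})}, with \eqn{r_l = GRR_l} for
#' risk-increasing sites and \eqn{1/GRR_l} for protective ones. The null
#' model returns its flat penetrance regardless of genotype.
#'
#' @param model a `disease_model`.
#' @param genotype a vector of per-site minor-allele counts, or a matrix
#'   with one row per individual (all sites of the model, in order).
#' @return Affection probabilities.
#' @examples
#' s <- tibble::tibble(site = 1:10, maf = rep(0.01, 10))
#' m <- sim_disease_model(s, d_causal = 1, r_risk = 1)
#' penetrance(m, rep(0, 10))  # baseline 0.10
#' @export
penetrance <- function(model, genotype) {
  stopifnot(inherits(model, "disease_model"))
  G <- if (is.matrix(genotype)) genotype else matrix(genotype, nrow = 1)
  if (model$type == "null") {
    return(rep(model$f0, nrow(G)))
  }
  cs <- which(model$sites$causal)
  logr <- model$sites$direction[cs] * log(model$sites$grr[cs])
  lp <- as.vector(G[, cs, drop = FALSE] %*% logr)
  pmin(1, model$f0 * exp(lp))
}

# rejection sampler for the variant design (compact form)
r_var_families <- function(n, sites, model, n_children = 3, n_affected = 2) {
  maf <- sites$maf
  M <- length(maf)
  got <- 0
  tried <- 0
  acc <- list()
  while (got < n) {
    m <- max(200L, ceiling((n - got) / 0.1))
    draw_chrom <- function() {
      matrix(rbinom(m * M, 1L, rep(maf, each = m)), m, M)
    }
    F1 <- draw_chrom(); F2 <- draw_chrom()
    M1 <- draw_chrom(); M2 <- draw_chrom()
    kid_pat <- kid_mat <- vector("list", n_children)
    aff <- matrix(FALSE, m, n_children)
    for (j in seq_len(n_children)) {
      bp <- runif(m) < 0.5
      bm <- runif(m) < 0.5
      kp <- F1; kp[bp, ] <- F2[bp, , drop = FALSE]
      km <- M1; km[bm, ] <- M2[bm, , drop = FALSE]
      kid_pat[[j]] <- kp
      kid_mat[[j]] <- km
      aff[, j] <- runif(m) < penetrance(model, kp + km)
    }
    paff <- cbind(runif(m) < penetrance(model, F1 + F2),
                  runif(m) < penetrance(model, M1 + M2))
    ok <- which(rowSums(aff) == n_affected)
    tried <- tried + m
    if (length(ok)) {
      acc[[length(acc) + 1]] <- list(
        F1 = F1[ok, , drop = FALSE], F2 = F2[ok, , drop = FALSE],
        M1 = M1[ok, , drop = FALSE], M2 = M2[ok, , drop = FALSE],
        kp = lapply(kid_pat, function(x) x[ok, , drop = FALSE]),
        km = lapply(kid_mat, function(x) x[ok, , drop = FALSE]),
        aff = aff[ok, , drop = FALSE], paff = paff[ok, , drop = FALSE])
      got <- got + length(ok)
    }
    if (tried >= 2e4 && got / tried < 1e-4) {
      abort(paste0("ascertainment acceptance probability below 1e-4 ",
                   "(accepted ", got, " of ", tried,
                   " sibships); adjust the disease model"))
    }
  }
  bindf <- function(get) do.call(rbind, lapply(acc, get))
  F1 <- bindf(function(a) a$F1)[seq_len(n), , drop = FALSE]
  F2 <- bindf(function(a) a$F2)[seq_len(n), , drop = FALSE]
  M1 <- bindf(function(a) a$M1)[seq_len(n), , drop = FALSE]
  M2 <- bindf(function(a) a$M2)[seq_len(n), , drop = FALSE]
  kp <- lapply(seq_len(n_children), function(j) {
    bindf(function(a) a$kp[[j]])[seq_len(n), , drop = FALSE]
  })
  km <- lapply(seq_len(n_children), function(j) {
    bindf(function(a) a$km[[j]])[seq_len(n), , drop = FALSE]
  })
  aff <- bindf(function(a) a$aff)[seq_len(n), , drop = FALSE]
  paff <- bindf(function(a) a$paff)[seq_len(n), , drop = FALSE]

  # reorder children affected-first
  ord <- t(vapply(seq_len(n), function(i) order(!aff[i, ]),
                  integer(n_children)))
  fam_size <- 2L + n_children
  pat <- matrix(0L, n * fam_size, M)
  mat <- matrix(0L, n * fam_size, M)
  affv <- logical(n * fam_size)
  for (i in seq_len(n)) {
    b <- (i - 1L) * fam_size
    pat[b + 1L, ] <- F1[i, ]; mat[b + 1L, ] <- F2[i, ]
    pat[b + 2L, ] <- M1[i, ]; mat[b + 2L, ] <- M2[i, ]
    affv[b + 1:2] <- paff[i, ]
    for (j in seq_len(n_children)) {
      oj <- ord[i, j]
      pat[b + 2L + j, ] <- kp[[oj]][i, ]
      mat[b + 2L + j, ] <- km[[oj]][i, ]
      affv[b + 2L + j] <- aff[i, oj]
    }
  }
  fam <- rep(seq_len(n), each = fam_size)
  member <- rep(seq_len(fam_size), times = n)
  base <- (fam - 1L) * fam_size
  cp <- structure(list(
    n = n * fam_size, M = M,
    fam_id = sprintf("F%04d", seq_len(n)), fam = fam,
    id = c("fa", "mo", paste0("s", seq_len(n_children)))[member],
    father = ifelse(member > 2, base + 1L, NA_integer_),
    mother = ifelse(member > 2, base + 2L, NA_integer_),
    sex = ifelse(member == 1, 1L, ifelse(member == 2, 2L, NA_integer_)),
    affected = affv,
    geno = pat + mat, pat = pat, mat = mat, phased = TRUE
  ), class = "cped")
  attr(cp, "acceptance_rate") <- got / tried
  cp
}

#' Simulate ascertained nuclear families under a rare-variant disease model
#'
#' Founder haplotypes are built by independent per-site Bernoulli(MAF) draws
#' (linkage equilibrium among founders) and transmitted to three children
#' without recombination; affection comes from [penetrance()] under `model`;
#' sibships are rejection-sampled until exactly two affected and one
#' unaffected child are present (affected first). Parental affection is
#' simulated but not conditioned on.
#'
#' @param n_families number of ascertained families.
#' @param sites site tibble from [sim_variant_sites()].
#' @param model a `disease_model` ([sim_disease_model()] or
#'   [sim_null_model()]).
#' @param seed optional RNG seed.
#' @return A phased pedigree tibble with attributes `sites`, `model` and
#'   `acceptance_rate`.
#' @examples
#' sites <- sim_variant_sites()
#' ped <- sim_variant_pedigrees(5, sites, sim_null_model(), seed = 3)
#' @export
sim_variant_pedigrees <- function(n_families, sites,
                                  model = sim_null_model(), seed = NULL) {
  stopifnot(n_families >= 1)
  if (!is.null(seed)) set.seed(seed)
  cp <- r_var_families(n_families, sites, model)
  out <- cped_to_tibble(cp)
  attr(out, "sites") <- sites
  attr(out, "model") <- model
  attr(out, "acceptance_rate") <- attr(cp, "acceptance_rate")
  out
}
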