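# Replicate orchestration: simulation studies of type I error and power
# with pooled permutation p-values for the maximum tests.

#' Study design: the 15-haplotype linkage-disequilibrium simulator
#'
#' @param beta_case built-in effect setting (0 = null, 1-3; see
#'   [sim_hap_setting()]).
#' @param n_families ascertained families per replicate.
#' @return A `pdt_design` object for [pdt_study()].
#' @export
design_haplotype_study <- function(beta_case = 1, n_families = 200) {
  structure(list(type = "haplotype",
                 label = paste0("haplotype beta setting ", beta_case),
                 setting = sim_hap_setting(beta_case),
                 n_families = n_families),
            class = "pdt_design")
}

#' Study design: the rare-variant-spectrum simulator
#'
#' Each replicate draws a fresh site spectrum ([sim_variant_sites()]) and,
#' unless `null = TRUE`, a fresh disease model ([sim_disease_model()]), then
#' generates ascertained families. Under the null, affection has flat
#' penetrance `null_penetrance` independent of genotype.
#'
#' @param n_families ascertained families per replicate.
#' @param d_causal,r_risk,par,f0 disease-model parameters.
#' @param null simulate under the null model instead.
#' @param null_penetrance flat penetrance of the null model.
#' @param site_mean,site_sd,site_min site-count distribution.
#' @param maf_range rare window for simulated site frequencies.
#' @return A `pdt_design` object for [pdt_study()].
#' @export
design_variant_study <- function(n_families = 200, d_causal = 0.5,
                                 r_risk = 1, par = 0.006, f0 = 0.10,
                                 null = FALSE, null_penetrance = 0.30,
                                 site_mean = 22, site_sd = 4.7,
                                 site_min = 5, maf_range = c(0.001, 0.05)) {
  structure(list(type = "variant",
                 label = if (null) "variant null model" else
                   sprintf("variant d=%g r=%g", d_causal, r_risk),
                 n_families = n_families, d_causal = d_causal,
                 r_risk = r_risk, par = par, f0 = f0, null = null,
                 null_penetrance = null_penetrance,
                 site_mean = site_mean, site_sd = site_sd,
                 site_min = site_min, maf_range = maf_range),
            class = "pdt_design")
}

# one replicate's data in compact form (uses the current RNG stream)
gen_design <- function(design) {
  if (design$type == "haplotype") {
    r_hap_families(design$n_families, design$setting)
  } else {
    sites <- sim_variant_sites(design$site_mean, design$site_sd,
                               design$site_min, design$maf_range)
    model <- if (design$null) {
      sim_null_model(design$null_penetrance)
    } else {
      sim_disease_model(sites, design$d_causal, design$r_risk,
                        design$par, design$f0)
    }
    r_var_families(design$n_families, sites, model)
  }
}

#' Simulation study of the six tests
#'
#' Runs `R` replicates of a simulation design, computing all requested
#' statistics per replicate. The collapsing tests (hPDT, vPDT) and the
#' training-split tests (hPDT-t, vPDT-t) use two-sided asymptotic normal
#' p-values; the maximum tests store their observed statistic together with
#' `B` transmission-permutation statistics per replicate, and after the
#' replicate loop their p-values are computed against the pooled `B * R`
#' null sample ([pooled_permutation_pvalues()]) -- with `R = 1000` and
#' `B = 10` each replicate effectively sees 10,000 permutations. The
#' rejection fraction at level `alpha` estimates power (or, under a null
#' design, type I error); degenerate training-split replicates carry p = 1
#' and therefore count as non-rejections.
#'
#' Every source of randomness derives from `seed`: per-replicate seeds are
#' drawn once from the master seed, so re-running with the same seed
#' reproduces the study exactly.
#'
#' @param design a [design_haplotype_study()] or [design_variant_study()]
#'   object.
#' @param R number of replicates.
#' @param B permutations per replicate for the maximum tests.
#' @param alpha significance level of the rejection tally.
#' @param methods subset of the six method names.
#' @param seed master seed.
#' @param mu,train_fraction,rare_range,signed_max see [pdt_test()].
#' @param progress print a progress note every `progress` replicates
#'   (0 = silent).
#' @return An object of class `pdt_study`; `tidy()` gives per-method
#'   rejection rates, `glance()` the study settings, and the `replicates`
#'   element the per-replicate results.
#' @examples
#' st <- pdt_study(design_haplotype_study(1, n_families = 50),
#'                 R = 20, B = 10, seed = 1)
#' tidy(st)
#' @export
pdt_study <- function(design, R = 1000, B = 10, alpha = 0.05,
                      methods = pdt_methods, seed = 1,
                      mu = 1.04, train_fraction = 0.3,
                      rare_range = c(0.001, 0.05), signed_max = TRUE,
                      progress = 0) {
  stopifnot(inherits(design, "pdt_design"), R >= 1, B >= 1)
  methods <- match.arg(methods, pdt_methods, several.ok = TRUE)
  set.seed(seed)
  seeds <- sample.int(2147483646L, R)

  need_h <- any(methods %in% c("hPDT", "maxH", "hPDT-t"))
  need_v <- any(methods %in% c("vPDT", "maxV", "vPDT-t"))
  asym <- intersect(methods, c("hPDT", "vPDT", "hPDT-t", "vPDT-t"))
  pvals <- matrix(NA_real_, R, length(asym),
                  dimnames = list(NULL, asym))
  stats <- matrix(NA_real_, R, length(asym),
                  dimnames = list(NULL, asym))
  degen <- matrix(FALSE, R, length(asym), dimnames = list(NULL, asym))
  t_obs <- matrix(NA_real_, R, 2, dimnames = list(NULL, c("maxH", "maxV")))
  t_perm_h <- if ("maxH" %in% methods) matrix(NA_real_, R, B) else NULL
  t_perm_v <- if ("maxV" %in% methods) matrix(NA_real_, R, B) else NULL
  n_sites <- integer(R)

  for (r in seq_len(R)) {
    set.seed(seeds[r])
    cp <- gen_design(design)
    n_sites[r] <- cp$M
    si_h <- if (need_h) score_inputs_hap(cp) else NULL
    si_v <- if (need_v) score_inputs_var(cp, rare_range) else NULL
    train <- if (any(methods %in% c("hPDT-t", "vPDT-t"))) {
      sample.int(design$n_families,
                 max(1, round(train_fraction * design$n_families)))
    } else NULL

    put <- function(m, res) {
      pvals[r, m] <<- res$p_value
      stats[r, m] <<- res$statistic
      degen[r, m] <<- res$degenerate
    }
    if ("hPDT" %in% methods) put("hPDT", collapse_stat(d_matrix(si_h), si_h$w))
    if ("vPDT" %in% methods) put("vPDT", collapse_stat(d_matrix(si_v), si_v$w))
    if ("hPDT-t" %in% methods) put("hPDT-t", trained_split_stat(si_h, train, mu))
    if ("vPDT-t" %in% methods) put("vPDT-t", trained_split_stat(si_v, train, mu))
    if ("maxH" %in% methods) {
      t_obs[r, "maxH"] <- max_stat(unit_z_vec(d_matrix(si_h)),
                                   signed = signed_max)
      t_perm_h[r, ] <- perm_max_stats(si_h, B, signed = signed_max)
    }
    if ("maxV" %in% methods) {
      t_obs[r, "maxV"] <- max_stat(unit_z_vec(d_matrix(si_v)),
                                   signed = signed_max)
      t_perm_v[r, ] <- perm_max_stats(si_v, B, signed = signed_max)
    }
    if (progress > 0 && r %% progress == 0) {
      message("replicate ", r, "/", R)
    }
  }

  rep_rows <- list()
  for (m in asym) {
    rep_rows[[m]] <- tibble(replicate = seq_len(R), method = m,
                            statistic = stats[, m], p_value = pvals[, m],
                            degenerate = degen[, m])
  }
  if ("maxH" %in% methods) {
    rep_rows[["maxH"]] <- tibble(
      replicate = seq_len(R), method = "maxH", statistic = t_obs[, "maxH"],
      p_value = pooled_permutation_pvalues(t_obs[, "maxH"], t_perm_h),
      degenerate = is.na(t_obs[, "maxH"]))
  }
  if ("maxV" %in% methods) {
    rep_rows[["maxV"]] <- tibble(
      replicate = seq_len(R), method = "maxV", statistic = t_obs[, "maxV"],
      p_value = pooled_permutation_pvalues(t_obs[, "maxV"], t_perm_v),
      degenerate = is.na(t_obs[, "maxV"]))
  }
  replicates <- dplyr::bind_rows(rep_rows[methods])
  replicates$p_value[is.na(replicates$p_value)] <- 1

  summary <- replicates |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_reject = sum(.data$p_value <= alpha),
      rejection_rate = mean(.data$p_value <= alpha),
      n_degenerate = sum(.data$degenerate),
      .groups = "drop") |>
    dplyr::arrange(match(.data$method, pdt_methods))

  structure(list(
    replicates = replicates, summary = summary,
    design = design, R = R, B = B, alpha = alpha, seed = seed,
    n_sites_mean = mean(n_sites), n_sites_sd = sd(n_sites),
    perm = list(maxH = t_perm_h, maxV = t_perm_v, obs = t_obs)
  ), class = "pdt_study")
}

#' @export
tidy.pdt_study <- function(x, ...) {
  x$summary
}

#' @export
glance.pdt_study <- function(x, ...) {
  tibble(design = x$design$label, n_families = x$design$n_families,
         R = x$R, B = x$B, alpha = x$alpha, seed = x$seed,
         n_sites_mean = x$n_sites_mean, n_sites_sd = x$n_sites_sd)
}

#' @export
print.pdt_study <- function(x, ...) {
  cat("<pdt_study> ", x$design$label, ": R = ", x$R, ", B = ", x$B,
      ", alpha = ", x$alpha, "\n", sep = "")
  cat(sprintf("  sites per replicate: %.2f (sd %.2f)\n",
              x$n_sites_mean, x$n_sites_sd))
  print(x$summary)
  invisible(x)
}

#' @export
autoplot.pdt_study <- function(object, ...) {
  d <- tidy(object)
  d$method <- factor(d$method, levels = pdt_methods)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method,
                                  y = .data$rejection_rate)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = NULL, y = paste0("rejection rate at alpha = ",
                                       object$alpha),
                  title = object$design$label) +
    ggplot2::theme_minimal()
}
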