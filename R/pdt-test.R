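# User-facing test runner: the six pedigree disequilibrium tests on one
# pedigree set.

pdt_methods <- c("hPDT", "vPDT", "maxH", "maxV", "hPDT-t", "vPDT-t")

#' Run pedigree disequilibrium tests for rare variants
#'
#' Computes any subset of the six tests on a pedigree set:
#' \describe{
#'   \item{hPDT}{weighted collapsing over all observed haplotypes except the
#'     most frequent one; two-sided asymptotic normal p-value.}
#'   \item{vPDT}{weighted collapsing over the sites whose sample minor allele
#'     frequency falls in `rare_range`; two-sided asymptotic p-value.}
#'   \item{maxH / maxV}{signed maximum of the per-unit statistics with a
#'     permutation p-value over `B` transmission permutations (each parental
#'     meiosis re-draws its transmitted haplotype -- or allele, per variant --
#'     with probability 1/2; each discordant sib pair swaps labels with
#'     probability 1/2).}
#'   \item{hPDT-t / vPDT-t}{a random `train_fraction` of the families
#'     estimates each unit's direction; units with training statistic
#'     exceeding `mu` in absolute value keep their frequency weight, signed;
#'     the collapsed statistic is then evaluated on the remaining families.
#'     If no unit passes the threshold the test is degenerate with p = 1.}
#' }
#'
#' Haplotype-mode tests need phase: either phased input (`hap_pat`/`hap_mat`
#' columns) or, for unphased genotypes, Mendelian-consistent phase
#' configurations are enumerated and weighted by EM ([phase_families()]),
#' and family scores are flow-weighted across configurations.
#'
#' @param ped a pedigree tibble.
#' @param methods subset of `c("hPDT","vPDT","maxH","maxV","hPDT-t","vPDT-t")`.
#' @param B permutations for the maximum tests.
#' @param mu training threshold for the split tests (1.04 keeps units whose
#'   training-stage two-sided p is below 0.3).
#' @param train_fraction fraction of families (not individuals) assigned to
#'   the training split.
#' @param rare_range sample-MAF window defining a rare variant.
#' @param signed_max use the signed maximum (default); `FALSE` maximises
#'   `|Z|` instead.
#' @param founders_only estimate unit frequencies from founders only
#'   (default; keeps collapsing weights independent of the transmissions
#'   under the null -- see [pdt_scores()]).
#' @param seed optional RNG seed (permutations and the training split).
#' @param max_configs,em_tol,em_max_iter phasing controls for unphased input.
#' @return An object of class `pdt_test`; `tidy()` gives a tibble with one
#'   row per method (`method`, `statistic`, `p_value`, `n_perm`,
#'   `degenerate`).
#' @examples
#' ped <- sim_hap_pedigrees(50, sim_hap_setting(1), seed = 11)
#' fit <- pdt_test(ped, B = 200, seed = 1)
#' tidy(fit)
#' @export
pdt_test <- function(ped, methods = pdt_methods,
                     B = 1000, mu = 1.04, train_fraction = 0.3,
                     rare_range = c(0.001, 0.05), signed_max = TRUE,
                     founders_only = TRUE, seed = NULL,
                     max_configs = 4096, em_tol = 1e-6, em_max_iter = 500) {
  methods <- match.arg(methods, pdt_methods, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  cp <- as_cped(ped)

  need_h <- any(methods %in% c("hPDT", "maxH", "hPDT-t"))
  need_v <- any(methods %in% c("vPDT", "maxV", "vPDT-t"))
  si_h <- si_v <- NULL
  phases <- NULL
  if (need_h) {
    phased_ok <- cp$phased && !anyNA(cp$pat) && !anyNA(cp$mat)
    if (phased_ok) {
      si_h <- score_inputs_hap(cp, founders_only = founders_only)
    } else {
      phases <- phase_families(cped_to_tibble(cp, phased = FALSE),
                               max_configs = max_configs, tol = em_tol,
                               max_iter = em_max_iter)
      si_h <- score_inputs_hap_flows(cp, phases)
    }
  }
  if (need_v) {
    si_v <- score_inputs_var(cp, rare_range, founders_only = founders_only)
  }

  N <- length(unique(cp$fam))
  if (sum((si_h %||% si_v)$n_units_fam > 0) == 0) {
    warn("no informative families: all results are degenerate")
  }

  train <- NULL
  if (any(methods %in% c("hPDT-t", "vPDT-t"))) {
    if (N < 2) abort("the training-split tests need at least 2 families")
    train <- sample.int(N, max(1, round(train_fraction * N)))
  }

  rows <- list()
  add_row <- function(method, res, n_perm = 0L) {
    rows[[length(rows) + 1]] <<- tibble(
      method = method, statistic = res$statistic, p_value = res$p_value,
      n_perm = n_perm, degenerate = res$degenerate)
  }
  for (m in methods) {
    if (m == "hPDT") {
      add_row(m, collapse_stat(d_matrix(si_h), si_h$w))
    } else if (m == "vPDT") {
      add_row(m, collapse_stat(d_matrix(si_v), si_v$w))
    } else if (m %in% c("maxH", "maxV")) {
      si <- if (m == "maxH") si_h else si_v
      t_obs <- max_stat(unit_z_vec(d_matrix(si)), signed = signed_max)
      if (is.na(t_obs)) {
        add_row(m, list(statistic = 0, p_value = 1, degenerate = TRUE), B)
      } else {
        t_perm <- perm_max_stats(si, B, signed = signed_max)
        add_row(m, list(statistic = t_obs,
                        p_value = permutation_pvalue(t_obs, t_perm),
                        degenerate = FALSE), as.integer(B))
      }
    } else {
      si <- if (m == "hPDT-t") si_h else si_v
      add_row(m, trained_split_stat(si, train, mu))
    }
  }

  structure(list(
    results = dplyr::bind_rows(rows),
    n_families = N,
    n_informative = sum((si_h %||% si_v)$n_units_fam > 0),
    n_units_hap = if (!is.null(si_h)) si_h$K else NA_integer_,
    n_units_var = if (!is.null(si_v)) si_v$K else NA_integer_,
    train_families = train,
    phases = phases,
    B = B, mu = mu, train_fraction = train_fraction,
    rare_range = rare_range
  ), class = "pdt_test")
}

#' Training-split collapsing test
#'
#' Direct access to the hPDT-t / vPDT-t construction: a random family-level
#' split, per-unit statistics on the training families, signed thresholded
#' weights, and the collapsed statistic on the testing families.
#'
#' @inheritParams pdt_test
#' @param unit `"haplotype"` or `"variant"`.
#' @return One-row tibble: `statistic`, `p_value`, `degenerate`,
#'   `n_train`, `n_test`, `n_active` (units with nonzero trained weight).
#' @export
pdt_split_test <- function(ped, unit = c("haplotype", "variant"),
                           train_fraction = 0.3, mu = 1.04,
                           rare_range = c(0.001, 0.05), seed = NULL) {
  unit <- match.arg(unit)
  if (!is.null(seed)) set.seed(seed)
  cp <- as_cped(ped)
  si <- si_for(cp, unit, rare_range)
  N <- si$N
  if (N < 2) abort("the training-split tests need at least 2 families")
  train <- sample.int(N, max(1, round(train_fraction * N)))
  res <- trained_split_stat(si, train, mu)
  tibble(statistic = res$statistic, p_value = res$p_value,
         degenerate = res$degenerate,
         n_train = length(train), n_test = N - length(train),
         n_active = sum(res$weights != 0))
}

#' @export
print.pdt_test <- function(x, ...) {
  cat("<pdt_test> ", x$n_families, " families (",
      x$n_informative, " informative)", sep = "")
  if (!is.na(x$n_units_hap)) cat(", ", x$n_units_hap, " haplotype units", sep = "")
  if (!is.na(x$n_units_var)) cat(", ", x$n_units_var, " rare variants", sep = "")
  cat("\n")
  print(x$results)
  invisible(x)
}

#' @export
tidy.pdt_test <- function(x, ...) {
  x$results
}

#' @export
glance.pdt_test <- function(x, ...) {
  tibble(n_families = x$n_families,
         n_informative = x$n_informative,
         n_units_hap = x$n_units_hap,
         n_units_var = x$n_units_var,
         n_methods = nrow(x$results),
         p_min = min(x$results$p_value))
}

#' @export
autoplot.pdt_test <- function(object, ...) {
  d <- object$results
  d$method <- factor(d$method, levels = pdt_methods)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method,
                                  y = -log10(.data$p_value))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = "Pedigree disequilibrium tests") +
    ggplot2::theme_minimal()
}
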