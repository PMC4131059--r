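# Exported building blocks of the PDT family of tests. These mirror the
# internal engine on small, explicit inputs so that each step of the method
# can be inspected, tested and reused on its own.

#' Trio transmission score for a single unit
#'
#' For one case-parent trio and one analysis unit (a haplotype or the minor
#' allele of a variant), the score is the number of transmissions minus the
#' number of non-transmissions over the two parental meioses:
#' `sum(transmitted) - sum(untransmitted)`, an integer in `[-2, 2]`.
#'
#' @param transmitted length-2 vector: for each parent, 1 (or `TRUE`) if the
#'   haplotype transmitted to the affected child carries the unit, else 0.
#' @param untransmitted length-2 vector for the two untransmitted haplotypes.
#' @return Integer score in `[-2, 2]`.
#' @examples
#' trio_score(c(1, 0), c(0, 0))  # +1: one het carrier parent transmits
#' trio_score(c(0, 0), c(1, 1))  # -2: both het parents withhold the unit
#' @export
trio_score <- function(transmitted, untransmitted) {
  stopifnot(length(transmitted) == 2, length(untransmitted) == 2,
            all(transmitted %in% 0:1), all(untransmitted %in% 0:1))
  as.integer(sum(transmitted) - sum(untransmitted))
}

#' Discordant sib pair score for a single unit
#'
#' Number of copies of the unit carried by the affected sib minus the number
#' carried by the unaffected sib.
#'
#' @param affected,unaffected copy counts in `{0, 1, 2}`.
#' @return Integer score in `[-2, 2]`.
#' @export
sibpair_score <- function(affected, unaffected) {
  stopifnot(affected %in% 0:2, unaffected %in% 0:2)
  as.integer(affected - unaffected)
}

#' Per-family, per-unit PDT score table
#'
#' Computes the family summary scores
#' \eqn{D_i^{(k)} = (\sum_j D_{T_j}^{(k)} + \sum_j D_{S_j}^{(k)}) / (n_T + n_S)}
#' for every family `i` and unit `k`, where the sums run over the family's
#' case-parent trios and discordant sib pairs. Families contributing no unit
#' (`n_T + n_S = 0`) are flagged uninformative and score zero.
#'
#' In haplotype mode the units are the distinct haplotypes observed in the
#' sample minus the most frequent one; phased data (or [phase_families()]
#' output passed as `phases`) is required. In variant mode the units are the
#' sites whose sample minor-allele frequency lies within `rare_range`; phase
#' is not needed.
#'
#' @param ped a pedigree tibble.
#' @param unit `"haplotype"` or `"variant"`.
#' @param rare_range numeric length-2: the minor-allele-frequency window
#'   defining a rare variant (variant mode).
#' @param phases optional [phase_families()] result for unphased haplotype
#'   scoring (flow-weighted scores).
#' @param founders_only if `TRUE` (the default), estimate unit frequencies
#'   from founders only. Children's haplotypes are transmitted copies of
#'   parental ones, so frequencies taken over all individuals would absorb
#'   the very transmission counts being tested and bias the weighted
#'   statistics; founder-based estimates keep the weights independent of the
#'   transmissions under the null.
#' @return A long tibble with columns `family_id`, `unit`, `score`,
#'   `informative`, carrying attributes `units` (tibble of `unit`, `q`,
#'   `weight`), `lambda` (number of individuals) and `unit_kind`.
#' @examples
#' ped <- sim_hap_pedigrees(5, seed = 1)
#' pdt_scores(ped, unit = "haplotype")
#' @export
pdt_scores <- function(ped, unit = c("haplotype", "variant"),
                       rare_range = c(0.001, 0.05), phases = NULL,
                       founders_only = TRUE) {
  unit <- match.arg(unit)
  cp <- as_cped(ped)
  si <- si_for(cp, unit, rare_range, phases, founders_only)
  si_to_scores(si)
}

si_for <- function(cp, unit, rare_range, phases = NULL,
                   founders_only = TRUE) {
  if (unit == "variant") {
    score_inputs_var(cp, rare_range, founders_only = founders_only)
  } else if (!is.null(phases)) {
    score_inputs_hap_flows(cp, phases)
  } else {
    score_inputs_hap(cp, founders_only = founders_only)
  }
}

si_to_scores <- function(si) {
  D <- d_matrix(si)
  out <- tibble(
    family_id = rep(si$fam_ids, times = si$K),
    unit = rep(si$unit_labels, each = si$N),
    score = as.vector(D),
    informative = rep(si$n_units_fam > 0, times = si$K))
  attr(out, "units") <- tibble(unit = si$unit_labels, q = si$q,
                               weight = si$w)
  attr(out, "lambda") <- si$lambda
  attr(out, "unit_kind") <- si$kind
  out
}

# accept either a families x units matrix or the long tibble from pdt_scores
scores_to_matrix <- function(scores) {
  if (is.matrix(scores)) return(scores)
  stopifnot(is.data.frame(scores),
            all(c("family_id", "unit", "score") %in% names(scores)))
  wide <- tidyr::pivot_wider(scores[c("family_id", "unit", "score")],
                             names_from = "unit", values_from = "score")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$family_id
  # preserve the original unit order
  m[, unique(scores$unit), drop = FALSE]
}

#' Frequency-based collapsing weights
#'
#' The weight of unit `k` is \eqn{w_k = 1 / \sqrt{\lambda q_k (1 - q_k)}},
#' the inverse of the estimated binomial standard deviation of the unit count
#' over `lambda` individuals, so rarer units receive larger weights. Units
#' with `q` of exactly 0 or 1 carry no information and are given weight `NA`
#' with a warning.
#'
#' @param q unit (haplotype or minor-allele) frequencies in `[0, 1]`.
#' @param lambda total number of individuals in the families analysed.
#' @return Numeric vector of weights, same length as `q`.
#' @examples
#' frequency_weights(0.5, 1)            # 2
#' frequency_weights(0.01, 1000)        # ~ 0.318
#' @export
frequency_weights <- function(q, lambda) {
  stopifnot(is.numeric(q), all(q >= 0 & q <= 1, na.rm = TRUE),
            is.numeric(lambda), length(lambda) == 1, lambda > 0)
  fixed <- !is.na(q) & (q == 0 | q == 1)
  if (any(fixed)) {
    warn(sprintf("%d unit(s) with frequency 0 or 1 excluded from weighting",
                 sum(fixed)))
  }
  ifelse(fixed, NA_real_, 1 / sqrt(lambda * q * (1 - q)))
}

#' Collapsed PDT statistic
#'
#' Collapses per-family, per-unit scores into the weighted family summaries
#' \eqn{D_i = \sum_k w_k D_i^{(k)}} and the statistic
#' \eqn{Z = \sum_i D_i / \sqrt{\sum_i D_i^2}}, which is asymptotically
#' standard normal under the null hypothesis of no association; the reported
#' p-value is the two-sided normal tail. If all weights are zero or every
#' family scores zero the result is degenerate with `p_value = 1`.
#'
#' @param scores a families x units score matrix, or the long tibble from
#'   [pdt_scores()].
#' @param weights per-unit weights; defaults to the frequency weights
#'   attached to a [pdt_scores()] tibble.
#' @return One-row tibble: `statistic`, `p_value`, `degenerate`.
#' @examples
#' collapsed_statistic(matrix(c(2, 1, 1), 3, 1), 1)  # Z = 4 / sqrt(6)
#' @export
collapsed_statistic <- function(scores, weights = NULL) {
  D <- scores_to_matrix(scores)
  if (is.null(weights)) {
    u <- attr(scores, "units")
    if (is.null(u)) {
      abort("`weights` must be given when `scores` carries no units attribute")
    }
    weights <- u$weight[match(colnames(D), u$unit)]
  }
  stopifnot(length(weights) == ncol(D))
  weights[is.na(weights)] <- 0
  res <- collapse_stat(D, weights)
  tibble(statistic = res$statistic, p_value = res$p_value,
         degenerate = res$degenerate)
}

#' Per-unit PDT statistics
#'
#' \eqn{Z^{(k)} = \sum_i D_i^{(k)} / \sqrt{\sum_i (D_i^{(k)})^2}} for each
#' unit; a unit whose scores are all zero gets `z = 0`.
#'
#' @inheritParams collapsed_statistic
#' @return Tibble with columns `unit`, `z`.
#' @export
per_unit_z <- function(scores) {
  D <- scores_to_matrix(scores)
  tibble(unit = colnames(D) %||% paste0("u", seq_len(ncol(D))),
         z = unit_z_vec(D))
}

#' Maximum single-unit statistic
#'
#' The maximal tests (maxH over haplotypes excluding the most frequent one,
#' maxV over rare variants) use the signed maximum \eqn{T = \max_k Z^{(k)}}
#' of the per-unit statistics; set `signed = FALSE` for the two-sided
#' variant \eqn{\max_k |Z^{(k)}|}.
#'
#' @param z numeric vector of per-unit statistics, or the tibble from
#'   [per_unit_z()].
#' @param signed use the signed maximum (default) or the maximum absolute
#'   value.
#' @return One-row tibble: `statistic`, `degenerate` (`TRUE` when there are
#'   no units, in which case `statistic` is `NA`).
#' @export
max_statistic <- function(z, signed = TRUE) {
  if (is.data.frame(z)) z <- z$z
  tibble(statistic = max_stat(z, signed = signed),
         degenerate = length(z) == 0)
}

#' Permutation p-value
#'
#' Add-one permutation p-value
#' \eqn{\hat p = (1 + \#\{b : T_b \ge T\}) / (B + 1)}; ties count as
#' exceedances and the estimate is never zero.
#'
#' @param t_obs observed statistic.
#' @param t_perm numeric vector of `B` statistics computed on permuted data.
#' @return p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(t_obs, t_perm) {
  stopifnot(length(t_obs) == 1, length(t_perm) >= 1)
  (1 + sum(t_perm >= t_obs)) / (length(t_perm) + 1)
}

#' Pooled permutation p-values across simulation replicates
#'
#' In a simulation with `R` replicates sharing one null-generating design,
#' the permuted statistics of all replicates form a joint sample of size
#' `B * R` from the common null distribution, so each replicate's p-value can
#' be computed against the pooled sample:
#' \eqn{p_r = (1 + \#\{(r', b) : T_{r'b} \ge T_r\}) / (BR + 1)}. With
#' `R = 1000` replicates, `B = 10` permutations each give the resolution of
#' 10,000 permutations per replicate.
#'
#' @param t_obs numeric vector of `R` observed statistics.
#' @param t_perm an `R x B` matrix (or vector) of permuted statistics.
#' @return Numeric vector of `R` p-values. `NA` observed statistics
#'   (degenerate replicates) give `NA`.
#' @export
pooled_permutation_pvalues <- function(t_obs, t_perm) {
  pool <- sort(as.vector(t_perm[!is.na(t_perm)]))
  nb <- length(pool)
  stopifnot(nb >= 1)
  # count of pool values >= t via binary search on the sorted pool
  ge <- nb - findInterval(t_obs, pool, left.open = TRUE)
  ifelse(is.na(t_obs), NA_real_, (1 + ge) / (nb + 1))
}

#' Training-split signed weights
#'
#' Converts per-unit statistics estimated on a training subset of families
#' into signed, thresholded collapsing weights:
#' \eqn{w'_k = \mathrm{sign}(Z^{(k)}_{train}) w_k} when
#' \eqn{|Z^{(k)}_{train}| > \mu}, else 0. The default threshold
#' `mu = 1.04` is the two-sided standard-normal critical value for a
#' training-stage type I error of 0.3, chosen to preserve more nonzero
#' weights (1.28 and 1.64 correspond to 0.2 and 0.1).
#'
#' @param z_train per-unit statistics from the training families (vector or
#'   [per_unit_z()] tibble).
#' @param weights base frequency weights `w_k` (computed on all data).
#' @param mu training threshold.
#' @return Numeric vector of signed weights (entries in `{-w_k, 0, +w_k}`).
#' @examples
#' trained_weights(c(0.5, -2.0), c(1, 3))  # 0, -3
#' @export
trained_weights <- function(z_train, weights, mu = 1.04) {
  if (is.data.frame(z_train)) z_train <- z_train$z
  stopifnot(length(z_train) == length(weights), mu >= 0)
  weights[is.na(weights)] <- 0
  ifelse(abs(z_train) > mu, sign(z_train) * weights, 0)
}
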