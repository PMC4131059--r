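# Phase-configuration enumeration and EM over gene flows for nuclear
# families with unphased (possibly partially missing) genotypes.

#' Enumerate Mendelian-consistent phase configurations
#'
#' For each nuclear family, enumerates every assignment of an ordered
#' haplotype pair to each member ("gene flow") that is consistent with the
#' observed genotypes, assigns children one haplotype from each parent, and
#' assumes no recombination within the region. Missing sites are enumerated
#' over both alleles. Configurations start with uniform weights; run
#' [em_hap_frequencies()] (or use [phase_families()]) to estimate haplotype
#' frequencies and configuration weights jointly.
#'
#' @param ped a pedigree tibble (genotypes required, phase ignored).
#' @param max_configs abort with an "ambiguity overflow" error if a family
#'   admits more configurations than this cap; prune sites or individuals in
#'   that case.
#' @return An object of class `ped_phases`: a list with a haplotype
#'   `catalog` (matrix + string keys), initial `freq` (uniform-weight founder
#'   counting), and per-family configuration lists. `tidy()` renders it as a
#'   tibble. Families whose genotypes admit no consistent configuration get
#'   an empty configuration list.
#' @export
enumerate_phases <- function(ped, max_configs = 4096) {
  cp <- as_cped(ped, require_phased = FALSE)
  fam_list <- list()
  all_haps <- list()
  for (f in seq_along(cp$fam_id)) {
    members <- which(cp$fam == f)
    cfgs <- enumerate_family_configs(cp, members, max_configs)
    fam_list[[f]] <- list(fam = f, family_id = cp$fam_id[f],
                          members = members, raw = cfgs)
    for (cfg in cfgs) {
      all_haps[[length(all_haps) + 1]] <- cfg$pat
      all_haps[[length(all_haps) + 1]] <- cfg$mat
    }
  }
  if (length(all_haps) == 0) {
    catalog <- list(key = character(0),
                    hap = matrix(integer(), 0, cp$M))
  } else {
    hm <- do.call(rbind, all_haps)
    keys <- hap_keys(hm)
    uk <- sort(unique(keys))
    catalog <- list(key = uk, hap = hm[match(uk, keys), , drop = FALSE])
  }

  families <- lapply(fam_list, function(fl) {
    configs <- lapply(fl$raw, function(cfg) {
      list(pat = match(hap_keys(cfg$pat), catalog$key),
           mat = match(hap_keys(cfg$mat), catalog$key))
    })
    nc <- length(configs)
    list(fam = fl$fam, family_id = fl$family_id, members = fl$members,
         configs = configs,
         weights = if (nc > 0) rep(1 / nc, nc) else numeric(0))
  })

  out <- list(catalog = catalog,
              freq = founder_freq(families, catalog, cp),
              families = families,
              cp = cp,
              loglik = numeric(0),
              converged = NA)
  class(out) <- "ped_phases"
  out
}

# founder haplotype frequencies under the current configuration weights
founder_freq <- function(families, catalog, cp) {
  H <- length(catalog$key)
  if (H == 0) return(numeric(0))
  cnt <- numeric(H)
  tot <- 0
  for (fl in families) {
    if (length(fl$configs) == 0) next
    founders <- which(is.na(cp$father[fl$members]))
    for (ci in seq_along(fl$configs)) {
      cfg <- fl$configs[[ci]]
      idx <- c(cfg$pat[founders], cfg$mat[founders])
      cnt <- cnt + fl$weights[ci] * tabulate(idx, nbins = H)
      tot <- tot + fl$weights[ci] * length(idx)
    }
  }
  if (tot == 0) rep(0, H) else cnt / tot
}

# All phased ordered completions of one genotype vector (NA = missing).
phased_completions <- function(g, cap) {
  opts <- lapply(g, function(x) {
    if (is.na(x)) {
      cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
    } else if (x == 0) {
      cbind(0L, 0L)
    } else if (x == 2) {
      cbind(1L, 1L)
    } else {
      cbind(c(0L, 1L), c(1L, 0L))
    }
  })
  n <- prod(vapply(opts, nrow, numeric(1)))
  if (n > cap) {
    abort(paste0("ambiguity overflow: a single genotype admits ", n,
                 " phased completions (cap ", cap,
                 "); prune sites before phasing"),
          class = "rvpdt_ambiguity_overflow")
  }
  idx <- expand.grid(lapply(opts, function(o) seq_len(nrow(o))),
                     KEEP.OUT.ATTRS = FALSE)
  h1 <- vapply(seq_along(opts), function(j) opts[[j]][idx[[j]], 1],
               integer(nrow(idx)))
  h2 <- vapply(seq_along(opts), function(j) opts[[j]][idx[[j]], 2],
               integer(nrow(idx)))
  if (nrow(idx) == 1) {
    h1 <- matrix(h1, 1)
    h2 <- matrix(h2, 1)
  }
  list(h1 = h1, h2 = h2)
}

# unordered deduplication of a parent's phased pairs
parent_pairs <- function(g, cap) {
  pc <- phased_completions(g, cap)
  k1 <- hap_keys(pc$h1)
  k2 <- hap_keys(pc$h2)
  key <- paste(pmin(k1, k2), pmax(k1, k2))
  keep <- !duplicated(key)
  lapply(which(keep), function(i) {
    rbind(pc$h1[i, ], pc$h2[i, ])
  })
}

# Enumerate configurations for one family (cp row indices `members`).
# Returns a list of configs, each with pat/mat matrices (rows = members, in
# `members` order; parents get an arbitrary but fixed hap order).
enumerate_family_configs <- function(cp, members, max_configs) {
  father <- cp$father[members]
  mother <- cp$mother[members]
  is_kid <- !is.na(father)
  founders <- members[!is_kid]
  kids <- members[is_kid]
  if (length(founders) == 0) return(list())
  if (length(founders) > 2 || length(unique(father[is_kid])) > 1 ||
      length(unique(mother[is_kid])) > 1) {
    abort("phasing supports nuclear families only; pre-split the pedigree")
  }
  if (length(kids) == 0) {
    # no children: each founder phases independently; keep the first-founder
    # enumeration only to the extent needed (still bounded by the cap)
    fa_pairs <- lapply(founders, function(i) {
      parent_pairs(cp$geno[i, ], max_configs)
    })
    n <- prod(lengths(fa_pairs))
    if (n > max_configs) {
      abort("ambiguity overflow: too many phase configurations; prune sites",
            class = "rvpdt_ambiguity_overflow")
    }
    grid <- expand.grid(lapply(fa_pairs, seq_along), KEEP.OUT.ATTRS = FALSE)
    return(lapply(seq_len(nrow(grid)), function(r) {
      pat <- do.call(rbind, lapply(seq_along(founders), function(j) {
        fa_pairs[[j]][[grid[r, j]]][1, ]
      }))
      mat <- do.call(rbind, lapply(seq_along(founders), function(j) {
        fa_pairs[[j]][[grid[r, j]]][2, ]
      }))
      list(pat = pat, mat = mat)
    }))
  }

  fa <- unique(father[is_kid])
  mo <- unique(mother[is_kid])
  fp <- parent_pairs(cp$geno[fa, ], max_configs)
  mp <- parent_pairs(cp$geno[mo, ], max_configs)

  configs <- list()
  seen <- character(0)
  for (F in fp) {
    for (Mo in mp) {
      # per-child consistent (paternal, maternal) choices
      kid_opts <- lapply(kids, function(k) {
        g <- cp$geno[k, ]
        opts <- list()
        for (i in 1:2) {
          for (j in 1:2) {
            implied <- F[i, ] + Mo[j, ]
            if (all(is.na(g) | implied == g)) {
              opts[[length(opts) + 1]] <- c(i, j)
            }
          }
        }
        unique(opts)
      })
      if (any(lengths(kid_opts) == 0)) next
      n_new <- prod(lengths(kid_opts))
      if (length(configs) + n_new > max_configs) {
        abort(paste0("ambiguity overflow: family admits more than ",
                     max_configs,
                     " phase configurations; prune sites before phasing"),
              class = "rvpdt_ambiguity_overflow")
      }
      grid <- expand.grid(lapply(kid_opts, seq_along),
                          KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(grid))) {
        nmem <- length(members)
        pat <- matrix(NA_integer_, nmem, cp$M)
        mat <- matrix(NA_integer_, nmem, cp$M)
        # canonical parent order: lexicographically smaller hap first
        ford <- order(hap_keys(F))
        mord <- order(hap_keys(Mo))
        pat[match(fa, members), ] <- F[ford[1], ]
        mat[match(fa, members), ] <- F[ford[2], ]
        pat[match(mo, members), ] <- Mo[mord[1], ]
        mat[match(mo, members), ] <- Mo[mord[2], ]
        for (kk in seq_along(kids)) {
          ij <- kid_opts[[kk]][[grid[r, kk]]]
          pat[match(kids[kk], members), ] <- F[ij[1], ]
          mat[match(kids[kk], members), ] <- Mo[ij[2], ]
        }
        key <- paste(c(hap_keys(pat), hap_keys(mat)), collapse = "|")
        if (!key %in% seen) {
          seen <- c(seen, key)
          configs[[length(configs) + 1]] <- list(pat = pat, mat = mat)
        }
      }
    }
  }
  configs
}

#' Estimate haplotype frequencies and flow weights by EM
#'
#' Treats each family's phase configurations as the missing data of a
#' finite-mixture model under random mating: the E-step sets a
#' configuration's weight proportional to the product of the current
#' frequencies of its four founder haplotypes; the M-step re-estimates the
#' frequencies from the weighted founder haplotype counts. Only founders
#' enter the frequency estimates (children's haplotypes are transmitted
#' copies). The observed-data log-likelihood is non-decreasing across
#' iterations; iteration stops when no frequency moves by more than `tol`.
#'
#' @param phases a `ped_phases` object from [enumerate_phases()].
#' @param tol convergence threshold on the haplotype frequencies.
#' @param max_iter maximum number of EM iterations; if reached without
#'   convergence the last iterate is returned with `converged = FALSE`.
#' @return The updated `ped_phases` object with fields `freq` (haplotype
#'   frequencies), per-family `weights` summing to one, `loglik` (the
#'   per-iteration log-likelihood trace) and `converged`.
#' @export
em_hap_frequencies <- function(phases, tol = 1e-6, max_iter = 500) {
  stopifnot(inherits(phases, "ped_phases"))
  cp <- phases$cp
  H <- length(phases$catalog$key)
  if (H == 0) {
    phases$converged <- TRUE
    return(phases)
  }
  fams <- Filter(function(fl) length(fl$configs) > 0, phases$families)
  # per-family founder-index matrix (configs x founder chromosomes)
  fidx <- lapply(fams, function(fl) {
    founders <- which(is.na(cp$father[fl$members]))
    t(vapply(fl$configs, function(cfg) {
      c(cfg$pat[founders], cfg$mat[founders])
    }, integer(2 * length(founders))))
  })

  q <- phases$freq
  if (sum(q) == 0) q <- rep(1 / H, H)
  loglik <- numeric(0)
  converged <- FALSE
  weights <- lapply(fams, function(fl) fl$weights)

  for (it in seq_len(max_iter)) {
    ll <- 0
    cnt <- numeric(H)
    tot <- 0
    for (fi in seq_along(fams)) {
      Fx <- fidx[[fi]]
      L <- apply(Fx, 1, function(ix) prod(q[ix]))
      sL <- sum(L)
      w <- if (sL > 0) L / sL else rep(1 / length(L), length(L))
      ll <- ll + if (sL > 0) log(sL) else -Inf
      weights[[fi]] <- w
      for (ci in seq_len(nrow(Fx))) {
        cnt <- cnt + w[ci] * tabulate(Fx[ci, ], nbins = H)
      }
      tot <- tot + ncol(Fx)
    }
    loglik <- c(loglik, ll)
    q_new <- if (tot > 0) cnt / tot else q
    delta <- max(abs(q_new - q))
    q <- q_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  wi <- 1
  for (i in seq_along(phases$families)) {
    if (length(phases$families[[i]]$configs) > 0) {
      phases$families[[i]]$weights <- weights[[wi]]
      wi <- wi + 1
    }
  }
  phases$freq <- q
  phases$loglik <- loglik
  phases$converged <- converged
  phases
}

#' Phase a pedigree set: enumeration plus EM
#'
#' Convenience wrapper chaining [enumerate_phases()] and
#' [em_hap_frequencies()].
#'
#' @inheritParams enumerate_phases
#' @inheritParams em_hap_frequencies
#' @return A converged (or flagged) `ped_phases` object.
#' @export
phase_families <- function(ped, max_configs = 4096, tol = 1e-6,
                           max_iter = 500) {
  em_hap_frequencies(enumerate_phases(ped, max_configs = max_configs),
                     tol = tol, max_iter = max_iter)
}

#' Flow-weighted family scores
#'
#' Applies a per-configuration family scorer to every phase configuration and
#' returns the weighted combination
#' \eqn{D_i = \sum_f \mathrm{Weight}^{(f)} D_i^{(f)}} for each family, the
#' modification of the family scores used when phase is ambiguous.
#'
#' @param phases a `ped_phases` object (weights normalised, e.g. after EM).
#' @param score_fn a function taking one configuration -- a list with
#'   `family_id`, `member_id`, and `pat`/`mat` allele matrices (rows =
#'   members) -- and returning a numeric scalar or vector.
#' @return A tibble with `family_id` and `score` (a list-column when
#'   `score_fn` returns vectors). Families without configurations get `NA`.
#' @export
flow_weighted_scores <- function(phases, score_fn) {
  stopifnot(inherits(phases, "ped_phases"), is.function(score_fn))
  cp <- phases$cp
  hap <- phases$catalog$hap
  res <- purrr::map(phases$families, function(fl) {
    if (length(fl$configs) == 0) return(NA_real_)
    parts <- purrr::map2(fl$configs, fl$weights, function(cfg, w) {
      w * score_fn(list(
        family_id = fl$family_id,
        member_id = cp$id[fl$members],
        pat = hap[cfg$pat, , drop = FALSE],
        mat = hap[cfg$mat, , drop = FALSE]))
    })
    Reduce(`+`, parts)
  })
  scalar <- all(vapply(res, length, integer(1)) == 1)
  tibble(
    family_id = vapply(phases$families, `[[`, character(1), "family_id"),
    score = if (scalar) unlist(res) else res)
}

#' @export
tidy.ped_phases <- function(x, ...) {
  rows <- purrr::map(x$families, function(fl) {
    if (length(fl$configs) == 0) return(NULL)
    purrr::imap(fl$configs, function(cfg, ci) {
      tibble(family_id = fl$family_id, config = ci,
             member_id = x$cp$id[fl$members],
             hap_pat = x$catalog$key[cfg$pat],
             hap_mat = x$catalog$key[cfg$mat],
             weight = fl$weights[ci])
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' @export
print.ped_phases <- function(x, ...) {
  nc <- vapply(x$families, function(fl) length(fl$configs), integer(1))
  cat("<ped_phases> ", length(x$families), " families, ",
      length(x$catalog$key), " haplotypes\n", sep = "")
  cat("  configurations per family: ",
      paste(range(nc), collapse = "-"), "\n", sep = "")
  if (length(x$loglik)) {
    cat("  EM: ", length(x$loglik), " iterations, converged = ",
        x$converged, "\n", sep = "")
  }
  invisible(x)
}
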