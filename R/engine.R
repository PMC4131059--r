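# Internal scoring engine. Everything here works on the compact pedigree
# representation (see as_cped) and plain matrices; the tidy user-facing
# wrappers live in pdt-components.R / pdt-test.R.

# concatenate allele columns into one string key per haplotype row
hap_keys <- function(m) {
  if (ncol(m) == 0) return(rep("", nrow(m)))
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

# catalog of distinct haplotypes: lexicographic order, frequencies over the
# supplied chromosomes, most-frequent index with ties to the lowest index
build_catalog <- function(hmat) {
  keys <- hap_keys(hmat)
  uk <- sort(unique(keys))
  idx <- match(keys, uk)
  freq <- tabulate(idx, nbins = length(uk)) / length(idx)
  list(key = uk,
       hap = hmat[match(uk, keys), , drop = FALSE],
       freq = freq,
       most = which.max(freq),
       idx = idx)
}

# score-input object `si`:
#   kind        "haplotype" | "variant"
#   unit_labels, K, q, w, lambda
#   Cm (meiosis rows x K), fam_m, mult_m   -- trio transmission contributions
#   Cs (DSP rows x K),     fam_s, mult_s   -- sib-pair contributions
#   n_units_fam (n_T + n_S per family), N, fam_ids

new_si <- function(kind, unit_labels, q, lambda, Cm, fam_m, Cs, fam_s,
                   n_units_fam, fam_ids, mult_m = NULL, mult_s = NULL) {
  K <- length(unit_labels)
  w <- if (K > 0) 1 / sqrt(lambda * q * (1 - q)) else numeric(0)
  list(kind = kind, unit_labels = unit_labels, K = K, q = q, w = w,
       lambda = lambda,
       Cm = Cm, fam_m = fam_m,
       mult_m = mult_m %||% rep(1, length(fam_m)),
       Cs = Cs, fam_s = fam_s,
       mult_s = mult_s %||% rep(1, length(fam_s)),
       n_units_fam = n_units_fam, N = length(n_units_fam), fam_ids = fam_ids)
}

# per-family score matrix D (families x units); optionally restricted to a
# subset of family indices (rows of the result follow `fams` order)
d_matrix <- function(si, Cm = si$Cm, Cs = si$Cs, fams = NULL) {
  if (is.null(fams)) fams <- seq_len(si$N)
  D <- matrix(0, length(fams), si$K)
  if (si$K == 0 || length(fams) == 0) {
    return(D)
  }
  pos <- rep(NA_integer_, si$N)
  pos[fams] <- seq_along(fams)
  add <- function(D, C, f, mult) {
    if (is.null(C) || nrow(C) == 0) return(D)
    keep <- !is.na(pos[f])
    if (!any(keep)) return(D)
    A <- rowsum(C[keep, , drop = FALSE] * mult[keep], pos[f][keep])
    r <- as.integer(rownames(A))
    D[r, ] <- D[r, , drop = FALSE] + A
    D
  }
  D <- add(D, Cm, si$fam_m, si$mult_m)
  D <- add(D, Cs, si$fam_s, si$mult_s)
  D / pmax(si$n_units_fam[fams], 1)
}

# per-unit PDT statistics Z^(k) = sum_i D_i^(k) / sqrt(sum_i D_i^(k)^2)
unit_z_vec <- function(D) {
  s <- colSums(D)
  ss <- sqrt(colSums(D * D))
  ifelse(ss > 0, s / ss, 0)
}

# collapsed statistic Z = sum_i D_i / sqrt(sum_i D_i^2), D_i = sum_k w_k D_i^(k)
collapse_stat <- function(D, w) {
  if (length(w) == 0 || all(w == 0)) {
    return(list(statistic = 0, p_value = 1, degenerate = TRUE))
  }
  d <- as.vector(D %*% w)
  ss <- sum(d * d)
  if (ss <= 0) {
    return(list(statistic = 0, p_value = 1, degenerate = TRUE))
  }
  z <- sum(d) / sqrt(ss)
  list(statistic = z, p_value = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

max_stat <- function(z, signed = TRUE) {
  if (length(z) == 0) return(NA_real_)
  if (signed) max(z) else max(abs(z))
}

# transmission permutation: each meiosis independently flips which parental
# haplotype counts as transmitted (haplotype mode: one sign per meiosis;
# variant mode: independent sign per meiosis and site); each DSP swaps sib
# labels with probability 1/2 (one sign per pair)
perm_max_stats <- function(si, B, per_site = identical(si$kind, "variant"),
                           signed = TRUE) {
  if (si$K == 0) return(rep(NA_real_, B))
  nm <- nrow(si$Cm)
  ns <- nrow(si$Cs)
  vapply(seq_len(B), function(b) {
    Cm <- si$Cm
    if (nm > 0) {
      s <- if (per_site) {
        matrix(sample(c(-1, 1), nm * si$K, replace = TRUE), nm)
      } else {
        sample(c(-1, 1), nm, replace = TRUE)
      }
      Cm <- Cm * s
    }
    Cs <- si$Cs
    if (ns > 0) {
      Cs <- Cs * sample(c(-1, 1), ns, replace = TRUE)
    }
    max_stat(unit_z_vec(d_matrix(si, Cm, Cs)), signed = signed)
  }, numeric(1))
}

# training-split signed-weight test: unit directions learned on `train`
# families, collapsed statistic evaluated on the complement
trained_split_stat <- function(si, train, mu) {
  test <- setdiff(seq_len(si$N), train)
  zt <- unit_z_vec(d_matrix(si, fams = train))
  w2 <- ifelse(abs(zt) > mu, sign(zt) * si$w, 0)
  res <- collapse_stat(d_matrix(si, fams = test), w2)
  res$weights <- w2
  res$z_train <- zt
  res
}

# incremental cell update helper: one target cell per row, cols may be NA
add_cells <- function(C, rows, cols, delta) {
  ok <- !is.na(cols)
  if (!any(ok)) return(C)
  idx <- cbind(rows[ok], cols[ok])
  C[idx] <- C[idx] + delta
  C
}

# ---- haplotype-mode score inputs ------------------------------------------

# Build meiosis/DSP contribution rows for one set of per-individual haplotype
# indices (global catalog indices). unit_col maps catalog index -> column.
build_hap_rows <- function(trio, dsp, pi_, mi_, unit_col, K) {
  nt <- nrow(trio)
  Cm <- matrix(0, 2 * nt, K)
  drop_trio <- logical(nt)
  if (nt > 0) {
    tf <- pi_[trio$child]
    pf <- pi_[trio$father]
    mf <- mi_[trio$father]
    uf <- ifelse(!is.na(pf) & pf == tf, mf,
                 ifelse(!is.na(mf) & mf == tf, pf, NA_integer_))
    tm <- mi_[trio$child]
    pm <- pi_[trio$mother]
    mm <- mi_[trio$mother]
    um <- ifelse(!is.na(pm) & pm == tm, mm,
                 ifelse(!is.na(mm) & mm == tm, pm, NA_integer_))
    drop_trio <- is.na(uf) | is.na(um) | is.na(tf) | is.na(tm)
    rf <- seq_len(nt)
    rm_ <- nt + seq_len(nt)
    keep <- !drop_trio
    Cm <- add_cells(Cm, rf[keep], unit_col[tf[keep]], +1)
    Cm <- add_cells(Cm, rf[keep], unit_col[uf[keep]], -1)
    Cm <- add_cells(Cm, rm_[keep], unit_col[tm[keep]], +1)
    Cm <- add_cells(Cm, rm_[keep], unit_col[um[keep]], -1)
  }
  nd <- nrow(dsp)
  Cs <- matrix(0, nd, K)
  if (nd > 0) {
    rd <- seq_len(nd)
    Cs <- add_cells(Cs, rd, unit_col[pi_[dsp$aff]], +1)
    Cs <- add_cells(Cs, rd, unit_col[mi_[dsp$aff]], +1)
    Cs <- add_cells(Cs, rd, unit_col[pi_[dsp$un]], -1)
    Cs <- add_cells(Cs, rd, unit_col[mi_[dsp$un]], -1)
  }
  list(Cm = Cm, fam_m = c(trio$fam, trio$fam), Cs = Cs, fam_s = dsp$fam,
       drop_trio = drop_trio)
}

# score inputs in haplotype mode from fully phased data
score_inputs_hap <- function(cp, exclude_most = TRUE, founders_only = TRUE) {
  if (is.null(cp$pat)) {
    abort("haplotype-mode scoring requires phased haplotypes (or run phase_families() first)")
  }
  complete <- rowSums(is.na(cp$pat)) == 0 & rowSums(is.na(cp$mat)) == 0
  if (!any(complete)) {
    abort("no individuals with complete phased haplotypes")
  }
  freq_rows <- if (founders_only) {
    complete & is.na(cp$father)
  } else {
    complete
  }
  cat <- build_catalog(rbind(cp$pat[freq_rows, , drop = FALSE],
                             cp$mat[freq_rows, , drop = FALSE]))
  pi_ <- mi_ <- rep(NA_integer_, cp$n)
  pi_[complete] <- match(hap_keys(cp$pat[complete, , drop = FALSE]), cat$key)
  mi_[complete] <- match(hap_keys(cp$mat[complete, , drop = FALSE]), cat$key)
  # haplotypes carried only by non-frequency individuals: extend catalog
  if (anyNA(pi_[complete]) || anyNA(mi_[complete])) {
    extra <- unique(c(
      hap_keys(cp$pat[complete, , drop = FALSE]),
      hap_keys(cp$mat[complete, , drop = FALSE])))
    extra <- setdiff(extra, cat$key)
    allk <- sort(c(cat$key, extra))
    freq <- setNames(numeric(length(allk)), allk)
    freq[cat$key] <- cat$freq
    hm <- rbind(cp$pat[complete, , drop = FALSE], cp$mat[complete, , drop = FALSE])
    cat <- list(key = allk, hap = hm[match(allk, hap_keys(hm)), , drop = FALSE],
                freq = unname(freq), most = which.max(unname(freq)))
    pi_[complete] <- match(hap_keys(cp$pat[complete, , drop = FALSE]), cat$key)
    mi_[complete] <- match(hap_keys(cp$mat[complete, , drop = FALSE]), cat$key)
  }

  H <- length(cat$key)
  units <- seq_len(H)
  if (exclude_most && H > 0) units <- setdiff(units, cat$most)
  units <- units[cat$freq[units] > 0 & cat$freq[units] < 1]
  unit_col <- rep(NA_integer_, H)
  unit_col[units] <- seq_along(units)

  u <- cped_units(cp, typed_trio = complete, typed_dsp = complete)
  rows <- build_hap_rows(u$trio, u$dsp, pi_, mi_, unit_col, length(units))
  n_units_fam <- u$n_units_fam
  if (any(rows$drop_trio)) {
    warn(sprintf("%d trio(s) dropped: child haplotype matches neither parental haplotype",
                 sum(rows$drop_trio)))
    n_units_fam <- n_units_fam - tabulate(u$trio$fam[rows$drop_trio],
                                          nbins = length(cp$fam_id))
  }
  new_si("haplotype", cat$key[units], cat$freq[units], cp$n,
         rows$Cm, rows$fam_m, rows$Cs, rows$fam_s, n_units_fam, cp$fam_id)
}

# ---- variant-mode score inputs --------------------------------------------

# Per-meiosis transmitted allele at each site. Homozygous parents are forced;
# heterozygous parents are resolved from the child's genotype and the other
# parent (phased child haplotypes override when available). When both parents
# are heterozygous and the child is too, the split is arbitrary: the total
# trio score and the permutation distribution are unaffected.
resolve_transmissions <- function(Gf, Gm, Gc, Pf = NULL, Pm = NULL) {
  Tf <- matrix(NA_real_, nrow(Gc), ncol(Gc))
  Tm <- Tf
  Tf[!is.na(Gf) & Gf == 0] <- 0
  Tf[!is.na(Gf) & Gf == 2] <- 1
  Tm[!is.na(Gm) & Gm == 0] <- 0
  Tm[!is.na(Gm) & Gm == 2] <- 1
  if (!is.null(Pf)) {
    i <- !is.na(Pf)
    Tf[i] <- Pf[i]
  }
  if (!is.null(Pm)) {
    i <- !is.na(Pm)
    Tm[i] <- Pm[i]
  }
  i <- is.na(Tf) & !is.na(Tm) & !is.na(Gc)
  Tf[i] <- Gc[i] - Tm[i]
  i <- is.na(Tm) & !is.na(Tf) & !is.na(Gc)
  Tm[i] <- Gc[i] - Tf[i]
  i <- is.na(Tf) & is.na(Tm) & !is.na(Gc)
  Tf[i] <- pmin(Gc[i], 1)
  Tm[i] <- Gc[i] - Tf[i]
  Tf[!is.na(Tf) & (Tf < 0 | Tf > 1)] <- NA_real_
  Tm[!is.na(Tm) & (Tm < 0 | Tm > 1)] <- NA_real_
  list(Tf = Tf, Tm = Tm)
}

score_inputs_var <- function(cp, rare_range = c(0.001, 0.05),
                             founders_only = TRUE) {
  if (cp$M == 0) {
    abort("pedigree has no genotyped sites")
  }
  freq_rows <- if (founders_only) is.na(cp$father) else rep(TRUE, cp$n)
  q_all <- colMeans(cp$geno[freq_rows, , drop = FALSE], na.rm = TRUE) / 2
  q_all[is.nan(q_all)] <- NA_real_
  units <- which(!is.na(q_all) & q_all >= rare_range[1] &
                   q_all <= rare_range[2] & q_all > 0 & q_all < 1)
  K <- length(units)

  typed <- rowSums(!is.na(cp$geno)) > 0
  u <- cped_units(cp, typed_trio = typed, typed_dsp = typed)
  nt <- nrow(u$trio)
  Cm <- matrix(0, 2 * nt, K)
  if (nt > 0 && K > 0) {
    Gf <- cp$geno[u$trio$father, units, drop = FALSE]
    Gm <- cp$geno[u$trio$mother, units, drop = FALSE]
    Gc <- cp$geno[u$trio$child, units, drop = FALSE]
    Pf <- Pm <- NULL
    if (cp$phased) {
      Pf <- cp$pat[u$trio$child, units, drop = FALSE]
      Pm <- cp$mat[u$trio$child, units, drop = FALSE]
    }
    tr <- resolve_transmissions(Gf, Gm, Gc, Pf, Pm)
    rowF <- ifelse(!is.na(Gf) & Gf == 1 & !is.na(tr$Tf), 2 * tr$Tf - 1, 0)
    rowM <- ifelse(!is.na(Gm) & Gm == 1 & !is.na(tr$Tm), 2 * tr$Tm - 1, 0)
    Cm[seq_len(nt), ] <- rowF
    Cm[nt + seq_len(nt), ] <- rowM
  }
  nd <- nrow(u$dsp)
  Cs <- matrix(0, nd, K)
  if (nd > 0 && K > 0) {
    Ga <- cp$geno[u$dsp$aff, units, drop = FALSE]
    Gu <- cp$geno[u$dsp$un, units, drop = FALSE]
    d <- Ga - Gu
    d[is.na(d)] <- 0
    Cs[] <- d
  }
  labels <- if (length(units)) paste0("v", units) else character(0)
  new_si("variant", labels, q_all[units], cp$n,
         Cm, c(u$trio$fam, u$trio$fam), Cs, u$dsp$fam,
         u$n_units_fam, cp$fam_id)
}

# ---- haplotype-mode score inputs from phase configurations ----------------

# Flow-weighted rows: each family's configurations contribute rows multiplied
# by the configuration weight, so per-family scores are
# D_i = sum_f Weight^(f) D_i^(f).
score_inputs_hap_flows <- function(cp, phases, exclude_most = TRUE) {
  cat <- phases$catalog
  freq <- phases$freq
  H <- length(cat$key)
  units <- seq_len(H)
  if (exclude_most && H > 0) {
    units <- setdiff(units, which.max(freq))
  }
  units <- units[freq[units] > 0 & freq[units] < 1]
  unit_col <- rep(NA_integer_, H)
  unit_col[units] <- seq_along(units)
  K <- length(units)

  typed <- if (cp$M > 0) rowSums(!is.na(cp$geno)) > 0 else rep(TRUE, cp$n)
  u <- cped_units(cp, typed_trio = typed, typed_dsp = typed)

  Cm_list <- list()
  fam_m <- integer(0)
  mult_m <- numeric(0)
  Cs_list <- list()
  fam_s <- integer(0)
  mult_s <- numeric(0)
  for (ph in phases$families) {
    f <- ph$fam
    trio_f <- u$trio[u$trio$fam == f, , drop = FALSE]
    dsp_f <- u$dsp[u$dsp$fam == f, , drop = FALSE]
    if (nrow(trio_f) == 0 && nrow(dsp_f) == 0) next
    for (ci in seq_along(ph$configs)) {
      cfg <- ph$configs[[ci]]
      wt <- ph$weights[ci]
      pi_ <- mi_ <- rep(NA_integer_, cp$n)
      pi_[ph$members] <- cfg$pat
      mi_[ph$members] <- cfg$mat
      rows <- build_hap_rows(trio_f, dsp_f, pi_, mi_, unit_col, K)
      if (nrow(rows$Cm) > 0) {
        Cm_list[[length(Cm_list) + 1]] <- rows$Cm
        fam_m <- c(fam_m, rows$fam_m)
        mult_m <- c(mult_m, rep(wt, nrow(rows$Cm)))
      }
      if (nrow(rows$Cs) > 0) {
        Cs_list[[length(Cs_list) + 1]] <- rows$Cs
        fam_s <- c(fam_s, rows$fam_s)
        mult_s <- c(mult_s, rep(wt, nrow(rows$Cs)))
      }
    }
  }
  Cm <- if (length(Cm_list)) do.call(rbind, Cm_list) else matrix(0, 0, K)
  Cs <- if (length(Cs_list)) do.call(rbind, Cs_list) else matrix(0, 0, K)
  new_si("haplotype", cat$key[units], freq[units], cp$n,
         Cm, fam_m, Cs, fam_s, u$n_units_fam, cp$fam_id,
         mult_m = mult_m, mult_s = mult_s)
}
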