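`%||%` <- function(x, y) if (is.null(x)) y else x

# Shared fixture builders and independent oracles. Everything here is
# deliberately written from first principles (explicit loops over strings)
# so it never shares code with the package's engine.

# build a pedigree tibble for one or more nuclear families from a compact
# description: each family is a list of members, each member a list with
# id, father, mother (NULL for founders), affected (TRUE/FALSE/NA) and
# either `hap = c("10", "01")` (ordered paternal, maternal) or `geno`.
make_ped <- function(families, phased = TRUE) {
  rows <- list()
  for (fi in seq_along(families)) {
    fam_id <- names(families)[fi] %||% paste0("F", fi)
    for (m in families[[fi]]) {
      g <- if (!is.null(m$hap)) {
        as.integer(strsplit(m$hap[1], "")[[1]]) +
          as.integer(strsplit(m$hap[2], "")[[1]])
      } else {
        m$geno
      }
      row <- tibble::tibble(
        family_id = fam_id, id = m$id,
        father_id = m$father %||% NA_character_,
        mother_id = m$mother %||% NA_character_,
        sex = NA_integer_,
        affected = m$affected,
        genotype = list(g))
      if (phased) {
        row$hap_pat <- list(if (!is.null(m$hap))
          as.integer(strsplit(m$hap[1], "")[[1]]) else NULL)
        row$hap_mat <- list(if (!is.null(m$hap))
          as.integer(strsplit(m$hap[2], "")[[1]]) else NULL)
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  dplyr::bind_rows(rows)
}

# a standard 3-family, 2-site phased toy used by the oracle tests: each
# family has two parents, one affected and one unaffected child
toy_families <- function() {
  list(
    FA = list(
      list(id = "fa", affected = FALSE, hap = c("10", "00")),
      list(id = "mo", affected = FALSE, hap = c("01", "00")),
      list(id = "s1", father = "fa", mother = "mo", affected = TRUE,
           hap = c("10", "01")),
      list(id = "s2", father = "fa", mother = "mo", affected = FALSE,
           hap = c("00", "00"))),
    FB = list(
      list(id = "fa", affected = FALSE, hap = c("11", "00")),
      list(id = "mo", affected = FALSE, hap = c("00", "00")),
      list(id = "s1", father = "fa", mother = "mo", affected = TRUE,
           hap = c("11", "00")),
      list(id = "s2", father = "fa", mother = "mo", affected = FALSE,
           hap = c("11", "00"))),
    FC = list(
      list(id = "fa", affected = FALSE, hap = c("10", "10")),
      list(id = "mo", affected = FALSE, hap = c("00", "01")),
      list(id = "s1", father = "fa", mother = "mo", affected = TRUE,
           hap = c("10", "00")),
      list(id = "s2", father = "fa", mother = "mo", affected = FALSE,
           hap = c("10", "01"))))
}

# ---- independent oracle: haplotype-collapsing PDT from first principles ----
#
# Input: the same `families` list accepted by make_ped (phased members).
# Recomputes catalog (founder chromosomes), weights, per-family scores and
# the collapsed statistic with explicit loops.
oracle_hpdt <- function(families) {
  # founder chromosomes
  chroms <- character(0)
  n_ind <- 0
  for (fam in families) {
    for (m in fam) {
      n_ind <- n_ind + 1
      if (is.null(m$father)) chroms <- c(chroms, m$hap)
    }
  }
  haps <- sort(unique(chroms))
  freq <- vapply(haps, function(h) mean(chroms == h), numeric(1))
  most <- haps[which.max(freq)]
  units <- setdiff(haps, most)
  units <- units[freq[units] > 0 & freq[units] < 1]
  w <- 1 / sqrt(n_ind * freq[units] * (1 - freq[units]))

  count_unit <- function(m, u) sum(m$hap == u)
  D <- numeric(length(families))
  for (fi in seq_along(families)) {
    fam <- families[[fi]]
    byid <- stats::setNames(fam, vapply(fam, `[[`, "", "id"))
    kids <- Filter(function(m) !is.null(m$father), fam)
    dsum <- stats::setNames(numeric(length(units)), units)
    n_units <- 0
    # trios: affected children
    for (k in kids) {
      if (!isTRUE(k$affected)) next
      n_units <- n_units + 1
      fa <- byid[[k$father]]
      mo <- byid[[k$mother]]
      tf <- k$hap[1]
      uf <- if (fa$hap[1] == tf) fa$hap[2] else fa$hap[1]
      tm <- k$hap[2]
      um <- if (mo$hap[1] == tm) mo$hap[2] else mo$hap[1]
      for (u in units) {
        dsum[u] <- dsum[u] + (tf == u) - (uf == u) + (tm == u) - (um == u)
      }
    }
    # discordant sib pairs
    for (a in kids) {
      if (!isTRUE(a$affected)) next
      for (b in kids) {
        if (!isFALSE(b$affected)) next
        n_units <- n_units + 1
        for (u in units) {
          dsum[u] <- dsum[u] + count_unit(a, u) - count_unit(b, u)
        }
      }
    }
    D[fi] <- if (n_units > 0) sum(w * dsum) / n_units else 0
  }
  z <- sum(D) / sqrt(sum(D^2))
  list(z = z, D = D, units = units, w = unname(w), freq = freq)
}

# ---- independent oracle: brute-force phase enumeration --------------------
#
# Enumerates every assignment of ordered haplotype pairs to parents and
# every transmission choice for children, keeps the Mendelian-consistent
# ones, and returns the set of distinct configurations as canonical strings.
oracle_phase_configs <- function(geno_father, geno_mother, geno_kids) {
  M <- length(geno_father)
  expand_pairs <- function(g) {
    per_site <- lapply(g, function(x) {
      if (is.na(x)) list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
      else if (x == 0) list(c(0, 0))
      else if (x == 2) list(c(1, 1))
      else list(c(0, 1), c(1, 0))
    })
    combos <- expand.grid(lapply(per_site, seq_along))
    lapply(seq_len(nrow(combos)), function(r) {
      h1 <- vapply(seq_len(M), function(j) per_site[[j]][[combos[r, j]]][1], 0)
      h2 <- vapply(seq_len(M), function(j) per_site[[j]][[combos[r, j]]][2], 0)
      list(h1 = h1, h2 = h2)
    })
  }
  key <- function(h) paste(h, collapse = "")
  out <- character(0)
  for (fp in expand_pairs(geno_father)) {
    for (mp in expand_pairs(geno_mother)) {
      kid_choices <- lapply(geno_kids, function(gk) {
        ch <- list()
        for (i in 1:2) {
          for (j in 1:2) {
            kid <- list(pat = fp[[i]], mat = mp[[j]])
            implied <- kid$pat + kid$mat
            if (all(is.na(gk) | implied == gk)) {
              ch[[length(ch) + 1]] <- kid
            }
          }
        }
        ch
      })
      if (any(lengths(kid_choices) == 0)) next
      combos <- expand.grid(lapply(kid_choices, seq_along))
      for (r in seq_len(nrow(combos))) {
        fkey <- paste(sort(c(key(fp$h1), key(fp$h2))), collapse = ",")
        mkey <- paste(sort(c(key(mp$h1), key(mp$h2))), collapse = ",")
        kkeys <- vapply(seq_along(geno_kids), function(ki) {
          kid <- kid_choices[[ki]][[combos[r, ki]]]
          paste(key(kid$pat), key(kid$mat), sep = "/")
        }, "")
        out <- c(out, paste(c(fkey, mkey, kkeys), collapse = "|"))
      }
    }
  }
  sort(unique(out))
}

# canonical strings for the package's enumeration, comparable with the
# oracle's output
package_phase_keys <- function(phases, family_index = 1) {
  fl <- phases$families[[family_index]]
  cp <- phases$cp
  members <- fl$members
  founders <- members[is.na(cp$father[members])]
  kids <- members[!is.na(cp$father[members])]
  vapply(fl$configs, function(cfg) {
    keyof <- function(i) phases$catalog$key[i]
    pk <- vapply(seq_along(members), function(mi) {
      i <- members[mi]
      if (i %in% founders) {
        paste(sort(c(keyof(cfg$pat[mi]), keyof(cfg$mat[mi]))),
              collapse = ",")
      } else {
        paste(keyof(cfg$pat[mi]), keyof(cfg$mat[mi]), sep = "/")
      }
    }, "")
    # founders first (father, mother order as stored), then children
    paste(pk[c(match(founders, members), match(kids, members))],
          collapse = "|")
  }, "") |> sort()
}
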