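# Pedigree tables: linkage-format I/O, validation, and decomposition of
# nuclear families into the transmission units the PDT consumes.

ped_required_cols <- c("family_id", "id", "father_id", "mother_id",
                       "affected", "genotype")

#' Empty pedigree table
#'
#' Returns a zero-row pedigree tibble with the canonical column set. A
#' pedigree table has one row per individual with columns `family_id`, `id`,
#' `father_id`, `mother_id` (`NA` for founders), `sex` (1 = male, 2 = female,
#' `NA` unknown), `affected` (logical; `NA` = unknown affection), and a
#' `genotype` list-column of per-site minor-allele counts (0, 1, 2 or `NA`).
#' Phased pedigrees additionally carry `hap_pat` and `hap_mat` list-columns of
#' binary allele vectors (1 = minor allele) ordered paternal, maternal.
#'
#' @param phased if `TRUE`, include the phased haplotype columns.
#' @return A tibble with zero rows.
#' @export
empty_pedigree <- function(phased = FALSE) {
  out <- tibble(
    family_id = character(), id = character(),
    father_id = character(), mother_id = character(),
    sex = integer(), affected = logical(),
    genotype = list())
  if (phased) {
    out$hap_pat <- list()
    out$hap_mat <- list()
  }
  out
}

#' Read a linkage-format (PED) pedigree file
#'
#' Reads a whitespace-delimited pre-makeped linkage file with columns
#' `family id father mother sex affection` followed by one allele pair per
#' site. Affection is coded 2 = affected, 1 = unaffected, 0 = unknown;
#' parent id `0` means founder; allele `0` means missing (one missing allele
#' sets the whole site missing). Alleles are recoded to minor-allele counts,
#' the minor allele being the less frequent allele in the sample at each site
#' (ties broken towards the lexicographically smaller allele label).
#'
#' Each family must be nuclear: at most one parental couple, and every
#' non-founder must reference both members of that couple. Genotypes that are
#' impossible under Mendelian transmission given the parental genotypes are
#' set to missing with a warning rather than aborting the read.
#'
#' @param path path to the PED file.
#' @param phased if `TRUE`, allele pairs are interpreted as ordered
#'   (paternal, maternal) haplotypes and returned in `hap_pat` / `hap_mat`
#'   list-columns.
#' @return A pedigree tibble (see [empty_pedigree()] for the schema).
#' @examples
#' ped <- sim_hap_pedigrees(3, sim_hap_setting(1), seed = 1)
#' f <- tempfile(fileext = ".ped")
#' write_ped(ped, f, phased = TRUE)
#' read_ped(f, phased = TRUE)
#' @export
read_ped <- function(path, phased = FALSE) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort(paste0("cannot open PED file: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- trimws(lines[keep])
  line_no <- which(keep)
  if (length(lines) == 0) {
    return(empty_pedigree(phased))
  }

  toks <- strsplit(lines, "[ \t]+")
  nt <- lengths(toks)
  bad <- which(nt < 6L | (nt - 6L) %% 2L != 0L | nt != nt[1L])
  if (length(bad)) {
    abort(sprintf("malformed PED line %d: expected %d fields, found %d",
                  line_no[bad[1]], nt[1], nt[bad[1]]))
  }
  M <- (nt[1L] - 6L) %/% 2L
  n <- length(toks)
  tok <- matrix(unlist(toks), nrow = n, byrow = TRUE)

  fam <- tok[, 1]
  id <- tok[, 2]
  father <- ifelse(tok[, 3] == "0", NA_character_, tok[, 3])
  mother <- ifelse(tok[, 4] == "0", NA_character_, tok[, 4])
  sex <- suppressWarnings(as.integer(tok[, 5]))
  aff_code <- tok[, 6]
  bad_aff <- which(!aff_code %in% c("0", "1", "2"))
  if (length(bad_aff)) {
    abort(sprintf("malformed PED line %d: affection code '%s' (expected 0/1/2)",
                  line_no[bad_aff[1]], aff_code[bad_aff[1]]))
  }
  affected <- ifelse(aff_code == "2", TRUE, ifelse(aff_code == "1", FALSE, NA))

  if (anyDuplicated(paste(fam, id))) {
    dup <- paste(fam, id)[duplicated(paste(fam, id))][1]
    abort(paste0("duplicate individual in PED file: ", dup))
  }

  hap1 <- matrix(NA_integer_, n, M)
  hap2 <- matrix(NA_integer_, n, M)
  if (M > 0) {
    for (l in seq_len(M)) {
      x1 <- tok[, 6L + 2L * l - 1L]
      x2 <- tok[, 6L + 2L * l]
      obs <- c(x1[x1 != "0"], x2[x2 != "0"])
      labs <- sort(unique(obs))
      if (length(labs) > 2) {
        abort(sprintf("site %d is not biallelic (alleles %s)",
                      l, paste(labs, collapse = "/")))
      }
      minor <- if (length(labs) < 2) {
        NA_character_  # monomorphic or fully missing: no minor allele
      } else {
        cnt <- c(sum(obs == labs[1]), sum(obs == labs[2]))
        labs[order(cnt, labs)][1]
      }
      m1 <- ifelse(x1 == "0", NA_integer_,
                   as.integer(!is.na(minor) & x1 == minor))
      m2 <- ifelse(x2 == "0", NA_integer_,
                   as.integer(!is.na(minor) & x2 == minor))
      miss <- is.na(m1) | is.na(m2)
      m1[miss] <- NA_integer_
      m2[miss] <- NA_integer_
      hap1[, l] <- m1
      hap2[, l] <- m2
    }
  }
  geno <- hap1 + hap2

  # structure checks (nuclear families) and Mendelian screening
  key <- paste(fam, id)
  fidx <- ifelse(is.na(father), NA_integer_, match(paste(fam, father), key))
  midx <- ifelse(is.na(mother), NA_integer_, match(paste(fam, mother), key))
  orphan <- which((!is.na(father) & is.na(fidx)) | (!is.na(mother) & is.na(midx)))
  if (length(orphan)) {
    abort(sprintf("structure error: individual %s in family %s references an absent parent",
                  id[orphan[1]], fam[orphan[1]]))
  }
  half <- which(xor(is.na(father), is.na(mother)))
  if (length(half)) {
    abort(sprintf("structure error: individual %s in family %s references only one parent",
                  id[half[1]], fam[half[1]]))
  }
  for (f in unique(fam)) {
    rows <- which(fam == f)
    couples <- unique(stats::na.omit(cbind(fidx[rows], midx[rows])))
    if (nrow(couples) > 1) {
      abort(sprintf("structure error: family %s is not nuclear (multiple parental couples); pre-split it",
                    f))
    }
  }

  kids <- which(!is.na(fidx))
  if (length(kids) && M > 0) {
    bad <- mendel_mask(geno, kids, fidx[kids], midx[kids])
    n_bad <- sum(bad)
    if (n_bad > 0) {
      for (j in seq_along(kids)) {
        mk <- bad[j, ]
        if (any(mk)) {
          geno[kids[j], mk] <- NA_integer_
          hap1[kids[j], mk] <- NA_integer_
          hap2[kids[j], mk] <- NA_integer_
        }
      }
      warn(sprintf("%d genotype(s) inconsistent with Mendelian transmission; set to missing",
                   n_bad))
    }
  }

  out <- tibble(
    family_id = fam, id = id, father_id = father, mother_id = mother,
    sex = sex, affected = affected,
    genotype = lapply(seq_len(n), function(i) unname(geno[i, ])))
  if (phased) {
    out$hap_pat <- lapply(seq_len(n), function(i) unname(hap1[i, ]))
    out$hap_mat <- lapply(seq_len(n), function(i) unname(hap2[i, ]))
  }
  out
}

# Sites where a child's minor-allele count is impossible given the parents.
# Returns a children x M logical matrix.
mendel_mask <- function(geno, child, father, mother) {
  gc <- geno[child, , drop = FALSE]
  gf <- geno[father, , drop = FALSE]
  gm <- geno[mother, , drop = FALSE]
  lo <- (gf == 2) + (gm == 2)
  hi <- (gf >= 1) + (gm >= 1)
  out <- !is.na(gc) & !is.na(lo) & (gc < lo | gc > hi)
  out[is.na(out)] <- FALSE
  out
}

#' Write a pedigree table in linkage (PED) format
#'
#' The minor allele is written as allele `1` and the major allele as `2`, so
#' that re-reading with [read_ped()] reproduces the minor-allele coding
#' exactly (the minor allele keeps the lower label under the tie-break rule).
#' Missing genotypes are written `0 0`.
#'
#' @param ped a pedigree tibble.
#' @param path output path.
#' @param phased write ordered (paternal, maternal) alleles from the
#'   `hap_pat`/`hap_mat` columns; defaults to `TRUE` when those columns are
#'   present.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path,
                      phased = all(c("hap_pat", "hap_mat") %in% names(ped))) {
  cp <- as_cped(ped, require_phased = phased)
  n <- cp$n
  aff <- ifelse(is.na(cp$affected), 0L, ifelse(cp$affected, 2L, 1L))
  sex <- if (is.null(cp$sex)) rep(0L, n) else ifelse(is.na(cp$sex), 0L, cp$sex)

  allele_str <- function(a1, a2) {
    # a1, a2: matrices of 0/1 minor indicators (NA missing)
    s1 <- ifelse(is.na(a1), "0", ifelse(a1 == 1, "1", "2"))
    s2 <- ifelse(is.na(a2), "0", ifelse(a2 == 1, "1", "2"))
    # one missing allele implies both written missing
    miss <- is.na(a1) | is.na(a2)
    s1[miss] <- "0"
    s2[miss] <- "0"
    m <- matrix("", nrow(s1), 2 * ncol(s1))
    m[, seq(1, 2 * ncol(s1), by = 2)] <- s1
    m[, seq(2, 2 * ncol(s1), by = 2)] <- s2
    m
  }

  if (phased) {
    am <- allele_str(cp$pat, cp$mat)
  } else {
    g <- cp$geno
    a1 <- ifelse(is.na(g), NA_integer_, as.integer(g >= 1))  # minor first
    a2 <- ifelse(is.na(g), NA_integer_, as.integer(g == 2))
    am <- allele_str(a1, a2)
  }

  fields <- cbind(cp$fam_id[cp$fam], cp$id,
                  ifelse(is.na(cp$father), "0", cp$id[cp$father]),
                  ifelse(is.na(cp$mother), "0", cp$id[cp$mother]),
                  sex, aff, am)
  writeLines(apply(fields, 1, paste, collapse = " "), path)
  invisible(path)
}

#' Decompose nuclear families into PDT transmission units
#'
#' The pedigree disequilibrium test scores a nuclear family through two kinds
#' of units: one case-parent trio per affected child whose parents are both
#' genotyped, and one discordant sib pair (DSP) per unordered pair of one
#' affected and one unaffected sibling. Individuals with unknown affection
#' enter no unit.
#'
#' @param ped a pedigree tibble.
#' @return A tibble with one row per unit: `family_id`, `kind`
#'   (`"trio"`/`"dsp"`), `affected_id` (the affected child or sib),
#'   `unaffected_id` (DSP only), `father_id`, `mother_id` (trio only).
#' @examples
#' ped <- sim_hap_pedigrees(2, seed = 1)
#' decompose_families(ped)  # 2 trios + 2 DSPs per family
#' @export
decompose_families <- function(ped) {
  cp <- as_cped(ped, require_phased = FALSE)
  typed <- if (cp$M > 0) rowSums(!is.na(cp$geno)) > 0 else rep(TRUE, cp$n)
  u <- cped_units(cp, typed_trio = typed, typed_dsp = rep(TRUE, cp$n))
  trio <- tibble(
    family_id = cp$fam_id[cp$fam[u$trio$child]],
    kind = rep("trio", nrow(u$trio)),
    affected_id = cp$id[u$trio$child],
    unaffected_id = NA_character_,
    father_id = cp$id[u$trio$father],
    mother_id = cp$id[u$trio$mother])
  dsp <- tibble(
    family_id = cp$fam_id[cp$fam[u$dsp$aff]],
    kind = rep("dsp", nrow(u$dsp)),
    affected_id = cp$id[u$dsp$aff],
    unaffected_id = cp$id[u$dsp$un],
    father_id = NA_character_,
    mother_id = NA_character_)
  dplyr::arrange(dplyr::bind_rows(trio, dsp), .data$family_id,
                 dplyr::desc(.data$kind))
}

# ---- internal compact representation --------------------------------------

# as_cped() turns the tidy per-individual table into plain matrices/indices
# used by the scoring engine and the simulators' fast paths.
as_cped <- function(ped, require_phased = FALSE) {
  if (inherits(ped, "cped")) {
    if (require_phased && is.null(ped$pat)) {
      abort("phased haplotypes required but absent")
    }
    return(ped)
  }
  stopifnot(is.data.frame(ped))
  missing_cols <- setdiff(ped_required_cols, names(ped))
  if (length(missing_cols)) {
    abort(paste0("pedigree table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(ped)
  lens <- lengths(ped$genotype)
  if (n > 0 && length(unique(lens)) > 1) {
    abort("all individuals must be genotyped at the same number of sites")
  }
  M <- if (n > 0) lens[1] else 0L
  geno <- if (n > 0) {
    matrix(as.integer(unlist(ped$genotype)), nrow = n, byrow = TRUE)
  } else {
    matrix(integer(), 0, 0)
  }

  fam_id <- unique(ped$family_id)
  fam <- match(ped$family_id, fam_id)
  key <- paste(ped$family_id, ped$id)
  if (anyDuplicated(key)) {
    abort("duplicate (family_id, id) pairs in pedigree table")
  }
  father <- ifelse(is.na(ped$father_id), NA_integer_,
                   match(paste(ped$family_id, ped$father_id), key))
  mother <- ifelse(is.na(ped$mother_id), NA_integer_,
                   match(paste(ped$family_id, ped$mother_id), key))
  orphan <- which((!is.na(ped$father_id) & is.na(father)) |
                    (!is.na(ped$mother_id) & is.na(mother)))
  if (length(orphan)) {
    abort(sprintf("structure error: individual %s in family %s references an absent parent",
                  ped$id[orphan[1]], ped$family_id[orphan[1]]))
  }

  phased <- all(c("hap_pat", "hap_mat") %in% names(ped)) && n > 0
  pat <- mat <- NULL
  if (phased) {
    unrow <- function(col) {
      out <- matrix(NA_integer_, n, M)
      has <- !vapply(col, is.null, logical(1))
      if (any(has)) {
        out[has, ] <- matrix(as.integer(unlist(col[has])), nrow = sum(has),
                             byrow = TRUE)
      }
      out
    }
    pat <- unrow(ped$hap_pat)
    mat <- unrow(ped$hap_mat)
    implied <- pat + mat
    chk <- !is.na(implied) & !is.na(geno) & implied != geno
    if (any(chk)) {
      i <- which(rowSums(chk) > 0)[1]
      abort(sprintf("haplotypes of individual %s in family %s are inconsistent with the genotype",
                    ped$id[i], ped$family_id[i]))
    }
  } else if (require_phased) {
    abort("phased haplotypes required: pedigree has no hap_pat/hap_mat columns")
  }

  structure(list(
    n = n, M = M,
    fam_id = fam_id, fam = fam, id = ped$id,
    father = father, mother = mother,
    sex = if ("sex" %in% names(ped)) ped$sex else rep(NA_integer_, n),
    affected = ped$affected,
    geno = geno, pat = pat, mat = mat,
    phased = phased
  ), class = "cped")
}

# Trio/DSP decomposition on the compact form. `typed_trio` gates which
# individuals can enter a trio (child and both parents must pass);
# `typed_dsp` gates sibs.
cped_units <- function(cp, typed_trio, typed_dsp = typed_trio) {
  kids <- which(!is.na(cp$father) & !is.na(cp$mother))
  aff <- cp$affected

  trio_child <- kids[!is.na(aff[kids]) & aff[kids] &
                       typed_trio[kids] &
                       typed_trio[cp$father[kids]] &
                       typed_trio[cp$mother[kids]]]
  trio <- data.frame(fam = cp$fam[trio_child],
                     child = trio_child,
                     father = cp$father[trio_child],
                     mother = cp$mother[trio_child])

  akids <- kids[!is.na(aff[kids]) & aff[kids] & typed_dsp[kids]]
  ukids <- kids[!is.na(aff[kids]) & !aff[kids] & typed_dsp[kids]]
  nfam <- length(cp$fam_id)
  fa <- factor(cp$fam[akids], levels = seq_len(nfam))
  fu <- factor(cp$fam[ukids], levels = seq_len(nfam))
  al <- split(akids, fa)
  ul <- split(ukids, fu)
  pairs <- purrr::map2(al, ul, function(a, u) {
    if (length(a) == 0 || length(u) == 0) return(NULL)
    expand.grid(aff = a, un = u)
  })
  dsp <- dplyr::bind_rows(pairs)
  if (nrow(dsp) == 0) dsp <- data.frame(aff = integer(), un = integer())
  dsp$fam <- cp$fam[dsp$aff]

  n_units <- tabulate(trio$fam, nbins = nfam) + tabulate(dsp$fam, nbins = nfam)
  list(trio = trio, dsp = dsp, n_units_fam = n_units)
}

# Convert a compact pedigree back to the tidy representation.
cped_to_tibble <- function(cp, phased = cp$phased) {
  n <- cp$n
  out <- tibble(
    family_id = cp$fam_id[cp$fam], id = cp$id,
    father_id = ifelse(is.na(cp$father), NA_character_, cp$id[cp$father]),
    mother_id = ifelse(is.na(cp$mother), NA_character_, cp$id[cp$mother]),
    sex = cp$sex, affected = cp$affected,
    genotype = lapply(seq_len(n), function(i) unname(cp$geno[i, ])))
  if (phased) {
    out$hap_pat <- lapply(seq_len(n), function(i) unname(cp$pat[i, ]))
    out$hap_mat <- lapply(seq_len(n), function(i) unname(cp$mat[i, ]))
  }
  out
}
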