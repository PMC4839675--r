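# Parental origin of a supernumerary chromosome 21 from STR trio
# genotypes.
#
# A trisomic child carries three chromosome-21 haplotypes: two gametes
# from the nondisjunction parent and one from the other. At an STR locus
# this shows up either as a triallelic ~1:1:1 peak pattern or as a
# biallelic pattern with a consistent 2:1 peak ratio. Comparing the
# dosage-resolved child genotype against the parental genotypes
# identifies, locus by locus, which parent must have contributed the
# doubled dose; a family verdict requires at least three informative loci
# in unanimous agreement.

#' Resolve STR allele dosage from peak areas
#'
#' Peak areas are roughly proportional to template copy number. For a
#' trisomic biallelic genotype the larger peak is called copy-2 when the
#' larger:smaller area ratio falls in `ratio_21`; a triallelic genotype is
#' called 1:1:1 when max:min area ratio is at most `tri_max_ratio`.
#' Patterns outside these windows get no dosage call.
#'
#' @param alleles Character vector of distinct allele labels (1-3).
#' @param areas Positive peak areas, parallel to `alleles`.
#' @param ploidy Child ploidy: 2 (disomy) or 3 (trisomy).
#' @param ratio_21 Acceptance window for the 2:1 biallelic ratio
#'   (default `c(1.5, 3)`).
#' @param tri_max_ratio Maximum max:min ratio for a 1:1:1 triallelic call
#'   (default 1.6).
#' @return List with `pattern` (one of `"triallelic_111"`,
#'   `"biallelic_21"`, `"biallelic_11"`, `"other"`) and `dosage` (named
#'   integer vector allele -> copy number, or `NULL` when no call).
#' @examples
#' dosage_from_peaks(c("a", "c"), c(1000, 500), ploidy = 3)
#' @export
dosage_from_peaks <- function(alleles, areas, ploidy = 3,
                              ratio_21 = c(1.5, 3), tri_max_ratio = 1.6) {
  if (length(alleles) != length(areas) || length(alleles) < 1 ||
      length(alleles) > 3) {
    stop("need 1-3 alleles with matching peak areas", call. = FALSE)
  }
  if (anyDuplicated(alleles)) stop("allele labels must be distinct", call. = FALSE)
  .check_finite_positive(areas, "areas")
  stopifnot(ploidy %in% c(2L, 3L))
  no_call <- list(pattern = "other", dosage = NULL)
  k <- length(alleles)
  if (ploidy == 2L) {
    if (k == 1L) {
      return(list(pattern = "other", dosage = stats::setNames(2L, alleles)))
    }
    if (k == 2L) {
      r <- max(areas) / min(areas)
      if (r <= tri_max_ratio) {
        return(list(
          pattern = "biallelic_11",
          dosage = stats::setNames(c(1L, 1L), alleles)
        ))
      }
    }
    return(no_call)
  }
  # trisomic child
  if (k == 1L) {
    return(list(pattern = "other", dosage = stats::setNames(3L, alleles)))
  }
  if (k == 2L) {
    big <- which.max(areas)
    r <- areas[big] / areas[-big]
    if (r >= ratio_21[1] && r <= ratio_21[2]) {
      d <- stats::setNames(rep(1L, 2L), alleles)
      d[big] <- 2L
      return(list(pattern = "biallelic_21", dosage = d))
    }
    return(no_call)
  }
  # triallelic
  if (max(areas) / min(areas) <= tri_max_ratio) {
    return(list(
      pattern = "triallelic_111",
      dosage = stats::setNames(rep(1L, 3L), alleles)
    ))
  }
  no_call
}

# Expand a named dosage vector into the allele multiset it represents.
.dosage_multiset <- function(dosage) rep(names(dosage), times = dosage)

# All distinct (pair, single) partitions of a 3-allele multiset: the pair
# is the candidate nondisjoined gamete contribution.
.trisomy_splits <- function(multiset) {
  stopifnot(length(multiset) == 3L)
  splits <- lapply(1:3, function(i) {
    list(pair = sort(multiset[-i]), single = multiset[i])
  })
  keys <- vapply(
    splits, function(s) paste(c(s$pair, "|", s$single), collapse = ","),
    character(1)
  )
  splits[!duplicated(keys)]
}

#' Call parental origin of the extra dose at one STR locus
#'
#' Enumerates all splits of the child's dosage-resolved genotype into a
#' two-allele contribution from one parent (the nondisjoined pair, modeled
#' as two independent gametes so both reduced and non-reduced pairs are
#' allowed) and a single allele from the other, keeping those compatible
#' with the parental genotypes. The locus is informative when every
#' compatible split puts the doubled contribution on the same parent.
#'
#' @param mother,father Character vectors of parental alleles (genotypes;
#'   1 or 2 distinct labels each).
#' @param child Named integer vector mapping allele label to copy number
#'   (as produced by [dosage_from_peaks()]), or a list as returned by that
#'   function. A `NULL` dosage (no call) yields an uninformative result.
#' @param child_ploidy 2 or 3; must equal `sum(child)`.
#' @return List with `pattern`, `origin` (one of `"maternal"`,
#'   `"paternal"`, `"uninformative"`, `"inconsistent"`).
#' @examples
#' call_locus_segregation(c("a", "b"), c("c", "d"),
#'   c(a = 1L, b = 1L, c = 1L),
#'   child_ploidy = 3
#' ) # maternal
#' @export
call_locus_segregation <- function(mother, father, child, child_ploidy = 3) {
  if (is.list(child) && !is.null(child$pattern)) {
    pattern <- child$pattern
    dosage <- child$dosage
  } else {
    dosage <- child
    pattern <- if (is.null(dosage)) {
      "other"
    } else if (length(dosage) == 3L) {
      "triallelic_111"
    } else if (length(dosage) == 2L && child_ploidy == 3L) {
      "biallelic_21"
    } else if (length(dosage) == 2L) {
      "biallelic_11"
    } else {
      "other"
    }
  }
  if (is.null(dosage)) {
    return(list(pattern = pattern, origin = "uninformative"))
  }
  stopifnot(sum(dosage) == child_ploidy)
  multiset <- .dosage_multiset(dosage)
  mother <- unique(mother)
  father <- unique(father)
  if (child_ploidy == 2L) {
    ok <- any(vapply(seq_along(multiset), function(i) {
      multiset[i] %in% mother && multiset[-i] %in% father
    }, logical(1)))
    return(list(
      pattern = pattern,
      origin = if (ok) "uninformative" else "inconsistent"
    ))
  }
  splits <- .trisomy_splits(multiset)
  maternal_ok <- any(vapply(splits, function(s) {
    all(s$pair %in% mother) && s$single %in% father
  }, logical(1)))
  paternal_ok <- any(vapply(splits, function(s) {
    all(s$pair %in% father) && s$single %in% mother
  }, logical(1)))
  origin <- if (maternal_ok && paternal_ok) {
    "uninformative"
  } else if (maternal_ok) {
    "maternal"
  } else if (paternal_ok) {
    "paternal"
  } else {
    "inconsistent"
  }
  list(pattern = pattern, origin = origin)
}

#' Aggregate per-locus origin calls into a family verdict
#'
#' A verdict of MT21 (maternal trisomy 21) requires at least
#' `min_informative` informative loci, all maternal; PT21 symmetric. Any
#' maternal/paternal conflict yields `"inconsistent"`; too few informative
#' loci yield `"indeterminate"`.
#'
#' @param origins Character vector of per-locus origin calls (values from
#'   [call_locus_segregation()]).
#' @param min_informative Minimum unanimous informative loci (default 3).
#' @return List with `verdict` (`"MT21"`, `"PT21"`, `"indeterminate"`,
#'   `"inconsistent"`), `n_informative`, `n_maternal`, `n_paternal`.
#' @export
aggregate_origin <- function(origins, min_informative = 3) {
  if (length(origins) < 1) stop("no locus calls supplied", call. = FALSE)
  n_mat <- sum(origins == "maternal")
  n_pat <- sum(origins == "paternal")
  n_inf <- n_mat + n_pat
  verdict <- if (any(origins == "inconsistent") || (n_mat > 0 && n_pat > 0)) {
    "inconsistent"
  } else if (n_mat >= min_informative) {
    "MT21"
  } else if (n_pat >= min_informative) {
    "PT21"
  } else {
    "indeterminate"
  }
  list(
    verdict = verdict, n_informative = n_inf,
    n_maternal = n_mat, n_paternal = n_pat
  )
}

#' Verify the uniparental (androgenetic) nature of a sample
#'
#' A complete androgenetic hydatidiform mole carries no maternal genome:
#' a monospermic mole is homozygous at every STR, and at loci where the
#' mole's allele is absent from the maternal donor's genotype, maternal
#' transmission is excluded outright. The sample is classified
#' androgenetic-consistent when it is homozygous at every shared locus and
#' donor transmission is excluded at `min_excluding` or more loci.
#'
#' @param sample,donor Named lists (by locus) of character allele vectors;
#'   only shared loci are compared (at least 10 required).
#' @param min_excluding Minimum loci excluding donor transmission
#'   (default 3).
#' @return List with `verdict` (`"androgenetic_consistent"`,
#'   `"not_homogeneous"` when heterozygous, `"not_androgenetic"`),
#'   `n_loci`, `n_homozygous`, `n_excluding`, and a per-locus data.frame
#'   `loci` with `homozygous` and `excludes_donor` flags.
#' @export
verify_uniparental <- function(sample, donor, min_excluding = 3) {
  shared <- intersect(names(sample), names(donor))
  if (length(shared) < 10) {
    stop("need at least 10 shared loci, got ", length(shared), call. = FALSE)
  }
  homo <- vapply(shared, function(l) length(unique(sample[[l]])) == 1L, logical(1))
  excl <- vapply(shared, function(l) {
    length(intersect(unique(sample[[l]]), unique(donor[[l]]))) == 0L
  }, logical(1))
  n_homo <- sum(homo)
  n_excl <- sum(excl)
  verdict <- if (n_homo < length(shared)) {
    "not_homogeneous"
  } else if (n_excl >= min_excluding) {
    "androgenetic_consistent"
  } else {
    "not_androgenetic"
  }
  list(
    verdict = verdict, n_loci = length(shared),
    n_homozygous = n_homo, n_excluding = n_excl,
    loci = data.frame(
      locus_id = shared, homozygous = homo,
      excludes_donor = excl, row.names = NULL
    )
  )
}

#' Call parental origin for a cohort of trio genotype tables
#'
#' Table-level driver: resolves dosage from peak areas per locus, calls
#' segregation against the parents and aggregates per family.
#'
#' @param genotypes data.frame with columns `family_id`, `locus_id`,
#'   `person` (`"mother"`, `"father"`, `"child"`), `allele`, `peak_area`.
#' @param ploidy Named vector mapping family_id to child ploidy, or a
#'   single value for all families.
#' @param ... Passed to [dosage_from_peaks()] and [aggregate_origin()]
#'   via `ratio_21`, `tri_max_ratio`, `min_informative`.
#' @param ratio_21,tri_max_ratio See [dosage_from_peaks()].
#' @param min_informative See [aggregate_origin()].
#' @return List of two data.frames: `loci` (family_id, locus_id, pattern,
#'   origin) and `families` (family_id, verdict, n_informative,
#'   n_maternal, n_paternal).
#' @export
call_trio_origins <- function(genotypes, ploidy = 3, ratio_21 = c(1.5, 3),
                              tri_max_ratio = 1.6, min_informative = 3) {
  need <- c("family_id", "locus_id", "person", "allele", "peak_area")
  if (!all(need %in% names(genotypes))) {
    stop("genotype table needs columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  fams <- unique(genotypes$family_id)
  if (length(ploidy) == 1L && is.null(names(ploidy))) {
    ploidy <- stats::setNames(rep(ploidy, length(fams)), fams)
  }
  loci_rows <- list()
  fam_rows <- list()
  for (fam in fams) {
    g <- genotypes[genotypes$family_id == fam, ]
    pl <- as.integer(ploidy[[as.character(fam)]])
    origins <- character(0)
    for (loc in unique(g$locus_id)) {
      gl <- g[g$locus_id == loc, ]
      ch <- gl[gl$person == "child", ]
      dos <- dosage_from_peaks(ch$allele, ch$peak_area,
        ploidy = pl,
        ratio_21 = ratio_21, tri_max_ratio = tri_max_ratio
      )
      seg <- call_locus_segregation(
        gl$allele[gl$person == "mother"],
        gl$allele[gl$person == "father"],
        dos,
        child_ploidy = pl
      )
      origins <- c(origins, seg$origin)
      loci_rows[[length(loci_rows) + 1L]] <- data.frame(
        family_id = fam, locus_id = loc,
        pattern = seg$pattern, origin = seg$origin
      )
    }
    agg <- aggregate_origin(origins, min_informative = min_informative)
    fam_rows[[length(fam_rows) + 1L]] <- data.frame(
      family_id = fam, verdict = agg$verdict,
      n_informative = agg$n_informative,
      n_maternal = agg$n_maternal, n_paternal = agg$n_paternal
    )
  }
  list(
    loci = do.call(rbind, loci_rows),
    families = do.call(rbind, fam_rows)
  )
}
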