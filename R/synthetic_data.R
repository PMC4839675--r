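# Synthetic data generators.
#
# Each generator emulates the statistical structure one analysis stage
# assumes — trio STR genotypes under a known trisomy origin, MSRE-PCR
# peak-area quartets around a true methylation fraction, allele-specific
# read sets and motif-bearing sequences — and records the ground truth,
# so the whole pipeline is testable without any external download.

#' Simulation configuration
#'
#' Bundles every generator parameter with reproducibility semantics:
#' when `seed` is non-NULL each generator seeds the RNG on entry, so the
#' same config yields identical output.
#'
#' @param seed Integer RNG seed, or `NULL` to use the current RNG stream.
#' @param n_families Number of trio families to simulate.
#' @param origin_mix Proportions of `N21` (disomic), `MT21`, `PT21`
#'   families; must sum to 1.
#' @param n_str_loci STR loci per family.
#' @param str_allele_count Equifrequent alleles per STR locus (>= 2).
#' @param str_noise_cv Coefficient of variation of STR peak areas.
#' @param base_area Mean peak area per template copy (fluorescence
#'   units).
#' @param meth_noise_cv Coefficient of variation of MSRE-PCR peak areas.
#'   Applied as a run-level scale factor shared by the peaks of one
#'   capillary injection (injection amount and detector gain dominate
#'   area variation and are common-mode within a run, which is why the
#'   assay reads within-run ratios).
#' @param peak_resid_cv Residual per-peak integration noise, independent
#'   across peaks (default `meth_noise_cv / 3`).
#' @param assay_imbalance True undigested query:reference amplification
#'   ratio A/B.
#' @param read_depth Reads per simulated SNP.
#' @param base_error_rate Per-base substitution error rate.
#' @param read_length Read length (>= 29).
#' @param motif_units Tandem units for sequence simulation.
#' @param motif_spacing Start-to-start unit spacing in bp.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = NULL,
                       n_families = 90,
                       origin_mix = c(N21 = 1 / 3, MT21 = 1 / 3, PT21 = 1 / 3),
                       n_str_loci = 5,
                       str_allele_count = 8,
                       str_noise_cv = 0.05,
                       base_area = 1000,
                       meth_noise_cv = 0.03,
                       peak_resid_cv = meth_noise_cv / 3,
                       assay_imbalance = 1.2,
                       read_depth = 100,
                       base_error_rate = 0.001,
                       read_length = 50,
                       motif_units = 7,
                       motif_spacing = 62) {
  stopifnot(
    abs(sum(origin_mix) - 1) < 1e-9,
    all(names(origin_mix) %in% c("N21", "MT21", "PT21")),
    str_allele_count >= 2, n_str_loci >= 1,
    str_noise_cv >= 0, meth_noise_cv >= 0, peak_resid_cv >= 0,
    base_error_rate >= 0, base_error_rate <= 1,
    read_length >= 29, assay_imbalance > 0
  )
  structure(
    list(
      seed = seed, n_families = n_families, origin_mix = origin_mix,
      n_str_loci = n_str_loci, str_allele_count = str_allele_count,
      str_noise_cv = str_noise_cv, base_area = base_area,
      meth_noise_cv = meth_noise_cv, peak_resid_cv = peak_resid_cv,
      assay_imbalance = assay_imbalance,
      read_depth = read_depth, base_error_rate = base_error_rate,
      read_length = read_length, motif_units = motif_units,
      motif_spacing = motif_spacing
    ),
    class = "sim_config"
  )
}

.seed_from_config <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
}

# Multiplicative lognormal noise factors with unit mean and the given CV.
.lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Peak-area rows for one person at one locus from an allele multiset.
.str_peak_rows <- function(family_id, locus_id, person, gamete_alleles, cfg) {
  dosage <- table(gamete_alleles)
  areas <- as.integer(dosage) * cfg$base_area *
    .lnoise(length(dosage), cfg$str_noise_cv)
  data.frame(
    family_id = family_id, locus_id = locus_id, person = person,
    allele = names(dosage), peak_area = areas,
    stringsAsFactors = FALSE
  )
}

#' Simulate trio STR genotype tables with known trisomy origin
#'
#' Parents are drawn from equifrequent allele pools per locus. Disomic
#' (N21) children receive one gamete from each parent; trisomic children
#' receive two independent gametes from the origin parent (nondisjunction
#' without meiotic-stage modeling) plus one from the other. Peak areas
#' are proportional to copy number with multiplicative lognormal noise.
#'
#' @param cfg A [sim_config()].
#' @param n_families Override for `cfg$n_families`.
#' @return List with `genotypes` (data.frame: family_id, locus_id,
#'   person, allele, peak_area), `truth` (data.frame: family_id, origin,
#'   ploidy).
#' @export
sim_trios <- function(cfg = sim_config(), n_families = cfg$n_families) {
  .seed_from_config(cfg)
  alleles <- paste0("a", seq_len(cfg$str_allele_count))
  origins <- sample(names(cfg$origin_mix), n_families,
    replace = TRUE, prob = cfg$origin_mix
  )
  rows <- vector("list", n_families * cfg$n_str_loci * 3L)
  k <- 0L
  for (fam in seq_len(n_families)) {
    fid <- sprintf("F%03d", fam)
    origin <- origins[fam]
    for (loc in seq_len(cfg$n_str_loci)) {
      lid <- sprintf("STR%02d", loc)
      mother <- sample(alleles, 2, replace = TRUE)
      father <- sample(alleles, 2, replace = TRUE)
      child <- switch(origin,
        N21 = c(sample(mother, 1), sample(father, 1)),
        MT21 = c(sample(mother, 2, replace = TRUE), sample(father, 1)),
        PT21 = c(sample(mother, 1), sample(father, 2, replace = TRUE))
      )
      rows[[k + 1L]] <- .str_peak_rows(fid, lid, "mother", mother, cfg)
      rows[[k + 2L]] <- .str_peak_rows(fid, lid, "father", father, cfg)
      rows[[k + 3L]] <- .str_peak_rows(fid, lid, "child", child, cfg)
      k <- k + 3L
    }
  }
  list(
    genotypes = do.call(rbind, rows),
    truth = data.frame(
      family_id = sprintf("F%03d", seq_len(n_families)),
      origin = origins,
      ploidy = ifelse(origins == "N21", 2L, 3L),
      stringsAsFactors = FALSE
    )
  )
}

#' Simulate MSRE-PCR peak-area quartets
#'
#' The undigested run carries the configured query:reference
#' amplification imbalance (`A/B = assay_imbalance`); in the digested run
#' the query amplimer survives in proportion to the true methylation
#' fraction while the reference is enzyme-refractory. Peak areas get
#' multiplicative lognormal noise in two components: a run-level scale
#' factor with CV `meth_noise_cv` shared by the peaks of each capillary
#' injection (common-mode, so it cancels in within-run ratios) and an
#' independent per-peak integration residual with CV `peak_resid_cv`.
#'
#' @param true_meth True percent methylation in `[0, 100]` (recycled
#'   against `n`).
#' @param cfg A [sim_config()].
#' @param n Number of quartets.
#' @return data.frame with columns `true_meth`, `A`, `B`, `C`, `D`.
#' @export
sim_msre <- function(true_meth, cfg = sim_config(), n = length(true_meth)) {
  if (any(!is.finite(true_meth)) || any(true_meth < 0) || any(true_meth > 100)) {
    stop("'true_meth' must be in [0, 100]", call. = FALSE)
  }
  .seed_from_config(cfg)
  m <- rep_len(true_meth, n)
  base <- cfg$base_area
  run_undig <- .lnoise(n, cfg$meth_noise_cv)
  run_dig <- .lnoise(n, cfg$meth_noise_cv)
  resid <- function() .lnoise(n, cfg$peak_resid_cv)
  data.frame(
    true_meth = m,
    A = base * cfg$assay_imbalance * run_undig * resid(),
    B = base * run_undig * resid(),
    C = base * cfg$assay_imbalance * (m / 100) * run_dig * resid(),
    D = base * run_dig * resid()
  )
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_bases <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  chars
}

#' Simulate an allele-specific read set for a SNP query
#'
#' Each read embeds one allele's 29-mer (allele `a` with probability
#' `allele_fraction`) at a random offset inside random flanking sequence,
#' on a random strand, with per-base substitution errors and plausible
#' Phred qualities.
#'
#' @param q A [snp_query()].
#' @param allele_fraction Probability a read carries allele `a`.
#' @param cfg A [sim_config()] (`read_depth`, `read_length`,
#'   `base_error_rate`).
#' @return A `read_set` (see [read_fastq()]).
#' @export
sim_reads <- function(q, allele_fraction, cfg = sim_config()) {
  stopifnot(inherits(q, "snp_query"))
  if (allele_fraction < 0 || allele_fraction > 1) {
    stop("'allele_fraction' must be in [0, 1]", call. = FALSE)
  }
  if (cfg$read_length < 29) stop("read_length must be >= 29", call. = FALSE)
  .seed_from_config(cfg)
  subs <- expand_query(q)
  n <- cfg$read_depth
  len <- cfg$read_length
  pad <- len - 29L
  is_a <- stats::runif(n) < allele_fraction
  left <- sample.int(pad + 1L, n, replace = TRUE) - 1L
  # read matrix: random background overwritten by the allele 29-mer
  bases <- c("A", "C", "G", "T")
  mat <- matrix(sample(bases, n * len, replace = TRUE), nrow = n)
  core_a <- strsplit(subs[["a"]], "")[[1]]
  core_b <- strsplit(subs[["b"]], "")[[1]]
  for (i in seq_len(n)) {
    mat[i, (left[i] + 1L):(left[i] + 29L)] <-
      if (is_a[i]) core_a else core_b
  }
  # per-base substitution errors
  err <- which(matrix(stats::runif(n * len) < cfg$base_error_rate, nrow = n))
  for (j in err) {
    mat[j] <- sample(setdiff(bases, mat[j]), 1)
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  flip <- stats::runif(n) < 0.5
  if (any(flip)) seqs[flip] <- .revcomp(seqs[flip])
  quals <- lapply(seq_len(n), function(i) {
    pmin(pmax(round(stats::rnorm(len, 36, 2)), 2L), 40L)
  })
  structure(
    list(
      id = sprintf("%s_read%04d", q$snp_id, seq_len(n)),
      seq = seqs, qual = quals
    ),
    class = "read_set"
  )
}

#' Simulate a sequence carrying a tandem motif array
#'
#' Places `n_units` concrete instances of a degenerate consensus
#' (degenerate positions resolved randomly per unit) at constant
#' start-to-start spacing inside random flanks, and returns the truth
#' coordinates.
#'
#' @param motif IUPAC consensus string.
#' @param n_units Number of tandem units (>= 1).
#' @param spacing Start-to-start spacing in bp (>= motif length; units do
#'   not overlap).
#' @param cfg A [sim_config()].
#' @param flank Random flank length on each side (default 200 bp).
#' @return List with `seq` (the sequence string), `starts` (0-based truth
#'   unit starts), `n_units` and `span_bp`
#'   (`(n_units - 1) * spacing + motif length`).
#' @export
sim_motif_seq <- function(motif, n_units = cfg$motif_units,
                          spacing = cfg$motif_spacing,
                          cfg = sim_config(), flank = 200) {
  motif <- toupper(motif)
  L <- nchar(motif)
  if (spacing < L) stop("spacing must be >= motif length", call. = FALSE)
  if (n_units < 1) stop("n_units must be >= 1", call. = FALSE)
  .seed_from_config(cfg)
  pattern <- strsplit(motif, "")[[1]]
  unit <- function() {
    paste(vapply(pattern, function(p) {
      opts <- .IUPAC[[p]]
      if (length(opts) == 1L) opts else sample(opts, 1)
    }, character(1)), collapse = "")
  }
  gap <- spacing - L
  body <- character(0)
  for (u in seq_len(n_units)) {
    body <- c(body, unit(), if (u < n_units) .random_dna(gap))
  }
  seq <- paste0(.random_dna(flank), paste(body, collapse = ""), .random_dna(flank))
  list(
    seq = seq,
    starts = flank + (seq_len(n_units) - 1L) * spacing,
    n_units = n_units,
    span_bp = (n_units - 1L) * spacing + L
  )
}
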