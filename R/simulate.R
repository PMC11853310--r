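#' Configuration for the synthetic-data generators
#'
#' Collects the parameters that define the statistical structure the labeling
#' pipeline assumes: a substoichiometric treated sample (per-site
#' stoichiometry `s`), a control with residual modification `epsilon`
#' (knockout-like controls are not completely devoid of the modification), a
#' per-feature effect specification for modified reads, and the target
#' modification-probability distributions of the two read classes.
#'
#' Effect model for modified reads (unmodified reads in either sample draw
#' from the baseline): signal intensity is Normal per k-mer and shifts by
#' `delta_si` baseline standard deviations; trace of the reference base and
#' the basecaller error probability are Beta-distributed with separate
#' (unmodified, modified) parameter pairs; dwell times are log-Normal with a
#' multiplicative `dwell_factor` for modified reads.
#'
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @param n_reads_per_sample Reads per site per sample.
#' @param stoichiometry Per-site modified fraction `s` in the treated sample.
#' @param epsilon Residual modification rate in the control; must satisfy
#'   `0 <= epsilon <= s <= 1`.
#' @param delta_si Signal-intensity shift for modified reads, in units of the
#'   baseline standard deviation.
#' @param dwell_factor Multiplicative dwell-time factor for modified reads.
#' @param trace_unmod,trace_mod `c(shape1, shape2)` of the Beta distributions
#'   of the reference-base trace for unmodified and modified reads. Defaults
#'   give high trace (confident canonical call) for unmodified reads and
#'   near-0 trace for modified reads.
#' @param mp_unmod,mp_mod Beta parameters of the basecaller
#'   modification/error-probability feature for the two classes.
#' @param modprob_unmod,modprob_mod Beta parameters of the per-read
#'   modification probability emitted for unmodified and modified bases.
#'   Defaults are calibrated so the class medians are ~0.002 and ~0.70.
#' @param affected_kmers Character vector of 7-mers carrying the modification
#'   (central base A); `NULL` lets the generators construct them.
#' @param n_kmers,n_unaffected_kmers Number of affected / unaffected 7-mers
#'   when `affected_kmers` is `NULL`.
#' @param n_sites_per_kmer Reference positions sharing each 7-mer.
#'
#' @return A list of class `permod_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_reads_per_sample = 100L,
                             stoichiometry = 0.5,
                             epsilon = 0,
                             delta_si = 2,
                             dwell_factor = 1.5,
                             trace_unmod = c(10, 1.5),
                             trace_mod = c(1.5, 10),
                             mp_unmod = c(1, 15),
                             mp_mod = c(4, 4),
                             modprob_unmod = c(0.3, 30),
                             modprob_mod = c(4.3, 2),
                             affected_kmers = NULL,
                             n_kmers = 5L,
                             n_unaffected_kmers = 5L,
                             n_sites_per_kmer = 2L) {
  if (epsilon < 0 || stoichiometry > 1 || epsilon > stoichiometry) {
    abort("generator config requires 0 <= epsilon <= stoichiometry <= 1")
  }
  pars <- list(seed = as.integer(seed),
               n_reads_per_sample = as.integer(n_reads_per_sample),
               stoichiometry = stoichiometry, epsilon = epsilon,
               delta_si = delta_si, dwell_factor = dwell_factor,
               trace_unmod = trace_unmod, trace_mod = trace_mod,
               mp_unmod = mp_unmod, mp_mod = mp_mod,
               modprob_unmod = modprob_unmod, modprob_mod = modprob_mod,
               affected_kmers = affected_kmers,
               n_kmers = as.integer(n_kmers),
               n_unaffected_kmers = as.integer(n_unaffected_kmers),
               n_sites_per_kmer = as.integer(n_sites_per_kmer))
  stopifnot(all(vapply(pars[c("delta_si", "dwell_factor")], is.finite, TRUE)))
  structure(pars, class = "permod_config")
}

random_kmers <- function(n, prefix_pool = c("A", "C", "G", "T")) {
  if (n == 0) return(character(0))
  flank <- function() paste(sample(prefix_pool, 3, replace = TRUE), collapse = "")
  pool <- unique(replicate(n * 20, paste0(flank(), "A", flank())))
  if (length(pool) < n) abort("could not draw enough distinct 7-mers")
  pool[seq_len(n)]
}

draw_trace_block <- function(n, tr, ref_base) {
  # distribute the non-reference trace mass across the other three bases
  rest <- matrix(stats::rgamma(3 * n, shape = 1), ncol = 3)
  rest <- rest / rowSums(rest) * (1 - tr)
  out <- matrix(0, nrow = n, ncol = 4,
                dimnames = list(NULL, c("TA", "TC", "TG", "TT")))
  ref_col <- paste0("T", chartr("U", "T", ref_base))
  out[, ref_col] <- tr
  out[, setdiff(colnames(out), ref_col)] <- rest
  out
}

#' Simulate a two-sample per-base feature dataset with ground truth
#'
#' Generates control and treated feature records with the two-population
#' structure the labeling pipeline assumes: at sites whose centered 7-mer is
#' affected, treated reads are modified at rate `s` (`stoichiometry`) and
#' control reads at the residual rate `epsilon`; modified reads draw their
#' features from shifted distributions (see [generator_config()]); at
#' unaffected 7-mers the two samples are distributionally identical.
#'
#' @param config A [generator_config()].
#' @return A list with elements `records` (feature tibble in RNA002 layout,
#'   both samples) and `truth` (tibble `read_id`, `ref_id`, `pos`, `kmer`,
#'   `sample`, `modified`).
#' @export
simulate_feature_dataset <- function(config) {
  stopifnot(inherits(config, "permod_config"))
  with_seed(config$seed, {
    affected <- config$affected_kmers %||% random_kmers(config$n_kmers)
    unaffected <- setdiff(random_kmers(config$n_unaffected_kmers * 2),
                          affected)[seq_len(config$n_unaffected_kmers)]
    kmers <- c(affected, unaffected)
    # per-k-mer baselines, deterministic given the seed
    base_si <- stats::rnorm(length(kmers), 100, 5)
    base_sd <- stats::runif(length(kmers), 2, 4)
    base_dt_meanlog <- stats::runif(length(kmers), 2, 2.5)

    rows <- list(); truths <- list()
    for (ki in seq_along(kmers)) {
      km <- kmers[ki]
      is_affected <- km %in% affected
      for (si in seq_len(config$n_sites_per_kmer)) {
        ref_id <- sprintf("ref_%s_%d", km, si)
        pos <- 100L + si
        for (smp in c("control", "treated")) {
          n <- config$n_reads_per_sample
          rate <- if (!is_affected) 0 else if (smp == "treated")
            config$stoichiometry else config$epsilon
          modified <- stats::runif(n) < rate
          nm <- sum(modified)
          si_vals <- stats::rnorm(n, base_si[ki], base_sd[ki])
          si_vals[modified] <- si_vals[modified] +
            config$delta_si * base_sd[ki]
          mp <- numeric(n)
          mp[!modified] <- stats::rbeta(n - nm, config$mp_unmod[1], config$mp_unmod[2])
          mp[modified] <- stats::rbeta(nm, config$mp_mod[1], config$mp_mod[2])
          tr <- numeric(n)
          tr[!modified] <- stats::rbeta(n - nm, config$trace_unmod[1], config$trace_unmod[2])
          tr[modified] <- stats::rbeta(nm, config$trace_mod[1], config$trace_mod[2])
          dt <- stats::rlnorm(n, base_dt_meanlog[ki], 0.3)
          dt10 <- stats::rlnorm(n, base_dt_meanlog[ki], 0.3)
          dt[modified] <- dt[modified] * config$dwell_factor
          dt10[modified] <- dt10[modified] * config$dwell_factor
          traces <- draw_trace_block(n, tr, "A")
          read_id <- sprintf("%s_%s_r%04d", ref_id, smp, seq_len(n))
          rows[[length(rows) + 1]] <- tibble(
            read_id = read_id, ref_id = ref_id, pos = pos, strand = "+",
            ref_base = "A", kmer = km, sample = smp,
            SI = si_vals, MP = mp, DT = dt, DT10 = dt10, TR = tr,
            TA = traces[, "TA"], TC = traces[, "TC"],
            TG = traces[, "TG"], TT = traces[, "TT"])
          truths[[length(truths) + 1]] <- tibble(
            read_id = read_id, ref_id = ref_id, pos = pos, kmer = km,
            sample = smp, modified = modified)
        }
      }
    }
    list(records = bind_rows(rows), truth = bind_rows(truths))
  })
}

#' Simulate per-read modification-probability calls with ground truth
#'
#' Emits one modification-probability call per read per A position of a set
#' of synthetic reference transcripts. A subset of A positions are
#' modification sites with stoichiometry `s` (treated sample) or residual
#' rate `epsilon` (control-like sample); all other positions draw from the
#' unmodified probability distribution. Default class distributions are
#' calibrated to the observed per-class medians of ~0.0 (unmodified) and
#' ~0.7 (modified).
#'
#' @param config A [generator_config()].
#' @param n_refs Number of synthetic transcripts.
#' @param ref_length Transcript length (nt).
#' @param n_sites_per_ref Modification sites per transcript.
#' @param coverage Reads per transcript (all reads span the full transcript).
#' @param sample Which condition to emulate: `"treated"` (rate `s`) or
#'   `"control"` (rate `epsilon`).
#' @param sequences Optional named character vector of transcript sequences
#'   to reuse (e.g. to build a fully modified and a fully unmodified pool
#'   over the same references); generated when `NULL`.
#' @param sites Optional tibble (`ref_id`, `pos`) of modification sites to
#'   reuse; generated when `NULL`.
#' @param read_prefix Prefix for read identifiers (keeps pools built over
#'   the same references distinguishable).
#' @return A list with `calls` (tibble `read_id`, `ref_id`, `pos`, `strand`,
#'   `base`, `modProb`), `truth` (per read x site `modified` flag plus
#'   per-site `stoichiometry`), `sites` (site positions per transcript) and
#'   `sequences` (named character vector of transcript sequences, DNA
#'   alphabet).
#' @export
simulate_modprob_dataset <- function(config,
                                     n_refs = 3L,
                                     ref_length = 300L,
                                     n_sites_per_ref = 3L,
                                     coverage = 100L,
                                     sample = c("treated", "control"),
                                     sequences = NULL, sites = NULL,
                                     read_prefix = "") {
  stopifnot(inherits(config, "permod_config"))
  sample <- match.arg(sample)
  rate <- if (sample == "treated") config$stoichiometry else config$epsilon
  with_seed(config$seed, {
    seqs <- sequences %||% {
      s <- vapply(seq_len(n_refs), function(i) {
        paste(base::sample(c("A", "C", "G", "T"), ref_length, replace = TRUE,
                           prob = c(0.35, 0.2, 0.25, 0.2)), collapse = "")
      }, character(1))
      names(s) <- sprintf("tx%02d", seq_len(n_refs))
      s
    }

    calls <- list(); truths <- list(); site_tbl <- list()
    for (r in names(seqs)) {
      len_r <- nchar(seqs[[r]])
      a_pos <- which(strsplit(seqs[[r]], "")[[1]] == "A") - 1L  # 0-based
      stopifnot(length(a_pos) > n_sites_per_ref)
      r_sites <- if (!is.null(sites)) {
        sort(sites$pos[sites$ref_id == r])
      } else {
        sort(base::sample(a_pos[a_pos > 10 & a_pos < len_r - 10],
                          n_sites_per_ref))
      }
      site_tbl[[r]] <- tibble(ref_id = r, pos = r_sites, stoichiometry = rate)
      read_id <- sprintf("%s%s_read%05d", read_prefix, r, seq_len(coverage))
      n_a <- length(a_pos)
      is_site <- a_pos %in% r_sites
      for (i in seq_len(coverage)) {
        modified <- rep(FALSE, n_a)
        modified[is_site] <- stats::runif(sum(is_site)) < rate
        p <- numeric(n_a)
        p[!modified] <- stats::rbeta(sum(!modified),
                                     config$modprob_unmod[1], config$modprob_unmod[2])
        p[modified] <- stats::rbeta(sum(modified),
                                    config$modprob_mod[1], config$modprob_mod[2])
        calls[[length(calls) + 1]] <- tibble(
          read_id = read_id[i], ref_id = r, pos = a_pos, strand = "+",
          base = "A", modProb = p)
        truths[[length(truths) + 1]] <- tibble(
          read_id = read_id[i], ref_id = r, pos = a_pos[is_site],
          modified = modified[is_site])
      }
    }
    list(calls = bind_rows(calls), truth = bind_rows(truths),
         sites = bind_rows(site_tbl), sequences = seqs)
  })
}

#' Simulate transcripts with pairs of co-occurring modification sites
#'
#' Each transcript carries two modification sites with marginal per-read
#' modification frequencies `fA` and `fB` and a tunable per-read dependence
#' `rho`, the Pearson correlation of the two modification indicators. The
#' joint modification probability is
#' `P(both) = fA*fB + rho*sqrt(fA(1-fA)*fB(1-fB))`, which preserves the
#' marginals exactly for any attainable `rho`; `rho = 0` gives independence
#' and the upper Frechet bound gives comonotone co-modification.
#'
#' @param n_transcripts Number of transcripts.
#' @param coverage Reads per transcript (all spanning both sites).
#' @param fA,fB Marginal modification frequencies in `(0, 1)`.
#' @param rho Indicator correlation; must lie within the Frechet-attainable
#'   range for `(fA, fB)`.
#' @param seed Integer seed.
#' @param config Optional [generator_config()] supplying the per-class
#'   modification-probability distributions.
#' @return A list with `calls`, `truth` (per read: modified at A/B), and
#'   `pairs` (per transcript: positions, `fA`, `fB`, `rho`, expected joint
#'   probability `p11`).
#' @export
simulate_cooccurring_transcripts <- function(n_transcripts, coverage,
                                             fA, fB, rho, seed = 1L,
                                             config = generator_config(seed = seed)) {
  stopifnot(fA > 0, fA < 1, fB > 0, fB < 1)
  sdAB <- sqrt(fA * (1 - fA) * fB * (1 - fB))
  p11 <- fA * fB + rho * sdAB
  lo <- max(0, fA + fB - 1)
  hi <- min(fA, fB)
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12) {
    abort(sprintf(
      "rho = %.3f is outside the Frechet-attainable range [%.3f, %.3f] for fA = %g, fB = %g",
      rho, (lo - fA * fB) / sdAB, (hi - fA * fB) / sdAB, fA, fB))
  }
  p11 <- min(max(p11, lo), hi)
  p10 <- fA - p11; p01 <- fB - p11; p00 <- 1 - p11 - p10 - p01
  with_seed(seed, {
    calls <- list(); truths <- list(); pairs <- list()
    for (t in seq_len(n_transcripts)) {
      tx <- sprintf("cotx%04d", t)
      posA <- 50L
      posB <- 50L + base::sample(50:500, 1)
      joint <- base::sample(c("11", "10", "01", "00"), coverage,
                            replace = TRUE, prob = c(p11, p10, p01, p00))
      modA <- joint %in% c("11", "10")
      modB <- joint %in% c("11", "01")
      read_id <- sprintf("%s_read%05d", tx, seq_len(coverage))
      draw <- function(mod) {
        p <- numeric(length(mod))
        p[!mod] <- stats::rbeta(sum(!mod), config$modprob_unmod[1], config$modprob_unmod[2])
        p[mod] <- stats::rbeta(sum(mod), config$modprob_mod[1], config$modprob_mod[2])
        p
      }
      calls[[length(calls) + 1]] <- bind_rows(
        tibble(read_id = read_id, ref_id = tx, pos = posA, strand = "+",
               base = "A", modProb = draw(modA)),
        tibble(read_id = read_id, ref_id = tx, pos = posB, strand = "+",
               base = "A", modProb = draw(modB)))
      truths[[length(truths) + 1]] <- tibble(
        read_id = read_id, ref_id = tx,
        modified_A = modA, modified_B = modB)
      pairs[[length(pairs) + 1]] <- tibble(
        ref_id = tx, posA = posA, posB = posB, fA = fA, fB = fB,
        rho = rho, p11 = p11)
    }
    list(calls = bind_rows(calls), truth = bind_rows(truths),
         pairs = bind_rows(pairs))
  })
}

#' Mix modified and unmodified read pools at an exact target stoichiometry
#'
#' Draws exactly `round(n * target)` reads (without replacement) from the
#' modified pool and the remainder from the unmodified pool, emulating
#' in-silico mixtures of fully modified and fully unmodified reads used to
#' benchmark stoichiometry estimation.
#'
#' @param modified_pool,unmodified_pool Tibbles of per-read calls with a
#'   `read_id` column (e.g. `calls` from [simulate_modprob_dataset()]).
#' @param target_stoichiometry Target modified fraction in `[0, 1]`.
#' @param n Total number of reads in the mixture.
#' @param seed Integer seed.
#' @return A tibble of calls for the sampled reads, with a logical
#'   `from_modified_pool` column; the attribute `"sampled_ids"` is a list
#'   with the modified and unmodified read ids drawn.
#' @export
mix_pools <- function(modified_pool, unmodified_pool, target_stoichiometry,
                      n, seed = 1L) {
  stopifnot(target_stoichiometry >= 0, target_stoichiometry <= 1)
  n_mod <- round(n * target_stoichiometry)
  n_unm <- n - n_mod
  mod_ids <- unique(modified_pool$read_id)
  unm_ids <- unique(unmodified_pool$read_id)
  if (length(mod_ids) < n_mod) {
    abort(sprintf("modified pool has %d reads but %d are required (deficit %d)",
                  length(mod_ids), n_mod, n_mod - length(mod_ids)))
  }
  if (length(unm_ids) < n_unm) {
    abort(sprintf("unmodified pool has %d reads but %d are required (deficit %d)",
                  length(unm_ids), n_unm, n_unm - length(unm_ids)))
  }
  with_seed(seed, {
    take_mod <- sample(mod_ids, n_mod)
    take_unm <- sample(unm_ids, n_unm)
    out <- bind_rows(
      modified_pool %>% filter(.data$read_id %in% take_mod) %>%
        mutate(from_modified_pool = TRUE),
      unmodified_pool %>% filter(.data$read_id %in% take_unm) %>%
        mutate(from_modified_pool = FALSE))
    attr(out, "sampled_ids") <- list(modified = take_mod, unmodified = take_unm)
    out
  })
}
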