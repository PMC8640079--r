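# Synthetic case/control cohorts with planted reversed pairs, correlated
# clinical covariates, and strictly monotone per-sample distortions.
# Ground truth is recorded so every downstream stage can be scored.

#' Specification of a synthetic case/control cohort
#'
#' Expression is simulated directly on the log2 scale: background miRNAs
#' get a per-miRNA baseline drawn uniformly from `baseline_log_mean_range`
#' plus Gaussian noise, independent of class. Each planted pair `(i, j)`
#' is given, per sample, member means offset by `+/- pair_separation / 2`
#' around the pair's per-sample level, oriented by the pair's control
#' direction in controls and reversed in cases; the class-specific
#' orientation is applied independently per sample with probability
#' `fidelity` and flipped otherwise. The per-sample pair level is the
#' pair's shared baseline plus a class-independent Gaussian component
#' (`pair_level_sd`) common to both members: it models the large
#' between-sample variability of co-regulated transcripts, cancels in the
#' within-pair difference (the planted ordering signal is untouched), and
#' keeps the planted pairs identifiable -- without it, every bystander
#' miRNA whose baseline falls inside a planted pair's oscillation window
#' would itself form a reversed pair with the planted members, making the
#' recorded truth an incomplete description of the reversal structure.
#' Ages are integer years truncated to
#' 40--100, controls centred near 72 and cases shifted upward by
#' `age_case_shift`; APOE e4 allele counts are Binomial(2, p) with
#' class-specific p.
#'
#' The defaults describe the reference simulation used throughout the
#' package's validation: 150 cases and 150 controls, 100 miRNAs, 10
#' planted pairs at fidelity 0.85 with a pair separation of three noise
#' standard deviations.
#'
#' @param n_case,n_control Positive class sizes.
#' @param m_mirnas Number of miRNAs simulated.
#' @param planted_pairs Number of vertex-disjoint reversed pairs planted
#'   (at most `m_mirnas / 2`).
#' @param fidelity Probability, in (0.5, 1], that a planted pair shows its
#'   class-specific orientation in a given sample.
#' @param baseline_log_mean_range Two numbers: range of per-miRNA baseline
#'   means (log2 expression units).
#' @param pair_separation Log2-unit separation between the two members of
#'   a planted pair.
#' @param noise_sd Per-measurement Gaussian noise standard deviation
#'   (log2 units).
#' @param pair_level_sd Standard deviation (log2 units) of the per-sample
#'   expression level shared by the two members of a planted pair.
#' @param age_case_shift Upward shift (years) of the case age distribution.
#' @param apoe_p_case,apoe_p_control Per-allele e4 probabilities by class.
#' @param age_sd Standard deviation (years) of the age distributions.
#' @param seed Master seed; the full output is a deterministic function of
#'   the spec including this seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_case = 150, n_control = 150, m_mirnas = 100,
                           planted_pairs = 10, fidelity = 0.85,
                           baseline_log_mean_range = c(4, 12),
                           pair_separation = 1.5, noise_sd = 0.5,
                           pair_level_sd = 4, age_case_shift = 3,
                           apoe_p_case = 0.20, apoe_p_control = 0.12,
                           age_sd = 8, seed = 16) {
  stopifnot(n_case >= 1, n_control >= 1, m_mirnas >= 2)
  if (planted_pairs < 1 || planted_pairs > m_mirnas / 2) {
    stop("planted_pairs must be in [1, m_mirnas / 2]", call. = FALSE)
  }
  if (fidelity <= 0.5 || fidelity > 1) {
    stop("fidelity must lie in (0.5, 1]", call. = FALSE)
  }
  stopifnot(length(baseline_log_mean_range) == 2,
            baseline_log_mean_range[1] < baseline_log_mean_range[2],
            pair_separation > 0, noise_sd > 0, pair_level_sd >= 0,
            age_case_shift >= 0,
            apoe_p_case >= 0, apoe_p_case <= 1,
            apoe_p_control >= 0, apoe_p_control <= 1)
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 m_mirnas = as.integer(m_mirnas),
                 planted_pairs = as.integer(planted_pairs),
                 fidelity = fidelity,
                 baseline_log_mean_range = as.numeric(baseline_log_mean_range),
                 pair_separation = pair_separation, noise_sd = noise_sd,
                 pair_level_sd = pair_level_sd,
                 age_case_shift = age_case_shift,
                 apoe_p_case = apoe_p_case, apoe_p_control = apoe_p_control,
                 age_sd = age_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate a case/control cohort with planted reversed pairs
#'
#' One master seed drives a dedicated RNG stream per component (pair
#' layout, expression, ages, APOE, sex), so adding draws to one component
#' never perturbs another's. Identical specs give bit-identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `expression` (miRNA x sample log2 matrix), `meta`
#'   (a [cohort_metadata()]; controls first, then cases) and `truth`
#'   (class `planted_truth`): data.frame of planted directed pairs with
#'   their control direction, plus the fidelity used.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seeds <- derive_seeds(spec$seed, 5)
  n <- spec$n_control + spec$n_case
  mirna_ids <- sprintf("mir-%04d", seq_len(spec$m_mirnas))
  sample_ids <- c(sprintf("ctrl-%04d", seq_len(spec$n_control)),
                  sprintf("case-%04d", seq_len(spec$n_case)))
  labels <- rep(c("control", "case"), c(spec$n_control, spec$n_case))
  is_case <- labels == "case"

  # component 1: planted-pair layout (vertex-disjoint) and control direction
  layout <- with_seed(seeds[1], {
    members <- sample(spec$m_mirnas, 2L * spec$planted_pairs)
    dirs <- sample(c(1L, -1L), spec$planted_pairs, replace = TRUE)
    list(i = members[seq_len(spec$planted_pairs)],
         j = members[spec$planted_pairs + seq_len(spec$planted_pairs)],
         dir = dirs)
  })

  # component 2: expression
  expr <- with_seed(seeds[2], {
    base <- runif(spec$m_mirnas, spec$baseline_log_mean_range[1],
                  spec$baseline_log_mean_range[2])
    em <- matrix(base, nrow = spec$m_mirnas, ncol = n) +
      matrix(rnorm(spec$m_mirnas * n, sd = spec$noise_sd),
             nrow = spec$m_mirnas)
    for (p in seq_len(spec$planted_pairs)) {
      i <- layout$i[p]; j <- layout$j[p]
      # per-sample level shared by both members: pair baseline plus a
      # class-independent common component (cancels within the pair)
      level <- (base[i] + base[j]) / 2 + rnorm(n, sd = spec$pair_level_sd)
      class_orient <- ifelse(is_case, -layout$dir[p], layout$dir[p])
      faithful <- runif(n) < spec$fidelity
      orient <- ifelse(faithful, class_orient, -class_orient)
      em[i, ] <- level + orient * spec$pair_separation / 2 +
        rnorm(n, sd = spec$noise_sd)
      em[j, ] <- level - orient * spec$pair_separation / 2 +
        rnorm(n, sd = spec$noise_sd)
    }
    dimnames(em) <- list(mirna_ids, sample_ids)
    em
  })

  # component 3: ages (integer years, truncated to [40, 100])
  ages <- with_seed(seeds[3], {
    centre <- ifelse(is_case, 72 + spec$age_case_shift, 72)
    pmin(pmax(round(rnorm(n, mean = centre, sd = spec$age_sd)), 40), 100)
  })

  # component 4: APOE e4 allele counts
  apoe <- with_seed(seeds[4], {
    p <- ifelse(is_case, spec$apoe_p_case, spec$apoe_p_control)
    rbinom(n, 2, p)
  })

  # component 5: sex, balanced and label-independent
  sex <- with_seed(seeds[5],
                   sample(c("female", "male"), n, replace = TRUE))

  truth <- data.frame(mirna_i = mirna_ids[layout$i],
                      mirna_j = mirna_ids[layout$j],
                      control_direction = layout$dir,
                      stringsAsFactors = FALSE)
  # report planted pairs in their control-majority direction
  flip <- truth$control_direction == -1L
  tmp <- truth$mirna_i[flip]
  truth$mirna_i[flip] <- truth$mirna_j[flip]
  truth$mirna_j[flip] <- tmp
  truth$control_direction <- 1L
  truth <- truth[order(truth$mirna_i, truth$mirna_j), , drop = FALSE]
  rownames(truth) <- NULL

  list(expression = expr,
       meta = cohort_metadata(sample_ids, labels, ages, apoe, sex),
       truth = structure(list(pairs = truth, fidelity = spec$fidelity),
                         class = "planted_truth"))
}

#' Apply an independent strictly increasing distortion to each sample
#'
#' Emulates batch and normalisation effects: each sample's values are
#' passed through an independently drawn strictly increasing map, a random
#' positive affine map composed with a cubic warp centred on the sample
#' median. Within-sample value order is preserved exactly, so all REO
#' features are invariant. `strength = 0` is the identity.
#'
#' @param em Numeric feature x sample matrix.
#' @param seed Seed for the per-sample map parameters.
#' @param strength Mixing weight in \[0, 1\] between the identity and the
#'   drawn distortion; both endpoints are strictly increasing maps, hence
#'   so is every mixture.
#' @return A matrix with the same dimnames as `em`.
#' @export
apply_monotone_distortion <- function(em, seed = 1, strength = 1) {
  validate_expression_matrix(em)
  stopifnot(strength >= 0, strength <= 1)
  if (strength == 0) return(em)
  n <- ncol(em)
  par <- with_seed(seed, list(a = runif(n, -2, 2),
                              b = runif(n, 0.5, 2),
                              cc = runif(n, 0.01, 0.1)))
  out <- em
  for (s in seq_len(n)) {
    x <- em[, s]
    m <- stats::median(x)
    warped <- par$a[s] + par$b[s] * x + par$cc[s] * (x - m)^3
    out[, s] <- (1 - strength) * x + strength * warped
  }
  out
}
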