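#' Expected number of exocytosis events for a pulse train
#'
#' Release follows the saturating form N(p) = N_max * (1 - exp(-p / p0)).
#' The defaults (N_max = 123 vesicles, p0 = 100 pulses) keep 5, 20 and 50
#' pulses near-proportional (about 6, 22 and 48 vesicles) while 125
#' pulses is clearly sub-proportional (N(125)/N(50) = 1.8), reflecting
#' depletion of the readily releasable pool.
#'
#' @param n_pulses Number of stimulation pulses (>= 0, vectorized).
#' @param n_max Pool size (vesicles).
#' @param p0 Saturation scale (pulses).
#' @return Expected event count(s).
#' @export
expected_exo_count <- function(n_pulses, n_max = 123, p0 = 100) {
  .assert(all(n_pulses >= 0), "n_pulses must be >= 0")
  n_max * (1 - exp(-n_pulses / p0))
}

#' Simulate ground-truth exo- and endocytosis events around one AZLM
#'
#' Draws a Poisson number of fusion events (mean [expected_exo_count()]),
#' places them uniformly inside the AZLM disc at times spread over the
#' pulse train, and retrieves a binomial fraction of them as endocytosis
#' events on an annulus around the disc edge. Endocytosis modes are
#' assigned from `mode_mix`; ultrafast endocytosis (UFE) is suppressed
#' below 30 C (its share is renormalized onto CME/ADBE), and when it does
#' occur its events fall within 0.3 s of stimulation onset, versus
#' 0.5-10 s for CME/ADBE.
#'
#' Mode-specific annulus offsets (radial distance of the vesicle center
#' from the disc edge, nm): CME ~ N(100, 80), ADBE ~ N(140, 80),
#' UFE ~ N(20, 60). Endo vesicle depths are uniform in 50-150 nm above
#' the coverslip (the presynaptic cytosol starts about 50 nm up);
#' acidification time constants are uniform in 3-15 s.
#'
#' @param n_pulses Number of stimulation pulses (>= 0).
#' @param temperature_C Bath temperature; gates UFE at 30 C.
#' @param mode_mix Named fractions for CME/ADBE/UFE; must sum to 1.
#' @param seed Optional RNG seed.
#' @param azlm_radius_nm AZLM disc radius.
#' @param endo_prob Probability that a fused vesicle's worth of membrane
#'   is retrieved within the recording.
#' @param n_max,p0 Saturation parameters, see [expected_exo_count()].
#' @param molecules_per_vesicle SEP copies per synaptic vesicle
#'   (~32 synaptophysin copies per vesicle).
#' @param drift_nm_per_s,bleach,exchange_down_ms,exchange_up_ms Passed to
#'   [ground_truth()].
#' @return A [ground_truth()] with `t_event` measured from stimulation
#'   onset.
#' @export
simulate_events <- function(n_pulses, temperature_C = 22,
                            mode_mix = c(CME = 0.4, ADBE = 0.4, UFE = 0.2),
                            seed = NULL, azlm_radius_nm = 252.3,
                            endo_prob = 0.8, n_max = 123, p0 = 100,
                            molecules_per_vesicle = 32,
                            drift_nm_per_s = c(0, 0),
                            bleach = bleach_model(1, Inf),
                            exchange_down_ms = 100, exchange_up_ms = 200) {
  .assert(n_pulses >= 0, "n_pulses must be >= 0")
  .assert(all(c("CME", "ADBE", "UFE") %in% names(mode_mix)),
          "mode_mix needs named CME/ADBE/UFE fractions")
  .assert(abs(sum(mode_mix) - 1) < 1e-6, "mode_mix must sum to 1")
  mix <- mode_mix[c("CME", "ADBE", "UFE")]
  if (temperature_C < 30) {           # UFE requires near-physiological T
    mix["UFE"] <- 0
    if (sum(mix) > 0) mix <- mix / sum(mix)
  }

  .with_seed(seed, {
    n_exo <- if (n_pulses == 0) 0L else
      stats::rpois(1, expected_exo_count(n_pulses, n_max, p0))
    events <- list()
    train_dur <- max(n_pulses, 1) / 50  # pulse train length at 50 Hz
    if (n_exo > 0) {
      r <- azlm_radius_nm * sqrt(stats::runif(n_exo))
      th <- stats::runif(n_exo, 0, 2 * pi)
      t_exo <- stats::runif(n_exo, 0, train_dur)
      for (i in seq_len(n_exo))
        events[[length(events) + 1]] <- gt_event(
          kind = "exo", mode = "none", t_event = t_exo[i],
          xy_nm = c(r[i] * cos(th[i]), r[i] * sin(th[i])),
          amplitude_molecules = molecules_per_vesicle)
      n_endo <- stats::rbinom(1, n_exo, endo_prob)
      if (n_endo > 0 && sum(mix) > 0) {
        modes <- sample(names(mix), n_endo, replace = TRUE, prob = mix)
        off_mean <- c(CME = 100, ADBE = 140, UFE = 20)
        off_sd <- c(CME = 80, ADBE = 80, UFE = 60)
        amp_ves <- c(CME = 1, ADBE = 4, UFE = 4)  # vesicle-area equivalents
        for (m in modes) {
          t_e <- if (m == "UFE") stats::runif(1, 0.05, 0.3) else
            stats::runif(1, 0.5, 10)
          off <- stats::rnorm(1, off_mean[[m]], off_sd[[m]])
          rr <- max(azlm_radius_nm + off, 10)
          ang <- stats::runif(1, 0, 2 * pi)
          events[[length(events) + 1]] <- gt_event(
            kind = "endo", mode = m, t_event = t_e,
            xy_nm = c(rr * cos(ang), rr * sin(ang)),
            z_nm = stats::runif(1, 50, 150),
            amplitude_molecules = amp_ves[[m]] * molecules_per_vesicle,
            acidification_tau = stats::runif(1, 3, 15))
        }
      }
    }
    ground_truth(events = events, azlm_radius_nm = azlm_radius_nm,
                 drift_nm_per_s = drift_nm_per_s, bleach = bleach,
                 exchange_down_ms = exchange_down_ms,
                 exchange_up_ms = exchange_up_ms,
                 temperature_C = temperature_C)
  })
}
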