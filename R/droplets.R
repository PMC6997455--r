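#' Generate a droplet train at the first capillary junction
#'
#' Droplets form where the two aqueous streams (iron precursor mix and
#' ammonia) meet the carrier oil. Under the twin's segmentation model the
#' generator runs at a fixed frequency, so each droplet takes up the
#' dispersed-phase volume delivered per cycle, and droplet composition
#' follows from the aqueous split and the precursor concentrations
#' (0.06 M Fe(III), 0.03 M Fe(II) in stream 1; 4 M ammonia in stream 2).
#'
#' @param flows A [flow_settings()]; the dispersed flow must be positive.
#' @param cal A [calibration_model()] supplying `droplet_frequency`.
#' @param duration Generation window in minutes (non-negative).
#' @param seed Optional integer seed; the generator itself is deterministic,
#'   the seed is accepted for interface symmetry with the stochastic
#'   operations and reserved for future volume jitter.
#' @param fe3_conc,fe2_conc,ammonia_conc Molar concentrations of the aqueous
#'   feeds (mol/L).
#' @return A `droplet_train` data.frame with one row per droplet: `volume`
#'   (uL), `generation_time` (min), `gold_injection_rate` (uL/min),
#'   `fe3_umol`, `fe2_umol`, `ammonia_umol`, `au_umol` (umol), and
#'   `secondary_droplet_flag`.
#' @examples
#' train <- generate_droplets(flow_settings(), calibration_model(), duration = 1)
#' nrow(train)        # 60 droplets at 60/min
#' train$volume[1]    # 20/60 uL
#' @export
generate_droplets <- function(flows, cal, duration, seed = NULL,
                              fe3_conc = 0.06, fe2_conc = 0.03,
                              ammonia_conc = 4) {
  if (duration < 0) stop("duration must be non-negative", call. = FALSE)
  qd <- dispersed_flow(flows)
  if (qd <= 0) stop("no droplets: dispersed flow is zero", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration * cal$droplet_frequency)
  volume <- qd / cal$droplet_frequency
  # even spacing, one droplet per generator cycle
  generation_time <- if (n > 0) (seq_len(n) - 1) / cal$droplet_frequency else numeric(0)
  aq1_frac <- flows$q_aqueous_1 / qd
  vol_aq1 <- volume * aq1_frac        # uL; umol = uL * mol/L
  vol_aq2 <- volume * (1 - aq1_frac)
  train <- data.frame(
    volume = rep(volume, n),
    generation_time = generation_time,
    gold_injection_rate = rep(0, n),
    fe3_umol = rep(vol_aq1 * fe3_conc, n),
    fe2_umol = rep(vol_aq1 * fe2_conc, n),
    ammonia_umol = rep(vol_aq2 * ammonia_conc, n),
    au_umol = rep(0, n),
    secondary_droplet_flag = rep(FALSE, n))
  class(train) <- c("droplet_train", "data.frame")
  train
}

#' @export
print.droplet_train <- function(x, ...) {
  cat(sprintf("<droplet_train> %d droplets, volume %s uL, Au %s umol/droplet\n",
              nrow(x),
              if (nrow(x)) format(x$volume[1], digits = 4) else "-",
              if (nrow(x)) format(x$au_umol[1], digits = 4) else "-"))
  invisible(x)
}

#' Inject gold precursor into passing droplets
#'
#' Models one injection junction: each droplet grows by the reagent volume
#' delivered per droplet period, so the merged volume normalised to the
#' original droplet volume is linear in the injection flowrate with intercept
#' one. Gold moles increase by injected volume times the precursor
#' concentration (0.03 M). Above the merge capacity (30 uL/min by default)
#' satellite droplets of pure reagent form between the original droplets; the
#' train is flagged and a warning emitted, mirroring the physical failure
#' mode.
#'
#' @param train A `droplet_train` (or a single-droplet data.frame slice).
#' @param q_inject Reagent injection flowrate, uL/min (non-negative).
#' @param cal A [calibration_model()].
#' @param au_conc Gold precursor concentration, mol/L.
#' @return The updated `droplet_train`.
#' @examples
#' train <- generate_droplets(flow_settings(), calibration_model(), 1)
#' merged <- merge_inject(train, 20, calibration_model())
#' merged$volume[1] / train$volume[1]  # 2: normalised merged volume
#' @export
merge_inject <- function(train, q_inject, cal, au_conc = 0.03) {
  if (q_inject < 0) stop("q_inject must be non-negative", call. = FALSE)
  added_vol <- q_inject / cal$droplet_frequency
  train$volume <- train$volume + added_vol
  train$au_umol <- train$au_umol + added_vol * au_conc
  train$gold_injection_rate <- q_inject
  if (q_inject > cal$secondary_droplet_limit) {
    train$secondary_droplet_flag <- TRUE
    warning(sprintf(
      "injection at %g uL/min exceeds the %g uL/min merge capacity: secondary droplets form",
      q_inject, cal$secondary_droplet_limit), call. = FALSE)
  }
  train
}

#' Run a droplet train through all three injection junctions
#'
#' Convenience wrapper applying [merge_inject()] once per injection junction
#' at the shared gold flowrate.
#'
#' @param train A `droplet_train`.
#' @param q_gold Shared gold-precursor flowrate per junction, uL/min.
#' @param cal A [calibration_model()].
#' @param n_injections Number of injection junctions.
#' @return The fully injected `droplet_train`.
#' @export
inject_all <- function(train, q_gold, cal, n_injections = 3) {
  for (i in seq_len(n_injections)) train <- merge_inject(train, q_gold, cal)
  train
}
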