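#' Place and calibrate the synaptic population
#'
#' Distributes `n_e` excitatory (AMPA-like) and `n_i` inhibitory
#' (GABA-A-like) dual-exponential synapses uniformly along the basal and
#' apical dendrites and sets their peak conductances from target somatic
#' current amplitudes, emulating how synaptic strength is measured in a
#' somatic voltage-clamp recording:
#'
#' * Excitatory amplitudes are drawn from a miniature-event
#'   [amplitude_model()] (the naive mEPSC shape) and scaled to the target
#'   mean `e_target_pA`; synapses whose base miniature draw is at least
#'   13 pA (the tail of the distribution) are flagged `strong`.
#' * Inhibitory amplitudes are uniform with mean `i_target_pA`.
#'
#' For every dendritic compartment a passive soma-clamp simulation of a
#' unit-conductance event gives the somatic current per nS (the cable
#' attenuation a recording at the soma actually sees); the peak
#' conductance of each synapse is then the target amplitude divided by
#' that transfer amplitude.  Calibration driving forces follow the
#' recording conditions: excitatory events at a holding potential of
#' -80 mV (reversal 0 mV), inhibitory events at -60 mV against the
#' near-0 mV chloride reversal of a CsCl-filled electrode.  In the
#' running model the inhibitory reversal is `i_rev` (default -75 mV).
#'
#' Alternatively pass `e_gbar_nS`/`i_gbar_nS` to set the mean peak
#' conductances directly (the parameter-space protocols specify
#' conductances, not currents); the amplitude distribution shapes are kept.
#'
#' @param cell A [cell_model()].
#' @param n_e,n_i Numbers of excitatory and inhibitory synapses.
#' @param e_target_pA,i_target_pA Target mean somatic current amplitudes.
#' @param e_gbar_nS,i_gbar_nS Optional mean peak conductances (nS)
#'   overriding the current-based calibration.
#' @param e_model Miniature amplitude model for the excitatory weights.
#' @param i_rel_range Inhibitory uniform amplitude range relative to its
#'   mean.
#' @param e_kin,i_kin Named vectors `c(rise, decay)` in ms.
#' @param e_rev,i_rev Synaptic reversal potentials in the model, mV.
#' @param e_hold,i_hold Calibration holding potentials, mV.
#' @param i_cal_rev Reversal assumed for the inhibitory calibration
#'   (recording condition), mV.
#' @param strong_cut Strong/weak boundary on the miniature scale, pA.
#' @param seed Optional integer seed.
#' @return A tibble of class `synapse_set` with one row per synapse:
#'   `syn_id`, `kind` (`"E"`/`"I"`), `comp`, `g_peak_nS`, `amp_pA`,
#'   `strong`, `amplification`; kinetics and reversals in attributes.
#' @export
configure_synapses <- function(cell, n_e = 350, n_i = 350,
                               e_target_pA = 70, i_target_pA = 100,
                               e_gbar_nS = NULL, i_gbar_nS = NULL,
                               e_model = amplitude_model(),
                               i_rel_range = c(0.5, 1.5),
                               e_kin = c(rise = 0.5, decay = 1.5),
                               i_kin = c(rise = 1, decay = 5),
                               e_rev = 0, i_rev = -75,
                               e_hold = -80, i_hold = -60, i_cal_rev = 0,
                               strong_cut = 13, seed = NULL) {
  stopifnot(inherits(cell, "cell_model"))
  if (length(cell$dend_idx) == 0) abort("cell has no dendritic compartments")
  with_seed_maybe(seed, {
    dend <- cell$dend_idx
    wts <- cell$lens[dend]
    comp_e <- sample(dend, n_e, replace = TRUE, prob = wts)
    comp_i <- sample(dend, n_i, replace = TRUE, prob = wts)

    base_e <- draw_base_amplitudes(e_model, n_e)
    strong <- base_e >= strong_cut
    amp_e <- base_e * e_target_pA / mean(e_model)
    amp_i <- runif(n_i, i_rel_range[1], i_rel_range[2]) * i_target_pA

    if (is.null(e_gbar_nS) || is.null(i_gbar_nS)) {
      att_e <- clamp_transfer_amplitude(cell, dend, e_kin, e_rev, e_hold)
      att_i <- clamp_transfer_amplitude(cell, dend, i_kin, i_cal_rev, i_hold)
    }
    g_e <- if (is.null(e_gbar_nS)) {
      amp_e / att_e[match(comp_e, dend)]
    } else {
      base_e * e_gbar_nS / mean(e_model)
    }
    g_i <- if (is.null(i_gbar_nS)) {
      amp_i / att_i[match(comp_i, dend)]
    } else {
      runif(n_i, i_rel_range[1], i_rel_range[2]) * i_gbar_nS
    }
    out <- tibble(
      syn_id = seq_len(n_e + n_i),
      kind = rep(c("E", "I"), c(n_e, n_i)),
      comp = c(comp_e, comp_i),
      g_peak_nS = c(g_e, g_i),
      amp_pA = c(amp_e, amp_i),
      strong = c(strong, rep(NA, n_i)),
      amplification = 1)
    attr(out, "kinetics") <- list(E = e_kin, I = i_kin)
    attr(out, "reversals") <- c(E = e_rev, I = i_rev)
    class(out) <- c("synapse_set", class(out))
    out
  })
}

# Somatic voltage-clamp current amplitude (pA) per nS of peak conductance
# for a synapse in each compartment of `comps`, on the passive cell.
clamp_transfer_amplitude <- function(cell, comps, kin, syn_rev, v_hold,
                                     dt = 0.025, t_event = 60,
                                     t_total = 120) {
  vapply(comps, function(cc) {
    syn <- list(comp = as.integer(cc - 1L), type = 0L,
                g_peak_uS = 1e-3,
                tau_rise = c(kin[["rise"]], 1), tau_decay = c(kin[["decay"]], 8),
                e_rev = c(syn_rev, syn_rev))
    ev <- list(time = t_event, syn = 0L)
    ctrl <- sim_ctrl(duration = t_total, dt = dt, clamp_mode = 2L,
                     v_hold = v_hold, passive_only = TRUE,
                     soma_idx = as.integer(cell$soma_idx - 1L))
    res <- .sim_core(cell_core_list(cell), syn, ev, ctrl)
    icl <- res$i_clamp * 1e3   # nA -> pA
    # the dendrites need ~5 tau_m after the clamp engages; take the
    # baseline just before the event
    base <- mean(icl[res$time > t_event - 10 & res$time < t_event])
    max(abs(icl[res$time >= t_event] - base))
  }, numeric(1))
}

#' Whole-cell balanced amplification
#'
#' Multiplies the peak conductance of every synapse (excitatory and
#' inhibitory alike) by `factor`, leaving kinetics, placements and any
#' activation schedule untouched -- the whole-cell balanced amplification
#' operator.
#'
#' @param synapses A [configure_synapses()] set.
#' @param factor Conductance multiplication factor (> 0).
#' @return The amplified `synapse_set`.
#' @export
apply_whole_cell_amplification <- function(synapses, factor = 2) {
  stopifnot(inherits(synapses, "synapse_set"))
  if (factor <= 0) abort("`factor` must be positive")
  synapses$g_peak_nS <- synapses$g_peak_nS * factor
  synapses$amplification <- synapses$amplification * factor
  synapses
}

# Internal: synapse list for the compiled core.
syn_core_list <- function(synapses) {
  kin <- attr(synapses, "kinetics")
  rev <- attr(synapses, "reversals")
  list(comp = as.integer(synapses$comp - 1L),
       type = as.integer(synapses$kind == "I"),
       g_peak_uS = synapses$g_peak_nS * 1e-3,
       tau_rise = c(kin$E[["rise"]], kin$I[["rise"]]),
       tau_decay = c(kin$E[["decay"]], kin$I[["decay"]]),
       e_rev = unname(rev[c("E", "I")]))
}
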