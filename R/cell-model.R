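#' Conductance-based three-cylinder pyramidal cell
#'
#' Builds the discretised cable model of a simplified pyramidal cell:
#' apical and basal dendritic cylinders joined to a somatic cylinder.
#' Spike-generating conductances (transient Na, delayed-rectifier K,
#' A-type K) are placed in the soma; the adaptation-related conductances
#' (M-type K, high-threshold Ca and the Ca-dependent AHP K) in the
#' proximal apical dendrite, together with a single-pool calcium
#' homeostasis mechanism `d[Ca]/dt = -phi * I_Ca - ([Ca] - [Ca]_rest)/tau`.
#' Defaults give a regular-spiking cell with moderate firing-rate
#' adaptation.
#'
#' @param apical,basal,soma Named vectors `c(length, diam)` in um.
#' @param ra Axial resistivity, Ohm cm.
#' @param cm Specific membrane capacitance, uF/cm^2.
#' @param g_leak Leak conductance density, S/cm^2.
#' @param e_leak Leak reversal potential, mV (swept -100..-70 in the
#'   excitability protocols).
#' @param g_na,g_kdr,g_ka,g_km,g_cah,g_kahp Channel conductance densities,
#'   S/cm^2.
#' @param e_na,e_k,e_ca Ionic reversal potentials, mV.
#' @param ca_tau Calcium removal time constant, ms.
#' @param ca_rest Resting calcium concentration, uM.
#' @param ca_depth Effective depth of the calcium pool, um (the cell
#'   diameter); sets the current-to-concentration conversion.
#' @param max_seg Maximum compartment length, um.
#' @param proximal_um Extent of the proximal apical region carrying the
#'   adaptation conductances, um.
#' @return An object of class `cell_model` holding the per-compartment
#'   vectors consumed by the compiled integrator.
#' @export
cell_model <- function(apical = c(length = 200, diam = 2.5),
                       basal = c(length = 80, diam = 3),
                       soma = c(length = 12, diam = 20),
                       ra = 50, cm = 2, g_leak = 2e-4, e_leak = -80,
                       g_na = 0.2, g_kdr = 0.14, g_ka = 0.1,
                       g_km = 0.01, g_cah = 0.003, g_kahp = 0.002,
                       e_na = 55, e_k = -90, e_ca = 90,
                       ca_tau = 10, ca_rest = 0.05, ca_depth = 20,
                       max_seg = 10, proximal_um = 30) {
  stopifnot(ra > 0, cm > 0, g_leak >= 0, max_seg > 0)
  dens <- c(g_na, g_kdr, g_ka, g_km, g_cah, g_kahp)
  if (any(dens < 0)) abort("channel densities must be non-negative")

  seg <- function(total, n) rep(total / n, n)
  n_b <- max(1L, ceiling(basal["length"] / max_seg))
  n_s <- max(1L, ceiling(soma["length"] / max_seg))
  n_a <- max(1L, ceiling(apical["length"] / max_seg))
  # chain: basal tip .. basal prox | soma | apical prox .. apical tip
  lens <- c(seg(basal["length"], n_b), seg(soma["length"], n_s),
            seg(apical["length"], n_a))
  diams <- c(rep(basal["diam"], n_b), rep(soma["diam"], n_s),
             rep(apical["diam"], n_a))
  region <- c(rep("basal", n_b), rep("soma", n_s), rep("apical", n_a))
  nc <- length(lens)
  area_cm2 <- pi * diams * lens * 1e-8            # um^2 -> cm^2
  cap_nF <- cm * area_cm2 * 1e3                   # uF/cm^2 * cm^2 -> nF
  gleak_uS <- g_leak * area_cm2 * 1e6

  # axial conductance between neighbouring compartment centres
  half_r <- ra * (lens * 1e-4 / 2) / (pi * (diams * 1e-4 / 2)^2)  # Ohm
  gax_uS <- 1e6 / (half_r[-nc] + half_r[-1])

  soma_idx <- which(region == "soma")
  apical_idx <- which(region == "apical")
  prox <- apical_idx[cumsum(lens[apical_idx]) <= proximal_um + 1e-9]

  dens_vec <- function(d, idx) {
    out <- numeric(nc); out[idx] <- d * area_cm2[idx] * 1e6; out
  }
  structure(list(
    nc = nc, region = region, lens = lens, diams = diams,
    area_cm2 = area_cm2, cap_nF = cap_nF, gleak_uS = gleak_uS,
    gax_uS = gax_uS, e_leak = e_leak, e_na = e_na, e_k = e_k, e_ca = e_ca,
    gna_uS = dens_vec(g_na, soma_idx), gkdr_uS = dens_vec(g_kdr, soma_idx),
    gka_uS = dens_vec(g_ka, soma_idx), gkm_uS = dens_vec(g_km, prox),
    gcah_uS = dens_vec(g_cah, prox), gkahp_uS = dens_vec(g_kahp, prox),
    ca_phi = 1e3 / (2 * 96485 * ca_depth * 1e-4),  # uM cm^2 / (mA ms)
    ca_tau = ca_tau, ca_rest = ca_rest,
    soma_idx = soma_idx,
    dend_idx = which(region != "soma"),
    densities = list(g_na = g_na, g_kdr = g_kdr, g_ka = g_ka, g_km = g_km,
                     g_cah = g_cah, g_kahp = g_kahp, g_leak = g_leak),
    params = list(ra = ra, cm = cm, e_leak = e_leak, max_seg = max_seg)),
    class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf(
    "<cell_model> %d compartments (%d basal, %d soma, %d apical); E_leak %.4g mV; total membrane area %.3g um^2\n",
    x$nc, sum(x$region == "basal"), sum(x$region == "soma"),
    sum(x$region == "apical"), x$e_leak, sum(x$area_cm2) * 1e8))
  invisible(x)
}

#' Build a cell from a configuration list
#'
#' Thin constructor accepting a (possibly partial) named list of
#' [cell_model()] arguments, e.g. parsed from a YAML/JSON configuration.
#'
#' @param config Named list of `cell_model` arguments.
#' @return A `cell_model`.
#' @export
build_cell <- function(config = list()) {
  do.call(cell_model, config)
}

# Internal: the list layout consumed by the compiled core.
cell_core_list <- function(cell) {
  list(cap_nF = cell$cap_nF, gleak_uS = cell$gleak_uS, gax_uS = cell$gax_uS,
       e_leak = cell$e_leak, e_na = cell$e_na, e_k = cell$e_k,
       e_ca = cell$e_ca, gna_uS = cell$gna_uS, gkdr_uS = cell$gkdr_uS,
       gka_uS = cell$gka_uS, gkm_uS = cell$gkm_uS, gcah_uS = cell$gcah_uS,
       gkahp_uS = cell$gkahp_uS, area_cm2 = cell$area_cm2,
       ca_phi = cell$ca_phi, ca_tau = cell$ca_tau, ca_rest = cell$ca_rest)
}

#' Resting potential of a cell
#'
#' Runs the cell with no synaptic input for `t_equil` ms and returns the
#' final somatic potential.
#'
#' @param cell A [cell_model()].
#' @param t_equil Equilibration time, ms.
#' @param dt Time step, ms.
#' @return Resting potential, mV.
#' @export
resting_potential <- function(cell, t_equil = 500, dt = 0.025) {
  res <- simulate(cell, synapses = NULL, schedule = NULL,
                  duration = t_equil, dt = dt)
  tail(res$trace$v_soma, 1)
}
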