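#' LIF neuron parameters
#'
#' Container for the membrane constants of one leaky integrate-and-fire
#' population. Units: potentials in mV, capacitance in pF, conductance in
#' nS, times in ms. The membrane obeys
#' \deqn{C_m dV/dt = -g_L (V - V_{rest}) - \sum_c G_c(t) (V - E_c) + I_{ext}}
#' with threshold `V_th`, reset to `V_reset`, and absolute refractory
#' period `t_ref` during which V is clamped at `V_reset` while synaptic
#' conductances continue to evolve.
#'
#' @param V_reset reset potential after a spike (mV)
#' @param V_th spike threshold (mV)
#' @param V_rest resting (leak reversal) potential (mV)
#' @param C_m membrane capacitance (pF)
#' @param g_L leak conductance (nS)
#' @param t_ref absolute refractory period (ms)
#' @param I_ext constant external current (pA), default 0
#' @return an object of class `neuron_params`
#' @export
neuron_params <- function(V_reset, V_th, V_rest, C_m, g_L, t_ref, I_ext = 0) {
  stopifnot(V_reset < V_th, t_ref > 0, C_m > 0, g_L > 0)
  structure(list(V_reset = V_reset, V_th = V_th, V_rest = V_rest,
                 C_m = C_m, g_L = g_L, t_ref = t_ref, I_ext = I_ext),
            class = "neuron_params")
}

#' Receptor channel definition
#'
#' One synaptic conductance channel of a population: an alpha-function
#' kernel time constant and a reversal potential. A channel whose reversal
#' lies above the population threshold is excitatory, below is inhibitory.
#'
#' @param name one of "AMPA", "NMDA", "GABA" (free-form names allowed)
#' @param tau_syn kernel time constant (ms)
#' @param E_rev reversal potential (mV)
#' @export
receptor <- function(name, tau_syn, E_rev) {
  stopifnot(tau_syn > 0)
  list(name = name, tau_syn = tau_syn, E_rev = E_rev)
}

#' STN / GPe neuron parameters
#'
#' LIF constants used for both the subthalamic (STN, excitatory) and
#' pallidal (GPe, inhibitory) populations: V_reset -70, V_th -54, C_m 200,
#' g_L 10, t_ref 5 (membrane time constant 20 ms). The resting potential is
#' not part of the published table; it defaults to -70 mV (equal to
#' V_reset) and is exposed here.
#'
#' @param V_rest resting potential (mV)
#' @export
stn_gpe_neuron <- function(V_rest = -70) {
  neuron_params(V_reset = -70, V_th = -54, V_rest = V_rest,
                C_m = 200, g_L = 10, t_ref = 5)
}

#' Neocortical neuron parameters
#'
#' LIF constants shared by the pyramidal (E) and interneuron (I)
#' populations: V_reset -65, V_th -54, E_L -70, C_m 60, g_L 12, t_ref 2.
#' @export
cortex_neuron <- function() {
  neuron_params(V_reset = -65, V_th = -54, V_rest = -70,
                C_m = 60, g_L = 12, t_ref = 2)
}

#' Receptor sets for the two motifs
#'
#' STN-GPe populations carry one excitatory channel (tau 5 ms, E_rev 0 mV)
#' and one inhibitory channel (tau 10 ms, E_rev -80 mV). Neocortical
#' populations carry AMPA (tau 3 ms), NMDA (tau 30 ms) and GABA (tau 5 ms)
#' channels; the excitatory reversal is -10 mV as published (still above
#' threshold, hence depolarizing), switchable to 0 mV via `E_ex`.
#'
#' @param E_ex excitatory reversal potential (mV) for the cortex set
#' @return list of `receptor` objects
#' @export
stn_gpe_receptors <- function() {
  list(ex = receptor("AMPA", tau_syn = 5, E_rev = 0),
       inh = receptor("GABA", tau_syn = 10, E_rev = -80))
}

#' @rdname stn_gpe_receptors
#' @export
cortex_receptors <- function(E_ex = -10) {
  list(AMPA = receptor("AMPA", tau_syn = 3, E_rev = E_ex),
       NMDA = receptor("NMDA", tau_syn = 30, E_rev = E_ex),
       GABA = receptor("GABA", tau_syn = 5, E_rev = -84))
}
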