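#' Resting state of the minimal ventricular model
#'
#' The true fixed point of the model with zero stimulus:
#' `u = u_o`, `v = 1`, `w = 1`, `s = s_inf(u_o)`, where
#' `s_inf(u) = (1 + tanh(k_s (u - u_s))) / 2`. All four time derivatives
#' vanish exactly at this state.
#'
#' @param params A `bofc_params` object.
#' @return Named numeric vector `(u, v, w, s)`.
#' @export
rest_state <- function(params = base_params()) {
  cpp_rest_state(as.numeric(bofc_params(params)))
}

#' Time derivatives and transmembrane currents of the minimal model
#'
#' Evaluates the four state-variable rates and the three currents (fast
#' inward `J_fi`, slow outward `J_so`, slow inward `J_si`) at one state.
#' The voltage rate satisfies `du/dt = -(J_fi + J_so + J_si) + i_stim`
#' identically. Heaviside switches use the convention `H(0) = 1`.
#'
#' This is a plain-R reference implementation; the integrators use an
#' equivalent compiled kernel.
#'
#' @param state Numeric vector `(u, v, w, s)`.
#' @param params A `bofc_params` object.
#' @param i_stim External stimulus current (1/ms), default 0.
#' @return List with `rates` (named 4-vector) and `J_fi`, `J_so`, `J_si`.
#' @export
bofc_derivatives <- function(state, params = base_params(), i_stim = 0) {
  p <- bofc_params(params)
  if (length(state) != 4 || any(!is.finite(state)))
    stop("state must be 4 finite values (u, v, w, s)")
  if (!is.finite(i_stim)) stop("non-finite stimulus")
  u <- state[[1]]; v <- state[[2]]; w <- state[[3]]; s <- state[[4]]
  H <- function(x) as.numeric(x >= 0)

  hv <- H(u - p[["theta_v"]]); hw <- H(u - p[["theta_w"]])
  hvm <- H(u - p[["theta_v_minus"]]); ho <- H(u - p[["theta_o"]])

  tau_v_minus <- (1 - hvm) * p[["tau_v1_minus"]] + hvm * p[["tau_v2_minus"]]
  tau_w_minus <- p[["tau_w1_minus"]] +
    (p[["tau_w2_minus"]] - p[["tau_w1_minus"]]) *
      (1 + tanh(p[["k_w_minus"]] * (u - p[["u_w_minus"]]))) / 2
  tau_so <- p[["tau_so1"]] + (p[["tau_so2"]] - p[["tau_so1"]]) *
    (1 + tanh(p[["k_so"]] * (u - p[["u_so"]]))) / 2
  tau_s <- (1 - hw) * p[["tau_s1"]] + hw * p[["tau_s2"]]
  tau_o <- (1 - ho) * p[["tau_o1"]] + ho * p[["tau_o2"]]

  v_inf <- as.numeric(u < p[["theta_v_minus"]])
  w_inf <- (1 - ho) * (1 - u / p[["tau_w_inf"]]) + ho * p[["w_inf_star"]]
  s_inf <- (1 + tanh(p[["k_s"]] * (u - p[["u_s"]]))) / 2

  J_fi <- -v * hv * (u - p[["theta_v"]]) * (p[["u_u"]] - u) / p[["tau_fi"]]
  J_so <- (u - p[["u_o"]]) * (1 - hw) / tau_o + hw / tau_so
  J_si <- -hw * w * s / p[["tau_si"]]

  rates <- c(
    u = -(J_fi + J_so + J_si) + i_stim,
    v = (1 - hv) * (v_inf - v) / tau_v_minus - hv * v / p[["tau_v_plus"]],
    w = (1 - hw) * (w_inf - w) / tau_w_minus - hw * w / p[["tau_w_plus"]],
    s = (s_inf - s) / tau_s
  )
  list(rates = rates, J_fi = J_fi, J_so = J_so, J_si = J_si)
}
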