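# Canonical parameter order for the four-variable minimal ventricular model.
# Every numeric interface (CSV rows, population matrices, the C++ kernels)
# uses this order; JSON uses the names.
.param_names <- c(
  "u_o", "u_u", "theta_v", "theta_w", "theta_v_minus", "theta_o",
  "tau_v1_minus", "tau_v2_minus", "tau_v_plus",
  "tau_w1_minus", "tau_w2_minus", "k_w_minus", "u_w_minus", "tau_w_plus",
  "tau_fi", "tau_o1", "tau_o2",
  "tau_so1", "tau_so2", "k_so", "u_so",
  "tau_s1", "tau_s2", "k_s", "u_s",
  "tau_si", "tau_w_inf", "w_inf_star"
)

.base_values <- c(
  u_o = 0, u_u = 1.56, theta_v = 0.3, theta_w = 0.13,
  theta_v_minus = 0.2, theta_o = 0.006,
  tau_v1_minus = 75, tau_v2_minus = 10, tau_v_plus = 1.4506,
  tau_w1_minus = 6, tau_w2_minus = 140, k_w_minus = 200,
  u_w_minus = 0.016, tau_w_plus = 280,
  tau_fi = 0.1, tau_o1 = 470, tau_o2 = 6,
  tau_so1 = 40, tau_so2 = 1.2, k_so = 2, u_so = 0.65,
  tau_s1 = 2.7342, tau_s2 = 2, k_s = 2.0994, u_s = 0.9087,
  tau_si = 2.9013, tau_w_inf = 0.0273, w_inf_star = 0.78
)

#' Names of the 28 model parameters in canonical order
#'
#' @return Character vector of length 28.
#' @export
param_names <- function() .param_names

#' Construct a validated minimal-model parameter set
#'
#' A `bofc_params` object is a named numeric vector of the 28 parameters of
#' the minimal ventricular model, stored in a fixed canonical order (see
#' [param_names()]). All time constants (`tau_*`) must be strictly positive.
#'
#' @param x Named numeric vector or list containing all 28 parameters
#'   (any order; reordered canonically).
#' @return An object of class `bofc_params`.
#' @export
bofc_params <- function(x) {
  x <- unlist(x)
  if (is.null(names(x)) || !all(.param_names %in% names(x)))
    stop("parameter set must be named and contain all 28 parameters; missing: ",
         paste(setdiff(.param_names, names(x)), collapse = ", "))
  extra <- setdiff(names(x), .param_names)
  if (length(extra))
    stop("unknown parameter(s): ", paste(extra, collapse = ", "))
  p <- as.numeric(x[.param_names])
  names(p) <- .param_names
  if (any(!is.finite(p)))
    stop("non-finite parameter value(s): ",
         paste(.param_names[!is.finite(p)], collapse = ", "))
  taus <- grepl("^tau_", .param_names)
  if (any(p[taus] <= 0))
    stop("time constants must be > 0; offending: ",
         paste(.param_names[taus][p[taus] <= 0], collapse = ", "))
  structure(p, class = "bofc_params")
}

#' Baseline endocardial parameter set
#'
#' The endocardial column of the published minimal ventricular model, used as
#' the starting point and reference for all calibration, normalization and
#' fold-change computations.
#'
#' @return A `bofc_params` object.
#' @export
base_params <- function() bofc_params(.base_values)

#' @export
print.bofc_params <- function(x, ...) {
  cat("<bofc_params> 28-parameter minimal ventricular model\n")
  print(format(unclass(x), digits = 6), quote = FALSE)
  invisible(x)
}

#' Parameter fold change relative to a reference set
#'
#' Element-wise ratio `params / base` over the 27 parameters with non-zero
#' base value. `u_o` (base value 0, pinned during calibration) is excluded;
#' any other zero base entry is an error.
#'
#' @param params,base `bofc_params` objects (or named 28-vectors).
#' @return Named numeric vector of 27 ratios.
#' @export
param_fold_change <- function(params, base = base_params()) {
  p <- bofc_params(params)
  b <- bofc_params(base)
  keep <- setdiff(.param_names, "u_o")
  if (any(b[keep] == 0))
    stop("zero base entry for: ", paste(keep[b[keep] == 0], collapse = ", "))
  p[keep] / b[keep]
}

#' Read/write parameter sets
#'
#' JSON files hold a single name-to-value map with exactly 28 keys; CSV files
#' hold one header row (canonical order) and one value row.
#'
#' @param params A `bofc_params` object.
#' @param path File path.
#' @return `read_params()` returns a `bofc_params`; writers return `path`
#'   invisibly.
#' @export
write_params <- function(params, path) {
  params <- bofc_params(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(unclass(params)), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    df <- as.data.frame(as.list(unclass(params)), check.names = FALSE)
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path)
    missing <- setdiff(.param_names, names(x))
    if (length(missing))
      stop("parameter JSON missing key(s): ", paste(missing, collapse = ", "))
    bofc_params(unlist(x))
  } else {
    df <- read.csv(path, check.names = FALSE)
    bofc_params(unlist(df[1, , drop = TRUE]))
  }
}

# Affine map between the dimensionless transmembrane variable and millivolts.
.mv_slope <- 85.7
.mv_offset <- -84

#' Rescale the dimensionless voltage to millivolts (and back)
#'
#' Affine map `V = 85.7 u - 84` mV, the model's published rescaling; the
#' resting value `u = 0` maps to -84 mV.
#'
#' @param u Dimensionless voltage.
#' @param v Voltage in mV.
#' @return Numeric vector.
#' @export
rescale_voltage <- function(u) .mv_slope * u + .mv_offset

#' @rdname rescale_voltage
#' @export
unscale_voltage <- function(v) (v - .mv_offset) / .mv_slope
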