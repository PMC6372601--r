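#' Model parameters for the SAC bursting model
#'
#' Builds a validated parameter set for the five-variable conductance-based
#' model of immature starburst amacrine cell (SAC) bursting. Defaults are the
#' calibrated biophysical values of the model; all quantities use a fixed unit
#' system (ms, mV, pF, pA, nS, nM), chosen so that nS*mV = pA and pA/pF =
#' mV/ms and no hidden scale factors are needed anywhere.
#'
#' The conductances `g_C` (voltage-gated calcium) and `g_K` (fast
#' voltage-gated potassium) have no unique physiological value; the default
#' working point (g_C = 12 nS, g_K = 10 nS) is the configuration used
#' throughout the bifurcation analysis. `sigma` is the amplitude of the white
#' current noise entering the voltage equation (pA ms^(1/2)); `I_ext_baseline`
#' is the constant external current used when no stimulation protocol is
#' given.
#'
#' @param ... named overrides of any default parameter, e.g. `g_K = 8`,
#'   `V_3 = -34`. Unknown names are an error.
#' @return An object of class `sac_params`: a named list with components
#'   `C_m` (pF), `g_L`, `g_C`, `g_K`, `g_sAHP` (nS), `V_L`, `V_C`, `V_K`,
#'   `V_1`, `V_2`, `V_3`, `V_4` (mV), `tau_N`, `tau_R`, `tau_S`, `tau_C`
#'   (ms), `delta_C` (nM/pA), `alpha_S` (nM^-4), `alpha_C` (nM), `alpha_R`
#'   (dimensionless), `H_X` (nM), `C_0` (nM), `sigma` (pA ms^(1/2)),
#'   `I_ext_baseline` (pA).
#' @examples
#' p <- sac_params()                 # reference working point
#' p8 <- sac_params(g_K = 10, V_3 = -34)  # silent, more mature configuration
#' @export
sac_params <- function(...) {
  p <- sac_param_defaults()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(over)] <- lapply(over, as.numeric)
  }
  validate_sac_params(structure(p, class = "sac_params"))
}

# Single source of the default parameter table.
sac_param_defaults <- function() {
  list(
    C_m = 22, g_L = 2, g_C = 12, g_K = 10, g_sAHP = 2,
    V_L = -70, V_C = 50, V_K = -90,
    V_1 = -20, V_2 = 20, V_3 = -25, V_4 = 7,
    tau_N = 5, tau_R = 8300, tau_S = 8300, tau_C = 2000,
    delta_C = 10.503, alpha_S = 1 / 200^4, alpha_C = 4865,
    alpha_R = 4.25, H_X = 1800, C_0 = 88,
    sigma = 4, I_ext_baseline = 0
  )
}

validate_sac_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p))
    if (!num1(p[[nm]])) stop("parameter ", nm, " must be a finite scalar")
  pos <- c("C_m", "tau_N", "tau_R", "tau_S", "tau_C", "V_2", "V_4", "H_X")
  for (nm in pos)
    if (p[[nm]] <= 0) stop("parameter ", nm, " must be > 0")
  nonneg <- c("g_L", "g_C", "g_K", "g_sAHP", "sigma", "alpha_S", "alpha_C",
              "alpha_R", "C_0")
  for (nm in nonneg)
    if (p[[nm]] < 0) stop("parameter ", nm, " must be >= 0")
  if (!(p$V_K < p$V_L && p$V_L < p$V_C))
    stop("reversal potentials must satisfy V_K < V_L < V_C")
  p
}

#' @export
print.sac_params <- function(x, ...) {
  cat("SAC bursting model parameters (ms, mV, pF, pA, nS, nM)\n")
  d <- sac_param_defaults()
  for (nm in names(x)) {
    tag <- if (!identical(x[[nm]], d[[nm]])) "  *" else ""
    cat(sprintf("  %-14s %.10g%s\n", nm, x[[nm]], tag))
  }
  if (any(vapply(names(x), function(nm) !identical(x[[nm]], d[[nm]]), TRUE)))
    cat("  (* differs from default)\n")
  invisible(x)
}

# Parameter vector in the fixed order expected by the compiled integrators.
param_vector <- function(p) {
  unlist(p[c("C_m", "g_L", "g_C", "g_K", "g_sAHP",
             "V_L", "V_C", "V_K", "V_1", "V_2", "V_3", "V_4",
             "tau_N", "tau_R", "tau_S", "tau_C",
             "delta_C", "alpha_S", "alpha_C", "alpha_R", "H_X", "C_0")])
}

#' Read or write a parameter configuration file
#'
#' Parameter sets are stored as flat `key = value` text, one key per model
#' symbol, in the package's fixed units. Unknown keys are an error; missing
#' keys are filled from the defaults with a notice (suppress with
#' `quiet = TRUE`).
#'
#' @param path file path.
#' @param quiet suppress the notice listing defaulted keys.
#' @return `read_params_config`: a `sac_params` object.
#' @export
read_params_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- sac_param_defaults()
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("cannot parse config line: '", ln, "'")
    key <- trimws(kv[1]); val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    if (is.na(val)) stop("non-numeric value for key ", key)
    over[[key]] <- val
  }
  missing <- setdiff(names(defaults), names(over))
  if (length(missing) && !quiet)
    message("config ", path, ": ", length(missing),
            " key(s) filled from defaults (",
            paste(missing, collapse = ", "), ")")
  do.call(sac_params, over)
}

#' @rdname read_params_config
#' @param params a `sac_params` object.
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "sac_params"))
  lines <- sprintf("%s = %.9g", names(params), unlist(params))
  writeLines(lines, path)
  invisible(path)
}
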