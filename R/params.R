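#' Circuit parameters for a plasmid-borne repressible expression system
#'
#' Describes either a bicistronic autoregulated circuit (repressor and
#' reporter translated from the same repressible mRNA, so the repressor
#' feeds back on its own promoter) or a circuit whose repressor is expressed
#' constitutively at a fixed level.
#'
#' @param mode `"autoregulated"` (negative feedback through the bicistron) or
#'   `"constitutive_repressor"` (fixed repressor pool `R0`).
#' @param alpha Transcription-translation gain per plasmid copy: the reporter
#'   level one fully active copy sustains (protein units, AU).
#' @param basal Basal promoter activity fraction in `[0, 1]` (leakiness under
#'   saturating repression).
#' @param K_R Active-repressor concentration at half-maximal repression
#'   (protein units).
#' @param hill_R Hill coefficient of repression (>= 1).
#' @param Kd_I Inducer concentration at half de-repression, in the inducer's
#'   own units (nM for an ATc-like inducer, uM for an IPTG-like one).
#' @param hill_I Hill coefficient of inducer binding (>= 1).
#' @param r_ratio Repressor:reporter translation ratio of the bicistron (> 0);
#'   only used in autoregulated mode.
#' @param R0 Constitutive repressor level (protein units); only used in
#'   constitutive mode.
#' @param N_mean Mean plasmid copy number (> 0).
#' @param N_disp Copy-number dispersion, variance/mean. Values > 1 give an
#'   overdispersed (negative binomial) law, 0 < values <= 1 fall back to
#'   Poisson, and 0 gives a constant copy number `round(N_mean)`. Draws are
#'   floored at 1: a transformed cell carries at least one plasmid.
#' @param burst Intrinsic burst size b (proteins); the reporter is drawn as
#'   Gamma(shape = G_det/b, scale = b). `burst = 0` is the deterministic
#'   limit (no intrinsic noise).
#' @param size_cv2 Extrinsic cell-size CV^2; cell sizes are lognormal with
#'   mean 1. `0` disables size variation.
#'
#' @return An object of class `circuit_params` (a validated named list).
#' @seealso [tetr_circuit()], [laci_circuit()], [simulate_population()]
#' @examples
#' p <- circuit_params(alpha = 2000, N_mean = 10)
#' steady_state_reporter(p, inducer = 25, N = 10)
#' @export
circuit_params <- function(mode = c("autoregulated", "constitutive_repressor"),
                           alpha = 3000,
                           basal = 0.002,
                           K_R = 30,
                           hill_R = 2,
                           Kd_I = 10,
                           hill_I = 2,
                           r_ratio = 1,
                           R0 = 500,
                           N_mean = 10,
                           N_disp = 2,
                           burst = 10,
                           size_cv2 = 0.05) {
  mode <- match.arg(mode)
  p <- list(mode = mode, alpha = as.numeric(alpha), basal = as.numeric(basal),
            K_R = as.numeric(K_R), hill_R = as.numeric(hill_R),
            Kd_I = as.numeric(Kd_I), hill_I = as.numeric(hill_I),
            r_ratio = as.numeric(r_ratio), R0 = as.numeric(R0),
            N_mean = as.numeric(N_mean), N_disp = as.numeric(N_disp),
            burst = as.numeric(burst), size_cv2 = as.numeric(size_cv2))
  class(p) <- "circuit_params"
  validate_circuit_params(p)
  p
}

validate_circuit_params <- function(p) {
  chk <- function(cond, what) {
    if (!isTRUE(cond)) stop("invalid circuit_params: ", what, call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("alpha", "basal", "K_R", "hill_R", "Kd_I", "hill_I", "r_ratio",
              "R0", "N_mean", "N_disp", "burst", "size_cv2")) {
    chk(num1(p[[f]]), paste(f, "must be a finite numeric scalar"))
  }
  chk(p$mode %in% c("autoregulated", "constitutive_repressor"), "unknown mode")
  chk(p$alpha >= 0, "alpha must be >= 0")
  chk(p$basal >= 0 && p$basal <= 1, "basal must be in [0, 1]")
  chk(p$K_R > 0, "K_R must be > 0")
  chk(p$hill_R >= 1, "hill_R must be >= 1")
  chk(p$Kd_I > 0, "Kd_I must be > 0")
  chk(p$hill_I >= 1, "hill_I must be >= 1")
  chk(p$r_ratio > 0, "r_ratio must be > 0")
  chk(p$R0 >= 0, "R0 must be >= 0")
  chk(p$N_mean > 0, "N_mean must be > 0")
  chk(p$N_disp >= 0, "N_disp must be >= 0")
  chk(p$burst >= 0, "burst must be >= 0")
  chk(p$size_cv2 >= 0, "size_cv2 must be >= 0")
  invisible(p)
}

#' Default TetR-like and LacI-like circuit parameter sets
#'
#' Convenience constructors encoding the qualitative contrasts between the
#' two regulators: ATc binds TetR roughly three orders of magnitude more
#' strongly (in molar terms) than IPTG binds LacI, so the TetR-like `Kd_I`
#' is 10 on an nM scale while the LacI-like `Kd_I` is 10 on a uM scale.
#' The `backbone` argument selects the plasmid copy-number regime:
#' a p15A-like medium-copy origin (`N_mean = 10`) or a pSC101-like low-copy
#' origin (`N_mean = 4`).
#'
#' @param backbone `"p15A"` (N_mean = 10) or `"pSC101"` (N_mean = 4).
#' @param mode Passed to [circuit_params()].
#' @param ... Further overrides passed to [circuit_params()].
#' @return A `circuit_params` object.
#' @export
tetr_circuit <- function(backbone = c("p15A", "pSC101"),
                         mode = "autoregulated", ...) {
  backbone <- match.arg(backbone)
  args <- list(mode = mode, Kd_I = 10, hill_I = 2,
               N_mean = if (backbone == "p15A") 10 else 4)
  args <- utils::modifyList(args, list(...))
  do.call(circuit_params, args)
}

#' @rdname tetr_circuit
#' @export
laci_circuit <- function(backbone = c("p15A", "pSC101"),
                         mode = "autoregulated", ...) {
  backbone <- match.arg(backbone)
  args <- list(mode = mode, Kd_I = 10, hill_I = 1.3,
               N_mean = if (backbone == "p15A") 10 else 4)
  args <- utils::modifyList(args, list(...))
  do.call(circuit_params, args)
}

#' Cytometer measurement model parameters
#'
#' Parameters of the mapping from a cell's ground-truth state (reporter
#' molecules G, cell size s) to recorded cytometry channels. Fluorescence:
#' `fl1 = (G * maturation_fraction + autofluorescence * s) * (1 + eps)`, with
#' `eps` Gaussian of SD `instrument_cv`. Scatter channels are proportional to
#' cell size with their own multiplicative noise, which makes scatter only
#' weakly correlated with fluorescence. A `debris_fraction` of events is
#' replaced by small low-fluorescence particles unrelated to the population.
#'
#' Default maturation fractions correspond to a 60-minute translation-arrest
#' chase with maturation time constants of 5.6 min (GFP-like, channel 1) and
#' 25.7 min (RFP-like, channel 2): `1 - exp(-60/tau)`.
#'
#' @param autofluorescence Cell autofluorescence per unit size (AU).
#' @param instrument_cv Multiplicative measurement noise CV (>= 0).
#' @param maturation_fraction,maturation_fraction2 Fraction of matured
#'   (fluorescent) reporter per channel, in `[0, 1]`.
#' @param debris_fraction Fraction of events that are debris, in `[0, 1)`.
#' @param debris_scale Mean fluorescence of debris events (AU).
#' @param fsc_gain,ssc_gain Scatter channel gains (AU per unit size, > 0).
#' @param fsc_cv,ssc_cv Scatter channel noise CVs (>= 0).
#' @param n_events Default number of events recorded per sample.
#' @return An object of class `measurement_params`.
#' @export
measurement_params <- function(autofluorescence = 100,
                               instrument_cv = 0.05,
                               maturation_fraction = 1 - exp(-60 / 5.6),
                               maturation_fraction2 = 1 - exp(-60 / 25.7),
                               debris_fraction = 0.02,
                               debris_scale = 20,
                               fsc_gain = 5e4,
                               fsc_cv = 0.15,
                               ssc_gain = 2e4,
                               ssc_cv = 0.25,
                               n_events = 30000L) {
  m <- list(autofluorescence = as.numeric(autofluorescence),
            instrument_cv = as.numeric(instrument_cv),
            maturation_fraction = as.numeric(maturation_fraction),
            maturation_fraction2 = as.numeric(maturation_fraction2),
            debris_fraction = as.numeric(debris_fraction),
            debris_scale = as.numeric(debris_scale),
            fsc_gain = as.numeric(fsc_gain), fsc_cv = as.numeric(fsc_cv),
            ssc_gain = as.numeric(ssc_gain), ssc_cv = as.numeric(ssc_cv),
            n_events = as.integer(n_events))
  class(m) <- "measurement_params"
  validate_measurement_params(m)
  m
}

validate_measurement_params <- function(m) {
  chk <- function(cond, what) {
    if (!isTRUE(cond)) stop("invalid measurement_params: ", what, call. = FALSE)
  }
  chk(m$autofluorescence >= 0, "autofluorescence must be >= 0")
  chk(m$instrument_cv >= 0, "instrument_cv must be >= 0")
  chk(m$maturation_fraction >= 0 && m$maturation_fraction <= 1,
      "maturation_fraction must be in [0, 1]")
  chk(m$maturation_fraction2 >= 0 && m$maturation_fraction2 <= 1,
      "maturation_fraction2 must be in [0, 1]")
  chk(m$debris_fraction >= 0 && m$debris_fraction < 1,
      "debris_fraction must be in [0, 1)")
  chk(m$debris_scale >= 0, "debris_scale must be >= 0")
  chk(m$fsc_gain > 0 && m$ssc_gain > 0, "scatter gains must be > 0")
  chk(m$fsc_cv >= 0 && m$ssc_cv >= 0, "scatter noise CVs must be >= 0")
  chk(m$n_events >= 1, "n_events must be >= 1")
  invisible(m)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params> mode:", x$mode, "\n")
  flds <- setdiff(names(x), "mode")
  cat(paste0("  ", flds, " = ", unlist(x[flds]), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.measurement_params <- function(x, ...) {
  cat("<measurement_params>\n")
  cat(paste0("  ", names(x), " = ", unlist(x), collapse = "\n"), "\n")
  invisible(x)
}
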