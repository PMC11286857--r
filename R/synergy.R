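#' Bliss independent-action expectation
#'
#' Under the independence assumption, a drug causing effect fraction `v` and
#' a drug causing effect fraction `w` jointly produce
#' `CI_mix = 1 - (1 - v)(1 - w)`. Effects are fractions of maximal response
#' (e.g. 1 - survival fraction) in \[0, 1\].
#'
#' @param v,w Effect fractions in \[0, 1\] (vectorized).
#' @return Expected combined effect fraction in \[0, 1\].
#' @export
bliss_ci <- function(v, w) {
  if (any(v < 0 | v > 1 | w < 0 | w > 1)) {
    stop("effect fractions must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - v) * (1 - w)
}

#' Single-drug dose-response curve
#'
#' Stores an ordered concentration / survival-fraction table for one drug.
#' Concentrations must be positive and strictly increasing; survival
#' fractions in \[0, 1.5\] (values above 1 indicate stimulation and are
#' flagged). Effects are defined as `1 - survival`, clamped at 0 when
#' survival exceeds 1.
#'
#' @param concentration Positive, strictly increasing numeric vector.
#' @param survival Mean survival fractions (same length).
#' @param sd,n_replicates Optional per-point dispersion and replicate count.
#' @param drug Drug identifier.
#' @return A `dose_response` object with an `effect` column.
#' @export
dose_response <- function(concentration, survival, sd = NA_real_,
                          n_replicates = NA_integer_, drug = "drug") {
  stopifnot(length(concentration) == length(survival))
  if (any(concentration <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (is.unsorted(concentration, strictly = TRUE)) {
    stop("concentrations must be strictly increasing", call. = FALSE)
  }
  if (any(survival < 0 | survival > 1.5)) {
    stop("survival fractions must lie in [0, 1.5]", call. = FALSE)
  }
  stimulated <- survival > 1
  if (any(stimulated)) {
    warning(sprintf("%d well(s) with survival > 100%% (stimulation); effect clamped at 0",
                    sum(stimulated)), call. = FALSE)
  }
  structure(data.frame(concentration = concentration, survival = survival,
                       effect = pmax(0, 1 - survival), sd = sd,
                       n_replicates = n_replicates),
            class = c("dose_response", "data.frame"), drug = drug)
}

#' Equi-effective concentration EC_u from a dose-response curve
#'
#' The concentration at which a single drug produces effect fraction `u`,
#' interpolated log-linearly (linear in `log10` concentration vs effect)
#' between the bracketing measured points. No parametric curve is fitted and
#' no extrapolation is performed: `u` outside the observed effect range is an
#' error. A non-monotone curve is first cleaned up by isotonic regression
#' (with a warning); `u` equal to a measured effect returns that measured
#' concentration.
#'
#' @param curve A [dose_response()] object (or data.frame with
#'   `concentration` and `effect` columns).
#' @param u Target effect fraction.
#' @return Interpolated concentration.
#' @export
ec_u <- function(curve, u) {
  stopifnot(is.data.frame(curve),
            all(c("concentration", "effect") %in% names(curve)))
  conc <- curve$concentration
  eff <- curve$effect
  if (is.unsorted(eff)) {
    warning("non-monotone dose-response curve; isotonic regression applied",
            call. = FALSE)
    eff <- stats::isoreg(log10(conc), eff)$yf
  }
  hit <- which(eff == u)
  if (length(hit) > 0L) return(conc[hit[1L]])
  if (u < min(eff) || u > max(eff)) {
    stop(sprintf("effect u = %.3f outside observed range [%.3f, %.3f]; no extrapolation",
                 u, min(eff), max(eff)), call. = FALSE)
  }
  # first bracketing interval with strictly increasing effect
  i <- max(which(eff < u))
  frac <- (u - eff[i]) / (eff[i + 1L] - eff[i])
  10^(log10(conc[i]) + frac * (log10(conc[i + 1L]) - log10(conc[i])))
}

#' Interpolate the effect of a single drug at a concentration
#'
#' Inverse companion of [ec_u()]: log-linear interpolation of the effect at
#' a concentration inside the measured range.
#'
#' @inheritParams ec_u
#' @param conc Concentration inside the measured range.
#' @export
effect_at <- function(curve, conc) {
  stopifnot(is.data.frame(curve))
  x <- curve$concentration
  eff <- curve$effect
  if (is.unsorted(eff)) eff <- stats::isoreg(log10(x), eff)$yf
  if (conc < min(x) || conc > max(x)) {
    stop("concentration outside measured range; no extrapolation", call. = FALSE)
  }
  stats::approx(log10(x), eff, xout = log10(conc), ties = "ordered")$y
}

#' Loewe concentration-addition toxic unit
#'
#' `TU = Ca / EC_u^A + Cb / EC_u^B`: each combination dose expressed as a
#' fraction of its drug's equi-effective concentration at the combination's
#' observed effect level `u`, then summed. TU = 1 on the additivity
#' (sham-combination) line; TU < 1 indicates synergy, and the smaller the TU
#' the stronger the synergy.
#'
#' @param Ca,Cb Combination concentrations (positive).
#' @param EC_u_A,EC_u_B Equi-effective concentrations at the observed
#'   combination effect (positive; see [ec_u()]).
#' @return The toxic unit (positive real).
#' @export
loewe_tu <- function(Ca, Cb, EC_u_A, EC_u_B) {
  if (any(c(EC_u_A, EC_u_B) <= 0)) stop("EC values must be positive", call. = FALSE)
  if (any(c(Ca, Cb) < 0)) stop("concentrations must be non-negative", call. = FALSE)
  Ca / EC_u_A + Cb / EC_u_B
}

#' Score combination wells of a dose-response plate
#'
#' For each combination well, computes both synergy statistics from the
#' single-drug curves:
#' * the Loewe/concentration-addition score `ca` ([loewe_tu()]) at the
#'   combination's observed effect level (wells whose effect falls outside a
#'   single-drug curve's observed range get `NA` with a note -- no
#'   extrapolation);
#' * the Bliss expectation `bliss_expected` from the single-drug effects at
#'   the combination concentrations ([bliss_ci()]), the observed effect, and
#'   the excess over Bliss `ia_excess = observed - expected`.
#'
#' @param plate A `dose_response_plate`: list with `curves` (named list of
#'   [dose_response()] objects) and `combos` (`data.frame` with `drug_a`,
#'   `conc_a`, `drug_b`, `conc_b`, `survival`).
#' @return `data.frame` with one row per combination well: observed effect,
#'   `ca`, `bliss_expected`, `ia_excess`, and synergy calls `ca_synergy`
#'   (`ca < 1`) and `ia_synergy` (`observed > bliss_expected`).
#' @export
plate_synergy <- function(plate) {
  stopifnot(is.list(plate), !is.null(plate$curves), !is.null(plate$combos))
  combos <- plate$combos
  out <- lapply(seq_len(nrow(combos)), function(i) {
    w <- combos[i, ]
    ca_curve <- plate$curves[[as.character(w$drug_a)]]
    cb_curve <- plate$curves[[as.character(w$drug_b)]]
    observed <- max(0, 1 - w$survival)
    tu <- tryCatch({
      loewe_tu(w$conc_a, w$conc_b,
               ec_u(ca_curve, observed), ec_u(cb_curve, observed))
    }, error = function(e) NA_real_)
    va <- tryCatch(effect_at(ca_curve, w$conc_a), error = function(e) NA_real_)
    vb <- tryCatch(effect_at(cb_curve, w$conc_b), error = function(e) NA_real_)
    expected <- if (is.na(va) || is.na(vb)) NA_real_ else bliss_ci(va, vb)
    data.frame(drug_a = w$drug_a, conc_a = w$conc_a,
               drug_b = w$drug_b, conc_b = w$conc_b,
               observed_effect = observed, ca = tu,
               bliss_expected = expected,
               ia_excess = observed - expected,
               ca_synergy = !is.na(tu) & tu < 1,
               ia_synergy = !is.na(expected) & observed > expected,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize synergy calls over a set of drug combinations
#'
#' Applies the two standard calls and reports the synergistic fractions:
#' * concentration-addition (CA / Loewe): synergy when the CA score (toxic
#'   unit) is strictly below 1;
#' * independent action (IA / Bliss): synergy when the reported IA score is
#'   at least 1 (for published IA score columns), or -- when plate-level
#'   `ia_excess` values are supplied instead -- when the observed effect
#'   strictly exceeds the Bliss expectation.
#'
#' Missing scores (untested combinations) are excluded from the denominator
#' of their model. Percentages are reported to one decimal.
#'
#' @param scores `data.frame` with any of the columns `ca` (CA score / toxic
#'   unit), `ia` (reported IA score) or `ia_excess` (observed minus Bliss
#'   expectation).
#' @return List with per-model counts (`n`), synergy counts (`n_synergistic`)
#'   and percentage (`pct`), as a named list per model.
#' @export
classify_and_summarize <- function(scores) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1L)
  out <- list()
  if ("ca" %in% names(scores)) {
    v <- scores$ca[!is.na(scores$ca)]
    out$ca <- list(n = length(v), n_synergistic = sum(v < 1),
                   pct = round(100 * sum(v < 1) / length(v), 1))
  }
  if ("ia" %in% names(scores)) {
    v <- scores$ia[!is.na(scores$ia)]
    out$ia <- list(n = length(v), n_synergistic = sum(v >= 1),
                   pct = round(100 * sum(v >= 1) / length(v), 1))
  } else if ("ia_excess" %in% names(scores)) {
    v <- scores$ia_excess[!is.na(scores$ia_excess)]
    out$ia <- list(n = length(v), n_synergistic = sum(v > 0),
                   pct = round(100 * sum(v > 0) / length(v), 1))
  }
  if (length(out) == 0L) stop("no synergy score columns (ca / ia / ia_excess)",
                              call. = FALSE)
  out
}
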