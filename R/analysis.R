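# Mechanics observables: stress-strain curves, peak stress, work to
# failure, the elastic-limit strain, per-species force histories, failure
# fractions, and the sliding decomposition.

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Stress-strain curve of a tensile run
#'
#' Engineering stress (clamp force over the construction cross-section
#' area) against global strain, with an optional centered moving-average
#' smoothing of the stress over a strain window (raw values are kept).
#'
#' @param run a `tensile_run`, or a series data frame with `strain` and
#'   `stress` columns.
#' @param area cross-section area (A^2); only needed when `run` is a bare
#'   force series with a `force` column instead of `stress`.
#' @param smooth_window smoothing window in strain units (default 0.002);
#'   0 disables smoothing.
#' @return data frame with `strain`, `stress` (raw) and `stress_smooth`;
#'   the window used is recorded in `attr(, "smooth_window")`.
#' @export
stress_strain <- function(run, area = NULL, smooth_window = 0.002) {
  ser <- if (inherits(run, "tensile_run")) run$series else run
  if (nrow(ser) == 0) stop("empty series")
  stress <- if (!is.null(ser$stress)) ser$stress else {
    if (is.null(area) || area <= 0) stop("positive area required")
    ser$force / area
  }
  curve <- data.frame(strain = ser$strain, stress = stress)
  curve$stress_smooth <- smooth_stress(curve$strain, curve$stress, smooth_window)
  attr(curve, "smooth_window") <- smooth_window
  curve
}

smooth_stress <- function(strain, stress, window) {
  n <- length(stress)
  if (window <= 0 || n < 5) return(stress)
  dstrain <- stats::median(diff(strain))
  if (!is.finite(dstrain) || dstrain <= 0) return(stress)
  k <- max(1L, round(window / dstrain))
  if (k %% 2 == 0) k <- k + 1L
  if (k >= n) k <- if (n %% 2 == 0) n - 1L else n
  if (k < 3) return(stress)
  sm <- stats::filter(stress, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  # fill the ends with shrinking one-sided means
  h <- (k - 1L) %/% 2L
  for (q in seq_len(h)) {
    sm[q] <- mean(stress[1:(q + h)])
    sm[n - q + 1L] <- mean(stress[(n - q + 1L - h):n])
  }
  sm
}

#' Summary metrics of a stress-strain curve
#'
#' Peak stress, work to failure (trapezoidal integral of the raw stress up
#' to the failure strain), the stress at the elastic limit, the
#' elastic-to-peak stress difference (floored at zero), and terminal
#' broken fractions per bond species when a full run is supplied.
#'
#' The failure strain is the first strain after the peak where the
#' smoothed stress falls below 5 percent of the peak; if the curve ends
#' before that, the metrics are flagged partial and the last strain is
#' used.
#'
#' @param run a `tensile_run` or a curve from [stress_strain()].
#' @param eps0_policy `"fixed"` (use `eps0`) or `"detect"`
#'   ([detect_linear_limit()]).
#' @param eps0 elastic-limit strain for the fixed policy (default 0.15).
#' @param smooth_window passed to [stress_strain()].
#' @return list of class `fibril_metrics`: `sigma_peak`, `strain_at_peak`,
#'   `w_f`, `eps0`, `sigma_0`, `delta_sigma`, `failure_strain`, `partial`,
#'   `broken_fractions` (named vector, runs only).
#' @export
summarize_mechanics <- function(run, eps0_policy = c("fixed", "detect"),
                                eps0 = 0.15, smooth_window = 0.002) {
  eps0_policy <- match.arg(eps0_policy)
  curve <- if (inherits(run, "tensile_run")) {
    stress_strain(run, smooth_window = smooth_window)
  } else run
  if (is.null(curve$stress_smooth)) {
    curve$stress_smooth <- smooth_stress(curve$strain, curve$stress,
                                         smooth_window)
  }
  if (all(curve$stress == 0)) {
    return(structure(list(sigma_peak = 0, strain_at_peak = 0, w_f = 0,
                          eps0 = eps0, sigma_0 = 0, delta_sigma = 0,
                          failure_strain = max(curve$strain), partial = FALSE,
                          broken_fractions = NULL),
                     class = "fibril_metrics"))
  }
  ipk <- which.max(curve$stress_smooth)
  sigma_peak <- curve$stress_smooth[ipk]
  after <- seq(ipk, nrow(curve))
  below <- after[curve$stress_smooth[after] < 0.05 * sigma_peak]
  partial <- length(below) == 0
  ifail <- if (partial) nrow(curve) else below[1]
  failure_strain <- curve$strain[ifail]
  w_f <- trapz(curve$strain[1:ifail], curve$stress[1:ifail])
  if (eps0_policy == "detect") {
    det <- detect_linear_limit(curve)
    eps0 <- det$eps0
  }
  if (max(curve$strain) < eps0) {
    sigma_0 <- NA_real_; delta_sigma <- NA_real_; partial <- TRUE
  } else {
    sigma_0 <- stats::approx(curve$strain, curve$stress_smooth, xout = eps0,
                             ties = "ordered")$y
    delta_sigma <- max(sigma_peak - sigma_0, 0)
  }
  bf <- NULL
  if (inherits(run, "tensile_run")) {
    bf <- terminal_broken_fractions(run, failure_strain)
  }
  structure(list(sigma_peak = sigma_peak, strain_at_peak = curve$strain[ipk],
                 w_f = w_f, eps0 = eps0, sigma_0 = sigma_0,
                 delta_sigma = delta_sigma, failure_strain = failure_strain,
                 partial = partial, broken_fractions = bf),
            class = "fibril_metrics")
}

#' @export
print.fibril_metrics <- function(x, ...) {
  cat(sprintf("<fibril_metrics> sigma_peak=%.4g @ eps=%.3f | W_f=%.4g | eps0=%.3f sigma_0=%.4g dsigma=%.4g | fail @ %.3f%s\n",
              x$sigma_peak, x$strain_at_peak, x$w_f, x$eps0, x$sigma_0,
              x$delta_sigma, x$failure_strain,
              if (x$partial) " (partial)" else ""))
  invisible(x)
}

#' Detect the limit of the initial linear regime
#'
#' Fits the initial modulus on `fit_window` (least squares on the smoothed
#' curve) and reports the first strain beyond the window where the running
#' tangent deviates from it by more than `dev_frac`, sustained over
#' `sustain` strain. Returns the curve end when no deviation occurs
#' (an exactly linear curve).
#'
#' @param curve a curve from [stress_strain()] (or a `tensile_run`).
#' @param fit_window strain interval for the reference modulus.
#' @param dev_frac relative tangent deviation that ends the linear regime.
#' @param tangent_window strain half-width of the running tangent fit.
#' @param sustain deviation must persist over this much strain.
#' @return list with `eps0`, `modulus`, `method`.
#' @export
detect_linear_limit <- function(curve, fit_window = c(0.02, 0.10),
                                dev_frac = 0.10, tangent_window = 0.02,
                                sustain = 0.01) {
  if (inherits(curve, "tensile_run")) curve <- stress_strain(curve)
  if (sum(curve$strain < fit_window[2]) < 50) {
    stop("curve too short below the nominal elastic limit; use the fixed policy")
  }
  s <- curve$strain; y <- curve$stress_smooth
  infit <- s >= fit_window[1] & s <= fit_window[2]
  fit <- stats::lm.fit(cbind(1, s[infit]), y[infit])
  e0 <- fit$coefficients[2]
  # running tangent: symmetric-difference slope over the tangent window
  ds <- stats::median(diff(s))
  h <- max(2L, round(tangent_window / 2 / ds))
  n <- length(s)
  idx <- seq_len(n)
  lo <- pmax(1L, idx - h); hi <- pmin(n, idx + h)
  tang <- (y[hi] - y[lo]) / (s[hi] - s[lo])
  dev <- abs(tang - e0) > dev_frac * abs(e0)
  need <- max(1L, round(sustain / ds))
  cand <- which(dev & s > fit_window[2])
  eps0 <- max(s)
  if (length(cand) > 0) {
    runs <- rle(seq_along(s) %in% cand)
    # first index where the deviation is sustained
    pos <- cumsum(runs$lengths)
    j <- which(runs$values & runs$lengths >= need)
    if (length(j) > 0) eps0 <- s[pos[j[1]] - runs$lengths[j[1]] + 1L]
    else eps0 <- s[cand[1]]
  }
  list(eps0 = unname(eps0), modulus = unname(e0), method = "tangent-deviation")
}

#' Per-species mean bond-force histories
#'
#' Mean tension over the intact bonds of each species at every sample:
#' the backbone (`f_backbone`), enzymatic cross-links (divalent +
#' trivalent pooled into `f_ecl`) and AGEs (`f_age`). Species that were
#' never present are reported absent (dropped), not zero.
#'
#' @param run a `tensile_run`.
#' @return data frame in long format: `strain`, `species`, `force`.
#' @export
bond_force_by_type <- function(run) {
  stopifnot(inherits(run, "tensile_run"))
  ser <- run$series
  c0 <- run$census0
  out <- list()
  if (c0$n_total[c0$species == "backbone"] > 0) {
    out$tc <- data.frame(strain = ser$strain, species = "backbone",
                         force = ser$f_backbone)
  }
  n_div <- c0$n_total[c0$species == "ecl_divalent"]
  n_tri <- c0$n_total[c0$species == "ecl_trivalent"]
  if (n_div + n_tri > 0) {
    fd <- ifelse(is.na(ser$f_ecl_divalent), 0, ser$f_ecl_divalent * ser$n_ecl_divalent)
    ft <- ifelse(is.na(ser$f_ecl_trivalent), 0, ser$f_ecl_trivalent * ser$n_ecl_trivalent)
    ntot <- ser$n_ecl_divalent + ser$n_ecl_trivalent
    out$ecl <- data.frame(strain = ser$strain, species = "ecl",
                          force = ifelse(ntot > 0, (fd + ft) / ntot, NA_real_))
  }
  if (c0$n_total[c0$species == "age"] > 0) {
    out$age <- data.frame(strain = ser$strain, species = "age",
                          force = ser$f_age)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cumulative broken fraction per species against strain
#'
#' Step functions in `[0, 1]` with the initially inserted count of each
#' species as denominator; species with no initial bonds are reported
#' absent.
#'
#' @param run a `tensile_run`.
#' @return data frame: `strain`, `species`, `fraction`.
#' @export
broken_fraction_by_type <- function(run) {
  stopifnot(inherits(run, "tensile_run"))
  ser <- run$series
  c0 <- run$census0
  out <- list()
  for (sp in BOND_SPECIES) {
    n0 <- c0$n_intact[c0$species == sp]
    if (n0 == 0) next
    frac <- 1 - ser[[paste0("n_", sp)]] / n0
    out[[sp]] <- data.frame(strain = ser$strain, species = sp,
                            fraction = pmin(1, pmax(0, frac)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

terminal_broken_fractions <- function(run, failure_strain = NULL) {
  bf <- broken_fraction_by_type(run)
  if (is.null(bf) || nrow(bf) == 0) return(NULL)
  if (is.null(failure_strain)) failure_strain <- max(run$series$strain)
  sel <- bf[bf$strain <= failure_strain + 1e-12, , drop = FALSE]
  vapply(split(sel, sel$species),
         function(d) d$fraction[which.max(d$strain)], numeric(1))
}

#' Sliding decomposition of the deformation
#'
#' The mean intra-molecular bond strain `eps_tc` (over intact helical
#' backbone bonds) and the sliding contribution
#' `delta = strain - eps_tc`. Negative growth of `delta` past the elastic
#' limit marks sliding-dominated deformation.
#'
#' @param run a `tensile_run`.
#' @return data frame: `strain`, `eps_tc`, `delta`.
#' @export
sliding_decomposition <- function(run) {
  stopifnot(inherits(run, "tensile_run"))
  ser <- run$series
  data.frame(strain = ser$strain, eps_tc = ser$eps_tc,
             delta = ser$strain - ser$eps_tc)
}
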