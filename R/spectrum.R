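## Turning traces and ensembles into observables: running averages, maximum
## unfolding force per trace, Gaussian / two-Gaussian mixture fits of F_max
## distributions, pointwise-averaged force-extension curves, relative
## extension at the force peak, and the qualitative unfolding-scenario labels
## (uniform 0 / N-terminal / C-terminal / symmetric NC).

#' Centered running average
#'
#' Centered moving mean with shrinking windows at the edges; output length
#' equals input length. For a `force_trace` the force series is smoothed and
#' all other fields kept.
#'
#' @param x Numeric vector or `force_trace`.
#' @param window Odd window size in samples (>= 1).
#' @return Same shape as `x`.
#' @export
running_average <- function(x, window = 51L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (inherits(x, "force_trace")) {
    x$force <- running_average(x$force, window)
    return(x)
  }
  n <- length(x)
  if (window > n) stop("window larger than series length")
  if (window == 1L) return(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Summarize one stretching trace
#'
#' `F_max` is the global maximum of the running-averaged force series, with
#' the final 2% of the extension range excluded as a detachment guard; the
#' extension and time of that sample are reported alongside.
#'
#' @param trace A `force_trace`.
#' @param smoothing_window Running-average window in samples (odd; default 51,
#'   i.e. 51 ps at the default 1 ps cadence).
#' @return A `trace_summary` list: `F_max` (pN), `r_NC_at_max` (nm),
#'   `t_at_max` (ns), `index` (frame of the maximum), `seed`, `degenerate`
#'   (TRUE with a warning when the force series is identically zero).
#' @export
summarize_trace <- function(trace, smoothing_window = 51L) {
  stopifnot(inherits(trace, "force_trace"), length(trace$time) > 0)
  f <- running_average(trace$force, min(smoothing_window,
                                        .odd_floor(length(trace$force))))
  ext <- trace$extension
  guard <- ext <= (min(ext) + 0.98 * (max(ext) - min(ext)))
  if (!any(guard)) guard <- rep(TRUE, length(ext))
  if (all(trace$force == 0)) {
    warning("force series identically zero")
    idx <- 1L
    return(structure(list(F_max = 0, r_NC_at_max = ext[1],
                          t_at_max = trace$time[1] / 1000, index = idx,
                          seed = trace$seed, degenerate = TRUE),
                     class = "trace_summary"))
  }
  idx <- which(guard)[which.max(f[guard])]
  structure(list(F_max = f[idx], r_NC_at_max = ext[idx],
                 t_at_max = trace$time[idx] / 1000, index = idx,
                 seed = trace$seed, degenerate = FALSE),
            class = "trace_summary")
}

.odd_floor <- function(n) if (n %% 2L == 0L) n - 1L else n

#' Fit Gaussian components to a maximum-force distribution
#'
#' Fits one- and two-component Gaussian mixtures (EM, through mclust) and
#' selects by BIC, requiring a margin of `bic_margin` points before the
#' two-component (bimodal) description is preferred. Both candidates are
#' reported. Degenerate input (all values equal) returns a single component
#' with the standard deviation floored at `sd_floor`.
#'
#' @param fmax Numeric vector of per-replica maximum forces, pN (n >= 10).
#' @param max_components Largest number of components tried (1 or 2).
#' @param bic_margin BIC improvement required to accept the extra component.
#' @param sd_floor Lower bound on a fitted standard deviation, pN.
#' @return A `gaussian_fit` list: `components` data frame (`mean`, `sd`,
#'   `weight`) of the selected model, `n_components`, `n_samples`, `bic`
#'   (named vector over candidates), `candidates` (per-candidate component
#'   tables).
#' @export
fit_force_distribution <- function(fmax, max_components = 2L,
                                   bic_margin = 2, sd_floor = 1e-6) {
  fmax <- as.numeric(fmax)
  if (length(fmax) < 10L) stop("need at least 10 maxima to fit")
  if (stats::sd(fmax) < sd_floor) {
    warning("degenerate force distribution (all values equal)")
    comp <- data.frame(mean = mean(fmax), sd = sd_floor, weight = 1)
    return(structure(list(components = comp, n_components = 1L,
                          n_samples = length(fmax),
                          bic = c(g1 = NA_real_),
                          candidates = list(g1 = comp)),
                     class = "gaussian_fit"))
  }
  n <- length(fmax)
  cands <- list()
  bic <- numeric(0)
  for (g in seq_len(max_components)) {
    fit <- Mclust(fmax, G = g, modelNames = "V", verbose = FALSE)
    if (is.null(fit)) next
    comp <- data.frame(mean = as.numeric(fit$parameters$mean),
                       sd = sqrt(as.numeric(fit$parameters$variance$sigmasq)),
                       weight = as.numeric(fit$parameters$pro))
    if (nrow(comp) == 1L && is.na(comp$weight)) comp$weight <- 1
    comp <- comp[order(comp$mean), , drop = FALSE]
    k <- 3 * g - 1                              # free parameters
    cands[[paste0("g", g)]] <- comp
    bic[paste0("g", g)] <- -2 * fit$loglik + k * log(n)   # lower is better
  }
  pick <- 1L
  if (length(bic) >= 2L && (bic["g1"] - bic["g2"]) > bic_margin) pick <- 2L
  sel <- cands[[paste0("g", pick)]]
  structure(list(components = sel, n_components = as.integer(pick),
                 n_samples = n, bic = bic, candidates = cands),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("gaussian_fit: %d component(s), n = %d\n",
              x$n_components, x$n_samples))
  print(round(x$components, 2))
  invisible(x)
}

#' Average an ensemble of force-extension curves
#'
#' Interpolates every trace onto a common extension grid and reports the
#' pointwise mean and standard deviation of the force; grid points covered
#' by fewer than `min_coverage` of the traces are masked (NA), never
#' extrapolated.
#'
#' @param traces List of `force_trace` objects (>= 2).
#' @param grid Extension grid in nm; default 200 points spanning the pooled
#'   range.
#' @param min_coverage Minimum fraction of traces that must cover a grid
#'   point.
#' @return Data frame: `extension_nm`, `mean_force_pN`, `sd_force_pN`,
#'   `coverage`.
#' @export
average_curves <- function(traces, grid = NULL, min_coverage = 0.5) {
  stopifnot(length(traces) >= 2L)
  ranges <- vapply(traces, function(tr) range(tr$extension), numeric(2))
  if (max(ranges[1, ]) >= min(ranges[2, ])) {
    stop("traces have disjoint extension ranges: [",
         paste(sprintf("%.2f-%.2f", ranges[1, ], ranges[2, ]),
               collapse = "], ["), "] nm")
  }
  if (is.null(grid)) grid <- seq(min(ranges[1, ]), max(ranges[2, ]),
                                 length.out = 200L)
  vals <- vapply(traces, function(tr) {
    stats::approx(tr$extension, tr$force, xout = grid, rule = 1,
                  ties = mean)$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  cov <- rowMeans(!is.na(vals))
  m <- rowMeans(vals, na.rm = TRUE)
  s <- apply(vals, 1, stats::sd, na.rm = TRUE)
  mask <- cov < min_coverage
  m[mask] <- NA_real_; s[mask] <- NA_real_
  data.frame(extension_nm = grid, mean_force_pN = m, sd_force_pN = s,
             coverage = cov)
}

#' Relative extension at the force maximum
#'
#' Position of the force peak along the full unfolding path:
#' `(r_NC_at_max - r_NC_native) / (L_contour - r_NC_native)` with
#' `L_contour = (N - 1) * 3.8` Angstrom. 0 means the peak occurs at the
#' native extension, 1 at full stretch.
#'
#' @param summary A `trace_summary` (or anything with `r_NC_at_max` in nm).
#' @param model The `go_model` the trace came from.
#' @return Fraction in `[0, 1]` (can exceed marginally through thermal noise).
#' @export
relative_extension_at_fmax <- function(summary, model) {
  r0 <- native_end_distance(model)
  lc <- contour_length(model)
  if (lc <= r0) stop("contour length does not exceed native end distance")
  (summary$r_NC_at_max - r0) / (lc - r0)
}

#' Classify the unfolding scenario of a trace
#'
#' Contacts are split into an N-half and a C-half by the midpoint of their
#' bead pair. Force peaks are detected on the smoothed force with a
#' prominence merge (bumps on a rising flank coalesce into the rupture peak
#' they precede); each peak is then read out where its rupture completes —
#' the first frame after the peak where the force has dropped to half the
#' peak value (or the valley before the next peak). At the first peak the
#' cumulative rupture fractions of the two halves are compared: the C-half
#' leading by at least `delta` gives type C (unfolding starts at the pulled
#' C-terminal side), the N-half leading type N, both halves engaged with a
#' smaller difference type NC (symmetric), and neither half above
#' `threshold` type 0 (uniform, no clear intermediate). The rule is
#' evaluated again at the largest distinct later peak (a mechanically stable
#' intermediate) and the two labels joined with "/"; when no secondary peak
#' exists, "/0" is appended instead (one mechanical barrier, then uniform
#' unfolding).
#'
#' @param trace A `force_trace` with recorded contact history.
#' @param delta Rupture-fraction margin separating N/C dominance.
#' @param threshold Rupture fraction above which a half counts as unfolding.
#' @param smoothing_window Running-average window for peak detection.
#' @param peak_frac Peaks must exceed this fraction of the global maximum.
#' @param min_separation Minimum separation of distinct peaks, in frames;
#'   `NULL` = 10% of the trace length (coarse features only).
#' @return A `scenario_label` list: `primary` (one of `"0"`, `"N"`, `"C"`,
#'   `"NC"`, or `"none"` when nothing ruptures), `label` (full string, e.g.
#'   `"C/0"`), `peaks` (frame indices), `fractions` (per-peak N/C rupture
#'   fractions).
#' @export
classify_scenario <- function(trace, delta = 0.2, threshold = 0.3,
                              smoothing_window = 51L, peak_frac = 0.5,
                              min_separation = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  if (is.null(min_separation)) {
    min_separation <- max(25L, as.integer(0.1 * length(trace$time)))
  }
  intact <- trace$contact_intact
  if (is.null(intact) || ncol(intact) == 0L) {
    warning("no contact history recorded")
    return(structure(list(primary = "none", label = "none",
                          peaks = integer(0), fractions = NULL),
                     class = "scenario_label"))
  }
  broken <- apply(!intact, 2, cummax)        # has-ruptured-by-frame history
  if (is.null(dim(broken))) broken <- matrix(broken, nrow = nrow(intact))
  if (max(broken[nrow(broken), ]) == 0) {
    warning("no contact ruptures in trace")
    return(structure(list(primary = "none", label = "none",
                          peaks = integer(0), fractions = NULL),
                     class = "scenario_label"))
  }
  mid <- (trace$contacts$i + trace$contacts$j) / 2
  n_half <- mid < (trace$n_beads + 1) / 2
  if (!any(n_half) || all(n_half)) {
    # every contact on one side: dominance is decided by that side alone
    n_half <- mid <= stats::median(mid)
  }
  # cap the window at ~10% of the trace so short traces are not edge-distorted
  win <- max(1L, min(smoothing_window, .odd_floor(length(trace$force) %/% 10L)))
  f <- running_average(trace$force, win)
  ext <- trace$extension
  guard <- ext <= (min(ext) + 0.98 * (max(ext) - min(ext)))
  peaks <- .find_peaks(f, guard, peak_frac, min_separation)
  if (length(peaks) == 0L) peaks <- which(guard)[which.max(f[guard])]
  frac_at <- function(frame) {
    c(N = mean(broken[frame, n_half]), C = mean(broken[frame, !n_half]))
  }
  lab_at <- function(fr) {
    if (max(fr) < threshold) return("0")
    if (fr["C"] - fr["N"] >= delta) return("C")
    if (fr["N"] - fr["C"] >= delta) return("N")
    "NC"
  }
  first <- peaks[1L]
  later <- peaks[peaks >= first + min_separation]
  second <- if (length(later) > 0L) later[which.max(f[later])] else NA_integer_
  eval_peaks <- c(first, if (!is.na(second)) second)
  # read each peak out where its rupture has completed: first frame after
  # the peak with the force at half the peak value, else the valley before
  # the next peak (or the end of the guarded range)
  nfr <- length(f)
  read_frame <- function(p, nxt) {
    stop_at <- if (is.na(nxt)) max(which(guard)) else nxt
    if (stop_at <= p) return(p)
    seg <- p:stop_at
    drop <- seg[f[seg] <= 0.5 * f[p]]
    if (length(drop) > 0L) drop[1L] else seg[which.min(f[seg])]
  }
  eval_at <- c(read_frame(first, second), if (!is.na(second))
    read_frame(second, NA_integer_))
  fr_list <- lapply(eval_at, frac_at)
  labs <- vapply(fr_list, lab_at, "")
  label <- paste(labs, collapse = "/")
  if (is.na(second)) label <- paste0(label, "/0")
  structure(list(primary = labs[1L], label = label, peaks = eval_peaks,
                 fractions = fr_list),
            class = "scenario_label")
}

#' @export
print.scenario_label <- function(x, ...) {
  cat("unfolding scenario:", x$label, "\n")
  invisible(x)
}

# local maxima above peak_frac * global max, merged by prominence: two
# maxima remain distinct only if the valley between them dips well below
# the lower of the two (otherwise the higher one absorbs the bump)
.find_peaks <- function(f, guard, peak_frac, min_separation,
                        prominence_frac = 0.15) {
  n <- length(f)
  if (n < 3L) return(integer(0))
  fmax <- max(f[guard])
  prom <- prominence_frac * fmax
  cand <- which(guard & c(FALSE, diff(f) > 0) & c(f[-n] >= f[-1], FALSE) &
                f >= peak_frac * fmax)
  if (length(cand) == 0L) return(integer(0))
  keep <- cand[1L]
  for (p in cand[-1L]) {
    last <- keep[length(keep)]
    valley <- min(f[last:p])
    if (valley <= min(f[last], f[p]) - prom &&
        p - last >= min_separation) {
      keep <- c(keep, p)
    } else if (f[p] > f[last]) {
      keep[length(keep)] <- p
    }
  }
  keep
}
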