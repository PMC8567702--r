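#' Kernel density curve of a Ks sample
#'
#' Gaussian-kernel density on a fixed grid over `[0, ksMax]` (step
#' `gridStep`), renormalised so the trapezoidal integral over the grid is
#' 1 (boundary mass is renormalised over the grid rather than reflected).
#' Values outside `[0, ksMax]` or non-finite are discarded first.
#'
#' @param values Numeric Ks values (at least 10 finite values in range).
#' @param bandwidth Kernel standard deviation (default 0.025).
#' @param gridStep Grid step (default 0.001).
#' @param ksMax Upper end of the grid (default 3).
#' @return A `DensityCurve`: list with `grid`, `density`, `bandwidth`, `n`.
#' @export
kdeDensity <- function(values, bandwidth = 0.025, gridStep = 0.001,
                       ksMax = 3) {
  v <- values[is.finite(values) & values >= 0 & values <= ksMax]
  if (length(v) < 10L) {
    stop("insufficient data: need >= 10 finite Ks values in [0, ksMax]")
  }
  nGrid <- round(ksMax / gridStep) + 1L
  d <- stats::density(v, bw = bandwidth, kernel = "gaussian",
                      from = 0, to = ksMax, n = nGrid)
  dens <- d$y
  area <- sum((dens[-1] + dens[-nGrid]) / 2) * gridStep
  dens <- dens / area
  structure(list(grid = d$x, density = dens, bandwidth = bandwidth,
                 n = length(v)),
            class = "DensityCurve")
}

#' @export
print.DensityCurve <- function(x, ...) {
  cat(sprintf(
    "DensityCurve: %d values, grid [0, %g] step %g, bandwidth %g, peak at %.3f\n",
    x$n, max(x$grid), x$grid[2] - x$grid[1], x$bandwidth,
    x$grid[which.max(x$density)]))
  invisible(x)
}

#' Gaussian multipeak fit of a Ks density curve
#'
#' Least-squares fit of a sum of `k` Gaussian components to the density
#' curve, for `k = 1..kMax`, each fit initialised at the `k` highest local
#' maxima of the curve (values of `k` exceeding the number of local
#' maxima are not attempted).  The component count is selected by the
#' penalised residual `RSS + 3k log(G)` with `G` the grid size.  Fitting
#' is to the curve (the kernel-density-then-curve-fit workflow of the
#' field's interactive tools), not an EM fit to the raw values; the
#' result is deterministic given the curve.
#'
#' @param curve A `DensityCurve` from [kdeDensity()].
#' @param kMax Maximum number of components (default 4).
#' @return A [KsPeakSet-class] with components sorted by mean.
#' @importFrom minpack.lm nls.lm nls.lm.control
#' @export
fitKsMixture <- function(curve, kMax = 4L) {
  g <- curve$grid
  y <- curve$density
  if (all(y <= 0) || !any(is.finite(y))) {
    stop("degenerate density curve: nothing to fit")
  }
  n <- length(g)
  inner <- 2:(n - 1L)
  isMax <- y[inner] > y[inner - 1L] & y[inner] >= y[inner + 1L]
  peaks <- inner[isMax]
  if (y[1] > y[2]) peaks <- c(1L, peaks)
  if (y[n] > y[n - 1L]) peaks <- c(peaks, n)
  peaks <- peaks[order(-y[peaks])]
  if (!length(peaks)) {
    stop("degenerate density curve: no local maxima")
  }
  fits <- list()
  for (k in seq_len(min(kMax, length(peaks)))) {
    mu0 <- g[peaks[seq_len(k)]]
    s0 <- rep(max(4 * curve$bandwidth, 0.02), k)
    w0 <- pmax(y[peaks[seq_len(k)]] * s0 * sqrt(2 * pi), 1e-3)
    par0 <- c(mu0, log(s0), log(w0))
    model <- function(p) {
      mu <- p[seq_len(k)]
      sig <- exp(p[k + seq_len(k)])
      w <- exp(p[2L * k + seq_len(k)])
      rowSums(vapply(seq_len(k), function(i) {
        w[i] * stats::dnorm(g, mu[i], sig[i])
      }, numeric(n)))
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, fn = function(p) y - model(p),
                         lower = c(rep(min(g), k), rep(log(1e-4), 2L * k)),
                         upper = c(rep(max(g), k), rep(log(10), 2L * k)),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    fits[[length(fits) + 1L]] <- list(k = k, par = fit$par, rss = rss,
                                      crit = rss + 3 * k * log(n))
  }
  if (!length(fits)) {
    stop("mixture fit failed at every component count")
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "crit"))]]
  k <- best$k
  comp <- data.frame(mean = best$par[seq_len(k)],
                     sd = exp(best$par[k + seq_len(k)]),
                     weight = exp(best$par[2L * k + seq_len(k)]))
  comp <- comp[order(comp$mean), , drop = FALSE]
  rownames(comp) <- NULL
  new("KsPeakSet", components = comp, k = as.integer(k),
      residual = best$rss, bandwidth = curve$bandwidth)
}

#' Lineage rate-correction model from ortholog peaks
#'
#' Given the ortholog-versus-outgroup Ks peak of each species (all
#' reflecting the same divergence time), computes the reference peak as
#' their arithmetic mean and multiplicative correction coefficients
#' `c_i = reference / K_i`, so that corrected peaks `c_i * K_i` coincide
#' exactly.  The calibration age range (My) of the shared divergence is
#' stored for dating.
#'
#' @param orthologPeaks Named numeric vector of per-species ortholog Ks
#'   peaks (all > 0).
#' @param calibration Length-2 age range in My (default `c(163, 184)`,
#'   the monocot-eudicot divergence).
#' @return A [CorrectionModel-class].
#' @export
computeCorrection <- function(orthologPeaks, calibration = c(163, 184)) {
  if (any(orthologPeaks <= 0)) {
    stop("all ortholog peaks must be > 0")
  }
  ref <- mean(orthologPeaks)
  new("CorrectionModel", peaks = orthologPeaks, reference = ref,
      coefficients = ref / orthologPeaks,
      calibration = as.numeric(calibration))
}

#' Apply a lineage rate correction to Ks values
#'
#' Within-species paralog Ks values are scaled by the species coefficient
#' `c_i`; between-species ortholog values by `sqrt(c_i * c_j)`.
#'
#' @param ks Numeric Ks values.
#' @param model A [CorrectionModel-class].
#' @param speciesA Species of the first gene of each pair.
#' @param speciesB Species of the second gene (default `speciesA`:
#'   paralog values).
#' @return Corrected Ks values.
#' @export
applyCorrection <- function(ks, model, speciesA, speciesB = speciesA) {
  cc <- model@coefficients
  if (!all(c(speciesA, speciesB) %in% names(cc))) {
    stop("unknown species: ",
         paste(setdiff(c(speciesA, speciesB), names(cc)), collapse = ", "))
  }
  ks * sqrt(cc[[speciesA]] * cc[[speciesB]])
}

#' Date events from corrected Ks peaks
#'
#' Linear molecular clock on corrected Ks: an event with corrected peak
#' `P` is dated to the age range `[T_lo * P / reference,
#' T_hi * P / reference]` where `[T_lo, T_hi]` is the calibration range
#' and `reference` the corrected calibration peak of the model.
#'
#' @param peaks Named numeric vector of corrected event peaks (>= 0).
#' @param model A [CorrectionModel-class].
#' @return data.frame with `event`, `peak`, `age_lo`, `age_hi` (My).
#' @export
dateEvents <- function(peaks, model) {
  if (any(peaks < 0)) stop("corrected peaks must be >= 0")
  cal <- model@calibration
  data.frame(event = names(peaks), peak = unname(peaks),
             age_lo = unname(cal[1] * peaks / model@reference),
             age_hi = unname(cal[2] * peaks / model@reference),
             stringsAsFactors = FALSE)
}

#' Simulate block-median Ks data for a rate-asymmetric dating experiment
#'
#' Two ingroup lineages diverge from a shared ancestor that underwent a
#' WGD at `trueAge`; one lineage evolves 1.5x faster than the other.  An
#' outgroup lineage, diverged at the calibration age (range midpoint) and
#' evolving at the ingroup-average rate, provides the ortholog peaks used
#' for rate correction.  Block-median Ks values are drawn around the true
#' peak positions with a relative spread typical of collinear-block
#' medians.
#'
#' @param seed RNG seed.
#' @param n Block medians per distribution (default 1500).
#' @param trueAge True WGD age in My (default 50).
#' @param calibration Calibration age range (default `c(163, 184)`).
#' @param baseRate Slow-lineage synonymous rate (Ks/site/My,
#'   default 0.003).
#' @param rateRatio Fast/slow lineage rate ratio (default 1.5).
#' @param relSd Relative standard deviation of block medians around the
#'   true peak (default 0.08).
#' @return List with per-lineage paralog samples (`paralog`), per-lineage
#'   ortholog-vs-outgroup samples (`ortholog`), and the ground truth.
#' @export
simulateKsDating <- function(seed = 1L, n = 1500L, trueAge = 50,
                             calibration = c(163, 184),
                             baseRate = 0.003, rateRatio = 1.5,
                             relSd = 0.08) {
  set.seed(seed)
  calMid <- mean(calibration)
  rates <- c(sp1 = baseRate, sp2 = baseRate * rateRatio)
  outRate <- mean(rates)
  draw <- function(peak) {
    v <- stats::rnorm(n, peak, relSd * peak)
    v[v > 0]
  }
  paralog <- lapply(rates, function(r) draw(2 * r * trueAge))
  ortholog <- lapply(rates, function(r) draw((r + outRate) * calMid))
  list(paralog = paralog, ortholog = ortholog,
       truth = list(rates = rates, outRate = outRate, trueAge = trueAge,
                    calMid = calMid,
                    paralogPeaks = vapply(rates, function(r)
                      2 * r * trueAge, numeric(1)),
                    orthologPeaks = vapply(rates, function(r)
                      (r + outRate) * calMid, numeric(1))))
}
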