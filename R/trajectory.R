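# Diphthong quantification. For each coda and spectral-peak index, two signed
# summary distances are computed over the click sequence: c1dist (mean
# displacement of each non-initial click's peak from the first click's
# corresponding peak) and cndist (mean displacement from the preceding
# click's peak). Bimodality of these distances across codas is then tested
# with 1-D Gaussian mixtures selected by BIC.

#' Signed peak-distance statistics for one coda
#'
#' Distances are signed: a level coda gives both near 0, a monotone rise gives
#' both positive, and a rise-fall gives a large c1dist with cndist near 0
#' (cndist telescopes to (p_n - p_1)/(n - 1)).
#'
#' @param peaks_hz numeric vector of one peak index's frequency across clicks,
#'   in click order; `NA` for clicks where that peak was not found (skipped,
#'   with a count).
#' @param peak_index which spectral peak this is (1 or 2), carried through.
#' @param coda_id identifier carried through.
#' @return list with `coda_id`, `peak_index`, `c1dist_hz`, `cndist_hz`,
#'   `n_used`, `n_skipped`, and the cleaned `sequence_hz`; errors if fewer
#'   than 2 clicks carry the peak.
#' @export
peak_distances <- function(peaks_hz, peak_index = 1L, coda_id = NA_character_) {
  keep <- !is.na(peaks_hz)
  n_skipped <- sum(!keep)
  p <- peaks_hz[keep]
  if (length(p) < 2)
    stop("fewer than 2 clicks carry peak ", peak_index,
         " in coda ", coda_id)
  list(coda_id = coda_id, peak_index = as.integer(peak_index),
       c1dist_hz = mean(p[-1] - p[1]),
       cndist_hz = mean(diff(p)),
       n_used = length(p), n_skipped = n_skipped, sequence_hz = p)
}

#' Peak-distance statistics for a click table
#'
#' @param clicks data.frame as produced by [analyze_click_spectra()]`$clicks`
#'   (columns `coda_id`, `click_index`, `peak1_hz`, `peak2_hz`).
#' @return data.frame with one row per (coda, peak index) for which at least
#'   two clicks carry the peak.
#' @export
trajectory_stats <- function(clicks) {
  rows <- list()
  for (cid in unique(clicks$coda_id)) {
    g <- clicks[clicks$coda_id == cid, , drop = FALSE]
    g <- g[order(g$click_index), , drop = FALSE]
    for (pi in 1:2) {
      pk <- g[[paste0("peak", pi, "_hz")]]
      if (sum(!is.na(pk)) < 2) next
      st <- peak_distances(pk, pi, cid)
      rows[[length(rows) + 1]] <- data.frame(
        coda_id = cid, peak_index = pi, c1dist_hz = st$c1dist_hz,
        cndist_hz = st$cndist_hz, n_used = st$n_used,
        n_skipped = st$n_skipped, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no coda has a peak present in at least 2 clicks")
  do.call(rbind, rows)
}

# One EM run for a k-component 1-D Gaussian mixture from given initial means.
em_gmm_1d <- function(x, k, mu0, max_iter = 300, tol = 1e-8,
                      var_floor = NULL) {
  n <- length(x)
  if (is.null(var_floor)) var_floor <- 1e-6 * stats::var(x) + 1e-12
  w <- rep(1 / k, k); mu <- mu0; s2 <- rep(stats::var(x), k)
  ll_old <- -Inf; ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sqrt(s2[j])), numeric(n))
    if (k == 1) dens <- matrix(dens, ncol = 1)
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    ll_trace <- c(ll_trace, ll)
    r <- dens / rowsum_d
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * x) / nk
    for (j in seq_len(k))
      s2[j] <- max(sum(r[, j] * (x - mu[j])^2) / nk[j], var_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(k = k, weights = w, means = mu, variances = s2,
       log_likelihood = ll, ll_trace = ll_trace)
}

#' Fit 1-D Gaussian mixtures over a range of k and select by BIC
#'
#' EM with k-means-style initialization and independent restarts; the best
#' log-likelihood per k is kept. BIC = -2 logL + p ln(n) with p = 3k - 1 free
#' parameters; the selected model minimizes BIC. A variance floor guards
#' against component collapse.
#'
#' @param values numeric data (e.g. per-coda c1dist values).
#' @param k_range component counts to try (default 1:5).
#' @param n_restarts independent EM starts per k (default 5).
#' @param seed RNG seed for initialization.
#' @param max_iter,tol EM controls.
#' @return list with `fits` (one per k: weights, means_hz, variances,
#'   log_likelihood, bic, ll_trace of the winning run), `bic_table`
#'   (data.frame k, log_likelihood, bic), and `selected_k`.
#' @export
fit_gmm_bic <- function(values, k_range = 1:5, n_restarts = 5L, seed = 1L,
                        max_iter = 300L, tol = 1e-8) {
  x <- as.numeric(values[is.finite(values)])
  n <- length(x)
  if (n < 10 * max(k_range))
    stop("insufficient data: need at least 10 observations per maximum ",
         "component count (", 10 * max(k_range), "), got ", n)
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fits <- list()
  for (k in k_range) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      mu0 <- if (k == 1) mean(x)
             else tryCatch(stats::kmeans(x, k, nstart = 1)$centers[, 1],
                           error = function(e) sample(x, k))
      fit <- em_gmm_1d(x, k, as.numeric(mu0), max_iter, tol)
      if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
    }
    p <- 3 * k - 1
    best$bic <- -2 * best$log_likelihood + p * log(n)
    ord <- order(best$means)
    fits[[as.character(k)]] <- list(
      k = k, weights = best$weights[ord], means_hz = best$means[ord],
      variances = best$variances[ord], log_likelihood = best$log_likelihood,
      bic = best$bic, ll_trace = best$ll_trace)
  }
  bic_table <- data.frame(
    k = k_range,
    log_likelihood = vapply(fits, `[[`, 0, "log_likelihood"),
    bic = vapply(fits, `[[`, 0, "bic"))
  list(fits = fits, bic_table = bic_table,
       selected_k = k_range[which.min(bic_table$bic)])
}

#' Label a coda's trajectory shape
#'
#' Uses the signed distance summaries plus the per-click peak sequence:
#' "level" when both |c1dist| and |cndist| are below the threshold;
#' "rising"/"falling" by the sign of the net movement when the per-click
#' increments never change sign; "rise_fall"/"fall_rise" when the increments
#' change sign exactly once (the hallmark of a large |c1dist| with |cndist|
#' near 0). The threshold is a free parameter — the reference analysis
#' classifies trajectories visually; a data-driven choice is the crossover of
#' the 2-component mixture (see [gmm_crossover()]).
#'
#' @param sequence_hz per-click peak frequencies (NA clicks dropped).
#' @param threshold_hz movement below this is "level" (default 200 Hz).
#' @return one of "level", "rising", "falling", "rise_fall", "fall_rise".
#' @export
diphthong_flag <- function(sequence_hz, threshold_hz = 200) {
  p <- sequence_hz[!is.na(sequence_hz)]
  if (length(p) < 2) stop("need at least 2 peaks")
  c1 <- mean(p[-1] - p[1]); cn <- mean(diff(p))
  excursion <- max(p) - min(p)
  if (abs(c1) < threshold_hz && abs(cn) < threshold_hz &&
      excursion < 2 * threshold_hz) return("level")
  d <- diff(p)
  d <- d[d != 0]
  flips <- if (length(d) > 1) sum(diff(sign(d)) != 0) else 0
  if (flips == 0) {
    if (sum(d) > 0) "rising" else "falling"
  } else if (flips == 1) {
    if (d[1] > 0) "rise_fall" else "fall_rise"
  } else {
    # multiple direction changes: fall back on the net movement
    if (abs(c1) < threshold_hz) "level" else if (c1 > 0) "rising" else "falling"
  }
}

#' Crossover point of a 2-component 1-D Gaussian mixture
#'
#' The value between the two component means where their weighted densities
#' are equal; usable as a data-driven level/diphthong threshold.
#'
#' @param fit a 2-component entry from [fit_gmm_bic()]`$fits`.
#' @return numeric crossover.
#' @export
gmm_crossover <- function(fit) {
  stopifnot(fit$k == 2)
  f <- function(z) fit$weights[1] * stats::dnorm(z, fit$means_hz[1], sqrt(fit$variances[1])) -
    fit$weights[2] * stats::dnorm(z, fit$means_hz[2], sqrt(fit$variances[2]))
  stats::uniroot(f, sort(fit$means_hz))$root
}
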