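#' Posterior-predictive flow summary
#'
#' Samples parameter vectors (without replacement) from the pooled retained
#' posterior draws, computes the expected admin-level flow matrix for each,
#' and summarises every OD pair by its mean and equal-tailed 95% credible
#' interval across draws. By default the "simulated flows" are the expected
#' flows per draw; with `nb_noise = TRUE` a negative binomial count (with the
#' draw's `disp`) is generated around each expected flow instead, which is the
#' appropriate predictive for calibration checks against observed counts.
#'
#' @param fit a [fit_model()] result.
#' @param system the `spatial_system` the fit was computed on.
#' @param n_draws number of posterior samples (default 100; must not exceed
#'   the retained draw count).
#' @param seed integer RNG seed.
#' @param nb_noise logical; add negative binomial observation noise.
#' @param rings precomputed ring populations (radiation models).
#' @return data.frame of class `flow_summary` with columns `origin`,
#'   `destination`, `mean`, `lo95`, `hi95`; within-unit pairs are included
#'   only when the model defines them.
#' @export
posterior_predictive_flows <- function(fit, system, n_draws = 100, seed = 1,
                                       nb_noise = FALSE, rings = NULL) {
  draws <- posterior_draws(fit)
  if (nrow(draws) == 0L) stop("empty posterior")
  if (n_draws > nrow(draws)) {
    stop("n_draws exceeds the number of retained posterior draws")
  }
  if (!identical(fit$model, "GM") && is.null(rings)) {
    rings <- ring_population(system)
  }
  set.seed(seed)
  take <- sample.int(nrow(draws), n_draws, replace = FALSE)
  u <- as.character(system$units$id)
  nu <- length(u)
  sims <- array(NA_real_, c(nu, nu, n_draws))
  include_diag <- identical(fit$model, "GM")
  for (s in seq_len(n_draws)) {
    pars <- draws[take[s], fit$param_names]
    F <- expected_admin_flows(system, pars, fit$model, fit$symmetrised,
                              rings = rings,
                              kappa_adjusted = fit$kappa_adjusted)
    F <- unclass(F)
    if (nb_noise) {
      F[] <- .rnb_disp(length(F), as.vector(F), pars[["disp"]])
      if (fit$symmetrised) F[lower.tri(F)] <- t(F)[lower.tri(F)]
      if (!include_diag) diag(F) <- 0
    }
    sims[, , s] <- F
  }
  pair <- expand.grid(oi = seq_len(nu), dj = seq_len(nu))
  if (!include_diag) pair <- pair[pair$oi != pair$dj, , drop = FALSE]
  vals <- matrix(sims[cbind(rep(pair$oi, n_draws), rep(pair$dj, n_draws),
                            rep(seq_len(n_draws), each = nrow(pair)))],
                 nrow(pair), n_draws)
  out <- data.frame(
    origin = u[pair$oi],
    destination = u[pair$dj],
    mean = rowMeans(vals),
    lo95 = apply(vals, 1, stats::quantile, 0.025, names = FALSE),
    hi95 = apply(vals, 1, stats::quantile, 0.975, names = FALSE)
  )
  structure(out, class = c("flow_summary", "data.frame"),
            n_draws = n_draws, nb_noise = nb_noise)
}

#' Credible-interval coverage of observed flows
#'
#' Proportion of the dataset's masked OD counts falling inside the 95%
#' credible interval of the predictive flow summary.
#'
#' @param data a [flow_dataset()].
#' @param summary a `flow_summary` covering every pair in the dataset.
#' @return proportion in [0, 1].
#' @export
cri_coverage <- function(data, summary) {
  stopifnot(inherits(data, "flow_dataset"))
  key <- function(o, d) paste(o, d, sep = "\r")
  sk <- key(summary$origin, summary$destination)
  idx <- match(key(data$counts$origin, data$counts$destination), sk)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("mask mismatch: pair (%s, %s) absent from the flow summary",
                 data$counts$origin[bad], data$counts$destination[bad]))
  }
  mean(data$counts$count >= summary$lo95[idx] &
       data$counts$count <= summary$hi95[idx])
}

.pair_values <- function(flows) {
  # normalise flow_matrix / flow_dataset / flow_summary to (origin,
  # destination, value) with character unit ids
  if (inherits(flows, "flow_dataset")) {
    data.frame(origin = as.character(flows$counts$origin),
               destination = as.character(flows$counts$destination),
               value = flows$counts$count)
  } else if (inherits(flows, "flow_summary")) {
    data.frame(origin = as.character(flows$origin),
               destination = as.character(flows$destination),
               value = flows$mean)
  } else if (is.matrix(flows)) {
    ids <- rownames(flows)
    if (is.null(ids)) ids <- as.character(attr(flows, "ids"))
    if (is.null(ids)) ids <- as.character(seq_len(nrow(flows)))
    g <- expand.grid(oi = seq_len(nrow(flows)), dj = seq_len(ncol(flows)))
    if (identical(attr(flows, "diagonal_policy"), "excluded")) {
      g <- g[g$oi != g$dj, , drop = FALSE]
    }
    data.frame(origin = ids[g$oi], destination = ids[g$dj],
               value = unclass(flows)[cbind(g$oi, g$dj)])
  } else stop("unsupported flow container")
}

#' Trip-distance profile
#'
#' Accumulates trips into distance bins according to the centroid distance of
#' each OD pair's administrative units, and computes the cumulative trip
#' frequency curve (normalised by total trips).
#'
#' @param flows a `flow_matrix` over admin units, a [flow_dataset()], or a
#'   `flow_summary` (whose predictive means are used).
#' @param system the `spatial_system` providing unit centroids.
#' @param bin_width bin width in metres (default 10 km).
#' @return data.frame of class `distance_profile` with columns `bin_lo`,
#'   `bin_hi`, `freq` (trips) and `cumfreq`.
#' @export
distance_profile <- function(flows, system, bin_width = 10000) {
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  pv <- .pair_values(flows)
  ids <- as.character(system$units$id)
  i <- match(pv$origin, ids); j <- match(pv$destination, ids)
  if (anyNA(i) || anyNA(j)) stop("flows reference units missing from system")
  d <- system$unit_D[cbind(i, j)]
  nb <- max(1L, ceiling(max(d) / bin_width + 1e-12))
  bin <- pmin(nb, floor(d / bin_width) + 1L)  # d exactly on the top edge
  freq <- vapply(seq_len(nb), function(b) sum(pv$value[bin == b]), numeric(1))
  total <- sum(freq)
  if (total <= 0) stop("no trips to profile")
  structure(
    data.frame(bin_lo = (seq_len(nb) - 1) * bin_width,
               bin_hi = seq_len(nb) * bin_width,
               freq = freq, cumfreq = cumsum(freq) / total),
    class = c("distance_profile", "data.frame"), bin_width = bin_width)
}

#' Power-law fit to a distance profile
#'
#' Least-squares line on (log10 bin-centre distance, log10 trip frequency)
#' over non-empty bins. The exponent is reported as the positive decay power
#' (the negated slope), so frequencies proportional to `d^-2` yield exponent
#' 2.
#'
#' @param profile a [distance_profile()].
#' @param level confidence level for the exponent interval.
#' @return list with `exponent`, `intercept`, `exponent_ci` (confidence
#'   interval for the exponent) and `n_bins` used.
#' @export
powerlaw_fit <- function(profile, level = 0.95) {
  use <- profile$freq > 0
  if (sum(use) < 2L) stop("need at least 2 non-empty bins")
  centre <- (profile$bin_lo[use] + profile$bin_hi[use]) / 2
  ld <- log10(centre)
  lf <- log10(profile$freq[use])
  fit <- stats::lm(lf ~ ld)
  # confint warns on numerically perfect fits; the point estimate is exact
  ci <- tryCatch(
    suppressWarnings(-rev(stats::confint(fit, "ld", level = level))),
    error = function(e) c(NA_real_, NA_real_))
  list(exponent = -unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       exponent_ci = ci, n_bins = sum(use))
}

#' Origin-destination symmetry statistic
#'
#' For each unordered unit pair with at least one non-zero flow, computes
#' `F_ij = 100 * (f_ij - f_ji) / max(f_ij, f_ji)`, a value in [-100, 100]
#' that is 0 for perfectly symmetric flows and +/-100 for one-way flows.
#' Pairs with both flows zero are skipped and counted. A pair direction
#' absent from the table is treated as zero flow for this diagnostic.
#'
#' @param data a directional [flow_dataset()].
#' @return list with `pairs` (data.frame `origin`, `destination`, `F`;
#'   antisymmetric, both orders listed), `mean_abs` (mean of `|F|` over
#'   unordered pairs), `q95` (2.5% and 97.5% quantiles of `|F|`),
#'   `n_pairs`, `n_skipped`.
#' @export
symmetry_statistic <- function(data) {
  stopifnot(inherits(data, "flow_dataset"))
  if (!data$directional) stop("symmetry statistic requires directional data")
  cnt <- data$counts[data$counts$origin != data$counts$destination, ,
                     drop = FALSE]
  ids <- sort(unique(c(as.character(cnt$origin),
                       as.character(cnt$destination))))
  M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  M[cbind(match(as.character(cnt$origin), ids),
          match(as.character(cnt$destination), ids))] <- cnt$count
  ut <- which(upper.tri(M), arr.ind = TRUE)
  fij <- M[ut]; fji <- t(M)[ut]
  mx <- pmax(fij, fji)
  ok <- mx > 0
  Fv <- 100 * (fij[ok] - fji[ok]) / mx[ok]
  pairs <- data.frame(
    origin = c(ids[ut[ok, 1]], ids[ut[ok, 2]]),
    destination = c(ids[ut[ok, 2]], ids[ut[ok, 1]]),
    F = c(Fv, -Fv))
  list(pairs = pairs,
       mean_abs = mean(abs(Fv)),
       q95 = stats::quantile(abs(Fv), c(0.025, 0.975), names = FALSE),
       n_pairs = sum(ok), n_skipped = sum(!ok))
}
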