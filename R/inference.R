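#' Parameter names for a mobility model
#'
#' Every model additionally carries the negative binomial dispersion `disp`.
#'
#' @param model `"GM"` or `"RM1"`-`"RM4"`.
#' @return character vector of parameter names in sampling order.
#' @export
model_param_names <- function(model) {
  switch(model,
    GM  = c("kappa", "alpha", "beta", "gamma", "epsilon", "disp"),
    RM1 = c("kappa", "disp"),
    RM2 = c("kappa", "alpha", "disp"),
    RM3 = c("kappa", "theta", "disp"),
    RM4 = c("kappa", "alpha", "theta", "disp"),
    stop("unknown model: ", model))
}

#' Default uniform prior box
#'
#' Independent uniform priors per parameter. Bounds are deliberately wide:
#' `kappa` in [-15, 15] (log10; natural-scale [0, 100] for RM1 whose rate
#' constant is a trips-per-resident rate), population powers and the kernel
#' power in [0, 6], `gamma` in [0, 7] (log10 metres, i.e. kernel scales from
#' 1 m to 10 000 km), `theta` in [0, 1e7] persons, `disp` in [0, 10].
#'
#' @param model `"GM"` or `"RM1"`-`"RM4"`.
#' @return list with named numeric vectors `lower` and `upper`.
#' @export
default_prior <- function(model) {
  lo <- c(kappa = -15, alpha = 0, beta = 0, gamma = 0, epsilon = 0,
          theta = 0, disp = 0)
  hi <- c(kappa = 15, alpha = 6, beta = 6, gamma = 7, epsilon = 6,
          theta = 1e7, disp = 10)
  if (model == "RM1") {
    lo[["kappa"]] <- 0
    hi[["kappa"]] <- 100
  }
  nm <- model_param_names(model)
  list(lower = lo[nm], upper = hi[nm])
}

#' Build a fast log-likelihood objective for MCMC
#'
#' Returns a closure `f(params)` computing the dataset log-likelihood of the
#' given model on the given system. The closure caches the expensive pieces of
#' the flow computation (distance kernel, population-power numerator,
#' travellers vector, aggregated flows) and, by diffing the incoming parameter
#' vector against the previously evaluated one, recomputes only what a
#' single-component Metropolis update actually changed. Results are identical
#' to evaluating [expected_admin_flows()] plus [dataset_loglik()] from
#' scratch.
#'
#' @inheritParams expected_admin_flows
#' @param data a [flow_dataset()] over the system's administrative units.
#' @return function of a named parameter vector returning the log-likelihood
#'   (`-Inf` never arises for in-bounds parameters with positive flows).
#' @export
make_objective <- function(system, data, model = "GM", symmetrised = FALSE,
                           rings = NULL, kappa_adjusted = TRUE) {
  stopifnot(inherits(system, "spatial_system"), inherits(data, "flow_dataset"))
  is_gm <- identical(model, "GM")
  if (!is_gm && is.null(rings)) rings <- ring_population(system)

  m <- system$cells$population
  if (is_gm && any(m <= 0)) stop("all cell populations must be positive")
  n <- length(m)
  D <- system$D
  idx <- system$unit_index
  n_units <- nrow(system$units)
  Z <- matrix(0, n, n_units)
  Z[cbind(seq_len(n), idx)] <- 1

  # precompute likelihood-term bookkeeping
  ids <- as.character(system$units$id)
  cnt <- data$counts
  model_has_diag <- is_gm  # radiation models never define within-unit flows
  if (!model_has_diag) {
    cnt <- cnt[cnt$origin != cnt$destination, , drop = FALSE]
  }
  ti <- match(as.character(cnt$origin), ids)
  tj <- match(as.character(cnt$destination), ids)
  if (anyNA(ti) || anyNA(tj)) stop("dataset units not covered by the system")
  term_idx <- cbind(ti, tj)
  obs <- cnt$count
  mcol <- rep(m, each = n)        # m_j laid out over an n x n matrix

  # cache
  last <- NULL
  kern <- NULL; num <- NULL       # gravity pieces
  core <- NULL; Ti <- NULL        # radiation pieces
  admin <- NULL

  agg <- function(F) crossprod(Z, F %*% Z)

  logD <- log(D)
  diag(logD) <- -Inf          # exp gives 0, kernel 1 at d = 0
  logm <- log(m)
  log10_ <- log(10)

  recompute <- function(p, diff) {
    full <- is.null(diff)
    if (is_gm) {
      if (full || any(c("gamma", "epsilon") %in% diff)) {
        # 1 + (d/10^gamma)^eps written as exp() of precomputed log d
        kern <<- 1 + exp(p[["epsilon"]] * (logD - p[["gamma"]] * log10_))
      }
      if (full || any(c("alpha", "beta") %in% diff)) {
        a <- exp(p[["alpha"]] * logm); b <- exp(p[["beta"]] * logm)
        num <<- if (symmetrised) {
          nm0 <- tcrossprod(a, b); nm0 + t(nm0)
        } else tcrossprod(a, b)
      }
      lc <- if (symmetrised && kappa_adjusted) {
        p[["kappa"]] - p[["gamma"]] * p[["epsilon"]]
      } else p[["kappa"]]
      if (full || any(c("alpha", "beta", "gamma", "epsilon") %in% diff)) {
        admin <<- 10^lc * agg(num / kern)
      } else if ("kappa" %in% diff) {
        lc_old <- if (symmetrised && kappa_adjusted) {
          last[["kappa"]] - last[["gamma"]] * last[["epsilon"]]
        } else last[["kappa"]]
        admin <<- admin * 10^(lc - lc_old)
      }
    } else {
      theta_changed <- full || "theta" %in% diff
      if (theta_changed) {
        theta <- if (model %in% c("RM3", "RM4")) p[["theta"]] else 0
        a <- m + theta
        s1 <- a + rings
        core <<- matrix(a * mcol / ((s1 + mcol) * s1), n, n)
        diag(core) <<- 0
      }
      if (theta_changed || "alpha" %in% diff || "kappa" %in% diff) {
        Ti <<- switch(model,
          RM1 = p[["kappa"]] * m,
          RM2 = 10^p[["kappa"]] * m^p[["alpha"]],
          RM3 = 10^p[["kappa"]] * m,
          RM4 = 10^p[["kappa"]] * m^p[["alpha"]])
        F <- Ti * core
        if (symmetrised) F <- F + t(F)
        admin <<- agg(F)
      }
    }
    last <<- p
    invisible(NULL)
  }

  function(params) {
    p <- params
    if (is.null(last)) {
      recompute(p, NULL)
    } else {
      diff <- names(p)[p != last]
      flow_diff <- setdiff(diff, "disp")
      if (length(flow_diff) > 0L) recompute(p, flow_diff) else last <<- p
    }
    mu <- admin[term_idx]
    if (any(!is.finite(mu) | mu <= 0)) return(-Inf)
    sum(nb_loglik_term(obs, mu, p[["disp"]]))
  }
}

#' Latin hypercube candidates for chain starting points
#'
#' Draws `n_samples` Latin hypercube points in the prior box, evaluates the
#' objective at each, and returns the `n_chains` best as starting points.
#'
#' @param prior list with `lower`/`upper` named vectors.
#' @param n_samples number of LHS points (>= `n_chains`).
#' @param objective function of a named parameter vector returning a
#'   log-likelihood.
#' @param n_chains number of starting points wanted.
#' @param seed integer RNG seed.
#' @param repair optional function applied to each candidate to enforce
#'   constraints (e.g. swapping `alpha`/`beta` for the symmetrised gravity
#'   model); must map the box into itself.
#' @return list with `starts` (list of named vectors, best first) and
#'   `objectives` (their log-likelihoods).
#' @export
lhs_candidates <- function(prior, n_samples, objective, n_chains, seed,
                           repair = NULL) {
  stopifnot(n_samples >= n_chains)
  p <- length(prior$lower)
  set.seed(seed)
  U <- lhs::randomLHS(n_samples, p)
  X <- sweep(sweep(U, 2, prior$upper - prior$lower, `*`), 2, prior$lower, `+`)
  colnames(X) <- names(prior$lower)
  cands <- lapply(seq_len(n_samples), function(i) {
    v <- X[i, ]
    if (!is.null(repair)) v <- repair(v)
    v
  })
  obj <- vapply(cands, objective, numeric(1))
  if (all(!is.finite(obj))) stop("objective is -Inf at every LHS candidate")
  ord <- order(obj, decreasing = TRUE)
  sel <- ord[seq_len(n_chains)]
  list(starts = cands[sel], objectives = obj[sel])
}

#' Run one adaptive Metropolis chain
#'
#' Metropolis random walk with Gaussian proposals and two update modes.
#' `mode = "joint"` (the default used by [fit_model()]) proposes all
#' components at once from a multivariate Gaussian whose covariance is learned
#' from the chain history during burn-in (adaptive Metropolis), with a global
#' step scale tuned towards `target_accept`; this mixes efficiently across the
#' strong posterior ridges (e.g. between the gravity scaling constant and the
#' kernel parameters) that defeat single-coordinate updates.
#' `mode = "component"` performs random-scan single-component updates with
#' per-component scale adaptation. Proposals outside the prior box or
#' violating `constraint` are rejected. Adaptation stops after `adapt_until`
#' iterations, so the retained portion is a valid Markov chain. Fully
#' reproducible given `seed`.
#'
#' @param start named parameter vector inside the prior box.
#' @param prior list with `lower`/`upper` named vectors.
#' @param objective log-likelihood function of a named parameter vector.
#' @param n_iter number of iterations (one proposal each).
#' @param proposal_scales initial per-component proposal standard deviations
#'   (default: box width / 20).
#' @param seed integer RNG seed.
#' @param constraint optional predicate on the parameter vector; proposals for
#'   which it returns FALSE are rejected.
#' @param adapt_until iterations of adaptation (default half of `n_iter`).
#' @param target_accept adaptation target acceptance rate (default 0.234, the
#'   classical optimum for multivariate random-walk Metropolis).
#' @param mode `"joint"` or `"component"`; see Details.
#' @return list with `params` (n_iter x p matrix), `loglik` (trace),
#'   `scales` (final proposal scales) and `accept_rate` (post-adaptation;
#'   per component in component mode, overall in joint mode).
#' @export
run_chain <- function(start, prior, objective, n_iter, proposal_scales = NULL,
                      seed = 1, constraint = NULL,
                      adapt_until = floor(n_iter / 2),
                      target_accept = 0.234,
                      mode = c("joint", "component")) {
  mode <- match.arg(mode)
  d <- length(start)
  nm <- names(start)
  lower <- prior$lower[nm]; upper <- prior$upper[nm]
  if (any(start < lower | start > upper)) stop("start outside prior box")
  if (is.null(proposal_scales)) proposal_scales <- (upper - lower) / 20

  set.seed(seed)
  cur <- start
  curll <- objective(cur)
  if (!is.finite(curll)) stop("objective not finite at start")

  P <- matrix(NA_real_, n_iter, d, dimnames = list(NULL, nm))
  ll <- numeric(n_iter)
  us <- stats::runif(n_iter)

  in_box <- function(v) all(v >= lower & v <= upper) &&
    (is.null(constraint) || isTRUE(constraint(v)))

  if (mode == "component") {
    logs <- log(proposal_scales)
    nprop <- integer(d); nacc_post <- integer(d); nprop_post <- integer(d)
    ks <- sample.int(d, n_iter, replace = TRUE)
    zs <- stats::rnorm(n_iter)
    for (t in seq_len(n_iter)) {
      k <- ks[t]
      prop <- cur
      prop[k] <- cur[k] + zs[t] * exp(logs[k])
      aprob <- 0
      if (in_box(prop)) {
        pll <- objective(prop)
        aprob <- if (is.finite(pll)) min(1, exp(pll - curll)) else 0
        if (us[t] < aprob) {
          cur <- prop; curll <- pll
          if (t > adapt_until) nacc_post[k] <- nacc_post[k] + 1L
        }
      }
      nprop[k] <- nprop[k] + 1L
      if (t > adapt_until) nprop_post[k] <- nprop_post[k] + 1L
      if (t <= adapt_until && proposal_scales[k] > 0) {
        logs[k] <- logs[k] + (aprob - target_accept) / max(1, nprop[k])^0.6
      }
      P[t, ] <- cur
      ll[t] <- curll
    }
    objective(cur)  # re-sync cache after a possible final rejection
    rate <- ifelse(nprop_post > 0, nacc_post / nprop_post, NA_real_)
    return(list(params = P, loglik = ll, scales = exp(logs),
                accept_rate = stats::setNames(rate, nm)))
  }

  # joint adaptive Metropolis
  lsc <- 0                              # log global scale multiplier
  S0 <- diag(proposal_scales^2, d)
  L <- diag(proposal_scales, d)         # proposal factor: prop = cur + z L
  mu_run <- cur
  M2 <- matrix(0, d, d)
  ncov <- 1L
  nacc_post <- 0L; nprop_post <- 0L
  Z <- matrix(stats::rnorm(n_iter * d), n_iter, d)
  degenerate <- all(proposal_scales == 0)

  for (t in seq_len(n_iter)) {
    prop <- cur + (2.38 / sqrt(d)) * exp(lsc) * drop(Z[t, ] %*% L)
    aprob <- 0
    if (in_box(prop)) {
      pll <- objective(prop)
      aprob <- if (is.finite(pll)) min(1, exp(pll - curll)) else 0
      if (us[t] < aprob) {
        cur <- prop; curll <- pll
        if (t > adapt_until) nacc_post <- nacc_post + 1L
      }
    }
    if (t > adapt_until) nprop_post <- nprop_post + 1L
    P[t, ] <- cur
    ll[t] <- curll
    if (t <= adapt_until && !degenerate) {
      lsc <- lsc + (aprob - target_accept) / max(1, t)^0.6
      # running covariance of the chain states
      delta <- cur - mu_run
      mu_run <- mu_run + delta / (ncov + 1L)
      M2 <- M2 + tcrossprod(delta, cur - mu_run)
      ncov <- ncov + 1L
      if (ncov > 10L * d && t %% 25L == 0L) {
        Sig <- M2 / (ncov - 1L)
        ridge <- 1e-10 * max(diag(Sig), proposal_scales^2)
        ch <- tryCatch(chol(Sig + ridge * diag(d)), error = function(e) NULL)
        if (!is.null(ch)) L <- ch
      }
    }
  }
  objective(cur)
  list(params = P, loglik = ll,
       scales = (2.38 / sqrt(d)) * exp(lsc) * sqrt(diag(crossprod(L))),
       accept_rate = if (nprop_post > 0) nacc_post / nprop_post else NA_real_)
}

.split_rhat_one <- function(segs) {
  # segs: list of numeric vectors (one per chain); split each in half
  halves <- unlist(lapply(segs, function(v) {
    n2 <- floor(length(v) / 2)
    list(v[seq_len(n2)], v[n2 + seq_len(n2)])
  }), recursive = FALSE)
  N <- min(lengths(halves))
  if (N < 2L) return(NA_real_)
  halves <- lapply(halves, function(v) v[seq_len(N)])
  mu <- vapply(halves, mean, numeric(1))
  s2 <- vapply(halves, stats::var, numeric(1))
  W <- mean(s2)
  B <- N * stats::var(mu)
  if (B == 0) return(1)          # no between-(half)chain variance at all
  if (W == 0) return(Inf)
  sqrt(((N - 1) / N * W + B / N) / W)
}

#' Split R-hat convergence assessment with automatic truncation
#'
#' Computes the split R-hat diagnostic per parameter on a ladder of candidate
#' truncations (dropping the first 0%, 10%, ..., 50% of each chain) and
#' retains samples from the earliest truncation at which every parameter's
#' R-hat falls below `threshold`. If none does, the truncation with the
#' smallest worst-case R-hat is used and `converged` is FALSE.
#'
#' @param chains list of chains from [run_chain()] (>= 2).
#' @param threshold R-hat threshold (default 1.05).
#' @param fracs candidate burn-in fractions.
#' @return list with `rhat` (named vector at the chosen truncation),
#'   `converged_from` (first retained iteration), `converged` (logical).
#' @export
assess_convergence <- function(chains, threshold = 1.05,
                               fracs = seq(0, 0.5, by = 0.1)) {
  if (length(chains) < 2L) stop("need at least 2 chains")
  nm <- colnames(chains[[1]]$params)
  n <- nrow(chains[[1]]$params)
  best <- NULL
  for (f in fracs) {
    from <- floor(f * n) + 1L
    rh <- vapply(nm, function(par) {
      .split_rhat_one(lapply(chains, function(ch) ch$params[from:n, par]))
    }, numeric(1))
    cand <- list(rhat = rh, converged_from = from,
                 converged = all(is.finite(rh) & rh < threshold))
    if (cand$converged) return(cand)
    if (is.null(best) || max(rh) < max(best$rhat)) best <- cand
  }
  warning("no candidate truncation reached R-hat < ", threshold)
  best
}

#' Posterior summary over retained draws pooled across chains
#'
#' @param chains list of chains from [run_chain()].
#' @param converged_from first retained iteration (from
#'   [assess_convergence()]; default 1).
#' @return data.frame with one row per parameter plus a `loglik` row: mean,
#'   2.5% and 97.5% equal-tailed quantiles.
#' @export
summarise_posterior <- function(chains, converged_from = 1L) {
  n <- nrow(chains[[1]]$params)
  if (converged_from > n) stop("no retained draws")
  draws <- do.call(rbind, lapply(chains, function(ch) {
    cbind(ch$params[converged_from:n, , drop = FALSE],
          loglik = ch$loglik[converged_from:n])
  }))
  data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    lo95 = apply(draws, 2, stats::quantile, 0.025, names = FALSE),
    hi95 = apply(draws, 2, stats::quantile, 0.975, names = FALSE),
    row.names = NULL
  )
}

#' Fit a mobility model to aggregated flow data
#'
#' Full inference protocol: Latin hypercube search of the prior box for
#' chain starting points, `n_chains` adaptive Metropolis chains, split R-hat
#' convergence assessment with automatic burn-in truncation, and a pooled
#' posterior summary. For the symmetrised gravity model the identifiability
#' constraint `alpha > beta` is enforced by proposal rejection (and by
#' swapping the two coordinates of LHS candidates).
#'
#' @inheritParams make_objective
#' @param prior prior box (default [default_prior()]).
#' @param n_chains number of MCMC chains (default 4).
#' @param n_iter iterations per chain.
#' @param n_lhs Latin hypercube sample size.
#' @param seed root seed; LHS and per-chain RNG streams are derived from it.
#' @param rhat_threshold convergence threshold for truncation selection.
#' @param ... passed to [run_chain()].
#' @return object of class `mobility_fit` with elements `chains`, `summary`,
#'   `rhat`, `converged_from`, `converged`, `model`, `symmetrised`,
#'   `kappa_adjusted`, `param_names`, `seed`.
#' @export
fit_model <- function(system, data, model = "GM", symmetrised = FALSE,
                      kappa_adjusted = TRUE, rings = NULL,
                      prior = default_prior(model), n_chains = 4,
                      n_iter = 20000, n_lhs = 100, seed = 1,
                      rhat_threshold = 1.05, ...) {
  nm <- model_param_names(model)
  stopifnot(identical(sort(names(prior$lower)), sort(nm)))
  if (!identical(model, "GM") && is.null(rings)) {
    rings <- ring_population(system)
  }
  objective <- make_objective(system, data, model, symmetrised, rings,
                              kappa_adjusted)
  constraint <- repair <- NULL
  if (identical(model, "GM") && symmetrised) {
    constraint <- function(p) p[["alpha"]] > p[["beta"]]
    repair <- function(p) {
      if (p[["alpha"]] <= p[["beta"]]) {
        tmp <- p[["alpha"]]; p[["alpha"]] <- p[["beta"]]; p[["beta"]] <- tmp
      }
      p
    }
  }
  cand <- lhs_candidates(prior, n_lhs, objective, n_chains, seed = seed,
                         repair = repair)
  chains <- lapply(seq_len(n_chains), function(c) {
    run_chain(cand$starts[[c]], prior, objective, n_iter,
              seed = seed * 101L + c, constraint = constraint, ...)
  })
  conv <- assess_convergence(chains, threshold = rhat_threshold)
  structure(
    list(chains = chains,
         summary = summarise_posterior(chains, conv$converged_from),
         rhat = conv$rhat, converged_from = conv$converged_from,
         converged = conv$converged, model = model,
         symmetrised = symmetrised, kappa_adjusted = kappa_adjusted,
         param_names = nm, prior = prior, seed = seed),
    class = "mobility_fit")
}

#' @export
print.mobility_fit <- function(x, ...) {
  cat(sprintf("<mobility_fit: %s%s, %d chains, retained from iteration %d%s>\n",
              x$model, if (x$symmetrised) " (symmetrised)" else "",
              length(x$chains), x$converged_from,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$summary, digits = 4)
  cat("R-hat:", paste(sprintf("%s=%.3f", names(x$rhat), x$rhat),
                      collapse = " "), "\n")
  invisible(x)
}

#' Pooled retained posterior draws
#'
#' @param fit a `mobility_fit`.
#' @return matrix of retained draws (rows) by parameter (columns), pooled
#'   across chains, with a `loglik` column.
#' @export
posterior_draws <- function(fit) {
  n <- nrow(fit$chains[[1]]$params)
  do.call(rbind, lapply(fit$chains, function(ch) {
    cbind(ch$params[fit$converged_from:n, , drop = FALSE],
          loglik = ch$loglik[fit$converged_from:n])
  }))
}
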