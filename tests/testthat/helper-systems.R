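# Fixtures are built in code; oracles below are deliberately naive
# scalar/loop implementations, independent of the package's vectorised paths.

line_system <- function(pops, xs = NULL, admin = NULL, spacing_km = 1) {
  n <- length(pops)
  if (is.null(xs)) xs <- (seq_len(n) - 1) * spacing_km * 1000
  if (is.null(admin)) admin <- seq_len(n)
  spatial_system(data.frame(id = seq_len(n), x = xs, y = 0,
                            population = pops, admin_id = admin),
                 scale_label = "toy")
}

random_system <- function(n_cells, n_units, seed, extent = 2e5,
                          pop_meanlog = 8, pop_sdlog = 1.5) {
  set.seed(seed)
  cells <- data.frame(
    id = seq_len(n_cells),
    x = runif(n_cells, 0, extent),
    y = runif(n_cells, 0, extent),
    population = ceiling(rlnorm(n_cells, pop_meanlog, pop_sdlog)),
    admin_id = sample(rep_len(seq_len(n_units), n_cells))
  )
  spatial_system(cells, scale_label = "random")
}

# degenerate "posterior" concentrated on one parameter vector
constant_fit <- function(truth, model, symmetrised, n = 600,
                         kappa_adjusted = TRUE) {
  structure(list(
    chains = list(list(
      params = matrix(rep(truth, each = n), n,
                      dimnames = list(NULL, names(truth))),
      loglik = rep(0, n))),
    converged_from = 1L, model = model, symmetrised = symmetrised,
    kappa_adjusted = kappa_adjusted, param_names = names(truth)),
    class = "mobility_fit")
}

## ---- oracles -------------------------------------------------------------

oracle_distance <- function(cells) {
  n <- nrow(cells)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sqrt((cells$x[i] - cells$x[j])^2 +
                    (cells$y[i] - cells$y[j])^2)
  }
  D
}

oracle_rings <- function(cells, D) {
  n <- nrow(cells)
  r <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    tot <- 0
    for (k in seq_len(n)) {
      if (k != i && k != j && D[i, k] <= D[i, j]) {
        tot <- tot + cells$population[k]
      }
    }
    r[i, j] <- tot
  }
  r
}

oracle_gravity <- function(cells, D, kappa, alpha, beta, gamma, epsilon,
                           symmetrised = FALSE, kappa_adjusted = TRUE) {
  n <- nrow(cells)
  m <- cells$population
  F <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    kern <- 1 + (D[i, j] / 10^gamma)^epsilon
    F[i, j] <- if (symmetrised) {
      lc <- if (kappa_adjusted) kappa - gamma * epsilon else kappa
      10^lc * (m[i]^alpha * m[j]^beta + m[j]^alpha * m[i]^beta) / kern
    } else {
      10^kappa * m[i]^alpha * m[j]^beta / kern
    }
  }
  F
}

oracle_radiation <- function(cells, D, variant, kappa, alpha = NULL,
                             theta = 0) {
  n <- nrow(cells)
  m <- cells$population
  r <- oracle_rings(cells, D)
  F <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    Ti <- switch(variant,
      RM1 = kappa * m[i], RM2 = 10^kappa * m[i]^alpha,
      RM3 = 10^kappa * m[i], RM4 = 10^kappa * m[i]^alpha)
    th <- if (variant %in% c("RM3", "RM4")) theta else 0
    F[i, j] <- Ti * (m[i] + th) * m[j] /
      ((m[i] + th + r[i, j] + m[j]) * (m[i] + th + r[i, j]))
  }
  F
}

oracle_aggregate <- function(F, cells, unit_ids, include_diag) {
  k <- length(unit_ids)
  A <- matrix(0, k, k, dimnames = list(unit_ids, unit_ids))
  n <- nrow(cells)
  for (ci in seq_len(n)) for (cj in seq_len(n)) {
    I <- match(cells$admin_id[ci], unit_ids)
    J <- match(cells$admin_id[cj], unit_ids)
    if (!include_diag && I == J) next
    A[I, J] <- A[I, J] + F[ci, cj]
  }
  A
}

# literal product-form NB probability (Eq-style scalar, not via lgamma)
oracle_nb_prob <- function(D, M, disp) {
  r <- 1 / disp
  gamma(D + r) / (factorial(D) * gamma(r)) *
    (M / (M + r))^D * (r / (M + r))^r
}
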