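#' @title Mobility model kernels
#' @description
#' Expected-flow matrices for the gravity model (directional and symmetrised)
#' and four radiation model variants, evaluated on the cells of a
#' [spatial_system()], plus aggregation of cell-pair flows to
#' administrative-unit origin-destination pairs.
#'
#' The gravity model uses an offset power-law distance kernel
#' `f(d) = 1 + (d / 10^gamma)^epsilon`, finite at d = 0 so that self-flows are
#' defined. Radiation models depend on distance only through the ring
#' population [ring_population()] and do not define self-flows.
#' @name mobility-models
NULL

.flow_matrix <- function(F, diagonal_policy, symmetrised, ids) {
  structure(F, class = c("flow_matrix", "matrix"),
            diagonal_policy = diagonal_policy, symmetrised = symmetrised,
            ids = as.character(ids))
}

#' @export
print.flow_matrix <- function(x, ...) {
  cat(sprintf("<flow_matrix %d x %d, diagonal %s%s>\n", nrow(x), ncol(x),
              attr(x, "diagonal_policy"),
              if (isTRUE(attr(x, "symmetrised"))) ", symmetrised" else ""))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

.check_gm_params <- function(params) {
  need <- c("kappa", "alpha", "beta", "gamma", "epsilon")
  miss <- setdiff(need, names(params))
  if (length(miss) > 0L) {
    stop("gravity model needs parameters: ", paste(miss, collapse = ", "))
  }
}

#' Directional gravity model flows
#'
#' Expected flow from location i to location j:
#' `F[i,j] = 10^kappa * m_i^alpha * m_j^beta / (1 + (d_ij/10^gamma)^epsilon)`.
#' At i = j the distance vanishes and the kernel equals 1, so
#' `F[i,i] = 10^kappa * m_i^(alpha+beta)`.
#'
#' @param system a `spatial_system`; flows are computed between its cells.
#' @param params named numeric vector with `kappa` (log10 proportionality
#'   constant), `alpha`, `beta` (powers on origin/destination population),
#'   `gamma` (log10 metres; kernel distance scale is `10^gamma`) and
#'   `epsilon` (kernel power).
#' @return a `flow_matrix` with diagonal policy `"included"`.
#' @export
gravity_flow_directional <- function(system, params) {
  .check_gm_params(params)
  m <- system$cells$population
  if (any(m <= 0)) stop("all cell populations must be positive")
  kern <- 1 + (system$D / 10^params[["gamma"]])^params[["epsilon"]]
  F <- 10^params[["kappa"]] *
    tcrossprod(m^params[["alpha"]], m^params[["beta"]]) / kern
  .flow_matrix(F, "included", FALSE, system$cells$id)
}

#' Symmetrised gravity model flows
#'
#' For undirected data (outbound and return trips indistinguishable) the
#' gravity model is symmetrised over origin and destination:
#' `F[i,j] = C * (m_i^alpha m_j^beta + m_j^alpha m_i^beta) /
#'   (1 + (d_ij/10^gamma)^epsilon)`.
#'
#' With `kappa_adjusted = TRUE` (default) the scaling constant is
#' `C = 10^(kappa - gamma*epsilon)`: when the kernel is in its power-law
#' regime the flow then depends on the sampled `kappa` directly, which
#' improves MCMC convergence when no within-unit data is available to pin the
#' constant. With `kappa_adjusted = FALSE` the plain `C = 10^kappa` scaling is
#' used; in that parameterisation only the combination
#' `kappa + gamma*epsilon` is identified from between-unit flows.
#'
#' @inheritParams gravity_flow_directional
#' @param kappa_adjusted logical; see Details.
#' @return a symmetric `flow_matrix` with diagonal policy `"included"`.
#' @export
gravity_flow_symmetrised <- function(system, params, kappa_adjusted = TRUE) {
  .check_gm_params(params)
  m <- system$cells$population
  if (any(m <= 0)) stop("all cell populations must be positive")
  g <- params[["gamma"]]; e <- params[["epsilon"]]
  lc <- if (kappa_adjusted) params[["kappa"]] - g * e else params[["kappa"]]
  kern <- 1 + (system$D / 10^g)^e
  num <- tcrossprod(m^params[["alpha"]], m^params[["beta"]])
  F <- 10^lc * (num + t(num)) / kern
  F <- (F + t(F)) / 2  # remove rounding asymmetry: exact symmetry guaranteed
  .flow_matrix(F, "included", TRUE, system$cells$id)
}

.rad_variants <- c("RM1", "RM2", "RM3", "RM4")

.check_rm_params <- function(params, variant) {
  need <- switch(variant,
    RM1 = "kappa", RM2 = c("kappa", "alpha"),
    RM3 = c("kappa", "theta"), RM4 = c("kappa", "alpha", "theta"))
  miss <- setdiff(need, names(params))
  if (length(miss) > 0L) {
    stop(variant, " needs parameters: ", paste(miss, collapse = ", "))
  }
  if (variant %in% c("RM3", "RM4") && params[["theta"]] < 0) {
    stop("theta must be >= 0")
  }
  if (variant == "RM1" && params[["kappa"]] < 0) {
    stop("RM1 kappa is natural-scale and must be >= 0")
  }
}

#' Directional radiation model flows
#'
#' Expected flow from i to j (i != j):
#' `F[i,j] = T_i * (m_i+theta) * m_j /
#'    ((m_i+theta+r_ij+m_j) * (m_i+theta+r_ij))`
#' where `r_ij` is the ring population and `theta` (RM3/RM4 only; 0 for
#' RM1/RM2) down-weights short trips by inflating the origin population. The
#' number of travellers `T_i` is estimated from the data through:
#' \itemize{
#'   \item RM1: `T_i = kappa * m_i` (kappa natural-scale, >= 0; a constant
#'     trips-per-resident rate, deliberately not capped at 1),
#'   \item RM2: `T_i = 10^kappa * m_i^alpha`,
#'   \item RM3: `T_i = 10^kappa * m_i`,
#'   \item RM4: `T_i = 10^kappa * m_i^alpha`.
#' }
#' Radiation models do not define within-location trips: the diagonal is zero
#' and flagged excluded.
#'
#' @inheritParams gravity_flow_directional
#' @param rings ring-population matrix from [ring_population()].
#' @param variant one of `"RM1"`, `"RM2"`, `"RM3"`, `"RM4"`.
#' @return a `flow_matrix` with diagonal policy `"excluded"`.
#' @export
radiation_flow <- function(system, rings, params,
                           variant = c("RM1", "RM2", "RM3", "RM4")) {
  variant <- match.arg(variant)
  .check_rm_params(params, variant)
  m <- system$cells$population
  n <- length(m)
  if (!is.matrix(rings) || nrow(rings) != n) {
    stop("rings must be an n x n matrix on the same system")
  }
  theta <- if (variant %in% c("RM3", "RM4")) params[["theta"]] else 0
  Ti <- switch(variant,
    RM1 = params[["kappa"]] * m,
    RM2 = 10^params[["kappa"]] * m^params[["alpha"]],
    RM3 = 10^params[["kappa"]] * m,
    RM4 = 10^params[["kappa"]] * m^params[["alpha"]])
  a <- m + theta                                # inflated origin population
  s1 <- a + rings                               # m_i + theta + r_ij
  F <- (Ti * a) * rep(m, each = n) / ((s1 + rep(m, each = n)) * s1)
  dim(F) <- c(n, n)
  diag(F) <- 0
  .flow_matrix(F, "excluded", FALSE, system$cells$id)
}

#' Symmetrised radiation model flows
#'
#' For undirected data the directional radiation flows are symmetrised by the
#' transpose sum `F[i,j] + F[j,i]`, mirroring the numerator sum of the
#' symmetrised gravity model.
#'
#' @inheritParams radiation_flow
#' @return a symmetric `flow_matrix` with diagonal policy `"excluded"`.
#' @export
radiation_flow_symmetrised <- function(system, rings, params,
                                       variant = c("RM1", "RM2", "RM3",
                                                   "RM4")) {
  Fd <- radiation_flow(system, rings, params, variant)
  F <- unclass(Fd) + t(unclass(Fd))
  .flow_matrix(F, "excluded", TRUE, attr(Fd, "ids"))
}

#' Aggregate cell-pair flows to administrative OD pairs
#'
#' Sums the expected flows over all pairs of cells belonging to a given origin
#' and destination administrative unit pair. Within-unit aggregates (the
#' diagonal) are kept only when the cell model defines self/within flows
#' (diagonal policy `"included"`, i.e. the gravity model); for radiation
#' models the diagonal is zeroed and stays flagged excluded.
#'
#' @param cell_flow a `flow_matrix` over the system's cells.
#' @param system the `spatial_system` the flows were computed on.
#' @return a `flow_matrix` over administrative units, with unit ids as
#'   dimnames and the cell matrix's diagonal policy.
#' @export
aggregate_to_admin <- function(cell_flow, system) {
  idx <- system$unit_index
  n_units <- nrow(system$units)
  if (length(idx) != nrow(cell_flow)) {
    stop("cell_flow does not match the system's cells")
  }
  Z <- matrix(0, length(idx), n_units)
  Z[cbind(seq_along(idx), idx)] <- 1
  A <- crossprod(Z, unclass(cell_flow) %*% Z)
  policy <- attr(cell_flow, "diagonal_policy")
  if (identical(policy, "excluded")) diag(A) <- 0
  out <- .flow_matrix(A, policy, isTRUE(attr(cell_flow, "symmetrised")),
                      system$units$id)
  dimnames(out) <- list(system$units$id, system$units$id)
  out
}

#' Expected administrative-level flows for any model
#'
#' Convenience wrapper: evaluates the requested model on the system's cells
#' and aggregates to administrative units.
#'
#' @inheritParams gravity_flow_directional
#' @param model `"GM"` or a radiation variant `"RM1"`-`"RM4"`.
#' @param symmetrised logical; use the symmetrised form (undirected data).
#' @param rings ring-population matrix (radiation models only; computed on
#'   the fly if missing).
#' @param kappa_adjusted see [gravity_flow_symmetrised()].
#' @return a `flow_matrix` over administrative units.
#' @export
expected_admin_flows <- function(system, params, model = "GM",
                                 symmetrised = FALSE, rings = NULL,
                                 kappa_adjusted = TRUE) {
  F <- if (identical(model, "GM")) {
    if (symmetrised) gravity_flow_symmetrised(system, params, kappa_adjusted)
    else gravity_flow_directional(system, params)
  } else {
    if (is.null(rings)) rings <- ring_population(system)
    if (symmetrised) radiation_flow_symmetrised(system, rings, params, model)
    else radiation_flow(system, rings, params, model)
  }
  aggregate_to_admin(F, system)
}
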