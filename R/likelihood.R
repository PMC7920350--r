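#' Observed origin-destination flow dataset
#'
#' Container for admin-level trip counts. For undirected data
#' (`directional = FALSE`) counts are the symmetrised sums of outbound and
#' return journeys and each unordered pair may appear only once; the
#' constructor normalises pairs so that origin sorts before destination and
#' rejects tables listing both orders. Pairs absent from the table are treated
#' as unobserved (excluded from the likelihood mask), not as zero counts.
#'
#' @param counts data.frame with columns `origin`, `destination`, `count`
#'   (non-negative integers).
#' @param directional logical; can outbound and return journeys be
#'   distinguished?
#' @param has_diagonal logical; does the dataset report within-unit trips?
#' @return object of class `flow_dataset`.
#' @export
flow_dataset <- function(counts, directional, has_diagonal) {
  stopifnot(is.data.frame(counts),
            all(c("origin", "destination", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("counts must be non-negative")
  if (any(abs(counts$count - round(counts$count)) > 1e-8)) {
    stop("counts must be integers")
  }
  counts$count <- round(counts$count)
  diag_rows <- counts$origin == counts$destination
  if (!has_diagonal && any(diag_rows)) {
    stop("dataset flagged has_diagonal = FALSE but contains diagonal pairs")
  }
  if (!directional) {
    o <- as.character(counts$origin); d <- as.character(counts$destination)
    swap <- o > d
    tmp <- counts$origin[swap]
    counts$origin[swap] <- counts$destination[swap]
    counts$destination[swap] <- tmp
  }
  key <- paste(counts$origin, counts$destination, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate OD pairs in counts table",
         if (!directional) " (undirected data must list each unordered pair once)")
  }
  structure(list(counts = counts, directional = directional,
                 has_diagonal = has_diagonal),
            class = "flow_dataset")
}

#' @export
print.flow_dataset <- function(x, ...) {
  cat(sprintf(
    "<flow_dataset: %d OD pairs, %s, diagonal %s, total trips %.0f>\n",
    nrow(x$counts), if (x$directional) "directional" else "symmetrised",
    if (x$has_diagonal) "present" else "absent", sum(x$counts$count)))
  invisible(x)
}

#' Negative binomial log-likelihood term
#'
#' Log-probability of observing `count` trips when the model expects `mean`,
#' under a negative binomial with over-dispersion `disp` (variance
#' `mean + disp * mean^2`; size parameter `1/disp`). Written out via
#' log-gamma:
#' `lgamma(D + 1/disp) - lgamma(D + 1) - lgamma(1/disp)
#'  + D*log(M/(M + 1/disp)) + (1/disp)*log((1/disp)/(M + 1/disp))`.
#' For `disp` below 1e-8 the Poisson limit `D*log(M) - M - lgamma(D + 1)` is
#' used for numerical stability.
#'
#' @param count observed trips (non-negative integer; vectorised).
#' @param mean expected trips (> 0; vectorised).
#' @param disp dispersion (>= 0, scalar).
#' @return log-likelihood value(s).
#' @export
nb_loglik_term <- function(count, mean, disp) {
  if (any(count < 0)) stop("negative count")
  if (any(mean <= 0)) stop("mean must be positive")
  if (length(disp) != 1L || disp < 0) stop("disp must be a scalar >= 0")
  if (disp < 1e-8) {
    return(count * log(mean) - mean - lgamma(count + 1))
  }
  r <- 1 / disp
  lgamma(count + r) - lgamma(count + 1) - lgamma(r) +
    count * (log(mean) - log(mean + r)) + r * (log(r) - log(mean + r))
}

#' Dataset log-likelihood under a model flow matrix
#'
#' Sums [nb_loglik_term()] over the dataset's masked OD pairs, matching
#' observed counts against the model's expected admin-level flows. Diagonal
#' pairs enter only when the dataset reports them AND the model defines
#' within-unit flows; a masked off-diagonal pair with zero or non-finite
#' expected flow is an error naming the pair.
#'
#' @param data a [flow_dataset()].
#' @param model_flows a `flow_matrix` over administrative units with unit ids
#'   as dimnames (e.g. from [expected_admin_flows()]).
#' @param disp negative binomial dispersion.
#' @return list with `loglik` and `n_terms`.
#' @export
dataset_loglik <- function(data, model_flows, disp) {
  stopifnot(inherits(data, "flow_dataset"))
  ids <- rownames(model_flows)
  if (is.null(ids)) ids <- as.character(attr(model_flows, "ids"))
  cnt <- data$counts
  model_has_diag <- identical(attr(model_flows, "diagonal_policy"), "included")
  use <- rep(TRUE, nrow(cnt))
  if (!model_has_diag) use <- cnt$origin != cnt$destination
  cnt <- cnt[use, , drop = FALSE]
  i <- match(as.character(cnt$origin), ids)
  j <- match(as.character(cnt$destination), ids)
  if (anyNA(i) || anyNA(j)) {
    bad <- which(is.na(i) | is.na(j))[1]
    stop(sprintf("model flows do not cover pair (%s, %s)",
                 cnt$origin[bad], cnt$destination[bad]))
  }
  mu <- unclass(model_flows)[cbind(i, j)]
  if (any(!is.finite(mu) | mu <= 0)) {
    bad <- which(!is.finite(mu) | mu <= 0)[1]
    stop(sprintf("masked pair (%s, %s) has zero or undefined model flow",
                 cnt$origin[bad], cnt$destination[bad]))
  }
  list(loglik = sum(nb_loglik_term(cnt$count, mu, disp)),
       n_terms = nrow(cnt))
}

#' Build a flow dataset from visit proportions
#'
#' Some mobility datasets report, for each unit of residence, the proportion
#' of nights its residents spend in each unit (including at home). Multiplying
#' by the resident population and rounding half-up yields integer trip counts,
#' directional and including the diagonal. Units absent from the proportions
#' table or with zero resident population are dropped.
#'
#' @param shares data.frame with columns `origin` (unit of residence),
#'   `destination` (unit visited) and `proportion` (>= 0; per-origin sums may
#'   not exceed 1 + `tol`).
#' @param residents data.frame with columns `id` and `population`.
#' @param tol tolerance on per-origin proportion sums.
#' @return a directional [flow_dataset()] with diagonal counts.
#' @export
ingest_proportions <- function(shares, residents, tol = 1e-6) {
  stopifnot(is.data.frame(shares),
            all(c("origin", "destination", "proportion") %in% names(shares)))
  if (any(shares$proportion < 0)) stop("negative proportion")
  sums <- tapply(shares$proportion, shares$origin, sum)
  if (any(sums > 1 + tol)) {
    stop("per-origin proportions sum to more than 1")
  }
  keep_units <- as.character(residents$id[residents$population > 0])
  present <- union(unique(as.character(shares$origin)),
                   unique(as.character(shares$destination)))
  keep_units <- intersect(keep_units, present)
  keep <- as.character(shares$origin) %in% keep_units &
    as.character(shares$destination) %in% keep_units
  shares <- shares[keep, , drop = FALSE]
  res <- residents$population[match(as.character(shares$origin),
                                    as.character(residents$id))]
  counts <- data.frame(
    origin = shares$origin,
    destination = shares$destination,
    count = floor(shares$proportion * res + 0.5)  # round half-up
  )
  flow_dataset(counts, directional = TRUE, has_diagonal = TRUE)
}
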