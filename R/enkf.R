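#' Ensemble of state vectors
#'
#' An ensemble is an `Ne x n` numeric matrix, one member per row, with column
#' names labelling the state variables (here `LAI` and `SM`). This
#' constructor validates and stamps the class; plain matrices with column
#' names are accepted everywhere.
#'
#' @param members `Ne x n` matrix, one state vector per row.
#' @param labels state variable names (default: existing column names).
#' @return the validated ensemble matrix.
#' @export
ensemble_matrix <- function(members, labels = colnames(members)) {
  members <- as.matrix(members)
  if (is.null(labels)) stop("ensemble needs state labels")
  colnames(members) <- labels
  if (nrow(members) < 2L) stop("an ensemble needs Ne >= 2 members")
  if (!all(is.finite(members))) stop("ensemble contains non-finite values")
  members
}

#' Ensemble mean and sample covariance
#'
#' The mean is the member average; the covariance uses the `1 / (Ne - 1)`
#' divisor. The returned matrix is symmetrised against rounding.
#'
#' @param ensemble `Ne x n` member matrix.
#' @return list with `mean` (named vector) and `cov` (`n x n` matrix).
#' @export
ensemble_stats <- function(ensemble) {
  ensemble <- as.matrix(ensemble)
  if (nrow(ensemble) < 2L) {
    stop("ensemble covariance undefined for Ne < 2")
  }
  m <- colMeans(ensemble)
  p <- stats::cov(ensemble)
  p <- (p + t(p)) / 2
  list(mean = m, cov = p)
}

#' Observation vector
#'
#' A set of simultaneous observations of state variables, with a diagonal
#' error covariance. The observation operator is implied by the labels: each
#' observed variable maps to the state component of the same name (an
#' identity/selection matrix).
#'
#' @param values observed values (length m).
#' @param labels names of the observed state variables.
#' @param variances observation error variances (diagonal of R).
#' @return an `obs_vector` list.
#' @export
obs_vector <- function(values, labels, variances) {
  stopifnot(length(values) == length(labels),
            length(values) == length(variances))
  if (length(values) < 1L) stop("observation vector must have m >= 1")
  if (any(variances < 0)) stop("observation variances must be >= 0")
  structure(list(values = as.numeric(values), labels = as.character(labels),
                 variances = as.numeric(variances)),
            class = "obs_vector")
}

# selection matrix H mapping state space -> observation space by label
selection_matrix <- function(obs_labels, state_labels) {
  miss <- setdiff(obs_labels, state_labels)
  if (length(miss)) {
    stop("observed variables absent from the state: ",
         paste(miss, collapse = ", "))
  }
  H <- matrix(0, nrow = length(obs_labels), ncol = length(state_labels),
              dimnames = list(obs_labels, state_labels))
  for (i in seq_along(obs_labels)) H[i, obs_labels[i]] <- 1
  H
}

#' Kalman gain
#'
#' `K = Pf H' (H Pf H' + R)^{-1}`. For a scalar observed state this reduces
#' to `p / (p + r)`, which lies in `[0, 1]`.
#'
#' @param Pf forecast error covariance (`n x n`).
#' @param H observation/selection matrix (`m x n`).
#' @param R observation error covariance (`m x m`, or the diagonal as a
#'   vector).
#' @return the `n x m` gain matrix.
#' @export
kalman_gain <- function(Pf, H, R) {
  Pf <- as.matrix(Pf)
  H <- as.matrix(H)
  if (length(R) == nrow(H) && is.null(dim(R))) R <- diag(R, nrow = nrow(H))
  S <- H %*% Pf %*% t(H) + R
  sol <- tryCatch(solve(S), error = function(e) {
    vars <- rownames(H)
    stop("singular innovation covariance for observed variable(s): ",
         paste(if (is.null(vars)) seq_len(nrow(H)) else vars, collapse = ", "),
         call. = FALSE)
  })
  Pf %*% t(H) %*% sol
}

#' Perturbed observation replicates
#'
#' Draws one noisy replicate of the observation per ensemble member:
#' `y_i = y_obs + v_i`, `v_i ~ N(0, R)`, so the analysis ensemble carries the
#' observation uncertainty. By default the draws are second-order exact:
#' the replicate set is centered on the observation and rescaled so its
#' sample covariance equals R exactly, removing the sampling noise that a
#' finite ensemble otherwise injects into the analysis mean and variance.
#' `exact = FALSE` gives plain independent draws.
#'
#' @param obs an [obs_vector()].
#' @param ne ensemble size (>= 2).
#' @param rng_seed integer seed; the same seed reproduces the replicates.
#' @param exact center and rescale the perturbations to their exact first
#'   and second moments (requires `ne > m + 1`; falls back to centering
#'   alone otherwise).
#' @param anomalies optional `ne x n` matrix of ensemble anomalies; when
#'   given (and `exact`), the perturbations are also made orthogonal to them
#'   in sample, so observation noise cannot correlate with the forecast
#'   ensemble by chance.
#' @return `ne x m` matrix of replicates, columns named by observed variable.
#' @export
perturb_observations <- function(obs, ne, rng_seed, exact = TRUE,
                                 anomalies = NULL) {
  if (ne < 2L) stop("need Ne >= 2 replicates")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  m <- length(obs$values)
  noise <- matrix(stats::rnorm(ne * m), nrow = ne)
  if (exact) {
    noise <- exact_noise(noise, diag(obs$variances, nrow = m), anomalies)
  } else {
    noise <- noise %*% diag(sqrt(obs$variances), nrow = m)
  }
  reps <- sweep(noise, 2, obs$values, `+`)
  colnames(reps) <- obs$labels
  reps
}

# Center a raw N(0, I) draw and rescale it so the sample covariance equals
# `target` exactly (1/(Ne-1) convention); optionally first project out the
# span of `anomalies` so the noise is uncorrelated with the ensemble in
# sample. Falls back gracefully when Ne is too small for the whitening.
exact_noise <- function(noise, target, anomalies = NULL) {
  ne <- nrow(noise)
  m <- ncol(noise)
  noise <- sweep(noise, 2, colMeans(noise))
  if (!is.null(anomalies)) {
    G <- crossprod(anomalies)
    ok <- ne > ncol(anomalies) + m + 1
    if (ok && rcond(G) > 1e-12) {
      noise <- noise - anomalies %*% solve(G, crossprod(anomalies, noise))
      noise <- sweep(noise, 2, colMeans(noise))
    }
  }
  S <- stats::cov(noise)
  if (ne > m + 1 && rcond(S) > 1e-12) {
    noise <- noise %*% solve(chol_psd_t(S)) %*% chol_psd_t(target)
  } else {
    sd_t <- sqrt(diag(target))
    sd_s <- sqrt(pmax(diag(S), .Machine$double.eps))
    noise <- noise %*% diag(sd_t / sd_s, nrow = m)
  }
  noise
}

# upper-triangular-like PSD factor with L %*% t(L) = Q, as t(L) for
# right-multiplication; eigen-based so semidefinite matrices work
chol_psd_t <- function(Q) {
  t(chol_psd(Q))
}

#' Ensemble forecast step
#'
#' Propagates each member independently through the model operator and adds
#' model-error noise `N(0, Q)`. With `Q = 0` (this study's setting: structural
#' and input uncertainties are ignored) the forecast is pure propagation.
#'
#' @param ensemble `Ne x n` member matrix.
#' @param step function mapping a named state vector to the next time.
#' @param Q process-noise covariance (`n x n`, vector diagonal, or 0).
#' @param rng_seed integer seed for the noise draws.
#' @param exact second-order exact noise: centered, orthogonal to the
#'   propagated ensemble anomalies, with sample covariance exactly Q.
#' @return forecast ensemble matrix.
#' @export
enkf_forecast <- function(ensemble, step, Q = 0, rng_seed = NULL,
                          exact = TRUE) {
  ensemble <- as.matrix(ensemble)
  n <- ncol(ensemble)
  labs <- colnames(ensemble)
  out <- t(apply(ensemble, 1, step))
  if (ncol(out) != n) out <- t(out)  # guard scalar-state apply() collapse
  colnames(out) <- labs
  if (length(Q) == 1 && !is.matrix(Q)) Q <- diag(Q, n)
  if (is.null(dim(Q))) Q <- diag(Q, n)
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10 * max(1, sum(abs(diag(Q)))))) {
    stop("process-noise covariance Q must be positive semidefinite")
  }
  if (any(diag(Q) > 0)) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    raw <- matrix(stats::rnorm(nrow(out) * n), ncol = n)
    if (exact) {
      A <- sweep(out, 2, colMeans(out))
      out <- out + exact_noise(raw, Q, A)
    } else {
      out <- out + raw %*% t(chol_psd(Q))
    }
  }
  out
}

# Cholesky-like factor for a PSD matrix (eigendecomposition fallback keeps
# semidefinite Q usable).
chol_psd <- function(Q) {
  e <- eigen((Q + t(Q)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(v), length(v))
}

#' EnKF analysis step
#'
#' One perturbed-observation update: forecast statistics from
#' [ensemble_stats()], gain from [kalman_gain()], observation replicates from
#' [perturb_observations()], then each member moves by
#' `x_i <- x_i + K (y_i - H x_i)`. Unobserved components move only through
#' the forecast cross-covariance.
#'
#' @param ensemble `Ne x n` forecast member matrix.
#' @param obs an [obs_vector()]; labels must be a subset of the state labels.
#' @param rng_seed integer seed for the observation perturbations.
#' @param diagnostics if `TRUE`, attach prior/posterior means, variances and
#'   the gain as attributes.
#' @param exact second-order exact observation perturbations (centered,
#'   orthogonal to the forecast anomalies, sample covariance exactly R);
#'   with it the posterior sample covariance follows the Joseph form
#'   `(I - KH) Pf (I - KH)' + K R K'` identically, so the analysis always
#'   contracts the observed-variable variance.
#' @return analysis ensemble matrix.
#' @export
enkf_analysis <- function(ensemble, obs, rng_seed = NULL,
                          diagnostics = FALSE, exact = TRUE) {
  ensemble <- as.matrix(ensemble)
  labs <- colnames(ensemble)
  H <- selection_matrix(obs$labels, labs)
  st <- ensemble_stats(ensemble)
  K <- kalman_gain(st$cov, H, obs$variances)
  reps <- perturb_observations(obs, nrow(ensemble), rng_seed, exact = exact,
                               anomalies = if (exact)
                                 sweep(ensemble, 2, colMeans(ensemble)))
  innov <- reps - ensemble %*% t(H)
  out <- ensemble + innov %*% t(K)
  colnames(out) <- labs
  if (diagnostics) {
    post <- ensemble_stats(out)
    attr(out, "diagnostics") <- list(
      prior_mean = st$mean, prior_var = diag(st$cov),
      post_mean = post$mean, post_var = diag(post$cov), gain = K)
  }
  out
}
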