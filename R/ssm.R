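#' Continuous state-space parameters
#'
#' Holds the continuous linear time-invariant system `h' = A h + B x`,
#' `y = C h + D x` that TreeSSM discretizes. `A` is stored through
#' `a_log` with `A = -exp(a_log)`, so `A < 0` (stability) holds by
#' construction throughout training. `delta_weight`/`delta_bias`
#' parameterize the linear map that produces the input-dependent step size
#' `Delta`; `delta_bias = 0` makes the initial `Delta` equal
#' `softplus(0) = log 2`.
#'
#' @param state_size hidden state dimension N (default 16)
#' @param channels feature channel count F
#' @param seed integer seed for parameter initialization
#' @return a `continuous_ssm`: list with `state_size`, `channels`, `a_log`
#'   (N x F), `B` (length N), `C` (length N), `D` (length F),
#'   `delta_weight` (F x F), `delta_bias` (length F)
#' @export
continuous_ssm <- function(state_size = 16L, channels, seed = 0L) {
  stopifnot(state_size >= 1L, channels >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  N <- as.integer(state_size); F <- as.integer(channels)
  structure(list(
    state_size = N, channels = F,
    # A starts in [-1, -0.1]
    a_log = matrix(stats::runif(N * F, log(0.1), 0), N, F),
    B = stats::rnorm(N, sd = 0.1),
    C = stats::rnorm(N, sd = 1 / sqrt(N)),
    D = rep(1, F),
    delta_weight = matrix(stats::rnorm(F * F, sd = 0.02), F, F),
    delta_bias = rep(0, F)
  ), class = "continuous_ssm")
}

#' Continuous transition matrix A of a [continuous_ssm()]
#'
#' @param ssm a [continuous_ssm()]
#' @return the N x F matrix `A = -exp(a_log)`, strictly negative
#' @export
ssm_A <- function(ssm) -exp(ssm$a_log)

# numerically stable softplus
softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

#' Input-dependent step size
#'
#' `Delta = softplus(x %*% delta_weight + delta_bias)`: a per-(vertex,
#' channel) positive step size for the zero-order-hold discretization.
#'
#' @param x V x F matrix of per-vertex features
#' @param delta_weight F x F matrix
#' @param delta_bias length-F vector
#' @return V x F matrix, strictly positive
#' @export
compute_delta <- function(x, delta_weight, delta_bias) {
  if (!all(is.finite(x))) stop("non-finite input features")
  x <- as.matrix(x)
  pre <- sweep(x %*% delta_weight, 2L, delta_bias, "+")
  softplus(pre)
}

#' Zero-order-hold discretization
#'
#' `A_bar = exp(Delta * A)` elementwise; `B_bar = Delta * B` (the usual
#' first-order approximation of the exact integral); `C_bar = C` and
#' `D_bar = D` pass through unchanged. `Delta` is per (vertex, channel),
#' `A` per (state, channel), and the discrete operators broadcast to
#' (vertex, state, channel).
#'
#' @param ssm a [continuous_ssm()]
#' @param Delta V x F matrix of positive step sizes
#' @return a `discrete_ssm`: list with `A_bar`, `B_bar` (V x N x F arrays),
#'   `C_bar` (length N), `D_bar` (length F), `Delta`
#' @export
discretize <- function(ssm, Delta) {
  Delta <- as.matrix(Delta)
  if (any(Delta < 0)) stop("Delta must be positive")
  if (ncol(Delta) != ssm$channels) stop("Delta channel count mismatch")
  V <- nrow(Delta); N <- ssm$state_size; F <- ssm$channels
  A <- ssm_A(ssm)                               # N x F
  # broadcast: [v, n, f] = Delta[v, f] * A[n, f]
  dA <- array(0, dim = c(V, N, F))
  Bb <- array(0, dim = c(V, N, F))
  for (n in seq_len(N)) {
    dA[, n, ] <- Delta * matrix(A[n, ], V, F, byrow = TRUE)
    Bb[, n, ] <- Delta * ssm$B[n]
  }
  structure(list(A_bar = exp(dA), B_bar = Bb,
                 C_bar = ssm$C, D_bar = ssm$D, Delta = Delta),
            class = "discrete_ssm")
}

# save/restore of the global RNG state so constructors can seed locally
# without disturbing the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
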