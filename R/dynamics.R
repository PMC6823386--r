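#' Linear feedforward/recurrent rate model
#'
#' The rate model `tau dv/dt = -v + M_rec v + W u`: input activity `u`
#' (e.g. the command interneurons) is fed forward through `W` into a
#' recurrent population `v` (e.g. an imprimitivity block) whose loops are
#' encoded by `M_rec`, typically a circulant filter.
#'
#' @param W Feedforward matrix (`length(v) x length(u)`).
#' @param M_rec Recurrent square matrix over the output population.
#' @param u Input activity vector.
#' @param tau Time constant (> 0), in arbitrary time units (defaults 1;
#'   results are in units of tau).
#' @return A `linear_filter_model`.
#' @export
linear_filter_model <- function(W, M_rec, u, tau = 1) {
  W <- as.matrix(W)
  M_rec <- as.matrix(M_rec)
  u <- as.numeric(u)
  if (tau <= 0) stop("tau must be positive")
  if (ncol(W) != length(u)) stop("ncol(W) must equal length(u)")
  if (nrow(M_rec) != ncol(M_rec) || nrow(M_rec) != nrow(W)) {
    stop("M_rec must be square with dimension nrow(W)")
  }
  structure(list(W = W, M_rec = M_rec, u = u, tau = tau),
            class = "linear_filter_model")
}

#' @export
print.linear_filter_model <- function(x, ...) {
  lam <- eigen(x$M_rec, only.values = TRUE)$values
  cat(sprintf("<linear_filter_model> %d -> %d units, tau = %g\n",
              length(x$u), nrow(x$W), x$tau))
  cat("  recurrent eigenvalues:",
      paste(format(lam, digits = 3), collapse = ", "), "\n")
  cat("  modes with Re(lambda) > 1 grow (linearly unstable)\n")
  invisible(x)
}

#' Steady state of the rate model
#'
#' Solves `v = (I - M_rec)^{-1} W u`, which exists iff 1 is not an
#' eigenvalue of the recurrent matrix.
#'
#' @param m A [linear_filter_model()].
#' @return Numeric steady-state vector.
#' @export
steady_state <- function(m) {
  stopifnot(inherits(m, "linear_filter_model"))
  n <- nrow(m$M_rec)
  lam <- eigen(m$M_rec, only.values = TRUE)$values
  if (any(abs(lam - 1) < 1e-10)) {
    stop("steady state undefined: recurrent matrix has eigenvalue 1 ",
         "(found lambda = ", format(lam[which.min(abs(lam - 1))]), ")")
  }
  bad <- lam[Re(lam) > 1]
  v <- solve(diag(n) - m$M_rec, m$W %*% m$u)
  if (length(bad)) {
    warning("recurrent eigenvalue ", format(bad[1], digits = 3),
            " exceeds 1: dynamics are non-contracting; the fixed point is unstable")
  }
  drop(v)
}

#' Simulate the rate model
#'
#' Fixed-step classical 4th-order Runge-Kutta integration of the linear
#' ODE `tau dv/dt = -v + M_rec v + W u` from `v0`.
#'
#' @param m A [linear_filter_model()].
#' @param v0 Initial activity vector.
#' @param dt Time step; must satisfy `dt < tau / 2` (explicit-scheme
#'   guard).
#' @param T_end Final time (> 0).
#' @return A tibble trajectory: column `time` plus one activity column
#'   per unit (`v1..vn`, or `M_rec`'s dimnames).
#' @export
simulate_filter <- function(m, v0, dt, T_end) {
  stopifnot(inherits(m, "linear_filter_model"))
  if (dt >= m$tau / 2) stop("dt must be smaller than tau / 2 for stability")
  if (T_end <= 0) stop("T_end must be positive")
  v0 <- as.numeric(v0)
  n <- nrow(m$M_rec)
  stopifnot(length(v0) == n)
  drive <- as.numeric(m$W %*% m$u)
  f <- function(v) (-v + m$M_rec %*% v + drive) / m$tau
  steps <- ceiling(T_end / dt)
  out <- matrix(0, steps + 1L, n)
  out[1, ] <- v0
  v <- v0
  for (s in seq_len(steps)) {
    k1 <- f(v)
    k2 <- f(v + dt / 2 * k1)
    k3 <- f(v + dt / 2 * k2)
    k4 <- f(v + dt * k3)
    v <- v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[s + 1L, ] <- v
  }
  nms <- rownames(m$M_rec)
  if (is.null(nms)) nms <- paste0("v", seq_len(n))
  traj <- tibble::as_tibble(stats::setNames(as.data.frame(out), nms))
  dplyr::bind_cols(tibble::tibble(time = seq(0, by = dt, length.out = steps + 1L)),
                   traj)
}

#' Project a trajectory on the Fourier eigenmodes of a circulant
#' recurrent matrix
#'
#' Requires `M_rec` to be exactly circulant. Each activity snapshot is
#' projected on the (real) Fourier eigenbasis; per mode, the closed-form
#' exponential rate `(lambda_i - 1) / tau` is reported, so modes with
#' `lambda < 1` decay, `lambda = 1` is marginal, and `lambda > 1` grows.
#'
#' @param m A [linear_filter_model()] with circulant `M_rec`.
#' @param trajectory A tibble from [simulate_filter()].
#' @return A list with `amplitudes` (tibble: `time`, `mode`, `amplitude`),
#'   `eigen` (the [circulant_eigen()]), `rates` (`(lambda - 1) / tau`).
#' @export
mode_projection <- function(m, trajectory) {
  stopifnot(inherits(m, "linear_filter_model"))
  if (!is_circulant_matrix(m$M_rec)) {
    stop("mode projection requires a circulant recurrent matrix")
  }
  ce <- circulant_eigen(m$M_rec[1, ])
  V <- ce$vectors
  acts <- as.matrix(trajectory[, setdiff(names(trajectory), "time")])
  amp <- acts %*% Conj(V)  # orthonormal columns: coefficients
  amps <- tibble::tibble(
    time = rep(trajectory$time, times = ncol(V)),
    mode = rep(seq_len(ncol(V)), each = nrow(acts)),
    amplitude = as.numeric(Re(amp))
  )
  list(amplitudes = amps,
       eigen = ce,
       rates = (Re(ce$values) - 1) / m$tau)
}

#' Plot a simulated trajectory
#'
#' @param trajectory A tibble from [simulate_filter()].
#' @return A ggplot line plot of unit activities over time (in units of
#'   tau).
#' @export
plot_trajectory <- function(trajectory) {
  long <- tidyr::pivot_longer(trajectory, -"time",
                              names_to = "unit", values_to = "activity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$activity,
                                     color = .data$unit)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (tau)", y = "activity") +
    ggplot2::theme_minimal()
}
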