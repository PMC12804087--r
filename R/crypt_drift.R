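# Neutral-drift clonal dynamics of intestinal crypt stem cells: a labelled
# clone of k cells in a niche of Ns is a birth-death chain on {0, ..., Ns}
# with absorbing boundaries (extinction at 0, crypt fixation at Ns). Between
# the boundaries the clone gains a cell at rate lambda * pr * w(k) and loses
# one at rate lambda * (1 - pr) * w(k). The default contact kernel w(k) = 1
# reflects the boundary-driven one-dimensional niche model (a contiguous clone
# on a ring has two boundaries, so the replacement propensity does not grow
# with clone size); w(k) = k gives the per-cell-rate variant.
#
# The exact occupancy distribution is obtained by matrix exponentiation of the
# (Ns+1)-state generator; the stochastic simulator is a Gillespie event loop.

#' Neutral-drift model parameters
#'
#' @param ns Stem cells per crypt (integer >= 2).
#' @param lambda Replacement rate (events per day).
#' @param pr Probability that a replacement expands the labelled clone;
#'   0.5 is neutral, > 0.5 positive bias, < 0.5 negative bias.
#' @param tau Start of the reporting time grid (days).
#' @param t_max End of the time grid (days).
#' @param t_step Grid spacing (days).
#' @param kernel `"boundary"` (w(k) = 1, default) or `"percell"` (w(k) = k).
#' @return A `drift_params` list, including the time grid `times`.
#' @export
drift_params <- function(ns = 5, lambda = 0.1, pr = 0.5, tau = 1,
                         t_max = 30, t_step = 0.5,
                         kernel = c("boundary", "percell")) {
  kernel <- match.arg(kernel)
  stopifnot(ns >= 2, ns == floor(ns), lambda > 0, pr > 0, pr < 1,
            tau >= 0, t_max >= tau, t_step > 0)
  structure(list(ns = as.integer(ns), lambda = lambda, pr = pr, tau = tau,
                 t_max = t_max, t_step = t_step, kernel = kernel,
                 times = seq(tau, t_max, by = t_step)),
            class = "drift_params")
}

.drift_generator <- function(params) {
  ns <- params$ns
  Q <- matrix(0, ns + 1L, ns + 1L)   # states 0..ns in rows/cols 1..ns+1
  for (k in seq_len(ns - 1L)) {
    w <- if (params$kernel == "boundary") 1 else k
    up <- params$lambda * params$pr * w
    dn <- params$lambda * (1 - params$pr) * w
    Q[k + 1L, k + 2L] <- up
    Q[k + 1L, k] <- dn
    Q[k + 1L, k + 1L] <- -(up + dn)
  }
  Q
}

# occupancy distribution over states 0..ns at each requested time, starting
# from clone size `init`
.drift_occupancy <- function(params, times, init = 1L) {
  Q <- .drift_generator(params)
  p0 <- numeric(params$ns + 1L)
  p0[init + 1L] <- 1
  occ <- t(vapply(times, function(t) {
    if (t == 0) p0
    else as.numeric(p0 %*% as.matrix(Matrix::expm(Q * t)))
  }, numeric(params$ns + 1L)))
  colnames(occ) <- as.character(0:params$ns)
  occ
}

#' Exact clone-survival (decay) curve
#'
#' Solves the birth-death chain exactly (matrix exponential of the generator;
#' no time-discretisation error). The surviving fraction at time t is the
#' probability the clone is not extinct, starting from a single labelled cell;
#' it equals 1 at t = 0 and is monotone non-increasing, with long-time limit
#' equal to the fixation probability (1/Ns when pr = 0.5).
#'
#' @param params A `drift_params`.
#' @param times Evaluation times (defaults to the parameter grid).
#' @param init Initial clone size (default 1).
#' @return A `decay_curve` data frame `time`, `surviving`, with the full
#'   occupancy matrix in attribute `occupancy`.
#' @export
drift_oracle <- function(params, times = params$times, init = 1L) {
  occ <- .drift_occupancy(params, times, init = init)
  out <- data.frame(time = times, surviving = 1 - occ[, "0"])
  class(out) <- c("decay_curve", "data.frame")
  attr(out, "occupancy") <- occ
  out
}

#' Stochastic clone-fate simulation
#'
#' Gillespie event simulation of independent labelled clones; reports the
#' empirical surviving fraction on the time grid and (optionally) the clone
#' size trajectories. Bitwise reproducible under a fixed seed.
#'
#' @param params A `drift_params`.
#' @param n_clones Number of independent clones.
#' @param seed RNG seed.
#' @param keep_states Keep the clone-size matrix (clones x grid times).
#' @return List with `curve` (a `decay_curve`) and, if requested, `states`.
#' @export
drift_simulate <- function(params, n_clones = 1000L, seed = 1L,
                           keep_states = FALSE) {
  stopifnot(n_clones >= 1)
  set.seed(seed)
  times <- params$times
  nt <- length(times)
  ns <- params$ns
  states <- matrix(NA_integer_, n_clones, nt)
  for (i in seq_len(n_clones)) {
    k <- 1L; t <- 0; idx <- 1L
    out <- integer(nt)
    repeat {
      if (k == 0L || k == ns) { out[idx:nt] <- k; break }
      w <- if (params$kernel == "boundary") 1 else k
      t2 <- t + stats::rexp(1L, params$lambda * w)
      while (idx <= nt && times[idx] < t2) { out[idx] <- k; idx <- idx + 1L }
      if (idx > nt) break
      t <- t2
      k <- k + if (stats::runif(1L) < params$pr) 1L else -1L
    }
    states[i, ] <- out
  }
  curve <- data.frame(time = times, surviving = colMeans(states > 0L))
  class(curve) <- c("decay_curve", "data.frame")
  res <- list(curve = curve, n_clones = n_clones)
  if (keep_states) res$states <- states
  res
}

#' Exact surviving fraction at a given day
#'
#' Evaluates the chain solution at the requested day (exactly, via the matrix
#' exponential, rather than interpolating a pre-computed grid). Day 0 returns
#' 1 by definition of the curve normalisation.
#'
#' @param params A `drift_params`.
#' @param day Days since clone induction (vectorised, >= 0).
#' @return Surviving fraction(s).
#' @export
neutral_fraction_at <- function(params, day) {
  stopifnot(all(day >= 0))
  drift_oracle(params, times = day)$surviving
}

#' Write a decay curve as TSV
#' @param curve A `decay_curve`.
#' @param path Output path.
#' @export
write_decay_curve_tsv <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
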