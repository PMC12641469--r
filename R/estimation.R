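# Free energy estimation: fixed-rule subsampling, Bennett acceptance ratio
# (the production estimator), its multistate generalization with a
# pathological-weight diagnostic, and repeat statistics.

#' Subsample saved frames
#'
#' The fixed production rule: the first 20% of the saved frames (floor) are
#' discarded as window-specific equilibration, then every fourth remaining
#' frame is retained, starting at the first retained frame. 4000 saved
#' frames yield 800 retained. No autocorrelation analysis is applied beyond
#' this rule; that is a deliberate fidelity choice.
#'
#' @param frames an `md_trajectory`, or the number of saved frames.
#' @return integer vector of retained frame indices.
#' @export
subsample_frames <- function(frames) {
  n <- if (inherits(frames, "md_trajectory")) dim(frames$frames)[1]
       else as.integer(frames)
  if (n < 5) stop("need at least 5 frames to subsample")
  n_drop <- floor(0.2 * n)
  rest <- (n_drop + 1):n
  rest[seq(1, length(rest), by = 4)]
}

#' Bennett acceptance ratio (BAR)
#'
#' Solves Bennett's self-consistent acceptance-ratio equation for the
#' reduced free energy difference between two neighboring states, given
#' reduced (dimensionless, beta * energy) work values in both directions,
#' by bisection to residual < 1e-10. The asymptotic variance estimate uses
#' the standard Fermi-function expression.
#'
#' @param w_forward reduced forward work values `u_1(x) - u_0(x)` for
#'   samples from state 0.
#' @param w_reverse reduced reverse work values `u_0(x) - u_1(x)` for
#'   samples from state 1.
#' @param thermo optional [thermo_state()]; when supplied, `dg` and `se`
#'   are in kcal/mol, otherwise in reduced units (k_B T).
#' @return Object of class `bar_result`: `dg`, `se`, `dg_reduced`,
#'   `se_reduced`, `low_overlap` flag (TRUE when the forward and
#'   negated-reverse work distributions do not overlap; the estimate then
#'   carries a large, unreliable uncertainty), `residual`.
#' @examples
#' bar(rep(1.5, 100), rep(-1.5, 100))$dg_reduced  # degenerate: exactly 1.5
#' @export
bar <- function(w_forward, w_reverse, thermo = NULL) {
  wf <- as.numeric(w_forward)
  wr <- as.numeric(w_reverse)
  if (!length(wf) || !length(wr)) stop("both work sample sets must be non-empty")
  nf <- length(wf)
  nr <- length(wr)
  M <- log(nf / nr)
  g <- function(f) {
    sum(stats::plogis(-(M + wf - f))) - sum(stats::plogis(-(-M + wr + f)))
  }
  # bracket the root (g is monotone increasing in f)
  f0 <- (mean(wf) - mean(wr)) / 2
  lo <- f0 - 1
  hi <- f0 + 1
  while (g(lo) > 0) lo <- f0 - 2 * (f0 - lo)
  while (g(hi) < 0) hi <- f0 + 2 * (hi - f0)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (abs(gm) < 1e-10 || (hi - lo) < 1e-15) break
    if (gm > 0) hi <- mid else lo <- mid
  }
  f <- mid
  a <- stats::plogis(-(M + wf - f))
  b <- stats::plogis(-(-M + wr + f))
  var_f <- (mean(a^2) / mean(a)^2 - 1) / nf +
           (mean(b^2) / mean(b)^2 - 1) / nr
  se <- sqrt(max(var_f, 0))
  low_overlap <- min(wf) > max(-wr)
  if (low_overlap) {
    warning("no overlap between forward and reverse work distributions; ",
            "BAR estimate is unreliable")
  }
  scale <- if (is.null(thermo)) 1 else 1 / thermo$beta
  structure(list(dg = f * scale, se = se * scale, dg_reduced = f,
                 se_reduced = se, low_overlap = low_overlap,
                 residual = g(f), n_forward = nf, n_reverse = nr),
            class = "bar_result")
}

#' @export
print.bar_result <- function(x, ...) {
  cat(sprintf("<bar_result> dG = %.4f +/- %.4f%s\n", x$dg, x$se,
              if (x$low_overlap) "  [LOW OVERLAP]" else ""))
  invisible(x)
}

#' Sum per-window free energy differences
#'
#' @param dg_windows numeric vector of per-window free energy differences,
#'   ordered along the schedule.
#' @param schedule optional [lambda_schedule()]; when given, it is checked
#'   to be a valid contiguous schedule with one more lambda value than there
#'   are windows (a gap is an error).
#' @return the total (plain sum).
#' @export
sum_windows <- function(dg_windows, schedule = NULL) {
  if (!is.null(schedule)) {
    schedule <- lambda_schedule(values = schedule)
    if (length(schedule) != length(dg_windows) + 1) {
      stop("schedule does not match the number of windows (gap in coverage)")
    }
  }
  sum(dg_windows)
}

#' Cross-state reduced energy matrix
#'
#' @param u numeric matrix, `K x N`: reduced energy of each of the `N`
#'   samples (columns, concatenated state by state) at each of the `K`
#'   states (rows).
#' @param n_k integer vector of length `K`: number of samples drawn from
#'   each state; `sum(n_k)` must equal `N`.
#' @param lambdas optional lambda value per state.
#' @return Object of class `energy_matrix`.
#' @export
energy_matrix <- function(u, n_k, lambdas = NULL) {
  u <- as.matrix(u)
  n_k <- as.integer(n_k)
  if (length(n_k) != nrow(u)) stop("one sample count per state required")
  if (sum(n_k) != ncol(u)) stop("sample counts do not add up to ncol(u)")
  if (any(n_k <= 0)) stop("every state must contribute samples")
  structure(list(u = u, n_k = n_k, lambdas = lambdas),
            class = "energy_matrix")
}

#' MBAR with pathological-weight diagnostics
#'
#' Attempts the self-consistent multistate (MBAR) solution on a full
#' cross-state reduced energy matrix. Every sample whose re-evaluated
#' reduced energy at a distant state lies more than `threshold` k_B T below
#' that state's own sampled minimum is flagged; such unphysically low
#' cross-energies attract disproportionately high weights and corrupt the
#' multistate estimate, which is why pairwise BAR is the production default.
#' Non-convergence returns the diagnostic report with `converged = FALSE`
#' rather than failing.
#'
#' @param em an [energy_matrix()].
#' @param threshold pathology threshold in k_B T (default 50).
#' @param tol convergence tolerance on the reduced free energies.
#' @param max_iter maximum self-consistent iterations.
#' @param thermo optional [thermo_state()] to report `dg` in kcal/mol.
#' @return Object of class `mbar_result`: `converged`, `f` (reduced free
#'   energy per state, first state 0), `dg` (total, last minus first state),
#'   `pathology` (data.frame of flagged samples; `weight` is each flagged
#'   sample's share of the total weight its evaluation state assigns to
#'   cross-state samples), `weights` (K x N matrix of raw MBAR weights).
#' @export
mbar_with_diagnostics <- function(em, threshold = 50, tol = 1e-8,
                                  max_iter = 2000, thermo = NULL) {
  stopifnot(inherits(em, "energy_matrix"))
  u <- em$u
  K <- nrow(u)
  N <- ncol(u)
  n_k <- em$n_k
  logn <- log(n_k)
  f <- numeric(K)
  logsumexp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # log denominator per sample: log sum_l N_l exp(f_l - u_ln)
    ld <- apply(logn + f - u, 2, logsumexp)
    f_new <- -vapply(seq_len(K),
                     function(k) logsumexp(-u[k, ] - ld), numeric(1))
    f_new <- f_new - f_new[1]
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
  }
  ld <- apply(logn + f - u, 2, logsumexp)
  W <- exp(sweep(-u, 2, ld) + f)   # W[k, n], columns of N_k W sum to 1 per k
  # pathology scan: sampled minimum of each state's own reduced energy.
  # The reported weight is the flagged sample's share of the total MBAR
  # weight the state assigns to cross-state samples (samples not drawn from
  # it) - the "disproportionate weight" signature: a healthy cross sample
  # at a distant state carries essentially no weight, a pathological one
  # carries the maximum attainable.
  state_of <- rep(seq_len(K), n_k)
  flags <- list()
  for (l in seq_len(K)) {
    own_min <- min(u[l, state_of == l])
    bad <- which(state_of != l & u[l, ] < own_min - threshold)
    if (length(bad)) {
      cross_total <- sum(W[l, state_of != l])
      flags[[length(flags) + 1]] <- data.frame(
        sample = bad, sampled_state = state_of[bad], eval_state = l,
        u = u[l, bad], state_min = own_min,
        weight = W[l, bad] / cross_total)
    }
  }
  pathology <- if (length(flags)) do.call(rbind, flags) else
    data.frame(sample = integer(0), sampled_state = integer(0),
               eval_state = integer(0), u = numeric(0),
               state_min = numeric(0), weight = numeric(0))
  scale <- if (is.null(thermo)) 1 else 1 / thermo$beta
  structure(list(converged = converged,
                 f = if (converged) f else NULL,
                 f_last = f,
                 dg = if (converged) (f[K] - f[1]) * scale else NA_real_,
                 pathology = pathology, weights = W,
                 iterations = it),
            class = "mbar_result")
}

#' @export
print.mbar_result <- function(x, ...) {
  cat(sprintf("<mbar_result> %s after %d iterations, dG = %s, %d flagged sample(s)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations,
              if (is.na(x$dg)) "NA" else sprintf("%.4f", x$dg),
              nrow(x$pathology)))
  invisible(x)
}

#' Mean and standard deviation over independent repeats
#'
#' The headline uncertainty convention: each full calculation is repeated
#' with independent seeds and the sample standard deviation (n - 1
#' denominator) of the per-repeat totals is the error estimate.
#'
#' @param totals numeric vector of per-repeat total free energy differences.
#' @return list with `mean`, `sd` (NA with `sd_undefined = TRUE` for a
#'   single repeat), `n`.
#' @export
repeat_statistics <- function(totals) {
  totals <- as.numeric(totals)
  if (!length(totals)) stop("no repeats supplied")
  if (length(totals) == 1) {
    return(list(mean = totals, sd = NA_real_, n = 1L, sd_undefined = TRUE))
  }
  list(mean = mean(totals), sd = stats::sd(totals), n = length(totals),
       sd_undefined = FALSE)
}

# one-sided exponential averaging (internal baseline for estimator
# comparisons; deliberately not exported as a production estimator)
exp_averaging <- function(w_forward) {
  m <- min(w_forward)
  m - log(mean(exp(-(w_forward - m))))
}
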