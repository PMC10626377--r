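#' Branched Bateman decay-chain kinetics
#'
#' Closed-form solution of the linear decay-chain rate equations for an
#' initially pure parent. Each member's abundance is a linear combination of
#' the exponentials `exp(-lambda_k t)` of its ancestors; the coefficients are
#' propagated down the DAG by partial fractions. Requires all decay constants
#' in the chain to be distinct (true for the bundled chains); near-degenerate
#' rates raise an error rather than returning an ill-conditioned answer.
#'
#' @name bateman
NULL

# Coefficient matrix C with N_i(t) = sum_k C[i,k] exp(-lambda_k t), for an
# initial condition of unit *activity* of the pure parent (N_parent(0) =
# 1/lambda_parent). Stable terminal members carry lambda = 0.
bateman_coefficients <- function(chain) {
  ch <- as_chain(chain)
  ord <- ch$order
  n <- length(ord)
  lam <- vapply(ord, function(nm) {
    nuc <- ch$members[[nm]]
    if (nuc$stable) 0 else log(2) / nuc$half_life_h
  }, numeric(1))
  rad <- lam > 0
  if (any(rad)) {
    l <- sort(lam[rad])
    if (length(l) > 1 && any(diff(l) / l[-length(l)] < 1e-9)) {
      stop("decay constants too close for the closed-form Bateman solution")
    }
  }
  C <- matrix(0, n, n, dimnames = list(ord, ord))
  C[1, 1] <- 1 / lam[1]  # unit parent activity at t = 0
  for (i in seq_len(n)[-1]) {
    nm <- ord[i]
    # inflow f_k e^{-lambda_k t} from every parent j with a mode to nm
    f <- numeric(n)
    for (j in seq_len(i - 1)) {
      pj <- ch$members[[ord[j]]]
      if (pj$stable) next
      hit <- pj$decay_modes$daughter == nm
      if (any(hit)) {
        b <- sum(pj$decay_modes$branching[hit])
        f <- f + b * lam[j] * C[j, ]
      }
    }
    active <- which(f != 0)
    for (k in active) {
      ck <- f[k] / (lam[i] - lam[k])
      C[i, k] <- C[i, k] + ck
      C[i, i] <- C[i, i] - ck
    }
  }
  list(C = C, lambda = lam, order = ord)
}

#' Per-member activities of a decay chain over time
#'
#' Activities (decays per unit time, normalised to unit parent activity at
#' t = 0) of every chain member on a time grid, from the closed-form branched
#' Bateman solution. Stable members have activity 0 by definition.
#'
#' @param chain `decay_chain` or parent nuclide name.
#' @param t_hours nondecreasing vector of times in hours (>= 0).
#' @return matrix `[length(t_hours) x members]` of activities; attribute
#'   `"t_hours"` carries the grid.
#' @examples
#' A <- bateman_activities("225Ac", c(0, 1, 24))
#' A[1, ]  # parent 1, progeny 0 at t = 0
#' @export
bateman_activities <- function(chain, t_hours) {
  stopifnot(all(is.finite(t_hours)), all(t_hours >= 0),
            !is.unsorted(t_hours))
  bc <- bateman_coefficients(chain)
  E <- exp(-outer(t_hours, bc$lambda))       # [t x k]
  A <- E %*% t(bc$C * bc$lambda)             # activities lambda_i N_i
  A[abs(A) < 1e-9] <- 0                      # clip closed-form cancellation noise
  dimnames(A) <- list(NULL, bc$order)
  if (any(t_hours == 0)) {                   # initial condition is exact
    A[t_hours == 0, ] <- 0
    A[t_hours == 0, 1] <- 1
  }
  attr(A, "t_hours") <- t_hours
  A
}

# Long-time asymptote of the member/parent activity ratio (parent must be the
# slowest-decaying member, as in the bundled chains).
activity_ratio_asymptote <- function(chain, member) {
  bc <- bateman_coefficients(chain)
  ch <- as_chain(chain)
  p <- ch$parent
  if (!member %in% bc$order) stop("member not in chain: ", member)
  lam <- bc$lambda
  if (any(lam > 0 & lam < lam[p] - 1e-12)) {
    stop("asymptote undefined: a progeny outlives the parent")
  }
  unname((lam[member] * bc$C[member, p]) / (lam[p] * bc$C[p, p]))
}

#' Time to reach transient/secular equilibrium
#'
#' Hours after which the member/parent activity ratio stays within `tolerance`
#' (relative) of its long-time asymptote. For the Ac-225 chain at 1%
#' tolerance every member equilibrates within 24 h, which is the delayed
#' gamma-counting rule the quantification layer enforces.
#'
#' @param chain `decay_chain` or parent name.
#' @param member member nuclide name.
#' @param tolerance relative tolerance in (0, 1).
#' @param horizon_h search horizon in hours.
#' @return hours (0 for the parent itself).
#' @examples
#' equilibrium_time("225Ac", "Fr-221")  # < 1 h
#' @export
equilibrium_time <- function(chain, member, tolerance = 0.01, horizon_h = 240) {
  stopifnot(tolerance > 0, tolerance < 1)
  ch <- as_chain(chain)
  member <- normalize_nuclide(member)
  if (!member %in% ch$order) stop("member not in chain: ", member)
  if (member == ch$parent) return(0)
  if (ch$members[[member]]$stable) stop("stable member has no activity ratio")
  r_inf <- activity_ratio_asymptote(ch, member)
  tt <- c(0, 10^seq(-5, log10(horizon_h), length.out = 4000))
  A <- bateman_activities(ch, tt)
  ratio <- A[, member] / A[, ch$parent]
  dev <- abs(ratio / r_inf - 1)
  ok <- rev(cumprod(rev(dev <= tolerance))) == 1  # within tol from here on
  if (!any(ok)) stop("equilibrium not reached within ", horizon_h, " h")
  tt[which(ok)[1]]
}

# Analytic time-integral of each member's activity over [0, Inf): equals the
# cumulative branch probability divided by lambda_parent for unit initial
# parent activity (total-decay conservation).
bateman_integrated_activity <- function(chain) {
  bc <- bateman_coefficients(chain)
  rad <- bc$lambda > 0
  out <- vapply(seq_along(bc$order), function(i) {
    if (!rad[i]) return(0)
    sum(bc$lambda[i] * bc$C[i, rad] / bc$lambda[rad])
  }, numeric(1))
  setNames(out, bc$order)
}
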