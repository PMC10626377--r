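# Independent oracles used by the test suite. These deliberately do not share
# code paths with the package internals they check.

# --- Stiff-chain ODE oracle -------------------------------------------------
# Fixed-step RK4 integration of the Ac-225 chain rate equations. The two
# ultra-short-lived members (At-217, T1/2 = 32.6 ms; Po-213, T1/2 = 3.7 us)
# are slaved by quasi-steady-state -- their activity equals the
# branching-weighted inflow activity -- which removes the stiffness. The QSS
# hand-off drops the members' ~50 ms equilibration lag, giving a relative
# error of order (mean life)/t that compounds with chain depth: measured
# maximum 7.5e-4 for Pb-209 at the earliest grid time (0.05 h), decaying as
# ~1/t, always inside the 0.1% comparison band. Integrated states:
# Ac-225 -> Fr-221 -> [At-217 QSS] -> Bi-213 -(0.9784)-> [Po-213 QSS] -> Pb-209
#                                      \-(0.0216)-> Tl-209 -> Pb-209
# Initial condition: unit parent activity. Returns activities of all 7
# radioactive members at the requested times (which must be multiples of h).
ode_oracle_ac225 <- function(chain, t_out, h = 0.001) {
  hl <- vapply(c("Ac-225", "Fr-221", "Bi-213", "Tl-209", "Pb-209"),
               function(nm) chain$members[[nm]]$half_life_h, numeric(1))
  lam <- log(2) / hl
  bi <- chain$members[["Bi-213"]]$decay_modes
  b_beta <- bi$branching[bi$daughter == "Po-213"]
  b_alpha <- bi$branching[bi$daughter == "Tl-209"]

  deriv <- function(N) {
    c(-lam[1] * N[1],
      lam[1] * N[1] - lam[2] * N[2],                          # Fr (At inflow = Fr outflow, QSS)
      lam[2] * N[2] - lam[3] * N[3],                          # Bi
      b_alpha * lam[3] * N[3] - lam[4] * N[4],                # Tl
      b_beta * lam[3] * N[3] + lam[4] * N[4] - lam[5] * N[5]) # Pb (Po QSS)
  }
  N <- c(1 / lam[1], 0, 0, 0, 0)
  steps_out <- round(t_out / h)
  stopifnot(max(abs(steps_out * h - t_out)) < 1e-9)
  out <- matrix(NA_real_, length(t_out), 7,
                dimnames = list(NULL, c("Ac-225", "Fr-221", "At-217", "Bi-213",
                                        "Tl-209", "Po-213", "Pb-209")))
  record <- function(row, N) {
    A <- lam * N
    out[row, ] <<- c(A[1], A[2], A[2], A[3], A[4], b_beta * A[3], A[5])
  }
  step <- 0L
  for (j in seq_along(t_out)) {
    while (step < steps_out[j]) {
      k1 <- deriv(N)
      k2 <- deriv(N + h / 2 * k1)
      k3 <- deriv(N + h / 2 * k2)
      k4 <- deriv(N + h * k3)
      N <- N + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      step <- step + 1L
    }
    record(j, N)
  }
  out
}

# --- Sum-of-exponentials quadrature oracle ----------------------------------
# Integrated in two pieces so the adaptive rule resolves the fast component,
# whose support is tiny relative to the slow component's 20/l2 horizon.
quadrature_cumulated <- function(A1, l1, A2, l2, upper) {
  f <- function(t) A1 * exp(-l1 * t) + A2 * exp(-l2 * t)
  split <- min(20 / l1, upper)
  q1 <- stats::integrate(f, 0, split, rel.tol = 1e-10, subdivisions = 2000L)$value
  q2 <- if (split < upper) {
    stats::integrate(f, split, upper, rel.tol = 1e-10, subdivisions = 2000L)$value
  } else 0
  q1 + q2
}

# --- Summary-preserving raw samples -----------------------------------------
# Construct n raw values with exactly the requested mean and sample SD, so
# stats::t.test can serve as an independent check of welch_compare.
raw_with_moments <- function(mean, sd, n, shape = seq_len(n)) {
  z <- scale(shape)[, 1]
  mean + sd * z
}

# --- Simple deterministic biodist row builder -------------------------------
biodist_row <- function(animal_id = "m1", organ = "tumor", time_pi = 4,
                        measured_activity = 10, count_time = time_pi,
                        sample_mass = 0.3, injected_activity = 1000) {
  data.frame(animal_id = animal_id, organ = organ, time_pi = time_pi,
             measured_activity = measured_activity, count_time = count_time,
             sample_mass = sample_mass, injected_activity = injected_activity,
             stringsAsFactors = FALSE)
}

# Lu-177 tumor truth of the default generator, in %IA (mass 0.3 g), and its
# analytic cumulated activity with physical decay applied.
default_lu_tumor_truth <- function() {
  cfg <- sim_config(seed = 1)
  k <- cfg$organ_kinetics
  row <- k[k$nuclide == "Lu-177" & k$organ == "tumor", ]
  c(A1 = row$A1 * row$mass_g, lambda1 = row$lambda1,
    A2 = row$A2 * row$mass_g, lambda2 = row$lambda2)
}
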