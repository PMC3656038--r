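# Independent oracles for the daily pool map.
#
# With a constant modifier f and constant daily inputs (bL, bR) the daily
# operator is the affine map x -> A x + c on the pool vector
# (labile, resistant, light, heavy), written down here directly from the
# model definition and iterated in closed form via matrix powers.

daily_map_matrix <- function(params, f = 1) {
  a <- exp(-c(params$K_L, params$K_R, params$K_LC, params$K_HC) * f)
  d <- 1 - a
  matrix(c(
    a[1],                0,                0,    0,
    0,                   a[2],             0,    0,
    params$F_LL * d[1],  params$F_RL * d[2], a[3], 0,
    0,                   0,                params$F_LH * d[3], a[4]
  ), nrow = 4, byrow = TRUE)
}

daily_map_offset <- function(params, f = 1, bL = 0, bR = 0) {
  daily_map_matrix(params, f) %*% c(bL, bR, 0, 0)
}

mat_pow <- function(A, n) {
  out <- diag(nrow(A))
  P <- A
  while (n > 0) {
    if (n %% 2 == 1) out <- out %*% P
    P <- P %*% P
    n <- n %/% 2
  }
  out
}

# x_n = A^n x0 + (I - A)^{-1} (I - A^n) c
closed_form_state <- function(x0, params, f, bL, bR, n_days) {
  A <- daily_map_matrix(params, f)
  cc <- daily_map_offset(params, f, bL, bR)
  An <- mat_pow(A, n_days)
  I <- diag(4)
  as.numeric(An %*% x0 + solve(I - A, (I - An) %*% cc))
}

random_params <- function() {
  soc_params(K_L = runif(1, 5e-3, 5e-2), K_R = runif(1, 2e-4, 2e-3),
             K_LC = runif(1, 1e-4, 5e-4), K_HC = runif(1, 1e-5, 5e-5),
             F_LL = runif(1, 0.1, 0.6), F_RL = runif(1, 0.1, 0.6),
             F_LH = runif(1, 0.1, 0.6))
}
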