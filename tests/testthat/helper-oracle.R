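# Independent two-link Newton-Euler oracle.
#
# Derived separately from the package implementation: moments are taken about
# the ankle (shank) and the hip (femur) with the transport terms
# r_{COM/pivot} x m a_COM, instead of about each COM, and the unknowns are
# eliminated sequentially instead of via a 6x6 solve.  Frame and sign
# conventions match the package API (x anterior, y up, hip at origin,
# theta_f/theta_t from the downward vertical anterior-positive, CCW moments,
# knee-extensor moment positive, acting +M on the shank and -M on the femur).
oracle_joint_loads <- function(state, params, Fay) {
  lf <- params$lf; lt <- params$lt
  pf <- params$pf; pt <- params$pt
  mf <- params$mf; mt <- params$mt
  wf <- params$wf; wt <- params$wt
  th_f <- state$theta_f; th_t <- state$theta_t

  # geometry, written out independently
  Kx <- lf * sin(th_f);  Ky <- -lf * cos(th_f)
  Ax <- Kx + lt * sin(th_t); Ay <- Ky - lt * cos(th_t)
  Cfx <- Kx + pf * (0 - Kx) / lf; Cfy <- Ky + pf * (0 - Ky) / lf
  Ctx <- Kx + pt * (Ax - Kx) / lt; Cty <- Ky + pt * (Ay - Ky) / lt

  # shank vertical force balance gives Fky directly
  Fky <- mt * state$ddy_t + wt - Fay

  # shank moments about the ankle:
  #   (K-A) x Fk + (Ct-A) x (0,-wt) + M = It*alpha_t + (Ct-A) x mt*a_Ct
  # femur moments about the hip:
  #   K x (-Fk) + Cf x (0,-wf) - M = If*alpha_f + Cf x mf*a_Cf
  # two equations in (Fkx, M):
  a1 <- -(Ky - Ay); b1 <- 1
  c1 <- params$It * state$alpha_t +
    (Ctx - Ax) * mt * state$ddy_t - (Cty - Ay) * mt * state$ddx_t -
    (Kx - Ax) * Fky + (Ctx - Ax) * wt
  a2 <- Ky; b2 <- -1
  c2 <- params$If * state$alpha_f +
    Cfx * mf * state$ddy_f - Cfy * mf * state$ddx_f +
    Kx * Fky + Cfx * wf
  det <- a1 * b2 - a2 * b1
  Fkx <- (c1 * b2 - c2 * b1) / det
  M <- (a1 * c2 - a2 * c1) / det

  Fax <- mt * state$ddx_t - Fkx
  Fhx <- Fkx + mf * state$ddx_f
  Fhy <- Fky + wf + mf * state$ddy_f
  c(Fax = Fax, Fkx = Fkx, Fky = Fky, Fhx = Fhx, Fhy = Fhy, M = M)
}

random_dynamic_state <- function() {
  list(theta_f = runif(1, -0.3, 0.9),
       theta_t = runif(1, -1.2, 0.5),
       alpha_f = runif(1, -80, 80), alpha_t = runif(1, -80, 80),
       ddx_f = runif(1, -20, 20), ddy_f = runif(1, -20, 20),
       ddx_t = runif(1, -20, 20), ddy_t = runif(1, -20, 20))
}

random_params <- function() {
  lf <- runif(1, 0.2, 0.5); lt <- runif(1, 0.2, 0.5)
  phantom_params("braceless", lf = lf, lt = lt,
                 wf = runif(1, 5, 30), wt = runif(1, 5, 30),
                 If = runif(1, 5e-3, 5e-2), It = runif(1, 5e-3, 5e-2),
                 pf = runif(1, 0.05, lf), pt = runif(1, 0.05, lt))
}
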