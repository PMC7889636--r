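#' Womersley number
#'
#' `alpha = r sqrt(omega / nu)`: the ratio of oscillatory inertial to viscous
#' effects in a tube of radius `r` driven at angular frequency `omega` in a
#' fluid of kinematic viscosity `nu`.
#'
#' @param radius tube radius, mm.
#' @param angular_frequency rad/s.
#' @param nu kinematic viscosity, mm^2/s.
#' @return dimensionless Womersley number.
#' @export
womersley_alpha <- function(radius, angular_frequency, nu) {
  if (any(radius <= 0) || any(angular_frequency <= 0) || any(nu <= 0))
    stop("radius, angular_frequency and nu must all be positive")
  radius * sqrt(angular_frequency / nu)
}

## Bessel functions J0, J1 of a complex argument by power series.
## Converges for any z; usable in double precision for |z| <~ 15 (the
## cancellation factor exp(|Im z|) stays below ~1e5 there).
.besselJ01 <- function(z) {
  q <- -(z * z) / 4
  t0 <- 1 + 0i; t1 <- 1 + 0i
  s0 <- t0; s1 <- t1
  for (k in 1:400) {
    t0 <- t0 * q / (k * k)
    t1 <- t1 * q / (k * (k + 1))
    s0 <- s0 + t0; s1 <- s1 + t1
    if (Mod(t0) < 1e-18 * Mod(s0) && Mod(t1) < 1e-18 * Mod(s1)) break
  }
  list(J0 = s0, J1 = (z / 2) * s1)
}

## asymptotic J1(z)/J0(z) for Im(z) >> 0 (our Lambda has arg 3*pi/4):
## the exponentially growing parts cancel, leaving
##   J1/J0 -> i (P1 - i Q1) / (P0 - i Q0)
.besselJ_ratio_asym <- function(z) {
  z2 <- z * z; z3 <- z2 * z
  P0 <- 1 - 9 / (128 * z2)
  Q0 <- -1 / (8 * z) + 75 / (1024 * z3)
  P1 <- 1 + 15 / (128 * z2)
  Q1 <- 3 / (8 * z) - 105 / (1024 * z3)
  1i * (P1 - 1i * Q1) / (P0 - 1i * Q0)
}

## F(alpha) = 1 - 2 J1(L)/(L J0(L)), L = i^{3/2} alpha.
## Small alpha: F -> i alpha^2 / 8 (Poiseuille); large alpha: F -> 1
## (inertance-dominated plug flow).
.womersley_factor <- function(alpha) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (alpha > 1e4)
    stop("Womersley number ", signif(alpha, 3), " too large for a stable ",
         "Bessel evaluation; reduce harmonic count or check units")
  L <- complex(modulus = alpha, argument = 3 * pi / 4)  # i^{3/2} alpha
  if (alpha <= 15) {
    J <- .besselJ01(L)
    1 - 2 * J$J1 / (L * J$J0)
  } else {
    1 - 2 * .besselJ_ratio_asym(L) / L
  }
}

#' Oscillatory (Womersley) impedance of a vessel segment
#'
#' Rigid-tube, fully developed oscillatory flow: the pressure-gradient to
#' flow transfer at angular frequency `omega` is
#' `Z = (i omega rho L / (pi r^2)) / F(alpha)` with
#' `F = 1 - 2 J1(Lambda) / (Lambda J0(Lambda))`, `Lambda = i^(3/2) alpha`.
#' At `omega = 0` this reduces exactly to the Poiseuille resistance
#' `1/G = 8 mu L / (pi r^4)`; at large `alpha` it tends to the pure
#' inertance `i omega rho L / (pi r^2)`.
#'
#' @param seg one row of a network's `segments` table.
#' @param blood a [blood_properties()] object.
#' @param angular_frequency rad/s (>= 0).
#' @return complex impedance, mmHg per (mm^3/s).
#' @export
segment_impedance <- function(seg, blood = blood_properties(),
                              angular_frequency = 0) {
  if (angular_frequency < 0) stop("angular_frequency must be >= 0")
  if (angular_frequency == 0)
    return(complex(real = 1 / segment_conductance(seg, blood)))
  r <- equivalent_radius(seg$area)
  alpha <- womersley_alpha(r, angular_frequency, blood$nu_mm2_s)
  Fw <- .womersley_factor(alpha)
  Z_pa <- 1i * angular_frequency * blood$rho_g_mm3 * seg$length /
    (pi * r^2) / Fw
  Z_pa / .PA_PER_MMHG
}

## normalized Womersley radial profile phi(y), y = r/R in [0,1]:
## velocity(y) = mean_velocity * phi(y), phi = (1 - J0(L y)/J0(L)) / F.
## Series-based; guarded to the range where the series is accurate.
.womersley_profile <- function(alpha, y) {
  if (alpha > 15)
    stop("Womersley number ", signif(alpha, 3), " too large for radial ",
         "profile reconstruction; use steady mode or fewer harmonics")
  L <- complex(modulus = alpha, argument = 3 * pi / 4)
  J0L <- .besselJ01(L)$J0
  Fw <- .womersley_factor(alpha)
  vapply(y, function(yy) (1 - .besselJ01(L * yy)$J0 / J0L) / Fw,
         complex(1))
}
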