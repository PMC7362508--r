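#' @include AllClasses.R
NULL

#' Construct an EchoPair
#'
#' @param s1,s2 complex volumes at the two echo times.
#' @param te1Ms,te2Ms echo times in ms.
#' @param deltaFHz assumed water-fat shift in Hz (default -220, the 3.5 ppm
#'   main fat peak at 1.5 T).
#' @return An \code{\linkS4class{EchoPair}}.
#' @export
EchoPair <- function(s1, s2, te1Ms, te2Ms, deltaFHz = -220) {
  s1 <- as.array(s1); s2 <- as.array(s2)
  storage.mode(s1) <- "complex"; storage.mode(s2) <- "complex"
  new("EchoPair", s1 = s1, s2 = s2, te1Ms = te1Ms, te2Ms = te2Ms,
      deltaFHz = deltaFHz)
}

#' Fat phasor angle at an echo time
#'
#' \eqn{\theta(TE) = 2\pi \Delta f_{fw} TE / 1000} (TE in ms, shift in Hz).
#'
#' @param teMs echo time in ms.
#' @param deltaFHz water-fat shift in Hz.
#' @return Angle in radians.
#' @export
fatPhasorAngle <- function(teMs, deltaFHz = -220) {
  2 * pi * deltaFHz * teMs / 1000
}

#' Two-point Dixon water-fat separation
#'
#' Per voxel, solves the linear model
#' \eqn{s_k = W + F e^{i\theta_k}}, \eqn{k \in \{1,2\}}, for real
#' \eqn{W, F \ge 0} in the least-squares sense (four real equations, two
#' unknowns), with \eqn{\theta_k} from the echo times and the assumed
#' water-fat shift. Negative least-squares solutions, which arise under
#' noise, are clipped to zero. When a field map \code{psiHz} is supplied,
#' the background phase \eqn{e^{i 2\pi \psi TE/1000}} is demodulated from
#' each echo first; the separation is exact on noiseless input generated
#' with the same field map. Without demodulation the background phase is
#' assumed zero.
#'
#' @param pair an \code{\linkS4class{EchoPair}}.
#' @param psiHz optional off-resonance field map (Hz), same spatial shape
#'   as the echoes (a 3D map is recycled over frames of 4D echoes).
#' @return List with \code{water} and \code{fat} non-negative arrays.
#' @examples
#' # in-phase / opposed-phase pair: W = (S_IP + S_OP)/2, F = (S_IP - S_OP)/2
#' df <- -220
#' teIP <- 1000 / abs(df)    # theta = -2*pi (in phase)
#' teOP <- 1500 / abs(df)    # theta = -3*pi (opposed)
#' p <- EchoPair(array(1.5 + 0i, c(1, 1, 1)), array(0.5 + 0i, c(1, 1, 1)),
#'               teIP, teOP, df)
#' dixonSeparate(p)
#' @export
dixonSeparate <- function(pair, psiHz = NULL) {
  validObject(pair)
  th1 <- fatPhasorAngle(pair@te1Ms, pair@deltaFHz)
  th2 <- fatPhasorAngle(pair@te2Ms, pair@deltaFHz)
  dth <- (th1 - th2) %% (2 * pi)
  if (min(dth, 2 * pi - dth) < 1e-8)
    stop("echo times do not separate water and fat")
  s1 <- pair@s1; s2 <- pair@s2
  if (!is.null(psiHz)) {
    psiHz <- as.array(psiHz)
    d <- dim(s1)
    if (identical(dim(psiHz), d[1:3]) && length(d) == 4L)
      psiHz <- array(rep(psiHz, d[4L]), dim = d)
    if (!identical(dim(psiHz), d))
      stop("field map shape does not match the echoes")
    s1 <- s1 * exp(-1i * 2 * pi * psiHz * pair@te1Ms / 1000)
    s2 <- s2 * exp(-1i * 2 * pi * psiHz * pair@te2Ms / 1000)
  }
  # Normal equations of the stacked real system
  #   [Re s_k; Im s_k] = [1 cos(th_k); 0 sin(th_k)] [W; F]:
  #   A'A = [2, c1+c2; c1+c2, 2], since cos^2 + sin^2 = 1.
  c1 <- cos(th1); c2 <- cos(th2)
  b1 <- Re(s1) + Re(s2)
  b2 <- Re(s1) * c1 + Im(s1) * sin(th1) + Re(s2) * c2 + Im(s2) * sin(th2)
  det <- 4 - (c1 + c2)^2
  if (abs(det) < 1e-12)
    stop("echo times do not separate water and fat")
  W <- (2 * b1 - (c1 + c2) * b2) / det
  F <- (2 * b2 - (c1 + c2) * b1) / det
  W[W < 0] <- 0
  F[F < 0] <- 0
  list(water = array(W, dim(s1)), fat = array(F, dim(s1)))
}
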