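# Versioned coefficients of the toy dynamical systems shipped with causalts.
# These are the single source of truth: simulators read this file, and the
# methods vignette documents the rationale for each choice.
version: 1

# Five-variable linear network. X, Y, W, V are undamped linear oscillators
# x(t+1) = 2 cos(2*pi/period) x(t) - x(t-1) (exact sinusoids, unit amplitude,
# random phase). Z is a damped linear response driven by X and Y only:
# Z(t+1) = z_self * Z(t) + z_from_x * X(t) + z_from_y * Y(t) [+ noise].
# Periods are chosen so Z's fundamental period (lcm of its drivers') is three
# times X's period, and W, V are incommensurate bystanders.
linear_network:
  period_x: 10
  period_y: 30
  period_w: 14
  period_v: 22
  z_self: 0.5
  z_from_x: 0.5
  z_from_y: 0.5
  burn_in: 100

# Two-species community with unidirectional coupling S1 -> S2 and optional
# unobserved periodic drivers:
# S1(t+1) = max(0, s1_self*S1(t) + s1_base + d1_amp*sin(2*pi*t/d1_period + phi1) + ep1(t))
# S2(t+1) = max(0, s2_self*S2(t) + s2_base + coupling*S1(t)
#                  + d2_amp*sin(2*pi*t/d2_period + phi2) + ep2(t))
# Process noise ep* enters the recursion (propagates); measurement noise is
# added to the recorded output only. States are floored at 0 (abundances).
two_species:
  s1_self: 0.5
  s1_base: 5
  s2_self: 0.5
  s2_base: 2
  coupling: 0.4
  driver1_period: 23
  driver2_period: 11
  driver1_amplitude: 4
  driver2_amplitude: 4
  burn_in: 100

# Linear stochastic chain X -> Y -> Z used for the Granger noise/subsampling
# pathologies; process noise is unit-variance IID normal on every variable.
noisy_chain:
  self_x: 0.5
  self_y: 0.5
  self_z: 0.5
  x_to_y: 0.5
  y_to_z: 0.5
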