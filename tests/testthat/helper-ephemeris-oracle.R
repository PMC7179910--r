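# Independent astronomical reference used only by the tests.
#
# Deliberately implemented from different published algorithms than the
# package (which uses a Meeus-style theory): the solar position follows
# Michalsky (1988, Solar Energy 40:227-235, the Astronomical Almanac
# algorithm), and the lunar position follows the Astronomical Almanac's
# low-precision series (accuracy ~0.3 deg), so agreement between the two
# routes is a genuine cross-implementation check.

.orc_d2r <- pi / 180

# Michalsky solar position: returns ra/dec (deg) and GMST (deg)
oracle_sun <- function(time) {
  n <- .julian_day_oracle(time) - 2451545
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360
  lambda <- L + 1.915 * sin(g * .orc_d2r) + 0.020 * sin(2 * g * .orc_d2r)
  eps <- 23.439 - 0.0000004 * n
  ra <- atan2(cos(eps * .orc_d2r) * sin(lambda * .orc_d2r),
    cos(lambda * .orc_d2r)) / .orc_d2r
  dec <- asin(sin(eps * .orc_d2r) * sin(lambda * .orc_d2r)) / .orc_d2r
  hours_ut <- (as.numeric(time) %% 86400) / 3600
  gmst <- ((6.697375 + 0.0657098242 * (n - hours_ut / 24) +
    1.00273790935 * hours_ut) %% 24) * 15
  list(ra = ra %% 360, dec = dec, gmst = gmst)
}

.julian_day_oracle <- function(time) as.numeric(time) / 86400 + 2440587.5

# Astronomical Almanac low-precision lunar position (geocentric),
# plus horizontal parallax series for the topocentric correction.
oracle_moon <- function(time) {
  tt <- (.julian_day_oracle(time) - 2451545) / 36525
  s <- function(x) sin(x * .orc_d2r)
  co <- function(x) cos(x * .orc_d2r)
  lambda <- 218.32 + 481267.883 * tt +
    6.29 * s(134.9 + 477198.85 * tt) -
    1.27 * s(259.2 - 413335.38 * tt) +
    0.66 * s(235.7 + 890534.23 * tt) +
    0.21 * s(269.9 + 954397.70 * tt) -
    0.19 * s(357.5 + 35999.05 * tt) -
    0.11 * s(186.6 + 966404.05 * tt)
  beta <- 5.13 * s(93.3 + 483202.03 * tt) +
    0.28 * s(228.2 + 960400.87 * tt) -
    0.28 * s(318.3 + 6003.18 * tt) -
    0.17 * s(217.6 - 407332.20 * tt)
  par_deg <- 0.9508 +
    0.0518 * co(134.9 + 477198.85 * tt) +
    0.0095 * co(259.2 - 413335.38 * tt) +
    0.0078 * co(235.7 + 890534.23 * tt) +
    0.0028 * co(269.9 + 954397.70 * tt)
  eps <- 23.439 - 0.013 * tt
  lam <- lambda %% 360
  ra <- atan2(s(lam) * co(eps) - tan(beta * .orc_d2r) * s(eps),
    co(lam)) / .orc_d2r
  dec <- asin(s(beta) * co(eps) + co(beta) * s(eps) * s(lam)) / .orc_d2r
  list(ra = ra %% 360, dec = dec, parallax = par_deg,
    dist_km = 6378.14 / sin(par_deg * .orc_d2r))
}

.oracle_altitude <- function(ra, dec, gmst, lon, lat) {
  ha <- gmst + lon - ra
  asin(pmin(1, pmax(-1,
    sin(lat * .orc_d2r) * sin(dec * .orc_d2r) +
      cos(lat * .orc_d2r) * cos(dec * .orc_d2r) * cos(ha * .orc_d2r)))) /
    .orc_d2r
}

oracle_sun_altitude <- function(time, lon, lat) {
  su <- oracle_sun(time)
  .oracle_altitude(su$ra, su$dec, su$gmst, lon, lat)
}

oracle_moon_altitude <- function(time, lon, lat) {
  mo <- oracle_moon(time)
  gmst <- oracle_sun(time)$gmst
  alt <- .oracle_altitude(mo$ra, mo$dec, gmst, lon, lat)
  alt - mo$parallax * cos(alt * .orc_d2r)
}

oracle_moon_fraction <- function(time) {
  su <- oracle_sun(time)
  mo <- oracle_moon(time)
  cos_psi <- sin(su$dec * .orc_d2r) * sin(mo$dec * .orc_d2r) +
    cos(su$dec * .orc_d2r) * cos(mo$dec * .orc_d2r) *
      cos((su$ra - mo$ra) * .orc_d2r)
  cos_psi <- pmin(1, pmax(-1, cos_psi))
  psi <- acos(cos_psi)
  sun_km <- 1.496e8
  i <- atan2(sun_km * sin(psi), mo$dist_km - sun_km * cos(psi))
  (1 + cos(i)) / 2
}

# uniform random instants in [2010, 2030), reproducible under the suite seed
random_instants <- function(n, seed = 42) {
  set.seed(seed)
  t0 <- as.numeric(as.POSIXct("2010-01-01", tz = "UTC"))
  t1 <- as.numeric(as.POSIXct("2030-01-01", tz = "UTC"))
  as.POSIXct(stats::runif(n, t0, t1), origin = "1970-01-01", tz = "UTC")
}
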