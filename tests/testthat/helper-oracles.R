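# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Brute-force twilight finder: scan solar elevation on a 1-minute grid and
# interpolate the crossings of the elevation angle `a0`.
oracle_twilights <- function(date, lat, lon, a0) {
  t0 <- as.POSIXct(paste(as.Date(date), "00:00:00"), tz = "UTC")
  tt <- seq(t0, t0 + 86400, by = 60)
  el <- ternlight::solar_elevation(tt, lat, lon)
  idx <- which(diff(el > a0) != 0)
  if (!length(idx)) return(NULL)
  frac <- (a0 - el[idx]) / (el[idx + 1] - el[idx])
  data.frame(
    time = tt[idx] + frac * 60,
    kind = ifelse(el[idx + 1] > a0, "sunrise", "sunset")
  )
}

# Day length (hours above elevation a0) from the same 1-minute scan.
oracle_day_length <- function(date, lat, lon, a0) {
  ev <- oracle_twilights(date, lat, lon, a0)
  if (is.null(ev) || nrow(ev) < 2) return(NA_real_)
  sr <- ev$time[ev$kind == "sunrise"][1]
  ss <- ev$time[ev$kind == "sunset" & ev$time > sr][1]
  as.numeric(difftime(ss, sr, units = "hours"))
}

# Piecewise constant-bearing walk: numerically integrate the rhumb-line arc
# length in latitude steps of `step` degrees (1 deg latitude = 111.12 km).
oracle_loxodrome <- function(lat1, lon1, lat2, lon2, step = 0.01) {
  merc <- function(phi) 180 / pi * log(tan(pi / 4 + phi * pi / 360))
  if (abs(lat2 - lat1) < 1e-9) {
    return(abs(lon2 - lon1) * 111.12 * cos(lat1 * pi / 180))
  }
  theta <- atan2(lon2 - lon1, merc(lat2) - merc(lat1))
  phis <- seq(lat1, lat2, length.out = ceiling(abs(lat2 - lat1) / step) + 1)
  dphi <- diff(phis)
  dlam <- diff(merc(phis)) * tan(theta)
  mid <- (phis[-1] + phis[-length(phis)]) / 2
  sum(sqrt(dphi^2 + (dlam * cos(mid * pi / 180))^2)) * 111.12
}

# Exhaustive Fisher exact probability for a 2x2 table with fixed margins,
# using binomial coefficients directly ("prob" two-tailed rule).
oracle_fisher_p <- function(a, b, c_, d) {
  n1 <- a + b
  n2 <- c_ + d
  m <- a + c_
  amin <- max(0, m - n2)
  amax <- min(m, n1)
  ptab <- function(x) {
    choose(n1, x) * choose(n2, m - x) / choose(n1 + n2, m)
  }
  pobs <- ptab(a)
  ps <- vapply(amin:amax, ptab, numeric(1))
  sum(ps[ps <= pobs * (1 + 1e-7)])
}

# simple linear-interpolation oracle for trajectory positions
oracle_linear_lon <- function(t, t0, t1, lon0, lon1) {
  lon0 + (lon1 - lon0) * as.numeric(difftime(t, t0, units = "secs")) /
    as.numeric(difftime(t1, t0, units = "secs"))
}
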