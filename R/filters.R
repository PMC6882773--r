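# Elliptic IIR design in zero-pole-gain form, cascaded second-order
# sections, and zero-phase (forward-backward) filtering.  High filter
# orders (up to 26 poles for the band-stop) are numerically hopeless as a
# single transfer function, so the design never leaves zpk/sos form.

# Digital elliptic filter as sos: analog Cauer lowpass prototype
# (signal's ncauer), frequency transform (sftrans), bilinear transform.
# type: "low" | "high" | "stop" | "pass"; w in Hz (length 2 for stop/pass).
ellip_sos <- function(n, rp, rs, w, type, fs) {
  ncauer <- getFromNamespace("ncauer", "signal")
  proto <- ncauer(rp, rs, n)
  warp <- function(f) 2 * fs * tan(pi * f / fs)   # bilinear prewarping
  zpg <- signal::Zpg(zero = proto$zero, pole = proto$pole, gain = proto$gain)
  s <- switch(type,
    low  = signal::sftrans(zpg, W = warp(w), stop = FALSE),
    high = signal::sftrans(zpg, W = warp(w), stop = TRUE),
    pass = signal::sftrans(zpg, W = warp(w), stop = FALSE),
    stop = signal::sftrans(zpg, W = warp(w), stop = TRUE),
    stop("unknown filter type: ", type))
  d <- signal::bilinear(s, T = 1 / fs)
  zpk2sos(d$zero, d$pole, d$gain)
}

# Pair digital zeros/poles into biquad sections.  Poles are processed from
# nearest the unit circle outward, each conjugate pair (or real pair/
# singleton) matched with the closest remaining zeros.  Returns a matrix
# with columns b0 b1 b2 a0 a1 a2, gain folded into the first section.
zpk2sos <- function(z, p, k) {
  pair_up <- function(r) {
    r <- r[order(-abs(Im(r)), Re(r))]
    used <- rep(FALSE, length(r))
    out <- list()
    for (i in seq_along(r)) {
      if (used[i]) next
      used[i] <- TRUE
      if (abs(Im(r[i])) > 1e-8) {
        j <- which(!used & abs(r - Conj(r[i])) < 1e-6)[1]
        if (is.na(j)) stop("unpaired complex root in filter design")
        used[j] <- TRUE
        out[[length(out) + 1]] <- c(r[i], r[j])
      } else {
        j <- which(!used & abs(Im(r)) <= 1e-8)[1]
        if (!is.na(j)) { used[j] <- TRUE; out[[length(out) + 1]] <- c(r[i], r[j]) }
        else out[[length(out) + 1]] <- r[i]
      }
    }
    out
  }
  # order pole groups by closeness to the unit circle (most selective first)
  pg <- pair_up(p)
  pg <- pg[order(-vapply(pg, function(g) max(abs(g)), 0))]
  zg_pool <- z
  sections <- vector("list", length(pg))
  for (i in seq_along(pg)) {
    poles <- pg[[i]]
    want <- length(poles)
    zeros <- complex(0)
    for (rep in seq_len(want)) {
      if (!length(zg_pool)) break
      j <- which.min(abs(zg_pool - poles[1]))
      zeros <- c(zeros, zg_pool[j])
      # remove the zero and, if complex, its conjugate partner
      zj <- zg_pool[j]; zg_pool <- zg_pool[-j]
      if (abs(Im(zj)) > 1e-8) {
        jc <- which.min(abs(zg_pool - Conj(zj)))
        if (length(jc) && abs(zg_pool[jc] - Conj(zj)) < 1e-6) {
          zeros <- c(zeros, zg_pool[jc]); zg_pool <- zg_pool[-jc]
        }
      }
      if (length(zeros) >= want) break
    }
    b <- Re(poly_from_roots(zeros))
    a <- Re(poly_from_roots(poles))
    sections[[i]] <- c(b, rep(0, 3 - length(b)), a, rep(0, 3 - length(a)))
  }
  sos <- do.call(rbind, sections)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  sos[1, 1:3] <- sos[1, 1:3] * Re(k)
  sos
}

# Monic polynomial coefficients from roots (highest order first).
poly_from_roots <- function(r) {
  cf <- 1
  for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
  cf
}

# Direct-form II transposed single-section IIR filter.
.sosfilter1 <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  signal::filter(signal::Arma(b = b, a = a), x)
}

#' Zero-phase filtering through a cascade of second-order sections
#'
#' Applies each biquad forward and backward (filtfilt), with odd-reflection
#' edge padding to suppress startup transients.  The cascade is therefore
#' zero-phase and its amplitude response is the squared magnitude of the
#' designed filter.
#'
#' @param sos matrix with columns `b0 b1 b2 a0 a1 a2`, one row per section.
#' @param x numeric vector.
#' @return filtered vector, same length as `x`.
#' @export
sosfiltfilt <- function(sos, x) {
  n <- length(x)
  npad <- min(n - 1, 3L * 6L * nrow(sos))
  if (npad > 0) {
    head_pad <- 2 * x[1] - x[(npad + 1):2]
    tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
    xe <- c(head_pad, x, tail_pad)
  } else xe <- x
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]; a <- sos[i, 4:6]
    xe <- .sosfilter1(b, a, xe)
    xe <- rev(.sosfilter1(b, a, rev(xe)))
  }
  as.numeric(xe[(npad + 1):(npad + n)])
}

# Frequency response of an sos cascade at frequencies f (Hz).
sos_freq_response <- function(sos, f, fs) {
  w <- exp(-1i * 2 * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(sos))) {
    num <- sos[i, 1] + sos[i, 2] * w + sos[i, 3] * w^2
    den <- sos[i, 4] + sos[i, 5] * w + sos[i, 6] * w^2
    h <- h * num / den
  }
  h
}

# The high-gamma cascade: high-pass 70 Hz (order 13), low-pass 170 Hz
# (order 14), band-stop 118-122 Hz (order 13) for the first line-noise
# harmonic; elliptic, 0.5 dB passband ripple, 50 dB stopband attenuation.
.hg_cascade <- function(fs = 600, rp = 0.5, rs = 50) {
  list(hp   = ellip_sos(13, rp, rs, 70, "high", fs),
       lp   = ellip_sos(14, rp, rs, 170, "low", fs),
       stop = ellip_sos(13, rp, rs, c(118, 122), "stop", fs))
}
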