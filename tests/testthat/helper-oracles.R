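# Independent oracles and fixture builders shared across the suite.
# Each oracle re-derives a quantity from its definition by a route that is
# deliberately different from the package implementation.

# Rotated-coordinate route to SD1/SD2: rotate the cloud by 45 degrees and
# take plain standard deviations of the rotated coordinates.
rotation_oracle <- function(x, y) {
  u <- (x - y) / sqrt(2)
  w <- (x + y) / sqrt(2)
  list(sd1 = stats::sd(u), sd2 = stats::sd(w))
}

# Literal replay of the relative-threshold artifact rule: forward pass,
# first valid sample seeds the reference, reject iff |x - r| / r > thr.
filter_replay_oracle <- function(values, valid, thr) {
  mask <- valid
  idx <- which(valid)
  r <- values[idx[1]]
  for (i in idx[-1]) {
    if (abs(values[i] - r) / r > thr) mask[i] <- FALSE else r <- values[i]
  }
  mask
}

# Exact two-sided rank-sum p-value by full enumeration of all
# choose(na + nb, na) group labelings, using midranks. For a tie-free
# pooled sample the null distribution of U is symmetric, so the
# symmetric-tail probability equals the doubled-minimum-tail convention.
ranksum_enumeration_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  rk <- rank(pooled)
  u_of <- function(ix) sum(rk[ix]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  m <- na * (n - na) / 2
  labelings <- utils::combn(n, na)
  u_all <- apply(labelings, 2, u_of)
  mean(abs(u_all - m) >= abs(u_obs - m) - 1e-9)
}

# Minimal MIT-format annotation writer, built from the format definition:
# 16-bit little-endian words, top 6 bits the type code, low 10 bits the
# time increment in samples; a zero word terminates the stream. Increments
# over 1023 samples are encoded with a SKIP (59) pseudo-annotation whose
# following four bytes hold the increment, high 16-bit word first.
write_wfdb_fixture <- function(path, samples, codes) {
  stopifnot(length(samples) == length(codes), !is.unsorted(samples))
  con <- file(path, "wb")
  on.exit(close(con))
  put_word <- function(w) {
    writeBin(as.raw(c(w %% 256, w %/% 256)), con)
  }
  prev <- 0
  for (i in seq_along(samples)) {
    inc <- samples[i] - prev
    prev <- samples[i]
    if (inc > 1023) {
      put_word(59 * 1024)
      put_word(inc %/% 65536)
      put_word(inc %% 65536)
      inc <- 0
    }
    put_word(codes[i] * 1024 + inc)
  }
  put_word(0)
  invisible(path)
}

# Random all-valid heart-rate series for property tests.
random_series <- function(n, seed, base = 70, sd = 8) {
  withr::with_seed(seed, {
    hr_series(pmax(20, base + stats::rnorm(n, sd = sd)))
  })
}

# Push an entire series through a fresh streaming engine, returning the
# accumulated emissions.
stream_replay <- function(series, spec, filter = NULL) {
  eng <- stream_engine(spec, filter)
  t <- hr_times(series)
  for (i in seq_along(series$values)) stream_push(eng, t[i], series$values[i])
  stream_emissions(eng)
}
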