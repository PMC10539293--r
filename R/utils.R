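#' @keywords internal
#' Run an expression with a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic child-seed derivation (kept below 2^31 - 1; exact in doubles).
derive_seed <- function(master, ...) {
  ks <- c(...)
  s <- as.numeric(master) %% 2147483647
  for (k in ks) s <- (s * 69069 + as.numeric(k) + 1) %% 2147483647
  as.integer(s)
}

prime_factors <- function(n) {
  n <- as.integer(n)
  out <- integer(0)
  d <- 2L
  while (d * d <= n) {
    while (n %% d == 0L) { out <- c(out, d); n <- n %/% d }
    d <- d + 1L
  }
  if (n > 1L) out <- c(out, n)
  out
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# DFT of the columns of a (possibly complex) matrix. stats::mvfft uses
# Singleton's mixed-radix algorithm, which degrades to O(n^2) when n has a
# large prime factor; for those lengths fall back to the Bluestein chirp-z
# identity evaluated with power-of-two FFTs.
fft_cols <- function(x, inverse = FALSE) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n <= 1024 || max(prime_factors(n)) <= 127) {
    return(mvfft(x, inverse = inverse))
  }
  bluestein_mv(x, inverse = inverse)
}

bluestein_mv <- function(x, inverse = FALSE) {
  n <- nrow(x)
  if (inverse) {
    return(Conj(bluestein_mv(Conj(x), inverse = FALSE)))
  }
  m <- next_pow2(2L * n - 1L)
  idx <- 0:(n - 1)
  # exp(-i*pi*k^2/n) with k^2 mod 2n computed exactly in doubles
  ksq <- (idx * idx) %% (2 * n)
  w <- exp(-1i * pi * ksq / n)
  a <- matrix(0i, m, ncol(x))
  a[1:n, ] <- x * w
  b <- complex(real = rep(0, m))
  b[1:n] <- Conj(w)
  if (n > 1) b[m - (1:(n - 1)) + 1] <- Conj(w[2:n])
  fb <- fft(b)
  fa <- mvfft(a)
  conv <- mvfft(fa * fb, inverse = TRUE) / m
  conv[1:n, , drop = FALSE] * w
}

# Real-input convenience: returns complex DFT of each column.
fft_real_cols <- function(x) fft_cols(x + 0i, inverse = FALSE)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
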