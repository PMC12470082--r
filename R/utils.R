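.safe_div <- function(a, b) if (b == 0) NA_real_ else a / b

# maximal run length of `value` covering each element of logical vector
.run_lengths_at <- function(flag) {
  r <- rle(flag)
  rep(r$lengths, r$lengths)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.assert <- function(ok, ...) if (!ok) .stopf(...)

# cheap byte checksum for run manifests (hex of a 32-bit running sum)
.checksum <- function(txt) {
  b <- utf8ToInt(paste(txt, collapse = "\n"))
  s <- 0
  for (x in b) s <- (s * 31 + x) %% 2147483647
  sprintf("%08x", as.integer(s))
}
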