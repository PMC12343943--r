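# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Vectorized bilinear sampling of a pixel matrix at fractional 0-based
# (r, c) positions. Positions outside the grid return NA.
bilinear_sample <- function(pixels, r, c) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  ok <- r0 >= 0 & c0 >= 0 & r0 <= nr - 2 + (fr == 0) & c0 <= nc - 2 + (fc == 0)
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  out <- rep(NA_real_, length(r))
  i <- which(ok)
  if (length(i)) {
    p <- function(rr, cc) pixels[cbind(rr + 1L, cc + 1L)]
    out[i] <- (1 - fr[i]) * (1 - fc[i]) * p(r0[i], c0[i]) +
      (1 - fr[i]) * fc[i] * p(r0[i], c1[i]) +
      fr[i] * (1 - fc[i]) * p(r1[i], c0[i]) +
      fr[i] * fc[i] * p(r1[i], c1[i])
  }
  out
}
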