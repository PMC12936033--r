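# Single-level undecimated 3-D Haar wavelet decomposition.
#
# Along each axis the low-pass (L) filter is (x[i] + x[i+1]) / sqrt(2) and
# the high-pass (H) filter is (x[i] - x[i+1]) / sqrt(2), with a replicated
# (symmetric) boundary at the far edge. No downsampling, so every sub-band
# stays on the original grid and the region mask applies unchanged. Band
# names give the filter per axis in order (x, y, z): e.g. "HHL" = high-pass
# along x and y, low-pass along z.

haar_axis <- function(a, axis, type = c("L", "H")) {
  type <- match.arg(type)
  d <- dim(a)
  idx <- lapply(d, seq_len)
  nxt <- idx
  nxt[[axis]] <- pmin(idx[[axis]] + 1L, d[axis])   # replicate last plane
  shifted <- a[nxt[[1]], nxt[[2]], nxt[[3]], drop = FALSE]
  if (type == "L") (a + shifted) / sqrt(2) else (a - shifted) / sqrt(2)
}

#' Wavelet sub-bands of a 3-D image
#'
#' @param values 3-D numeric array.
#' @return named list of 8 arrays (`LLL` ... `HHH`), same dimensions as the
#'   input.
#' @export
wavelet_bands <- function(values) {
  out <- list()
  for (band in wavelet_band_names()) {
    f <- strsplit(band, "")[[1]]
    a <- values
    for (ax in 1:3) a <- haar_axis(a, ax, f[ax])
    out[[band]] <- a
  }
  out
}
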