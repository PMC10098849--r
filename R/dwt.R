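# Discrete wavelet transform core: orthogonal Daubechies filter banks,
# half-point symmetric boundary extension, multi-level analysis/synthesis.
# Coefficient layout per level j: length floor((n_j + F - 1) / 2) where n_j
# is the input length at that level and F the filter length; the per-level
# input lengths are retained so the inverse reproduces the signal exactly.

# Tabulated low-pass decomposition filters (orthogonal families only; the
# other three filters of each bank follow from the QMF relations).
.db_dec_lo <- list(
  db5 = c(0.0033357252854737712, -0.012580751999081999, -0.006241490212798274,
          0.07757149384004572, -0.032244869584638375, -0.24229488706638203,
          0.13842814590132074, 0.7243085284377729, 0.6038292697971896,
          0.16010239797419293)
)

#' Quadrature-mirror filter bank for an orthogonal Daubechies wavelet
#'
#' @param wavelet Wavelet identifier; `"db5"` (Daubechies, 5 vanishing
#'   moments) is the basis used throughout the package.
#' @return List with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` filter vectors.
#' @keywords internal
wavelet_filters <- function(wavelet = "db5") {
  dec_lo <- .db_dec_lo[[as.character(wavelet)[1]]]
  if (is.null(dec_lo)) {
    stop("unknown wavelet identifier: '", wavelet, "'", call. = FALSE)
  }
  F <- length(dec_lo)
  dec_hi <- rev(dec_lo) * rep_len(c(-1, 1), F)
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi))
}

# Half-point symmetric reflection indices: m extra samples each side,
# valid for any m (the reflection tile is 2n-periodic).
.reflect_idx <- function(n, m) {
  pos <- seq.int(-m, n + m - 1L) %% (2L * n)
  ifelse(pos < n, pos + 1L, 2L * n - pos)
}

.conv_full <- function(a, b) {
  stats::convolve(a, rev(b), type = "open")
}

# One analysis step: x -> (approx, detail).
.dwt_step <- function(x, filt) {
  F <- length(filt$dec_lo)
  n <- length(x)
  ext <- x[.reflect_idx(n, F - 1L)]
  take <- seq.int(F + 1L, by = 2L, length.out = (n + F - 1L) %/% 2L)
  list(approx = .conv_full(ext, filt$dec_lo)[take],
       detail = .conv_full(ext, filt$dec_hi)[take])
}

# One synthesis step; out_len is the length of the signal that produced the
# coefficients (the raw inverse yields 2L - F + 2 >= out_len samples and
# the boundary surplus is dropped from the tail).
.idwt_step <- function(ca, cd, filt, out_len) {
  F <- length(filt$rec_lo)
  L <- length(ca)
  stopifnot(length(cd) == L)
  up <- function(cc) {
    u <- numeric(2L * L)
    u[seq.int(1L, by = 2L, length.out = L)] <- cc
    u
  }
  full <- .conv_full(up(ca), filt$rec_lo) + .conv_full(up(cd), filt$rec_hi)
  full[seq.int(F - 1L, length.out = out_len)]
}

# Multi-level analysis: detail coefficients D1..Dlevels plus the final
# approximation, with per-level input lengths for exact inversion.
.wavedec <- function(x, wavelet = "db5", levels = 5L) {
  filt <- wavelet_filters(wavelet)
  details <- vector("list", levels)
  lens <- integer(levels)
  cur <- as.numeric(x)
  for (j in seq_len(levels)) {
    lens[j] <- length(cur)
    st <- .dwt_step(cur, filt)
    details[[j]] <- st$detail
    cur <- st$approx
  }
  list(details = details, approx = cur, lens = lens,
       wavelet = wavelet, levels = as.integer(levels))
}

.waverec <- function(dec) {
  filt <- wavelet_filters(dec$wavelet)
  cur <- dec$approx
  for (j in rev(seq_len(dec$levels))) {
    cur <- .idwt_step(cur, dec$details[[j]], filt, dec$lens[j])
  }
  cur
}
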