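# Internal helpers shared across modules. Nothing here is exported.

# Planck * speed-of-light, fixed so wavelength computations are deterministic.
# Units: keV * nm.
HC_KEV_NM <- 1.23984193

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ptychor <- function(..., class = "ptychor_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_ptychor(name, " must be a single positive finite number",
                 class = "ptychor_invalid_input")
  invisible(x)
}

# Quadrant swap moving the zero-frequency sample to/from the array centre.
# For even dimensions fftshift and ifftshift coincide; both are kept for
# clarity and for odd-sized scratch arrays.
fftshift2 <- function(x) {
  d <- dim(x)
  i <- c(seq.int(floor(d[1] / 2) + 1L, d[1]), seq_len(floor(d[1] / 2)))
  j <- c(seq.int(floor(d[2] / 2) + 1L, d[2]), seq_len(floor(d[2] / 2)))
  x[i, j, drop = FALSE]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  i <- c(seq.int(ceiling(d[1] / 2) + 1L, d[1]), seq_len(ceiling(d[1] / 2)))
  j <- c(seq.int(ceiling(d[2] / 2) + 1L, d[2]), seq_len(ceiling(d[2] / 2)))
  x[i, j, drop = FALSE]
}

# Unitary, centred 2-D DFT pair. Parseval holds exactly up to float rounding,
# so the modulus projector needs no rescaling.
fft2_centered <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

ifft2_centered <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

# DFT sample frequencies in cycles per unit, matching the unshifted fft layout.
fft_freqs <- function(n, spacing) {
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  k / (n * spacing)
}

# 1-based row/col index ranges of the probe window anchored at a 0-based
# top-left offset.
window_index <- function(offset_rc, m) {
  list(rows = seq.int(offset_rc[1] + 1L, offset_rc[1] + m),
       cols = seq.int(offset_rc[2] + 1L, offset_rc[2] + m))
}

check_windows_inside <- function(offsets, m, canvas_dim) {
  bad <- which(offsets[, 1] < 0 | offsets[, 2] < 0 |
                 offsets[, 1] + m > canvas_dim[1] |
                 offsets[, 2] + m > canvas_dim[2])
  if (length(bad))
    stop_ptychor("object canvas too small: probe window(s) outside canvas at ",
                 "scan index(es) ", paste(bad, collapse = ", "),
                 class = "ptychor_canvas_error")
  invisible(TRUE)
}

# Probe modes are kept as an M x M x K complex array throughout.
as_mode_array <- function(modes) {
  if (is.matrix(modes)) modes <- array(modes, dim = c(dim(modes), 1L))
  if (length(dim(modes)) != 3L)
    stop_ptychor("probe modes must be an M x M matrix or M x M x K array")
  modes
}

mode_powers <- function(modes) {
  apply(modes, 3L, function(m) sum(Mod(m)^2))
}

complex_matrix <- function(n, m, data = 0 + 0i) {
  matrix(data, nrow = n, ncol = m)
}

# RMS difference between two complex arrays, used in tests and diagnostics.
rms_diff <- function(a, b) sqrt(mean(Mod(a - b)^2))
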