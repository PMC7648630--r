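# Flat binary morphology on 0/1 integer matrices.
#
# The structuring element is a Euclidean disk: offsets (dy, dx) with
# dy^2 + dx^2 <= radius^2. Borders are handled by padding with an explicit
# phase value so the caller controls whether the outside counts as airspace
# or wall.

pad_matrix <- function(mat, r, value) {
  out <- matrix(as.integer(value), nrow(mat) + 2L * r, ncol(mat) + 2L * r)
  out[(r + 1L):(r + nrow(mat)), (r + 1L):(r + ncol(mat))] <- mat
  out
}

shift_view <- function(padded, r, dy, dx, h, w) {
  padded[(r + 1L + dy):(r + h + dy), (r + 1L + dx):(r + w + dx), drop = FALSE]
}

# Dilation: out[p] = max over disk offsets of in[p + o].
dilate_disk <- function(mat, radius, pad_value) {
  r <- as.integer(radius)
  if (r == 0L) return(mat)
  off <- disk_offsets(r)
  padded <- pad_matrix(mat, r, pad_value)
  h <- nrow(mat); w <- ncol(mat)
  out <- shift_view(padded, r, off$dy[1L], off$dx[1L], h, w)
  for (k in seq_len(nrow(off))[-1L]) {
    out <- pmax(out, shift_view(padded, r, off$dy[k], off$dx[k], h, w))
  }
  storage.mode(out) <- "integer"
  out
}

# Erosion: out[p] = min over disk offsets of in[p + o].
erode_disk <- function(mat, radius, pad_value) {
  r <- as.integer(radius)
  if (r == 0L) return(mat)
  off <- disk_offsets(r)
  padded <- pad_matrix(mat, r, pad_value)
  h <- nrow(mat); w <- ncol(mat)
  out <- shift_view(padded, r, off$dy[1L], off$dx[1L], h, w)
  for (k in seq_len(nrow(off))[-1L]) {
    out <- pmin(out, shift_view(padded, r, off$dy[k], off$dx[k], h, w))
  }
  storage.mode(out) <- "integer"
  out
}
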