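# Internal helpers shared across modules.

# Classed abort so callers can condition on failure modes.
stop_cl <- function(class, msg, ...) {
  rlang::abort(message = msg, class = c(paste0("centistress_", class), "centistress_error"), ...)
}

warn_cl <- function(class, msg) {
  rlang::warn(message = msg, class = c(paste0("centistress_", class), "centistress_warning"))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Deterministic 31-bit seed for a subject derived from the root seed and the
# subject id.  Polynomial rolling hash; all arithmetic stays below 2^53 so the
# result is exact in doubles on every platform.
child_seed <- function(root_seed, id) {
  p <- 2147483647
  h <- 0
  for (code in utf8ToInt(as.character(id))) h <- (h * 31 + code) %% p
  as.integer((h * 131 + (root_seed %% p)) %% p)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed_cl <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Voxel-index -> world (mm) affine for a centred regular grid.
grid_affine <- function(dims, voxel_size) {
  a <- diag(4)
  a[1, 1] <- a[2, 2] <- a[3, 3] <- voxel_size
  a[1:3, 4] <- -(dims + 1) / 2 * voxel_size
  a
}

# Rigid-body transform in world coordinates (rotations in radians, XYZ order).
make_rigid <- function(angles = c(0, 0, 0), translation = c(0, 0, 0)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  t <- diag(4)
  t[1:3, 1:3] <- rz %*% ry %*% rx
  t[1:3, 4] <- translation
  t
}

# Voxel-centre index vectors (I, J, K) for an array of dimensions `d`,
# in column-major order matching as.vector(array).
grid_index_vectors <- function(d) {
  list(
    i = rep.int(seq_len(d[1]), d[2] * d[3]),
    j = rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
    k = rep(seq_len(d[3]), each = d[1] * d[2])
  )
}
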