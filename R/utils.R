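# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Keeps every stochastic component of the
# package reproducible without touching global RNG state.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Voxel coordinates (1-based, x/y/z columns) of TRUE entries of a 3D array.
voxelCoords <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  colnames(w) <- c("x", "y", "z")
  w
}

# Gaussian blur of a 2D/3D array via separable convolution along each axis.
# Kernel truncated at 3 sigma. Used by the phantom texture generator.
gaussBlur <- function(a, sigma) {
  if (sigma <= 0) return(a)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  convAxis <- function(x, axis) {
    d <- dim(x)
    perm <- c(axis, setdiff(seq_along(d), axis))
    m <- aperm(x, perm)
    dm <- dim(m)
    m <- matrix(m, nrow = dm[1])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in -half:half) {
      rows <- pmin(pmax(seq_len(n) + o, 1L), n)  # replicate edges
      out <- out + k[o + half + 1L] * m[rows, , drop = FALSE]
    }
    aperm(array(out, dm), order(perm))
  }
  for (ax in seq_along(dim(a))) a <- convAxis(a, ax)
  a
}

# Stop unless two gridded objects share shape (and spacing when present).
checkSameGrid <- function(a, b) {
  da <- dim(voxelData(a)); db <- dim(voxelData(b))
  if (!identical(da, db))
    stop("grid mismatch: shapes ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  invisible(TRUE)
}
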