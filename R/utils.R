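# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministically derive `n` independent sub-seeds from one master seed.
# Sub-seeds stay below 2^31 (R integers are 32-bit).
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

deg2rad <- function(x) x * pi / 180

# Membership of CCW angles (degrees) in a sector centered at `center` with
# total width `span`. Inclusive at both edges; empty when span <= 0.
in_sector <- function(theta, center, span) {
  if (span <= 0) return(rep(FALSE, length(theta)))
  if (span >= 360) return(rep(TRUE, length(theta)))
  d <- (theta - center + 180) %% 360 - 180
  abs(d) <= span / 2
}

circ_mean_deg <- function(theta) {
  (atan2(mean(sin(deg2rad(theta))), mean(cos(deg2rad(theta)))) * 180 / pi) %% 360
}

# Pull the intensity array out of a sim_image, or pass arrays through.
as_intensity <- function(image) {
  if (inherits(image, "sim_image")) image$intensity else image
}

# Coerce a mask to logical and check it matches the image dimensions.
check_mask <- function(mask, dims, arg = "mask") {
  m <- as_intensity(mask)
  if (!identical(dim(m), as.integer(dims)) && !identical(dim(m), dims)) {
    stop(sprintf("`%s` dimensions (%s) do not match image dimensions (%s)",
                 arg, paste(dim(m), collapse = "x"), paste(dims, collapse = "x")),
         call. = FALSE)
  }
  storage.mode(m) <- "logical"
  m
}
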