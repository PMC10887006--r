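#' @keywords internal
#' @useDynLib mffcnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never perturbs user-level RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Combine a base seed with a stream index into a valid 32-bit seed.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483647)
}

stop_mffc <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

tumor_classes <- function() c("GBM", "SBM", "PCNSL")

# Concatenate 3D arrays (H x W x C) along the channel axis.
cat_channels <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !is.array(xs[[1]])) xs <- xs[[1]]
  d <- dim(xs[[1]])
  array(unlist(xs, use.names = FALSE),
        dim = c(d[1], d[2], sum(vapply(xs, function(x) dim(x)[3], 0))))
}
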