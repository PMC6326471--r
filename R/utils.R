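#' Coerce frames to a 3-D stack array
#'
#' Accepts a single matrix, a list of same-shape matrices, or a 3-D array
#' (frames along the third dimension) and returns the 3-D array form used
#' throughout the package.
#'
#' @param frames matrix, list of matrices, or 3-D array.
#' @return Numeric array of dimension `c(nrow, ncol, n_frames)`.
#' @export
as_stack <- function(frames) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) stop("all frames must share one shape")
    return(array(unlist(frames, use.names = FALSE),
                 dim = c(dims[[1]], length(frames))))
  }
  if (is.matrix(frames)) return(array(frames, dim = c(dim(frames), 1L)))
  if (is.array(frames) && length(dim(frames)) == 3) return(frames)
  stop("frames must be a matrix, a list of matrices, or a 3-D array")
}

stack_to_list <- function(stack) {
  stack <- as_stack(stack)
  lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
}

# upsample a matrix by an integer factor with nearest-neighbor replication
upsample_nearest <- function(mat, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stop("upsample factor must be >= 1")
  if (factor == 1) return(mat)
  mat[rep(seq_len(nrow(mat)), each = factor),
      rep(seq_len(ncol(mat)), each = factor)]
}

# derive a stream of sub-seeds from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state))
    assign(".Random.seed", state, envir = globalenv())
}
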