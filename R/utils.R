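#' @keywords internal
#' @import stats
#' @import utils
"_PACKAGE"

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic entry points funnel
# through this so results are reproducible from a single integer.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_shape <- function(...) stop(structure(
  class = c("lesionseg_shape_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))))

stop_config <- function(...) stop(structure(
  class = c("lesionseg_config_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))))

stop_io <- function(...) stop(structure(
  class = c("lesionseg_io_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))))

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x > 0 && x == round(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
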