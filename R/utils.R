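#' @keywords internal
"_PACKAGE"

# Deterministic 32-bit FNV-1a hash of a character label, reduced to a
# positive int. Used to derive named random substreams so that adding a
# context/replicate/batch never perturbs draws of existing ones.
.label_hash <- function(label) {
  bytes <- utf8ToInt(enc2utf8(label))
  h <- 17
  for (b in bytes) h <- (h * 1299709 + b) %% 2147483647
  h
}

#' Derive a deterministic substream seed from a root seed and labels
#'
#' Combines a root seed with one or more character labels (for example
#' `"FA-free"`, `"bio2"`, `"batch1"`) into a reproducible child seed.
#' Substreams for distinct labels are independent of how many other labels
#' are in use, so enlarging a design never changes existing draws.
#'
#' @param seed Integer root seed.
#' @param ... Character labels naming the substream.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "FA-free", "bio1")
substream_seed <- function(seed, ...) {
  labels <- as.character(unlist(list(...)))
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- as.numeric(seed) %% 2147483647
  for (lab in labels) {
    h <- (h * 31 + .label_hash(lab)) %% 2147483647
  }
  as.integer(h)
}

# Evaluate with a temporary RNG state; restores the caller's state.
.with_seed <- function(seed, expr) {
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
  })
  set.seed(as.integer(seed))
  expr
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
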