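## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

.is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

## coerce a mask argument (logical/0-1 matrix or structure_mask) to a logical matrix
.as_mask_grid <- function(mask) {
  if (inherits(mask, "structure_mask")) mask <- mask$grid
  .assert(is.matrix(mask), "mask must be a matrix or structure_mask")
  if (!is.logical(mask)) {
    .assert(all(mask %in% c(0, 1)), "mask must be binary")
    mask <- mask > 0
  }
  mask
}

## deterministic fan-out of a stage seed into sub-seeds (kept < 2^31)
.sub_seed <- function(seed, k) (as.integer(seed) + 1000L * as.integer(k)) %% 2147483629L

## population standard deviation (divide by n, not n - 1)
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

## cosine similarity of two vectors; NA when either has zero norm
.cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}
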