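#' Normalize chromosome names to the internal "X" convention
#'
#' Maps common aliases of the human X chromosome ("chrX", "x", "23",
#' "NC_000023*") onto the single internal name `"X"`. Other names are
#' returned unchanged (callers decide whether to skip them).
#'
#' @param x character vector of chromosome names.
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_chrom(c("chrX", "X", "23", "chr1"))
normalize_chrom <- function(x) {
  x <- as.character(x)
  out <- sub("^chr", "", x, ignore.case = TRUE)
  out[toupper(out) == "X" | out == "23" | grepl("^NC_000023", out)] <- "X"
  out
}

## stop() with a classed condition so callers can distinguish eligibility
## failures (tier skipped) from genuine errors
stop_classed <- function(class, msg) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## run expr with a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## deterministic per-index sub-seed kept inside 32-bit integer range
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483647)
}
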