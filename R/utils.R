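## small shared helpers

#' Round half away from zero
#'
#' Plain decimal rounding (0.5 always rounds up in magnitude), as used by the
#' report layer for index and percentage values. Base `round()` rounds half to
#' even, which is wrong for comparing against conventionally rounded published
#' numbers.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# collapse internal whitespace, trim ends
squish <- function(x) {
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x))
}

# taxon label <-> tree tip label (spaces are not Newick-safe)
label_to_tip <- function(x) gsub(" ", "_", x)
tip_to_label <- function(x) gsub("_", " ", x)

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# derive a stream of sub-seeds from one seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
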